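# Interruptible solves at two decision costs, shared across blocks
.thr_p1 <- coarse_params(c_d = 0.1)
.thr_p2 <- coarse_params(c_d = 0.2)
.thr_s1 <- value_iteration(.thr_p1, interruptible = TRUE)
.thr_s2 <- value_iteration(.thr_p2, interruptible = TRUE)
.thr_tab <- rbind(
  extract_thresholds(.thr_s1, "feed", "patch"),
  extract_thresholds(.thr_s1, "assess", "patch"),
  extract_thresholds(.thr_s1, "assess", "refuge"),
  extract_thresholds(.thr_s2, "feed", "patch"),
  extract_thresholds(.thr_s2, "assess", "patch"),
  extract_thresholds(.thr_s2, "assess", "refuge"))

test_that("feed has an upper boundary rising with habitat belief;
           assess has both boundaries rising", {
  feed <- .thr_tab[.thr_tab$activity == "feed", ]
  expect_true(all(feed$boundary == "upper"))
  for (cd in unique(feed$c_d)) {
    th <- feed$theta[feed$c_d == cd][order(feed$beta_G[feed$c_d == cd])]
    expect_true(all(diff(th) >= 0))
    expect_gt(th[length(th)], th[1])
  }
  ap <- .thr_tab[.thr_tab$activity == "assess" & .thr_tab$location == "patch", ]
  expect_setequal(unique(ap$boundary), c("lower", "upper"))
  for (cd in unique(ap$c_d)) for (bnd in c("lower", "upper")) {
    sub <- ap[ap$c_d == cd & ap$boundary == bnd, ]
    th <- sub$theta[order(sub$beta_G)]
    expect_true(all(diff(th) >= 0))
  }
  # lower <= upper wherever both exist
  for (bg in unique(ap$beta_G)) for (cd in unique(ap$c_d)) {
    sub <- ap[ap$beta_G == bg & ap$c_d == cd, ]
    expect_lte(sub$theta[sub$boundary == "lower"],
               sub$theta[sub$boundary == "upper"])
  }
  # activities without interruption structure are rejected
  expect_error(extract_thresholds(.thr_s1, "rest", "refuge"))
  sol_n <- value_iteration(tiny_params())
  expect_error(extract_thresholds(sol_n, "feed", "patch"), "interruptible")
})

test_that("an activity dominated everywhere reports an empty initiation set", {
  p <- coarse_params(c_d = 0.05, r_feed_rich = 0, r_feed_poor = 0)
  si <- value_iteration(p, interruptible = TRUE)
  expect_equal(sum(si$policy$patch$action == "feed"), 0)
  tab <- extract_thresholds(si, "feed", "patch")
  expect_true(all(tab$empty_initiation))
  expect_true(all(is.na(tab$theta)))
})

test_that("plane-generated thresholds are recovered exactly and lm matches
           the normal equations", {
  grid <- expand.grid(beta_G = c(0.2, 0.5, 0.8), c_d = c(0.05, 0.1, 0.2))
  tab <- data.frame(activity = "feed", location = "patch",
                    beta_G = grid$beta_G, c_d = grid$c_d,
                    boundary = "upper",
                    theta = 0.3 + 0.25 * grid$beta_G + 0.4 * grid$c_d,
                    empty_initiation = FALSE)
  fit <- fit_linear_thresholds(tab)
  cf <- fit$coefficients
  expect_equal(cf$w0, 0.3, tolerance = 1e-10)
  expect_equal(cf$w1_beta_G, 0.25, tolerance = 1e-10)
  expect_equal(cf$w2_c_d, 0.4, tolerance = 1e-10)
  expect_lt(cf$rmse, 1e-12)
  expect_equal(predict_threshold(fit, "feed", "patch", "upper", 0.5, 0.1),
               0.3 + 0.125 + 0.04, tolerance = 1e-10)
  # real extracted table: lm coefficients equal the closed-form solution
  feed <- .thr_tab[.thr_tab$activity == "feed", ]
  fit2 <- fit_linear_thresholds(feed)
  X <- cbind(1, feed$beta_G, feed$c_d)
  beta_hat <- normal_equations_oracle(X, feed$theta)
  cf2 <- fit2$coefficients
  expect_equal(c(cf2$w0, cf2$w1_beta_G, cf2$w2_c_d), as.vector(beta_hat),
               tolerance = 1e-8)
  expect_error(fit_linear_thresholds(tab[1:2, ]), "at least 3")
})

test_that("thresholds set at the extracted optima reproduce the exact
           interruptible policy on matched streams", {
  si <- .thr_s2
  levels <- seq(0, 1, by = si$grid$d_beta)
  tab <- rbind(
    extract_thresholds(si, "feed", "patch", beta_G_levels = levels),
    extract_thresholds(si, "assess", "patch", beta_G_levels = levels),
    extract_thresholds(si, "assess", "refuge", beta_G_levels = levels))
  db <- si$grid$d_beta
  lookup <- function(act, location, bnd, bg) {
    sub <- tab[tab$activity == act & tab$location == location &
                 tab$boundary == bnd & !tab$empty_initiation, ]
    if (!nrow(sub)) return(NA_real_)
    sub$theta[which.min(abs(sub$beta_G - bg))]
  }
  thr_fn <- function(act, location, bp, bg) {
    bp <- round(bp / db) * db
    up <- lookup(act, location, "upper", bg)
    lo <- if (act == "assess") lookup(act, location, "lower", bg) else NA
    (!is.na(up) && bp > up + 1e-9) || (!is.na(lo) && bp < lo - 1e-9)
  }
  proto <- protocol()
  b_exact <- interforage:::.run_batch(si, proto, 40, seed = 5)
  b_thr <- interforage:::.run_batch(si, proto, 40, seed = 5,
                                    thresholds_fn = thr_fn)
  expect_equal(b_thr$mean_reward, b_exact$mean_reward, tolerance = 0.01)
})

test_that("disabling interrupts reduces to running commitments to term", {
  # thresholds pinned at 0 and 1 never fire inside (0, 1)
  fit <- fit_linear_thresholds(data.frame(
    activity = rep(c("feed", "assess", "assess"), each = 3),
    location = rep(c("patch", "patch", "patch"), each = 3),
    beta_G = rep(c(0.2, 0.5, 0.8), 3),
    c_d = 0.2,
    boundary = rep(c("upper", "upper", "lower"), each = 3),
    theta = rep(c(1, 1, 0), each = 3),
    empty_initiation = FALSE))
  expect_equal(predict_threshold(fit, "feed", "patch", "upper", 0.5, 0.2), 1)
  expect_equal(predict_threshold(fit, "assess", "patch", "lower", 0.5, 0.2), 0)
})

test_that("weaker indirect cues lower the feed interruption threshold", {
  tab <- sweep_cue_reliability(coarse_params(), "oi",
                               lambda_values = c(0.3, 0.5),
                               c_d_grid = 0.1,
                               activity = "feed", location = "patch")
  th_weak <- tab$theta[tab$lambda_setting == "oi+=0.3"]
  th_strong <- tab$theta[tab$lambda_setting == "oi+=0.5"]
  expect_lte(th_weak, th_strong)
})

test_that("uninformative cues collapse the assess initiation region", {
  pu <- coarse_params(c_d = 0.05, lambda_oi_plus = 0.1,
                      lambda_od_plus = 0.1)
  su <- value_iteration(pu, interruptible = TRUE)
  sd <- value_iteration(coarse_params(c_d = 0.05), interruptible = TRUE)
  n_u <- sum(su$policy$patch$action == "assess") +
    sum(su$policy$refuge$action == "assess")
  n_d <- sum(sd$policy$patch$action == "assess") +
    sum(sd$policy$refuge$action == "assess")
  expect_lt(n_u, n_d)
})
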