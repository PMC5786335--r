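test_that("closed-form propagation matches hand-derived values", {
  p <- model_params()
  # starting from certainty of absence, one second of symmetric 0.1 rates
  b <- propagate_belief(belief(0, 0.3), 1, p)
  expect_equal(b$beta_P, 0.5 * (1 - exp(-0.2)), tolerance = 1e-12)
  # equilibrium is a fixed point
  eq <- belief(0.5, 0.5)
  for (tau in c(0.5, 3, 50)) {
    b <- propagate_belief(eq, tau, p)
    expect_equal(b$beta_P, 0.5, tolerance = 1e-12)
    expect_equal(b$beta_G, 0.5, tolerance = 1e-12)
  }
  expect_error(propagate_belief(eq, -1, p), "non-negative")
})

test_that("symmetric rates relax any start toward 0.5", {
  p <- model_params()
  for (b0 in c(0, 0.2, 0.9, 1)) {
    b <- propagate_belief(belief(b0, b0), 1e4, p)
    expect_equal(b$beta_P, 0.5, tolerance = 1e-9)
    expect_equal(b$beta_G, 0.5, tolerance = 1e-9)
  }
})

test_that("one-step propagation composes to the closed form", {
  p <- model_params(dt = 0.01)
  b <- belief(0.1, 0.9)
  for (k in 1:100) b <- propagate_belief_step(b, p)
  closed <- propagate_belief(belief(0.1, 0.9), 1, model_params())
  # Eq 3/4 use exp(-gamma dt) per rate rather than the joint closed form,
  # so agreement is O(dt)
  expect_equal(b$beta_P, closed$beta_P, tolerance = 1e-3)
  expect_equal(b$beta_G, closed$beta_G, tolerance = 1e-3)
  # zero rates: identity
  p0 <- model_params(gamma_AP = 0, gamma_PA = 0, gamma_GB = 0, gamma_BG = 0)
  b <- propagate_belief_step(belief(0.37, 0.61), p0)
  expect_equal(b$beta_P, 0.37)
  expect_equal(b$beta_G, 0.61)
})

test_that("cue updates reproduce two-hypothesis Bayes by hand", {
  p <- model_params()
  prior <- belief(0.5, 0.5)
  # oi seen: 0.5*0.5 / (0.5*0.5 + 0.1*0.5)
  post <- update_predator_belief(prior, observation(oi = "seen"), p)
  expect_equal(post$beta_P, 0.25 / 0.30, tolerance = 1e-12)
  # assess: od seen, oi not seen: (0.9*0.5*0.5) vs (0.1*0.9*0.5)
  post <- update_predator_belief(prior,
                                 observation(oi = "not_seen", od = "seen"), p)
  expect_equal(post$beta_P,
               (0.9 * 0.5 * 0.5) / ((0.9 * 0.5 * 0.5) + (0.1 * 0.9 * 0.5)),
               tolerance = 1e-12)
  # uninformative cue leaves the belief unchanged
  pu <- model_params(lambda_oi_plus = 0.3, lambda_oi_minus = 0.3)
  for (o in c("seen", "not_seen")) {
    post <- update_predator_belief(belief(0.37, 0.5),
                                   observation(oi = o), pu)
    expect_equal(post$beta_P, 0.37, tolerance = 1e-12)
  }
})

test_that("omissions push the belief down when the cue is informative", {
  p <- model_params()
  for (b0 in c(0.1, 0.5, 0.9)) {
    post <- update_predator_belief(belief(b0, 0.5),
                                   observation(oi = "not_seen"), p)
    expect_lt(post$beta_P, b0)
    post <- update_predator_belief(belief(b0, 0.5),
                                   observation(oi = "seen"), p)
    expect_gt(post$beta_P, b0)
  }
})

test_that("habitat updates follow the encounter likelihoods", {
  p <- model_params()
  post <- update_habitat_belief(belief(0.5, 0.5), "rich", p)
  expect_equal(post$beta_G, 0.8, tolerance = 1e-12)
  post <- update_habitat_belief(belief(0.5, 0.5), "poor", p)
  expect_equal(post$beta_G, 0.2, tolerance = 1e-12)
  # degenerate prior is untouched by any outcome
  for (o in c("rich", "poor", "none", "unavailable")) {
    expect_equal(update_habitat_belief(belief(0.5, 1), o, p)$beta_G, 1)
  }
  # equal encounter rates are uninformative
  pu <- model_params(rho_rG = 0.4, rho_rB = 0.4, rho_pG = 0.3, rho_pB = 0.3)
  expect_equal(update_habitat_belief(belief(0.5, 0.42), "rich", pu)$beta_G,
               0.42, tolerance = 1e-12)
})

test_that("sequential filtering equals the brute-force HMM forward pass", {
  p <- model_params()
  set.seed(123)
  # simulate a predator trajectory and a mixed activity record
  n <- 300
  s <- world_state(predator = "absent")
  acts <- sample(c("feed", "assess", "freeze"), n, replace = TRUE)
  b <- belief(0.5, 0.5)
  ours <- numeric(n)
  lik <- matrix(1, n, 2)
  for (t in 1:n) {
    s <- step_hidden_state(s, p)
    o <- sample_observation(acts[t], "patch", s, p)
    b <- propagate_belief_step(b, p)
    b <- update_predator_belief(b, o, p)
    ours[t] <- b$beta_P
    l_oi <- switch(o$oi, seen = c(0.5, 0.1), not_seen = c(0.5, 0.9),
                   unavailable = c(1, 1))
    l_od <- switch(o$od, seen = c(0.9, 0.1), not_seen = c(0.1, 0.9),
                   unavailable = c(1, 1))
    lik[t, ] <- l_oi * l_od
  }
  oracle <- hmm_forward_oracle(0.5, 1 - exp(-0.1), 1 - exp(-0.1), lik)
  expect_equal(ours, oracle, tolerance = 1e-12)
})

test_that("grid snapping weights are convex and exact on nodes", {
  g <- belief_grid(0.01)
  # exact node
  w <- snap_to_grid(belief(0.25, 0.75), g)
  w <- w[w$weight > 0, ]
  expect_equal(nrow(w), 1L)
  expect_equal(w$weight, 1)
  # cell midpoint on one axis splits evenly
  w <- snap_to_grid(belief(0.005, 0), g)
  expect_equal(sort(w$weight[w$weight > 0]), c(0.5, 0.5))
  # random beliefs: weights non-negative, sum to 1, nearest mode one-hot
  set.seed(5)
  b <- belief(runif(1e4), runif(1e4))
  w <- snap_to_grid(b, g)
  expect_true(all(w$weight >= 0))
  sums <- tapply(w$weight, w$point, sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  wn <- snap_to_grid(b, g, mode = "nearest")
  expect_true(all(wn$weight == 1))
  expect_equal(nrow(wn), 1e4L)
})
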