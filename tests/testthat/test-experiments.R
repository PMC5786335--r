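# One coarse zero-cost solve shared across blocks
.p_exp <- coarse_params()
.sol_exp <- value_iteration(.p_exp)

test_that("identical seeds reproduce trial metrics bit for bit", {
  t1 <- run_trial(.sol_exp, protocol(), trial_seed = 5)
  t2 <- run_trial(.sol_exp, protocol(), trial_seed = 5)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$total_reward, t2$total_reward)
  t3 <- run_trial(.sol_exp, protocol(), trial_seed = 6)
  expect_false(identical(t1$trace, t3$trace))
})

test_that("a resting animal decides once and relaxes to equilibrium", {
  sol <- .sol_exp
  for (loc in c("refuge", "patch")) {
    sol$policy[[loc]]$action[] <- if (loc == "refuge") "rest" else "freeze"
    sol$policy[[loc]]$tau[] <- max(.p_exp$tau_set)
  }
  proto <- protocol(data.frame(duration = 45, predator = "absent"))
  tr <- run_trial(sol, proto, trial_seed = 1)
  expect_equal(tr$n_decisions, 3)   # 45 steps at tau = 15
  expect_true(all(tr$trace$action == "rest"))
  # no observations during rest: beliefs follow the prior relaxation
  b <- belief(0.5, 0.5)
  expected <- numeric(45)
  for (t in 1:45) {
    b <- propagate_belief_step(b, .p_exp)
    expected[t] <- b$beta_P
  }
  expect_equal(tr$trace$beta_P, expected, tolerance = 1e-12)
})

test_that("trial belief sequence replays through the standalone filter", {
  tr <- run_trial(.sol_exp, protocol(), trial_seed = 9)$trace
  b <- belief(0.5, 0.5)
  for (t in seq_len(nrow(tr))) {
    if (tr$detected[t]) {
      b <- belief(exp(-.p_exp$gamma_PA * .p_exp$dt),
                  propagate_belief_step(b, .p_exp)$beta_G)
    } else {
      b <- propagate_belief_step(b, .p_exp)
      b <- update_predator_belief(
        b, observation(oi = tr$oi[t], od = tr$od[t]), .p_exp)
      b <- update_habitat_belief(b, tr$feed_outcome[t], .p_exp)
    }
    expect_equal(b$beta_P, tr$beta_P[t], tolerance = 1e-12)
    expect_equal(b$beta_G, tr$beta_G[t], tolerance = 1e-12)
  }
})

test_that("predator presence drives refuge occupancy and activity shares", {
  ba <- behaviour_summary(.sol_exp, "absent", n_runs = 10,
                          run_length = 600, seed = 2)
  bp <- behaviour_summary(.sol_exp, "present", n_runs = 10,
                          run_length = 600, seed = 2)
  expect_gt(ba$pct_location[["patch"]], 50)
  expect_gt(bp$pct_location[["refuge"]], 50)
  expect_gt(ba$pct_activity[["feed"]], 50)
  expect_lt(bp$pct_activity[["feed"]], 10)
  expect_true(all(abs(sum(ba$pct_activity) - 100) < 1e-9))
  # bouts of feeding outlast the 1 s commitments through re-selection
  expect_gt(ba$bouts$mean_length[ba$bouts$action == "feed"], 1)
})

test_that("a single-action policy yields one bout spanning the run", {
  sol <- .sol_exp
  sol$policy$refuge$action[] <- "rest"
  sol$policy$refuge$tau[] <- 1
  b <- behaviour_summary(sol, "absent", n_runs = 3, run_length = 120,
                         seed = 4)
  expect_identical(b$bouts$action, "rest")
  expect_equal(b$bouts$n_bouts, 3)
  expect_equal(b$bouts$mean_length, 120)
})

test_that("i.i.d. two-action switching yields geometric bout lengths", {
  set.seed(21)
  p_a <- 0.3
  acts <- sample(c("rest", "assess"), 5e4, replace = TRUE,
                 prob = c(p_a, 1 - p_a))
  b <- bout_lengths(acts)
  # mean run length of an i.i.d.-selected action a is 1 / (1 - P(a))
  m_rest <- mean(b$length[b$action == "rest"])
  m_assess <- mean(b$length[b$action == "assess"])
  expect_equal(m_rest, 1 / (1 - p_a), tolerance = 0.05)
  expect_equal(m_assess, 1 / p_a, tolerance = 0.05)
})

test_that("bout accounting partitions every run exactly", {
  b <- behaviour_summary(.sol_exp, "absent", n_runs = 5, run_length = 300,
                         seed = 8)
  expect_equal(sum(b$bouts$mean_length * b$bouts$n_bouts), 5 * 300,
               tolerance = 1e-9)
})

test_that("matched-trial comparison is exactly 1 at zero cost and for
           self-comparison", {
  soli <- value_iteration(.p_exp, interruptible = TRUE)
  proto <- protocol()
  bn <- interforage:::.run_batch(.sol_exp, proto, 25, seed = 31)
  bi <- interforage:::.run_batch(soli, proto, 25, seed = 31)
  expect_equal(bn$mean_reward / bi$mean_reward, 1, tolerance = 1e-12)
  # a policy against itself, any cost
  p2 <- coarse_params(c_d = 0.15)
  s2 <- value_iteration(p2)
  b1 <- interforage:::.run_batch(s2, proto, 25, seed = 32)
  b2 <- interforage:::.run_batch(s2, proto, 25, seed = 32)
  expect_identical(b1$mean_reward, b2$mean_reward)
})

test_that("interruptible policies decide less often and rest collapse is
           ordered in c_d", {
  cmp <- compare_interruptibility(.p_exp, c_d_grid = c(0.1, 0.3),
                                  n_trials = 40, seed = 13)
  tab <- cmp$table
  # while both policies are still active, interruption cuts the decision
  # rate; once the non-interruptible policy has collapsed to permanent
  # rest its rate sits at the 1/tau_max floor, below everything
  active <- tab$pct_rest_nonint < 99.9
  expect_true(any(active))
  expect_true(all(tab$decisions_per_step_int[active] <=
                    tab$decisions_per_step_nonint[active] + 1e-12))
  expect_true(all(tab$ratio <= 1 + 0.05))
  expect_true(all(tab$pct_rest_nonint >= tab$pct_rest_int - 1e-9))
})
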