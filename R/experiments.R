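#' Experimental protocol with a scripted predator schedule
#'
#' Protocols script the predator's presence as a sequence of fixed-duration
#' segments (overriding its free dynamics), while habitat quality keeps its
#' free dynamics. The default is the 6-minute benchmark: 2 min absent,
#' 2 min present, 2 min absent.
#'
#' @param segments Data frame with columns `duration` (seconds) and
#'   `predator` (`"absent"`/`"present"`).
#' @return A `protocol` object.
#' @export
protocol <- function(segments = data.frame(
                       duration = c(120, 120, 120),
                       predator = c("absent", "present", "absent"))) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "predator") %in% names(segments)),
            all(segments$duration > 0),
            all(segments$predator %in% c("absent", "present")))
  structure(list(segments = segments,
                 total = sum(segments$duration)), class = "protocol")
}

# per-step predator presence implied by a protocol
.schedule_steps <- function(proto, dt) {
  rep(proto$segments$predator, times = round(proto$segments$duration / dt))
}

# nearest grid index of a belief pair
.nearest_index <- function(bp, bg, g) {
  i_P <- min(max(round(bp / g$d_beta), 0), g$n - 1) + 1
  i_G <- min(max(round(bg / g$d_beta), 0), g$n - 1) + 1
  .grid_index(g, as.integer(i_P), as.integer(i_G))
}

# The trial engine. Runs one trial of `sol` under a scripted predator
# schedule with free-running habitat, using a pre-drawn uniform matrix
# (columns: habitat flip, detection, oi, od, feed encounter) so that
# matched policies face identical event streams. If `thresholds_fn` is
# given it replaces the exact interrupt test for feed/assess (freeze runs
# to completion under the approximate rule).
.sim_trial <- function(sol, schedule, u, p, trace = FALSE,
                       thresholds_fn = NULL, interrupt_eps = 1e-7) {
  g <- sol$grid
  dt <- p$dt
  n_steps <- length(schedule)
  eq_P <- if (p$gamma_AP + p$gamma_PA > 0)
    p$gamma_AP / (p$gamma_AP + p$gamma_PA) else 0.5
  eq_G <- if (p$gamma_BG + p$gamma_GB > 0)
    p$gamma_BG / (p$gamma_BG + p$gamma_GB) else 0.5
  location <- "refuge"
  habitat <- if (u[1, 1] < eq_G) "good" else "bad"
  # trials start uninformed: beliefs at the hidden chains' equilibria
  bp <- eq_P
  bg <- eq_G
  pred_prev <- schedule[1]
  p_GB <- 1 - exp(-p$gamma_GB * dt)
  p_BG <- 1 - exp(-p$gamma_BG * dt)
  e_PA <- exp(-p$gamma_PA * dt)
  e_AP_c <- 1 - exp(-p$gamma_AP * dt)
  e_GB <- exp(-p$gamma_GB * dt)
  e_BG_c <- 1 - exp(-p$gamma_BG * dt)

  act <- ""
  remaining <- 0L
  total_reward <- 0
  n_decisions <- 0L
  n_captures <- 0L
  act_steps <- stats::setNames(numeric(length(.all_actions)), .all_actions)
  loc_steps <- c(refuge = 0, patch = 0)
  if (trace) {
    tr_time <- tr_reward <- tr_bp <- tr_bg <- numeric(n_steps)
    tr_loc <- tr_act <- tr_pred <- tr_hab <- tr_oi <- tr_od <-
      tr_feed <- character(n_steps)
    tr_rem <- integer(n_steps)
    tr_det <- tr_dec <- logical(n_steps)
  }
  action_seq <- character(n_steps)

  for (t in seq_len(n_steps)) {
    if (remaining == 0L) {
      n_decisions <- n_decisions + 1L
      total_reward <- total_reward - p$c_d
      i <- .nearest_index(bp, bg, g)
      act <- sol$policy[[location]]$action[i]
      remaining <- as.integer(round(sol$policy[[location]]$tau[i] / dt))
      decided <- TRUE
    } else decided <- FALSE

    pred_cur <- schedule[t]
    # habitat free dynamics
    hab_prev <- habitat
    p_flip <- if (habitat == "good") p_GB else p_BG
    if (u[t, 1] < p_flip) habitat <- if (habitat == "good") "bad" else "good"

    detected <- FALSE
    reward <- 0
    oi <- od <- "unavailable"; feed_outcome <- "unavailable"
    if (.is_exposed(location, act) && pred_prev == "present" &&
        u[t, 2] < 1 - exp(-p$delta_by_action[[act]] * dt)) {
      detected <- TRUE
      n_captures <- n_captures + 1L
      reward <- p$r_pred
      bp <- e_PA                                 # certainty, propagated
      bg <- bg * e_GB + (1 - bg) * e_BG_c
      location <- "refuge"
      remaining <- 0L
    } else {
      # cues and encounters from the post-transition state
      if (act != "rest") {
        rate <- if (pred_cur == "present") p$lambda_oi_plus else p$lambda_oi_minus
        oi <- if (u[t, 3] < rate * dt) "seen" else "not_seen"
      }
      if (act == "assess") {
        rate <- if (pred_cur == "present") p$lambda_od_plus else p$lambda_od_minus
        od <- if (u[t, 4] < rate * dt) "seen" else "not_seen"
      }
      reward <- .action_reward_rate(p, act) * dt
      if (act == "feed") {
        pr <- if (habitat == "good") p$rho_rG * dt else p$rho_rB * dt
        pp <- if (habitat == "good") p$rho_pG * dt else p$rho_pB * dt
        feed_outcome <- if (u[t, 5] < pr) "rich"
                        else if (u[t, 5] < pr + pp) "poor" else "none"
        reward <- reward + switch(feed_outcome, rich = p$r_feed_rich * dt,
                                  poor = p$r_feed_poor * dt, 0)
      }
      # belief: propagate one step, then Bayes on the step's observations
      bp <- bp * e_PA + (1 - bp) * e_AP_c
      bg <- bg * e_GB + (1 - bg) * e_BG_c
      if (oi != "unavailable" || od != "unavailable") {
        li <- .cue_likelihood(oi, p$lambda_oi_plus, p$lambda_oi_minus, dt)
        ld <- .cue_likelihood(od, p$lambda_od_plus, p$lambda_od_minus, dt)
        num <- li[["plus"]] * ld[["plus"]] * bp
        den <- num + li[["minus"]] * ld[["minus"]] * (1 - bp)
        if (den > 0) bp <- num / den
      }
      if (feed_outcome != "unavailable") {
        lik <- switch(feed_outcome,
          rich = c(p$rho_rG, p$rho_rB) * dt,
          poor = c(p$rho_pG, p$rho_pB) * dt,
          none = c(1 - (p$rho_rG + p$rho_pG) * dt,
                   1 - (p$rho_rB + p$rho_pB) * dt))
        num <- lik[1] * bg
        den <- num + lik[2] * (1 - bg)
        if (den > 0) bg <- num / den
      }
      remaining <- remaining - 1L
      if (remaining == 0L) {
        if (act == "transit") location <- "patch"
        if (act == "escape" && p$escape_effective) location <- "refuge"
      } else if (sol$interruptible && .is_interruptible_action(act)) {
        if (!is.null(thresholds_fn) && act %in% c("feed", "assess")) {
          # approximate regime: linear thresholds replace the exact test
          # for the activities the threshold analysis covers
          if (thresholds_fn(act, location, bp, bg)) remaining <- 0L
        } else {
          i <- .nearest_index(bp, bg, g)
          if (sol$value[[location]][i] >
              sol$continue_value[[location]][[act]][i, remaining] +
              interrupt_eps) remaining <- 0L
        }
      }
    }
    total_reward <- total_reward + reward
    act_steps[act] <- act_steps[act] + 1
    loc_steps[location] <- loc_steps[location] + 1
    action_seq[t] <- act
    if (trace) {
      tr_time[t] <- t * dt; tr_loc[t] <- location; tr_act[t] <- act
      tr_pred[t] <- pred_cur; tr_hab[t] <- habitat
      tr_rem[t] <- remaining; tr_oi[t] <- oi; tr_od[t] <- od
      tr_feed[t] <- feed_outcome; tr_det[t] <- detected
      tr_reward[t] <- reward; tr_dec[t] <- decided
      tr_bp[t] <- bp; tr_bg[t] <- bg
    }
    pred_prev <- pred_cur
  }
  out <- list(total_reward = total_reward, n_decisions = n_decisions,
              n_steps = n_steps, n_captures = n_captures,
              decisions_per_step = n_decisions / n_steps,
              activity_steps = act_steps, location_steps = loc_steps,
              action_seq = action_seq)
  if (trace) {
    out$trace <- data.frame(
      time = tr_time, location = tr_loc, predator = tr_pred,
      habitat = tr_hab, action = tr_act, tau_remaining = tr_rem,
      oi = tr_oi, od = tr_od, feed_outcome = tr_feed, detected = tr_det,
      reward = tr_reward, decision = tr_dec, beta_P = tr_bp, beta_G = tr_bg)
  }
  out
}

# uniforms for one trial: one row per step, one column per event channel
# (habitat, detection, oi, od, feed); fixed consumption order gives
# common random numbers across policies
.trial_uniforms <- function(n_steps, trial_seed) {
  set.seed(trial_seed)
  matrix(stats::runif(n_steps * 5), ncol = 5)
}

#' Run one closed-loop trial of a solved policy
#'
#' Executes the policy against a scripted predator schedule with
#' free-running habitat dynamics: at every decision epoch the decision
#' cost is paid and the policy's activity is looked up at the nearest
#' belief grid point; beliefs are filtered from the sampled observations
#' each step; interruptible policies re-decide whenever the solver's
#' interrupt condition fires. The trial starts in the refuge with the
#' predator absent, habitat drawn from its stationary distribution, and
#' beliefs at the hidden chains' equilibria.
#'
#' @param sol A [value_iteration()] solution.
#' @param proto A [protocol()].
#' @param trial_seed Integer seed for this trial's event streams.
#' @return A list with the full per-step `trace` (a data frame) and the
#'   aggregates `total_reward`, `n_decisions`, `decisions_per_step`,
#'   `n_captures`, `activity_steps`, `location_steps`.
#' @export
run_trial <- function(sol, proto = protocol(), trial_seed = 1) {
  p <- sol$params
  schedule <- .schedule_steps(proto, p$dt)
  u <- .trial_uniforms(length(schedule), trial_seed)
  .sim_trial(sol, schedule, u, p, trace = TRUE)
}

# batch of matched trials; trial t uses stream seed + t
.run_batch <- function(sol, proto, n_trials, seed, thresholds_fn = NULL) {
  p <- sol$params
  schedule <- .schedule_steps(proto, p$dt)
  reward <- decisions <- captures <- numeric(n_trials)
  act_steps <- stats::setNames(numeric(length(.all_actions)), .all_actions)
  loc_steps <- c(refuge = 0, patch = 0)
  for (tr in seq_len(n_trials)) {
    u <- .trial_uniforms(length(schedule), seed + tr)
    res <- .sim_trial(sol, schedule, u, p, thresholds_fn = thresholds_fn)
    reward[tr] <- res$total_reward
    decisions[tr] <- res$n_decisions
    captures[tr] <- res$n_captures
    act_steps <- act_steps + res$activity_steps
    loc_steps <- loc_steps + res$location_steps
  }
  n_steps <- length(schedule) * n_trials
  list(mean_reward = mean(reward), se_reward = stats::sd(reward) / sqrt(n_trials),
       rewards = reward, decisions_per_step = sum(decisions) / n_steps,
       pct_activity = 100 * act_steps / n_steps,
       pct_location = 100 * loc_steps / n_steps,
       mean_captures = mean(captures))
}

#' Compare interruptible and non-interruptible policies across decision costs
#'
#' For each decision cost in `c_d_grid`, solves the model with and without
#' interruption and runs `n_trials` matched trials of the protocol per
#' policy (common random numbers: trial t of every policy sees the same
#' event stream). Reports the non-interruptible/interruptible ratio of
#' mean total reward per trial alongside decision frequencies and the
#' percentage of time spent resting.
#'
#' @param p A [model_params()] object (its `c_d` is overridden per grid
#'   value).
#' @param c_d_grid Numeric vector of decision costs.
#' @param proto A [protocol()].
#' @param n_trials Matched trials per policy per cost.
#' @param seed Base seed for the trial streams.
#' @param solutions Optional pre-solved list (as returned in the result's
#'   `solutions` field) to skip re-solving.
#' @param ... Passed to [value_iteration()] (e.g. `tol`).
#' @return A list with `table` (data frame: `c_d`, `ratio`,
#'   `mean_reward_nonint`, `mean_reward_int`, `decisions_per_step_*`,
#'   `pct_rest_*`) and `solutions`.
#' @export
compare_interruptibility <- function(p, c_d_grid = seq(0, 0.5, by = 0.05),
                                     proto = protocol(), n_trials = 200,
                                     seed = 1, solutions = NULL, ...) {
  rows <- list()
  sols <- list()
  for (k in seq_along(c_d_grid)) {
    cd <- c_d_grid[k]
    pk <- p; pk$c_d <- cd
    key <- sprintf("c_d=%g", cd)
    if (!is.null(solutions) && !is.null(solutions[[key]])) {
      sn <- solutions[[key]]$nonint; si <- solutions[[key]]$int
    } else {
      sn <- value_iteration(pk, interruptible = FALSE, ...)
      si <- value_iteration(pk, interruptible = TRUE, ...)
    }
    sols[[key]] <- list(nonint = sn, int = si)
    bn <- .run_batch(sn, proto, n_trials, seed)
    bi <- .run_batch(si, proto, n_trials, seed)
    rows[[k]] <- data.frame(
      c_d = cd,
      ratio = bn$mean_reward / bi$mean_reward,
      mean_reward_nonint = bn$mean_reward, mean_reward_int = bi$mean_reward,
      se_nonint = bn$se_reward, se_int = bi$se_reward,
      decisions_per_step_nonint = bn$decisions_per_step,
      decisions_per_step_int = bi$decisions_per_step,
      pct_rest_nonint = bn$pct_activity[["rest"]],
      pct_rest_int = bi$pct_activity[["rest"]])
  }
  list(table = do.call(rbind, rows), solutions = sols)
}

#' Bout decomposition of an action sequence
#'
#' A bout is a maximal run of consecutive steps with the same action, as
#' an external observer would score behaviour; bouts can greatly outlast
#' the committed durations when the policy re-selects the same action.
#'
#' @param actions Character vector, one action per step.
#' @param dt Step length in seconds.
#' @return Data frame with columns `action` and `length` (seconds), one
#'   row per bout, in order of occurrence.
#' @export
bout_lengths <- function(actions, dt = 1) {
  runs <- rle(actions)
  data.frame(action = runs$values, length = runs$lengths * dt)
}

#' Behavioural summary under clamped predator presence
#'
#' Repeatedly exposes a solved policy to an environment where the predator
#' is clamped `present` or `absent` for the whole run (habitat free), and
#' summarizes where the animal spends its time, what it does, and the
#' distribution of behavioural bouts -- maximal runs of consecutive steps
#' of the same action, which can far exceed the committed durations when
#' the policy re-selects the same action.
#'
#' @param sol A [value_iteration()] solution.
#' @param condition `"absent"` or `"present"`.
#' @param n_runs Number of independent runs.
#' @param run_length Length of each run in seconds.
#' @param seed Base seed.
#' @return A list with `pct_location`, `pct_activity` (percent of time),
#'   and `bouts` (data frame: `action`, `mean_length`, `se_length`,
#'   `n_bouts`; lengths in seconds).
#' @export
behaviour_summary <- function(sol, condition = c("absent", "present"),
                              n_runs = 100, run_length = 900, seed = 1) {
  condition <- match.arg(condition)
  p <- sol$params
  proto <- protocol(data.frame(duration = run_length, predator = condition))
  schedule <- .schedule_steps(proto, p$dt)
  act_steps <- stats::setNames(numeric(length(.all_actions)), .all_actions)
  loc_steps <- c(refuge = 0, patch = 0)
  bout_act <- character(0); bout_len <- numeric(0)
  for (r in seq_len(n_runs)) {
    u <- .trial_uniforms(length(schedule), seed + r)
    res <- .sim_trial(sol, schedule, u, p)
    act_steps <- act_steps + res$activity_steps
    loc_steps <- loc_steps + res$location_steps
    bouts_r <- bout_lengths(res$action_seq, p$dt)
    bout_act <- c(bout_act, bouts_r$action)
    bout_len <- c(bout_len, bouts_r$length)
  }
  n_steps <- length(schedule) * n_runs
  bouts <- do.call(rbind, lapply(sort(unique(bout_act)), function(a) {
    len <- bout_len[bout_act == a]
    data.frame(action = a, mean_length = mean(len),
               se_length = stats::sd(len) / sqrt(length(len)),
               n_bouts = length(len))
  }))
  list(condition = condition,
       pct_location = 100 * loc_steps / n_steps,
       pct_activity = 100 * act_steps / n_steps,
       bouts = bouts)
}
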