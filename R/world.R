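#' World state
#'
#' The generative state of the environment: the animal's (observable)
#' location and the two hidden binary variables, predator presence and
#' habitat quality, plus a clock in seconds.
#'
#' @param location `"refuge"` or `"patch"`.
#' @param predator `"absent"` or `"present"`.
#' @param habitat `"good"` or `"bad"`.
#' @param clock Time in seconds.
#' @return A `world_state` object.
#' @export
world_state <- function(location = "refuge", predator = "absent",
                        habitat = "good", clock = 0) {
  structure(list(
    location = match.arg(location, c("refuge", "patch")),
    predator = match.arg(predator, c("absent", "present")),
    habitat  = match.arg(habitat, c("good", "bad")),
    clock    = clock
  ), class = "world_state")
}

#' Observation delivered in one time step
#'
#' Cue availability depends on the current activity: the indirect cue `oi`
#' is available during every action except `rest`; the direct cue `od` only
#' during `assess`; the feeding outcome only during `feed`. `detected`
#' records whether the predator detected (and caught) the animal this step.
#'
#' @param oi,od `"seen"`, `"not_seen"`, or `"unavailable"`.
#' @param feed_outcome `"rich"`, `"poor"`, `"none"`, or `"unavailable"`.
#' @param detected Logical.
#' @return An `observation` object.
#' @export
observation <- function(oi = "unavailable", od = "unavailable",
                        feed_outcome = "unavailable", detected = FALSE) {
  structure(list(
    oi = match.arg(oi, c("unavailable", "seen", "not_seen")),
    od = match.arg(od, c("unavailable", "seen", "not_seen")),
    feed_outcome = match.arg(feed_outcome,
                             c("unavailable", "rich", "poor", "none")),
    detected = isTRUE(detected)
  ), class = "observation")
}

#' Advance the hidden environment variables by one interval
#'
#' The predator flips absent-to-present with probability
#' `1 - exp(-gamma_AP * dt)` (and back with `1 - exp(-gamma_PA * dt)`);
#' habitat quality flips analogously with `(gamma_GB, gamma_BG)`. The two
#' flips are independent. Uniform draws can be supplied through `u`
#' (`u[1]` predator, `u[2]` habitat) so that matched comparisons can reuse
#' common random numbers; by default they come from the R session's RNG.
#'
#' @param s A [world_state()].
#' @param p A [model_params()] object.
#' @param dt Interval in seconds (default `p$dt`).
#' @param u Two uniforms in \[0, 1\); defaults to `runif(2)`.
#' @return The updated `world_state` (clock advanced by `dt`).
#' @export
step_hidden_state <- function(s, p, dt = p$dt, u = stats::runif(2)) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  p_flip_pred <- if (s$predator == "absent") {
    1 - exp(-p$gamma_AP * dt)
  } else {
    1 - exp(-p$gamma_PA * dt)
  }
  if (u[1] < p_flip_pred)
    s$predator <- if (s$predator == "absent") "present" else "absent"
  p_flip_hab <- if (s$habitat == "good") {
    1 - exp(-p$gamma_GB * dt)
  } else {
    1 - exp(-p$gamma_BG * dt)
  }
  if (u[2] < p_flip_hab)
    s$habitat <- if (s$habitat == "good") "bad" else "good"
  s$clock <- s$clock + dt
  s
}

#' Sample the observation generated by one step of an activity
#'
#' Given the true hidden state, draws the step's events on independent
#' channels: detection (only while exposed -- in the patch, or en route
#' during `transit` -- and only when the predator is present, with
#' probability `1 - exp(-delta_a * dt)`), the indirect cue (Bernoulli
#' `lambda_oi * dt` at the rate matching predator presence; unavailable
#' during `rest`), the direct cue (during `assess` only), and the feeding
#' outcome (categorical `rho_r * dt` / `rho_p * dt` under the true habitat;
#' during `feed` only). Uniforms may be supplied via `u` in the order
#' (detection, oi, od, feed) for common-random-number designs.
#'
#' Within a step, detection is evaluated first, against the state at the
#' step's start (`s_start`); the hidden variables then transition, and cues
#' and encounters are emitted from the post-transition state (`s`). Passing
#' the same state for both collapses this distinction.
#'
#' @param action The current action; must be legal at `location`
#'   (`transit` is treated as originating in the refuge).
#' @param location `"refuge"` or `"patch"`.
#' @param s A [world_state()]: the post-transition hidden state, which
#'   emits cues and encounters.
#' @param p A [model_params()] object.
#' @param dt Step length in seconds (default `p$dt`).
#' @param u Four uniforms; defaults to `runif(4)`.
#' @param s_start The hidden state at the step's start, against which
#'   detection is evaluated (defaults to `s`).
#' @return An [observation()].
#' @export
sample_observation <- function(action, location, s, p, dt = p$dt,
                               u = stats::runif(4), s_start = s) {
  if (!(action %in% legal_actions(location)))
    stop("action '", action, "' is illegal in location '", location, "'",
         call. = FALSE)
  detected <- FALSE
  if (.is_exposed(location, action) && s_start$predator == "present") {
    detected <- u[1] < 1 - exp(-p$delta_by_action[[action]] * dt)
  }
  oi <- "unavailable"
  if (action != "rest") {
    rate <- if (s$predator == "present") p$lambda_oi_plus else p$lambda_oi_minus
    oi <- if (u[2] < rate * dt) "seen" else "not_seen"
  }
  od <- "unavailable"
  if (action == "assess") {
    rate <- if (s$predator == "present") p$lambda_od_plus else p$lambda_od_minus
    od <- if (u[3] < rate * dt) "seen" else "not_seen"
  }
  feed_outcome <- "unavailable"
  if (action == "feed") {
    pr <- if (s$habitat == "good") p$rho_rG * dt else p$rho_rB * dt
    pp <- if (s$habitat == "good") p$rho_pG * dt else p$rho_pB * dt
    feed_outcome <- if (u[4] < pr) "rich"
                    else if (u[4] < pr + pp) "poor"
                    else "none"
  }
  observation(oi = oi, od = od, feed_outcome = feed_outcome,
              detected = detected)
}
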