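#' Belief state
#'
#' The agent's sufficient statistic (besides its observable location): the
#' probability `beta_P` that a predator is present and the probability
#' `beta_G` that the habitat is good. Both components may be vectors of
#' equal length; all belief operations are vectorized.
#'
#' @param beta_P Probability the predator is present, in \[0, 1\].
#' @param beta_G Probability the habitat is good, in \[0, 1\].
#' @return A `belief` object (list with fields `beta_P`, `beta_G`).
#' @export
belief <- function(beta_P, beta_G) {
  stopifnot(all(beta_P >= 0 & beta_P <= 1), all(beta_G >= 0 & beta_G <= 1),
            length(beta_P) == length(beta_G))
  structure(list(beta_P = as.numeric(beta_P), beta_G = as.numeric(beta_G)),
            class = "belief")
}

# one telegraph-process component: relax toward equilibrium rate_up /
# (rate_up + rate_down) with time constant 1 / (rate_up + rate_down)
.prop_component <- function(beta, tau, rate_up, rate_down) {
  s <- rate_up + rate_down
  if (s == 0) return(beta)
  eq <- rate_up / s
  eq + (beta - eq) * exp(-s * tau)
}

#' Observation-free belief propagation over an interval
#'
#' Closed-form relaxation of both belief components over `tau` seconds in
#' the absence of any observation. Each component decays exponentially
#' toward the stationary probability of its hidden two-state chain:
#' `beta_P` toward `gamma_AP / (gamma_AP + gamma_PA)` with rate
#' `gamma_AP + gamma_PA`, and `beta_G` toward
#' `gamma_BG / (gamma_BG + gamma_GB)` with rate `gamma_BG + gamma_GB`.
#'
#' @param b A [belief()].
#' @param tau Interval length in seconds (>= 0).
#' @param p A [model_params()] object.
#' @return The propagated `belief`.
#' @export
propagate_belief <- function(b, tau, p) {
  if (any(tau < 0)) stop("'tau' must be non-negative", call. = FALSE)
  belief(
    .prop_component(b$beta_P, tau, p$gamma_AP, p$gamma_PA),
    .prop_component(b$beta_G, tau, p$gamma_BG, p$gamma_GB)
  )
}

#' One-step belief propagation
#'
#' The discrete one-step prior used between observations: with per-step
#' flip probabilities `1 - exp(-rate * dt)`, the predator component becomes
#' `beta_P * exp(-gamma_PA * dt) + (1 - beta_P) * (1 - exp(-gamma_AP * dt))`
#' and analogously for the habitat component. This is exactly the prior of
#' the discrete-time hidden Markov chain that the simulator implements, and
#' composing `tau / dt` steps approaches the closed form of
#' [propagate_belief()] as `dt -> 0`.
#'
#' @inheritParams propagate_belief
#' @return The propagated `belief` after one step of `p$dt` seconds.
#' @export
propagate_belief_step <- function(b, p) {
  dt <- p$dt
  belief(
    b$beta_P * exp(-p$gamma_PA * dt) +
      (1 - b$beta_P) * (1 - exp(-p$gamma_AP * dt)),
    b$beta_G * exp(-p$gamma_GB * dt) +
      (1 - b$beta_G) * (1 - exp(-p$gamma_BG * dt))
  )
}

# per-step cue likelihoods under each hypothesis; emission probability is
# rate * dt, omission uses the complement 1 - rate * dt
.cue_likelihood <- function(outcome, rate_plus, rate_minus, dt) {
  switch(outcome,
    seen        = c(plus = rate_plus * dt, minus = rate_minus * dt),
    not_seen    = c(plus = 1 - rate_plus * dt, minus = 1 - rate_minus * dt),
    unavailable = c(plus = 1, minus = 1),
    stop("unknown cue outcome '", outcome, "'", call. = FALSE)
  )
}

#' Bayesian update of the predator belief from cues
#'
#' Multiplies the (already propagated) prior by the likelihood of the
#' step's indirect and, during assess, direct cue outcomes under each
#' hypothesis, and renormalizes. Emissions have per-step probability
#' `lambda * dt` (with `+` rates when the predator is present and `-` rates
#' when absent); omissions of an available cue carry the complementary
#' likelihood `1 - lambda * dt`; unavailable channels contribute nothing.
#'
#' @param prior A [belief()], already propagated one step.
#' @param obs An [observation()] (its `oi` and `od` fields are used).
#' @param p A [model_params()] object.
#' @return The posterior `belief` (habitat component unchanged).
#' @export
update_predator_belief <- function(prior, obs, p) {
  li <- .cue_likelihood(obs$oi, p$lambda_oi_plus, p$lambda_oi_minus, p$dt)
  ld <- .cue_likelihood(obs$od, p$lambda_od_plus, p$lambda_od_minus, p$dt)
  num <- li[["plus"]] * ld[["plus"]] * prior$beta_P
  den <- num + li[["minus"]] * ld[["minus"]] * (1 - prior$beta_P)
  post <- ifelse(den > 0, num / den, prior$beta_P)
  belief(post, prior$beta_G)
}

#' Bayesian update of the habitat belief from a feeding outcome
#'
#' While feeding, the encounter outcome in a step is `rich` with
#' probability `rho_r * dt`, `poor` with probability `rho_p * dt` (each
#' conditioned on the hidden habitat quality), or `none`. The posterior
#' multiplies the propagated prior by the outcome's likelihood under the
#' good and bad hypotheses; `none` uses the complements.
#'
#' @param prior A [belief()], already propagated one step.
#' @param feed_outcome One of `"rich"`, `"poor"`, `"none"`,
#'   `"unavailable"`.
#' @param p A [model_params()] object.
#' @return The posterior `belief` (predator component unchanged).
#' @export
update_habitat_belief <- function(prior, feed_outcome, p) {
  dt <- p$dt
  lik <- switch(feed_outcome,
    rich = c(good = p$rho_rG * dt, bad = p$rho_rB * dt),
    poor = c(good = p$rho_pG * dt, bad = p$rho_pB * dt),
    none = c(good = 1 - (p$rho_rG + p$rho_pG) * dt,
             bad  = 1 - (p$rho_rB + p$rho_pB) * dt),
    unavailable = c(good = 1, bad = 1),
    stop("unknown feed outcome '", feed_outcome, "'", call. = FALSE)
  )
  num <- lik[["good"]] * prior$beta_G
  den <- num + lik[["bad"]] * (1 - prior$beta_G)
  post <- ifelse(den > 0, num / den, prior$beta_G)
  belief(prior$beta_P, post)
}

#' Discretized belief grid
#'
#' The square grid `{0, d_beta, ..., 1} x {0, d_beta, ..., 1}` over
#' `(beta_P, beta_G)` on which values and policies are represented. Grid
#' points are indexed column-major with `beta_P` varying fastest.
#'
#' @param d_beta Grid resolution; `1 / d_beta` must be (nearly) an integer.
#' @return A `belief_grid` object with fields `points` (axis values), `n`
#'   (points per axis), `N` (total points), and `d_beta`.
#' @export
belief_grid <- function(d_beta = 0.01) {
  n_cells <- round(1 / d_beta)
  if (abs(n_cells * d_beta - 1) > 1e-8)
    stop("'d_beta' must divide 1", call. = FALSE)
  pts <- seq(0, 1, length.out = n_cells + 1)
  structure(list(points = pts, n = n_cells + 1L,
                 N = (n_cells + 1L)^2, d_beta = d_beta),
            class = "belief_grid")
}

# flat index of grid node (i_P, i_G), both 1-based
.grid_index <- function(g, i_P, i_G) i_P + (i_G - 1L) * g$n

# beliefs at every grid point, in flat order
.grid_beliefs <- function(g) {
  belief(rep(g$points, times = g$n), rep(g$points, each = g$n))
}

#' Map beliefs to grid points and interpolation weights
#'
#' Bilinear mode (the default) spreads each belief over the (up to) four
#' surrounding grid nodes with weights proportional to overlap, so that
#' value functions are interpolated smoothly; nearest mode assigns all
#' weight to the closest node, reproducing a severe discretization.
#' Weights are non-negative and sum to 1 for every input belief.
#'
#' @param b A [belief()] (components may be vectors).
#' @param g A [belief_grid()].
#' @param mode `"bilinear"` or `"nearest"`.
#' @return A data frame with columns `point` (input index), `index` (flat
#'   grid index), `weight`.
#' @export
snap_to_grid <- function(b, g, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  m <- length(b$beta_P)
  if (mode == "nearest") {
    i_P <- pmin(pmax(round(b$beta_P / g$d_beta), 0), g$n - 1L) + 1L
    i_G <- pmin(pmax(round(b$beta_G / g$d_beta), 0), g$n - 1L) + 1L
    return(data.frame(point = seq_len(m),
                      index = .grid_index(g, i_P, i_G),
                      weight = rep(1, m)))
  }
  w <- .bilinear_weights(b$beta_P, b$beta_G, g)
  data.frame(point = rep(seq_len(m), 4L),
             index = as.vector(w$index),
             weight = as.vector(w$weight))
}

# vectorized bilinear weights: returns m x 4 matrices of flat indices and
# weights (some weights may be 0 when the belief lies on a grid line)
.bilinear_weights <- function(bp, bg, g) {
  u <- pmin(pmax(bp, 0), 1) / g$d_beta
  v <- pmin(pmax(bg, 0), 1) / g$d_beta
  i0 <- pmin(floor(u), g$n - 2L)   # lower cell corner, 0-based
  j0 <- pmin(floor(v), g$n - 2L)
  fu <- u - i0
  fv <- v - j0
  i0 <- as.integer(i0) + 1L        # to 1-based node index
  j0 <- as.integer(j0) + 1L
  index <- cbind(.grid_index(g, i0,      j0),
                 .grid_index(g, i0 + 1L, j0),
                 .grid_index(g, i0,      j0 + 1L),
                 .grid_index(g, i0 + 1L, j0 + 1L))
  weight <- cbind((1 - fu) * (1 - fv), fu * (1 - fv),
                  (1 - fu) * fv,       fu * fv)
  list(index = index, weight = weight)
}
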