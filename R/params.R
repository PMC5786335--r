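#' Action sets by location
#'
#' The model has two locations. In the refuge the animal can `rest`,
#' `assess`, or `transit` (move out to the foraging patch); in the patch it
#' can `feed`, `assess`, `freeze`, or `escape` (return to the refuge).
#'
#' @param location `"refuge"` or `"patch"`.
#' @return Character vector of legal actions, in the canonical order used
#'   for deterministic tie-breaking.
#' @export
legal_actions <- function(location) {
  switch(match.arg(location, c("refuge", "patch")),
    refuge = c("rest", "assess", "transit"),
    patch  = c("feed", "assess", "freeze", "escape")
  )
}

# canonical action order used for deterministic argmax tie-breaking
.action_order <- c(rest = 1, feed = 1, assess = 2, freeze = 3,
                   transit = 4, escape = 5)

.all_actions <- c("rest", "feed", "assess", "freeze", "transit", "escape")

#' Model parameters for the two-location foraging model
#'
#' Constructs the full parameter set of the foraging-under-predation model:
#' switching rates of the two hidden telegraph processes (predator
#' present/absent, habitat good/bad), cue-emission rates, patch-encounter
#' rates, reward rates, detection rates, the one-off predation penalty, the
#' per-decision cost, the discount rate, and discretization settings. All
#' rates are per second. Defaults are the reference parameterization used
#' throughout the package.
#'
#' @param gamma_AP,gamma_PA Predator arrival / departure rates (per s).
#' @param gamma_GB,gamma_BG Habitat good-to-bad / bad-to-good rates (per s).
#' @param lambda_oi_plus,lambda_oi_minus Indirect ("passive") cue emission
#'   rates when the predator is present / absent (per s).
#' @param lambda_od_plus,lambda_od_minus Direct ("active", assess-only) cue
#'   emission rates when the predator is present / absent (per s).
#' @param rho_rG,rho_pG Encounter rates with rich / poor patches while
#'   feeding in a good habitat (per s).
#' @param rho_rB,rho_pB Same, in a bad habitat.
#' @param r_feed_rich,r_feed_poor Reward rates while feeding on a rich /
#'   poor encounter (per s).
#' @param r_rest,r_transit,r_assess,r_freeze,r_escape Reward rates of the
#'   non-feeding actions (per s); all non-positive, with
#'   `r_escape < r_transit <= r_assess <= r_freeze`.
#' @param r_pred One-off penalty for being detected and caught (not a rate).
#' @param delta_by_action Named vector of detection rates (per s) applying
#'   while exposed (in the patch, or en route during transit); must satisfy
#'   `escape >= transit >= feed > assess > freeze` and `rest = 0`.
#' @param c_d Decision cost charged at every deliberation epoch.
#' @param alpha Exponential discount rate (per s); present value of a unit
#'   reward delayed by tau seconds is `exp(-alpha * tau)`.
#' @param dt Time step (s).
#' @param d_beta Belief-grid resolution.
#' @param tau_set Allowed commitment durations (s); positive, sorted.
#' @param escape_effective If `FALSE`, completing `escape` leaves the animal
#'   in the patch instead of relocating it to the refuge (the
#'   escape-ineffectual variant).
#' @return A validated object of class `model_params`.
#' @seealso [validate_params()], [simple_params()]
#' @export
model_params <- function(gamma_AP = 0.1, gamma_PA = 0.1,
                         gamma_GB = 0.01, gamma_BG = 0.01,
                         lambda_oi_plus = 0.5, lambda_oi_minus = 0.1,
                         lambda_od_plus = 0.9, lambda_od_minus = 0.1,
                         rho_rG = 0.8, rho_pG = 0.2,
                         rho_rB = 0.2, rho_pB = 0.8,
                         r_feed_rich = 2, r_feed_poor = 1,
                         r_rest = 0, r_transit = -0.1, r_assess = -0.1,
                         r_freeze = -0.1, r_escape = -1,
                         r_pred = -100,
                         delta_by_action = c(feed = 0.05, assess = 0.02,
                                             freeze = 0.01, transit = 0.05,
                                             escape = 0.05, rest = 0),
                         c_d = 0, alpha = 0.1, dt = 1,
                         d_beta = 0.01, tau_set = 1:15,
                         escape_effective = TRUE) {
  p <- list(
    gamma_AP = gamma_AP, gamma_PA = gamma_PA,
    gamma_GB = gamma_GB, gamma_BG = gamma_BG,
    lambda_oi_plus = lambda_oi_plus, lambda_oi_minus = lambda_oi_minus,
    lambda_od_plus = lambda_od_plus, lambda_od_minus = lambda_od_minus,
    rho_rG = rho_rG, rho_pG = rho_pG, rho_rB = rho_rB, rho_pB = rho_pB,
    r_feed_rich = r_feed_rich, r_feed_poor = r_feed_poor,
    r_rest = r_rest, r_transit = r_transit, r_assess = r_assess,
    r_freeze = r_freeze, r_escape = r_escape, r_pred = r_pred,
    delta_by_action = delta_by_action,
    c_d = c_d, alpha = alpha, dt = dt, d_beta = d_beta,
    tau_set = as.numeric(tau_set),
    escape_effective = isTRUE(escape_effective)
  )
  class(p) <- "model_params"
  validate_params(p)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the model and reports the first one
#' violated by name: non-negative rates, per-step event probabilities not
#' exceeding 1 (`rate * dt <= 1`), the reward ordering
#' `r_escape < r_transit <= r_assess <= r_freeze`, the detection-rate
#' ordering `escape >= transit >= feed > assess > freeze`, a valid duration
#' set, `c_d >= 0`, and `alpha` in \[0, 1\].
#'
#' @param p A `model_params` object (or a bare list with the same fields).
#' @return `p`, unchanged, with class `model_params`.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  rate_fields <- c("gamma_AP", "gamma_PA", "gamma_GB", "gamma_BG",
                   "lambda_oi_plus", "lambda_oi_minus",
                   "lambda_od_plus", "lambda_od_minus",
                   "rho_rG", "rho_pG", "rho_rB", "rho_pB")
  for (f in rate_fields) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v))
      stop("parameter '", f, "' missing or not a number", call. = FALSE)
    if (v < 0) stop("rate '", f, "' is negative", call. = FALSE)
  }
  if (!is.numeric(p$dt) || length(p$dt) != 1 || p$dt <= 0)
    stop("'dt' must be a positive number", call. = FALSE)
  for (f in rate_fields) {
    if (p[[f]] * p$dt > 1)
      stop("per-step probability '", f, "' * dt exceeds 1", call. = FALSE)
  }
  # joint encounter probability must be a valid categorical
  if ((p$rho_rG + p$rho_pG) * p$dt > 1)
    stop("encounter probabilities 'rho_rG + rho_pG' * dt exceed 1",
         call. = FALSE)
  if ((p$rho_rB + p$rho_pB) * p$dt > 1)
    stop("encounter probabilities 'rho_rB + rho_pB' * dt exceed 1",
         call. = FALSE)

  d <- p$delta_by_action
  if (is.null(d) || !all(.all_actions %in% names(d)))
    stop("'delta_by_action' must name all of: ",
         paste(.all_actions, collapse = ", "), call. = FALSE)
  if (any(d < 0)) stop("'delta_by_action' has a negative rate", call. = FALSE)
  if (any(d * p$dt > 1))
    stop("per-step probability 'delta_by_action' * dt exceeds 1",
         call. = FALSE)
  if (!(d[["escape"]] >= d[["transit"]] && d[["transit"]] >= d[["feed"]] &&
        d[["feed"]] > d[["assess"]] && d[["assess"]] > d[["freeze"]]))
    stop("detection-rate ordering violated: require ",
         "delta_escape >= delta_transit >= delta_feed > delta_assess ",
         "> delta_freeze", call. = FALSE)

  if (!(p$r_escape < p$r_transit && p$r_transit <= p$r_assess &&
        p$r_assess <= p$r_freeze))
    stop("reward ordering violated: require ",
         "r_escape < r_transit <= r_assess <= r_freeze", call. = FALSE)

  if (length(p$tau_set) == 0)
    stop("'tau_set' is empty", call. = FALSE)
  if (any(p$tau_set <= 0) || is.unsorted(p$tau_set, strictly = TRUE))
    stop("'tau_set' must be positive and strictly increasing", call. = FALSE)
  if (p$c_d < 0) stop("'c_d' must be non-negative", call. = FALSE)
  if (p$alpha < 0 || p$alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  if (p$d_beta <= 0 || p$d_beta > 0.5)
    stop("'d_beta' must lie in (0, 0.5]", call. = FALSE)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Foraging POSMDP parameters\n")
  cat(sprintf("  predator rates  gamma_AP=%.3g gamma_PA=%.3g\n",
              x$gamma_AP, x$gamma_PA))
  cat(sprintf("  habitat rates   gamma_GB=%.3g gamma_BG=%.3g\n",
              x$gamma_GB, x$gamma_BG))
  cat(sprintf("  cues            oi +%.3g/-%.3g   od +%.3g/-%.3g\n",
              x$lambda_oi_plus, x$lambda_oi_minus,
              x$lambda_od_plus, x$lambda_od_minus))
  cat(sprintf("  encounters      good r/p %.3g/%.3g  bad r/p %.3g/%.3g\n",
              x$rho_rG, x$rho_pG, x$rho_rB, x$rho_pB))
  cat(sprintf("  decision cost   c_d=%.3g   discount alpha=%.3g\n",
              x$c_d, x$alpha))
  cat(sprintf("  discretization  dt=%.3g s  d_beta=%.3g  tau in {%s} s\n",
              x$dt, x$d_beta, paste(range(x$tau_set), collapse = "..")))
  invisible(x)
}

# reward rate of an action excluding feeding outcomes (per second)
.action_reward_rate <- function(p, action) {
  switch(action,
    rest = p$r_rest, assess = p$r_assess, freeze = p$r_freeze,
    transit = p$r_transit, escape = p$r_escape,
    feed = 0  # feeding reward comes from encounters only
  )
}

# whether the animal is exposed to detection while doing `action` at
# `location` (transit counts as exposed: the animal is en route)
.is_exposed <- function(location, action) {
  location == "patch" || action == "transit"
}
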