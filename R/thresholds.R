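#' Extract optimal interruption thresholds on the predator belief
#'
#' Under the interruptible policy, the points at which an ongoing activity
#' should be abandoned form a boundary in belief space. For each requested
#' `beta_G` level this scans `beta_P` along the grid and locates where
#' continuing the activity (with the full commitment `tau_max` remaining,
#' the duration at which interrupt-capable activities are initiated)
#' stops beating re-deciding. `feed` has an upper boundary only; `assess`
#' has both a lower and an upper boundary. Where the activity's initiation
#' set (the beliefs at which the policy selects it) is empty, the row is
#' flagged and carries no threshold.
#'
#' @param sol An interruptible [value_iteration()] solution.
#' @param activity `"feed"` or `"assess"` (activities whose commitments
#'   are extended and interruptible; `rest`, `transit` and `escape` have
#'   no interruption structure).
#' @param location Location of the activity (`"patch"` for feed;
#'   `"patch"` or `"refuge"` for assess).
#' @param beta_G_levels Habitat-belief levels at which to extract.
#' @param eps Numerical slack for the continue-vs-re-decide comparison.
#' @return A data frame with columns `activity`, `location`, `beta_G`,
#'   `c_d`, `boundary` (`"lower"`/`"upper"`), `theta`, and
#'   `empty_initiation`.
#' @export
extract_thresholds <- function(sol, activity = c("feed", "assess"),
                               location = "patch",
                               beta_G_levels = c(0.2, 0.5, 0.8),
                               eps = 1e-9) {
  activity <- match.arg(activity)
  if (!sol$interruptible)
    stop("thresholds are defined for interruptible solutions", call. = FALSE)
  if (!(activity %in% legal_actions(location)))
    stop("activity '", activity, "' is illegal in '", location, "'",
         call. = FALSE)
  g <- sol$grid
  K <- max(sol$tau_steps)
  cont <- sol$continue_value[[location]][[activity]][, K]
  V <- sol$value[[location]]
  pol <- sol$policy[[location]]$action
  boundaries <- if (activity == "feed") "upper" else c("lower", "upper")
  rows <- list()
  for (bg in beta_G_levels) {
    j <- which.min(abs(g$points - bg))
    idx <- .grid_index(g, seq_len(g$n), j)
    keep_going <- cont[idx] >= V[idx] - eps
    init <- pol[idx] == activity
    if (!any(init)) {
      for (bnd in boundaries) {
        rows[[length(rows) + 1L]] <- data.frame(
          activity = activity, location = location,
          beta_G = g$points[j], c_d = sol$params$c_d, boundary = bnd,
          theta = NA_real_, empty_initiation = TRUE)
      }
      next
    }
    # the continuation run containing (or nearest to) the initiation set
    runs <- rle(keep_going)
    hi <- cumsum(runs$lengths); lo <- hi - runs$lengths + 1L
    cand <- which(runs$values)
    anchor <- which(init)[ceiling(sum(init) / 2)]
    inside <- cand[lo[cand] <= anchor & hi[cand] >= anchor]
    pick <- if (length(inside)) inside[1] else
      cand[which.min(pmin(abs(lo[cand] - anchor), abs(hi[cand] - anchor)))]
    for (bnd in boundaries) {
      theta <- if (bnd == "upper") g$points[hi[pick]] else g$points[lo[pick]]
      rows[[length(rows) + 1L]] <- data.frame(
        activity = activity, location = location,
        beta_G = g$points[j], c_d = sol$params$c_d, boundary = bnd,
        theta = theta, empty_initiation = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fit linear approximations to interruption thresholds
#'
#' Least-squares planes `theta ~ w0 + w1 * beta_G + w2 * c_d`, fitted
#' separately per (activity, location, boundary) over the rows of a
#' threshold table (typically pooled across several decision costs).
#' Rows with empty initiation sets are excluded, not imputed.
#'
#' @param tab A data frame of [extract_thresholds()] rows.
#' @return A `threshold_fit`: list with `coefficients` (data frame:
#'   `activity`, `location`, `boundary`, `w0`, `w1_beta_G`, `w2_c_d`,
#'   `rmse`, `n`) and the fitted `models`.
#' @export
fit_linear_thresholds <- function(tab) {
  tab <- tab[!tab$empty_initiation & !is.na(tab$theta), , drop = FALSE]
  keys <- unique(tab[, c("activity", "location", "boundary")])
  coefs <- list(); models <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- merge(tab, keys[k, , drop = FALSE])
    if (nrow(sub) < 3)
      stop("need at least 3 threshold rows per boundary to fit (",
           paste(keys[k, ], collapse = "/"), ")", call. = FALSE)
    # degenerate designs (single beta_G or c_d level) drop that term
    form <- theta ~ beta_G + c_d
    if (length(unique(sub$beta_G)) < 2) form <- theta ~ c_d
    if (length(unique(sub$c_d)) < 2)
      form <- if (length(unique(sub$beta_G)) < 2) theta ~ 1 else theta ~ beta_G
    fit <- stats::lm(form, data = sub)
    cf <- stats::coef(fit)
    key_id <- paste(keys[k, ], collapse = ".")
    models[[key_id]] <- fit
    coefs[[k]] <- data.frame(
      keys[k, , drop = FALSE],
      w0 = unname(cf["(Intercept)"]),
      w1_beta_G = if ("beta_G" %in% names(cf)) unname(cf["beta_G"]) else 0,
      w2_c_d = if ("c_d" %in% names(cf)) unname(cf["c_d"]) else 0,
      rmse = sqrt(mean(stats::residuals(fit)^2)), n = nrow(sub))
  }
  structure(list(coefficients = do.call(rbind, coefs), models = models),
            class = "threshold_fit")
}

#' Predict a threshold from a linear fit
#'
#' @param fit A [fit_linear_thresholds()] object.
#' @param activity,location,boundary Which boundary.
#' @param beta_G,c_d Predictors.
#' @return The predicted threshold, clipped to \[0, 1\]; `NA` if the
#'   boundary was not fitted.
#' @export
predict_threshold <- function(fit, activity, location, boundary,
                              beta_G, c_d) {
  cf <- fit$coefficients
  row <- cf[cf$activity == activity & cf$location == location &
              cf$boundary == boundary, , drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  pmin(pmax(row$w0 + row$w1_beta_G * beta_G + row$w2_c_d * c_d, 0), 1)
}

#' Evaluate the threshold-approximated interruptible policy
#'
#' Runs the matched-trial comparison with interruption triggered by the
#' fitted linear thresholds instead of the exact value comparison: an
#' ongoing `feed` is interrupted when `beta_P` exceeds its upper
#' threshold, an ongoing `assess` when `beta_P` leaves its
#' \[lower, upper\] band. `freeze`, whose initiation set is too sparse to
#' support a stable fit, keeps the exact interrupt test. Action and
#' duration choices still come from the exact interruptible solution.
#'
#' @param fit A [fit_linear_thresholds()] object.
#' @param p A [model_params()] object.
#' @param c_d_grid Decision costs to evaluate.
#' @param proto A [protocol()].
#' @param n_trials Matched trials per policy per cost.
#' @param seed Base seed.
#' @param solutions Optional pre-solved list keyed `"c_d=<x>"` with
#'   fields `nonint`, `int`.
#' @param ... Passed to [value_iteration()].
#' @return Data frame: `c_d`, `ratio_approx`
#'   (non-interrupt / approx-interrupt mean reward), `ratio_exact`,
#'   `mean_reward_nonint`, `mean_reward_approx`, `mean_reward_int`.
#' @export
evaluate_approx_policy <- function(fit, p, c_d_grid = seq(0.05, 0.4, 0.05),
                                   proto = protocol(), n_trials = 200,
                                   seed = 1, solutions = NULL, ...) {
  rows <- list()
  for (cd in c_d_grid) {
    pk <- p; pk$c_d <- cd
    key <- sprintf("c_d=%g", cd)
    if (!is.null(solutions) && !is.null(solutions[[key]])) {
      sn <- solutions[[key]]$nonint; si <- solutions[[key]]$int
    } else {
      sn <- value_iteration(pk, interruptible = FALSE, ...)
      si <- value_iteration(pk, interruptible = TRUE, ...)
    }
    # thresholds mark the last belief at which continuing still wins, at
    # grid resolution; the crossing test therefore compares the belief's
    # nearest grid value against theta (matching the exact rule's
    # nearest-node lookup)
    d_beta <- p$d_beta
    thr_fn <- function(act, location, bp, bg) {
      bp_g <- round(bp / d_beta) * d_beta
      if (act == "feed") {
        up <- predict_threshold(fit, "feed", location, "upper", bg, cd)
        !is.na(up) && bp_g > up + 1e-9
      } else {
        lo <- predict_threshold(fit, "assess", location, "lower", bg, cd)
        up <- predict_threshold(fit, "assess", location, "upper", bg, cd)
        (!is.na(lo) && bp_g < lo - 1e-9) || (!is.na(up) && bp_g > up + 1e-9)
      }
    }
    bn <- .run_batch(sn, proto, n_trials, seed)
    bi <- .run_batch(si, proto, n_trials, seed)
    bapx <- .run_batch(si, proto, n_trials, seed, thresholds_fn = thr_fn)
    rows[[length(rows) + 1L]] <- data.frame(
      c_d = cd,
      ratio_approx = bn$mean_reward / bapx$mean_reward,
      ratio_exact = bn$mean_reward / bi$mean_reward,
      mean_reward_nonint = bn$mean_reward,
      mean_reward_approx = bapx$mean_reward,
      mean_reward_int = bi$mean_reward)
  }
  do.call(rbind, rows)
}

#' Interruption thresholds as a function of cue reliability
#'
#' Re-solves the interruptible model over a grid of true-positive cue
#' rates (indirect `lambda_oi_plus` or direct `lambda_od_plus`) and
#' decision costs, extracting thresholds at a fixed habitat belief.
#'
#' @param p A [model_params()] object (baseline).
#' @param channel `"oi"` or `"od"`: which cue's true-positive rate to vary.
#' @param lambda_values Values for the varied rate.
#' @param c_d_grid Decision costs.
#' @param activity,location Passed to [extract_thresholds()].
#' @param beta_G Fixed habitat-belief level (default 0.5).
#' @param ... Passed to [value_iteration()].
#' @return A threshold table with an extra `lambda_setting` column.
#' @export
sweep_cue_reliability <- function(p, channel = c("oi", "od"),
                                  lambda_values, c_d_grid,
                                  activity = "feed", location = "patch",
                                  beta_G = 0.5, ...) {
  channel <- match.arg(channel)
  field <- if (channel == "oi") "lambda_oi_plus" else "lambda_od_plus"
  rows <- list()
  for (lv in lambda_values) {
    for (cd in c_d_grid) {
      pk <- p; pk[[field]] <- lv; pk$c_d <- cd
      si <- value_iteration(validate_params(pk), interruptible = TRUE, ...)
      tab <- extract_thresholds(si, activity, location,
                                beta_G_levels = beta_G)
      tab$lambda_setting <- sprintf("%s+=%g", channel, lv)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  do.call(rbind, rows)
}
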