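#' Enumerate the stochastic consequences of one step of an action
#'
#' For beliefs `b` (vectorized), enumerates every joint outcome of a single
#' `dt`-step of `action` performed at `location`. Within a step the order
#' of events is: detection (while exposed, with probability
#' `beta_P * (1 - exp(-delta_a * dt))` -- the predator must already be
#' present), then the hidden-state transitions, then cue emission and
#' feeding encounters from the post-transition state. Branch probabilities
#' are the exact path probabilities of this generative order (detection and
#' cue emission are conditionally independent given the hidden state), so
#' they sum to exactly 1. Each branch carries the posterior belief that the
#' animal's own filter would hold afterwards -- the filter conditions on
#' cues and feeding outcomes but, like the planner, not on having survived
#' the step -- together with the branch reward and a terminal flag for
#' capture.
#'
#' @param p A [model_params()] object.
#' @param location `"refuge"` or `"patch"`.
#' @param action A legal action at `location`.
#' @param b A [belief()] (components may be vectors of length m).
#' @return A list of branches; each branch is a list with fields `prob`,
#'   `beta_P`, `beta_G` (length-m vectors), `reward` (length m), `capture`
#'   (logical), and `label`.
#' @export
step_branches <- function(p, location, action, b) {
  if (!(action %in% legal_actions(location)))
    stop("action '", action, "' is illegal in location '", location, "'",
         call. = FALSE)
  dt <- p$dt
  prior <- propagate_belief_step(b, p)
  q <- prior$beta_P        # agent's propagated predator prior (for Bayes)
  h <- prior$beta_G
  q0 <- b$beta_P           # step-start belief (sets detection risk)

  d <- if (.is_exposed(location, action)) {
    1 - exp(-p$delta_by_action[[action]] * dt)
  } else 0
  # true survive-and-end-state path masses given the generative order
  p_AP <- 1 - exp(-p$gamma_AP * dt)
  p_PA <- 1 - exp(-p$gamma_PA * dt)
  w_P <- q0 * (1 - d) * (1 - p_PA) + (1 - q0) * p_AP
  w_A <- q0 * (1 - d) * p_PA + (1 - q0) * (1 - p_AP)

  oi_outcomes <- if (action == "rest") "unavailable" else c("seen", "not_seen")
  od_outcomes <- if (action == "assess") c("seen", "not_seen") else "unavailable"
  feed_outcomes <- if (action == "feed") c("rich", "poor", "none") else "unavailable"

  # habitat channel: probability and posterior per feeding outcome
  hab <- lapply(feed_outcomes, function(fo) {
    lik <- switch(fo,
      rich = c(p$rho_rG, p$rho_rB) * dt,
      poor = c(p$rho_pG, p$rho_pB) * dt,
      none = c(1 - (p$rho_rG + p$rho_pG) * dt,
               1 - (p$rho_rB + p$rho_pB) * dt),
      unavailable = c(1, 1))
    num <- lik[1] * h
    den <- num + lik[2] * (1 - h)
    list(outcome = fo,
         prob = den,
         post = ifelse(den > 0, num / den, h),
         reward = switch(fo, rich = p$r_feed_rich * dt,
                         poor = p$r_feed_poor * dt, 0))
  })

  r_act <- .action_reward_rate(p, action) * dt
  branches <- list()
  for (oi in oi_outcomes) {
    li <- .cue_likelihood(oi, p$lambda_oi_plus, p$lambda_oi_minus, dt)
    for (od in od_outcomes) {
      ld <- .cue_likelihood(od, p$lambda_od_plus, p$lambda_od_minus, dt)
      L_plus <- li[["plus"]] * ld[["plus"]]
      L_minus <- li[["minus"]] * ld[["minus"]]
      # true joint probability of surviving and seeing this cue combination
      pr_pred <- w_P * L_plus + w_A * L_minus
      num <- q * L_plus
      den <- num + (1 - q) * L_minus
      bp_post <- ifelse(den > 0, num / den, q)
      for (hb in hab) {
        branches[[length(branches) + 1L]] <- list(
          prob = pr_pred * hb$prob,
          beta_P = bp_post,
          beta_G = hb$post,
          reward = rep(r_act + hb$reward, length.out = length(q)),
          capture = FALSE,
          label = paste0("oi=", oi, ",od=", od, ",feed=", hb$outcome)
        )
      }
    }
  }
  if (d > 0) {
    # captured: the predator was certainly present at the step's start, so
    # the belief carried to the post-capture decision is that certainty
    # propagated through the step's transition
    branches[[length(branches) + 1L]] <- list(
      prob = q0 * d,
      beta_P = rep(exp(-p$gamma_PA * dt), length(q)),
      beta_G = h,
      reward = rep(p$r_pred, length(q)),
      capture = TRUE,
      label = "capture"
    )
  }
  branches
}

#' Build the sparse one-step operator of an action on the belief grid
#'
#' Assembles the branches of [step_branches()] at every grid point into
#' sparse matrices acting on value vectors: `P_cont` carries the
#' non-capture branches onto the grid at the current location (via bilinear
#' interpolation of the posterior belief, or nearest-node assignment), and
#' `P_term` carries the capture branch onto the refuge grid, where the
#' animal makes a fresh decision after being caught. `r` is the expected
#' immediate reward at each grid point, including the capture penalty mass.
#'
#' @param p A [model_params()] object.
#' @param g A [belief_grid()].
#' @param location `"refuge"` or `"patch"`.
#' @param action A legal action at `location`.
#' @param grid_mode `"bilinear"` or `"nearest"` posterior-to-grid mapping.
#' @return A `step_operator`: list with `P_cont`, `P_term` (sparse
#'   `dgCMatrix`, `N x N`), `r` (length `N`), `location`, `action`,
#'   `end_location` (location after the full commitment completes).
#' @export
build_step_operator <- function(p, g, location, action,
                                grid_mode = c("bilinear", "nearest")) {
  grid_mode <- match.arg(grid_mode)
  b <- .grid_beliefs(g)
  branches <- step_branches(p, location, action, b)

  rows_c <- list(); cols_c <- list(); vals_c <- list()
  rows_t <- list(); cols_t <- list(); vals_t <- list()
  r <- numeric(g$N)
  idx <- seq_len(g$N)
  for (br in branches) {
    r <- r + br$prob * br$reward
    if (grid_mode == "bilinear") {
      w <- .bilinear_weights(br$beta_P, br$beta_G, g)
      i <- rep(idx, 4L)
      j <- as.vector(w$index)
      x <- as.vector(w$weight) * rep(br$prob, 4L)
    } else {
      i_P <- pmin(pmax(round(br$beta_P / g$d_beta), 0), g$n - 1L) + 1L
      i_G <- pmin(pmax(round(br$beta_G / g$d_beta), 0), g$n - 1L) + 1L
      i <- idx
      j <- .grid_index(g, i_P, i_G)
      x <- br$prob
    }
    keep <- x != 0
    if (br$capture) {
      rows_t[[length(rows_t) + 1L]] <- i[keep]
      cols_t[[length(cols_t) + 1L]] <- j[keep]
      vals_t[[length(vals_t) + 1L]] <- x[keep]
    } else {
      rows_c[[length(rows_c) + 1L]] <- i[keep]
      cols_c[[length(cols_c) + 1L]] <- j[keep]
      vals_c[[length(vals_c) + 1L]] <- x[keep]
    }
  }
  P_cont <- Matrix::sparseMatrix(
    i = unlist(rows_c), j = unlist(cols_c), x = unlist(vals_c),
    dims = c(g$N, g$N))
  P_term <- if (length(rows_t)) {
    Matrix::sparseMatrix(
      i = unlist(rows_t), j = unlist(cols_t), x = unlist(vals_t),
      dims = c(g$N, g$N))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(g$N, g$N))
  }
  end_location <- switch(action,
    transit = "patch",
    escape = if (p$escape_effective) "refuge" else "patch",
    location)
  structure(list(P_cont = P_cont, P_term = P_term, r = r,
                 location = location, action = action,
                 end_location = end_location, grid_mode = grid_mode),
            class = "step_operator")
}
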