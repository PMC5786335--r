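#' Q-values of committing to an action for each allowed duration
#'
#' Backward recursion over the steps of a commitment. With `k` steps
#' remaining, the value of continuing is
#' `C_k = r + e^(-alpha dt) * (P_cont C_(k-1) + P_term V_refuge)`, with
#' `C_0` equal to the decision value at the activity's end location
#' (relocation for `transit`/`escape` happens when the commitment
#' completes; capture relocates to the refuge immediately). If
#' `interruptible`, the continuation at every intermediate step is
#' `max(C_(k-1), V_here)`: interruption itself is free, and re-deciding is
#' worth the decision value `V` (which already carries the charge `c_d`).
#' Only `feed`, `assess` and `freeze` can be interrupted: `transit` and
#' `escape` are ballistic relocations, and beliefs evolve deterministically
#' during `rest`, so nothing can be learned mid-commitment that was not
#' known when the commitment was chosen.
#'
#' @param op A [build_step_operator()] result.
#' @param V Named list of decision-value vectors (`refuge`, `patch`).
#' @param p A [model_params()] object.
#' @param interruptible Logical.
#' @return An `N x K` matrix whose column `k` holds the value of committing
#'   to the action for `k` steps (`K = max(tau_set) / dt`).
#' @export
activity_value <- function(op, V, p, interruptible = FALSE) {
  disc <- exp(-p$alpha * p$dt)
  K <- round(max(p$tau_set) / p$dt)
  base <- op$r + disc * as.vector(op$P_term %*% V$refuge)
  cont <- V[[op$end_location]]
  can_interrupt <- interruptible && .is_interruptible_action(op$action)
  Q <- matrix(0, length(cont), K)
  V_here <- V[[op$location]]
  for (k in seq_len(K)) {
    Ck <- base + disc * as.vector(op$P_cont %*% cont)
    Q[, k] <- Ck
    cont <- if (can_interrupt) pmax(Ck, V_here) else Ck
  }
  Q
}

# operators for every legal (location, action) pair
.build_all_operators <- function(p, g, grid_mode) {
  lapply(stats::setNames(nm = c("refuge", "patch")), function(loc) {
    lapply(stats::setNames(nm = legal_actions(loc)), function(a) {
      build_step_operator(p, g, loc, a, grid_mode = grid_mode)
    })
  })
}

# actions whose commitments can be cut short by an interrupt
.is_interruptible_action <- function(action) {
  action %in% c("feed", "assess", "freeze")
}

# column order for the stacked Q matrix of one location. Value ties are
# broken deterministically: ballistic activities prefer the shortest
# duration; interrupt-capable activities in the interruptible regime
# prefer the longest (commit provisionally, rely on the interrupt); then
# the canonical action order decides.
.activity_columns <- function(actions, tau_set, interruptible = FALSE) {
  cols <- expand.grid(action = actions, tau = tau_set,
                      stringsAsFactors = FALSE)
  tau_key <- ifelse(interruptible & .is_interruptible_action(cols$action),
                    max(tau_set) - cols$tau, cols$tau)
  cols[order(tau_key, .action_order[cols$action]), , drop = FALSE]
}

#' Solve the belief-state semi-Markov decision problem by value iteration
#'
#' Iterates `V(b) <- max over legal activities of (-c_d + Q(b; a, tau))` on
#' the discretized belief grid, jointly over the two locations, until the
#' sup-norm change falls below `tol`. The optimal activity at each grid
#' point is extracted with deterministic tie-breaking (shorter duration
#' first, then the canonical action order rest/feed, assess, freeze,
#' transit, escape).
#'
#' @param p A [model_params()] object (its `c_d`, `alpha`, `d_beta`,
#'   `tau_set`, `dt` and `escape_effective` fields all matter here).
#' @param interruptible Should the solved policy be allowed to interrupt
#'   ongoing activities (free interruption, re-decision at cost `c_d`)?
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is reported with the
#'   final residual.
#' @param grid_mode Posterior-to-grid mapping, `"bilinear"` (default) or
#'   `"nearest"`.
#' @param verbose Print the residual every 25 sweeps.
#' @return A `forage_solution`: decision values, the optimal policy
#'   (`action`, `tau` per grid point and location), the per-activity
#'   continue-value tables used by the interruption rule, and convergence
#'   diagnostics.
#' @export
value_iteration <- function(p, interruptible = FALSE, tol = 1e-6,
                            max_iter = 10000,
                            grid_mode = c("bilinear", "nearest"),
                            verbose = FALSE) {
  grid_mode <- match.arg(grid_mode)
  p <- validate_params(p)
  tau_steps <- p$tau_set / p$dt
  if (any(abs(tau_steps - round(tau_steps)) > 1e-8))
    stop("every tau in 'tau_set' must be a multiple of dt", call. = FALSE)
  tau_steps <- as.integer(round(tau_steps))
  g <- belief_grid(p$d_beta)
  ops <- .build_all_operators(p, g, grid_mode)
  locs <- c("refuge", "patch")
  V <- stats::setNames(lapply(locs, function(l) numeric(g$N)), locs)

  iter <- 0L
  residual <- Inf
  while (iter < max_iter && residual > tol) {
    iter <- iter + 1L
    V_new <- V
    for (loc in locs) {
      best <- NULL
      for (a in legal_actions(loc)) {
        Q <- activity_value(ops[[loc]][[a]], V, p, interruptible)
        m <- do.call(pmax, lapply(tau_steps, function(k) Q[, k]))
        best <- if (is.null(best)) m else pmax(best, m)
      }
      V_new[[loc]] <- best - p$c_d
    }
    residual <- max(abs(V_new$refuge - V$refuge),
                    abs(V_new$patch - V$patch))
    V <- V_new
    if (verbose && iter %% 25L == 0L)
      message("sweep ", iter, "  residual ", signif(residual, 3))
  }

  # final policy extraction and continue-value tables at the converged V
  policy <- list()
  continue_value <- list()
  for (loc in locs) {
    acts <- legal_actions(loc)
    Qk <- lapply(stats::setNames(nm = acts), function(a) {
      activity_value(ops[[loc]][[a]], V, p, interruptible)
    })
    continue_value[[loc]] <- Qk
    cols <- .activity_columns(acts, p$tau_set, interruptible)
    Qstack <- vapply(seq_len(nrow(cols)), function(j) {
      Qk[[cols$action[j]]][, tau_steps[match(cols$tau[j], p$tau_set)]]
    }, numeric(g$N))
    row_max <- do.call(pmax, as.data.frame(Qstack))
    eps <- 1e-9 * (1 + abs(row_max))
    pick <- max.col(-(Qstack < row_max - eps), ties.method = "first")
    policy[[loc]] <- list(action = cols$action[pick], tau = cols$tau[pick])
  }

  structure(list(
    params = p, grid = g, interruptible = interruptible,
    grid_mode = grid_mode, value = V, policy = policy,
    continue_value = continue_value, tau_steps = tau_steps,
    iterations = iter, residual = residual, converged = residual <= tol,
    tol = tol
  ), class = "forage_solution")
}

#' @export
print.forage_solution <- function(x, ...) {
  cat(sprintf(
    "Foraging policy (%s, c_d=%.3g, d_beta=%.3g, %s grid): %d sweeps, residual %.2g%s\n",
    if (x$interruptible) "interruptible" else "non-interruptible",
    x$params$c_d, x$params$d_beta, x$grid_mode, x$iterations, x$residual,
    if (x$converged) "" else " (NOT converged)"))
  for (loc in names(x$policy)) {
    tab <- table(x$policy[[loc]]$action)
    cat(" ", loc, ": ",
        paste(sprintf("%s %.0f%%", names(tab), 100 * tab / sum(tab)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize the regions of belief space occupied by each action
#'
#' For each location and each `beta_G` grid level, finds the maximal runs
#' of consecutive `beta_P` grid points sharing the same optimal action.
#'
#' @param sol A [value_iteration()] solution.
#' @return A data frame with columns `location`, `beta_G`, `action`,
#'   `beta_P_lo`, `beta_P_hi` (inclusive run endpoints), and `n_points`.
#' @export
policy_regions <- function(sol) {
  g <- sol$grid
  out <- list()
  for (loc in names(sol$policy)) {
    act <- matrix(sol$policy[[loc]]$action, g$n, g$n)
    for (j in seq_len(g$n)) {
      runs <- rle(act[, j])
      hi <- cumsum(runs$lengths)
      lo <- hi - runs$lengths + 1L
      out[[length(out) + 1L]] <- data.frame(
        location = loc, beta_G = g$points[j], action = runs$values,
        beta_P_lo = g$points[lo], beta_P_hi = g$points[hi],
        n_points = runs$lengths)
    }
  }
  do.call(rbind, out)
}
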