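#' Parameters of the single-location foraging example
#'
#' A stripped-down, undiscounted, terminating version of the model: the
#' animal feeds in a habitat where a predator arrives with probability
#' `p_arrive` per step and then stays. While the predator is present the
#' animal is caught with probability `p_catch` per step (penalty
#' `r_catch`, terminal). It can `feed` (reward `r_feed` per step, poor
#' predator information via the indirect cue), `assess` (reward 0, better
#' information: direct plus indirect cues), or `escape` (reward 0,
#' terminal). The objective is the expected undiscounted sum of rewards
#' minus decision costs.
#'
#' @param p_arrive Predator arrival probability per step.
#' @param p_catch Catch probability per step while the predator is present.
#' @param r_feed Feeding reward per step.
#' @param r_catch Penalty on capture (terminal).
#' @param c_d Decision cost per deliberation.
#' @param tau_set Allowed commitment durations, in steps.
#' @param d_beta Belief-grid resolution on `beta_P`.
#' @param lambda_oi_plus,lambda_oi_minus Per-step indirect-cue emission
#'   probabilities with the predator present / absent (available during
#'   `feed` and `assess`).
#' @param lambda_od_plus,lambda_od_minus Per-step direct-cue emission
#'   probabilities (available during `assess` only).
#' @return A validated `simple_params` object.
#' @export
simple_params <- function(p_arrive = 0.01, p_catch = 0.1,
                          r_feed = 1, r_catch = -100, c_d = 0,
                          tau_set = 1:15, d_beta = 0.01,
                          lambda_oi_plus = 0.5, lambda_oi_minus = 0.1,
                          lambda_od_plus = 0.9, lambda_od_minus = 0.1) {
  probs <- c(p_arrive = p_arrive, p_catch = p_catch,
             lambda_oi_plus = lambda_oi_plus,
             lambda_oi_minus = lambda_oi_minus,
             lambda_od_plus = lambda_od_plus,
             lambda_od_minus = lambda_od_minus)
  for (f in names(probs)) {
    if (probs[[f]] < 0 || probs[[f]] > 1)
      stop("'", f, "' must be a probability in [0, 1]", call. = FALSE)
  }
  if (length(tau_set) == 0 || any(tau_set <= 0) ||
      is.unsorted(tau_set, strictly = TRUE))
    stop("'tau_set' must be positive and strictly increasing", call. = FALSE)
  if (c_d < 0) stop("'c_d' must be non-negative", call. = FALSE)
  structure(list(p_arrive = p_arrive, p_catch = p_catch, r_feed = r_feed,
                 r_catch = r_catch, c_d = c_d,
                 tau_set = as.integer(tau_set), d_beta = d_beta,
                 lambda_oi_plus = lambda_oi_plus,
                 lambda_oi_minus = lambda_oi_minus,
                 lambda_od_plus = lambda_od_plus,
                 lambda_od_minus = lambda_od_minus),
            class = "simple_params")
}

# one-step branches of the simple model at beliefs `beta` (vectorized):
# capture (terminal) plus the surviving cue outcomes with their filter
# posteriors. Catch is evaluated at the step's start; the arrival
# transition follows; cues are emitted from the post-transition state.
.simple_branches <- function(sp, action, beta) {
  q0 <- beta
  q <- q0 + (1 - q0) * sp$p_arrive       # agent's propagated prior
  w_P <- q0 * (1 - sp$p_catch) + (1 - q0) * sp$p_arrive
  w_A <- (1 - q0) * (1 - sp$p_arrive)
  oi <- c("seen", "not_seen")
  od <- if (action == "assess") c("seen", "not_seen") else "unavailable"
  r_step <- if (action == "feed") sp$r_feed else 0
  branches <- list()
  for (o1 in oi) {
    li <- .cue_likelihood(o1, sp$lambda_oi_plus, sp$lambda_oi_minus, 1)
    for (o2 in od) {
      ld <- .cue_likelihood(o2, sp$lambda_od_plus, sp$lambda_od_minus, 1)
      L_plus <- li[["plus"]] * ld[["plus"]]
      L_minus <- li[["minus"]] * ld[["minus"]]
      num <- q * L_plus
      den <- num + (1 - q) * L_minus
      branches[[length(branches) + 1L]] <- list(
        prob = w_P * L_plus + w_A * L_minus,
        beta = ifelse(den > 0, num / den, q),
        reward = r_step, capture = FALSE,
        label = paste0("oi=", o1, ",od=", o2))
    }
  }
  branches[[length(branches) + 1L]] <- list(
    prob = q0 * sp$p_catch, beta = rep(1, length(q0)),
    reward = sp$r_catch, capture = TRUE, label = "capture")
  branches
}

# linear interpolation weights on the 1-D belief grid
.linear_weights_1d <- function(beta, pts) {
  n <- length(pts)
  d <- pts[2] - pts[1]
  u <- pmin(pmax(beta, 0), 1) / d
  i0 <- pmin(floor(u), n - 2)
  f <- u - i0
  list(i = cbind(as.integer(i0) + 1L, as.integer(i0) + 2L),
       w = cbind(1 - f, f))
}

# dense one-step operator of one simple-model action: continuation matrix
# (survival branches), expected reward, and capture probability
.simple_operator <- function(sp, action, pts) {
  n <- length(pts)
  branches <- .simple_branches(sp, action, pts)
  P <- matrix(0, n, n)
  r <- numeric(n)
  for (br in branches) {
    r <- r + br$prob * br$reward
    if (br$capture) next
    lw <- .linear_weights_1d(br$beta, pts)
    for (k in 1:2) {
      P[cbind(seq_len(n), lw$i[, k])] <-
        P[cbind(seq_len(n), lw$i[, k])] + br$prob * lw$w[, k]
    }
  }
  list(P = P, r = r)
}

#' Solve the single-location example by value iteration
#'
#' Value iteration over the 1-D belief grid on `beta_P`. `escape` and
#' capture are terminal with continuation value 0; rewards are
#' undiscounted. With `interruptible = TRUE`, `feed` and `assess`
#' commitments can be cut short at any intermediate step (free
#' interruption, re-decision at cost `c_d`); value ties between durations
#' are then broken toward the longest commitment, and toward the shortest
#' otherwise.
#'
#' @param sp A [simple_params()] object.
#' @param interruptible Logical.
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `simple_solution`: grid, values, policy (`action`, `tau` per
#'   grid point), continue-value tables, and convergence diagnostics.
#' @export
solve_simple <- function(sp, interruptible = FALSE, tol = 1e-9,
                         max_iter = 50000) {
  pts <- seq(0, 1, by = sp$d_beta)
  n <- length(pts)
  K <- max(sp$tau_set)
  ops <- lapply(stats::setNames(nm = c("feed", "assess")),
                function(a) .simple_operator(sp, a, pts))

  chain <- function(op, V, interrupt) {
    Q <- matrix(0, n, K)
    cont <- V
    for (k in seq_len(K)) {
      Ck <- op$r + as.vector(op$P %*% cont)
      Q[, k] <- Ck
      cont <- if (interrupt) pmax(Ck, V) else Ck
    }
    Q
  }

  V <- numeric(n)
  iter <- 0L
  residual <- Inf
  while (iter < max_iter && residual > tol) {
    iter <- iter + 1L
    Qf <- chain(ops$feed, V, interruptible)
    Qa <- chain(ops$assess, V, interruptible)
    V_new <- pmax(do.call(pmax, as.data.frame(Qf[, sp$tau_set, drop = FALSE])),
                  do.call(pmax, as.data.frame(Qa[, sp$tau_set, drop = FALSE])),
                  0) - sp$c_d
    residual <- max(abs(V_new - V))
    V <- V_new
  }

  Qk <- list(feed = chain(ops$feed, V, interruptible),
             assess = chain(ops$assess, V, interruptible))
  cols <- .activity_columns(c("feed", "assess"), sp$tau_set, interruptible)
  cols <- rbind(cols, data.frame(action = "escape", tau = min(sp$tau_set)))
  Qstack <- vapply(seq_len(nrow(cols)), function(j) {
    if (cols$action[j] == "escape") rep(0, n)
    else Qk[[cols$action[j]]][, cols$tau[j]]
  }, numeric(n))
  row_max <- do.call(pmax, as.data.frame(Qstack))
  eps <- 1e-9 * (1 + abs(row_max))
  pick <- max.col(-(Qstack < row_max - eps), ties.method = "first")

  structure(list(
    params = sp, points = pts,
    value = V,
    policy = list(action = cols$action[pick], tau = cols$tau[pick]),
    continue_value = Qk,
    iterations = iter, residual = residual, converged = residual <= tol,
    interruptible = interruptible, tol = tol
  ), class = "simple_solution")
}

#' @export
print.simple_solution <- function(x, ...) {
  cat(sprintf(
    "Simple foraging policy (%s, c_d=%.3g): %d sweeps, residual %.2g\n",
    if (x$interruptible) "interruptible" else "non-interruptible",
    x$params$c_d, x$iterations, x$residual))
  runs <- rle(x$policy$action)
  hi <- cumsum(runs$lengths); lo <- hi - runs$lengths + 1L
  for (k in seq_along(runs$values))
    cat(sprintf("  beta_P in [%.2f, %.2f]: %s\n",
                x$points[lo[k]], x$points[hi[k]], runs$values[k]))
  invisible(x)
}

#' Simulate trials of the single-location example
#'
#' Runs `n_trials` independent trials of the task under a solved policy.
#' Each trial starts with the predator absent and belief `beta_P = 0`, and
#' ends when the animal escapes or is caught. Per-trial random streams are
#' derived from `seed`, with each event channel (arrival, catch, indirect
#' cue, direct cue) consuming its own uniform at every step whether or not
#' the step's action uses it -- so two policies simulated with the same
#' `seed` face identical environments (common random numbers).
#'
#' @param sol A [solve_simple()] solution.
#' @param n_trials Number of trials.
#' @param seed Integer seed for the trial streams.
#' @param max_steps Safety cap on steps per trial.
#' @return A list with `trials` (data frame: `reward`, `steps`,
#'   `decisions` per trial) and aggregate means (`mean_reward`,
#'   `mean_steps`, `decisions_per_step`).
#' @export
simulate_simple <- function(sol, n_trials = 1000, seed = 1,
                            max_steps = 100000) {
  sp <- sol$params
  pts <- sol$points
  n_pts <- length(pts)
  interrupt_eps <- 1e-7
  reward <- steps <- decisions <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(seed + tr)
    u_cache <- matrix(stats::runif(4 * 512), ncol = 4)
    u_row <- 0L
    next_u <- function() {
      u_row <<- u_row + 1L
      if (u_row > nrow(u_cache)) {
        u_cache <<- rbind(u_cache, matrix(stats::runif(4 * 512), ncol = 4))
      }
      u_cache[u_row, ]
    }
    present <- FALSE
    beta <- 0
    tot <- 0; n_step <- 0L; n_dec <- 0L
    remaining <- 0L
    act <- ""
    done <- FALSE
    while (!done && n_step < max_steps) {
      if (remaining == 0L) {
        n_dec <- n_dec + 1L
        tot <- tot - sp$c_d
        i <- min(max(round(beta / sp$d_beta), 0), n_pts - 1) + 1
        act <- sol$policy$action[i]
        remaining <- sol$policy$tau[i]
        if (act == "escape") { n_step <- n_step + 1L; break }
      }
      u <- next_u()
      n_step <- n_step + 1L
      if (present && u[2] < sp$p_catch) {    # caught (start-of-step state)
        tot <- tot + sp$r_catch
        break
      }
      if (!present && u[1] < sp$p_arrive) present <- TRUE
      if (act == "feed") tot <- tot + sp$r_feed
      # cue emission from the post-transition state
      rate_oi <- if (present) sp$lambda_oi_plus else sp$lambda_oi_minus
      oi <- if (u[3] < rate_oi) "seen" else "not_seen"
      od <- "unavailable"
      if (act == "assess") {
        rate_od <- if (present) sp$lambda_od_plus else sp$lambda_od_minus
        od <- if (u[4] < rate_od) "seen" else "not_seen"
      }
      q <- beta + (1 - beta) * sp$p_arrive
      li <- .cue_likelihood(oi, sp$lambda_oi_plus, sp$lambda_oi_minus, 1)
      ld <- .cue_likelihood(od, sp$lambda_od_plus, sp$lambda_od_minus, 1)
      num <- li[["plus"]] * ld[["plus"]] * q
      den <- num + li[["minus"]] * ld[["minus"]] * (1 - q)
      beta <- if (den > 0) num / den else q
      remaining <- remaining - 1L
      if (remaining > 0L && sol$interruptible &&
          .is_interruptible_action(act)) {
        i <- min(max(round(beta / sp$d_beta), 0), n_pts - 1) + 1
        if (sol$value[i] > sol$continue_value[[act]][i, remaining] +
            interrupt_eps) {
          remaining <- 0L    # interrupt: free, re-decide next step
        }
      }
    }
    reward[tr] <- tot; steps[tr] <- n_step; decisions[tr] <- n_dec
  }
  list(trials = data.frame(reward = reward, steps = steps,
                           decisions = decisions),
       mean_reward = mean(reward), mean_steps = mean(steps),
       decisions_per_step = sum(decisions) / sum(steps))
}
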