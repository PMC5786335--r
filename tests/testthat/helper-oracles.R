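# Independent oracles used across the test files. These deliberately avoid
# the package's sparse-operator / value-iteration code paths: plain loops,
# explicit enumeration, closed forms.

# Brute-force discrete HMM forward filter for one two-state chain
# (state 1 = "plus" hypothesis, e.g. predator present). `flip_up` is the
# per-step probability of entering state 1 from state 2, `flip_down` the
# reverse. `lik` is an n x 2 matrix of per-step observation likelihoods
# under (plus, minus). Returns the filtered P(state 1) after each step.
hmm_forward_oracle <- function(prior, flip_up, flip_down, lik) {
  Tm <- matrix(c(1 - flip_down, flip_down,
                 flip_up, 1 - flip_up), 2, 2, byrow = TRUE)
  b <- c(prior, 1 - prior)
  out <- numeric(nrow(lik))
  for (t in seq_len(nrow(lik))) {
    b <- as.vector(t(Tm) %*% b)            # propagate
    b <- b * lik[t, ]                      # observe
    b <- b / sum(b)
    out[t] <- b[1]
  }
  out
}

# Brute-force finite-horizon expansion of the discretized belief problem:
# repeated application of a plain-R Bellman backup built directly from
# step_branches(), with its own nearest-node grid mapping and no sparse
# algebra. Run for enough sweeps that the discount tail is below tol;
# cross-checks value_iteration(grid_mode = "nearest") on miniature models.
plain_value_iteration <- function(p, interruptible = FALSE,
                                  n_sweeps = 200) {
  g <- belief_grid(p$d_beta)
  gb <- interforage:::.grid_beliefs(g)
  disc <- exp(-p$alpha * p$dt)
  K <- max(p$tau_set) / p$dt
  nearest <- function(bp, bg) {
    iP <- pmin(pmax(round(bp / g$d_beta), 0), g$n - 1) + 1
    iG <- pmin(pmax(round(bg / g$d_beta), 0), g$n - 1) + 1
    as.integer(iP + (iG - 1) * g$n)
  }
  # branch tables do not depend on V: precompute them
  tables <- list()
  for (loc in c("refuge", "patch")) {
    for (a in legal_actions(loc)) {
      br <- step_branches(p, loc, a, gb)
      tables[[paste(loc, a)]] <- lapply(br, function(b) {
        list(prob = b$prob, idx = nearest(b$beta_P, b$beta_G),
             reward = b$reward, capture = b$capture)
      })
    }
  }
  V <- list(refuge = numeric(g$N), patch = numeric(g$N))
  for (sweep in seq_len(n_sweeps)) {
    V_new <- V
    for (loc in c("refuge", "patch")) {
      best <- rep(-Inf, g$N)
      for (a in legal_actions(loc)) {
        end_loc <- switch(a, transit = "patch",
                          escape = if (p$escape_effective) "refuge"
                                   else "patch",
                          loc)
        can_int <- interruptible && a %in% c("feed", "assess", "freeze")
        W <- V[[end_loc]]
        for (k in seq_len(K)) {
          Ck <- numeric(g$N)
          for (b in tables[[paste(loc, a)]]) {
            contv <- if (b$capture) V$refuge[b$idx] else W[b$idx]
            Ck <- Ck + b$prob * (b$reward + disc * contv)
          }
          if (k %in% (p$tau_set / p$dt)) best <- pmax(best, Ck)
          W <- if (can_int) pmax(Ck, V[[loc]]) else Ck
        }
      }
      V_new[[loc]] <- best - p$c_d
    }
    V <- V_new
  }
  V
}

# closed-form least squares through the normal equations
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# a tiny, fast parameterization of the full model used by many tests
tiny_params <- function(...) {
  model_params(d_beta = 0.1, tau_set = c(1, 2, 3), ...)
}

coarse_params <- function(...) {
  model_params(d_beta = 0.05, ...)
}
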