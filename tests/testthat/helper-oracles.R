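# Independent brute-force oracles used across test files.

# Absorbing-Markov-chain computation on the lattice {0..M} with absorbing
# boundaries: splitting probabilities from the fundamental matrix, and
# conditioned expected absorption times via the Doob-transformed chain.
# Dense linear algebra throughout - an independent route from the package's
# closed forms and tridiagonal solves.
absorbing_chain_oracle <- function(model, M, start, target) {
  n <- 0:M
  up <- transition_up(model, n)
  dn <- transition_down(model, n)
  P <- matrix(0, M + 1, M + 1)
  for (i in seq(2, M)) {  # interior states 1..M-1 (row i = state i-1)
    P[i, i + 1] <- up[i]
    P[i, i - 1] <- dn[i]
    P[i, i] <- 1 - up[i] - dn[i]
  }
  P[1, 1] <- 1
  P[M + 1, M + 1] <- 1
  Q <- P[2:M, 2:M, drop = FALSE]
  R <- P[2:M, c(1, M + 1), drop = FALSE]
  Nf <- solve(diag(M - 1) - Q)
  B <- Nf %*% R                        # cols: absorbed at 0, absorbed at M
  h <- B[, if (target == M) 2 else 1]  # P(absorbed at target | start)
  Qh <- Q * outer(1 / h, h)            # conditioned chain
  t_cond <- solve(diag(M - 1) - Qh, rep(1, M - 1))
  list(split = h[start], time = t_cond[start])
}

# Burst generation probability and expected duration assembled from the
# oracle pieces (forward phase on {0..H}, backward phase on {0..H+1}).
burst_oracle <- function(model, H) {
  fwd <- if (H == 1) list(split = 1, time = 0) else
    absorbing_chain_oracle(model, H, 1, H)
  bwd <- absorbing_chain_oracle(model, H + 1, H, 0)
  list(p_gen = transition_up(model, 0L) * fwd$split * bwd$split,
       t_gen = 1 / transition_up(model, 0L) + fwd$time + bwd$time)
}

# Monte-Carlo splitting of the focal-clone chain (n0 -> upper before lower).
mc_splitting <- function(model, n0, lower, upper, n_reps, seed) {
  set.seed(seed)
  r <- hncstem:::cpp_splitting_mc(model$epsilon, model$epsilon, model$lambda,
                                  model$K, model$N, n0, lower, upper, n_reps)
  r$hits_upper / r$n_reps
}
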