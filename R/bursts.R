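#' First-passage theory of clonal bursts
#'
#' A burst of height `H` is an excursion of a focal clone from size 0 up to a
#' maximum of exactly `H` and back to 0 without ever reaching `H + 1`. Bursts
#' are the signature of the hNC regime: neutral drift pushes clones toward
#' extinction or fixation, but infrequent master-cell supply keeps restarting
#' excursions from 0. These functions give the exact per-step-at-zero
#' generation probability and expected duration of bursts on the embedded
#' single-clone birth-death chain.
#'
#' @name burst-analytics
NULL

# log of rho_j = prod_{k=1..j} r_-(k)/r_+(k), j = 0..jmax, in log space:
# the ratios can be large for small epsilon.
log_rho <- function(model, jmax) {
  k <- seq_len(jmax)
  c(0, cumsum(log(transition_down(model, k)) - log(transition_up(model, k))))
}

check_height <- function(H, hi) {
  if (length(H) != 1 || !is.numeric(H) || H != round(H) || H < 1 || H > hi)
    stop(sprintf("burst height 'H' must be an integer in [1, %d]", hi))
  as.integer(H)
}

#' Forward splitting probability of a burst
#'
#' Probability that the focal clone, starting from size 1, reaches `H` before
#' returning to 0:
#' \deqn{P_{fwd}(1;H) = \left(1 + \sum_{j=1}^{H-1} \prod_{k=1}^{j}
#'   \frac{r_-(k)}{r_+(k)}\right)^{-1}.}
#' In the neutral limit (`epsilon = 0`) all ratios are 1 and the classic
#' result `1/H` is recovered.
#'
#' @param model An [hnc_model()] object.
#' @param H Burst height, integer in `[1, N]`.
#' @return Probability in `[0, 1]`.
#' @export
splitting_forward <- function(model, H) {
  stopifnot(inherits(model, "hnc_model"))
  H <- check_height(H, model$N)
  if (H == 1L) return(1)
  lr <- log_rho(model, H - 1L)
  exp(-log_sum_exp(lr))
}

#' Backward splitting probability of a burst
#'
#' Probability that the focal clone, starting from size `H`, returns to 0
#' before reaching `H + 1`:
#' \deqn{P_{bwd}(H;H+1) = \left(1 + \sum_{j=1}^{H} \prod_{k=j}^{H}
#'   \frac{r_+(k)}{r_-(k)}\right)^{-1},}
#' which equals `1/(H+1)` in the neutral limit.
#'
#' @inheritParams splitting_forward
#' @param H Burst height, integer in `[1, N - 1]`.
#' @export
splitting_backward <- function(model, H) {
  stopifnot(inherits(model, "hnc_model"))
  H <- check_height(H, model$N - 1L)
  lr <- log_rho(model, H)
  exp(lr[H + 1L] - log_sum_exp(lr))
}

# running log(cumsum(exp(x))) without leaving log space
cum_log_sum_exp <- function(x) {
  out <- numeric(length(x))
  acc <- x[1]
  out[1] <- acc
  for (i in seq_along(x)[-1]) {
    a <- max(acc, x[i])
    acc <- a + log(exp(acc - a) + exp(x[i] - a))
    out[i] <- acc
  }
  out
}

# Interior splitting probabilities on the lattice {0..M}:
# P(hit M before 0 | start n) for n = 0..M, from the same rho weights.
splitting_forward_profile <- function(model, M) {
  lr <- log_rho(model, M - 1L)                 # log rho_0..rho_{M-1}
  ls <- cum_log_sum_exp(lr)                    # ls[n] = log sum_{j<n} rho_j
  c(0, exp(ls - ls[M]))                        # n = 0..M
}

# P(hit 0 before M | start n) for n = 0..M.
splitting_backward_profile <- function(model, M) {
  1 - splitting_forward_profile(model, M)
}

#' Burst generation probability
#'
#' Probability, per step spent at clone size 0, that a burst of height exactly
#' `H` is generated:
#' \deqn{P_{gen}(H) = r_+(0) \, P_{fwd}(1;H) \, P_{bwd}(H;H+1).}
#' With `epsilon = 0` the clone cannot leave 0 (`r_+(0) = 0`) and the result
#' is 0 with a warning: the NC regime produces no bursts.
#'
#' @inheritParams splitting_backward
#' @return Probability in `[0, r_+(0)]`.
#' @export
burst_probability <- function(model, H) {
  stopifnot(inherits(model, "hnc_model"))
  H <- check_height(H, model$N - 1L)
  if (model$epsilon == 0) {
    warning("epsilon = 0: r_+(0) = 0, no bursts can start from size 0")
    return(0)
  }
  transition_up(model, 0L) * splitting_forward(model, H) *
    splitting_backward(model, H)
}

# Thomas algorithm for a tridiagonal system; diagonals (lower, mid, upper),
# lower[1] and upper[n] unused.
thomas_solve <- function(lower, mid, upper, rhs) {
  n <- length(rhs)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / mid[1]
  dp[1] <- rhs[1] / mid[1]
  for (i in seq_len(n - 1) + 1) {
    denom <- mid[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in rev(seq_len(n - 1))) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Conditioned expected passage time via the P*T transform: solve
# (r_up(n)+r_dn(n)) X(n) - r_up(n) X(n+1) - r_dn(n) X(n-1) = P(n), n = 1..M-1,
# with X(0) = X(M) = 0, where P(n) is the corresponding splitting probability;
# then T(n) = X(n)/P(n). Solved by direct tridiagonal elimination (one-way
# propagation of the recurrence is unstable near small pivots).
pt_transform_solve <- function(model, M, source) {
  n <- seq_len(M - 1L)
  up <- transition_up(model, n)
  dn <- transition_down(model, n)
  if (any(up <= 0) || any(dn <= 0))
    stop(sprintf("blocking state in 1..%d: some r_+ or r_- is zero, the ",
                 M - 1L),
         "passage problem is singular")
  thomas_solve(lower = -dn, mid = up + dn, upper = -up, rhs = source)
}

#' Expected burst duration
#'
#' Expected number of steps of a burst of height `H`, on the step clock:
#' the mean waiting time at 0 (`1/r_+(0)`), plus the conditioned forward
#' passage time from 1 to `H` (avoiding 0), plus the conditioned backward
#' passage time from `H` to 0 (avoiding `H + 1`). Conditioned times are
#' computed through the product transform `X(n) = P(n) T(n)`, which turns the
#' conditioned expectations into tridiagonal linear systems with zero
#' boundaries.
#'
#' @inheritParams splitting_backward
#' @param units `"steps"` (default) or `"time"` (calibrated via
#'   [steps_to_time()]).
#' @return Expected duration.
#' @export
burst_expected_duration <- function(model, H, units = c("steps", "time")) {
  stopifnot(inherits(model, "hnc_model"))
  units <- match.arg(units)
  H <- check_height(H, model$N - 1L)
  if (model$epsilon <= 0)
    stop("burst durations require epsilon > 0 (bursts start from size 0)")
  # forward phase: lattice {0..H}, start 1, absorb at H avoiding 0
  t_fwd <- 0
  if (H > 1L) {
    pf <- splitting_forward_profile(model, H)        # n = 0..H
    x <- pt_transform_solve(model, H, pf[seq_len(H - 1L) + 1L])
    t_fwd <- x[1] / pf[2]
  }
  # backward phase: lattice {0..H+1}, start H, absorb at 0 avoiding H+1
  M <- H + 1L
  pb <- splitting_backward_profile(model, M)         # n = 0..M
  x <- pt_transform_solve(model, M, pb[seq_len(M - 1L) + 1L])
  t_bwd <- x[H] / pb[H + 1L]
  tot <- 1 / transition_up(model, 0L) + t_fwd + t_bwd
  if (units == "time") steps_to_time(model, tot) else tot
}

#' Burst height profile
#'
#' Generation probability and expected duration for every burst height up to
#' `H_max`. `t_gen_steps` is the full expected duration including the
#' waiting time at 0; `t_excursion_steps` is the visible part only (from
#' leaving 0 to returning to 0), i.e. `t_gen_steps - 1/r_+(0)`.
#'
#' @inheritParams splitting_forward
#' @param H_max Largest height, integer in `[1, N - 1]`.
#' @return Data frame with columns `H`, `p_gen`, `t_gen_steps`,
#'   `t_excursion_steps`, `t_gen_time`.
#' @export
burst_profile <- function(model, H_max = model$N - 1L) {
  stopifnot(inherits(model, "hnc_model"))
  H_max <- check_height(H_max, model$N - 1L)
  H <- seq_len(H_max)
  p <- vapply(H, function(h) burst_probability(model, h), 0)
  t <- vapply(H, function(h) burst_expected_duration(model, h), 0)
  wait <- 1 / transition_up(model, 0L)
  data.frame(H = H, p_gen = p, t_gen_steps = t,
             t_excursion_steps = t - wait,
             t_gen_time = steps_to_time(model, t))
}

#' Mean duration over all burst heights
#'
#' The `P_gen`-weighted mean of the expected burst durations,
#' `sum(P_gen(H) T(H)) / sum(P_gen(H))` over `H = 1..H_max`. By default `T`
#' is the visible excursion duration (from the step the clone leaves 0 to its
#' return to 0, excluding the waiting time spent at 0) — the quantity a
#' lineage-tracing experiment averaging "the duration of all observed bursts"
#' measures. This average increases monotonically with `epsilon` at fixed
#' `N`, which is what makes it usable for rate estimation; including the
#' waiting time (`include_waiting = TRUE`, the per-height convention of
#' [burst_expected_duration()]) destroys the monotonicity, because the mean
#' wait `1/r_+(0)` diverges as `epsilon` shrinks.
#'
#' @inheritParams burst_profile
#' @inheritParams burst_expected_duration
#' @param include_waiting If `TRUE`, use the full duration including the
#'   waiting time at 0.
#' @return Expected duration (steps by default).
#' @export
mean_burst_duration <- function(model, H_max = model$N - 1L,
                                units = c("steps", "time"),
                                include_waiting = FALSE) {
  units <- match.arg(units)
  prof <- burst_profile(model, H_max)
  if (all(prof$p_gen == 0)) stop("all burst probabilities are zero")
  t <- if (include_waiting) prof$t_gen_steps else prof$t_excursion_steps
  tot <- sum(prof$p_gen * t) / sum(prof$p_gen)
  if (units == "time") steps_to_time(model, tot) else tot
}
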