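#' Clone-size distributions
#'
#' Light container for a probability mass function over clone sizes
#' `n = 0..N`, either at a given step of the master equation or at
#' stationarity.
#'
#' @param pmf Numeric vector of length `N + 1`, non-negative, summing to 1.
#' @param label Step index (integer) or `"stationary"`.
#' @return An object of class `"clone_size_dist"` with elements `n`, `pmf`,
#'   `label`.
#' @export
clone_size_dist <- function(pmf, label = "empirical") {
  if (any(pmf < 0)) stop("pmf entries must be non-negative")
  if (abs(sum(pmf) - 1) > 1e-10) stop("pmf must sum to 1 (within 1e-10)")
  structure(list(n = seq_along(pmf) - 1L, pmf = as.numeric(pmf),
                 label = label),
            class = "clone_size_dist")
}

#' @export
print.clone_size_dist <- function(x, ...) {
  cat(sprintf("Clone size distribution (%s): support 0..%d, mean %.4g\n",
              as.character(x$label), max(x$n), mean(x)))
  invisible(x)
}

#' @export
mean.clone_size_dist <- function(x, ...) sum(x$n * x$pmf)

#' @export
plot.clone_size_dist <- function(x, xlab = "clone size n", ylab = "P(n)",
                                 type = "h", ...) {
  graphics::plot(x$n, x$pmf, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log of the detailed-balance weights w_n = prod_{k=1..n} r_up(k-1)/r_dn(k),
# n = 0..N, accumulated in log space (for N ~ 1000 the raw products span
# hundreds of orders of magnitude).
log_stationary_weights <- function(model) {
  N <- model$N
  k <- seq_len(N)
  c(0, cumsum(log(transition_up(model, k - 1L)) -
              log(transition_down(model, k))))
}

#' Stationary clone-size distribution
#'
#' Closed-form stationary law of a focal clone's size, obtained from detailed
#' balance of the single-clone birth-death chain:
#' \deqn{P_n^\infty \propto \prod_{k=1}^{n} \frac{r_+(k-1)}{r_-(k)},}
#' normalized over `n = 0..N`. Products are accumulated in log space and
#' normalized by log-sum-exp. In the hierarchical limit (`lambda = 0`) this
#' reduces exactly to `Binomial(N, 1/K)`.
#'
#' Requires `epsilon > 0`: with no master-cell supply, size 0 is absorbing and
#' the chain has no non-degenerate stationary law (the long-run state is the
#' extinction/fixation mixture), so `epsilon = 0` is rejected rather than
#' silently returning a point mass.
#'
#' @param model An [hnc_model()] object with `epsilon > 0`.
#' @return A [clone_size_dist()] with `label = "stationary"`.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "hnc_model"))
  if (model$epsilon <= 0)
    stop("stationary distribution requires epsilon > 0: with epsilon = 0 ",
         "clone size 0 is absorbing and the long-run law is the degenerate ",
         "extinction/fixation mixture, not a detailed-balance stationary state")
  if (model$K == 1L) {  # single clone holds the whole open layer
    pmf <- c(rep(0, model$N), 1)
    return(clone_size_dist(pmf, "stationary"))
  }
  lw <- log_stationary_weights(model)
  pmf <- exp(lw - log_sum_exp(lw))
  clone_size_dist(pmf / sum(pmf), "stationary")
}

#' Evolve the focal-clone master equation
#'
#' Applies the exact one-step update
#' \deqn{P_n^{m+1} = r_+(n-1) P_{n-1}^m + r_-(n+1) P_{n+1}^m +
#'       (1 - r_+(n) - r_-(n)) P_n^m}
#' `m` times (out-of-range terms are zero). The update is a stochastic matrix,
#' so mass is conserved exactly; the result is renormalized only against
#' floating-point drift.
#'
#' @param model An [hnc_model()] object.
#' @param p0 Initial distribution: a [clone_size_dist()] or a numeric pmf of
#'   length `N + 1`.
#' @param m Number of steps (non-negative integer).
#' @return A [clone_size_dist()] labeled with the final step index.
#' @export
evolve_master_equation <- function(model, p0, m) {
  stopifnot(inherits(model, "hnc_model"), m >= 0, m == round(m))
  start <- 0L
  if (inherits(p0, "clone_size_dist")) {
    if (is.numeric(p0$label)) start <- as.integer(p0$label)
    p <- p0$pmf
  } else p <- as.numeric(p0)
  if (length(p) != model$N + 1L)
    stop("p0 must have length N + 1")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-10)
    stop("p0 must be a normalized distribution over 0..N")
  n <- 0:model$N
  up <- transition_up(model, n)
  dn <- transition_down(model, n)
  stay <- 1 - up - dn
  N1 <- model$N + 1L
  for (i in seq_len(m)) {
    p <- stay * p +
      c(0, up[-N1] * p[-N1]) +      # inflow from n-1
      c(dn[-1] * p[-1], 0)          # inflow from n+1
  }
  clone_size_dist(p / sum(p), start + as.integer(m))
}

#' Total variation distance between two clone-size distributions
#'
#' @param a,b [clone_size_dist()] objects (or numeric pmfs) on the same
#'   support.
#' @return Total variation distance in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  pa <- if (inherits(a, "clone_size_dist")) a$pmf else as.numeric(a)
  pb <- if (inherits(b, "clone_size_dist")) b$pmf else as.numeric(b)
  if (length(pa) != length(pb)) stop("distributions must share a support")
  sum(abs(pa - pb)) / 2
}
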