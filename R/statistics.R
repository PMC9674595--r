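#' Detect clonal bursts in an event-clock size series
#'
#' Partitions a single-clone size series at its visits to 0. Each maximal
#' segment strictly between two visits to 0 yields one burst whose height `H`
#' is the segment maximum. Durations follow the convention of the analytic
#' expected duration: a burst runs from the step at which the clone last
#' entered size 0 (or the series start) through its return to 0, so the
#' geometric waiting time at 0 is included. Excursions still open at the end
#' of the series are returned separately as censored.
#'
#' @param series Integer vector of clone sizes at consecutive steps (event
#'   clock: consecutive values differ by at most 1, no-change steps allowed).
#' @return An object of class `"hnc_bursts"`: list with `bursts` (data frame
#'   `start_step`, `end_step`, `H`, `duration`, `excursion`, where
#'   `excursion` is the visible part of the burst — the steps spent above 0 —
#'   and `duration` additionally includes the preceding waiting time at 0),
#'   `censored` (incomplete excursions at the series end), and
#'   `steps_at_zero` (number of steps spent at size 0, the denominator for
#'   per-step burst rates).
#' @examples
#' detect_bursts(c(0, 0, 1, 2, 1, 2, 1, 0))   # one burst, H = 2, duration 7
#' @export
detect_bursts <- function(series) {
  if (any(series < 0)) stop("clone sizes must be non-negative")
  if (any(series != round(series))) stop("clone sizes must be integers")
  series <- as.integer(series)
  if (any(abs(diff(series)) > 1))
    stop("not an event-clock series: consecutive sizes differ by more than 1 ",
         "(use detect_excursions() for coarsely sampled data)")
  r <- rle(series > 0)
  ends <- cumsum(r$lengths)           # 1-based positions
  starts <- ends - r$lengths + 1L
  pos_blocks <- which(r$values)
  n <- length(series)
  rows <- lapply(pos_blocks, function(b) {
    a <- starts[b]; e <- ends[b]
    # start of the burst: beginning of the preceding zero run (entry into 0),
    # or the series start if the series opens positive
    start_pos <- if (b > 1L) starts[b - 1L] else 1L
    start_step <- start_pos - 1L
    complete <- e < n                  # returned to 0 within the series
    end_step <- if (complete) e else n - 1L
    data.frame(start_step = start_step, end_step = end_step,
               H = max(series[a:e]), duration = end_step - start_step,
               excursion = e - a + 1L, complete = complete)
  })
  all_rows <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(start_step = integer(), end_step = integer(), H = integer(),
               duration = integer(), excursion = integer(),
               complete = logical())
  bursts <- all_rows[all_rows$complete, names(all_rows) != "complete"]
  censored <- all_rows[!all_rows$complete, names(all_rows) != "complete"]
  rownames(bursts) <- NULL; rownames(censored) <- NULL
  structure(list(bursts = bursts, censored = censored,
                 steps_at_zero = sum(series == 0)),
            class = "hnc_bursts")
}

#' @export
print.hnc_bursts <- function(x, ...) {
  cat(sprintf("Detected %d complete bursts (%d censored); %d steps at size 0\n",
              nrow(x$bursts), nrow(x$censored), x$steps_at_zero))
  if (nrow(x$bursts) > 0)
    cat(sprintf("  heights 1..%d; mean duration %.4g steps\n",
                max(x$bursts$H), mean(x$bursts$duration)))
  invisible(x)
}

#' Burst-like excursions in coarsely sampled series
#'
#' Descriptive relaxation of [detect_bursts()] for empirical tables sampled
#' at coarse intervals (e.g. monthly blood draws), where the event-clock
#' precondition fails: reports maximal runs above a size floor with their
#' peak and length in sampling units. Not comparable to the analytic burst
#' theory; use only to describe real data.
#'
#' @param series Numeric vector of clone sizes at successive sampling times.
#' @param floor Size threshold; an excursion is a maximal run with
#'   `size > floor`.
#' @return Data frame with columns `start_index`, `end_index`, `peak`,
#'   `length` (sampling intervals, 1-based indices).
#' @export
detect_excursions <- function(series, floor = 0) {
  if (any(series < 0)) stop("clone sizes must be non-negative")
  r <- rle(series > floor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_index = starts[keep], end_index = ends[keep],
    peak = vapply(keep, function(b) max(series[starts[b]:ends[b]]), 0),
    length = ends[keep] - starts[keep] + 1L)
}

#' Empirical clone-size distribution of a pulse-label ensemble
#'
#' @param ensemble An `"hnc_label_ensemble"` from [simulate_pulse_label()].
#' @param timepoint A recorded step index (one of `ensemble$steps`).
#' @param condition_on_survival If `TRUE` (default), restrict to surviving
#'   labeled clones (size >= 1) and renormalize; scaling-law plots are
#'   conventionally drawn for persisting clones, since the unconditioned law
#'   accumulates mass at 0.
#' @return A [clone_size_dist()].
#' @export
clone_size_distribution <- function(ensemble, timepoint,
                                    condition_on_survival = TRUE) {
  stopifnot(inherits(ensemble, "hnc_label_ensemble"))
  j <- match(timepoint, ensemble$steps)
  if (is.na(j)) stop("'timepoint' is not a recorded step of the ensemble")
  sizes <- ensemble$sizes[, j]
  N <- ensemble$model$N
  if (condition_on_survival) {
    sizes <- sizes[sizes >= 1L]
    if (length(sizes) == 0)
      stop("no surviving labeled clones at this timepoint")
  }
  pmf <- tabulate(sizes + 1L, nbins = N + 1L) / length(sizes)
  clone_size_dist(pmf, sprintf("step %d%s", timepoint,
                               if (condition_on_survival) " | survival" else ""))
}

#' Rescale a clone-size distribution by its mean
#'
#' Applies the scaling transform underlying the scaling law of neutral
#' competition: a distribution `P_n` with mean `<n>` is mapped to support
#' `x = n/<n>` with density values `<n> * P_n`, so that distributions obeying
#' `P_n(t) = F(n/<n(t)>)/<n(t)>` collapse onto the single curve `F`. The
#' transform is mean-preserving (the scaled first moment is 1).
#'
#' @param dist A [clone_size_dist()] with positive mean.
#' @return An object of class `"scaled_dist"`: list with `x` (scaled support),
#'   `density` (`<n> * P_n`), `weights` (the probability masses), `mean`,
#'   `label`.
#' @export
scale_distribution <- function(dist) {
  stopifnot(inherits(dist, "clone_size_dist"))
  mu <- mean(dist)
  if (mu <= 0) stop("distribution has zero mean; cannot rescale")
  structure(list(x = dist$n / mu, density = mu * dist$pmf,
                 weights = dist$pmf, mean = mu, label = dist$label),
            class = "scaled_dist")
}

#' @export
print.scaled_dist <- function(x, ...) {
  cat(sprintf("Scaled clone size distribution (%s): mean %.4g\n",
              as.character(x$label), x$mean))
  invisible(x)
}

#' @export
plot.scaled_dist <- function(x, xlab = "n / <n>", ylab = "<n> P(n)", ...) {
  keep <- x$weights > 0
  graphics::plot(x$x[keep], x$density[keep], xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Kolmogorov-Smirnov distance between two rescaled discrete distributions,
# compared as continuous laws: the mass at clone size n is spread over the
# cell (n - 1/2, n + 1/2)/<n> (histogram CDF). Without this continuity
# correction the KS distance between two *identical* scaled shapes at
# different means never falls below about half the largest cell mass, which
# would swamp the collapse signal at moderate means.
ks_distance_scaled <- function(a, b) {
  knots <- function(d) {
    keep <- d$weights > 0
    x <- d$x[keep]; w <- d$weights[keep]
    list(k = c(x[1] - 0.5 / d$mean, x + 0.5 / d$mean), v = c(0, cumsum(w)))
  }
  ka <- knots(a); kb <- knots(b)
  grid <- sort(unique(c(ka$k, kb$k)))
  cdf <- function(kn) stats::approx(kn$k, kn$v, xout = grid,
                                    method = "linear", yleft = 0, rule = 2)$y
  max(abs(cdf(ka) - cdf(kb)))
}

#' Scaling-collapse statistic
#'
#' Quantifies how well a set of rescaled clone-size distributions collapse
#' onto one curve: the maximum pairwise Kolmogorov-Smirnov distance between
#' the scaled distributions, each compared as a continuous law (the mass at
#' size n is spread over the cell `(n - 1/2, n + 1/2)/<n>`, since the
#' limiting scaled law is a continuous density). Small values mean the
#' scaling law holds (neutral competition: NC and hNC regimes); large values
#' mean it is violated (the hierarchical regime, whose distribution freezes
#' onto its stationary shape instead of spreading with its mean).
#'
#' @param dists A list of two or more [scale_distribution()] outputs.
#' @return The collapse score (maximum pairwise KS distance).
#' @export
scaling_collapse_statistic <- function(dists) {
  if (!is.list(dists) || length(dists) < 2)
    stop("need at least two scaled distributions")
  stopifnot(all(vapply(dists, inherits, TRUE, "scaled_dist")))
  pairs <- utils::combn(length(dists), 2)
  max(apply(pairs, 2, function(ij)
    ks_distance_scaled(dists[[ij[1]]], dists[[ij[2]]])))
}

#' Shannon diversity index of clone fractions
#'
#' `H = -sum_m P_m log(P_m)` in nats, with the `0 log 0 = 0` convention;
#' bounded by `log(M)` for `M` clones.
#'
#' @param fractions Non-negative clone fractions summing to 1 (tolerance
#'   1e-6).
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(0.1, 10))        # log(10)
#' shannon_index(c(0.5, 0.25, 0.25))  # 1.039721
#' @export
shannon_index <- function(fractions) {
  if (any(fractions < 0)) stop("clone fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("clone fractions must sum to 1 (tolerance 1e-6)")
  p <- fractions[fractions > 0]
  -sum(p * log(p))
}

#' Expected Shannon index of the model at stationarity
#'
#' Simulates the multi-clone process past burn-in and averages the Shannon
#' index of the clone fractions `n_k/N` over thinned snapshots and replicate
#' chains. Burn-in defaults to `50 + 20/epsilon` natural time units (one
#' unit = `lambda N + epsilon K` steps): the slowest relaxation mode is clone
#' extinction/resupply, whose timescale grows like `1/epsilon`, so a flat
#' burn-in that is ample at `epsilon ~ 1` is visibly unconverged at
#' `epsilon ~ 0.05`. Snapshots are thinned by one natural time unit and the
#' standard error is taken between independent chains (snapshots within a
#' chain are strongly autocorrelated).
#'
#' @param model An [hnc_model()] object with `epsilon > 0` (the NC regime has
#'   no stationary diversity: it decays to monoclonality).
#' @param n_snapshots Snapshots per chain.
#' @param n_chains Independent replicate chains (used for the standard
#'   error).
#' @param burn_in Burn-in steps (default `(50 + 20/epsilon)` natural time
#'   units).
#' @param thin Steps between snapshots (default one natural time unit).
#' @param seed Base seed; chain `c` uses `seed + c - 1`.
#' @return List with `mean`, `se` (between-chain standard error), `n_obs`.
#' @export
expected_shannon <- function(model, n_snapshots = 200L, n_chains = 4L,
                             burn_in = NULL, thin = NULL, seed = NULL) {
  stopifnot(inherits(model, "hnc_model"))
  unit <- max(1L, as.integer(round(rate_total(model))))
  if (is.null(burn_in))
    burn_in <- as.integer(round((50 + 20 / max(model$epsilon, 0.01)) * unit))
  if (is.null(thin)) thin <- unit
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - n_chains, 1L)
  record <- as.integer(burn_in + thin * seq_len(n_snapshots))
  init <- uniform_init(model)
  chain_means <- vapply(seq_len(n_chains), function(ch) {
    set.seed(seed + ch - 1L)
    counts <- cpp_simulate_multi(init, model$epsilon, model$lambda, record)
    mean(apply(counts, 2, function(nk) shannon_index(nk / model$N)))
  }, 0)
  list(mean = mean(chain_means),
       se = if (n_chains > 1) stats::sd(chain_means) / sqrt(n_chains) else NA_real_,
       n_obs = n_chains * n_snapshots)
}

new_epsilon_estimate <- function(estimate, lower, upper, grid, observed,
                                 method) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 grid = grid, observed = observed, method = method),
            class = "epsilon_estimate")
}

#' @export
print.epsilon_estimate <- function(x, ...) {
  cat(sprintf("Master-cell proliferation rate estimate (%s)\n", x$method))
  cat(sprintf("  epsilon_hat = %.4g", x$estimate))
  if (is.finite(x$lower) || is.finite(x$upper))
    cat(sprintf("  [%.4g, %.4g]", x$lower, x$upper))
  cat(sprintf("\n  observed statistic: %.4g\n", x$observed))
  invisible(x)
}

#' @export
coef.epsilon_estimate <- function(object, ...) c(epsilon = object$estimate)

# monotone inversion of y(x) tabulated on a grid: isotonic fit then linear
# interpolation of the inverse. Errors outside the simulated/analytic range.
invert_monotone <- function(x, y, y_obs, what) {
  iso <- stats::isoreg(x, y)
  yf <- iso$yf
  if (y_obs < min(yf) || y_obs > max(yf))
    stop(sprintf("observed %s (%.4g) lies outside the range [%.4g, %.4g] ",
                 what, y_obs, min(yf), max(yf)),
         "covered by the grid; extend 'eps_grid'")
  # collapse flat isotonic segments so the inverse is single-valued
  keep <- !duplicated(yf)
  stats::approx(x = yf[keep], y = x[keep], xout = y_obs, rule = 2)$y
}

#' Estimate the master-cell proliferation rate from clonal diversity
#'
#' Simulation-based inversion of the Shannon-diversity map: for each rate on
#' `eps_grid` the model is simulated to stationarity and the expected Shannon
#' index of the clone fractions is computed; the monotone (isotonic +
#' linear) interpolant of `H(epsilon)` is then inverted at the observed
#' index. More master-cell supply evens out clone sizes, so `H(epsilon)` is
#' increasing and the inversion is well posed. The returned band inverts
#' `H_obs` against the simulated surface shifted by +/- 2 standard errors.
#'
#' @param H_obs Observed Shannon index (nats), in `[0, log(K)]`.
#' @param N,K Open-layer size and clone count of the model to invert under.
#' @param eps_grid Grid of candidate `epsilon` values (default 12 log-spaced
#'   points in `[0.01, 1]`).
#' @param lambda Competitive proliferation rate (reference scale 1).
#' @param n_snapshots,n_chains Simulation budget per grid point (see
#'   [expected_shannon()]).
#' @param seed Base seed.
#' @return An `"epsilon_estimate"` with the point estimate, uncertainty band
#'   and the simulated grid.
#' @export
estimate_epsilon_from_shannon <- function(H_obs, N, K,
                                          eps_grid = exp(seq(log(0.01), log(1),
                                                             length.out = 12)),
                                          lambda = 1, n_snapshots = 200L,
                                          n_chains = 4L, seed = NULL) {
  if (H_obs < 0 || H_obs > log(K) + 1e-9)
    stop("'H_obs' must lie in [0, log(K)]")
  if (H_obs > log(K) - 1e-6)
    warning("H_obs is at the uniform-diversity bound log(K): the estimate ",
            "saturates at the top of the admissible range")
  eps_grid <- sort(eps_grid)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 10L, 1L)
  sims <- lapply(seq_along(eps_grid), function(i) {
    m <- hnc_model(K = K, N = N, epsilon = eps_grid[i], lambda = lambda)
    expected_shannon(m, n_snapshots = n_snapshots, n_chains = n_chains,
                     seed = seed + (i - 1L) * n_chains)
  })
  Hbar <- vapply(sims, `[[`, 0, "mean")
  se <- vapply(sims, `[[`, 0, "se")
  est <- invert_monotone(eps_grid, Hbar, H_obs, "Shannon index")
  lower <- tryCatch(invert_monotone(eps_grid, Hbar + 2 * se, H_obs,
                                    "Shannon index"),
                    error = function(e) min(eps_grid))
  upper <- tryCatch(invert_monotone(eps_grid, Hbar - 2 * se, H_obs,
                                    "Shannon index"),
                    error = function(e) max(eps_grid))
  new_epsilon_estimate(est, lower, upper,
                       data.frame(epsilon = eps_grid, shannon = Hbar, se = se),
                       H_obs, "Shannon index inversion")
}

#' Estimate the master-cell proliferation rate from burst durations
#'
#' Inverts the analytic mean-burst-duration map `epsilon ->`
#' [mean_burst_duration()] (monotone increasing at fixed `N`) at an observed
#' mean duration, via monotone interpolation over `eps_grid`. The observed
#' mean must come from an event-resolution series ([detect_bursts()] on a
#' per-step record); coarsely sampled data cannot resolve burst durations, so
#' `sampling_interval > 1` is refused.
#'
#' @param mean_dur_obs Observed mean burst duration, in steps. By default
#'   this is the mean visible excursion (the `excursion` column of
#'   [detect_bursts()], averaged over complete bursts); set
#'   `include_waiting = TRUE` if the observed mean includes the waiting time
#'   at 0 (the `duration` column) — but note that map is not monotone in
#'   `epsilon` and may not be invertible.
#' @param N,K Model dimensions.
#' @param eps_grid Grid of candidate `epsilon` values.
#' @param lambda Competitive proliferation rate.
#' @param H_max Largest burst height included in the analytic mean (default
#'   `N - 1`).
#' @param sampling_interval Steps between observations of the series the
#'   durations were measured on; must be 1.
#' @param include_waiting Convention of the observed mean (see
#'   `mean_dur_obs`).
#' @return An `"epsilon_estimate"` (deterministic map, so no band).
#' @export
estimate_epsilon_from_burst_duration <- function(mean_dur_obs, N, K,
                                                 eps_grid = exp(seq(log(0.01),
                                                                    log(1),
                                                                    length.out = 12)),
                                                 lambda = 1, H_max = N - 1L,
                                                 sampling_interval = 1L,
                                                 include_waiting = FALSE) {
  if (mean_dur_obs <= 0) stop("'mean_dur_obs' must be positive")
  if (sampling_interval != 1L)
    stop("burst durations require an event-resolution series ",
         "(sampling_interval = 1); coarsely sampled data cannot resolve ",
         "burst durations")
  eps_grid <- sort(eps_grid)
  dur <- vapply(eps_grid, function(e)
    mean_burst_duration(hnc_model(K = K, N = N, epsilon = e, lambda = lambda),
                        H_max = H_max, include_waiting = include_waiting), 0)
  est <- invert_monotone(eps_grid, dur, mean_dur_obs, "mean burst duration")
  new_epsilon_estimate(est, NA_real_, NA_real_,
                       data.frame(epsilon = eps_grid, mean_duration = dur),
                       mean_dur_obs, "mean burst duration inversion")
}
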