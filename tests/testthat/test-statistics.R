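test_that("burst detection reads excursions off the series", {
  b <- detect_bursts(c(0, 0, 1, 2, 1, 2, 1, 0))
  expect_identical(nrow(b$bursts), 1L)
  expect_identical(b$bursts$H, 2L)
  expect_identical(b$bursts$duration, 7L)    # includes the waiting time at 0
  expect_identical(b$bursts$excursion, 5L)   # visible part only
  expect_identical(nrow(b$censored), 0L)

  b2 <- detect_bursts(c(0, 1, 0, 1, 1, 0))
  expect_identical(nrow(b2$bursts), 2L)
  expect_identical(b2$bursts$H, c(1L, 1L))
  expect_identical(b2$bursts$duration, c(2L, 3L))

  # open excursion at the series end is censored, not a burst
  b3 <- detect_bursts(c(0, 1, 2, 3))
  expect_identical(nrow(b3$bursts), 0L)
  expect_identical(nrow(b3$censored), 1L)
  expect_identical(b3$censored$H, 3L)

  expect_error(detect_bursts(c(0, 2, 0)), "event-clock")
  expect_error(detect_bursts(c(0, -1, 0)), "non-negative")
})

test_that("burst census of a long focal-clone series matches the analytics", {
  m <- hnc_model(K = 10, N = 100, epsilon = 0.1, lambda = 1)
  s <- simulate_focal_clone(m, 2e6, n0 = 0, seed = 42)
  cen <- detect_bursts(s)
  prof <- burst_profile(m, 30)
  counts <- tabulate(factor(cen$bursts$H, levels = 1:30), nbins = 30)
  expected <- prof$p_gen * cen$steps_at_zero
  # normal z for well-populated heights, exact Poisson for rare ones
  for (h in 1:30) {
    if (expected[h] >= 25) {
      se <- sqrt(cen$steps_at_zero * prof$p_gen[h] * (1 - prof$p_gen[h]))
      expect_lt(abs(counts[h] - expected[h]), 3.5 * se)
    } else {
      expect_gt(stats::poisson.test(counts[h], expected[h])$p.value, 1e-4)
    }
  }
  # mean durations over bursts of covered heights, both conventions
  b <- cen$bursts[cen$bursts$H <= 99, ]
  se_exc <- stats::sd(b$excursion) / sqrt(nrow(b))
  expect_lt(abs(mean(b$excursion) - mean_burst_duration(m)), 3 * se_exc)
  se_dur <- stats::sd(b$duration) / sqrt(nrow(b))
  expect_lt(abs(mean(b$duration) -
                mean_burst_duration(m, include_waiting = TRUE)), 3 * se_dur)
})

test_that("coarse series are routed to the descriptive excursion detector", {
  ex <- detect_excursions(c(0, 5, 12, 3, 0, 0, 7, 0), floor = 0)
  expect_identical(nrow(ex), 2L)
  expect_identical(ex$peak, c(12, 7))
  ex2 <- detect_excursions(c(0, 5, 12, 3, 0, 0, 7, 0), floor = 6)
  expect_identical(nrow(ex2), 2L)
  expect_identical(ex2$length, c(1L, 1L))
})

test_that("ensemble clone-size distributions normalize and condition", {
  m <- hnc_model(K = 10, N = 100, epsilon = 0, lambda = 1)
  ens <- simulate_pulse_label(m, record_at = c(500, 2000), n_reps = 2000,
                              seed = 1)
  d <- clone_size_distribution(ens, 500, condition_on_survival = FALSE)
  expect_equal(sum(d$pmf), 1)
  dc <- clone_size_distribution(ens, 500, condition_on_survival = TRUE)
  expect_identical(dc$pmf[1], 0)
  expect_equal(sum(dc$pmf), 1)
  expect_error(clone_size_distribution(ens, 123), "not a recorded step")
  # all-extinct ensemble cannot be conditioned
  ens0 <- simulate_pulse_label(hnc_model(1, 5, epsilon = 0, lambda = 1),
                               record_at = 5000, n_reps = 50, seed = 2)
  ens0$sizes[] <- 0L
  expect_error(clone_size_distribution(ens0, 5000), "no surviving")
})

test_that("mean rescaling is mean-preserving and detects collapse", {
  # delta distribution maps to scaled mass at x = 1
  pmf <- rep(0, 101); pmf[21] <- 1
  sd1 <- scale_distribution(clone_size_dist(pmf))
  expect_equal(sd1$x[21], 1)
  expect_equal(sum(sd1$weights * sd1$x), 1)
  # geometric profiles with different means share one scaled shape
  g <- function(mu, nmax = 2000) {
    p <- stats::dgeom(0:nmax, 1 / mu)
    p[1] <- 0; p <- p / sum(p)
    clone_size_dist(p)
  }
  ks <- scaling_collapse_statistic(list(scale_distribution(g(10)),
                                        scale_distribution(g(40))))
  expect_lt(ks, 0.05)
  expect_identical(scaling_collapse_statistic(list(scale_distribution(g(10)),
                                                   scale_distribution(g(10)))),
                   0)
  expect_error(scaling_collapse_statistic(list(scale_distribution(g(10)))),
               "at least two")
  expect_error(scale_distribution(clone_size_dist(c(1, rep(0, 10)))),
               "zero mean")
})

test_that("Shannon index follows its closed form and bounds", {
  expect_equal(shannon_index(rep(0.1, 10)), log(10))
  expect_identical(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:10) {
    p <- stats::runif(12); p <- p / sum(p)
    h <- shannon_index(p)
    expect_true(h >= 0 && h <= log(12) + 1e-12)
  }
  expect_error(shannon_index(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_index(c(1.2, -0.2)), "non-negative")
})

test_that("stationary Shannon diversity is ordered across regimes", {
  # hierarchical evenness > bursty hNC at matched K, N; and H(eps) is
  # monotone increasing on a coarse grid
  mh <- hnc_model(K = 10, N = 100, epsilon = 0.5, lambda = 0)
  mb <- hnc_model(K = 10, N = 100, epsilon = 0.05, lambda = 1)
  Hh <- expected_shannon(mh, n_snapshots = 100, n_chains = 2, seed = 6)$mean
  Hb <- expected_shannon(mb, n_snapshots = 100, n_chains = 2, seed = 6)$mean
  expect_gt(Hh, Hb)
  Hs <- vapply(c(0.02, 0.1, 0.5), function(e)
    expected_shannon(hnc_model(K = 10, N = 100, epsilon = e, lambda = 1),
                     n_snapshots = 150, n_chains = 3, seed = 8)$mean, 0)
  expect_true(all(diff(Hs) > 0))
  # NC diversity decays toward monoclonality (H -> 0)
  mn <- hnc_model(K = 10, N = 100, epsilon = 0, lambda = 1)
  traj <- hnc_simulate(mn, n_steps = 2e5, seed = 10, record_every = 2e5)
  h_late <- shannon_index(traj$counts[, ncol(traj$counts)] / 100)
  expect_lt(h_late, 0.3)
})

test_that("burst-duration inversion is exact on its own map and guarded", {
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  truth <- mean_burst_duration(hnc_model(10, 100, epsilon = 0.1, lambda = 1))
  est <- estimate_epsilon_from_burst_duration(truth, N = 100, K = 10,
                                              eps_grid = grid)
  expect_equal(est$estimate, 0.1, tolerance = 1e-10)
  expect_error(
    estimate_epsilon_from_burst_duration(truth, N = 100, K = 10,
                                         eps_grid = grid,
                                         sampling_interval = 30),
    "event-resolution")
  expect_error(
    estimate_epsilon_from_burst_duration(1, N = 100, K = 10, eps_grid = grid),
    "outside the range")
})

test_that("Shannon inversion validates its inputs", {
  expect_error(estimate_epsilon_from_shannon(10, N = 100, K = 10),
               "log\\(K\\)")
  m <- hnc_model(K = 10, N = 100, epsilon = 0.1)
  est <- estimate_epsilon_from_shannon(
    expected_shannon(m, n_snapshots = 100, n_chains = 2, seed = 30)$mean,
    N = 100, K = 10, eps_grid = c(0.02, 0.05, 0.1, 0.2, 0.5),
    n_snapshots = 100, n_chains = 2, seed = 31)
  expect_s3_class(est, "epsilon_estimate")
  expect_identical(coef(est), c(epsilon = est$estimate))
  expect_true(est$estimate > 0.02 && est$estimate < 0.5)
})
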