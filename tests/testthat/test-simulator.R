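test_that("cell number is conserved on every recorded snapshot", {
  for (m in list(hnc_model(10, 100, epsilon = 0.05, lambda = 1),
                 hnc_model(10, 100, epsilon = 0.2, lambda = 0),
                 hnc_model(10, 100, epsilon = 0, lambda = 1),
                 hnc_model(7, 103, epsilon = 0.3, lambda = 0.5))) {
    traj <- hnc_simulate(m, n_steps = 5000, seed = 2, record_every = 37)
    expect_true(all(colSums(traj$counts) == m$N))
    expect_true(all(traj$counts >= 0))
    expect_identical(traj$steps[1], 0L)
    expect_identical(traj$steps[length(traj$steps)], 5000L)
    expect_true(all(diff(traj$times) > 0))
  }
})

test_that("trajectories are reproducible and zero-step runs return the start", {
  m <- hnc_model(10, 100, epsilon = 0.05)
  t1 <- hnc_simulate(m, n_steps = 2000, seed = 11)
  t2 <- hnc_simulate(m, n_steps = 2000, seed = 11)
  expect_identical(t1$counts, t2$counts)
  t0 <- hnc_simulate(m, n_steps = 0, seed = 11)
  expect_identical(as.vector(t0$counts), uniform_init(m))
  expect_error(hnc_simulate(m, n_steps = 10, init = rep(1L, 10)), "sum to N")
})

test_that("uniform initialization uses largest-remainder rounding", {
  expect_identical(uniform_init(hnc_model(10, 100, epsilon = 0.1)),
                   rep(10L, 10))
  init <- uniform_init(hnc_model(7, 100, epsilon = 0.1))
  expect_identical(sum(init), 100L)
  expect_true(max(init) - min(init) <= 1L)
  init <- uniform_init(hnc_model(420, 1000, epsilon = 0.1))
  expect_identical(sum(init), 1000L)
  expect_true(all(init %in% c(2L, 3L)))
})

test_that("marginal clone dynamics matches the single-clone birth-death chain", {
  # bridge between the multi-clone simulator and the analytic kernel:
  # transition frequencies of one clone inside the full simulation are
  # chi-square-consistent with r_up/r_down
  m <- hnc_model(K = 10, N = 100, epsilon = 0.1, lambda = 1)
  traj <- hnc_simulate(m, n_steps = 2e5, seed = 13, record_every = 1)
  s <- traj$counts[1, ]
  from <- s[-length(s)]
  move <- diff(s)
  expect_true(all(abs(move) <= 1))
  x2 <- 0; df <- 0
  for (n in sort(unique(from))) {
    visits <- sum(from == n)
    if (visits < 300) next
    p <- c(transition_up(m, n), transition_down(m, n))
    p <- c(p, 1 - sum(p))
    obs <- c(sum(move[from == n] == 1), sum(move[from == n] == -1),
             sum(move[from == n] == 0))
    exp_cnt <- visits * p
    keep <- exp_cnt > 5
    x2 <- x2 + sum((obs[keep] - exp_cnt[keep])^2 / exp_cnt[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(df, 10)
  expect_lt(x2, stats::qchisq(0.999, df))
})

test_that("NC fixation probability from size n equals n/N", {
  # classic neutral Moran result; 1e4 replicates, assert within 3 MC SE
  m <- hnc_model(K = 10, N = 100, epsilon = 0, lambda = 1)
  p_hat <- mc_splitting(m, n0 = 10, lower = 0, upper = 100,
                        n_reps = 10000, seed = 5)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(p_hat - 0.1), 3 * se)
})

test_that("hierarchical long-run clone size is Binomial(N, 1/K)", {
  m <- hnc_model(K = 10, N = 100, epsilon = 0.5, lambda = 0)
  traj <- hnc_simulate(m, n_steps = 2e6, seed = 17, record_every = 10)
  keep <- traj$steps >= 2e4
  obs <- tabulate(as.vector(traj$counts[, keep]) + 1L, nbins = 101)
  obs <- obs / sum(obs)
  expect_lt(tv_distance(obs, stats::dbinom(0:100, 100, 1 / 10)), 0.02)
})

test_that("pulse labeling tracks the labeled sub-lineage", {
  m <- hnc_model(K = 10, N = 100, epsilon = 0.1, lambda = 1)
  ens <- simulate_pulse_label(m, record_at = c(0, 100, 500), n_reps = 500,
                              seed = 21)
  expect_identical(dim(ens$sizes), c(500L, 3L))
  expect_true(all(ens$sizes >= 0 & ens$sizes <= 100))
  # at step 0 a competitive label is one cell, a master label none
  expect_true(all(ens$sizes[ens$origin == "competitive", 1] == 1L))
  expect_true(all(ens$sizes[ens$origin == "master", 1] == 0L))
  # master-origin labels never grow without supply
  mn <- hnc_model(K = 10, N = 100, epsilon = 0, lambda = 1)
  ens0 <- simulate_pulse_label(mn, record_at = c(0, 1000, 5000), n_reps = 400,
                               seed = 3)
  expect_true(all(ens0$sizes[ens0$origin == "master", ] == 0L))
  # NC competitive labels drift neutrally: extinction grows over time
  ext <- colMeans(ens0$sizes[ens0$origin == "competitive", ] == 0L)
  expect_true(all(diff(ext) > 0))
})

test_that("monoclonal probability is instantaneous and regime-consistent", {
  # hNC can leave monoclonality again; probabilities stay in [0,1]
  m <- hnc_model(K = 2, N = 10, epsilon = 0.5, lambda = 1)
  p <- monoclonal_probability(m, checkpoints = c(100, 1000, 5000),
                              n_reps = 200, seed = 9)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  # hierarchical model: no monoclonal conversion
  mh <- hnc_model(K = 10, N = 100, epsilon = 0.2, lambda = 0)
  ph <- monoclonal_probability(mh, checkpoints = c(1e4, 5e4), n_reps = 100,
                               seed = 9)
  expect_identical(ph$probability, c(0, 0))
})

test_that("focal-clone series respects the event clock", {
  m <- hnc_model(K = 10, N = 100, epsilon = 0.1)
  s <- simulate_focal_clone(m, 5e4, n0 = 10, seed = 2)
  expect_length(s, 5e4 + 1)
  expect_identical(s[1], 10L)
  expect_true(all(abs(diff(s)) <= 1))
  expect_true(all(s >= 0 & s <= 100))
})
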