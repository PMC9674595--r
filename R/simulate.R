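#' Uniform initial clone configuration
#'
#' Splits the `N` open-layer cells as evenly as possible over the `K` clones
#' (largest-remainder rounding when `K` does not divide `N`).
#'
#' @param model An [hnc_model()] object.
#' @return Integer vector of length `K` summing to `N`.
#' @export
uniform_init <- function(model) {
  stopifnot(inherits(model, "hnc_model"))
  base <- model$N %/% model$K
  rem <- model$N %% model$K
  counts <- rep.int(base, model$K)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  as.integer(counts)
}

check_init <- function(model, init) {
  if (length(init) != model$K)
    stop("'init' must have one entry per clone (length K)")
  if (any(init < 0) || any(init != round(init)))
    stop("'init' must contain non-negative integers")
  if (sum(init) != model$N)
    stop(sprintf("'init' must sum to N = %d (got %d)", model$N, sum(init)))
  as.integer(init)
}

record_grid <- function(n_steps, record_every) {
  if (n_steps < 0) stop("'n_steps' must be non-negative")
  if (record_every < 1) stop("'record_every' must be a positive integer")
  steps <- unique(c(seq.int(0L, n_steps, by = as.integer(record_every)),
                    as.integer(n_steps)))
  sort(as.integer(steps))
}

#' Simulate the multi-clone stem cell process
#'
#' Runs the discrete-step loss/compensation dynamics: per step, one
#' competitive cell is removed (clone k with probability n_k/N) and one added
#' from a source clone drawn with probability
#' (lambda n_k + epsilon)/(lambda N + epsilon K), both evaluated on the
#' pre-removal state. If loss and compensation pick the same clone the state
#' is unchanged.
#'
#' @param model An [hnc_model()] object.
#' @param n_steps Number of elementary steps.
#' @param init Initial clone sizes (default [uniform_init()]).
#' @param seed Optional integer seed; identical inputs give identical
#'   trajectories.
#' @param record_every Record every this many steps (step 0 and `n_steps` are
#'   always included).
#' @return An object of class `"hnc_trajectory"`: list with `model`, `steps`,
#'   `times` (calibrated), `counts` (K x length(steps) integer matrix), `seed`.
#' @seealso [simulate.hnc_model()] for replicate ensembles,
#'   [monoclonal_probability()], [simulate_pulse_label()].
#' @export
hnc_simulate <- function(model, n_steps, init = uniform_init(model),
                         seed = NULL, record_every = 1L) {
  stopifnot(inherits(model, "hnc_model"))
  init <- check_init(model, init)
  if (!is.null(seed)) set.seed(seed)
  steps <- record_grid(n_steps, record_every)
  counts <- cpp_simulate_multi(init, model$epsilon, model$lambda, steps)
  rownames(counts) <- paste0("clone", seq_len(model$K))
  structure(
    list(model = model, steps = steps, times = steps_to_time(model, steps),
         counts = counts, seed = seed),
    class = "hnc_trajectory"
  )
}

#' Simulate replicate trajectories
#'
#' `simulate()` method for `hnc_model`: returns `nsim` independent
#' trajectories; replicate `r` uses seed `seed + r - 1`.
#'
#' @param object An [hnc_model()] object.
#' @param nsim Number of replicate trajectories.
#' @param seed Base integer seed (required for reproducibility; defaults to a
#'   random draw).
#' @param n_steps,init,record_every Passed to [hnc_simulate()].
#' @param ... Unused.
#' @return A list of `"hnc_trajectory"` objects.
#' @export
simulate.hnc_model <- function(object, nsim = 1, seed = NULL, n_steps,
                               init = uniform_init(object),
                               record_every = 1L, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - nsim, 1L)
  lapply(seq_len(nsim), function(r)
    hnc_simulate(object, n_steps = n_steps, init = init,
                 seed = seed + r - 1L, record_every = record_every))
}

#' @export
print.hnc_trajectory <- function(x, ...) {
  cat(sprintf("hNC trajectory: K = %d clones, N = %d cells, %d steps (%d snapshots)\n",
              x$model$K, x$model$N, max(x$steps), length(x$steps)))
  cat(sprintf("  regime %s; calibrated time span [0, %.4g]\n",
              regime(x$model), max(x$times)))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' @export
as.data.frame.hnc_trajectory <- function(x, ...) {
  data.frame(
    step = rep(x$steps, each = x$model$K),
    time = rep(x$times, each = x$model$K),
    clone = rep(rownames(x$counts), times = length(x$steps)),
    size = as.vector(x$counts),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.hnc_trajectory <- function(x, clones = seq_len(min(5L, x$model$K)),
                                xlab = "calibrated time", ylab = "clone size",
                                ...) {
  graphics::matplot(x$times, t(x$counts[clones, , drop = FALSE]), type = "l",
                    lty = 1, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Probability of monoclonal conversion over time
#'
#' Fraction of replicate simulations in which some clone occupies the whole
#' open layer (`n_k = N`) at each checkpoint. Monoclonality is evaluated
#' instantaneously: in the hNC regime a monoclonal state can be left again
#' through master-cell supply, so the curve can plateau below one, while in
#' the NC regime fixation is absorbing and the curve converges to one.
#'
#' @param model An [hnc_model()] object.
#' @param checkpoints Increasing integer step indices at which monoclonality
#'   is evaluated.
#' @param n_reps Number of replicate simulations.
#' @param init Initial clone sizes (default uniform).
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return Data frame with columns `step`, `time`, `probability`.
#' @export
monoclonal_probability <- function(model, checkpoints, n_reps = 1000L,
                                   init = uniform_init(model), seed = NULL) {
  stopifnot(inherits(model, "hnc_model"), n_reps >= 1)
  init <- check_init(model, init)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - n_reps, 1L)
  mono <- matrix(FALSE, n_reps, length(checkpoints))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r - 1L)
    mono[r, ] <- cpp_monoclonal_one(init, model$epsilon, model$lambda,
                                    checkpoints)
  }
  data.frame(step = checkpoints,
             time = steps_to_time(model, checkpoints),
             probability = colMeans(mono))
}

#' Pulse-labeling ensemble of a single labeled lineage
#'
#' Emulates a pulse-labeling (lineage-tracing) experiment: one cell is chosen
#' uniformly from the `K + N` stem cells. A labeled master cell marks all
#' competitive cells it subsequently supplies; a labeled competitive cell
#' marks its symmetric-division descendants. The labeled competitive-cell
#' count then follows the exact marginal birth-death chain of the labeled
#' sub-lineage: it gains a cell with probability
#' `(e_label + lambda*l) / (epsilon*K + lambda*N) * (1 - l/N)` and loses one
#' with probability `(1 - (e_label + lambda*l)/(epsilon*K + lambda*N)) * l/N`,
#' where `e_label = epsilon` for a master-cell label and `0` for a
#' competitive-cell label. Because cells within a clone are exchangeable, this
#' marginal law is identical to tracking the label inside the full multi-clone
#' simulation, for any initial clone configuration.
#'
#' @param model An [hnc_model()] object.
#' @param record_at Increasing integer step indices at which the labeled clone
#'   size is recorded.
#' @param n_reps Number of independent labeling replicates.
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return An object of class `"hnc_label_ensemble"`: list with `model`,
#'   `steps`, `times`, `sizes` (n_reps x length(steps) integer matrix) and
#'   `origin` (`"master"` or `"competitive"` per replicate).
#' @export
simulate_pulse_label <- function(model, record_at, n_reps = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(model, "hnc_model"), n_reps >= 1)
  record_at <- sort(unique(as.integer(record_at)))
  if (any(record_at < 0)) stop("'record_at' steps must be non-negative")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - n_reps, 1L)
  p_master <- model$K / (model$K + model$N)
  sizes <- matrix(0L, n_reps, length(record_at))
  origin <- character(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r - 1L)
    master <- stats::runif(1) < p_master
    origin[r] <- if (master) "master" else "competitive"
    e_label <- if (master) model$epsilon else 0
    n0 <- if (master) 0L else 1L
    sizes[r, ] <- cpp_birth_death(e_label, model$epsilon, model$lambda,
                                  model$K, model$N, n0, record_at)
  }
  structure(
    list(model = model, steps = record_at,
         times = steps_to_time(model, record_at),
         sizes = sizes, origin = origin, seed = seed),
    class = "hnc_label_ensemble"
  )
}

#' @export
print.hnc_label_ensemble <- function(x, ...) {
  cat(sprintf("Pulse-label ensemble: %d replicates (%d master, %d competitive labels)\n",
              nrow(x$sizes), sum(x$origin == "master"),
              sum(x$origin == "competitive")))
  cat(sprintf("  model regime %s; recorded at steps %s\n", regime(x$model),
              paste(x$steps, collapse = ", ")))
  invisible(x)
}

#' Simulate the focal-clone birth-death chain
#'
#' Event-clock series of a single clone's size under the exact marginal
#' transition probabilities [transition_up()] / [transition_down()]. This is
#' the chain the master equation and the burst first-passage theory describe;
#' it is also the workhorse for burst censuses.
#'
#' @param model An [hnc_model()] object.
#' @param n_steps Number of steps.
#' @param n0 Initial clone size.
#' @param seed Optional seed.
#' @return Integer vector of length `n_steps + 1` (sizes at steps `0..n_steps`).
#' @export
simulate_focal_clone <- function(model, n_steps, n0 = 0L, seed = NULL) {
  stopifnot(inherits(model, "hnc_model"))
  check_clone_size(n0, model$N)
  if (!is.null(seed)) set.seed(seed)
  cpp_birth_death_series(model$epsilon, model$epsilon, model$lambda,
                         model$K, model$N, as.integer(n0),
                         as.integer(n_steps))
}
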