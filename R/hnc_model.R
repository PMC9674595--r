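#' Construct a hierarchical neutral competition (hNC) model
#'
#' Defines a multi-clone Moran-type model of stem cell homeostasis. A closed
#' layer holds `K` master stem cells (one per clone label), each self-renewing
#' by invariant asymmetric division and supplying competitive stem cells at
#' rate `epsilon`. An open layer holds `N` competitive stem cells which are
#' lost to differentiation and replaced either by master-cell supply or by
#' symmetric division of a competitive stem cell at rate `lambda`. Each
#' elementary simulation step removes one competitive cell chosen uniformly
#' (clone k with probability n_k/N) and adds one cell from a source clone
#' chosen with probability (lambda n_k + epsilon)/(lambda N + epsilon K).
#'
#' Special cases: `lambda = 0` is the classical hierarchical model (supply
#' only, no competition), `epsilon = 0` is the neutral-competition (NC) model
#' (no master cells), and `epsilon > 0, lambda > 0` is the intermediate hNC
#' model, which exhibits burst-like clonal expansions.
#'
#' @param K Number of master stem cells / clone labels (positive integer).
#' @param N Number of competitive stem cells in the open layer (positive
#'   integer).
#' @param epsilon Proliferation rate of master stem cells (non-negative).
#' @param lambda Proliferation rate of competitive stem cells (non-negative).
#'   `epsilon` and `lambda` must not both be zero. Only the ratio
#'   `epsilon/lambda` affects the embedded chain; the default reference scale
#'   is `lambda = 1`.
#' @return An object of class `"hnc_model"`: a list with elements `K`, `N`,
#'   `epsilon`, `lambda`.
#' @examples
#' m <- hnc_model(K = 10, N = 100, epsilon = 0.1)
#' regime(m)
#' transition_up(m, 0:5)
#' @export
hnc_model <- function(K, N, epsilon, lambda = 1) {
  stopifnot(length(K) == 1L, length(N) == 1L,
            length(epsilon) == 1L, length(lambda) == 1L)
  if (!is.numeric(K) || K < 1 || K != round(K))
    stop("'K' must be a positive integer")
  if (!is.numeric(N) || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (!is.numeric(epsilon) || is.na(epsilon) || epsilon < 0)
    stop("'epsilon' must be a non-negative number")
  if (!is.numeric(lambda) || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a non-negative number")
  if (epsilon + lambda <= 0)
    stop("'epsilon' and 'lambda' cannot both be zero: no compensation event exists")
  structure(
    list(K = as.integer(K), N = as.integer(N),
         epsilon = as.numeric(epsilon), lambda = as.numeric(lambda)),
    class = "hnc_model"
  )
}

#' @export
print.hnc_model <- function(x, ...) {
  cat(sprintf("hNC stem cell model (%s regime)\n", regime(x)))
  cat(sprintf("  K = %d master stem cells (closed layer)\n", x$K))
  cat(sprintf("  N = %d competitive stem cells (open layer)\n", x$N))
  cat(sprintf("  epsilon = %g (master proliferation rate)\n", x$epsilon))
  cat(sprintf("  lambda  = %g (competitive proliferation rate)\n", x$lambda))
  cat(sprintf("  step clock: one unit of time = %g steps\n", rate_total(x)))
  invisible(x)
}

#' @export
summary.hnc_model <- function(object, ...) {
  print(object)
  if (object$epsilon > 0) {
    p <- stationary_distribution(object)
    mu <- sum(seq(0, object$N) * p$pmf)
    cat(sprintf("  stationary focal-clone mean size: %.4g (N/K = %.4g)\n",
                mu, object$N / object$K))
  } else {
    cat("  NC regime: no non-degenerate stationary clone-size distribution\n")
  }
  invisible(object)
}

# total compensation weight lambda*N + epsilon*K, the per-step event rate
rate_total <- function(model) model$lambda * model$N + model$epsilon * model$K

#' Classify the model regime
#'
#' @param model An [hnc_model()] object.
#' @return `"hierarchical"` if `lambda == 0`, `"NC"` if `epsilon == 0`,
#'   `"hNC"` if both rates are positive.
#' @export
regime <- function(model) {
  stopifnot(inherits(model, "hnc_model"))
  if (model$lambda == 0) "hierarchical"
  else if (model$epsilon == 0) "NC"
  else "hNC"
}

#' Single-clone transition probabilities
#'
#' Per-step probabilities that a focal clone of size `n` grows or shrinks by
#' one cell:
#' \deqn{r_+(n) = \frac{\epsilon + \lambda n}{\epsilon K + \lambda N}
#'       \left(1 - \frac{n}{N}\right), \qquad
#'       r_-(n) = \left(1 - \frac{\epsilon + \lambda n}{\epsilon K + \lambda N}
#'       \right) \frac{n}{N}.}
#' The remaining mass `1 - r_up - r_down` is the probability the step leaves
#' the clone size unchanged.
#'
#' @param model An [hnc_model()] object.
#' @param n Clone size(s), integer in `0..N` (vectorized).
#' @return Numeric vector of probabilities.
#' @export
transition_up <- function(model, n) {
  stopifnot(inherits(model, "hnc_model"))
  check_clone_size(n, model$N)
  q <- (model$epsilon + model$lambda * n) / rate_total(model)
  q * (1 - n / model$N)
}

#' @rdname transition_up
#' @export
transition_down <- function(model, n) {
  stopifnot(inherits(model, "hnc_model"))
  check_clone_size(n, model$N)
  q <- (model$epsilon + model$lambda * n) / rate_total(model)
  (1 - q) * (n / model$N)
}

check_clone_size <- function(n, N) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) || any(n > N) ||
      any(n != round(n)))
    stop("clone size 'n' must be an integer in [0, N]")
  invisible(TRUE)
}

#' Convert simulation steps to calibrated time
#'
#' The step clock is calibrated by the mean number of compensation events per
#' unit time: `t = m / (lambda * N + epsilon * K)`. This makes models with
#' different rates comparable on one time axis.
#'
#' @param model An [hnc_model()] object.
#' @param m Step count(s), non-negative (vectorized).
#' @return Calibrated time(s).
#' @export
steps_to_time <- function(model, m) {
  stopifnot(inherits(model, "hnc_model"))
  if (any(m < 0)) stop("'m' must be non-negative")
  m / rate_total(model)
}

#' Serialize / deserialize a model as JSON
#'
#' The on-disk form is a flat JSON object with keys `K`, `N`, `epsilon`,
#' `lambda`.
#'
#' @param model An [hnc_model()] object.
#' @param path File path; if `NULL`, [hnc_model_to_json()] returns the JSON
#'   string.
#' @return `hnc_model_to_json()`: the path (invisibly) or a JSON string.
#'   `hnc_model_from_json()`: an [hnc_model()] object.
#' @export
hnc_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "hnc_model"))
  x <- list(K = model$K, N = model$N, epsilon = model$epsilon,
            lambda = model$lambda)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname hnc_model_to_json
#' @param json A JSON string (alternative to `path`).
#' @export
hnc_model_from_json <- function(path = NULL, json = NULL) {
  x <- if (!is.null(json)) jsonlite::fromJSON(json) else jsonlite::fromJSON(path)
  hnc_model(K = x$K, N = x$N, epsilon = x$epsilon, lambda = x$lambda)
}
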