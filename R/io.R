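#' Clone-count matrices
#'
#' Container for clonal-tracking tables in the style of published barcode /
#' vector-insertion time series: one row per clone, one column per sampling
#' timepoint.
#'
#' @param counts Non-negative numeric matrix, clones x timepoints.
#' @param clones Clone identifiers (default from rownames or `clone1..`).
#' @param timepoints Strictly increasing numeric sampling times (default from
#'   column names).
#' @param unit Time unit label (e.g. `"month"`).
#' @param integer_counts If `TRUE`, require integer counts (simulated
#'   fixtures); empirical tables may hold frequencies.
#' @return An object of class `"clone_matrix"`.
#' @export
clone_matrix <- function(counts, clones = rownames(counts),
                         timepoints = as.numeric(colnames(counts)),
                         unit = "month", integer_counts = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop("need at least one clone")
  if (any(is.na(counts))) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (integer_counts && any(counts != round(counts)))
    stop("fixture counts must be integers")
  if (is.null(clones)) clones <- paste0("clone", seq_len(nrow(counts)))
  clones <- as.character(clones)
  if (anyDuplicated(clones))
    stop("duplicate clone ids: ",
         paste(unique(clones[duplicated(clones)]), collapse = ", "))
  timepoints <- as.numeric(timepoints)
  if (any(is.na(timepoints)) || length(timepoints) != ncol(counts))
    stop("timepoints must be numeric, one per column")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  dimnames(counts) <- list(clones, format(timepoints, trim = TRUE))
  structure(list(counts = counts, clones = clones, timepoints = timepoints,
                 unit = unit),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("Clone count matrix: %d clones x %d timepoints (%.4g to %.4g %ss)\n",
              nrow(x$counts), ncol(x$counts), min(x$timepoints),
              max(x$timepoints), x$unit))
  invisible(x)
}

#' @export
as.data.frame.clone_matrix <- function(x, ...) {
  data.frame(
    clone = rep(x$clones, times = length(x$timepoints)),
    timepoint = rep(x$timepoints, each = length(x$clones)),
    count = as.vector(x$counts),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.clone_matrix <- function(x, sort_by_peak = TRUE,
                              xlab = NULL, ylab = "clone (sorted by peak time)",
                              ...) {
  ord <- if (sort_by_peak) sort_clones_by_peak(x) else x$clones
  m <- x$counts[ord, , drop = FALSE]
  if (is.null(xlab)) xlab <- paste0("time (", x$unit, "s)")
  graphics::image(x = x$timepoints, y = seq_len(nrow(m)),
                  z = t(log1p(m[rev(seq_len(nrow(m))), , drop = FALSE])),
                  xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read / write a clone-count table
#'
#' Canonical on-disk format: delimited text (CSV by default), UTF-8, first
#' column `clone`, remaining column headers the sampling timepoints. Missing
#' cells are read as 0 with a warning; duplicate clone ids and negative
#' counts are errors reporting the offending lines.
#'
#' @param path File path.
#' @param sep Field delimiter: `","` (default) or `"\t"`.
#' @param unit Time unit label to attach.
#' @return [read_clone_matrix()]: a [clone_matrix()].
#'   [write_clone_matrix()]: the path, invisibly.
#' @export
read_clone_matrix <- function(path, sep = ",", unit = "month") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2 || tolower(names(df)[1]) != "clone")
    stop("malformed header: first column must be 'clone', remaining columns ",
         "timepoints")
  tp <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(tp)))
    stop("malformed header: non-numeric timepoint column(s) ",
         paste(names(df)[-1][is.na(tp)], collapse = ", "))
  clones <- as.character(df[[1]])
  if (anyDuplicated(clones)) {
    dup <- which(duplicated(clones))
    stop("duplicate clone id(s) at data line(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(clones[dup]), collapse = ", "))
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric counts in table")
  if (any(is.na(m))) {
    warning(sum(is.na(m)), " missing cell(s) set to 0")
    m[is.na(m)] <- 0
  }
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg) > 0)
    stop("negative count(s) at data line(s) ", paste(neg, collapse = ", "))
  clone_matrix(m, clones = clones, timepoints = tp, unit = unit)
}

#' @rdname read_clone_matrix
#' @param x A [clone_matrix()].
#' @param long If `TRUE`, write the tidy long format (columns `clone`,
#'   `timepoint`, `count`) instead of the wide matrix.
#' @export
write_clone_matrix <- function(x, path, sep = ",", long = FALSE) {
  stopifnot(inherits(x, "clone_matrix"))
  if (long) {
    utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    df <- data.frame(clone = x$clones, x$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("clone", format(x$timepoints, trim = TRUE))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Order clones by the time of their population peak
#'
#' Returns clone ids ordered by the timepoint index at which each clone's
#' count is maximal (the heatmap ordering used for clonal-tracking time
#' series). Ties within a clone's series resolve to the earlier timepoint of
#' the maximum; clones sharing a peak timepoint keep their input order.
#'
#' @param x A [clone_matrix()].
#' @return Character vector of clone ids.
#' @export
sort_clones_by_peak <- function(x) {
  stopifnot(inherits(x, "clone_matrix"))
  peak <- apply(x$counts, 1, which.max)   # which.max takes the earliest tie
  x$clones[order(peak)]                   # order() is stable
}

#' Generate a synthetic clonal-tracking fixture
#'
#' Simulates the multi-clone process and samples clone sizes at regular
#' intervals, producing a synthetic clone x timepoint table with the
#' statistical structure of published clonal-tracking data (a stand-in for
#' real barcode tables; no external data required). Columns are labeled in
#' months, with a default calibration of 1000 steps per month.
#'
#' @param model An [hnc_model()] object.
#' @param months Number of monthly samples.
#' @param steps_per_month Simulation steps per month (default 1000).
#' @param seed Integer seed (the output is deterministic given the seed).
#' @param sampling_noise If `TRUE`, replace each column by a multinomial
#'   subsample of `sample_size` cells, emulating blood-draw sampling.
#' @param sample_size Cells drawn per timepoint when `sampling_noise = TRUE`
#'   (default `N`).
#' @return A [clone_matrix()] with integer counts; column sums equal `N`
#'   when `sampling_noise` is off.
#' @export
generate_fixture <- function(model, months, steps_per_month = 1000L,
                             seed = NULL, sampling_noise = FALSE,
                             sample_size = model$N) {
  stopifnot(inherits(model, "hnc_model"), months >= 1)
  if (!is.null(seed)) set.seed(seed)
  record <- as.integer(seq_len(months)) * as.integer(steps_per_month)
  counts <- cpp_simulate_multi(uniform_init(model), model$epsilon,
                               model$lambda, record)
  if (sampling_noise) {
    counts <- apply(counts, 2, function(nk)
      as.integer(stats::rmultinom(1, size = sample_size, prob = nk / model$N)))
  }
  rownames(counts) <- paste0("clone", seq_len(model$K))
  clone_matrix(counts, timepoints = seq_len(months), unit = "month",
               integer_counts = TRUE)
}

#' Clone fractions from a clone-count table
#'
#' @param x A [clone_matrix()].
#' @param timepoint A single timepoint to use, or `NULL` (default) to pool
#'   counts across all timepoints before normalizing.
#' @return Named vector of clone fractions summing to 1 (input to
#'   [shannon_index()]).
#' @export
clone_fractions <- function(x, timepoint = NULL) {
  stopifnot(inherits(x, "clone_matrix"))
  v <- if (is.null(timepoint)) {
    rowSums(x$counts)
  } else {
    j <- match(timepoint, x$timepoints)
    if (is.na(j)) stop("'timepoint' not found in the table")
    x$counts[, j]
  }
  if (sum(v) <= 0) stop("no cells observed")
  stats::setNames(v / sum(v), x$clones)
}
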