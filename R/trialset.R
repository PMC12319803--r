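#' Trial-structured segment of a recording
#'
#' Container for one segment class (`"baseline"` or `"post"`) of epoched
#' multi-unit data.  Data are stored sample-major, `[sample, unit, trial]`,
#' so that spectral estimators reduce to matrix products over the first
#' dimension; the time axis is implicit through `time_start` and
#' `sampling_rate` with half-open sample windows (`n` samples of a
#' `n / sampling_rate` second epoch).
#'
#' @param data numeric array `[sample, unit, trial]`.
#' @param time_start time (s) of the first sample, relative to stimulation
#'   offset for post segments and to segment start for baseline segments.
#' @param sampling_rate sampling rate in Hz.
#' @param segment_class `"baseline"` or `"post"`.
#' @param rejected logical per-trial artifact flags.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, time_start, sampling_rate,
                      segment_class = c("baseline", "post"),
                      rejected = NULL) {
  segment_class <- match.arg(segment_class)
  if (length(dim(data)) != 3)
    stop("'data' must be a 3-d array [sample, unit, trial]")
  if (is.null(rejected)) rejected <- rep(FALSE, dim(data)[3])
  stopifnot(length(rejected) == dim(data)[3], sampling_rate > 0)
  structure(list(data = data, time_start = time_start,
                 sampling_rate = sampling_rate,
                 segment_class = segment_class,
                 rejected = as.logical(rejected)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set:%s> %d units x %d trials x %d samples @ %g Hz, t = [%g, %g) s; %d rejected\n",
              x$segment_class, d[2], d[3], d[1], x$sampling_rate,
              x$time_start, x$time_start + d[1] / x$sampling_rate,
              sum(x$rejected)))
  invisible(x)
}

#' Time axis of a trial set
#' @param x a `trial_set`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  x$time_start + (seq_len(dim(x$data)[1]) - 1) / x$sampling_rate
}

#' @rdname ts_time
#' @export
n_trials <- function(x) dim(x$data)[3]

#' @rdname ts_time
#' @export
n_units <- function(x) dim(x$data)[2]

#' Restrict a trial set to a subset of units
#' @param x a `trial_set`.
#' @param units integer unit indices to keep.
#' @return A `trial_set` with only those units.
#' @export
ts_subset_units <- function(x, units) {
  x$data <- x$data[, units, , drop = FALSE]
  x
}

#' Flag artifact-contaminated trials
#'
#' Computes a robust z-score for every sample against the pooled amplitude
#' distribution of the whole segment (median / MAD based) and flags trials
#' whose peak absolute z exceeds `zmax`.  Flagged trials are retained in
#' the set (so trial order is preserved for order-sensitive analyses) but
#' are skipped by downstream estimators.
#'
#' @param trials a `trial_set`.
#' @param zmax positive robust-z threshold.
#' @return The `trial_set` with updated `rejected` flags.
#' @export
flag_artifact_trials <- function(trials, zmax = 8) {
  stopifnot(inherits(trials, "trial_set"), zmax > 0)
  x <- trials$data
  ctr <- median(x)
  scl <- mad(x, center = ctr)
  if (scl == 0) scl <- .Machine$double.eps
  peak <- apply(abs(x - ctr), 3, max)
  flags <- peak / scl > zmax
  trials$rejected <- trials$rejected | flags
  if (all(trials$rejected)) stop("no usable trials")
  trials
}

#' Indices of trials not flagged as artifacts
#' @param x a `trial_set`.
#' @return Integer trial indices.
#' @export
good_trials <- function(x) which(!x$rejected)
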