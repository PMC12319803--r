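#' Segment a continuous recording into baseline and post-stimulation trials
#'
#' The baseline occupies the start of the recording.  Its last 10 s are
#' discarded (they can carry device-related artifacts in real recordings
#' and dropping them yields a uniform trial count) and the remaining
#' portion is cut into consecutive 5.5 s epochs.  After every stimulation
#' train, the window 3.8--10 s relative to train offset (a 6.2 s epoch)
#' contains the usable part of the inter-stimulation interval; it is
#' trimmed to 4.2--9.7 s (5.5 s) to remove filter edge effects, and that
#' trimmed epoch becomes one post-stimulation trial.
#'
#' Sample windows are half-open `[start, end)`, so a 5.5 s epoch at
#' 1000 Hz has exactly 5500 samples.
#'
#' @param continuous numeric matrix `[unit, sample]`.
#' @param design a [study_design()].
#' @param train_onsets strictly increasing train onset times (s).
#' @param block block label selecting the train duration.
#' @param baseline_trim seconds dropped from the end of the baseline.
#' @param post_window usable window (s) relative to train offset.
#' @param post_trim retained sub-window (s) relative to train offset.
#' @param epoch_length baseline epoch length (s).
#' @return `list(baseline = , post = )` of [trial_set()] objects.
#' @export
segment_recording <- function(continuous, design, train_onsets,
                              block = design$blocks[1],
                              baseline_trim = 10,
                              post_window = c(3.8, 10),
                              post_trim = c(4.2, 9.7),
                              epoch_length = 5.5) {
  stopifnot(is.matrix(continuous), inherits(design, "study_design"))
  fs <- design$sampling_rate
  n_samp_rec <- ncol(continuous)
  dur_rec <- n_samp_rec / fs
  if (!block %in% design$blocks) stop("unknown block: ", block)
  train_dur <- design$train_durations[[block]]

  if (length(train_onsets) != design$trains_per_block)
    stop("expected ", design$trains_per_block, " train onsets, got ",
         length(train_onsets))
  if (any(diff(train_onsets) <= 0))
    stop("'train_onsets' must be strictly increasing")
  if (dur_rec < design$baseline_duration)
    stop("recording too short for the baseline segment (",
         design$baseline_duration, " s needed)")
  if (any(train_onsets < 0 | train_onsets > dur_rec))
    stop("train onsets fall outside the recording")

  base_keep <- design$baseline_duration - baseline_trim
  n_epoch <- floor(base_keep / epoch_length + 1e-9)

  cut_epochs <- function(starts_s, nsamp, time_start, class) {
    idx0 <- round(starts_s * fs)  # half-open [start, start + nsamp)
    if (any(idx0 < 0) || any(idx0 + nsamp > n_samp_rec))
      stop("recording too short for the ", class, " segment")
    dat <- array(0, c(nsamp, nrow(continuous), length(idx0)))
    for (k in seq_along(idx0))
      dat[, , k] <- t(continuous[, (idx0[k] + 1):(idx0[k] + nsamp),
                                 drop = FALSE])
    trial_set(dat, time_start, fs, class)
  }

  baseline <- cut_epochs(epoch_length * (seq_len(n_epoch) - 1),
                         round(epoch_length * fs), 0, "baseline")
  offsets <- train_onsets + train_dur
  post <- cut_epochs(offsets + post_trim[1],
                     round((post_trim[2] - post_trim[1]) * fs),
                     post_trim[1], "post")
  list(baseline = baseline, post = post)
}

#' Train onset times implied by a design
#'
#' Trains start after the baseline and are separated by
#' `train_duration + interval_duration`.
#'
#' @param design a [study_design()].
#' @param block block label.
#' @return Numeric vector of onset times (s).
#' @export
train_onsets <- function(design, block = design$blocks[1]) {
  dur <- design$train_durations[[block]]
  design$baseline_duration +
    (seq_len(design$trains_per_block) - 1) * (dur + design$interval_duration)
}

#' Total duration of one session block
#' @inheritParams train_onsets
#' @return Seconds from baseline start to the end of the last interval.
#' @export
block_duration <- function(design, block = design$blocks[1]) {
  dur <- design$train_durations[[block]]
  design$baseline_duration +
    design$trains_per_block * (dur + design$interval_duration)
}
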