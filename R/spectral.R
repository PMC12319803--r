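.hanning <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# projection basis for per-epoch mean + linear trend removal
.detrend_basis <- function(n) {
  qr.Q(qr(cbind(1, seq_len(n))))
}

# Hanning-taper power of columns of X (nsamp x N) at arbitrary frequencies.
# Detrending is folded into the projection so X is never copied.
# Normalisation: a pure sinusoid of amplitude A yields power ~ A^2.
.taper_power <- function(X, freqs, fs, detrend = TRUE) {
  n <- nrow(X)
  h <- .hanning(n)
  t <- (0:(n - 1)) / fs
  ang <- outer(t, 2 * pi * freqs)
  W <- cbind(h * cos(ang), h * sin(ang))      # n x 2F
  F <- crossprod(W, X)                        # 2F x N
  if (detrend) {
    Q <- .detrend_basis(n)
    F <- F - crossprod(W, Q) %*% crossprod(Q, X)
  }
  nf <- length(freqs)
  (4 / sum(h)^2) * (F[seq_len(nf), , drop = FALSE]^2 +
                    F[nf + seq_len(nf), , drop = FALSE]^2)
}

#' Whole-epoch Hanning-taper power per trial
#'
#' Single-taper power estimate over the full epoch, per unit and trial,
#' at the requested frequencies.  The per-epoch mean and linear trend are
#' removed first.  This is the time-collapsed power estimator used for
#' ISF-level (carrier-frequency) statistics.
#'
#' @param trials a [trial_set()].
#' @param freqs frequencies in Hz.
#' @param units optional integer subset of units.
#' @param detrend remove per-epoch mean and linear trend first.
#' @return Array `[freq, unit, trial]` of power (amplitude-squared units).
#' @export
trial_power <- function(trials, freqs, units = NULL, detrend = TRUE) {
  stopifnot(inherits(trials, "trial_set"))
  x <- trials$data
  if (!is.null(units)) x <- x[, units, , drop = FALSE]
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  p <- .taper_power(x, freqs, trials$sampling_rate, detrend)
  array(p, c(length(freqs), d[2], d[3]),
        dimnames = list(freq = freqs, NULL, NULL))
}

#' Estimate the individual stimulation frequency (ISF)
#'
#' Computes a Hanning-taper power spectrum at integer frequencies
#' (default 4--40 Hz) from baseline trials, averaged over unflagged trials
#' and over the declared unit subset, and takes the frequency of maximal
#' power within a broad alpha range (default 7--14 Hz) as the ISF.  Exact
#' ties are broken toward the lower frequency (with a message).
#'
#' @param baseline a baseline [trial_set()].
#' @param units integer unit subset over which power is averaged
#'   (typically the somatosensory region); `NULL` for all units.
#' @param freqs integer frequencies of the spectrum (Hz).
#' @param alpha_range search range for the peak (Hz).
#' @param window `"per_trial"`: taper each epoch and average spectra;
#'   `"single"`: one Hanning window over the concatenated baseline.
#' @return An object of class `power_spectrum` with fields `freqs`,
#'   `power` and `isf`.
#' @export
estimate_isf <- function(baseline, units = NULL, freqs = 4:40,
                         alpha_range = c(7, 14),
                         window = c("per_trial", "single")) {
  window <- match.arg(window)
  stopifnot(inherits(baseline, "trial_set"))
  keep <- good_trials(baseline)
  if (length(keep) == 0) stop("no usable trials")
  x <- baseline$data[, , keep, drop = FALSE]
  if (!is.null(units)) x <- x[, units, , drop = FALSE]
  if (dim(x)[2] == 0) stop("'units' selects no units")
  d <- dim(x)
  if (window == "per_trial") {
    dim(x) <- c(d[1], d[2] * d[3])
    p <- .taper_power(x, freqs, baseline$sampling_rate)
    power <- rowMeans(p)
  } else {
    # concatenate trials in time per unit, one taper over the whole series
    x <- aperm(x, c(1, 3, 2))
    dim(x) <- c(d[1] * d[3], d[2])
    power <- rowMeans(.taper_power(x, freqs, baseline$sampling_rate))
  }
  in_band <- freqs >= alpha_range[1] & freqs <= alpha_range[2]
  if (!any(in_band)) stop("no frequencies inside the alpha range")
  band_power <- power[in_band]
  if (all(band_power == 0))
    stop("no alpha peak: spectrum is zero over ", alpha_range[1], "-",
         alpha_range[2], " Hz")
  # ties are detected up to numerical precision (an exact floating-point
  # tie is measure-zero even for analytically tied spectra)
  peak_idx <- which(band_power >= max(band_power) * (1 - 1e-12))
  if (length(peak_idx) > 1)
    message("ISF tie at ", paste(freqs[in_band][peak_idx], collapse = ", "),
            " Hz; choosing the lower frequency")
  isf <- freqs[in_band][min(peak_idx)]
  structure(list(freqs = freqs, power = power, isf = isf,
                 alpha_range = alpha_range, window = window,
                 n_trials = length(keep)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", min(x$freqs), "-", max(x$freqs),
      " Hz; isf = ", x$isf, " Hz (search ", x$alpha_range[1], "-",
      x$alpha_range[2], " Hz, ", x$window, ")\n", sep = "")
  invisible(x)
}

#' Sliding-window Hanning time-frequency decomposition
#'
#' Short-time power per trial, unit, frequency and time, with a Hanning
#' taper.  The `"cycles7"` variant uses a frequency-dependent window of 7
#' cycles (the main analysis); `"win400ms"` uses a fixed 400 ms window
#' (the variant feeding the slow-modulation analysis).  Windows slide in
#' 100 ms steps; time points whose window does not fit inside the epoch
#' are `NA`, never zero-filled.
#'
#' @param trials a [trial_set()].
#' @param variant `"cycles7"` or `"win400ms"`.
#' @param freqs frequencies in Hz (default 5--40, 1 Hz steps).
#' @param step time step in seconds.
#' @param cycles cycles per window for the `"cycles7"` variant.
#' @param win_length window length (s) for the `"win400ms"` variant.
#' @param units optional integer subset of units.
#' @return An object of class `tfr`: `power [freq, time, unit, trial]`,
#'   `freqs`, `times`, `variant`.
#' @export
compute_tfr <- function(trials, variant = c("cycles7", "win400ms"),
                        freqs = 5:40, step = 0.1, cycles = 7,
                        win_length = 0.4, units = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$sampling_rate
  x <- trials$data
  if (!is.null(units)) x <- x[, units, , drop = FALSE]
  d <- dim(x)
  nsamp <- d[1]
  win <- if (variant == "cycles7") round(cycles / freqs * fs)
         else rep(round(win_length * fs), length(freqs))
  if (any(win > nsamp)) {
    bad <- freqs[which.max(win)]
    stop("epoch (", nsamp / fs, " s) shorter than the analysis window at ",
         bad, " Hz (", max(win) / fs, " s)")
  }

  # detrend epochs once, then slice windows
  dim(x) <- c(nsamp, d[2] * d[3])
  Q <- .detrend_basis(nsamp)
  x <- x - Q %*% crossprod(Q, x)

  times <- seq(0, (nsamp - 1) / fs, by = step)
  cs <- round(times * fs)                      # centre samples, 0-based
  P <- array(NA_real_, c(length(freqs), length(times), d[2], d[3]))
  tvec <- (0:(nsamp - 1)) / fs
  # frequencies sharing a window length share windows: one projection
  # matrix (all tapered exponentials side by side) per length
  for (L in unique(win)) {
    fset <- which(win == L)
    h <- .hanning(L)
    a <- cs - floor(L / 2)                     # window start, 0-based
    valid <- which(a >= 0 & a + L <= nsamp)
    if (length(valid) == 0) next
    ang <- outer(tvec[seq_len(L)], 2 * pi * freqs[fset])
    W <- cbind(h * cos(ang), h * sin(ang))     # L x 2m
    sc <- 4 / sum(h)^2
    m <- length(fset)
    for (j in valid) {
      F <- crossprod(W, x[(a[j] + 1):(a[j] + L), , drop = FALSE])
      P[fset, j, , ] <- sc * (F[seq_len(m), , drop = FALSE]^2 +
                              F[m + seq_len(m), , drop = FALSE]^2)
    }
  }
  structure(list(power = P, freqs = freqs,
                 times = trials$time_start + times, step = step,
                 variant = variant, sampling_rate = fs),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr:%s> %d freqs (%g-%g Hz) x %d times x %d units x %d trials\n",
              x$variant, d[1], min(x$freqs), max(x$freqs), d[2], d[3], d[4]))
  invisible(x)
}

#' Align a TFR's frequency axis to the individual stimulation frequency
#'
#' Re-indexes the frequency axis as offsets relative to the ISF so that
#' stimulation frequencies coincide across participants.  `"fundamental"`
#' mode spans offsets -2 ... +26 Hz around the ISF; `"harmonic"` mode
#' spans -4 ... +16 Hz around the first harmonic (2 ISF), the control
#' alignment that distinguishes genuine beta effects from harmonics of a
#' non-sinusoidal alpha rhythm.  Offsets whose absolute frequency is not
#' part of the TFR are `NA`, never extrapolated.
#'
#' @param tfr a [compute_tfr()] result.
#' @param isf individual stimulation frequency in Hz.
#' @param mode `"fundamental"` or `"harmonic"`.
#' @return An object of class `aligned_tfr`: `power
#'   [offset, time, unit, trial]`, `offsets`, `abs_freqs`, `isf_used`.
#' @export
align_tfr <- function(tfr, isf, mode = c("fundamental", "harmonic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tfr, "tfr"))
  offsets <- if (mode == "fundamental") -2:26 else -4:16
  centre <- if (mode == "fundamental") isf else 2 * isf
  abs_freqs <- centre + offsets
  rows <- match(abs_freqs, tfr$freqs)
  d <- dim(tfr$power)
  P <- array(NA_real_, c(length(offsets), d[2], d[3], d[4]))
  ok <- !is.na(rows)
  P[ok, , , ] <- tfr$power[rows[ok], , , ]
  structure(list(power = P, offsets = offsets, abs_freqs = abs_freqs,
                 times = tfr$times, step = tfr$step, isf_used = isf,
                 alignment_mode = mode, variant = tfr$variant),
            class = "aligned_tfr")
}

#' @export
print.aligned_tfr <- function(x, ...) {
  cat(sprintf("<aligned_tfr:%s> offsets %+d...%+d Hz around %s (isf = %g Hz)\n",
              x$alignment_mode, min(x$offsets), max(x$offsets),
              if (x$alignment_mode == "fundamental") "ISF" else "2*ISF",
              x$isf_used))
  invisible(x)
}
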