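#' Default modulation-frequency filter-bank centres
#'
#' Centres from 0.1 to 2 Hz with non-uniform spacing (0.1 Hz steps up to
#' 0.5 Hz, 0.25 Hz steps above), giving finer resolution where slow power
#' fluctuations live.
#'
#' @return Numeric vector of 11 centre frequencies (Hz).
#' @export
default_mod_centres <- function() {
  c(0.1, 0.2, 0.3, 0.4, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
}

#' Trial-to-trial power difference time courses
#'
#' For each trial n >= 2 and carrier-frequency offset, the time course
#' \deqn{d_n(t) = p_n(t) - \langle p_{n-1} \rangle_t}
#' i.e. the current trial's power minus the preceding trial's
#' time-averaged power, averaged over the cluster units.  The first trial
#' has no predecessor and is excluded.  Time points that are `NA` in the
#' TFR (incomplete windows) are dropped.
#'
#' @param atfr an [align_tfr()] result from the `"win400ms"` TFR variant,
#'   `power [offset, time, unit, trial]`.
#' @param units optional integer subset of (already subset) units to
#'   average; `NULL` averages all units present.
#' @return Object of class `trial_power_difference`: `values
#'   [offset, time, trial - 1]`, `times`, `offsets`, `trials` (indices of
#'   the retained trials).
#' @export
trial_power_difference <- function(atfr, units = NULL) {
  stopifnot(inherits(atfr, "aligned_tfr"))
  P <- atfr$power
  if (!is.null(units)) P <- P[, , units, , drop = FALSE]
  n_trial <- dim(P)[4]
  if (n_trial < 2) stop("need at least 2 trials")
  # unit average, then drop edge time points that are NA for any offset
  M <- apply(P, c(1, 2, 4), mean)                 # offset x time x trial
  first <- matrix(M[, , 1], dim(M)[1], dim(M)[2])
  valid_t <- which(colSums(is.na(first)) == 0)
  M <- M[, valid_t, , drop = FALSE]
  prev_avg <- apply(M[, , -n_trial, drop = FALSE], c(1, 3), mean)
  d <- M[, , -1, drop = FALSE] -
    aperm(array(prev_avg, c(dim(M)[1], n_trial - 1, length(valid_t))),
          c(1, 3, 2))
  structure(list(values = d, times = atfr$times[valid_t],
                 offsets = atfr$offsets, step = atfr$step,
                 trials = seq_len(n_trial)[-1]),
            class = "trial_power_difference")
}

# zero-phase band-pass power gains (squared Butterworth magnitude) on an
# FFT frequency grid; order-4 prototype, returns |H(f)|^2-shaped gain
.bandpass_gain <- function(freqs, centre, bw, order = 4) {
  fl <- centre - bw / 2; fh <- centre + bw / 2
  f0sq <- fl * fh; B <- fh - fl
  g <- numeric(length(freqs))
  nz <- freqs != 0
  x <- (freqs[nz]^2 - f0sq) / (freqs[nz] * B)
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

#' Modulatory-power spectrum of slow rhythmic power fluctuations
#'
#' Quantifies how strongly the (trial-to-trial corrected) power time
#' course fluctuates at slow modulation frequencies.  Trial time courses
#' are concatenated in trial order into one session-level series per
#' carrier offset (a single 5.5 s trial cannot resolve a 0.1 Hz
#' component), mirror-padded at both ends, band-pass filtered at each
#' filter-bank centre with a zero-phase (squared-Butterworth-magnitude)
#' filter, and converted to the analytic-signal envelope; the envelope
#' magnitude is averaged over the time points of each trial, yielding one
#' modulatory-power value per (modulation frequency, carrier offset,
#' trial).
#'
#' Filter bandwidth is `max(0.1, 0.5 * centre)` Hz around the centre.
#' Because wider bands collect more broadband noise, raw envelope power
#' is not comparable across centres; `normalize = "bandwidth"` divides
#' each centre by the square root of its bandwidth (the scaling of a
#' white-noise envelope), making the spectrum flat under white noise so
#' that a peak across centres identifies the modulation frequency.
#' Element-wise contrasts between conditions are invariant to this
#' per-centre scaling.
#'
#' @param diff a [trial_power_difference()] result.
#' @param centres filter-bank centre frequencies (Hz).
#' @param order Butterworth prototype order.
#' @param normalize `"none"` (raw envelope magnitude) or `"bandwidth"`.
#' @return Object of class `modulatory_spectrum`: `power
#'   [mod_freq, offset, trial]`, `mod_freqs`, `offsets`, `trials`.
#' @export
modulatory_power <- function(diff, centres = default_mod_centres(),
                             order = 4,
                             normalize = c("none", "bandwidth")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(diff, "trial_power_difference"))
  fs <- 1 / diff$step
  nyq <- fs / 2
  bw <- pmax(0.1, 0.5 * centres)
  lo <- centres - bw / 2; hi <- centres + bw / 2
  bad <- lo <= 0 | hi >= nyq
  if (any(bad))
    stop("filter band outside (0, Nyquist) for centre ",
         paste(centres[bad], collapse = ", "), " Hz")

  d <- diff$values                              # offset x time x trial
  n_off <- dim(d)[1]; n_t <- dim(d)[2]; n_tr <- dim(d)[3]
  len <- n_t * n_tr
  X <- matrix(aperm(d, c(2, 3, 1)), len, n_off)  # concatenated series
  # mirror padding (one series length at both ends)
  Xp <- rbind(X[len:1, , drop = FALSE], X, X[len:1, , drop = FALSE])
  np <- nrow(Xp)
  Fx <- mvfft(Xp)
  fgrid <- (seq_len(np) - 1) / np * fs
  fgrid[fgrid > nyq] <- fgrid[fgrid > nyq] - fs  # signed frequencies

  out <- array(NA_real_, c(length(centres), n_off, n_tr))
  pos <- fgrid > 0
  seg <- rep(seq_len(n_tr), each = n_t)
  for (ci in seq_along(centres)) {
    gain <- .bandpass_gain(abs(fgrid), centres[ci], bw[ci], order)
    # analytic signal of the zero-phase filtered series: one-sided spectrum
    G <- gain
    G[pos] <- 2 * G[pos]
    G[!pos & fgrid != 0] <- 0
    env <- Mod(mvfft(Fx * G, inverse = TRUE)) / np
    env <- env[(len + 1):(2 * len), , drop = FALSE]
    for (k in seq_len(n_tr))
      out[ci, , k] <- colMeans(env[seg == k, , drop = FALSE])
  }
  if (normalize == "bandwidth") out <- out / sqrt(bw)
  structure(list(power = out, mod_freqs = centres, offsets = diff$offsets,
                 trials = diff$trials, bandwidths = bw,
                 normalize = normalize),
            class = "modulatory_spectrum")
}

#' @export
print.modulatory_spectrum <- function(x, ...) {
  cat(sprintf("<modulatory_spectrum> %d mod freqs (%g-%g Hz) x %d carrier offsets x %d trials\n",
              length(x$mod_freqs), min(x$mod_freqs), max(x$mod_freqs),
              length(x$offsets), length(x$trials)))
  invisible(x)
}

#' Trial-averaged modulatory spectrum
#' @param x a `modulatory_spectrum`.
#' @return Matrix `[mod_freq, offset]`.
#' @export
mod_spectrum_mean <- function(x) {
  m <- apply(x$power, c(1, 2), mean)
  dimnames(m) <- list(mod_freq = x$mod_freqs, offset = x$offsets)
  m
}

#' Group contrast of modulatory power between conditions
#'
#' Cluster-based permutation test over the modulation-frequency x
#' carrier-offset plane (4-neighbour adjacency), contrasting
#' per-participant trial-averaged modulatory spectra between the tACS and
#' control conditions.
#'
#' @param tacs_spectra,control_spectra lists per participant of
#'   `modulatory_spectrum` objects (or `[mod_freq, offset]` matrices).
#' @param spec a [cluster_test_spec()].
#' @return A `cluster_test` whose element indices flatten the
#'   `[mod_freq, offset]` plane column-major.
#' @export
modulatory_contrast <- function(tacs_spectra, control_spectra, spec) {
  as_mat <- function(x) if (inherits(x, "modulatory_spectrum"))
    mod_spectrum_mean(x) else x
  A <- lapply(tacs_spectra, as_mat)
  B <- lapply(control_spectra, as_mat)
  adj <- grid_adjacency(dim(A[[1]]))
  cluster_permutation_test(A, B, spec, adj)
}
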