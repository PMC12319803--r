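# Shared fixtures and independent oracles, built in code at test time.

# small design for fast generator tests: 6 trains of 10 s, 43 s baseline
# (-> 6 baseline epochs after the 10 s trim)
small_design <- function(n_participants = 4L, trains = 6L,
                         durations = c(train10 = 10)) {
  study_design(n_participants = n_participants, trains_per_block = trains,
               train_durations = durations, baseline_duration = 43)
}

# trial_set of pure sinusoids (+ optional white noise), built without the
# package generator so spectral estimators can be tested independently
sine_trial_set <- function(freqs, amps, n_unit = 1, n_trial = 3,
                           fs = 250, dur = 2, noise_sd = 0,
                           segment_class = "baseline", phase = 0,
                           seed = 1) {
  set.seed(seed)
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  sig <- rowSums(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t + phase), numeric(n)))
  dat <- array(rep(sig, n_unit * n_trial), c(n, n_unit, n_trial))
  if (noise_sd > 0) dat <- dat + rnorm(length(dat), 0, noise_sd)
  trial_set(dat, 0, fs, segment_class)
}

# independent single-taper power oracle: direct complex-exponential sum,
# coded separately from the package implementation
oracle_taper_power <- function(x, f, fs, detrend = TRUE) {
  n <- length(x)
  if (detrend) x <- stats::resid(stats::lm(x ~ seq_len(n)))
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  z <- sum(h * x * exp(-2i * pi * f * (0:(n - 1)) / fs))
  4 * Mod(z)^2 / sum(h)^2
}

# textbook two-sample t with pooled variance (independent oracle)
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# build an aligned_tfr object directly from a power array
# [offset, time, unit, trial] (for modulatory-module unit tests)
fake_aligned_tfr <- function(power, step = 0.1, isf = 10) {
  structure(list(power = power, offsets = -2:(dim(power)[1] - 3),
                 abs_freqs = isf + (-2:(dim(power)[1] - 3)),
                 times = (seq_len(dim(power)[2]) - 1) * step + 0.2,
                 step = step, isf_used = isf,
                 alignment_mode = "fundamental", variant = "win400ms"),
            class = "aligned_tfr")
}
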