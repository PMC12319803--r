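#' Effect specification for the synthetic generator
#'
#' Collects every ground-truth parameter of a simulated participant.  The
#' generated signal of unit u in trial k is
#' \deqn{x(t) = j_k g_u A (1 + m \sin(2\pi f_m t + \phi_u))
#'   \sin(2\pi f_0 t + \theta_u) + \epsilon(t)}
#' where \eqn{f_0} is the individual alpha peak (`isf`), \eqn{m} the slow
#' modulation depth at `mod_freq`, \eqn{j_k} a per-trial lognormal
#' amplitude jitter, \eqn{g_u = \sqrt{1 + g}} with `g = tacs_gain` on
#' effect units in post-stimulation epochs of the tACS session (1
#' elsewhere, so the induced power gain is exactly `g`), and \eqn{\epsilon}
#' band-limited \eqn{1/f}-like Gaussian noise.  Phases advance on the
#' session clock so epochs behave like cut-outs of a continuous recording.
#'
#' @param isf individual stimulation frequency in Hz (7--14).
#' @param alpha_amp baseline alpha amplitude (arbitrary units).
#' @param tacs_gain fractional post-stimulation power increase at `isf` in
#'   the tACS session (e.g. 0.30 for a 30 percent increase); must
#'   exceed -1.
#' @param effect_units integer unit indices carrying the effect, or `NULL`
#'   to use the layout's `"somatosensory"` (plus `"frontal"`, if present)
#'   regions at generation time.
#' @param mod_freq frequency (Hz) of the slow sinusoidal amplitude
#'   modulation.
#' @param mod_depth modulation depth in `[0, 1]` (tACS session; also the
#'   control session unless `mod_depth_control` is given).
#' @param mod_depth_control optional separate modulation depth for the
#'   control session, for designs where stimulation amplifies the slow
#'   fluctuation itself.
#' @param mod_phase_unit_sd SD (radians) of the per-unit scatter of the
#'   slow-modulation phase around a session-wide common phase.  Slow
#'   power fluctuations are spatially coherent (a global drive), so the
#'   scatter is small by default; unit-independent phases would make the
#'   unit-averaged modulation cancel.
#' @param mod_phase_jitter SD (radians) of the random-walk phase step of
#'   the slow modulation between consecutive epochs.  Spontaneous slow
#'   power fluctuations are quasi-periodic, not phase-locked over
#'   minutes; a non-zero jitter also prevents the modulation phase from
#'   locking to the train cycle when the two periods are commensurate.
#' @param noise_exponent spectral exponent of the `1/f^a` noise.
#' @param noise_amp noise standard deviation (same units as `alpha_amp`).
#'   The default puts the single-epoch spectral floor at the ISF around
#'   1/15 of the alpha peak, in the typical range for a clear
#'   parietal/somatosensory alpha rhythm.
#' @param noise_band frequency support (Hz) of the synthesized noise.
#' @param amp_jitter_sd log-scale SD of the session-wide (shared across
#'   units) per-trial amplitude jitter, an arousal-like global
#'   fluctuation.
#' @param amp_jitter_local_sd log-scale SD of the unit-specific per-trial
#'   amplitude jitter (local excitability fluctuations); makes
#'   trial-to-trial power fluctuations strongly but not perfectly
#'   correlated across units.
#' @param local_smooth spatial coherence of the local jitter field:
#'   neighbour weight of the adjacency-kernel smoother applied to the
#'   per-unit jitter (0 = independent units).  Neighbouring source
#'   locations in real recordings fluctuate together (field spread and
#'   shared physiology), and spatial cluster statistics presuppose such
#'   smoothness.
#' @param seed integer RNG seed for this participant.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(isf = 10, alpha_amp = 1, tacs_gain = 0.30,
                        effect_units = NULL, mod_freq = 0.4,
                        mod_depth = 0.3, mod_depth_control = NULL,
                        mod_phase_unit_sd = 0.3, mod_phase_jitter = 0.5,
                        noise_exponent = 1,
                        noise_amp = 2.5, noise_band = c(0.5, 45),
                        amp_jitter_sd = 0.10, amp_jitter_local_sd = 0.15,
                        local_smooth = 0.8, seed = 1L) {
  if (isf < 7 || isf > 14) stop("'isf' must lie in [7, 14] Hz")
  if (mod_depth < 0 || mod_depth > 1) stop("'mod_depth' must lie in [0, 1]")
  if (!is.null(mod_depth_control) &&
      (mod_depth_control < 0 || mod_depth_control > 1))
    stop("'mod_depth_control' must lie in [0, 1]")
  if (tacs_gain <= -1) stop("'tacs_gain' must exceed -1")
  stopifnot(alpha_amp >= 0, noise_amp >= 0, amp_jitter_sd >= 0,
            amp_jitter_local_sd >= 0, local_smooth >= 0,
            mod_phase_jitter >= 0,
            length(noise_band) == 2, noise_band[1] > 0,
            noise_band[2] > noise_band[1])
  structure(list(isf = isf, alpha_amp = alpha_amp, tacs_gain = tacs_gain,
                 effect_units = effect_units, mod_freq = mod_freq,
                 mod_depth = mod_depth,
                 mod_depth_control = mod_depth_control,
                 mod_phase_unit_sd = mod_phase_unit_sd,
                 mod_phase_jitter = mod_phase_jitter,
                 noise_exponent = noise_exponent,
                 noise_amp = noise_amp, noise_band = noise_band,
                 amp_jitter_sd = amp_jitter_sd,
                 amp_jitter_local_sd = amp_jitter_local_sd,
                 local_smooth = local_smooth,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

.resolve_effect_units <- function(spec, layout) {
  eu <- spec$effect_units
  if (is.null(eu) && !is.null(layout$region_labels))
    eu <- which(layout$region_labels %in% c("somatosensory", "frontal"))
  if (spec$tacs_gain != 0 && length(eu) == 0)
    stop("empty 'effect_units' with a non-zero 'tacs_gain'")
  if (length(eu) && (min(eu) < 1 || max(eu) > length(layout$unit_ids)))
    stop("'effect_units' outside the layout")
  as.integer(eu)
}

# adjacency-kernel smoother with unit row norm, so the smoothed field
# keeps its marginal SD while neighbours become correlated
.layout_smoother <- function(layout, w) {
  if (is.null(w) || w <= 0) return(NULL)
  n <- length(layout$unit_ids)
  S <- diag(n) + w * layout$adjacency
  S <- S / rowSums(S)
  S / sqrt(rowSums(S^2))
}

.gen_segment <- function(t0, spec, theta, phi, amp, drift, fs, n_samp) {
  mod_phase0 <- 2 * pi * spec$mod_freq * t0 + drift
  cpp_generate_segment(nrow(amp), length(t0), n_samp, fs, t0, mod_phase0,
                       spec$isf, spec$mod_freq, spec$mod_depth,
                       theta, phi, amp, spec$noise_amp,
                       spec$noise_exponent, spec$noise_band[1],
                       spec$noise_band[2])
}

#' Generate one synthetic participant
#'
#' Simulates every session and block of the design for one participant.
#' In `"epochs"` mode only the analysis windows (baseline epochs and
#' trimmed post-stimulation epochs) are synthesized, directly as
#' [trial_set()] objects; in `"continuous"` mode a full continuous
#' recording per session and block is returned, to be cut with
#' [segment_recording()].  Both modes share the same session clock, effect
#' parameters and seeded RNG, so they emulate the same experiment.
#'
#' @param design a [study_design()].
#' @param layout a [unit_layout()].
#' @param spec an [effect_spec()].
#' @param sessions,blocks subsets of the design's sessions and blocks to
#'   generate.
#' @param mode `"epochs"` or `"continuous"`.
#' @return An object of class `participant_recording` with elements
#'   `design`, `layout`, `spec`, and `sessions` (epochs mode:
#'   `sessions[[ses]][[blk]]$baseline` / `$post` trial sets; continuous
#'   mode: `sessions[[ses]][[blk]]` numeric `[unit, sample]` matrices).
#' @export
generate_participant <- function(design, layout, spec,
                                 sessions = design$sessions,
                                 blocks = design$blocks,
                                 mode = c("epochs", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"),
            inherits(layout, "unit_layout"),
            inherits(spec, "effect_spec"))
  eff <- .resolve_effect_units(spec, layout)
  n_unit <- length(layout$unit_ids)
  fs <- design$sampling_rate
  nsamp <- round(5.5 * fs)
  n_base <- floor((design$baseline_duration - 10) / 5.5 + 1e-9)

  out <- list(design = design, layout = layout, spec = spec,
              effect_units = eff, mode = mode, sessions = list())
  Sm <- .layout_smoother(layout, spec$local_smooth)
  withr::with_seed(spec$seed, {
    for (ses in sessions) {
      theta <- runif(n_unit, 0, 2 * pi)
      phi <- runif(1, 0, 2 * pi) + rnorm(n_unit, 0, spec$mod_phase_unit_sd)
      gain_post <- rep(1, n_unit)
      if (ses == "tacs" && length(eff))
        gain_post[eff] <- sqrt(1 + spec$tacs_gain)
      spec_ses <- spec
      if (ses == "control" && !is.null(spec$mod_depth_control))
        spec_ses$mod_depth <- spec$mod_depth_control
      for (blk in blocks) {
        n_post <- design$trains_per_block
        jit_base <- exp(rnorm(n_base, 0, spec$amp_jitter_sd))
        jit_post <- exp(rnorm(n_post, 0, spec$amp_jitter_sd))
        drift_base <- cumsum(rnorm(n_base, 0, spec$mod_phase_jitter))
        drift_post <- cumsum(rnorm(n_post, 0, spec$mod_phase_jitter))
        zb <- matrix(rnorm(n_unit * n_base), n_unit)
        zp <- matrix(rnorm(n_unit * n_post), n_unit)
        if (!is.null(Sm)) { zb <- Sm %*% zb; zp <- Sm %*% zp }
        loc_base <- exp(spec$amp_jitter_local_sd * zb)
        loc_post <- exp(spec$amp_jitter_local_sd * zp)
        amp_base <- spec$alpha_amp * loc_base *
          rep(jit_base, each = n_unit)
        amp_post <- spec$alpha_amp * gain_post * loc_post *
          rep(jit_post, each = n_unit)
        t0_base <- 5.5 * (seq_len(n_base) - 1)
        offsets <- train_onsets(design, blk) + design$train_durations[[blk]]
        t0_post <- offsets + 4.2
        if (mode == "epochs") {
          base <- .gen_segment(t0_base, spec_ses, theta, phi, amp_base,
                               drift_base, fs, nsamp)
          post <- .gen_segment(t0_post, spec_ses, theta, phi, amp_post,
                               drift_post, fs, nsamp)
          out$sessions[[ses]][[blk]] <- list(
            baseline = trial_set(base, 0, fs, "baseline"),
            post = trial_set(post, 4.2, fs, "post"))
        } else {
          total <- block_duration(design, blk)
          # continuous mode: one uninterrupted stream (strictly periodic
          # modulation; epoch-level phase drift is an epochs-mode device);
          # the oscillation is generated noise-free so that the piecewise
          # amplitude scaling below leaves the noise floor untouched
          spec_sig <- spec_ses; spec_sig$noise_amp <- 0
          x <- .gen_segment(0, spec_sig, theta, phi,
                            matrix(spec$alpha_amp, n_unit, 1), 0, fs,
                            round(total * fs))
          x <- matrix(x, round(total * fs), n_unit)
          # piecewise amplitude scaling: per-epoch jitter, and the tACS
          # power gain over each post-stimulation interval on effect units
          for (j in seq_len(n_base)) {
            idx <- (round(5.5 * (j - 1) * fs) + 1):round(5.5 * j * fs)
            x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                              jit_base[j] * loc_base[, j], "*")
          }
          iv <- design$interval_duration
          for (k in seq_len(n_post)) {
            idx <- (round(offsets[k] * fs) + 1):
              min(round((offsets[k] + iv) * fs), nrow(x))
            x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                              jit_post[k] * loc_post[, k], "*")
            if (ses == "tacs" && length(eff))
              x[idx, eff] <- x[idx, eff] * sqrt(1 + spec$tacs_gain)
          }
          if (spec$noise_amp > 0) {
            nse <- .gen_segment(0, spec, theta, phi,
                                matrix(0, n_unit, 1), 0, fs,
                                round(total * fs))
            x <- x + matrix(nse, round(total * fs), n_unit)
          }
          out$sessions[[ses]][[blk]] <- t(x)
        }
      }
    }
  })
  class(out) <- "participant_recording"
  out
}

#' @export
print.participant_recording <- function(x, ...) {
  cat("<participant_recording> isf =", x$spec$isf, "Hz, gain =",
      x$spec$tacs_gain, ", mode =", x$mode, "; sessions:",
      paste(names(x$sessions), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic per-participant seed
#'
#' Maps a master seed and participant index to a participant seed.  The
#' mapping `(master + 104729 i) mod (2^31 - 1)` is injective over any
#' cohort (fixed master, consecutive indices).
#'
#' @param master_seed integer master seed.
#' @param i participant index.
#' @return Integer seed.
#' @export
participant_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(i)) %%
               2147483647)
}

#' Generate a synthetic cohort specification
#'
#' Draws per-participant alpha peak frequencies (by default a discrete
#' uniform over 8--13 Hz integers) and derives per-participant seeds from
#' the master seed.  Participant recordings are realized lazily with
#' [realize_participant()] so that a full cohort never has to be held in
#' memory at once.
#'
#' @param n number of participants (>= 2).
#' @param design a [study_design()].
#' @param layout a [unit_layout()].
#' @param spec_base an [effect_spec()] supplying all non-ISF parameters.
#' @param isf_values optional explicit per-participant ISFs.
#' @param master_seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
generate_cohort <- function(n, design, layout, spec_base = effect_spec(),
                            isf_values = NULL, master_seed = 1L) {
  if (n < 2) stop("a cohort needs at least 2 participants")
  isfs <- if (!is.null(isf_values)) {
    stopifnot(length(isf_values) == n)
    isf_values
  } else withr::with_seed(master_seed, sample(8:13, n, replace = TRUE))
  specs <- lapply(seq_len(n), function(i) {
    s <- spec_base
    s$isf <- isfs[i]
    s$seed <- participant_seed(master_seed, i)
    s
  })
  structure(list(n = n, design = design, layout = layout, specs = specs,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' @rdname generate_cohort
#' @param cohort a `cohort_spec`.
#' @param i participant index.
#' @param ... passed to [generate_participant()].
#' @export
realize_participant <- function(cohort, i, ...) {
  generate_participant(cohort$design, cohort$layout, cohort$specs[[i]], ...)
}

#' Write a cohort to disk as containers
#'
#' @param cohort a `cohort_spec`.
#' @param dir output directory; one container per participant.
#' @return Character vector of container paths.
#' @export
materialize_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(cohort$n)
  for (i in seq_len(cohort$n)) {
    p <- realize_participant(cohort, i, mode = "epochs")
    paths[i] <- file.path(dir, sprintf("participant%02d", i))
    write_container(paths[i], cohort$design, cohort$layout, p$sessions,
                    meta = list(seed = cohort$specs[[i]]$seed,
                                isf = cohort$specs[[i]]$isf,
                                provenance = "tacsalpha::materialize_cohort"))
  }
  paths
}
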