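#' Configuration for the synthetic two-lead beat generator
#'
#' Each beat is a sum of Gaussian bumps (P wave, QRS composite, T wave) on
#' both leads, placed at RR intervals `base_rr_s` scaled by the class's
#' prematurity factor, plus sinusoidal baseline wander and white noise. The
#' defaults emulate the class structure that drives inter-patient
#' classification: ventricular beats are wide with no P wave and inverted
#' lead-B polarity, supraventricular beats are premature with a damped P wave,
#' normals are regular. A Gaussian-bump morphology is deliberately simple —
#' enough to create separable classes and exercise every feature extractor,
#' not a biophysical simulation.
#'
#' @param fs Sampling rate (Hz).
#' @param base_rr_s Baseline RR interval in seconds.
#' @param noise_sd_mV Standard deviation of additive white noise (mV).
#' @param wander_amp_mV,wander_freq_hz Amplitude (mV) and frequency (Hz) of
#'   sinusoidal baseline wander.
#' @param class_params Named list (N, S, V) of per-class morphology lists with
#'   entries `qrs_width_ms`, `qrs_amp_mV` (length-2, one per lead),
#'   `p_amp_mV`, `t_amp_mV`, `prematurity_factor`, `t_end_ms`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 360,
                         base_rr_s = 0.8,
                         noise_sd_mV = 0.02,
                         wander_amp_mV = 0.1,
                         wander_freq_hz = 0.3,
                         class_params = NULL) {
  if (is.null(class_params)) {
    class_params <- list(
      N = list(qrs_width_ms = 80, qrs_amp_mV = c(1.0, 0.5), p_amp_mV = 0.15,
               t_amp_mV = 0.30, prematurity_factor = 1.0, t_end_ms = 400),
      S = list(qrs_width_ms = 80, qrs_amp_mV = c(0.9, 0.45), p_amp_mV = 0.05,
               t_amp_mV = 0.25, prematurity_factor = 0.6, t_end_ms = 400),
      V = list(qrs_width_ms = 150, qrs_amp_mV = c(1.4, -0.8), p_amp_mV = 0,
               t_amp_mV = 0.45, prematurity_factor = 0.85, t_end_ms = 420))
  }
  stopifnot(fs > 0, base_rr_s > 0, noise_sd_mV >= 0, wander_amp_mV >= 0)
  cp <- class_params
  if (cp$V$qrs_width_ms <= cp$N$qrs_width_ms)
    stop("config invariant violated: qrs_width_ms(V) must exceed qrs_width_ms(N)")
  if (!(cp$S$prematurity_factor < 1 && cp$N$prematurity_factor == 1))
    stop("config invariant violated: prematurity_factor(S) < 1 = prematurity_factor(N)")
  if (cp$V$p_amp_mV != 0)
    stop("config invariant violated: p_amp_mV(V) must be 0")
  structure(list(fs = fs, base_rr_s = base_rr_s, noise_sd_mV = noise_sd_mV,
                 wander_amp_mV = wander_amp_mV, wander_freq_hz = wander_freq_hz,
                 class_params = class_params),
            class = "synth_config")
}

# round half up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# symbol emitted per superclass (inverse of the AAMI table for one member)
.synth_symbols <- c(N = "N", S = "A", V = "V")

#' Generate a synthetic annotated two-lead record
#'
#' Deterministic given `(config, class_sequence, seed)`. Each QRS center is
#' annotated with a symbol mapping back to the requested superclass (N -> 'N',
#' S -> 'A', V -> 'V'). `morph_jitter` applies one per-record multiplicative
#' offset to amplitudes and widths so that distinct seeds behave like
#' distinct patients.
#'
#' @param config A [synth_config()].
#' @param class_sequence Character vector over `{"N","S","V"}`.
#' @param seed Integer seed.
#' @param record_id Identifier for the generated record.
#' @param morph_jitter Relative SD of the per-record morphology offset.
#' @return An [ecg_record].
#' @export
synth_record <- function(config, class_sequence, seed = 1L,
                         record_id = sprintf("synth%03d", seed %% 1000L),
                         morph_jitter = 0.1) {
  stopifnot(inherits(config, "synth_config"))
  if (length(class_sequence) == 0L) stop("class_sequence must be non-empty")
  if (!all(class_sequence %in% names(config$class_params)))
    stop("class_sequence entries must be in {",
         paste(names(config$class_params), collapse = ","), "}")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fs <- config$fs
  jit <- exp(stats::rnorm(2, 0, morph_jitter))  # [amp, width] patient offset

  # R-point times: each interval scaled by the incoming beat's prematurity
  prem <- vapply(class_sequence, function(cl)
    config$class_params[[cl]]$prematurity_factor, numeric(1))
  rr <- config$base_rr_s * prem
  r_times <- 0.5 + cumsum(c(0, rr[-1L]))
  r_times <- round_half_up(r_times * fs) / fs  # snap R points to the grid
  n_samp <- ceiling((r_times[length(r_times)] + 0.7) * fs)
  tt <- (seq_len(n_samp) - 1L) / fs

  lead_a <- numeric(n_samp)
  lead_b <- numeric(n_samp)
  # compact support (3.5 sd) so waves do not bleed into neighbouring beats
  bump <- function(center, sd, amp) {
    v <- amp * exp(-((tt - center)^2) / (2 * sd^2))
    v[abs(tt - center) > 3.5 * sd] <- 0
    v
  }
  for (k in seq_along(class_sequence)) {
    p <- config$class_params[[class_sequence[k]]]
    rt <- r_times[k]
    qrs_sd <- jit[2] * p$qrs_width_ms / 1000 / 4   # width ~ 4 sd of the bump
    qa <- jit[1] * p$qrs_amp_mV
    lead_a <- lead_a + bump(rt, qrs_sd, qa[1]) +
      bump(rt - 0.17, 0.02, jit[1] * p$p_amp_mV) +
      bump(rt + 0.28, 0.05, jit[1] * p$t_amp_mV)
    lead_b <- lead_b + bump(rt, qrs_sd, qa[2]) +
      bump(rt - 0.17, 0.02, 0.5 * jit[1] * p$p_amp_mV) +
      bump(rt + 0.28, 0.05, 0.5 * jit[1] * p$t_amp_mV)
  }
  wander <- config$wander_amp_mV * sin(2 * pi * config$wander_freq_hz * tt)
  lead_a <- lead_a + wander + stats::rnorm(n_samp, 0, config$noise_sd_mV)
  lead_b <- lead_b + wander + stats::rnorm(n_samp, 0, config$noise_sd_mV)

  beats <- data.frame(sample = as.integer(round_half_up(r_times * fs)),
                      symbol = unname(.synth_symbols[class_sequence]),
                      stringsAsFactors = FALSE)
  ecg_record(lead_a, lead_b, fs = fs, beats = beats, record_id = record_id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fiducial points for synthetic records
#'
#' Derives QRS onset/offset, T end and P presence from the generator
#' configuration rather than from the signal — the stand-in for an external
#' delineator, valid only for records built by [synth_record()]. The QRS span
#' is `round(qrs_width_ms/1000 * fs)` samples (round half up), centered on the
#' annotation.
#'
#' @param record An [ecg_record] produced by [synth_record()].
#' @param config The [synth_config()] used to generate it.
#' @return Data frame with one row per beat: `r_index`, `qrs_onset`,
#'   `qrs_offset`, `t_end` (0-based samples), `p_wave_present`, `label`.
#' @export
synth_fiducials <- function(record, config) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "synth_config"))
  fs <- record$fs
  cls <- aami_superclass(record$beats$symbol)
  w <- vapply(cls, function(cl)
    round_half_up(config$class_params[[cl]]$qrs_width_ms / 1000 * fs), numeric(1))
  t_end_off <- vapply(cls, function(cl)
    round_half_up(config$class_params[[cl]]$t_end_ms / 1000 * fs), numeric(1))
  p_present <- vapply(cls, function(cl)
    config$class_params[[cl]]$p_amp_mV > 0, logical(1))
  r <- record$beats$sample
  onset <- as.integer(r - floor(w / 2))
  data.frame(r_index = r,
             qrs_onset = onset,
             qrs_offset = as.integer(onset + w),
             t_end = as.integer(r + t_end_off),
             p_wave_present = unname(p_present),
             label = unname(cls),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-patient corpus
#'
#' One record per "patient", each with its own seeded morphology offset, so
#' tests can form inter-patient train/test splits. Class proportions default
#' to the imbalance typical of ambulatory recordings (mostly N, few S/V).
#'
#' @param n_patients Number of records.
#' @param beats_per_patient Beats per record.
#' @param seed Integer master seed; patient k uses `seed + k`.
#' @param config A [synth_config()].
#' @param class_prob Sampling probabilities for N, S, V.
#' @return List with one element per patient: `record`, `fiducials`.
#' @export
synth_corpus <- function(n_patients = 6, beats_per_patient = 100, seed = 1L,
                         config = synth_config(),
                         class_prob = c(N = 0.7, S = 0.15, V = 0.15)) {
  lapply(seq_len(n_patients), function(k) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed * 1000L + k)
    cls <- sample(names(class_prob), beats_per_patient, replace = TRUE,
                  prob = class_prob)
    rec <- synth_record(config, cls, seed = seed * 1000L + k,
                        record_id = sprintf("P%02d", k))
    list(record = rec, fiducials = synth_fiducials(rec, config))
  })
}
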