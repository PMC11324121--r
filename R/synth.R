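#' Beat morphology parameters
#'
#' Parameters of the five-bump (P, Q, R, S, T) Gaussian beat model used by
#' the synthetic generator. Each wave has an amplitude (mV), a center offset
#' within the beat (seconds from beat onset) and a Gaussian width (seconds).
#' Defaults sketch a generic normal sinus beat viewed from a lead-II-like
#' axis.
#'
#' @param amplitude Named numeric, mV, for waves P, Q, R, S, T.
#' @param center Named numeric, seconds from beat onset.
#' @param width Named numeric, seconds; all strictly positive.
#' @param heart_rate Beats per minute, in \[30, 200\].
#' @param rr_jitter_sd Standard deviation of the beat-to-beat RR jitter (s).
#' @return A `beat_params` list.
#' @export
beat_params <- function(amplitude = c(P = 0.15, Q = -0.10, R = 1.00,
                                      S = -0.20, T = 0.30),
                        center = c(P = 0.10, Q = 0.20, R = 0.23,
                                   S = 0.26, T = 0.42),
                        width = c(P = 0.025, Q = 0.010, R = 0.012,
                                  S = 0.012, T = 0.060),
                        heart_rate = 70,
                        rr_jitter_sd = 0.02) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amplitude), waves),
            setequal(names(center), waves),
            setequal(names(width), waves),
            all(width > 0),
            heart_rate >= 30, heart_rate <= 200,
            rr_jitter_sd >= 0)
  structure(list(amplitude = amplitude[waves], center = center[waves],
                 width = width[waves], heart_rate = heart_rate,
                 rr_jitter_sd = rr_jitter_sd),
            class = "beat_params")
}

#' Synthesize one beat
#'
#' Evaluates the sum of the five Gaussian bumps over one RR interval at the
#' given sampling rate. The waveform is linear in the amplitudes.
#'
#' @param params A [beat_params()] object.
#' @param sampling_rate Hz.
#' @param rr Optional RR interval in seconds (default `60 / heart_rate`).
#' @return Numeric vector of length `round(rr * sampling_rate)`, mV.
#' @export
synth_beat <- function(params, sampling_rate = 500, rr = NULL) {
  stopifnot(inherits(params, "beat_params"))
  if (is.null(rr)) rr <- 60 / params$heart_rate
  n <- round(rr * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  y <- numeric(n)
  for (w in c("P", "Q", "R", "S", "T")) {
    y <- y + params$amplitude[[w]] *
      exp(-(t - params$center[[w]])^2 / (2 * params$width[[w]]^2))
  }
  y
}

#' Default per-lead projection vector
#'
#' Fixed 12-entry projection mapping the scalar beat waveform to the 12
#' leads, roughly mimicking limb/precordial polarity patterns (positive
#' inferior-lateral leads, negative aVR, transitional V1). A documented
#' constant, not a physiological model.
#'
#' @format Named numeric vector of length 12 in [ECG_LEADS] order.
#' @export
LEAD_PROJECTION <- c(I = 0.6, II = 1.0, III = 0.5,
                     aVR = -0.8, aVL = 0.2, aVF = 0.7,
                     V1 = -0.4, V2 = 0.3, V3 = 0.6,
                     V4 = 0.9, V5 = 0.8, V6 = 0.7)

#' Synthesize one 12-lead record
#'
#' Concatenates beats with jittered RR intervals, projects the scalar
#' waveform to 12 leads with the patient's projection vector, adds a
#' sinusoidal baseline wander (shared phase across leads) and white Gaussian
#' noise per lead, and trims/pads to exactly 5000 samples at 500 Hz.
#' Fully deterministic given `seed`.
#'
#' @param state List with elements `beat` ([beat_params()]), `projection`
#'   (12-vector), `noise_sd` (mV), `wander_amp` (mV), `wander_freq` (Hz).
#' @param seed Integer seed.
#' @param record_id,patient_id,acquisition_date Metadata for the record.
#' @return An [ecg_record()].
#' @export
synth_record <- function(state, seed, record_id = "synth",
                         patient_id = "pt",
                         acquisition_date = as.Date("2020-01-01")) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  fs <- 500L
  n_target <- 5000L
  bp <- state$beat
  wave <- numeric(0)
  while (length(wave) < n_target) {
    rr <- 60 / bp$heart_rate +
      (if (bp$rr_jitter_sd > 0) stats::rnorm(1, 0, bp$rr_jitter_sd) else 0)
    rr <- max(rr, 0.25)
    wave <- c(wave, synth_beat(bp, fs, rr = rr))
  }
  wave <- wave[seq_len(n_target)]
  t <- (seq_len(n_target) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  wander <- if (state$wander_amp > 0) {
    state$wander_amp * sin(2 * pi * state$wander_freq * t + phase)
  } else {
    numeric(n_target)
  }
  sig <- matrix(0, 12L, n_target)
  for (k in 1:12) {
    noise <- if (state$noise_sd > 0) {
      stats::rnorm(n_target, 0, state$noise_sd)
    } else {
      numeric(n_target)
    }
    sig[k, ] <- state$projection[[k]] * wave + wander + noise
  }
  ecg_record(sig, record_id = record_id, patient_id = patient_id,
             acquisition_date = acquisition_date, sampling_rate = fs)
}

#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic multi-ECG-per-patient cohort. The
#' defaults emulate the scale of a hospital ECG-echocardiography population:
#' LVSD prevalence 8.3%, a normal-EF component with mean 61.6 and SD 14.2
#' (truncated to \[40, 95\]), LVSD EF uniform on \[15, 39.5\], and 1-3 ECGs
#' per patient (mean about 1.6).
#'
#' @param n_patients Number of patients.
#' @param ecgs_per_patient Probability weights for 1, 2, 3 ECGs per patient.
#' @param lvsd_prevalence Fraction of patients with LVSD.
#' @param effect_size Non-negative scalar scaling the LVSD morphology shift:
#'   at effect size `e` and ejection fraction EF, the R amplitude is
#'   multiplied by `1 - 0.4 * e * (1 - EF/60)`, the QRS (Q, R, S) widths by
#'   `1 + 0.5 * e`, and the heart rate increases by `10 * e` bpm. At
#'   `effect_size = 0` the LVSD and non-LVSD signal distributions coincide.
#' @param noise_sd White-noise SD per lead (mV).
#' @param wander_amp,wander_freq Baseline-wander amplitude (mV) / frequency
#'   (Hz).
#' @param ef_normal_mean,ef_normal_sd Moments of the non-LVSD EF component.
#' @param ef_lvsd_range EF range (uniform) for LVSD patients, below 40.
#' @param seed Integer seed; the whole cohort is deterministic in it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 400,
                         ecgs_per_patient = c(`1` = 0.55, `2` = 0.30,
                                              `3` = 0.15),
                         lvsd_prevalence = 0.083,
                         effect_size = 1.0,
                         noise_sd = 0.05,
                         wander_amp = 0.10,
                         wander_freq = 0.33,
                         ef_normal_mean = 61.6,
                         ef_normal_sd = 14.2,
                         ef_lvsd_range = c(15, 39.5),
                         seed = 1L) {
  stopifnot(n_patients >= 1,
            lvsd_prevalence >= 0, lvsd_prevalence <= 1,
            effect_size >= 0,
            all(ef_lvsd_range > 0), all(ef_lvsd_range < 40))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic ECG-echo cohort
#'
#' Draws per-patient LVSD status at the configured prevalence, an EF from
#' the matching component, and baseline beat morphology; applies the
#' EF-linked LVSD morphology shift scaled by `effect_size`; then emits 1-3
#' ECG records per patient plus exactly one echo exam, with ECG dates within
#' 28 days of the echo. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with `records` (list of [ecg_record()]), `echoes` (tibble of
#'   echo exams), `ecg_meta` (tibble of ECG metadata suitable for
#'   [pair_exams()]) and `patients` (tibble of per-patient ground truth).
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  base_date <- as.Date("2020-06-01")
  n <- config$n_patients
  records <- list()
  ecg_meta <- list()
  echoes <- list()
  patients <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("P%05d", p)
    lvsd <- stats::runif(1) < config$lvsd_prevalence
    # both branches consume exactly one uniform, so the downstream stream
    # (morphology, dates, record seeds) is identical across LVSD status:
    # at effect_size 0 the two groups generate identical signals
    u <- stats::runif(1)
    ef <- if (lvsd) {
      config$ef_lvsd_range[1] +
        u * diff(config$ef_lvsd_range)
    } else {
      # truncated normal on [40, 95] by inverse CDF
      mu <- config$ef_normal_mean; s <- config$ef_normal_sd
      lo <- stats::pnorm((40 - mu) / s); hi <- stats::pnorm((95 - mu) / s)
      mu + s * stats::qnorm(lo + u * (hi - lo))
    }
    # per-patient baseline variation around the template beat
    amp_scale <- exp(stats::rnorm(1, 0, 0.10))
    hr <- min(max(stats::rnorm(1, 70, 8), 45), 120)
    bp <- beat_params(heart_rate = hr)
    bp$amplitude <- bp$amplitude * amp_scale
    proj <- LEAD_PROJECTION * exp(stats::rnorm(12, 0, 0.05))
    if (lvsd && config$effect_size > 0) {
      e <- config$effect_size
      bp$amplitude[["R"]] <- bp$amplitude[["R"]] *
        (1 - 0.4 * e * (1 - ef / 60))
      bp$width[c("Q", "R", "S")] <- bp$width[c("Q", "R", "S")] *
        (1 + 0.5 * e)
      bp$heart_rate <- min(bp$heart_rate + 10 * e, 200)
    }
    state <- list(beat = bp, projection = proj,
                  noise_sd = config$noise_sd,
                  wander_amp = config$wander_amp,
                  wander_freq = config$wander_freq)
    echo_date <- base_date + sample.int(365L, 1L)
    n_ecg <- sample(seq_along(config$ecgs_per_patient), 1L,
                    prob = config$ecgs_per_patient)
    offsets <- sample(-20:20, n_ecg)
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_ecg)
    for (j in seq_len(n_ecg)) {
      rid <- sprintf("%s_E%d", pid, j)
      rec <- synth_record(state, seed = rec_seeds[[j]], record_id = rid,
                          patient_id = pid,
                          acquisition_date = echo_date + offsets[[j]])
      records[[rid]] <- rec
      ecg_meta[[rid]] <- tibble::tibble(
        record_id = rid, patient_id = pid,
        acquisition_date = rec$acquisition_date)
    }
    echoes[[pid]] <- tibble::tibble(
      exam_id = sprintf("%s_ECHO", pid), patient_id = pid,
      exam_date = echo_date, ejection_fraction = ef)
    patients[[pid]] <- tibble::tibble(
      patient_id = pid, lvsd = as.integer(lvsd), ejection_fraction = ef,
      n_ecg = n_ecg)
  }
  list(records = records,
       echoes = dplyr::bind_rows(echoes),
       ecg_meta = dplyr::bind_rows(ecg_meta),
       patients = dplyr::bind_rows(patients))
}
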