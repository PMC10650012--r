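#' Study design for a synthetic swallowing experiment
#'
#' Describes the experimental layout the generator emulates: subjects recorded
#' on two days with bilateral (right/left) sensors over the sternohyoid
#' muscles, performing cued drinking sips of graded volumes plus non-drinking
#' tasks (talking, coughing, saliva and solid swallows). Defaults reproduce
#' the reference protocol: 11 subjects x 2 days, 2.2 kHz sampling, five
#' volumes 5-25 mL with 12 sips each (60 drinking events) and 10 events for
#' each of four non-drinking classes (40 events) per subject-day.
#'
#' @param n_subjects number of subjects.
#' @param n_days number of recording days per subject.
#' @param sides character vector of recorded sides.
#' @param fs sampling rate in Hz.
#' @param volumes ordered sip volumes in mL.
#' @param sips_per_volume sips recorded per volume level.
#' @param nondrink_classes non-drinking event classes.
#' @param events_per_nondrink_class events per non-drinking class.
#' @param seed integer root seed; every random draw in the generated study is
#'   derived deterministically from it.
#' @return an object of class `study_design`.
#' @export
#' @examples
#' d <- study_design(n_subjects = 2, seed = 1)
#' d$n_subjects
study_design <- function(n_subjects = 11L,
                         n_days = 2L,
                         sides = c("right", "left"),
                         fs = 2200,
                         volumes = c(5, 10, 15, 20, 25),
                         sips_per_volume = 12L,
                         nondrink_classes = c("talk", "cough", "saliva", "solid"),
                         events_per_nondrink_class = 10L,
                         seed = 1L) {
  if (n_subjects < 1 || n_days < 1) stop("n_subjects and n_days must be positive", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (sips_per_volume < 0 || events_per_nondrink_class < 0)
    stop("event counts must be nonnegative", call. = FALSE)
  if (length(volumes) && any(volumes <= 0)) stop("volumes must be positive mL values", call. = FALSE)
  if (!length(sides)) stop("at least one side required", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_days = as.integer(n_days),
    sides = as.character(sides),
    fs = fs,
    volumes = as.numeric(volumes),
    sips_per_volume = as.integer(sips_per_volume),
    nondrink_classes = as.character(nondrink_classes),
    events_per_nondrink_class = as.integer(events_per_nondrink_class),
    seed = as.integer(seed)
  ), class = "study_design")
}

#' Parameters of the synthetic sEMG burst generator
#'
#' Each event is synthesised as band-limited Gaussian noise shaped by a smooth
#' unimodal (Hann) envelope on top of baseline noise. Class-specific
#' duration, amplitude and carrier band give the five event classes distinct
#' but overlapping signatures; for drinking events, envelope peak amplitude
#' and burst duration grow linearly with sip volume so that volume is
#' recoverable (imperfectly) from burst features. Multiplicative log-normal
#' subject gains, day drifts and per-sip noise, plus a fixed right/left gain
#' ratio, emulate between-subject, between-day and between-channel
#' variability. Setting both volume slopes to zero gives volume-uninformative
#' drinking bursts (null-effect mode).
#'
#' @param burst_duration_mean_s named numeric: mean burst duration per class
#'   (seconds).
#' @param burst_duration_sd_s named numeric: per-event duration SD per class.
#' @param burst_amplitude_base named numeric: envelope peak amplitude per
#'   class, arbitrary units on a millivolt-like scale.
#' @param volume_amplitude_slope relative amplitude gain per mL for drinking
#'   bursts.
#' @param volume_duration_slope seconds of extra burst duration per mL.
#' @param spectral_band named list of `c(low, high)` Hz carrier bands per
#'   class.
#' @param baseline_noise_sd SD of the ever-present baseline Gaussian noise.
#' @param subject_gain_sd SD (log scale) of the per-subject amplitude gain.
#' @param day_drift_sd SD (log scale) of the per-subject-day drift gain.
#' @param side_asymmetry right/left amplitude gain ratio.
#' @param sip_noise_sd SD (log scale) of per-event amplitude noise.
#' @param inter_event_gap_s nominal spacing between consecutive event centres
#'   (seconds).
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(
    burst_duration_mean_s = c(drink = 1.0, talk = 1.8, cough = 0.35,
                              saliva = 0.8, solid = 1.2),
    burst_duration_sd_s = c(drink = 0.10, talk = 0.20, cough = 0.05,
                            saliva = 0.10, solid = 0.15),
    burst_amplitude_base = c(drink = 1.0, talk = 0.45, cough = 2.2,
                             saliva = 0.85, solid = 0.95),
    volume_amplitude_slope = 0.02,
    volume_duration_slope = 0.01,
    spectral_band = list(drink = c(30, 150), talk = c(60, 250),
                         cough = c(20, 350), saliva = c(30, 150),
                         solid = c(40, 190)),
    baseline_noise_sd = 0.05,
    subject_gain_sd = 0.15,
    day_drift_sd = 0.10,
    side_asymmetry = 1.15,
    sip_noise_sd = 0.10,
    inter_event_gap_s = 4) {
  p <- structure(list(
    burst_duration_mean_s = burst_duration_mean_s,
    burst_duration_sd_s = burst_duration_sd_s,
    burst_amplitude_base = burst_amplitude_base,
    volume_amplitude_slope = volume_amplitude_slope,
    volume_duration_slope = volume_duration_slope,
    spectral_band = spectral_band,
    baseline_noise_sd = baseline_noise_sd,
    subject_gain_sd = subject_gain_sd,
    day_drift_sd = day_drift_sd,
    side_asymmetry = side_asymmetry,
    sip_noise_sd = sip_noise_sd,
    inter_event_gap_s = inter_event_gap_s
  ), class = "generator_params")
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p, fs = NULL) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(p$burst_duration_mean_s) || any(p$burst_duration_mean_s <= 0))
    stop("burst durations must be positive", call. = FALSE)
  if (!num_ok(p$burst_duration_sd_s) || any(p$burst_duration_sd_s < 0))
    stop("duration SDs must be nonnegative", call. = FALSE)
  if (!num_ok(p$burst_amplitude_base) || any(p$burst_amplitude_base <= 0))
    stop("burst amplitudes must be positive", call. = FALSE)
  for (v in c("baseline_noise_sd", "subject_gain_sd", "day_drift_sd", "sip_noise_sd"))
    if (p[[v]] < 0) stop(v, " must be nonnegative", call. = FALSE)
  if (p$side_asymmetry <= 0) stop("side_asymmetry must be positive", call. = FALSE)
  if (p$inter_event_gap_s <= 0) stop("inter_event_gap_s must be positive", call. = FALSE)
  for (cls in names(p$spectral_band)) {
    b <- p$spectral_band[[cls]]
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop("invalid spectral band for class '", cls, "' (need 0 < low < high)", call. = FALSE)
    if (!is.null(fs) && b[2] >= fs / 2)
      stop("spectral band for class '", cls, "' reaches the Nyquist frequency", call. = FALSE)
  }
  invisible(p)
}

# Per-subject-day event schedule implied by a design: one row per event with
# class, volume (NA for non-drinking) and within-class sip index.
design_event_table <- function(design) {
  cls <- character(0); vol <- numeric(0)
  for (v in design$volumes) {
    cls <- c(cls, rep("drink", design$sips_per_volume))
    vol <- c(vol, rep(v, design$sips_per_volume))
  }
  for (nc in design$nondrink_classes) {
    cls <- c(cls, rep(nc, design$events_per_nondrink_class))
    vol <- c(vol, rep(NA_real_, design$events_per_nondrink_class))
  }
  data.frame(label = cls, volume_ml = vol, stringsAsFactors = FALSE)
}
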