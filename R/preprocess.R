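#' Preprocessing configuration
#'
#' Settings for the filtering and burst-segmentation stage: a zero-phase
#' Butterworth band-pass (default 10-400 Hz, order 4, applied
#' forward-backward), a rectified-signal envelope low-pass (default 1 Hz),
#' the burst window length (default 2 s, i.e. 1 s either side of the envelope
#' peak) and the half-width of the peak search around each annotated event
#' time. The envelope here serves peak localisation, not burst morphology:
#' smoothing at the burst timescale (about 1 Hz for ~1-s bursts) acts as a
#' matched smoother and keeps the envelope argmax from wandering on the flat
#' top of a burst; a faster envelope (5-10 Hz) tracks the waveform more
#' closely but localises peaks of interference-pattern EMG far less stably.
#'
#' @param bp_low band-pass lower edge, Hz.
#' @param bp_high band-pass upper edge, Hz.
#' @param filter_order Butterworth order (before the forward-backward pass).
#' @param envelope_cutoff envelope low-pass cutoff, Hz.
#' @param window_s burst window duration, seconds.
#' @param search_halfwidth_s peak search half-width around the annotated
#'   event time, seconds.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(bp_low = 10, bp_high = 400, filter_order = 4,
                              envelope_cutoff = 1, window_s = 2.0,
                              search_halfwidth_s = 1.5) {
  if (bp_low <= 0 || bp_high <= bp_low)
    stop("need 0 < bp_low < bp_high", call. = FALSE)
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (envelope_cutoff <= 0) stop("envelope_cutoff must be positive", call. = FALSE)
  if (search_halfwidth_s <= 0) stop("search_halfwidth_s must be positive", call. = FALSE)
  structure(list(bp_low = bp_low, bp_high = bp_high,
                 filter_order = as.integer(filter_order),
                 envelope_cutoff = envelope_cutoff, window_s = window_s,
                 search_halfwidth_s = search_halfwidth_s),
            class = "preprocess_config")
}

check_band <- function(cfg, fs) {
  if (cfg$bp_high >= fs / 2)
    stop("bp_high (", cfg$bp_high, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  invisible(cfg)
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a Butterworth band-pass forward and backward (`filtfilt`), so the
#' output has no phase lag and burst peak times are not biased.
#'
#' @param recording an `emg_recording`.
#' @param cfg a [preprocess_config()].
#' @return the recording with filtered samples (same length).
#' @export
bandpass_filter <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(recording, "emg_recording"))
  check_band(cfg, recording$fs)
  bt <- signal::butter(cfg$filter_order,
                       c(cfg$bp_low, cfg$bp_high) / (recording$fs / 2),
                       type = "pass")
  recording$samples <- signal::filtfilt(bt, recording$samples)
  recording
}

#' Rectified-signal envelope
#'
#' Rectifies the (already band-passed) signal and low-passes the result with
#' a zero-phase Butterworth filter at `envelope_cutoff`; small negative
#' filter ringing is clipped to zero. The envelope's local maxima localise
#' muscle-activation bursts.
#'
#' @inheritParams bandpass_filter
#' @return the recording with envelope samples (nonnegative, same length).
#' @export
emg_envelope <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(recording, "emg_recording"))
  bt <- signal::butter(cfg$filter_order,
                       cfg$envelope_cutoff / (recording$fs / 2),
                       type = "low")
  env <- signal::filtfilt(bt, abs(recording$samples))
  recording$samples <- pmax(env, 0)
  recording
}

#' Extract peak-centred burst windows
#'
#' For each annotated event, searches the rectified-signal envelope within
#' `search_halfwidth_s` of the annotated time for its maximum, then cuts a
#' window of exactly `round(window_s * fs)` samples from the band-passed
#' (not rectified) signal, centred on that peak — with the default 2-s window
#' this is 1 s before and 1 s after the highest peak. Windows that would
#' extend past the recording edges are zero-padded and flagged. Annotations
#' falling outside the recording are skipped and reported in the `skipped`
#' attribute of the result.
#'
#' @param recording a raw `emg_recording` (filtering is applied internally).
#' @param annotations data frame with at least `time_s` and `label` columns;
#'   `volume_ml` and `event_index` are carried through when present.
#' @param cfg a [preprocess_config()].
#' @param filtered optionally, the already band-passed recording (to avoid
#'   refiltering); must match `recording` in length and fs.
#' @return a list of `burst_window` objects, each with fields `samples`
#'   (length exactly `round(window_s * fs)`), `fs`, `peak_index` (position of
#'   the envelope peak inside the window; the centre sample unless edge
#'   padding occurred), `peak_time_s`, `padded`, `label`, `volume_ml`,
#'   `subject`, `day`, `side`, `event_index`. Skipped events are recorded in
#'   `attr(, "skipped")`.
#' @export
extract_bursts <- function(recording, annotations, cfg = preprocess_config(),
                           filtered = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  check_band(cfg, recording$fs)
  fs <- recording$fs
  if (is.null(filtered)) filtered <- bandpass_filter(recording, cfg)
  env <- emg_envelope(filtered, cfg)$samples
  x <- filtered$samples
  n_sig <- length(x)
  n_win <- round(cfg$window_s * fs)
  half <- n_win %/% 2
  ord <- order(annotations$time_s)
  annotations <- annotations[ord, , drop = FALSE]

  windows <- list()
  skipped <- data.frame(event_index = integer(0), time_s = numeric(0),
                        reason = character(0))
  for (i in seq_len(nrow(annotations))) {
    t0 <- annotations$time_s[i]
    ev_idx <- if ("event_index" %in% names(annotations))
      annotations$event_index[i] else i
    if (!is.finite(t0) || t0 < 0 || t0 > (n_sig - 1) / fs) {
      skipped <- rbind(skipped, data.frame(
        event_index = ev_idx, time_s = t0,
        reason = "annotation outside recording"))
      next
    }
    c0 <- round(t0 * fs) + 1L
    lo <- max(1L, c0 - round(cfg$search_halfwidth_s * fs))
    hi <- min(n_sig, c0 + round(cfg$search_halfwidth_s * fs))
    peak <- lo + which.max(env[lo:hi]) - 1L
    start <- peak - half
    idx <- start:(start + n_win - 1L)
    keep <- idx >= 1L & idx <= n_sig
    seg <- numeric(n_win)
    seg[keep] <- x[idx[keep]]
    windows[[length(windows) + 1L]] <- structure(list(
      samples = seg, fs = fs,
      peak_index = peak - start + 1L,
      peak_time_s = (peak - 1L) / fs,
      start_time_s = (start - 1L) / fs,
      padded = !all(keep),
      label = annotations$label[i],
      volume_ml = if ("volume_ml" %in% names(annotations))
        annotations$volume_ml[i] else NA_real_,
      subject = recording$subject, day = recording$day, side = recording$side,
      event_index = ev_idx), class = "burst_window")
  }
  attr(windows, "skipped") <- skipped
  windows
}

#' Segment every recording of a study into burst windows
#'
#' Convenience wrapper applying [extract_bursts()] to each subject-day-side
#' recording with its matching annotation rows.
#'
#' @param study an `emg_study`.
#' @param cfg a [preprocess_config()].
#' @return a flat list of `burst_window` objects.
#' @export
extract_study_bursts <- function(study, cfg = preprocess_config()) {
  stopifnot(inherits(study, "emg_study"))
  out <- list()
  for (rec in study$recordings) {
    ann <- study$annotations[study$annotations$subject == rec$subject &
                               study$annotations$day == rec$day, , drop = FALSE]
    out <- c(out, extract_bursts(rec, ann, cfg))
  }
  out
}
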