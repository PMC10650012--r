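#' Generate a synthetic sEMG swallowing study
#'
#' Simulates one continuous two-channel recording per subject-day, with all
#' cued events (drinking sips of graded volume plus talk/cough/saliva/solid
#' events) laid out sequentially with gaps, and returns the matching
#' event-annotation table. Each burst is band-limited Gaussian noise shaped by
#' a smooth unimodal envelope whose peak amplitude and duration depend on
#' event class, sip volume, subject gain, day drift and recording side; the
#' talk class is an intermittent train of short sub-bursts. Both sides of a
#' subject-day share one event schedule (two channels of one session) but
#' carry independent carrier noise.
#'
#' All randomness derives from `design$seed`, split deterministically per
#' subject, day and side, so the same design and parameters always reproduce
#' bit-identical recordings.
#'
#' @param design a [study_design()].
#' @param params a [generator_params()].
#' @return an object of class `emg_study`: a list with elements
#'   `design`, `params`, `recordings` (list of `emg_recording`, one per
#'   subject-day-side, each with `samples`, `fs`, `subject`, `day`, `side`)
#'   and `annotations` (data frame with columns `subject`, `day`,
#'   `event_index`, `time_s`, `label`, `volume_ml`; shared by both sides).
#' @export
#' @examples
#' study <- generate_study(study_design(n_subjects = 1, n_days = 1, seed = 3),
#'                         generator_params())
#' table(subset(study$annotations, subject == 1 & day == 1)$label)
generate_study <- function(design, params = generator_params()) {
  stopifnot(inherits(design, "study_design"))
  validate_generator_params(params, fs = design$fs)
  ev_template <- design_event_table(design)
  n_ev <- nrow(ev_template)
  if (n_ev == 0) stop("design yields zero events per subject-day", call. = FALSE)

  fs <- design$fs
  gap <- params$inter_event_gap_s
  lead <- 2
  total_s <- lead + n_ev * gap + lead
  n_total <- round(total_s * fs)

  recordings <- list()
  ann_all <- list()
  filt_cache <- lapply(params$spectral_band, function(b)
    signal::butter(2, b / (fs / 2), type = "pass"))

  for (subj in seq_len(design$n_subjects)) {
    subj_gain <- with_seed(child_seed(design$seed, 7, subj),
                           exp(rnorm(1, 0, params$subject_gain_sd)))
    for (day in seq_len(design$n_days)) {
      day_drift <- with_seed(child_seed(design$seed, 11, subj, day),
                             exp(rnorm(1, 0, params$day_drift_sd)))
      sched <- with_seed(child_seed(design$seed, 13, subj, day), {
        ord <- sample.int(n_ev)
        ev <- ev_template[ord, , drop = FALSE]
        ev$time_s <- lead + gap / 2 + (seq_len(n_ev) - 1) * gap +
          runif(n_ev, -0.25, 0.25)
        mu <- params$burst_duration_mean_s[ev$label] +
          ifelse(ev$label == "drink",
                 params$volume_duration_slope * ev$volume_ml, 0)
        ev$duration_s <- pmax(0.12, mu + rnorm(n_ev, 0,
                              params$burst_duration_sd_s[ev$label]))
        amp <- params$burst_amplitude_base[ev$label] *
          ifelse(ev$label == "drink",
                 1 + params$volume_amplitude_slope * ev$volume_ml, 1) *
          exp(rnorm(n_ev, 0, params$sip_noise_sd))
        ev$amplitude <- amp * subj_gain * day_drift
        # talk: per-event sub-burst amplitude jitter, shared across sides
        ev$subburst_seed <- sample.int(2^30, n_ev)
        ev
      })
      for (si in seq_along(design$sides)) {
        side <- design$sides[si]
        side_gain <- if (side == "right") sqrt(params$side_asymmetry)
                     else 1 / sqrt(params$side_asymmetry)
        x <- with_seed(child_seed(design$seed, 17, subj, day, si), {
          sig <- rnorm(n_total, 0, params$baseline_noise_sd)
          for (i in seq_len(n_ev)) {
            env <- burst_envelope(sched$label[i], sched$duration_s[i], fs,
                                  sched$subburst_seed[i])
            m <- length(env)
            carrier <- band_noise(m, filt_cache[[sched$label[i]]])
            i0 <- round(sched$time_s[i] * fs) - m %/% 2
            idx <- i0:(i0 + m - 1)
            keep <- idx >= 1 & idx <= n_total
            sig[idx[keep]] <- sig[idx[keep]] +
              sched$amplitude[i] * side_gain * env[keep] * carrier[keep]
          }
          sig
        })
        recordings[[length(recordings) + 1L]] <- new_recording(
          samples = x, fs = fs, subject = subj, day = day, side = side)
      }
      ann_all[[length(ann_all) + 1L]] <- data.frame(
        subject = subj, day = day, event_index = seq_len(n_ev),
        time_s = sched$time_s, label = sched$label,
        volume_ml = sched$volume_ml, stringsAsFactors = FALSE)
    }
  }
  structure(list(design = design, params = params,
                 recordings = recordings,
                 annotations = do.call(rbind, ann_all)),
            class = "emg_study")
}

new_recording <- function(samples, fs, subject, day, side) {
  stopifnot(length(samples) > 0, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject = subject, day = day, side = side),
            class = "emg_recording")
}

#' @export
print.emg_study <- function(x, ...) {
  cat("<emg_study> ", x$design$n_subjects, " subjects x ", x$design$n_days,
      " days x ", length(x$design$sides), " sides, fs = ", x$design$fs,
      " Hz, ", nrow(x$annotations), " annotated events\n", sep = "")
  invisible(x)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> subject ", x$subject, ", day ", x$day, ", ", x$side,
      ": ", length(x$samples), " samples @ ", x$fs, " Hz (",
      round(length(x$samples) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

# Unit-RMS band-limited Gaussian noise of length n, shaped by a cached
# Butterworth band-pass. A short run-in pad absorbs the filter transient.
band_noise <- function(n, filt) {
  pad <- 200L
  w <- rnorm(n + 2L * pad)
  y <- signal::filtfilt(filt, w)[(pad + 1L):(pad + n)]
  y / sqrt(mean(y^2))
}

# Smooth unimodal burst envelope (Hann bump of the given duration), except for
# the talk class which is a train of short Hann sub-bursts with jittered
# amplitudes, emulating syllabic muscle activations.
burst_envelope <- function(label, duration_s, fs, subseed = 1L) {
  m <- max(3L, round(duration_s * fs))
  if (label != "talk") {
    return(hann_bump(m))
  }
  k <- max(2L, round(duration_s / 0.3))
  env <- numeric(m)
  w <- max(3L, round(0.18 * fs))
  amps <- with_seed(subseed, runif(k, 0.5, 1))
  centers <- round((seq_len(k) - 0.5) * m / k)
  bump <- hann_bump(w)
  for (j in seq_len(k)) {
    i0 <- centers[j] - w %/% 2
    idx <- i0:(i0 + w - 1)
    keep <- idx >= 1 & idx <= m
    env[idx[keep]] <- pmax(env[idx[keep]], amps[j] * bump[keep])
  }
  env
}

hann_bump <- function(m) {
  0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
}
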