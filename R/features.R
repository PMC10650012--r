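#' Spectral and threshold settings for feature extraction
#'
#' Holds every numeric setting the 26-feature catalogue depends on, so a
#' feature matrix is fully specified by its window set plus one
#' `spectral_config`. Power spectral densities use Welch's method with
#' Hann-tapered segments of `psd_seg_s` seconds and 50% overlap (0.5 s
#' segments give 2 Hz resolution at 2.2 kHz). Short-time features (SF, MFCC)
#' use `frame_len`-sample frames with 50% overlap. The ZC/WAMP/MYOP
#' amplitude thresholds are expressed as multiples of the window RMS, making
#' them robust to amplitude scaling across subjects and channels.
#'
#' @param psd_seg_s Welch segment length, seconds.
#' @param psd_overlap Welch segment overlap fraction.
#' @param fr_low_band,fr_high_band numerator and denominator bands (Hz) of
#'   the frequency-ratio feature.
#' @param ar_order autoregressive model order.
#' @param lpcc_order number of linear-prediction cepstral coefficients.
#' @param mfcc_n_filters number of mel filters.
#' @param mfcc_n_coeffs number of mel-cepstral coefficients retained.
#' @param frame_len short-time frame length, samples.
#' @param frame_overlap short-time frame overlap fraction.
#' @param zc_threshold,wamp_threshold,myop_threshold amplitude thresholds as
#'   multiples of the window RMS.
#' @param entropy_bins histogram bins for the amplitude-entropy feature.
#' @param ecdf_points evaluation points for the ECDF feature.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(psd_seg_s = 0.5, psd_overlap = 0.5,
                            fr_low_band = c(10, 250),
                            fr_high_band = c(250, 500),
                            ar_order = 4L, lpcc_order = 4L,
                            mfcc_n_filters = 20L, mfcc_n_coeffs = 12L,
                            frame_len = 256L, frame_overlap = 0.5,
                            zc_threshold = 0.05, wamp_threshold = 0.5,
                            myop_threshold = 0.5,
                            entropy_bins = 64L, ecdf_points = 10L) {
  if (ar_order < 1 || lpcc_order < 1) stop("model orders must be >= 1", call. = FALSE)
  if (fr_low_band[1] >= fr_low_band[2] || fr_high_band[1] >= fr_high_band[2] ||
      fr_low_band[2] > fr_high_band[1])
    stop("frequency-ratio bands must be increasing and disjoint", call. = FALSE)
  if (psd_overlap < 0 || psd_overlap >= 1 || frame_overlap < 0 || frame_overlap >= 1)
    stop("overlap fractions must be in [0, 1)", call. = FALSE)
  structure(list(psd_seg_s = psd_seg_s, psd_overlap = psd_overlap,
                 fr_low_band = fr_low_band, fr_high_band = fr_high_band,
                 ar_order = as.integer(ar_order),
                 lpcc_order = as.integer(lpcc_order),
                 mfcc_n_filters = as.integer(mfcc_n_filters),
                 mfcc_n_coeffs = as.integer(mfcc_n_coeffs),
                 frame_len = as.integer(frame_len),
                 frame_overlap = frame_overlap,
                 zc_threshold = zc_threshold, wamp_threshold = wamp_threshold,
                 myop_threshold = myop_threshold,
                 entropy_bins = as.integer(entropy_bins),
                 ecdf_points = as.integer(ecdf_points)),
            class = "spectral_config")
}

#' Canonical names of the 26 burst features
#'
#' Time-domain amplitude and slope features (MAV, WL, AAC, DASDV, VAR, LOG,
#' ZC, WAMP, MYOP, Skew, Kurt, Entropy, ECDF, CC), model-based features (AC,
#' LPCC, MFCC) and spectral features (MNF, MDF, PKF, MNP, FR, SC, SE, SF,
#' PW).
#'
#' @return character vector of length 26.
#' @export
feature_names <- function() {
  c("AC", "AAC", "CC", "DASDV", "Entropy", "ECDF", "FR", "LPCC", "LOG",
    "Kurt", "MNP", "MNF", "MDF", "MAV", "MYOP", "MFCC", "PKF", "PW",
    "Skew", "SC", "SE", "SF", "VAR", "WL", "WAMP", "ZC")
}

spectral_feature_names <- function() {
  c("AC", "LPCC", "MFCC", "MNF", "MDF", "PKF", "MNP", "FR", "SC", "SE",
    "SF", "PW")
}

#' Compute burst features for one window
#'
#' Evaluates the requested subset of the 26-feature catalogue on a burst
#' window. Definitions (x = samples, N = length, thresholds scaled by the
#' window RMS):
#' \itemize{
#' \item MAV `mean(|x|)`; WL `sum(|diff(x)|)`; AAC `WL/(N-1)`;
#'   DASDV `sqrt(mean(diff(x)^2))`; VAR unbiased sample variance;
#'   LOG `exp(mean(log|x|))`.
#' \item ZC: sign changes with amplitude step at least the ZC threshold;
#'   WAMP: steps `|x[i]-x[i+1]|` at least the WAMP threshold; MYOP: fraction
#'   of samples with `|x|` at least the MYOP threshold.
#' \item Skew/Kurt: standardised third/fourth sample moments; Entropy:
#'   Shannon entropy of a 64-bin amplitude histogram; ECDF: mean of the
#'   empirical CDF at 10 equally spaced amplitudes; CC: temporal centroid
#'   of signal energy, in seconds from window start.
#' \item AC: first coefficient of an order-4 autoregressive model fit by
#'   Levinson-Durbin on the biased autocorrelation; LPCC: mean of the first
#'   4 linear-prediction cepstral coefficients; MFCC: mean of the first 12
#'   mel-cepstral coefficients, averaged over short-time frames.
#' \item MNF/MDF/PKF/MNP: mean, median, peak frequency and mean power of the
#'   Welch PSD; FR: band power 10-250 Hz over 250-500 Hz; SC: centroid of
#'   the full-window magnitude spectrum; SE: normalised spectral entropy;
#'   SF: power-weighted mean of per-frame peak frequencies; PW: spectral
#'   spread around SC.
#' }
#'
#' @param window a `burst_window`, or a numeric vector (then `fs` must be
#'   given).
#' @param features character vector of feature names (default all 26).
#' @param scfg a [spectral_config()].
#' @param fs sampling rate, required when `window` is a bare numeric vector.
#' @return named numeric vector, one finite scalar per requested feature.
#' @export
#' @examples
#' extract_features(sin(2 * pi * 100 * (0:4399) / 2200), fs = 2200,
#'                  features = c("MNF", "MDF", "PKF"))
extract_features <- function(window, features = feature_names(),
                             scfg = spectral_config(), fs = NULL) {
  if (inherits(window, "burst_window")) {
    x <- window$samples
    fs <- window$fs
  } else {
    x <- as.numeric(window)
    if (is.null(fs)) stop("fs required for a bare numeric window", call. = FALSE)
  }
  if (!length(x)) stop("empty window", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("window contains NaN/Inf samples", call. = FALSE)
  unknown <- setdiff(features, feature_names())
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(x)
  if (any(features %in% spectral_feature_names()) && length(unique(x)) == 1L)
    stop("degenerate (constant) window: spectral features undefined", call. = FALSE)

  out <- setNames(numeric(length(features)), features)
  rms <- sqrt(mean(x^2))
  dx <- diff(x)
  need <- function(nm) any(nm %in% features)

  if (need("MAV")) out["MAV"] <- mean(abs(x))
  if (need("WL")) out["WL"] <- sum(abs(dx))
  if (need("AAC")) out["AAC"] <- sum(abs(dx)) / (n - 1)
  if (need("DASDV")) out["DASDV"] <- sqrt(mean(dx^2))
  if (need("VAR")) out["VAR"] <- var(x)
  if (need("LOG")) out["LOG"] <- exp(mean(log(pmax(abs(x), .Machine$double.xmin))))
  if (need("ZC")) {
    thr <- scfg$zc_threshold * rms
    out["ZC"] <- sum(x[-n] * x[-1] < 0 & abs(dx) >= thr)
  }
  if (need("WAMP")) out["WAMP"] <- sum(abs(dx) >= scfg$wamp_threshold * rms)
  if (need("MYOP")) out["MYOP"] <- mean(abs(x) >= scfg$myop_threshold * rms)
  if (need(c("Skew", "Kurt"))) {
    m <- mean(x); xc <- x - m
    m2 <- mean(xc^2)
    if (need("Skew")) out["Skew"] <- if (m2 > 0) mean(xc^3) / m2^1.5 else 0
    if (need("Kurt")) out["Kurt"] <- if (m2 > 0) mean(xc^4) / m2^2 else 0
  }
  if (need("Entropy")) out["Entropy"] <- amplitude_entropy(x, scfg$entropy_bins)
  if (need("ECDF")) {
    pts <- seq(min(x), max(x), length.out = scfg$ecdf_points)
    out["ECDF"] <- mean(ecdf(x)(pts))
  }
  if (need("CC")) {
    t <- (seq_len(n) - 1) / fs
    out["CC"] <- sum(t * x^2) / sum(x^2)
  }
  if (need(c("AC", "LPCC"))) {
    a <- ar_levinson(x, scfg$ar_order)
    if (need("AC")) out["AC"] <- a[1]
    if (need("LPCC")) out["LPCC"] <- mean(lpc_cepstrum(a, scfg$lpcc_order))
  }
  if (need("MFCC")) out["MFCC"] <- mfcc_scalar(x, fs, scfg)

  psd_feats <- c("MNF", "MDF", "PKF", "MNP", "FR", "SE", "PW")
  if (need(c(psd_feats, "SC"))) {
    sc_val <- NA_real_
    if (need(c("SC", "PW"))) {
      X <- abs(fft(x))[1:(floor(n / 2) + 1)]
      fX <- (seq_along(X) - 1) * fs / n
      sc_val <- sum(fX * X) / sum(X)
      if (need("SC")) out["SC"] <- sc_val
    }
    if (need(psd_feats)) {
      w <- welch_psd(x, fs, scfg)
      f <- w$f; p <- w$p
      tot <- sum(p)
      if (need("MNF")) out["MNF"] <- sum(f * p) / tot
      if (need("MDF")) out["MDF"] <- f[which(cumsum(p) >= tot / 2)[1]]
      if (need("PKF")) out["PKF"] <- f[which.max(p)]
      if (need("MNP")) out["MNP"] <- mean(p)
      if (need("FR")) {
        lo <- f >= scfg$fr_low_band[1] & f < scfg$fr_low_band[2]
        hi <- f >= scfg$fr_high_band[1] & f < scfg$fr_high_band[2]
        out["FR"] <- sum(p[lo]) / sum(p[hi])
      }
      if (need("SE")) {
        pr <- p / tot
        pr <- pr[pr > 0]
        out["SE"] <- -sum(pr * log(pr)) / log(length(p))
      }
      if (need("PW")) out["PW"] <- sqrt(sum((f - sc_val)^2 * p) / tot)
    }
  }
  if (need("SF")) out["SF"] <- spectrogram_peak_freq(x, fs, scfg)

  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(features[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

#' Build a feature matrix from a list of burst windows
#'
#' One row per window, in input order, with metadata columns (`subject`,
#' `day`, `side`, `event_index`, `label`, `volume_ml`) followed by one column
#' per feature. Windows on which extraction fails (e.g. constant signal) are
#' excluded; the failures are recorded in the `failures` attribute.
#'
#' @param windows list of `burst_window` objects.
#' @param features feature names, default all 26.
#' @param scfg a [spectral_config()].
#' @return a data frame of class `feature_matrix`.
#' @export
extract_feature_matrix <- function(windows, features = feature_names(),
                                   scfg = spectral_config()) {
  meta_cols <- c("subject", "day", "side", "event_index", "label", "volume_ml")
  empty <- function() {
    df <- data.frame(subject = integer(0), day = integer(0),
                     side = character(0), event_index = integer(0),
                     label = character(0), volume_ml = numeric(0))
    for (f in features) df[[f]] <- numeric(0)
    class(df) <- c("feature_matrix", "data.frame")
    df
  }
  if (!length(windows)) return(empty())
  rows <- vector("list", length(windows))
  fails <- data.frame(index = integer(0), reason = character(0))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    vals <- tryCatch(extract_features(w, features, scfg),
                     error = function(e) conditionMessage(e))
    if (is.character(vals)) {
      fails <- rbind(fails, data.frame(index = i, reason = vals))
      next
    }
    rows[[i]] <- cbind(data.frame(subject = w$subject, day = w$day,
                                  side = w$side, event_index = w$event_index,
                                  label = w$label,
                                  volume_ml = w$volume_ml,
                                  stringsAsFactors = FALSE),
                       as.data.frame(as.list(vals)))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else empty()
  rownames(df) <- NULL
  class(df) <- c("feature_matrix", "data.frame")
  attr(df, "failures") <- fails
  attr(df, "scfg") <- scfg
  df
}

# ---- internal numerical helpers ------------------------------------------

# Shannon entropy of the normalised amplitude histogram (fixed bin count over
# the window's min-max range).
amplitude_entropy <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), bins),
                  nbins = bins)
  p <- cnt / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Biased autocorrelation at lags 0..p.
biased_autocorr <- function(x, p) {
  n <- length(x)
  vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
}

# AR coefficients (convention x_t ~ sum_k a_k x_{t-k}) of order p via the
# Levinson-Durbin recursion on the biased autocorrelation.
ar_levinson <- function(x, p) {
  r <- biased_autocorr(x, p)
  a <- numeric(0)
  e <- r[1]
  for (m in seq_len(p)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a * r[m:2])
    k <- acc / e
    a <- if (m > 1) c(a - k * rev(a), k) else k
    e <- e * (1 - k^2)
  }
  a
}

# LPC -> cepstrum recursion; returns c_1..c_q for prediction coefficients a.
lpc_cepstrum <- function(a, q) {
  p <- length(a)
  cc <- numeric(q)
  for (m in seq_len(q)) {
    s <- if (m <= p) a[m] else 0
    if (m > 1) {
      k <- seq_len(m - 1)
      ak <- ifelse(m - k <= p, a[pmax(m - k, 1)], 0)
      ak[m - k > p] <- 0
      s <- s + sum((k / m) * cc[k] * ak)
    }
    cc[m] <- s
  }
  cc
}

hann_window <- function(m) 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
hamming_window <- function(m) 0.54 - 0.46 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))

# Welch PSD: Hann-tapered segments of psd_seg_s seconds with psd_overlap
# fractional overlap, averaged one-sided density.
welch_psd <- function(x, fs, scfg) {
  n <- length(x)
  seg <- min(n, round(scfg$psd_seg_s * fs))
  hop <- max(1L, round(seg * (1 - scfg$psd_overlap)))
  starts <- seq(1L, n - seg + 1L, by = hop)
  w <- hann_window(seg)
  u <- fs * sum(w^2)
  nb <- floor(seg / 2) + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- fft(x[s:(s + seg - 1L)] * w)
    pxx <- (Mod(X[1:nb])^2) / u
    # one-sided density: double all bins except DC (and Nyquist if present)
    dbl <- rep(2, nb); dbl[1] <- 1
    if (seg %% 2 == 0) dbl[nb] <- 1
    acc <- acc + pxx * dbl
  }
  list(f = (0:(nb - 1)) * fs / seg, p = acc / length(starts))
}

# Short-time frame starts for frame_len/frame_overlap settings.
frame_starts <- function(n, len, overlap) {
  hop <- max(1L, round(len * (1 - overlap)))
  seq(1L, max(1L, n - len + 1L), by = hop)
}

# Power-weighted mean over frames of each frame's peak frequency.
spectrogram_peak_freq <- function(x, fs, scfg) {
  len <- min(length(x), scfg$frame_len)
  starts <- frame_starts(length(x), len, scfg$frame_overlap)
  w <- hann_window(len)
  nb <- floor(len / 2) + 1L
  f <- (0:(nb - 1)) * fs / len
  num <- 0; den <- 0
  for (s in starts) {
    pxx <- Mod(fft(x[s:(s + len - 1L)] * w)[1:nb])^2
    pw <- sum(pxx)
    num <- num + pw * f[which.max(pxx)]
    den <- den + pw
  }
  num / den
}

# Mean of the first mfcc_n_coeffs mel-cepstral coefficients, averaged over
# Hamming-tapered short-time frames.
mfcc_scalar <- function(x, fs, scfg) {
  len <- min(length(x), scfg$frame_len)
  starts <- frame_starts(length(x), len, scfg$frame_overlap)
  w <- hamming_window(len)
  nb <- floor(len / 2) + 1L
  fb <- mel_filterbank(scfg$mfcc_n_filters, len, fs)   # n_filters x nb
  m <- scfg$mfcc_n_filters
  nc <- scfg$mfcc_n_coeffs
  dct <- outer(seq_len(nc), seq_len(m) - 0.5,
               function(i, j) cos(pi * i * j / m))      # nc x m
  acc <- numeric(nc)
  for (s in starts) {
    pxx <- Mod(fft(x[s:(s + len - 1L)] * w)[1:nb])^2 / len
    loge <- log(pmax(fb %*% pxx, 1e-12))
    acc <- acc + as.numeric(dct %*% loge)
  }
  mean(acc / length(starts))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank spanning 0..fs/2, returned as a matrix of
# weights over the one-sided FFT bin frequencies of an `nfft`-point frame.
mel_filterbank <- function(n_filters, nfft, fs) {
  nb <- floor(nfft / 2) + 1L
  fbin <- (0:(nb - 1)) * fs / nfft
  edges <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, nb)
  for (j in seq_len(n_filters)) {
    lo <- edges[j]; mid <- edges[j + 1]; hi <- edges[j + 2]
    rise <- (fbin - lo) / (mid - lo)
    fall <- (hi - fbin) / (hi - mid)
    fb[j, ] <- pmax(0, pmin(rise, fall))
  }
  fb
}
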