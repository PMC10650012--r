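# Independent direct-from-definition oracle for the 26 burst features.
# Deliberately written from the feature definitions themselves (Toeplitz
# solve for the AR fit, explicit histogramming, explicit per-segment
# periodograms), not by calling the package internals.

oracle_psd <- function(x, fs, seg_s = 0.5, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, round(seg_s * fs))
  hop <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
  nb <- floor(seg / 2) + 1
  p <- numeric(nb)
  for (s in starts) {
    X <- fft(x[s:(s + seg - 1)] * w)
    pk <- Mod(X[1:nb])^2 / (fs * sum(w^2))
    mult <- rep(2, nb)
    mult[1] <- 1
    if (seg %% 2 == 0) mult[nb] <- 1
    p <- p + pk * mult
  }
  list(f = (0:(nb - 1)) * fs / seg, p = p / length(starts))
}

oracle_frames <- function(n, len, overlap = 0.5) {
  hop <- max(1, round(len * (1 - overlap)))
  seq(1, max(1, n - len + 1), by = hop)
}

oracle_mel_fb <- function(n_filters, nfft, fs) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  nb <- floor(nfft / 2) + 1
  fbin <- (0:(nb - 1)) * fs / nfft
  pts <- imel(seq(0, mel(fs / 2), length.out = n_filters + 2))
  fb <- matrix(0, n_filters, nb)
  for (j in 1:n_filters) {
    for (k in 1:nb) {
      f <- fbin[k]
      if (f >= pts[j] && f <= pts[j + 1]) {
        fb[j, k] <- (f - pts[j]) / (pts[j + 1] - pts[j])
      } else if (f > pts[j + 1] && f <= pts[j + 2]) {
        fb[j, k] <- (pts[j + 2] - f) / (pts[j + 2] - pts[j + 1])
      }
    }
  }
  fb
}

oracle_features <- function(x, fs, scfg = spectral_config()) {
  n <- length(x)
  rms <- sqrt(sum(x^2) / n)
  d <- x[-1] - x[-n]
  out <- c()

  out["MAV"] <- sum(abs(x)) / n
  out["WL"] <- sum(abs(d))
  out["AAC"] <- sum(abs(d)) / (n - 1)
  out["DASDV"] <- sqrt(sum(d^2) / (n - 1))
  mu <- sum(x) / n
  out["VAR"] <- sum((x - mu)^2) / (n - 1)
  out["LOG"] <- exp(sum(log(pmax(abs(x), .Machine$double.xmin))) / n)
  out["ZC"] <- sum(x[-n] * x[-1] < 0 & abs(d) >= scfg$zc_threshold * rms)
  out["WAMP"] <- sum(abs(d) >= scfg$wamp_threshold * rms)
  out["MYOP"] <- sum(abs(x) >= scfg$myop_threshold * rms) / n
  m2 <- sum((x - mu)^2) / n
  out["Skew"] <- (sum((x - mu)^3) / n) / m2^1.5
  out["Kurt"] <- (sum((x - mu)^4) / n) / m2^2

  # amplitude-histogram entropy, fixed bins over min..max
  bins <- scfg$entropy_bins
  w_bin <- (max(x) - min(x)) / bins
  bi <- pmin(floor((x - min(x)) / w_bin) + 1, bins)
  pr <- as.numeric(table(bi)) / n
  out["Entropy"] <- -sum(pr * log(pr))

  pts <- min(x) + (0:(scfg$ecdf_points - 1)) *
    (max(x) - min(x)) / (scfg$ecdf_points - 1)
  pts[scfg$ecdf_points] <- max(x)  # endpoints are the observed extremes
  out["ECDF"] <- mean(vapply(pts, function(p) sum(x <= p) / n, 0))

  tt <- (0:(n - 1)) / fs
  out["CC"] <- sum(tt * x^2) / sum(x^2)

  # AR via Toeplitz solve on the biased autocorrelation
  p_ord <- scfg$ar_order
  r <- vapply(0:p_ord, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
  a <- solve(stats::toeplitz(r[1:p_ord]), r[2:(p_ord + 1)])
  out["AC"] <- a[1]
  cc <- numeric(scfg$lpcc_order)
  for (m in 1:scfg$lpcc_order) {
    s <- if (m <= p_ord) a[m] else 0
    if (m > 1) for (k in 1:(m - 1)) {
      am <- if (m - k <= p_ord) a[m - k] else 0
      s <- s + (k / m) * cc[k] * am
    }
    cc[m] <- s
  }
  out["LPCC"] <- mean(cc)

  # MFCC: Hamming frames, mel filterbank, log energies, DCT-II
  len <- min(n, scfg$frame_len)
  wh <- 0.54 - 0.46 * cos(2 * pi * (0:(len - 1)) / (len - 1))
  nb <- floor(len / 2) + 1
  fb <- oracle_mel_fb(scfg$mfcc_n_filters, len, fs)
  starts <- oracle_frames(n, len, scfg$frame_overlap)
  nco <- scfg$mfcc_n_coeffs
  nfil <- scfg$mfcc_n_filters
  coefs <- matrix(0, length(starts), nco)
  for (si in seq_along(starts)) {
    s <- starts[si]
    pxx <- Mod(fft(x[s:(s + len - 1)] * wh)[1:nb])^2 / len
    loge <- log(pmax(as.numeric(fb %*% pxx), 1e-12))
    for (i in 1:nco)
      coefs[si, i] <- sum(loge * cos(pi * i * ((1:nfil) - 0.5) / nfil))
  }
  out["MFCC"] <- mean(colMeans(coefs))

  ps <- oracle_psd(x, fs, scfg$psd_seg_s, scfg$psd_overlap)
  tot <- sum(ps$p)
  out["MNF"] <- sum(ps$f * ps$p) / tot
  cum <- 0
  for (j in seq_along(ps$p)) {
    cum <- cum + ps$p[j]
    if (cum >= tot / 2) { out["MDF"] <- ps$f[j]; break }
  }
  out["PKF"] <- ps$f[which.max(ps$p)]
  out["MNP"] <- tot / length(ps$p)
  lo <- ps$f >= scfg$fr_low_band[1] & ps$f < scfg$fr_low_band[2]
  hi <- ps$f >= scfg$fr_high_band[1] & ps$f < scfg$fr_high_band[2]
  out["FR"] <- sum(ps$p[lo]) / sum(ps$p[hi])
  pn <- ps$p / tot
  out["SE"] <- -sum(pn[pn > 0] * log(pn[pn > 0])) / log(length(ps$p))

  Xm <- Mod(fft(x))[1:(floor(n / 2) + 1)]
  fX <- (0:floor(n / 2)) * fs / n
  out["SC"] <- sum(fX * Xm) / sum(Xm)
  out["PW"] <- sqrt(sum((ps$f - out["SC"])^2 * ps$p) / tot)

  # spectrogram peak frequency, power-weighted over Hann frames
  wsf <- 0.5 * (1 - cos(2 * pi * (0:(len - 1)) / (len - 1)))
  fsf <- (0:(nb - 1)) * fs / len
  num <- 0; den <- 0
  for (s in starts) {
    pxx <- Mod(fft(x[s:(s + len - 1)] * wsf)[1:nb])^2
    num <- num + sum(pxx) * fsf[which.max(pxx)]
    den <- den + sum(pxx)
  }
  out["SF"] <- num / den

  out[feature_names()]
}
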