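test_that("time-domain features match hand-computed values on a square wave", {
  x <- c(1, -1, 1, -1)
  v <- extract_features(x, c("MAV", "WL", "ZC", "WAMP", "MYOP"), fs = 2200)
  expect_equal(unname(v["MAV"]), 1)
  expect_equal(unname(v["WL"]), 6)
  expect_equal(unname(v["ZC"]), 3)
  expect_equal(unname(v["WAMP"]), 3)
  expect_equal(unname(v["MYOP"]), 1)
})

test_that("spectral features locate a pure 100 Hz tone", {
  fs <- 2200
  x <- sin(2 * pi * 100 * (0:(2 * fs - 1)) / fs)
  v <- extract_features(x, c("MNF", "MDF", "PKF", "SC", "SE"), fs = fs)
  expect_lt(abs(v[["MNF"]] - 100), 2)
  expect_lt(abs(v[["MDF"]] - 100), 2)
  expect_lt(abs(v[["PKF"]] - 100), 2)
  noise <- withr::with_seed(3, rnorm(2 * fs))
  se_noise <- extract_features(noise, "SE", fs = fs)[["SE"]]
  expect_gt(se_noise, v[["SE"]])
  expect_true(v[["SE"]] >= 0 && se_noise <= 1)
})

test_that("every feature matches the direct-definition oracle on random windows", {
  set.seed(101)
  fs <- 2200
  scfg <- spectral_config()
  for (i in 1:200) {
    n <- sample(c(700, 1100, 2304), 1)
    kind <- i %% 3
    x <- if (kind == 0) rnorm(n)
    else if (kind == 1) {
      f0 <- runif(1, 20, 300)
      sin(2 * pi * f0 * (0:(n - 1)) / fs + runif(1, 0, pi)) + rnorm(n, 0, 0.3)
    } else cumsum(rnorm(n)) / 10 + rnorm(n)
    got <- extract_features(x, feature_names(), scfg, fs = fs)
    want <- oracle_features(x, fs, scfg)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("features obey scale homogeneity and invariance laws", {
  set.seed(7)
  fs <- 2200
  x <- rnorm(2304) * rep(c(0.2, 1, 0.2), c(800, 704, 800))
  v1 <- extract_features(x, feature_names(), fs = fs)
  v3 <- extract_features(3 * x, feature_names(), fs = fs)
  for (f in c("MAV", "WL", "DASDV", "LOG"))
    expect_equal(v3[[f]], 3 * v1[[f]], tolerance = 1e-12)
  for (f in c("Skew", "Kurt", "SE", "MYOP", "ZC", "WAMP", "MNF", "MDF",
              "PKF", "SC", "CC", "FR", "ECDF", "Entropy", "AC"))
    expect_equal(v3[[f]], v1[[f]], tolerance = 1e-9)
  expect_equal(v3[["VAR"]], 9 * v1[["VAR"]], tolerance = 1e-12)
})

test_that("time reversal changes only the temporal centroid", {
  set.seed(11)
  fs <- 2200
  # length chosen so both the Welch segment grid (1100-sample segments,
  # 550 hop) and the short-time frame grid (256/128) tile the window
  # symmetrically; reversal then maps each grid onto itself.
  n <- 35200
  x <- rnorm(n) * sipemg:::hann_bump(n)
  v <- extract_features(x, feature_names(), fs = fs)
  vr <- extract_features(rev(x), feature_names(), fs = fs)
  for (f in setdiff(feature_names(), "CC"))
    expect_equal(vr[[f]], v[[f]], tolerance = 1e-9)
  expect_equal(vr[["CC"]], (n - 1) / fs - v[["CC"]], tolerance = 1e-9)
})

test_that("feature values respect their analytic ranges and the MDF bisection", {
  scfg <- spectral_config()
  fs <- 2200
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(1500) + sin(2 * pi * runif(1, 15, 400) * (0:1499) / fs)
    v <- extract_features(x, feature_names(), scfg, fs = fs)
    expect_true(v[["MYOP"]] >= 0 && v[["MYOP"]] <= 1)
    expect_true(v[["SE"]] >= 0 && v[["SE"]] <= 1)
    expect_true(all(v[c("MNF", "MDF", "PKF", "SC")] >= 0))
    expect_true(all(v[c("MNF", "MDF", "PKF", "SC")] <= fs / 2))
    expect_gte(v[["MNP"]], 0)
    expect_gte(v[["PW"]], 0)
    # bisection: each side of MDF holds >= half the power minus one bin
    ps <- sipemg:::welch_psd(x, fs, scfg)
    tot <- sum(ps$p); mx <- max(ps$p)
    below <- sum(ps$p[ps$f <= v[["MDF"]]])
    above <- sum(ps$p[ps$f >= v[["MDF"]]])
    expect_gte(below, tot / 2 - mx)
    expect_gte(above, tot / 2 - mx)
  }
})

test_that("degenerate and invalid windows are rejected", {
  expect_error(extract_features(rep(1, 100), "MNF", fs = 2200), "degenerate")
  expect_error(extract_features(c(1, NA, 2), "MAV", fs = 2200), "NaN")
  expect_error(extract_features(rnorm(10), "NOPE", fs = 2200), "unknown feature")
  # constant window still yields time-domain features
  v <- extract_features(rep(2, 100), c("MAV", "WL"), fs = 2200)
  expect_equal(unname(v), c(2, 0))
})

test_that("the feature matrix has one row per window, excludes failures, and is deterministic", {
  w <- default_cell_windows()[1:30]
  fm <- extract_feature_matrix(w)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), 30L)
  expect_equal(sum(is.na(fm[, feature_names()])), 0L)
  fm2 <- extract_feature_matrix(w)
  expect_identical(fm, fm2)

  # a constant window among good ones is excluded and logged
  bad <- w[[1]]; bad$samples <- rep(0, length(bad$samples))
  fm3 <- extract_feature_matrix(c(w[1:5], list(bad)))
  expect_equal(nrow(fm3), 5L)
  expect_equal(attr(fm3, "failures")$index, 6L)

  # empty input keeps the schema
  fm0 <- extract_feature_matrix(list())
  expect_equal(nrow(fm0), 0L)
  expect_true(all(feature_names() %in% names(fm0)))
})
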