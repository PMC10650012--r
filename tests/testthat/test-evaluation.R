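test_that("fold assignment is deterministic, stratified and size-balanced", {
  y <- c(rep("drink", 60), rep("other", 40))
  f1 <- sipemg:::make_folds(y, 5, TRUE, 3)
  f2 <- sipemg:::make_folds(y, 5, TRUE, 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, sipemg:::make_folds(y, 5, TRUE, 4)))
  for (k in 1:5) {
    expect_equal(sum(y == "drink" & f1 == k), 12)
    expect_equal(sum(y == "other" & f1 == k), 8)
  }
  expect_error(sipemg:::make_folds(y[1:3], 5, TRUE, 1), "fewer samples")
})

test_that("a near-perfectly separable feature yields F-score >= 0.99", {
  fm <- planted_feature_matrix(seed = 2)
  for (m in c("LDA", "RF", "KNN1", "SVC", "QDA")) {
    r <- cv_classify(fm, "signal", classifier_spec(m))
    expect_gte(r$score, 0.99)
    expect_true(all(r$fold_scores >= 0) && all(r$fold_scores <= 1))
  }
  # the evaluation consumes the full 60/40 sample
  expect_equal(r$n, 100L)
})

test_that("permuted labels score inside the 200-permutation null band", {
  fm <- planted_feature_matrix(n_noise = 2, seed = 3)
  protocol <- eval_protocol("classify", seed = 11)
  for (m in c("LDA", "KNN1")) {
    spec <- classifier_spec(m)
    null_scores <- vapply(1:200, function(i) {
      fmp <- fm
      fmp$label <- withr::with_seed(1000 + i, sample(fm$label))
      cv_classify(fmp, c("noise1", "noise2"), spec, protocol)$score
    }, 0)
    fmo <- fm
    fmo$label <- withr::with_seed(77, sample(fm$label))
    obs <- cv_classify(fmo, c("noise1", "noise2"), spec, protocol)$score
    expect_gte(obs, min(null_scores))
    expect_lte(obs, max(null_scores))
  }
})

test_that("classification rejects degenerate inputs", {
  fm <- planted_feature_matrix()
  fm1 <- fm; fm1$label <- "drink"
  expect_error(cv_classify(fm1, "signal"), "both positive and negative")
})

test_that("a noiseless linear feature is recovered by linear regression", {
  fm <- planted_feature_matrix()
  fm$linvol <- ifelse(is.na(fm$volume_ml), 0, 2 + 0.3 * fm$volume_ml)
  r <- cv_regress(fm, "linvol", regressor_spec("LR"))
  expect_lte(r$score, 0.5)
})

test_that("a volume-independent feature lands in the analytic null band", {
  # always-predict-the-mean on balanced volumes {5..25} has RMSE sqrt(50)
  fm <- planted_feature_matrix(seed = 9)
  for (m in c("LR", "Ridge")) {
    r <- cv_regress(fm, "noise1", regressor_spec(m))
    expect_gte(r$score, 6.3)
    expect_lte(r$score, 7.8)
  }
  fm2 <- fm; fm2$volume_ml[3] <- NA
  expect_error(cv_regress(fm2, "noise1"), "missing volume")
})

test_that("subset search enumerates binomial counts and matches brute force", {
  fm <- small_features()
  fm <- fm[fm$subject == 1 & fm$day == 1, , drop = FALSE]
  cols <- c("MAV", "WL", "MDF", "MNF", "LOG", "ZC", "SE", "Kurt")
  protocol <- eval_protocol("classify", seed = 5)
  models <- list(LDA = classifier_spec("LDA"), KNN1 = classifier_spec("KNN1"))
  sr <- subset_search(fm, models, k_max = 2, protocol = protocol,
                      columns = cols)
  expect_equal(unname(sr$n_sets), c(choose(8, 1), choose(8, 2)))

  # brute-force re-enumeration with cv_classify directly
  for (m in names(models)) {
    sets <- c(as.list(cols), combn(cols, 2, simplify = FALSE))
    scores <- vapply(sets, function(s)
      cv_classify(fm, s, models[[m]], protocol)$score, 0)
    keys <- vapply(sets, function(s) paste(sort(s), collapse = "+"), "")
    got <- sr$best_subject[sr$best_subject$model == m, ]
    for (k in 1:2) {
      kk <- lengths(regmatches(keys, gregexpr("+", keys, fixed = TRUE))) + 1
      ordk <- order(-scores[kk == k], keys[kk == k])
      expect_equal(got$set[got$k == k], keys[kk == k][ordk[1]])
      expect_equal(got$score[got$k == k], max(scores[kk == k]))
    }
  }
})

test_that("subject-specific bests dominate the global best in every cell", {
  fm <- small_features()
  protocol <- eval_protocol("classify", seed = 5)
  models <- list(LDA = classifier_spec("LDA"))
  sr <- subset_search(fm, models, k_max = 2, protocol = protocol,
                      columns = c("MAV", "WL", "MDF", "LOG", "ZC"))
  for (i in seq_len(nrow(sr$best_global))) {
    g <- sr$best_global[i, ]
    cells <- sr$cell[sr$cell$day == g$day & sr$cell$side == g$side &
                       sr$cell$model == g$model & sr$cell$k == g$k, ]
    for (s in unique(cells$subject)) {
      best_s <- sr$best_subject[sr$best_subject$subject == s &
                                  sr$best_subject$day == g$day &
                                  sr$best_subject$side == g$side &
                                  sr$best_subject$model == g$model &
                                  sr$best_subject$k == g$k, ]
      glob_in_cell <- cells$score[cells$subject == s & cells$set == g$set]
      expect_gte(best_s$score, glob_in_cell)
    }
  }
})

test_that("a planted informative feature wins the size-1 search for every model", {
  fm <- planted_feature_matrix(n_noise = 7, seed = 4)
  protocol <- eval_protocol("classify", seed = 2)
  models <- default_classifiers()
  sr <- subset_search(fm, models, k_max = 1, protocol = protocol)
  expect_true(all(sr$best_subject$set == "signal"))
})

test_that("greedy size-4 search evaluates supersets of top size-3 sets", {
  fm <- planted_feature_matrix(n_noise = 5, seed = 6)
  protocol <- eval_protocol("classify", seed = 2)
  sr <- subset_search(fm, list(LDA = classifier_spec("LDA")), k_max = 4,
                      protocol = protocol, top_m = 3)
  expect_true(all(sr$cell$k[sr$cell$k == 4] == 4))
  b4 <- sr$best_subject[sr$best_subject$k == 4, ]
  expect_equal(lengths(strsplit(b4$set, "+", fixed = TRUE)), 4L)
  expect_match(b4$set, "signal")
})

test_that("cross-day scoring is direction-symmetric under day swap", {
  fm <- small_features()
  fm1 <- fm[fm$day == 1, ]; fm2 <- fm[fm$day == 2, ]
  m <- classifier_spec("LDA")
  a <- cross_day(fm1, fm2, c("MAV", "MDF"), c("LOG", "WL"), m)
  b <- cross_day(fm2, fm1, c("LOG", "WL"), c("MAV", "MDF"), m)
  expect_equal(a$score[a$direction == "day1->day2"],
               b$score[b$direction == "day2->day1"])
  expect_equal(a$score[a$direction == "day2->day1"],
               b$score[b$direction == "day1->day2"])
  # a subject present on only one day is excluded and reported
  fm2b <- fm2[fm2$subject == 1, ]
  cd <- cross_day(fm1, fm2b, "MAV", "MAV", m)
  expect_equal(attr(cd, "excluded"), 2)
  expect_true(all(cd$subject == 1))
})

test_that("grouped summaries report means, standard errors and counts", {
  rec <- data.frame(day = c(1, 1, 2), side = "right", model = "LDA",
                    k = 1, score = c(0.8, 0.9, 0.7))
  s <- summarize_scores(rec)
  expect_equal(s$mean[s$day == 1], 0.85)
  expect_equal(s$se[s$day == 2], 0)
  expect_equal(s$n, c(2L, 1L))
  one <- summarize_scores(rec[1, , drop = FALSE])
  expect_equal(one$mean, 0.8)
  expect_error(summarize_scores(rec[0, ]), "no records")
})
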