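#' Evaluation protocol
#'
#' Fixes the task, fold count, scoring rule and fold seed used by the
#' cross-validation machinery. Classification is binary (drinking versus all
#' other events) scored by the F-score of the drinking class; regression
#' predicts sip volume in mL on drinking events only, scored by RMSE.
#' Classification folds are stratified by default so every fold preserves the
#' 60/40 class ratio; a flag disables this.
#'
#' @param task `"classify"` or `"regress"`.
#' @param cv_folds number of cross-validation folds.
#' @param positive_class label of the positive (drinking) class.
#' @param stratified stratify classification folds by class?
#' @param seed integer seed controlling fold assignment.
#' @return an object of class `eval_protocol`.
#' @export
eval_protocol <- function(task = c("classify", "regress"), cv_folds = 5L,
                          positive_class = "drink", stratified = TRUE,
                          seed = 1L) {
  task <- match.arg(task)
  structure(list(task = task, cv_folds = as.integer(cv_folds),
                 scoring = if (task == "classify") "f_score" else "rmse",
                 positive_class = positive_class,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "eval_protocol")
}

# Deterministic fold assignment depending only on (seed, labels, n).
make_folds <- function(y, k, stratified, seed) {
  n <- length(y)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")", call. = FALSE)
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    fold
  })
}

# F-score (harmonic precision/recall mean) of the positive class.
f1_score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

feature_columns <- function(fm) {
  setdiff(names(fm), c("subject", "day", "side", "event_index", "label",
                       "volume_ml"))
}

# Precompute fold-wise standardised design matrices for one evaluation cell,
# so subset evaluation reduces to column selection plus fit/predict.
# Standardisation uses training-fold statistics only.
cv_engine <- function(fm, protocol) {
  cols <- feature_columns(fm)
  if (protocol$task == "classify") {
    if (!(protocol$positive_class %in% fm$label) ||
        all(fm$label == protocol$positive_class))
      stop("classification needs both positive and negative samples",
           call. = FALSE)
    y <- factor(ifelse(fm$label == protocol$positive_class, "drink", "other"),
                levels = c("drink", "other"))
  } else {
    if (!is.null(fm$label)) fm <- fm[fm$label == protocol$positive_class, ,
                                     drop = FALSE]
    if (anyNA(fm$volume_ml))
      stop("missing volume label on drinking event(s)", call. = FALSE)
    y <- fm$volume_ml
  }
  X <- as.matrix(fm[, cols, drop = FALSE])
  fold <- make_folds(if (is.factor(y)) as.character(y) else rep("r", nrow(X)),
                     protocol$cv_folds,
                     protocol$task == "classify" && protocol$stratified,
                     protocol$seed)
  splits <- lapply(seq_len(protocol$cv_folds), function(f) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    list(Xtr = sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/"),
         Xte = sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/"),
         ytr = y[tr], yte = y[!tr])
  })
  list(splits = splits, cols = cols, task = protocol$task, n = nrow(X),
       positive = "drink")
}

# Note: warnings from individual model fits are suppressed here. With
# fixed-length windows some catalogue features are exactly proportional
# (AAC = WL/(N-1)), so discriminant fits on such pairs legitimately warn
# about collinearity on a large fraction of the enumerated subsets.
eval_subset_on_engine <- function(engine, subset, model) {
  scores <- vapply(engine$splits, function(sp) suppressWarnings({
    Xtr <- sp$Xtr[, subset, drop = FALSE]
    Xte <- sp$Xte[, subset, drop = FALSE]
    if (engine$task == "classify") {
      fit <- fit_classifier(model, Xtr, sp$ytr)
      f1_score(sp$yte, predict_classifier(model, fit, Xte), engine$positive)
    } else {
      ytr <- sp$ytr
      if (model$name %in% c("ANN", "SVR")) {
        mu <- mean(ytr); sg <- sd(ytr); if (!is.finite(sg) || sg == 0) sg <- 1
        fit <- fit_regressor(model, Xtr, (ytr - mu) / sg)
        pred <- predict_regressor(model, fit, Xte) * sg + mu
      } else {
        fit <- fit_regressor(model, Xtr, ytr)
        pred <- predict_regressor(model, fit, Xte)
      }
      sqrt(mean((pred - sp$yte)^2))
    }
  }), 0)
  list(score = mean(scores), se = sd(scores) / sqrt(length(scores)),
       fold_scores = scores)
}

#' Cross-validated binary classification of drinking events
#'
#' Binarises labels (drinking versus all other events), z-scores the chosen
#' feature columns with training-fold statistics only, runs seeded
#' (stratified) k-fold cross-validation and returns the mean F-score of the
#' drinking class across folds with its standard error.
#'
#' @param fm a `feature_matrix` (one evaluation cell, e.g. one
#'   subject-day-side).
#' @param subset character vector of feature names to use.
#' @param model a [classifier_spec()].
#' @param protocol an [eval_protocol()] with `task = "classify"`.
#' @return an `eval_record` list: `score`, `se`, `fold_scores`, `model`,
#'   `features`, `task`, `n`.
#' @export
cv_classify <- function(fm, subset, model = classifier_spec("LDA"),
                        protocol = eval_protocol("classify")) {
  stopifnot(protocol$task == "classify", length(subset) >= 1)
  engine <- cv_engine(fm, protocol)
  stopifnot(all(subset %in% engine$cols))
  r <- eval_subset_on_engine(engine, subset, model)
  structure(c(r, list(model = model$name, features = subset,
                      task = "classify", n = engine$n)),
            class = "eval_record")
}

#' Cross-validated sip-volume regression
#'
#' Restricts the matrix to drinking events, then runs seeded k-fold
#' cross-validation of the chosen regressor on the selected features,
#' returning the mean RMSE (mL) across folds. Features are standardised on
#' training folds; for the ANN and SVR the target is also standardised and
#' predictions are back-transformed.
#'
#' @param fm a `feature_matrix` containing drinking events with `volume_ml`.
#' @param subset character vector of feature names to use.
#' @param model a [regressor_spec()].
#' @param protocol an [eval_protocol()] with `task = "regress"`.
#' @return an `eval_record` list (see [cv_classify()]); `score` is RMSE in
#'   mL.
#' @export
cv_regress <- function(fm, subset, model = regressor_spec("LR"),
                       protocol = eval_protocol("regress")) {
  stopifnot(protocol$task == "regress", length(subset) >= 1)
  engine <- cv_engine(fm, protocol)
  stopifnot(all(subset %in% engine$cols))
  r <- eval_subset_on_engine(engine, subset, model)
  structure(c(r, list(model = model$name, features = subset,
                      task = "regress", n = engine$n)),
            class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat("<eval_record> ", x$task, " | ", x$model, " | {",
      paste(x$features, collapse = ", "), "} : score ",
      signif(x$score, 4), " +/- ", signif(x$se, 3), " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

set_key <- function(s) paste(sort(s), collapse = "+")

#' Exhaustive feature-subset search
#'
#' Enumerates all feature subsets of sizes 1 to 3 (26 + 325 + 2600 = 2951
#' sets for the full catalogue) for every model and every subject-day-side
#' cell, and derives both subject-specific best sets (argmax per cell) and
#' global best sets (argmax of the across-subject mean, per day-side-model).
#' Size-4 sets are searched greedily by forward extension of the top
#' `top_m` size-3 sets (exhaustive enumeration of all 14950 sets behind the
#' `exhaustive_k4` flag); the global size-4 candidates are extensions of the
#' top size-3 sets on the across-subject mean and are evaluated in every
#' cell, so subject-specific bests always dominate the global choice. Ties
#' break deterministically towards the lexicographically first feature-name
#' set.
#'
#' @param fm a `feature_matrix` spanning one or more subject-day-side cells.
#' @param models named list of [classifier_spec()]s or [regressor_spec()]s,
#'   matching `protocol$task`.
#' @param k_max largest subset size, 1 to 4.
#' @param protocol an [eval_protocol()].
#' @param columns feature columns to search (default: all feature columns).
#' @param top_m number of size-3 sets greedily extended to size 4.
#' @param exhaustive_k4 enumerate all size-4 sets instead of the greedy
#'   extension.
#' @return a `subset_search_result` list: `cell` (data frame of every
#'   evaluated (cell, model, k, set, score)), `best_subject` (best set per
#'   cell-model-k), `best_global` (best set per day-side-model-k by mean
#'   score across subjects, with the mean score), and `n_sets` (sets
#'   enumerated per size).
#' @export
subset_search <- function(fm, models, k_max = 4L,
                          protocol = eval_protocol("classify"),
                          columns = NULL, top_m = 50L,
                          exhaustive_k4 = FALSE) {
  cols <- columns %||% feature_columns(fm)
  if (k_max < 1 || k_max > length(cols))
    stop("k_max must be between 1 and the number of feature columns",
         call. = FALSE)
  if (k_max > 26) stop("k_max must be <= 26", call. = FALSE)
  better <- if (protocol$task == "classify") `>` else `<`
  cells <- unique(fm[, c("subject", "day", "side")])
  rownames(cells) <- NULL

  k_exh <- seq_len(min(3L, k_max))
  sets_by_k <- lapply(k_exh, function(k)
    combn(sort(cols), k, simplify = FALSE))
  names(sets_by_k) <- k_exh
  n_sets <- vapply(sets_by_k, length, 0L)

  engines <- vector("list", nrow(cells))
  cell_scores <- vector("list", nrow(cells))  # env: key -> score per model
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sub_fm <- fm[fm$subject == cells$subject[ci] & fm$day == cells$day[ci] &
                   fm$side == cells$side[ci], , drop = FALSE]
    engines[[ci]] <- cv_engine(sub_fm[, c("subject", "day", "side",
                                          "event_index", "label", "volume_ml",
                                          cols)], protocol)
    cell_scores[[ci]] <- lapply(models, function(m) new.env(parent = emptyenv()))
  }
  score_cell_set <- function(ci, mi, set) {
    key <- set_key(set)
    env <- cell_scores[[ci]][[mi]]
    if (!is.null(env[[key]])) return(env[[key]])
    val <- tryCatch(
      eval_subset_on_engine(engines[[ci]], set, models[[mi]])$score,
      error = function(e) NA_real_)
    env[[key]] <- val
    val
  }
  eval_sets <- function(sets, k) {
    for (ci in seq_len(nrow(cells))) for (mi in seq_along(models)) {
      for (set in sets) {
        sc <- score_cell_set(ci, mi, set)
        rows[[length(rows) + 1L]] <<- data.frame(
          subject = cells$subject[ci], day = cells$day[ci],
          side = cells$side[ci], model = names(models)[mi], k = k,
          set = set_key(set), score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  for (k in k_exh) eval_sets(sets_by_k[[as.character(k)]], k)

  if (k_max >= 4L) {
    sets3 <- sets_by_k[["3"]]
    keys3 <- vapply(sets3, set_key, "")
    if (exhaustive_k4) {
      sets4 <- combn(sort(cols), 4, simplify = FALSE)
      n_sets <- c(n_sets, `4` = length(sets4))
      eval_sets(sets4, 4L)
    } else {
      extend_top <- function(score3) {
        ord <- order(if (protocol$task == "classify") -score3 else score3,
                     keys3)
        top <- sets3[head(ord, top_m)]
        out <- list()
        for (s in top) for (f in setdiff(cols, s))
          out[[set_key(c(s, f))]] <- sort(c(s, f))
        out
      }
      cand <- list()
      for (ci in seq_len(nrow(cells))) for (mi in seq_along(models)) {
        sc3 <- vapply(sets3, function(s) score_cell_set(ci, mi, s), 0)
        cand <- c(cand, extend_top(sc3))
      }
      # global candidates: extensions of the best mean size-3 sets
      for (mi in seq_along(models)) {
        mean3 <- vapply(sets3, function(s)
          mean(vapply(seq_len(nrow(cells)), function(ci)
            score_cell_set(ci, mi, s), 0), na.rm = TRUE), 0)
        cand <- c(cand, extend_top(mean3))
      }
      cand <- cand[!duplicated(names(cand))]
      n_sets <- c(n_sets, `4` = length(cand))
      eval_sets(unname(cand), 4L)
    }
  }

  cell_df <- do.call(rbind, rows)
  pick_best <- function(df) {
    df <- df[!is.na(df$score), , drop = FALSE]
    if (!nrow(df)) return(df)
    ord <- order(if (protocol$task == "classify") -df$score else df$score,
                 df$set)
    df[ord[1], , drop = FALSE]
  }
  split_apply <- function(df, by) {
    parts <- split(df, df[by], drop = TRUE)
    out <- do.call(rbind, lapply(parts, pick_best))
    rownames(out) <- NULL
    out
  }
  best_subject <- split_apply(cell_df, c("subject", "day", "side", "model", "k"))

  # global: mean score across subjects, only sets evaluated in every cell
  agg <- aggregate(score ~ day + side + model + k + set, data = cell_df,
                   FUN = mean, na.action = stats::na.pass)
  cnt <- aggregate(score ~ day + side + model + k + set, data = cell_df,
                   FUN = length, na.action = stats::na.pass)
  n_subj_per <- aggregate(subject ~ day + side, data = cells, FUN = length)
  agg$n_cells <- cnt$score
  agg <- merge(agg, n_subj_per, by = c("day", "side"))
  agg <- agg[agg$n_cells == agg$subject, , drop = FALSE]
  agg$subject <- NULL; agg$n_cells <- NULL
  best_global <- split_apply(agg, c("day", "side", "model", "k"))

  structure(list(cell = cell_df, best_subject = best_subject,
                 best_global = best_global, n_sets = n_sets,
                 task = protocol$task),
            class = "subset_search_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-day (twofold) transfer evaluation
#'
#' Trains on all of one day's data and tests on the other day, in both
#' directions, per subject and side: day-1 models use the day-1-selected
#' feature set and are scored on day 2, and vice versa. Subjects present on
#' only one day are excluded (and reported in the `excluded` attribute).
#' Features are standardised with training-day statistics; regression
#' targets likewise for ANN/SVR.
#'
#' @param fm_day1,fm_day2 `feature_matrix` objects for the two days (same
#'   subjects and feature schema).
#' @param set_day1,set_day2 feature sets selected on day 1 and day 2.
#' @param model a [classifier_spec()] or [regressor_spec()].
#' @param protocol an [eval_protocol()].
#' @return a data frame with one row per (subject, side, direction) plus the
#'   per-direction and overall means in `attr(, "summary")`.
#' @export
cross_day <- function(fm_day1, fm_day2, set_day1, set_day2, model,
                      protocol = eval_protocol("classify")) {
  subj1 <- unique(fm_day1$subject); subj2 <- unique(fm_day2$subject)
  common <- intersect(subj1, subj2)
  excluded <- setdiff(union(subj1, subj2), common)
  sides <- intersect(unique(fm_day1$side), unique(fm_day2$side))
  rows <- list()
  for (s in common) for (sd_ in sides) {
    a <- fm_day1[fm_day1$subject == s & fm_day1$side == sd_, , drop = FALSE]
    b <- fm_day2[fm_day2$subject == s & fm_day2$side == sd_, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, side = sd_, direction = "day1->day2",
      score = fit_score_transfer(a, b, set_day1, model, protocol),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, side = sd_, direction = "day2->day1",
      score = fit_score_transfer(b, a, set_day2, model, protocol),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  smry <- aggregate(score ~ direction, data = out, FUN = mean)
  smry <- rbind(smry, data.frame(direction = "mean",
                                 score = mean(smry$score)))
  attr(out, "summary") <- smry
  attr(out, "excluded") <- excluded
  out
}

# Train on all rows of `train`, score on all rows of `test`.
fit_score_transfer <- function(train, test, subset, model, protocol) {
  if (protocol$task == "classify") {
    ytr <- factor(ifelse(train$label == protocol$positive_class,
                         "drink", "other"), levels = c("drink", "other"))
    yte <- factor(ifelse(test$label == protocol$positive_class,
                         "drink", "other"), levels = c("drink", "other"))
  } else {
    train <- train[train$label == protocol$positive_class, , drop = FALSE]
    test <- test[test$label == protocol$positive_class, , drop = FALSE]
    ytr <- train$volume_ml; yte <- test$volume_ml
  }
  Xtr <- as.matrix(train[, subset, drop = FALSE])
  Xte <- as.matrix(test[, subset, drop = FALSE])
  mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
  if (protocol$task == "classify") {
    fit <- suppressWarnings(fit_classifier(model, Xtr, ytr))
    f1_score(yte, predict_classifier(model, fit, Xte), "drink")
  } else {
    if (model$name %in% c("ANN", "SVR")) {
      m0 <- mean(ytr); s0 <- sd(ytr); if (!is.finite(s0) || s0 == 0) s0 <- 1
      fit <- fit_regressor(model, Xtr, (ytr - m0) / s0)
      pred <- predict_regressor(model, fit, Xte) * s0 + m0
    } else {
      fit <- fit_regressor(model, Xtr, ytr)
      pred <- predict_regressor(model, fit, Xte)
    }
    sqrt(mean((pred - yte)^2))
  }
}

#' Summarise evaluation scores
#'
#' Grouped means and standard errors of a long score table (such as the
#' `cell` element of a [subset_search()] result), in the shape used for the
#' result tables: one row per group with `mean`, `se` and `n`.
#'
#' @param records data frame with a `score` column.
#' @param by grouping column names present in `records`.
#' @return data frame of grouped summaries.
#' @export
summarize_scores <- function(records, by = c("day", "side", "model", "k")) {
  by <- intersect(by, names(records))
  if (!nrow(records)) stop("no records to summarise", call. = FALSE)
  f <- stats::as.formula(paste("score ~", paste(by, collapse = " + ")))
  m <- aggregate(f, data = records, FUN = mean)
  s <- aggregate(f, data = records,
                 FUN = function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0)
  n <- aggregate(f, data = records, FUN = length)
  out <- m
  names(out)[names(out) == "score"] <- "mean"
  out$se <- s$score
  out$n <- n$score
  out
}

#' Best-set summary table
#'
#' Reshapes a [subset_search()] result into the familiar per-day best-set
#' table: for each (day, side, k), the best global feature set over all
#' models, its mean score, and the model(s) achieving it.
#'
#' @param search a `subset_search_result`.
#' @return data frame with columns `day`, `side`, `k`, `best_features`,
#'   `score`, `best_models`.
#' @export
best_set_table <- function(search) {
  bg <- search$best_global
  better <- if (search$task == "classify") `>=` else `<=`
  parts <- split(bg, bg[c("day", "side", "k")], drop = TRUE)
  rows <- lapply(parts, function(df) {
    best <- if (search$task == "classify") max(df$score) else min(df$score)
    hit <- df[df$score == best, , drop = FALSE]
    sets <- sort(unique(hit$set))
    data.frame(day = df$day[1], side = df$side[1], k = df$k[1],
               best_features = sets[1], score = best,
               best_models = paste(sort(hit$model[hit$set == sets[1]]),
                                   collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$day, out$side, out$k), , drop = FALSE]
}
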