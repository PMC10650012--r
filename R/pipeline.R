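#' Assemble a full pipeline run configuration
#'
#' Bundles every stage configuration — study design, generator parameters,
#' preprocessing, spectral settings, evaluation protocol seeds, model lists
#' and search depth — into one serialisable object with a stable content
#' hash. Re-running the pipeline with an identical configuration reproduces
#' identical outputs.
#'
#' @param design a [study_design()].
#' @param params a [generator_params()].
#' @param preprocess a [preprocess_config()].
#' @param spectral a [spectral_config()].
#' @param classifiers character vector of classifier names (see
#'   [classifier_spec()]).
#' @param regressors character vector of regressor names (see
#'   [regressor_spec()]); empty to skip regression.
#' @param k_max largest feature-subset size searched.
#' @param top_m greedy width for size-4 search.
#' @param cross_day_k subset size used for cross-day transfer.
#' @param cv_folds cross-validation folds.
#' @param stratified stratify classification folds?
#' @param seed root seed; overrides `design$seed`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(design = study_design(), params = generator_params(),
                       preprocess = preprocess_config(),
                       spectral = spectral_config(),
                       classifiers = c("SVC", "RF", "KNN1", "LDA", "QDA"),
                       regressors = c("SVR", "RF", "KNN1", "LR", "DT",
                                      "Lasso", "Ridge", "ANN"),
                       k_max = 3L, top_m = 50L, cross_day_k = 3L,
                       cv_folds = 5L, stratified = TRUE, seed = NULL) {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  structure(list(design = design, params = params, preprocess = preprocess,
                 spectral = spectral, classifiers = classifiers,
                 regressors = regressors, k_max = as.integer(k_max),
                 top_m = as.integer(top_m), cross_day_k = as.integer(cross_day_k),
                 cv_folds = as.integer(cv_folds),
                 stratified = isTRUE(stratified)),
            class = "run_config")
}

#' Validate a run configuration before any computation
#'
#' Fails fast on inconsistent settings: band edges at or above Nyquist,
#' invalid generator bands, unknown model names, or an out-of-range search
#' depth.
#'
#' @param config a [run_config()].
#' @return the config, invisibly.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  check_band(config$preprocess, config$design$fs)
  validate_generator_params(config$params, fs = config$design$fs)
  known_c <- c("SVC", "RF", "KNN1", "LDA", "QDA")
  known_r <- c("SVR", "RF", "KNN1", "LR", "DT", "Lasso", "Ridge", "ANN")
  if (length(setdiff(config$classifiers, known_c)))
    stop("unknown classifier(s): ",
         paste(setdiff(config$classifiers, known_c), collapse = ", "),
         call. = FALSE)
  if (length(setdiff(config$regressors, known_r)))
    stop("unknown regressor(s): ",
         paste(setdiff(config$regressors, known_r), collapse = ", "),
         call. = FALSE)
  if (config$k_max < 1 || config$k_max > 4)
    stop("k_max must be between 1 and 4", call. = FALSE)
  invisible(config)
}

canonical_list <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, canonical_list)
    if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[order(names(x))]
  }
  x
}

#' Stable content hash of a run configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation, so the
#' hash is invariant under key reordering.
#'
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical_list(rapply(unclass(config), identity,
                                             how = "replace")),
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a run configuration
#'
#' Configurations serialise to YAML or JSON (chosen by file extension) and
#' read back to an identical `run_config`.
#'
#' @param config a [run_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_run_config`: the path, invisibly. `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  lst <- rapply(unclass(config), identity, how = "replace")
  lst <- lapply(lst, function(x) if (is.list(x)) unclass(x) else x)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  d <- lst$design; p <- lst$params
  run_config(
    design = study_design(n_subjects = d$n_subjects, n_days = d$n_days,
                          sides = unlist(d$sides), fs = d$fs,
                          volumes = unlist(d$volumes),
                          sips_per_volume = d$sips_per_volume,
                          nondrink_classes = unlist(d$nondrink_classes),
                          events_per_nondrink_class = d$events_per_nondrink_class,
                          seed = d$seed),
    params = generator_params(
      burst_duration_mean_s = unlist(p$burst_duration_mean_s),
      burst_duration_sd_s = unlist(p$burst_duration_sd_s),
      burst_amplitude_base = unlist(p$burst_amplitude_base),
      volume_amplitude_slope = p$volume_amplitude_slope,
      volume_duration_slope = p$volume_duration_slope,
      spectral_band = lapply(p$spectral_band, unlist),
      baseline_noise_sd = p$baseline_noise_sd,
      subject_gain_sd = p$subject_gain_sd, day_drift_sd = p$day_drift_sd,
      side_asymmetry = p$side_asymmetry, sip_noise_sd = p$sip_noise_sd,
      inter_event_gap_s = p$inter_event_gap_s),
    preprocess = do.call(preprocess_config, lst$preprocess),
    spectral = do.call(spectral_config, lapply(lst$spectral, unlist)),
    classifiers = unlist(lst$classifiers),
    regressors = if (length(lst$regressors)) unlist(lst$regressors) else character(0),
    k_max = lst$k_max, top_m = lst$top_m, cross_day_k = lst$cross_day_k,
    cv_folds = lst$cv_folds, stratified = lst$stratified)
}

#' Run the full pipeline: generate, segment, extract, evaluate, summarise
#'
#' Executes every stage from one configuration: synthesises the study,
#' extracts peak-centred burst windows, computes the feature matrix, runs
#' the within-day feature-subset search for the configured classifiers (and
#' regressors, on drinking events), performs cross-day transfer with the
#' per-day global best sets when the design has two days, and writes all
#' artifacts (delimited tables plus JSON summaries) with a manifest of MD5
#' checksums. A stage failure aborts with the stage name; artifacts of
#' completed stages are retained and the manifest marks the run as failed.
#'
#' @param config a [run_config()].
#' @param output_dir directory for artifacts.
#' @return the manifest, invisibly: file list with checksums, config hash,
#'   and headline summaries.
#' @export
run_pipeline <- function(config, output_dir) {
  validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), status = "running",
                   stages = character(0), files = list())
  write_run_config(config, file.path(output_dir, "config.json"))
  add_file <- function(fn) {
    manifest$files[[fn]] <<- unname(tools::md5sum(file.path(output_dir, fn)))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  study <- stage("simulate", generate_study(config$design, config$params))
  windows <- stage("preprocess", extract_study_bursts(study, config$preprocess))
  fm <- stage("features",
              extract_feature_matrix(windows, feature_names(), config$spectral))
  write.table(fm, file.path(output_dir, "features.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  add_file("features.tsv")

  seed <- config$design$seed
  cls_protocol <- eval_protocol("classify", cv_folds = config$cv_folds,
                                stratified = config$stratified,
                                seed = child_seed(seed, 23))
  reg_protocol <- eval_protocol("regress", cv_folds = config$cv_folds,
                                seed = child_seed(seed, 29))
  classifiers <- setNames(lapply(config$classifiers, classifier_spec,
                                 seed = child_seed(seed, 31)),
                          config$classifiers)
  regressors <- setNames(lapply(config$regressors, regressor_spec,
                                seed = child_seed(seed, 37)),
                         config$regressors)

  searches <- stage("evaluate", {
    out <- list()
    out$classify <- subset_search(fm, classifiers, k_max = config$k_max,
                                  protocol = cls_protocol, top_m = config$top_m)
    if (length(regressors))
      out$regress <- subset_search(fm, regressors, k_max = config$k_max,
                                   protocol = reg_protocol,
                                   top_m = config$top_m)
    out
  })
  for (task in names(searches)) {
    write.table(searches[[task]]$cell,
                file.path(output_dir, paste0("scores_", task, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    add_file(paste0("scores_", task, ".tsv"))
  }

  crossday <- NULL
  if (config$design$n_days >= 2) {
    crossday <- stage("crossday", {
      rows <- list()
      for (task in names(searches)) {
        protocol <- if (task == "classify") cls_protocol else reg_protocol
        models <- if (task == "classify") classifiers else regressors
        kk <- min(if (task == "classify") config$cross_day_k else 1L,
                  config$k_max)
        bg <- searches[[task]]$best_global
        fm1 <- fm[fm$day == 1, , drop = FALSE]
        fm2 <- fm[fm$day == 2, , drop = FALSE]
        for (m in names(models)) for (sd_ in config$design$sides) {
          g1 <- bg[bg$day == 1 & bg$side == sd_ & bg$model == m & bg$k == kk, ]
          g2 <- bg[bg$day == 2 & bg$side == sd_ & bg$model == m & bg$k == kk, ]
          if (!nrow(g1) || !nrow(g2)) next
          cd <- cross_day(fm1[fm1$side == sd_, ], fm2[fm2$side == sd_, ],
                          strsplit(g1$set, "+", fixed = TRUE)[[1]],
                          strsplit(g2$set, "+", fixed = TRUE)[[1]],
                          models[[m]], protocol)
          cd$task <- task; cd$model <- m
          rows[[length(rows) + 1L]] <- cd
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(crossday)) {
      write.table(crossday, file.path(output_dir, "crossday.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      add_file("crossday.tsv")
    }
  }

  summaries <- stage("summarize", {
    s <- list()
    for (task in names(searches)) {
      s[[paste0(task, "_grouped")]] <-
        summarize_scores(searches[[task]]$best_subject)
      s[[paste0(task, "_best_sets")]] <- best_set_table(searches[[task]])
    }
    if (!is.null(crossday))
      s$crossday <- aggregate(score ~ task + model + direction,
                              data = crossday, FUN = mean)
    s
  })
  for (nm in names(summaries)) {
    fn <- paste0("summary_", nm, ".tsv")
    write.table(summaries[[nm]], file.path(output_dir, fn), sep = "\t",
                row.names = FALSE, quote = FALSE)
    add_file(fn)
  }
  add_file("config.json")

  manifest$status <- "ok"
  manifest$seed <- seed
  manifest$version <- as.character(packageVersion("sipemg"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
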