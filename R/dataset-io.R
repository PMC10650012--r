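# Plain-text dataset layout:
#   manifest.json            design, generator parameters, seed, file list
#   signal_S<s>_D<d>.tsv     one column per side, '# fs: <Hz>' header line
#   annotations.tsv          subject day event_index time_s label volume_ml

#' Write a synthetic study to a directory of delimited text files
#'
#' @param study an `emg_study` from [generate_study()].
#' @param directory output directory; created if needed.
#' @param digits significant digits for signal samples.
#' @return (invisibly) the manifest as a list; also written as
#'   `manifest.json`.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(study, directory, digits = 7) {
  stopifnot(inherits(study, "emg_study"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  design <- study$design
  files <- list()
  for (subj in seq_len(design$n_subjects)) {
    for (day in seq_len(design$n_days)) {
      recs <- Filter(function(r) r$subject == subj && r$day == day,
                     study$recordings)
      recs <- recs[match(design$sides, vapply(recs, `[[`, "", "side"))]
      fn <- sprintf("signal_S%02d_D%d.tsv", subj, day)
      path <- file.path(directory, fn)
      con <- file(path, "w")
      writeLines(sprintf("# fs: %s", format(design$fs, digits = 15)), con)
      writeLines(paste(design$sides, collapse = "\t"), con)
      mat <- vapply(recs, function(r) r$samples, numeric(length(recs[[1]]$samples)))
      write.table(signif(mat, digits), con, sep = "\t", row.names = FALSE,
                  col.names = FALSE, quote = FALSE)
      close(con)
      files[[length(files) + 1L]] <- list(path = fn, type = "signal",
                                          subject = subj, day = day)
    }
  }
  ann_path <- file.path(directory, "annotations.tsv")
  ann <- study$annotations
  ann$time_s <- format(ann$time_s, digits = 17)
  write.table(ann, ann_path, sep = "\t", row.names = FALSE, quote = FALSE)
  files[[length(files) + 1L]] <- list(path = "annotations.tsv",
                                      type = "annotations")
  manifest <- list(
    format = "sipemg-dataset",
    version = as.character(packageVersion("sipemg")),
    seed = design$seed,
    fs = design$fs,
    design = unclass(design),
    params = unclass(study$params),
    files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a study back from a dataset directory
#'
#' Validates the manifest, the per-file sampling rate, and annotation
#' invariants (volumes present if and only if the event is a drinking event,
#' volumes drawn from the design's volume list), and reconstructs an
#' `emg_study`.
#'
#' @param directory dataset directory written by [write_dataset()].
#' @return an `emg_study`.
#' @export
read_dataset <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest found in '", directory, "'", call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(man$format, "sipemg-dataset"))
    stop("manifest.json is not a sipemg dataset manifest", call. = FALSE)
  d <- man$design
  design <- study_design(
    n_subjects = d$n_subjects, n_days = d$n_days, sides = d$sides,
    fs = d$fs, volumes = d$volumes, sips_per_volume = d$sips_per_volume,
    nondrink_classes = d$nondrink_classes,
    events_per_nondrink_class = d$events_per_nondrink_class, seed = d$seed)
  p <- man$params
  params <- generator_params(
    burst_duration_mean_s = unlist(p$burst_duration_mean_s),
    burst_duration_sd_s = unlist(p$burst_duration_sd_s),
    burst_amplitude_base = unlist(p$burst_amplitude_base),
    volume_amplitude_slope = p$volume_amplitude_slope,
    volume_duration_slope = p$volume_duration_slope,
    spectral_band = lapply(p$spectral_band, unlist),
    baseline_noise_sd = p$baseline_noise_sd,
    subject_gain_sd = p$subject_gain_sd,
    day_drift_sd = p$day_drift_sd,
    side_asymmetry = p$side_asymmetry,
    sip_noise_sd = p$sip_noise_sd,
    inter_event_gap_s = p$inter_event_gap_s)

  files <- man$files  # data frame after simplification
  recordings <- list()
  for (i in seq_len(nrow(files))) {
    if (files$type[i] != "signal") next
    fn <- files$path[i]
    path <- file.path(directory, fn)
    if (!file.exists(path)) stop("missing file '", fn, "'", call. = FALSE)
    header <- readLines(path, n = 2L)
    fs_line <- header[1]
    if (!grepl("^# fs:", fs_line))
      stop("malformed header in '", fn, "' line 1 (expected '# fs: <Hz>')",
           call. = FALSE)
    fs_file <- as.numeric(sub("^# fs:\\s*", "", fs_line))
    if (!isTRUE(all.equal(fs_file, design$fs)))
      stop("fs mismatch in '", fn, "': manifest says ", design$fs,
           ", file header says ", fs_file, call. = FALSE)
    sides <- strsplit(header[2], "\t", fixed = TRUE)[[1]]
    mat <- tryCatch(
      as.matrix(read.table(path, skip = 2L, sep = "\t",
                           colClasses = "numeric")),
      error = function(e) stop("malformed rows in '", fn, "': ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(mat) != length(sides))
      stop("column count mismatch in '", fn, "'", call. = FALSE)
    for (si in seq_along(sides)) {
      recordings[[length(recordings) + 1L]] <- new_recording(
        samples = mat[, si], fs = design$fs,
        subject = files$subject[i], day = files$day[i], side = sides[si])
    }
  }
  if (!length(recordings))
    stop("manifest lists no signal files", call. = FALSE)

  ann_path <- file.path(directory, "annotations.tsv")
  if (!file.exists(ann_path)) stop("missing file 'annotations.tsv'", call. = FALSE)
  ann <- read.table(ann_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("subject", "day", "event_index", "time_s", "label", "volume_ml")
  if (!all(need %in% names(ann)))
    stop("annotations.tsv is missing columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "), call. = FALSE)
  bad_vol <- which(ann$label != "drink" & !is.na(ann$volume_ml))
  if (length(bad_vol))
    stop("annotations.tsv line ", bad_vol[1] + 1L,
         ": volume given for non-drinking event '", ann$label[bad_vol[1]], "'",
         call. = FALSE)
  miss_vol <- which(ann$label == "drink" & is.na(ann$volume_ml))
  if (length(miss_vol))
    stop("annotations.tsv line ", miss_vol[1] + 1L,
         ": drinking event without a volume", call. = FALSE)
  off_vol <- which(ann$label == "drink" &
                     !(ann$volume_ml %in% design$volumes))
  if (length(off_vol))
    stop("annotations.tsv line ", off_vol[1] + 1L, ": volume ",
         ann$volume_ml[off_vol[1]], " mL is not in the design volume list",
         call. = FALSE)
  structure(list(design = design, params = params,
                 recordings = recordings, annotations = ann),
            class = "emg_study")
}
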