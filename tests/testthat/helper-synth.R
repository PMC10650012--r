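# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# One default-parameter subject-day, right side only: 60 drink + 40 nondrink.
default_cell_study <- function() {
  cached("cell_study", generate_study(
    study_design(n_subjects = 1, n_days = 1, sides = "right", seed = 42),
    generator_params()))
}

default_cell_windows <- function() {
  cached("cell_windows", extract_study_bursts(default_cell_study()))
}

default_cell_features <- function() {
  cached("cell_features", extract_feature_matrix(default_cell_windows()))
}

# Reduced two-subject, two-day design for evaluation tests (25 drink + 16
# nondrink events per subject-day keeps generation fast).
small_design <- function(seed, n_subjects = 2, n_days = 2, sides = "right") {
  study_design(n_subjects = n_subjects, n_days = n_days, sides = sides,
               sips_per_volume = 5, events_per_nondrink_class = 4,
               seed = seed)
}

small_features <- function() {
  cached("small_features", extract_feature_matrix(extract_study_bursts(
    generate_study(small_design(19), generator_params()))))
}

# Label-plus-noise feature table: one informative column among noise.
planted_feature_matrix <- function(n_pos = 60, n_neg = 40, n_noise = 7,
                                   noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  lab <- c(rep("drink", n_pos), rep("talk", n_neg))
  df <- data.frame(subject = 1L, day = 1L, side = "right",
                   event_index = seq_along(lab), label = lab,
                   volume_ml = ifelse(lab == "drink",
                                      rep(c(5, 10, 15, 20, 25),
                                          length.out = n_pos), NA))
  df$signal <- as.numeric(lab == "drink") + rnorm(length(lab), 0, noise_sd)
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(length(lab))
  class(df) <- c("feature_matrix", "data.frame")
  df
}
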