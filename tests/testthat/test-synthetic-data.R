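test_that("event counts per subject-day follow the design arithmetic", {
  ann <- default_cell_study()$annotations
  expect_equal(sum(ann$label == "drink"), 60)
  expect_equal(sum(ann$label != "drink"), 40)
  expect_equal(unname(table(ann$label)[c("talk", "cough", "saliva", "solid")]),
               rep(10L, 4), ignore_attr = TRUE)
  expect_true(all(ann$volume_ml[ann$label == "drink"] %in% c(5, 10, 15, 20, 25)))
  expect_true(all(is.na(ann$volume_ml[ann$label != "drink"])))

  d2 <- study_design(n_subjects = 1, n_days = 1, volumes = 5,
                     sips_per_volume = 1, events_per_nondrink_class = 0,
                     seed = 1)
  st2 <- generate_study(d2, generator_params())
  expect_equal(nrow(st2$annotations), 1L)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  d <- study_design(n_subjects = 1, n_days = 1, sides = "right",
                    sips_per_volume = 2, events_per_nondrink_class = 1,
                    seed = 5)
  a <- generate_study(d, generator_params())
  b <- generate_study(d, generator_params())
  expect_identical(a$recordings[[1]]$samples, b$recordings[[1]]$samples)
  expect_identical(a$annotations, b$annotations)
  d$seed <- 6L
  c3 <- generate_study(d, generator_params())
  expect_false(identical(a$recordings[[1]]$samples, c3$recordings[[1]]$samples))
})

test_that("both sides of one subject-day share the event schedule", {
  st <- generate_study(
    study_design(n_subjects = 1, n_days = 1, sips_per_volume = 2,
                 events_per_nondrink_class = 1, seed = 8),
    generator_params())
  expect_equal(length(st$recordings), 2L)
  expect_setequal(vapply(st$recordings, `[[`, "", "side"), c("right", "left"))
  # one annotation table serves both channels
  expect_equal(nrow(st$annotations), 14L)
})

test_that("invalid parameters are rejected before generation", {
  expect_error(study_design(n_subjects = 0), "positive")
  expect_error(generator_params(spectral_band = list(drink = c(200, 100))),
               "band")
  p <- generator_params(spectral_band = list(drink = c(30, 1500),
                                             talk = c(60, 250),
                                             cough = c(20, 350),
                                             saliva = c(30, 150),
                                             solid = c(40, 190)))
  expect_error(generate_study(study_design(n_subjects = 1, seed = 1), p),
               "Nyquist")
})

test_that("mean burst RMS increases with sip volume when the amplitude slope is positive", {
  # raw-signal RMS around each annotated drinking event, >= 200 bursts/volume
  d <- study_design(n_subjects = 4, n_days = 1, sips_per_volume = 25,
                    events_per_nondrink_class = 0, seed = 31)
  st <- generate_study(d, generator_params())
  rms_by_vol <- lapply(setNames(nm = d$volumes), function(v) numeric(0))
  for (rec in st$recordings) {
    ann <- st$annotations[st$annotations$subject == rec$subject &
                            st$annotations$day == rec$day, ]
    for (i in seq_len(nrow(ann))) {
      idx <- round((ann$time_s[i] + c(-0.5, 0.5)) * rec$fs)
      seg <- rec$samples[max(1, idx[1]):min(length(rec$samples), idx[2])]
      v <- as.character(ann$volume_ml[i])
      rms_by_vol[[v]] <- c(rms_by_vol[[v]], sqrt(mean(seg^2)))
    }
  }
  expect_true(all(lengths(rms_by_vol) >= 200))
  means <- vapply(rms_by_vol, mean, 0)
  expect_true(all(diff(means) > 0))
  tr <- cor.test(rep(d$volumes, lengths(rms_by_vol)),
                 unlist(rms_by_vol), alternative = "greater")
  expect_lt(tr$p.value, 1e-6)
})

test_that("null-effect mode leaves burst RMS uninformative about volume", {
  p0 <- generator_params(volume_amplitude_slope = 0, volume_duration_slope = 0)
  pvals <- vapply(c(71, 72, 73), function(seed) {
    d <- study_design(n_subjects = 1, n_days = 1, sides = "right",
                      sips_per_volume = 12, events_per_nondrink_class = 0,
                      seed = seed)
    st <- generate_study(d, p0)
    rec <- st$recordings[[1]]
    ann <- st$annotations
    rms <- vapply(seq_len(nrow(ann)), function(i) {
      idx <- round((ann$time_s[i] + c(-0.5, 0.5)) * rec$fs)
      sqrt(mean(rec$samples[idx[1]:idx[2]]^2))
    }, 0)
    kruskal.test(rms, factor(ann$volume_ml))$p.value
  }, 0)
  # no systematic rejection across seeds
  expect_true(mean(pvals > 0.05) >= 2 / 3)
})
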