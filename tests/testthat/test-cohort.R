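test_that("default cohort reproduces the study marginals exactly", {
  for (s in c(1, 7, 42)) {
    co <- generate_cohort(cohort_config(seed = s))
    expect_equal(nrow(co), 51)
    expect_identical(names(co), raw_columns())
    expect_equal(unname(table(co$xla)[c("very severe", "severe", "less severe")]),
                 c(17, 22, 12), ignore_attr = TRUE)
    expect_equal(unname(table(co$mutation)[c("severe", "less severe")]),
                 c(28, 23), ignore_attr = TRUE)
  }
})

test_that("custom label counts are honoured exactly", {
  cfg <- cohort_config(n_patients = 20,
                       course_counts = c("very severe" = 5, "severe" = 10,
                                         "less severe" = 5),
                       mutation_counts = c("severe" = 12, "less severe" = 8),
                       seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$xla == "severe"), 10)
  expect_equal(sum(co$mutation == "severe"), 12)
})

test_that("zero-patient configuration yields an empty, schema-complete table", {
  cfg <- cohort_config(n_patients = 0,
                       course_counts = c("very severe" = 0, "severe" = 0,
                                         "less severe" = 0),
                       mutation_counts = c("severe" = 0, "less severe" = 0))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 0)
  expect_identical(names(co), raw_columns())
})

test_that("inconsistent configurations are rejected", {
  expect_error(cohort_config(course_counts = c("very severe" = 17,
                                               "severe" = 22,
                                               "less severe" = 13)),
               "sum")
  expect_error(cohort_config(mutation_counts = c("severe" = 1,
                                                 "less severe" = 1)),
               "sum")
  expect_error(cohort_config(noise_level = 1.5), "noise")
})

test_that("generated records respect the raw-schema invariants", {
  co <- generate_cohort(cohort_config(seed = 5))
  expect_true(all(co$age_of_dg >= co$age_of_onset))
  expect_true(all(co$age_of_onset >= 0))
  for (fl in disease_flags()) expect_true(all(co[[fl]] %in% c("yes", "")))
  expect_true(all(co$igg >= 0 & co$iga >= 0 & co$igm >= 0))
  expect_true(all(is.na(co$b_cells) | co$b_cells >= 0))
})

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(cohort_config(seed = 11))
  b <- generate_cohort(cohort_config(seed = 11))
  d <- generate_cohort(cohort_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("CSV export round-trips losslessly and is byte-stable", {
  co <- generate_cohort(cohort_config(seed = 2))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_raw_cohort(co, f1)
  write_raw_cohort(generate_cohort(cohort_config(seed = 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_raw_cohort(f1)
  expect_equal(back, co, ignore_attr = TRUE)
  header <- strsplit(readLines(f1, n = 1), ",")[[1]]
  expect_identical(gsub("\"", "", header), raw_columns())
  expect_error(write_raw_cohort(co[0, ], f1), "empty")
})

test_that("with zero noise, rule inference recovers every generating label", {
  for (s in c(1, 2, 3)) {
    pr <- preprocess_cohort(generate_cohort(
      cohort_config(seed = s, noise_level = 0, missing_fraction = 0)))
    expect_identical(kb1_conclusions(pr), as.character(pr$course))
  }
})

test_that("missing-value injection blanks the configured fraction", {
  co <- generate_cohort(cohort_config(seed = 4, missing_fraction = 0.2))
  expect_equal(sum(is.na(co$b_cells)), round(0.2 * 51))
  expect_equal(sum(is.na(co$btk_monocytes)), round(0.2 * 51))
  clean <- generate_cohort(cohort_config(seed = 4, missing_fraction = 0))
  expect_false(anyNA(clean$b_cells))
})

test_that("severe mutations come with low Btk expression and worse courses", {
  co <- generate_cohort(cohort_config(seed = 6, noise_level = 0,
                                      missing_fraction = 0))
  sev <- co$mutation == "severe"
  expect_true(mean(co$btk_lib[sev] <= 20) > 0.9)
  expect_true(mean(co$btk_lib[!sev] > 20) > 0.9)
  expect_true(all(co$mutation[co$xla == "very severe"] == "severe"))
  expect_true(all(co$mutation[co$xla == "less severe"] == "less severe"))
})
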