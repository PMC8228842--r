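test_that("ages convert from years and months to months", {
  expect_equal(normalize_age(1, 7), 19)
  expect_equal(normalize_age(0, 0), 0)
  expect_equal(normalize_age(10, 0), 120)
  expect_equal(normalize_age(c(1, 10), c(7, 0)), c(19, 120))
  expect_error(normalize_age(-1, 0), "non-negative")
  expect_error(normalize_age(1, 12), "< 12")
})

test_that("percent of norm follows the band reference", {
  rng <- default_reference_ranges()
  ref <- rng$igm$reference[rng$igm$min_months == 12]
  expect_equal(percent_of_norm(ref, 18, "igm", rng), 100)
  expect_equal(percent_of_norm(0, 18, "igm", rng), 0)
  expect_equal(percent_of_norm(ref / 2, 18, "igm", rng), 50)
  # scale equivariance
  v <- runif(5, 0, 3)
  expect_equal(percent_of_norm(2 * v, 30, "igg", rng),
               2 * percent_of_norm(v, 30, "igg", rng))
  expect_error(percent_of_norm(1, 18, "albumin", rng), "analyte")
  truncated <- structure(list(igm = data.frame(min_months = 0, max_months = 6,
                                               reference = 0.5)),
                         class = "xla_ranges")
  expect_error(percent_of_norm(1, 10, "igm", truncated), "no reference band")
})

test_that("disease flags group and count correctly", {
  co <- generate_cohort(cohort_config(seed = 1))
  none <- co[1, ]
  for (fl in disease_flags()) none[[fl]] <- ""
  expect_true(all(unlist(group_diseases(none)) == 0))
  expect_equal(count_severity(none), data.frame(severe_diseases = 0L,
                                                less_severe_diseases = 0L))

  two <- none
  two$pneumonia <- "yes"
  two$bronchitis <- "yes"
  g <- group_diseases(two)
  expect_equal(g$pulmonology, 2L)
  expect_equal(sum(unlist(g)), 2L)
  expect_equal(count_severity(two)$severe_diseases, 1L)  # pneumonia only

  all_yes <- none
  for (fl in disease_flags()) all_yes[[fl]] <- "yes"
  expect_equal(sum(unlist(group_diseases(all_yes))), 21L)
  cs <- count_severity(all_yes)
  expect_equal(cs$severe_diseases + cs$less_severe_diseases, 21L)

  expect_equal(count_severity(two, c("sepsis"))$severe_diseases, 0L)
  expect_error(group_diseases(two, list(pulmonology = "pneumonia")), "21 flags")
  expect_error(count_severity(two, c("gout")), "unknown")
})

test_that("median imputation fills blanks and logs counts", {
  df <- data.frame(a = c(1, NA, 3), b = c(5, 6, 7))
  out <- impute_missing(df, c("a", "b"))
  expect_equal(out$a, c(1, 2, 3))
  expect_equal(out$b, df$b)
  expect_equal(attr(out, "imputed"), c(a = 1L, b = 0L))
  expect_error(impute_missing(data.frame(a = c(NA_real_, NA_real_)), "a"),
               "entirely missing")
  expect_error(impute_missing(df, "z"), "not in table")
})

test_that("preprocessing yields the 18-attribute table and preserves rows", {
  co <- generate_cohort(cohort_config(seed = 1))
  pr <- preprocess_cohort(co)
  expect_equal(dim(pr), c(51, 18))
  expect_identical(names(pr), processed_columns())
  expect_false(anyNA(pr[, c("bcells_pct", "btk_monocytes")]))
  expect_true(sum(attr(pr, "imputed")) > 0)
  expect_identical(levels(pr$course), course_labels())
  # conservation: severity counts equal total set flags per record
  yes_total <- rowSums(vapply(disease_flags(), function(f) co[[f]] == "yes",
                              logical(51)))
  expect_equal(pr$severe_diseases + pr$less_severe_diseases,
               as.integer(yes_total))
  # group counts conserve the same total
  grp <- pr$rheumatology + pr$pulmonology + pr$otorhinolaryngology +
    pr$gastroenterology + pr$resistance
  expect_equal(grp, as.integer(yes_total))
})

test_that("percent columns invert the generator's reference scaling", {
  co <- generate_cohort(cohort_config(seed = 9, missing_fraction = 0))
  pr <- preprocess_cohort(co)
  rng <- default_reference_ranges()
  expect_equal(pr$igm_pct,
               percent_of_norm(co$igm, co$age_of_dg, "igm", rng))
})

test_that("empty and malformed inputs are handled explicitly", {
  co <- generate_cohort(cohort_config(seed = 1))
  empty <- co[0, ]
  out <- preprocess_cohort(empty)
  expect_equal(nrow(out), 0)
  expect_identical(names(out), processed_columns())

  broken <- co[, -3]
  expect_error(preprocess_cohort(broken), "igg")

  pr <- preprocess_cohort(co)
  expect_error(preprocess_cohort(pr), "already")
})
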