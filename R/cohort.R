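# Seeded synthetic XLA cohort generator. Produces raw 37-attribute records
# whose label marginals match the study population exactly and whose
# feature-label dependencies follow the disease-course knowledge base:
# each record is drawn from the region of the course rule it is generated
# from, so with noise 0 rule-based inference recovers every generating
# label. Raw immunoglobulin values are emitted in g/L against the bundled
# reference table so that the percent-of-norm preprocessing step is
# exercised end to end.

#' Configuration of the synthetic cohort
#'
#' Defaults are the study-population marginals: 51 patients, disease-course
#' counts 17 very severe / 22 severe / 12 less severe, mutation counts 28
#' severe / 23 less severe.
#'
#' @param n_patients Cohort size.
#' @param course_counts Named counts per course label; must sum to
#'   \code{n_patients}.
#' @param mutation_counts Named counts per mutation label; must sum to
#'   \code{n_patients}.
#' @param seed Integer RNG seed.
#' @param noise_level Fraction of records whose laboratory features are
#'   redrawn ignoring the label (0–1, default 0.1).
#' @param missing_fraction Fraction of blank cells injected into
#'   \code{missing_columns} (default 0.1).
#' @param missing_columns Raw numeric columns receiving blanks (default
#'   B cells and Btk monocytes).
#' @return A list of class \code{xla_cohort_config}.
#' @export
cohort_config <- function(n_patients = 51,
                          course_counts = c("very severe" = 17, "severe" = 22,
                                            "less severe" = 12),
                          mutation_counts = c("severe" = 28,
                                              "less severe" = 23),
                          seed = 1, noise_level = 0.1,
                          missing_fraction = 0.1,
                          missing_columns = c("b_cells", "btk_monocytes")) {
  if (!setequal(names(course_counts), course_labels()) ||
      sum(course_counts) != n_patients) {
    stop_config("course_counts must be named by the course labels and sum ",
                "to n_patients")
  }
  if (!setequal(names(mutation_counts), mutation_labels()) ||
      sum(mutation_counts) != n_patients) {
    stop_config("mutation_counts must be named by the mutation labels and ",
                "sum to n_patients")
  }
  if (noise_level < 0 || noise_level > 1) {
    stop_config("noise_level must be in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients),
                 course_counts = course_counts[course_labels()],
                 mutation_counts = mutation_counts[mutation_labels()],
                 seed = as.integer(seed), noise_level = noise_level,
                 missing_fraction = missing_fraction,
                 missing_columns = missing_columns),
            class = "xla_cohort_config")
}

# Feature domains used when a rule leaves an attribute unconstrained.
feature_domain <- function(attribute) {
  if (attribute == "age_ob") c(0, 216) else c(0, 200)
}

# [lo, hi) bounds per attribute for one compiled rule.
rule_bounds <- function(r, attributes) {
  out <- lapply(attributes, function(a) {
    b <- feature_domain(a)
    for (cn in r$conditions) {
      if (cn$attribute != a) next
      if (cn$op == "lt") b[2] <- min(b[2], cn$bound)
      if (cn$op == "ge") b[1] <- max(b[1], cn$bound)
      if (cn$op == "in") b <- c(max(b[1], cn$bound[1]), min(b[2], cn$bound[2]))
    }
    b
  })
  stats::setNames(out, attributes)
}

rule_constrains <- function(r, attribute) {
  any(vapply(r$conditions, function(cn) cn$attribute == attribute, logical(1)))
}

# Draw n values inside [lo + m, hi - m]; clinically centred, sd tied to
# the region width.
sample_region <- function(n, bounds, margin = 0.5) {
  lo <- bounds[1] + margin
  hi <- bounds[2] - margin
  rtruncnorm(n, mean = (lo + hi) / 2, sd = (hi - lo) / 6, lo, hi)
}

# Immunoglobulin percents not pinned down by the generating rule reflect
# panhypogammaglobulinemia: mass concentrated near the detectability
# cutoff. Within the IgM-undetectable stratum the unconstrained IgG of a
# severe-course patient stays in the detectable range — a patient whose
# IgG were also undetectable would belong to the very-severe stratum
# instead — so there the IgG level alone carries the course distinction.
sample_background_igg <- function(n, igm_undetectable, u) {
  if (igm_undetectable) rtruncnorm(n, mean = 1.5 * u, sd = u / 2, u + 0.5, 199.5)
  else rtruncnorm(n, mean = 1.25 * u, sd = 0.75 * u, 0.5, 199.5)
}

# Unconstrained IgA stays below the top of the middle band: an IgA percent
# above it is a feature of the early-onset severe stratum only.
sample_background_iga <- function(n, u, mid) {
  rtruncnorm(n, mean = u, sd = 0.6 * u, 0.5, mid - 0.5)
}

reference_at <- function(ranges, analyte, age_months) {
  b <- ranges[[analyte]]
  idx <- vapply(age_months, function(a) {
    which(a >= b$min_months & a < b$max_months)[1]
  }, integer(1))
  b$reference[idx]
}

empty_raw_cohort <- function() {
  cols <- raw_columns()
  df <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                             dimnames = list(NULL, cols)))
  for (cl in raw_numeric_columns()) df[[cl]] <- numeric(0)
  for (cl in setdiff(cols, raw_numeric_columns())) df[[cl]] <- character(0)
  df[, cols]
}

#' Generate a synthetic raw XLA cohort
#'
#' Course labels are drawn first with exactly the configured counts; each
#' record is then generated from one path of the disease-course rule set
#' (deterministic largest-remainder allocation of a label's count across
#' that label's rules), so its onset age and immunoglobulin percents lie
#' inside the generating rule's region. Mutation labels are assigned
#' worst-course-first with exactly the configured marginals, which yields
#' the course–mutation dependency the combined models rely on. Btk
#' expression and B-cell level are drawn conditionally on mutation
#' severity (low Btk in B lymphocytes and near-absent B cells with a
#' severe mutation), past-disease flags per organ system with rates
#' increasing with course severity. A \code{noise_level} fraction of
#' records has its laboratory features redrawn ignoring the labels, and a
#' \code{missing_fraction} of blanks is injected into two numeric columns.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param ranges Reference-range table used to convert generated
#'   percent-of-norm values back to raw g/L (and B-cell percent) values.
#' @param catalog Threshold catalog defining the rule regions.
#' @return Data frame with the 37 \code{\link{raw_columns}}, one row per
#'   patient. Identical configuration (including seed) gives identical
#'   output.
#' @export
generate_cohort <- function(config = cohort_config(),
                            ranges = default_reference_ranges(),
                            catalog = threshold_catalog()) {
  stopifnot(inherits(config, "xla_cohort_config"))
  n <- config$n_patients
  if (n == 0) return(empty_raw_cohort())
  set.seed(config$seed)

  kb1 <- load_kb("kb1_course_ig", catalog)
  concl <- vapply(kb1$rules, `[[`, character(1), "conclusion")
  feats <- c("age_ob", "igm_pct", "igg_pct", "iga_pct")

  course <- sample(rep(names(config$course_counts), config$course_counts))

  # Deterministic allocation of each label's count across its rules. Under
  # the default 51-patient counts the severe course populates only the
  # detectable-IgM paths (low-IgA heavily, high-IgA lightly), so that
  # undetectable IgM is specific to the very severe course and IgM is the
  # dominant first split, mirroring the shape of the source model; the
  # less severe course leans on the late-onset path for the same reason at
  # the onset-age boundary.
  rule_weights <- rep(1, length(kb1$rules))
  sev_rules <- which(concl == "severe")
  rule_weights[sev_rules] <- c(0, 0, 18, 4)[seq_along(sev_rules)]
  less_rules <- which(concl == "less severe")
  rule_weights[less_rules] <- c(1, 2)[seq_along(less_rules)]
  rule_of <- integer(n)
  for (lab in names(config$course_counts)) {
    rules_lab <- which(concl == lab)
    alloc <- largest_remainder(config$course_counts[[lab]],
                               rule_weights[rules_lab])
    rule_of[course == lab] <- rep(rules_lab, alloc)
  }

  vals <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  u <- catalog$undetectable_pct_max
  for (ri in sort(unique(rule_of))) {
    idx <- which(rule_of == ri)
    r <- kb1$rules[[ri]]
    k <- length(idx)
    bounds <- rule_bounds(r, feats)
    igm_undetectable <- bounds$igm_pct[2] <= u
    early <- bounds$age_ob[2] <= catalog$onset_early_max
    e <- catalog$onset_early_max
    vals[idx, "age_ob"] <- if (early && concl[ri] == "less severe") {
      # Early-onset less severe patients sit strictly interior to the
      # early band: the severe course keeps both its extremes, so the
      # early/late boundary stays the sharpest age cut in the cohort.
      rtruncnorm(k, mean = e / 2, sd = e / 6, e / 3, 0.58 * e)
    } else if (early && concl[ri] == "severe" &&
               rule_constrains(r, "iga_pct") &&
               bounds$iga_pct[1] >= catalog$iga_mid_max) {
      # the high-IgA severe stratum presents late within the early band,
      # so the severe course flanks the less severe onsets from above too
      rtruncnorm(k, mean = 0.75 * e, sd = e / 8, 0.58 * e + 0.5,
                 bounds$age_ob[2] - 0.5)
    } else if (early) {
      # severe and very severe onset leans to infancy across the band
      rtruncnorm(k, mean = 0.4 * e, sd = 0.2 * e, 0.5,
                 bounds$age_ob[2] - 0.5)
    } else {
      sample_region(k, bounds$age_ob)
    }
    early_less <- early && concl[ri] == "less severe"
    vals[idx, "igm_pct"] <- if (early_less) {
      # the early-onset less severe stratum sits in the middle of the
      # detectable IgM range — neither borderline-detectable nor extreme
      rtruncnorm(k, mean = mean(bounds$igm_pct + c(0.5, -0.5)),
                 sd = diff(bounds$igm_pct) / 12,
                 bounds$igm_pct[1] + 0.5, bounds$igm_pct[2] - 0.5)
    } else {
      sample_region(k, bounds$igm_pct)
    }
    vals[idx, "igg_pct"] <- if (rule_constrains(r, "igg_pct") &&
                                concl[ri] == "very severe") {
      sample_region(k, bounds$igg_pct)
    } else if (early_less) {
      rtruncnorm(k, mean = 1.25 * u, sd = 0.25 * u, 0.9 * u, 2 * u)
    } else {
      sample_background_igg(k, igm_undetectable, u)
    }
    vals[idx, "iga_pct"] <- if (rule_constrains(r, "iga_pct")) {
      sample_region(k, bounds$iga_pct)
    } else {
      sample_background_iga(k, u, catalog$iga_mid_max)
    }
  }

  # Label-inconsistent noise: redraw laboratory features for a fraction of
  # records from a label-agnostic distribution.
  n_noise <- round(config$noise_level * n)
  noisy <- if (n_noise > 0) sample.int(n, n_noise) else integer(0)
  if (length(noisy)) {
    vals[noisy, "age_ob"] <- runif(length(noisy), 0, 120)
    for (a in c("igm_pct", "igg_pct", "iga_pct")) {
      vals[noisy, a] <- rtruncnorm(length(noisy), 50, 40, 0.5, 199.5)
    }
  }

  age_ob <- pmax(0L, as.integer(floor(vals[, "age_ob"])))
  age_dg <- age_ob + sample(1:18, n, replace = TRUE)

  # Mutation severity: exact marginals, worst course first (random order
  # inside the boundary course class).
  sev_rank <- match(course, course_labels())
  ord <- order(sev_rank, sample.int(n))
  mutation <- character(n)
  mutation[ord] <- rep(names(config$mutation_counts), config$mutation_counts)

  msev <- mutation == "severe"
  btk_lib <- numeric(n)
  btk_lib[msev] <- rtruncnorm(sum(msev), 8, 5, 0.5, 19.5)
  btk_lib[!msev] <- rtruncnorm(sum(!msev), 45, 12, 20.5, 95)
  btk_mono <- numeric(n)
  btk_mono[msev] <- rtruncnorm(sum(msev), 40, 20, 1, 99)
  btk_mono[!msev] <- rtruncnorm(sum(!msev), 60, 20, 1, 99)
  b_cells <- numeric(n)
  b_cells[msev] <- rtruncnorm(sum(msev), 0.4, 0.3, 0, 0.9)
  b_cells[!msev] <- rtruncnorm(sum(!msev), 3, 2, 1.1, 10)
  if (length(noisy)) {
    btk_lib[noisy] <- runif(length(noisy), 0, 95)
    b_cells[noisy] <- runif(length(noisy), 0, 10)
  }

  # Raw laboratory values in the units of the reference table.
  igm <- round(vals[, "igm_pct"] / 100 * reference_at(ranges, "igm", age_dg), 4)
  igg <- round(vals[, "igg_pct"] / 100 * reference_at(ranges, "igg", age_dg), 4)
  iga <- round(vals[, "iga_pct"] / 100 * reference_at(ranges, "iga", age_dg), 4)

  # Past-disease flags: per-flag rates increase with course severity.
  flag_rate <- c("very severe" = 0.35, "severe" = 0.18, "less severe" = 0.08)
  flags <- matrix("", n, 21, dimnames = list(NULL, disease_flags()))
  for (fl in disease_flags()) {
    flags[, fl] <- ifelse(runif(n) < flag_rate[course], "yes", "")
  }
  family <- ifelse(runif(n) < 0.2, "yes", "")

  raw <- data.frame(
    age_of_onset = age_ob,
    age_of_dg = age_dg,
    igg = igg, iga = iga, igm = igm,
    b_cells = round(b_cells, 2),
    btk_monocytes = round(btk_mono, 1),
    btk_lib = round(btk_lib, 1),
    family_history = family,
    as.data.frame(flags),
    mutation = mutation,
    xla = course,
    exon = as.character(sample(1:19, n, replace = TRUE)),
    nucleotide_change = rep("c.?", n),
    protein_change = rep("p.?", n),
    other = rep("", n),
    n_a = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )

  # Inject blanks into the configured numeric columns.
  n_miss <- round(config$missing_fraction * n)
  if (n_miss > 0) {
    for (cl in config$missing_columns) {
      raw[[cl]][sample.int(n, n_miss)] <- NA_real_
    }
  }
  raw[, raw_columns()]
}

#' Write and read a raw cohort as CSV
#'
#' UTF-8 CSV with the 37 raw columns in canonical order; empty strings
#' encode the registry's empty cells (and blank numeric cells). The pair
#' round-trips a generated cohort losslessly.
#'
#' @param cohort Raw cohort data frame (non-empty).
#' @param path Output file path.
#' @return \code{write_raw_cohort} returns the path invisibly;
#'   \code{read_raw_cohort} returns the cohort data frame.
#' @export
write_raw_cohort <- function(cohort, path) {
  if (nrow(cohort) == 0) stop_config("refusing to export an empty cohort")
  validate_raw_cohort(cohort)
  write.csv(cohort[, raw_columns()], path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_raw_cohort
#' @export
read_raw_cohort <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(raw_columns(), names(df))
  if (length(missing)) {
    stop_config("file is not a raw cohort; missing columns: ",
                paste(missing, collapse = ", "))
  }
  for (cl in raw_numeric_columns()) {
    df[[cl]] <- suppressWarnings(as.numeric(ifelse(df[[cl]] == "", NA, df[[cl]])))
  }
  df[, raw_columns()]
}
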