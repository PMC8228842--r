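# Preprocessing: raw 37-attribute registry table -> 18-attribute modelling
# table.  Ages go to months, immunoglobulin and B-cell levels to percent of
# the age-specific reference value, past diseases to per-system counts and
# severe / less-severe counts; blanks in numeric columns are median-imputed.

#' Convert an age given in years and months to months
#'
#' @param years Whole years (non-negative integer).
#' @param months Residual months, \code{0 <= months < 12}.
#' @return Age in months (\code{12 * years + months}). Vectorized.
#' @examples
#' normalize_age(1, 7)   # 19
#' normalize_age(10, 0)  # 120
#' @export
normalize_age <- function(years, months) {
  if (any(years < 0) || any(months < 0)) {
    stop_config("ages must be non-negative")
  }
  if (any(months >= 12)) {
    stop_config("residual months must be < 12")
  }
  as.integer(12 * years + months)
}

#' Age-banded reference ranges bundled with the package
#'
#' Reads the default reference table (a synthetic placeholder documented in
#' \code{inst/extdata/reference_ranges.json}): for each analyte, half-open
#' age bands \code{[min, max)} in months with a single central reference
#' value. Supply your own file to use laboratory-specific norms.
#'
#' @param path Path to a JSON file in the same layout; default is the
#'   packaged table.
#' @return An object of class \code{xla_ranges}: a named list of data frames
#'   with columns \code{min_months}, \code{max_months}, \code{reference}.
#' @export
default_reference_ranges <- function(path = system.file("extdata", "reference_ranges.json",
                                                        package = "xlapipe")) {
  raw <- jsonlite::fromJSON(path)
  ranges <- lapply(raw$analytes, function(a) {
    hi <- suppressWarnings(as.numeric(unlist(lapply(a$max_months, `%||%`, Inf))))
    hi[is.na(hi)] <- Inf  # JSON null marks the open-ended last band
    data.frame(min_months = as.numeric(unlist(a$min_months)),
               max_months = hi,
               reference = as.numeric(unlist(a$reference)))
  })
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    if (any(b$reference <= 0)) stop_config("reference values must be > 0")
    if (b$min_months[1] != 0 || any(b$min_months[-1] != b$max_months[-nrow(b)])) {
      stop_config("age bands for ", nm, " must partition [0, Inf) without overlap")
    }
  }
  structure(ranges, class = "xla_ranges")
}

#' Express a laboratory value as percent of the age-specific reference
#'
#' @param value Measured value (same units as the reference table).
#' @param age_months Age in months at measurement.
#' @param analyte Analyte name present in \code{ranges} (e.g. \code{"igm"}).
#' @param ranges An \code{xla_ranges} table.
#' @return \code{100 * value / reference} for the band containing the age.
#'   Vectorized over \code{value} and \code{age_months}.
#' @export
percent_of_norm <- function(value, age_months, analyte,
                            ranges = default_reference_ranges()) {
  if (!analyte %in% names(ranges)) {
    stop_config("analyte '", analyte, "' not present in reference ranges")
  }
  if (any(value < 0, na.rm = TRUE)) stop_config("values must be non-negative")
  b <- ranges[[analyte]]
  idx <- vapply(age_months, function(a) {
    i <- which(a >= b$min_months & a < b$max_months)
    if (length(i) != 1) stop_config("age ", a, " months matches no reference band")
    i
  }, integer(1))
  100 * value / b$reference[idx]
}

#' Default disease-to-organ-system mapping and severe-disease set
#'
#' The mapping assigns each of the 21 past-disease flags to one organ-system
#' group (pulmonology, otorhinolaryngology, gastroenterology, rheumatology,
#' resistance); the severe set lists the diseases counted as severe invasive
#' infections. Both ship as an editable JSON resource.
#'
#' @param path Path to a JSON file in the packaged layout.
#' @return \code{default_disease_groups}: named list group -> flag names.
#'   \code{default_severe_set}: character vector of flag names.
#' @name disease_mapping
#' @export
default_disease_groups <- function(path = system.file("extdata", "disease_groups.json",
                                                      package = "xlapipe")) {
  jsonlite::fromJSON(path)$groups
}

#' @rdname disease_mapping
#' @export
default_severe_set <- function(path = system.file("extdata", "disease_groups.json",
                                                  package = "xlapipe")) {
  jsonlite::fromJSON(path)$severe
}

#' Count past diseases per organ-system group
#'
#' @param table Raw cohort data frame (must contain all 21 flag columns).
#' @param mapping Named list group -> flag names; must cover every flag.
#' @return Data frame with one count column per group, one row per patient.
#' @export
group_diseases <- function(table, mapping = default_disease_groups()) {
  flags <- disease_flags()
  covered <- unlist(mapping)
  if (!setequal(covered, flags) || anyDuplicated(covered)) {
    stop_config("disease mapping must cover each of the 21 flags exactly once; ",
                "unmapped: ", paste(setdiff(flags, covered), collapse = ", "))
  }
  out <- lapply(mapping, function(cols) {
    m <- vapply(cols, function(cl) table[[cl]] == "yes",
                logical(nrow(table)))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(table))
    as.integer(rowSums(m))
  })
  as.data.frame(out)
}

#' Count severe and less severe past diseases
#'
#' @param table Raw cohort data frame.
#' @param severe_set Flag names counted as severe invasive infections.
#' @return Data frame with columns \code{severe_diseases} and
#'   \code{less_severe_diseases}; the two always sum to the number of set
#'   flags.
#' @export
count_severity <- function(table, severe_set = default_severe_set()) {
  flags <- disease_flags()
  if (!all(severe_set %in% flags)) {
    stop_config("severe set contains unknown disease flags: ",
                paste(setdiff(severe_set, flags), collapse = ", "))
  }
  yes <- vapply(flags, function(cl) table[[cl]] == "yes", logical(nrow(table)))
  if (nrow(table) == 1) yes <- matrix(yes, nrow = 1, dimnames = list(NULL, flags))
  sev <- as.integer(rowSums(yes[, flags %in% severe_set, drop = FALSE]))
  data.frame(severe_diseases = sev,
             less_severe_diseases = as.integer(rowSums(yes)) - sev)
}

#' Median-impute blanks in numeric columns
#'
#' @param table A data frame.
#' @param columns Names of numeric columns to impute.
#' @return The table with \code{NA}s in the named columns replaced by the
#'   column median of the observed values; the number of imputations per
#'   column is attached as attribute \code{"imputed"}.
#' @export
impute_missing <- function(table, columns) {
  counts <- integer(length(columns))
  names(counts) <- columns
  for (cl in columns) {
    if (!cl %in% names(table)) stop_config("column '", cl, "' not in table")
    x <- table[[cl]]
    if (!is.numeric(x)) stop_config("column '", cl, "' is not numeric")
    miss <- is.na(x)
    if (all(miss)) stop_config("column '", cl, "' is entirely missing; cannot impute")
    if (any(miss)) table[[cl]][miss] <- median(x[!miss])
    counts[cl] <- sum(miss)
  }
  attr(table, "imputed") <- counts
  table
}

validate_raw_cohort <- function(raw) {
  missing <- setdiff(raw_columns(), names(raw))
  if (setequal(names(raw), processed_columns())) {
    stop_config("table already has the processed 18-attribute schema; ",
                "preprocessing is not re-applied")
  }
  if (length(missing)) {
    stop_config("raw table does not match the 37-attribute schema; missing: ",
                paste(missing, collapse = ", "))
  }
  bad <- vapply(disease_flags(), function(cl) any(!raw[[cl]] %in% c("yes", "")),
                logical(1))
  if (any(bad)) {
    stop_config("disease flags must be 'yes' or empty; offending columns: ",
                paste(disease_flags()[bad], collapse = ", "))
  }
  invisible(raw)
}

#' Transform a raw cohort into the 18-attribute modelling table
#'
#' Applies the full preprocessing chain: schema validation, median
#' imputation of blank numeric cells, percent-of-norm transformation of the
#' immunoglobulin and B-cell columns (using the age at diagnosis to pick the
#' reference band), organ-system disease counts, severe / less-severe
#' disease counts, and 0/1 recoding of the family-history flag. Row count is
#' always preserved; a table already in the processed schema is rejected.
#'
#' @param raw Raw cohort data frame in the 37-attribute schema.
#' @param ranges Reference-range table (\code{\link{default_reference_ranges}}).
#' @param mapping Disease-to-system mapping (\code{\link{default_disease_groups}}).
#' @param severe_set Severe-disease set (\code{\link{default_severe_set}}).
#' @return Data frame with the 18 \code{\link{processed_columns}}; labels are
#'   factors with the canonical level order.
#' @export
preprocess_cohort <- function(raw, ranges = default_reference_ranges(),
                              mapping = default_disease_groups(),
                              severe_set = default_severe_set()) {
  validate_raw_cohort(raw)
  if (nrow(raw) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = 18,
                                dimnames = list(NULL, processed_columns())))
    return(out)
  }
  num_cols <- setdiff(raw_numeric_columns(), "n_a")
  has_na <- num_cols[vapply(num_cols, function(cl) anyNA(raw[[cl]]), logical(1))]
  if (length(has_na)) raw <- impute_missing(raw, has_na)
  imputed <- attr(raw, "imputed")

  grp <- group_diseases(raw, mapping)
  sev <- count_severity(raw, severe_set)
  out <- data.frame(
    age_ob = raw$age_of_onset,
    age_dg = raw$age_of_dg,
    igg_pct = percent_of_norm(raw$igg, raw$age_of_dg, "igg", ranges),
    igm_pct = percent_of_norm(raw$igm, raw$age_of_dg, "igm", ranges),
    iga_pct = percent_of_norm(raw$iga, raw$age_of_dg, "iga", ranges),
    bcells_pct = percent_of_norm(raw$b_cells, raw$age_of_dg, "b_cells", ranges),
    btk_lib = raw$btk_lib,
    btk_monocytes = raw$btk_monocytes,
    family = as.integer(raw$family_history == "yes"),
    severe_diseases = sev$severe_diseases,
    less_severe_diseases = sev$less_severe_diseases,
    rheumatology = grp$rheumatology,
    pulmonology = grp$pulmonology,
    otorhinolaryngology = grp$otorhinolaryngology,
    gastroenterology = grp$gastroenterology,
    resistance = grp$resistance,
    mutation_severity = factor(raw$mutation, levels = mutation_labels()),
    course = factor(raw$xla, levels = course_labels())
  )
  if (anyNA(out$course) || anyNA(out$mutation_severity)) {
    stop_config("unknown severity labels in 'xla' or 'mutation' column")
  }
  out <- out[, processed_columns()]
  attr(out, "imputed") <- imputed
  out
}
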