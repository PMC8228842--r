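# Internal helpers: truncated-normal sampling, integer allocation, schema
# constants shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_config <- function(...) stop(..., call. = FALSE)

# Inverse-CDF truncated normal on [lo, hi]; degenerate bounds collapse to
# the midpoint.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (hi <= lo) return(rep((lo + hi) / 2, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(rep(pmin(pmax(mean, lo), hi), n))
  qnorm(runif(n, plo, phi), mean, sd)
}

# Largest-remainder apportionment of `total` into length(weights) integer
# parts proportional to weights. Deterministic; ties go to earlier entries.
largest_remainder <- function(total, weights) {
  if (total == 0) return(integer(length(weights)))
  ideal <- total * weights / sum(weights)
  base <- floor(ideal)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(-(ideal - base), seq_along(weights))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# --- registry schema -------------------------------------------------------

#' Names of the 21 past-disease flag columns in the raw registry schema
#' @return Character vector of 21 column names.
#' @export
disease_flags <- function() {
  c("sepsis", "meningitis", "pneumonia", "bronchitis", "otitis",
    "diarrhea", "urti", "uti", "sinusitis", "bronchiectasis", "abscess",
    "hemophilia_a", "ascariasis", "conjunctivitis", "arthritis",
    "stomatitis", "furunculosis", "encephalitis", "guillain_barre",
    "laryngitis", "ibd")
}

#' Column names of the raw 37-attribute registry table, in canonical order
#' @return Character vector of 37 column names.
#' @export
raw_columns <- function() {
  c("age_of_onset", "age_of_dg", "igg", "iga", "igm", "b_cells",
    "btk_monocytes", "btk_lib", "family_history", disease_flags(),
    "mutation", "xla", "exon", "nucleotide_change", "protein_change",
    "other", "n_a")
}

#' Column names of the processed 18-attribute modelling table
#' @return Character vector of 18 column names.
#' @export
processed_columns <- function() {
  c("age_ob", "age_dg", "igg_pct", "igm_pct", "iga_pct", "bcells_pct",
    "btk_lib", "btk_monocytes", "family", "severe_diseases",
    "less_severe_diseases", "rheumatology", "pulmonology",
    "otorhinolaryngology", "gastroenterology", "resistance",
    "mutation_severity", "course")
}

#' Canonical severity labels
#'
#' Disease-course labels are ordered worst first; mutation labels likewise.
#' The orders double as the tie-break order for leaf labelling.
#'
#' @name severity_labels
#' @return Character vector of labels.
#' @export
course_labels <- function() c("very severe", "severe", "less severe")

#' @rdname severity_labels
#' @export
mutation_labels <- function() c("severe", "less severe")

raw_numeric_columns <- function() {
  c("age_of_onset", "age_of_dg", "igg", "iga", "igm", "b_cells",
    "btk_monocytes", "btk_lib", "n_a")
}

# Guess canonical class ordering for a label vector.
canonical_classes <- function(y) {
  if (is.factor(y)) return(levels(y))
  u <- unique(as.character(y))
  for (lv in list(course_labels(), mutation_labels())) {
    if (all(u %in% lv)) return(lv)
  }
  sort(u)
}
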