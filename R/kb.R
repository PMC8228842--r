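# Curated XLA knowledge bases: the numeric threshold catalog grounding the
# qualitative clinical terms ("undetectable", "early onset", the IgA
# bands), the severity rule sets for disease course and mutation severity,
# and the verification harness that replays the reference test tables.

#' Threshold catalog grounding the qualitative severity terms
#'
#' All thresholds are configurable; the defaults are the unique simple
#' grounding consistent with every row of the bundled verification tables:
#' onset before 24 months counts as early, an immunoglobulin below 20
#' percent of the age norm counts as undetectable, IgA bands split at 20
#' and 50 percent, Btk expression in B lymphocytes above 20 percent
#' indicates a less severe mutation, B cells below 5 percent of norm count
#' as absent, and IgM at or above 60 percent marks the high-IgM branch of
#' the mutation rule set.
#'
#' @param onset_early_max Months; onset strictly below is "early".
#' @param undetectable_pct_max Percent of norm; IgM/IgG strictly below is
#'   "undetectable".
#' @param iga_low_max,iga_mid_max IgA percent band edges (low < mid).
#' @param btk_lib_low_max Btk-in-B-lymphocytes cut for mutation severity.
#' @param bcells_absent_max B-cell percent-of-norm below which B cells
#'   count as absent.
#' @param igm_high_min IgM percent at or above which the deep branch of
#'   the mutation rule set concludes a severe mutation.
#' @return A list of class \code{xla_catalog}.
#' @export
threshold_catalog <- function(onset_early_max = 24, undetectable_pct_max = 20,
                              iga_low_max = 20, iga_mid_max = 50,
                              btk_lib_low_max = 20, bcells_absent_max = 5,
                              igm_high_min = 60) {
  if (iga_low_max >= iga_mid_max) stop_config("iga_low_max must be < iga_mid_max")
  vals <- c(onset_early_max, undetectable_pct_max, iga_low_max, iga_mid_max,
            btk_lib_low_max, bcells_absent_max, igm_high_min)
  if (any(vals <= 0)) stop_config("all thresholds must be > 0")
  structure(list(onset_early_max = onset_early_max,
                 undetectable_pct_max = undetectable_pct_max,
                 iga_low_max = iga_low_max, iga_mid_max = iga_mid_max,
                 btk_lib_low_max = btk_lib_low_max,
                 bcells_absent_max = bcells_absent_max,
                 igm_high_min = igm_high_min),
            class = "xla_catalog")
}

leaf_node <- function(label) list(type = "leaf", label = label, n = 0L,
                                  counts = NULL)
split_node <- function(attribute, threshold, left, right) {
  list(type = "split", attribute = attribute, threshold = threshold,
       n = 0L, counts = NULL, left = left, right = right)
}

hand_tree <- function(root, target, attributes, classes) {
  structure(list(root = root, target = target, attributes = attributes,
                 classes = classes, control = NULL, n = 0L),
            class = "xla_tree")
}

#' Source decision tree of the disease-course knowledge base
#'
#' The seven-leaf tree over IgM percent, onset age, IgG percent and IgA
#' percent whose paths are the seven disease-course rules: IgM undetectable
#' with early onset concludes very severe when IgG is also undetectable and
#' severe otherwise; IgM undetectable with late onset is severe; detectable
#' IgM with early onset follows the IgA bands (low: severe, middle: less
#' severe, high: severe); detectable IgM with late onset is less severe.
#'
#' @param catalog A \code{\link{threshold_catalog}}.
#' @return An \code{xla_tree} (leaves carry labels only, no training
#'   counts).
#' @export
kb1_course_tree <- function(catalog = threshold_catalog()) {
  u <- catalog$undetectable_pct_max
  e <- catalog$onset_early_max
  root <- split_node("igm_pct", u,
    split_node("age_ob", e,
      split_node("igg_pct", u,
        leaf_node("very severe"),
        leaf_node("severe")),
      leaf_node("severe")),
    split_node("age_ob", e,
      split_node("iga_pct", catalog$iga_low_max,
        leaf_node("severe"),
        split_node("iga_pct", catalog$iga_mid_max,
          leaf_node("less severe"),
          leaf_node("severe"))),
      leaf_node("less severe")))
  hand_tree(root, "course", c("igm_pct", "age_ob", "igg_pct", "iga_pct"),
            course_labels())
}

#' Source decision tree of the immunoglobulin mutation knowledge base
#'
#' Reconstruction of the mutation-severity tree over the immunoglobulin
#' percents: undetectable IgM concludes a severe mutation outright;
#' otherwise detectable IgG concludes less severe; otherwise reduced IgA
#' concludes severe; otherwise high IgM (at or above the catalog's
#' \code{igm_high_min}) concludes severe and moderate IgM less severe. The
#' final split is a reconstruction, not a transcription — the source
#' figure's threshold is not printed.
#'
#' @inheritParams kb1_course_tree
#' @return An \code{xla_tree}.
#' @export
kb2_mutation_tree <- function(catalog = threshold_catalog()) {
  u <- catalog$undetectable_pct_max
  root <- split_node("igm_pct", u,
    leaf_node("severe"),
    split_node("igg_pct", u,
      split_node("iga_pct", catalog$iga_low_max,
        leaf_node("severe"),
        split_node("igm_pct", catalog$igm_high_min,
          leaf_node("less severe"),
          leaf_node("severe"))),
      leaf_node("less severe")))
  hand_tree(root, "mutation_severity", c("igm_pct", "igg_pct", "iga_pct"),
            mutation_labels())
}

kb_names <- c("kb1_course_ig", "kb2_mutation_ig", "kb3_course_btk",
              "kb4_course_combined", "kb5_mutation_btk",
              "kb6_mutation_history")

#' Load a named severity knowledge base
#'
#' \code{kb1_course_ig} and \code{kb2_mutation_ig} are compiled from their
#' source trees (\code{\link{kb1_course_tree}},
#' \code{\link{kb2_mutation_tree}}) and are mutually exclusive and
#' exhaustive. \code{kb3}–\code{kb6} are partial rule sets transcribed from
#' prose descriptions of the remaining models (Btk expression and B-cell
#' level for disease course; combined mutation/onset/history; Btk for
#' mutation; past-disease history for mutation); they are flagged
#' non-exhaustive and inference outside their coverage concludes
#' \code{NA}.
#'
#' @param name One of \code{"kb1_course_ig"}, \code{"kb2_mutation_ig"},
#'   \code{"kb3_course_btk"}, \code{"kb4_course_combined"},
#'   \code{"kb5_mutation_btk"}, \code{"kb6_mutation_history"}.
#' @param catalog A \code{\link{threshold_catalog}}.
#' @return An \code{xla_ruleset}.
#' @export
load_kb <- function(name, catalog = threshold_catalog()) {
  if (!name %in% kb_names) {
    stop_config("unknown knowledge base '", name, "'; available: ",
                paste(kb_names, collapse = ", "))
  }
  u <- catalog$undetectable_pct_max
  e <- catalog$onset_early_max
  switch(name,
    kb1_course_ig = compile_rules(kb1_course_tree(catalog), id_prefix = "kb1",
                                  name = name),
    kb2_mutation_ig = compile_rules(kb2_mutation_tree(catalog),
                                    id_prefix = "kb2", name = name),
    kb3_course_btk = rule_set(list(
      rule("kb3-1", list(condition("btk_lib", "lt", catalog$btk_lib_low_max),
                         condition("bcells_pct", "lt", catalog$bcells_absent_max)),
           "severe"),
      rule("kb3-2", list(condition("btk_lib", "ge", catalog$btk_lib_low_max),
                         condition("bcells_pct", "ge", catalog$bcells_absent_max)),
           "less severe")),
      exhaustive = FALSE, mutually_exclusive = TRUE, name = name),
    kb4_course_combined = rule_set(list(
      rule("kb4-1", list(condition("mutation_severity", "eq", "severe"),
                         condition("severe_diseases", "ge", 1),
                         condition("age_ob", "lt", e)),
           "very severe"),
      rule("kb4-2", list(condition("mutation_severity", "eq", "less severe"),
                         condition("age_ob", "ge", e)),
           "less severe")),
      exhaustive = FALSE, mutually_exclusive = TRUE, name = name),
    kb5_mutation_btk = rule_set(list(
      rule("kb5-1", list(condition("btk_lib", "ge", catalog$btk_lib_low_max)),
           "less severe"),
      rule("kb5-2", list(condition("btk_lib", "lt", catalog$btk_lib_low_max),
                         condition("age_ob", "ge", e)),
           "severe"),
      rule("kb5-3", list(condition("btk_lib", "lt", catalog$btk_lib_low_max),
                         condition("bcells_pct", "lt", catalog$bcells_absent_max)),
           "severe")),
      exhaustive = FALSE, mutually_exclusive = FALSE, name = name),
    kb6_mutation_history = rule_set(list(
      rule("kb6-1", list(condition("less_severe_diseases", "ge", 3)),
           "severe"),
      rule("kb6-2", list(condition("less_severe_diseases", "lt", 3),
                         condition("pulmonology", "ge", 2)),
           "severe"),
      rule("kb6-3", list(condition("less_severe_diseases", "lt", 3),
                         condition("pulmonology", "lt", 2),
                         condition("otorhinolaryngology", "lt", 2)),
           "less severe")),
      exhaustive = FALSE, mutually_exclusive = FALSE, name = name))
}

#' Load a bundled verification table
#'
#' The two reference test tables for the immunoglobulin knowledge bases:
#' \code{"table2"} carries the seven disease-course cases, \code{"table3"}
#' the five mutation-severity cases. Inputs are onset age in months and
#' IgM/IgG/IgA percent of norm; \code{expected} is the reference label.
#'
#' @param name \code{"table2"} or \code{"table3"}.
#' @return Data frame of verification cases.
#' @export
verification_cases <- function(name = c("table2", "table3")) {
  name <- match.arg(name)
  file <- if (name == "table2") "table2_course_cases.csv" else
    "table3_mutation_cases.csv"
  read.csv(system.file("extdata", file, package = "xlapipe"),
           stringsAsFactors = FALSE)
}

#' Replay verification cases against a knowledge base
#'
#' Runs forward-chaining inference on each case and compares the conclusion
#' to the expected label. Mismatches are data, not errors: the report lists
#' them with their traces.
#'
#' @param kb An \code{xla_ruleset}.
#' @param cases Data frame with one column per input attribute plus
#'   \code{expected} (and optionally \code{case}).
#' @return An object of class \code{xla_verification}: per-case data frame
#'   (\code{$results}), number of matches (\code{$matches}), case count
#'   (\code{$n}), and traces of mismatching cases (\code{$mismatch_traces}).
#' @export
run_verification <- function(kb, cases) {
  if (nrow(cases) == 0) stop_config("no verification cases supplied")
  inputs <- setdiff(names(cases), c("case", "expected"))
  got <- character(nrow(cases))
  traces <- list()
  for (i in seq_len(nrow(cases))) {
    res <- run_inference(kb, as.list(cases[i, inputs, drop = FALSE]))
    got[i] <- res$conclusion
    if (is.na(res$conclusion) || res$conclusion != cases$expected[i]) {
      traces[[as.character(i)]] <- res$trace
    }
  }
  results <- data.frame(case = cases$case %||% seq_len(nrow(cases)),
                        expected = cases$expected, got = got,
                        pass = !is.na(got) & got == cases$expected)
  structure(list(results = results, matches = sum(results$pass),
                 n = nrow(results), mismatch_traces = traces),
            class = "xla_verification")
}

#' @export
print.xla_verification <- function(x, ...) {
  cat("Verification:", x$matches, "/", x$n, "cases match\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}
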