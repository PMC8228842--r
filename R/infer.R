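# Forward-chaining production system: working memory of attribute facts,
# rule matching with a fixed conflict-resolution strategy (specificity,
# then declaration order), and single-cycle firing — conclusions are
# terminal and do not re-enter working memory.

#' Build a working memory from attribute facts
#'
#' @param ... Named values, e.g. \code{facts(age_ob = 19, igm_pct = 12)};
#'   alternatively a single named list or named vector.
#' @return Named list of class \code{xla_facts}; one fact per attribute.
#' @export
facts <- function(...) {
  args <- list(...)
  unnamed <- is.null(names(args)) || identical(names(args)[1], "")
  if (length(args) == 1 && unnamed &&
      (is.list(args[[1]]) || !is.null(names(args[[1]])))) {
    args <- as.list(args[[1]])
  }
  if (is.null(names(args)) || any(names(args) == "")) {
    stop_config("every fact must be named")
  }
  if (anyDuplicated(names(args))) {
    stop_config("duplicate facts for attribute: ",
                names(args)[duplicated(names(args))][1])
  }
  structure(args, class = "xla_facts")
}

#' Validate raw user inputs into numeric facts
#'
#' Mirrors the data-entry contract of a clinical questionnaire front end:
#' every entered value must be numeric and non-negative, and must fall in
#' the plausible range declared for its attribute.
#'
#' @param values Named character or numeric vector/list of raw inputs.
#' @param schema Named list attribute -> \code{c(low, high)} admissible
#'   range; attributes absent from the schema only get the numeric and
#'   non-negativity checks.
#' @return An \code{xla_facts} working memory of numeric values.
#' @export
validate_facts <- function(values, schema = default_fact_schema()) {
  out <- list()
  for (nm in names(values)) {
    v <- suppressWarnings(as.numeric(values[[nm]]))
    if (is.na(v)) stop_config("'", nm, "': value '", values[[nm]],
                              "' is not numeric")
    if (v < 0) stop_config("'", nm, "': value must be non-negative")
    rng <- schema[[nm]]
    if (!is.null(rng) && (v < rng[1] || v > rng[2])) {
      stop_config("'", nm, "': value ", v, " outside admissible range [",
                  rng[1], ", ", rng[2], "]")
    }
    out[[nm]] <- v
  }
  facts(out)
}

#' Default admissible ranges for user-entered facts
#' @return Named list attribute -> \code{c(low, high)}.
#' @export
default_fact_schema <- function() {
  list(age_ob = c(0, 1200), age_dg = c(0, 1200),
       igg_pct = c(0, 1000), igm_pct = c(0, 1000), iga_pct = c(0, 1000),
       bcells_pct = c(0, 1000), btk_lib = c(0, 100),
       btk_monocytes = c(0, 100))
}

#' Match rules against a working memory
#'
#' Returns the agenda: every rule whose conditions all hold, ordered by the
#' conflict-resolution strategy — more specific rules (more conditions)
#' first, ties by declaration order. The working memory must carry a fact
#' for every attribute the rule set references.
#'
#' @param ruleset An \code{xla_ruleset}.
#' @param wm An \code{xla_facts} working memory.
#' @return Character vector of rule ids in firing order.
#' @export
match_rules <- function(ruleset, wm) {
  attrs <- ruleset_attribute_names(ruleset$rules)
  referenced <- c(attrs$numeric, attrs$categorical)
  missing <- setdiff(referenced, names(wm))
  if (length(missing)) {
    stop_config("working memory is missing facts for: ",
                paste(missing, collapse = ", "))
  }
  sat <- vapply(ruleset$rules, function(r) {
    all(vapply(r$conditions,
               function(cn) isTRUE(condition_holds(cn, wm[[cn$attribute]])),
               logical(1)))
  }, logical(1))
  idx <- which(sat)
  nc <- vapply(ruleset$rules, function(r) length(r$conditions), integer(1))
  idx <- idx[order(-nc[idx], idx)]
  vapply(ruleset$rules[idx], `[[`, character(1), "id")
}

#' Run one forward-chaining inference cycle
#'
#' Builds the agenda with \code{\link{match_rules}} and fires its top rule;
#' the rule's conclusion is the result. Conclusions are terminal (the rule
#' sets here are one level deep), so exactly one rule fires; for a compiled
#' — mutually exclusive and exhaustive — rule set the agenda has exactly
#' one entry and the conclusion is deterministic. An empty agenda yields
#' conclusion \code{NA} with a full diagnostic trace.
#'
#' @param ruleset An \code{xla_ruleset}.
#' @param wm An \code{xla_facts} working memory (or anything
#'   \code{\link{facts}} accepts).
#' @return An object of class \code{xla_inference}: \code{conclusion}
#'   (label or \code{NA}), \code{fired} (ids), \code{agenda}, and
#'   \code{trace} (data frame of every condition evaluation).
#' @export
run_inference <- function(ruleset, wm) {
  if (!inherits(wm, "xla_facts")) wm <- facts(wm)
  agenda <- match_rules(ruleset, wm)
  trace <- do.call(rbind, lapply(ruleset$rules, function(r) {
    if (length(r$conditions) == 0) {
      return(data.frame(rule_id = r$id, condition = "TRUE",
                        value = NA_character_, satisfied = TRUE))
    }
    data.frame(
      rule_id = r$id,
      condition = vapply(r$conditions, format_condition, character(1)),
      value = vapply(r$conditions,
                     function(cn) as.character(wm[[cn$attribute]]),
                     character(1)),
      satisfied = vapply(r$conditions,
                         function(cn) isTRUE(condition_holds(cn, wm[[cn$attribute]])),
                         logical(1)))
  }))
  fired <- if (length(agenda)) agenda[1] else character(0)
  conclusion <- if (length(fired)) {
    ids <- vapply(ruleset$rules, `[[`, character(1), "id")
    ruleset$rules[[which(ids == fired)]]$conclusion
  } else NA_character_
  structure(list(conclusion = conclusion, fired = fired, agenda = agenda,
                 trace = trace),
            class = "xla_inference")
}

#' Batch forward-chaining inference over a table of records
#'
#' Vectorized equivalent of calling \code{\link{run_inference}} on every
#' row: each record's conclusion is the top-agenda rule's conclusion under
#' the same conflict-resolution strategy (specificity, then declaration
#' order), \code{NA} where no rule matches.
#'
#' @param ruleset An \code{xla_ruleset}.
#' @param table Data frame with one column per referenced attribute.
#' @return Character vector of conclusions, one per row.
#' @export
apply_ruleset <- function(ruleset, table) {
  attrs <- ruleset_attribute_names(ruleset$rules)
  referenced <- c(attrs$numeric, attrs$categorical)
  missing <- setdiff(referenced, names(table))
  if (length(missing)) {
    stop_config("table is missing attributes: ", paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  nc <- vapply(ruleset$rules, function(r) length(r$conditions), integer(1))
  order_idx <- order(-nc, seq_along(ruleset$rules))
  out <- rep(NA_character_, n)
  open <- rep(TRUE, n)
  for (i in order_idx) {
    if (!any(open)) break
    r <- ruleset$rules[[i]]
    sat <- rep(TRUE, n)
    for (cn in r$conditions) {
      sat <- sat & condition_holds(cn, table[[cn$attribute]])
    }
    hit <- open & sat
    out[hit] <- r$conclusion
    open <- open & !hit
  }
  out
}

#' @export
print.xla_inference <- function(x, ...) {
  cat("Conclusion:", if (is.na(x$conclusion)) "none (no rule matched)"
      else x$conclusion, "\n")
  if (length(x$fired)) cat("Fired:", x$fired, "\n")
  invisible(x)
}
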