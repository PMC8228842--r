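# Production rules: conditions, rule sets, tree-to-rule compilation,
# interval-arithmetic validation of exhaustiveness / mutual exclusivity,
# and serialization to JSON (canonical) and a CLIPS-style defrule dialect.
#
# Numeric conditions use the same boundary convention as the trees:
# `lt` is strict, `ge` is inclusive, and `in` denotes the half-open
# interval [low, high). A record exactly at a split threshold therefore
# satisfies the right-branch (`ge`) condition, and compiled rule sets
# cover the whole attribute domain with no gaps or overlaps.

#' Build a single rule condition
#'
#' @param attribute Attribute name.
#' @param op One of \code{"lt"} (\code{value < bound}), \code{"ge"}
#'   (\code{value >= bound}), \code{"in"} (\code{low <= value < high}),
#'   or \code{"eq"} (label equality).
#' @param bound A number for \code{lt}/\code{ge}, a length-2 numeric
#'   \code{c(low, high)} with \code{low < high} for \code{in}, or a label
#'   string for \code{eq}.
#' @return A list of class \code{xla_condition}.
#' @export
condition <- function(attribute, op = c("lt", "ge", "in", "eq"), bound) {
  op <- match.arg(op)
  if (op == "in") {
    if (length(bound) != 2 || !is.numeric(bound) || bound[1] >= bound[2]) {
      stop_config("interval bound must be numeric c(low, high) with low < high")
    }
  } else if (op == "eq") {
    if (!is.character(bound) || length(bound) != 1) {
      stop_config("eq bound must be a single label")
    }
  } else if (!is.numeric(bound) || length(bound) != 1) {
    stop_config("bound must be a single number")
  }
  structure(list(attribute = attribute, op = op, bound = bound),
            class = "xla_condition")
}

condition_holds <- function(cond, value) {
  switch(cond$op,
         lt = value < cond$bound,
         ge = value >= cond$bound,
         "in" = value >= cond$bound[1] & value < cond$bound[2],
         eq = as.character(value) == cond$bound)
}

format_condition <- function(cond) {
  switch(cond$op,
         lt = paste0(cond$attribute, " < ", format(cond$bound)),
         ge = paste0(cond$attribute, " >= ", format(cond$bound)),
         "in" = paste0(cond$attribute, " in [", format(cond$bound[1]), ", ",
                       format(cond$bound[2]), ")"),
         eq = paste0(cond$attribute, " = \"", cond$bound, "\""))
}

#' Build a production rule
#'
#' @param id Rule identifier.
#' @param conditions List of \code{\link{condition}} objects (conjunction);
#'   may be empty for an unconditional rule.
#' @param conclusion Severity label concluded when all conditions hold.
#' @param provenance \code{"tree"} for compiled rules, \code{"manual"}
#'   otherwise.
#' @return A list of class \code{xla_rule}.
#' @export
rule <- function(id, conditions, conclusion, provenance = "manual") {
  structure(list(id = id, conditions = conditions, conclusion = conclusion,
                 provenance = provenance),
            class = "xla_rule")
}

#' Build a rule set
#'
#' @param rules Ordered list of \code{\link{rule}} objects.
#' @param domain Named list attribute -> numeric \code{c(low, high)} range
#'   metadata; defaults to \code{c(0, Inf)} for every numeric attribute
#'   referenced.
#' @param exhaustive,mutually_exclusive Flags claiming that every point of
#'   the domain satisfies at least / at most one rule; verify with
#'   \code{\link{check_ruleset}}.
#' @param name Optional rule-set name.
#' @return A list of class \code{xla_ruleset}.
#' @export
rule_set <- function(rules, domain = NULL, exhaustive = NA,
                     mutually_exclusive = NA, name = NULL) {
  attrs <- ruleset_attribute_names(rules)
  if (is.null(domain)) {
    domain <- stats::setNames(rep(list(c(0, Inf)), length(attrs$numeric)),
                              attrs$numeric)
  }
  structure(list(rules = rules, domain = domain, exhaustive = exhaustive,
                 mutually_exclusive = mutually_exclusive, name = name),
            class = "xla_ruleset")
}

ruleset_attribute_names <- function(rules) {
  num <- character(0)
  cat <- character(0)
  for (r in rules) for (cn in r$conditions) {
    if (cn$op == "eq") cat <- union(cat, cn$attribute)
    else num <- union(num, cn$attribute)
  }
  list(numeric = num, categorical = cat)
}

#' @export
print.xla_ruleset <- function(x, ...) {
  cat("Rule set", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", length(x$rules), "rules\n")
  for (r in x$rules) {
    lhs <- if (length(r$conditions)) {
      paste(vapply(r$conditions, format_condition, character(1)),
            collapse = " AND ")
    } else "TRUE"
    cat("  [", r$id, "] IF ", lhs, " THEN ", r$conclusion, "\n", sep = "")
  }
  invisible(x)
}

# --- compilation -----------------------------------------------------------

#' Compile a decision tree into an ordered production-rule set
#'
#' One rule per root-to-leaf path, taken left to right. Conditions on the
#' same attribute along a path are merged into a single bound or half-open
#' interval, so each rule carries at most one condition per attribute. The
#' resulting set covers the attribute domain exactly once (mutually
#' exclusive and exhaustive by construction; see
#' \code{\link{check_ruleset}} for the constructive verification).
#'
#' @param tree An \code{xla_tree}.
#' @param id_prefix Prefix for rule ids (default \code{"rule"}).
#' @param domain Optional named domain ranges for the metadata slot.
#' @param name Optional rule-set name.
#' @return An \code{xla_ruleset} with one rule per leaf.
#' @export
compile_rules <- function(tree, id_prefix = "rule", domain = NULL,
                          name = NULL) {
  leaves <- list()
  walk <- function(node, lo, hi, order) {
    if (node$type == "leaf") {
      conds <- list()
      for (a in order) {
        l <- lo[[a]]
        h <- hi[[a]]
        conds[[length(conds) + 1]] <-
          if (is.finite(l) && is.finite(h)) condition(a, "in", c(l, h))
          else if (is.finite(h)) condition(a, "lt", h)
          else condition(a, "ge", l)
      }
      leaves[[length(leaves) + 1]] <<- list(conds = conds,
                                            conclusion = node$label)
      return(invisible())
    }
    a <- node$attribute
    if (!a %in% order) order <- c(order, a)
    hi_l <- hi; hi_l[[a]] <- min(hi[[a]] %||% Inf, node$threshold)
    lo_r <- lo; lo_r[[a]] <- max(lo[[a]] %||% -Inf, node$threshold)
    walk(node$left, lo, hi_l, order)
    walk(node$right, lo_r, hi, order)
  }
  empty <- stats::setNames(rep(list(-Inf), length(tree$attributes)),
                           tree$attributes)
  emptyh <- stats::setNames(rep(list(Inf), length(tree$attributes)),
                            tree$attributes)
  walk(tree$root, empty, emptyh, character(0))
  rules <- lapply(seq_along(leaves), function(i) {
    rule(paste0(id_prefix, "-", i), leaves[[i]]$conds,
         leaves[[i]]$conclusion, provenance = "tree")
  })
  rule_set(rules, domain = domain, exhaustive = TRUE,
           mutually_exclusive = TRUE, name = name)
}

# --- interval-arithmetic validation ---------------------------------------

# Representative test points for one numeric attribute: every finite bound
# appearing in the rule set, midpoints between consecutive bounds, and one
# point on each open side — enough to realize every satisfiability pattern
# of half-open interval conditions.
attribute_test_points <- function(rules, attribute, domain = c(0, Inf)) {
  bs <- numeric(0)
  for (r in rules) for (cn in r$conditions) {
    if (cn$attribute == attribute && cn$op != "eq") bs <- c(bs, cn$bound)
  }
  bs <- sort(unique(bs[is.finite(bs)]))
  bs <- bs[bs >= domain[1] & (bs <= domain[2])]
  lo <- domain[1]
  hi <- if (is.finite(domain[2])) domain[2] else max(c(bs, lo)) + 1
  pts <- c(bs, lo, hi)
  if (length(bs)) pts <- c(pts, (c(lo, bs) + c(bs, hi)) / 2)
  sort(unique(pts[pts >= domain[1] & (!is.finite(domain[2]) | pts <= domain[2])]))
}

#' Verify exhaustiveness and mutual exclusivity of a rule set
#'
#' Constructive check by interval arithmetic: for every attribute the
#' bounds appearing in the rule set cut the domain into finitely many
#' cells; one representative point per cell (plus every boundary point) is
#' enumerated on a full grid and the number of satisfied rules is counted
#' at each grid point.
#'
#' @param ruleset An \code{xla_ruleset}.
#' @return List with logical \code{exhaustive} (every grid point satisfies
#'   at least one rule), \code{mutually_exclusive} (at most one), and the
#'   grid size \code{n_points}.
#' @export
check_ruleset <- function(ruleset) {
  attrs <- ruleset_attribute_names(ruleset$rules)
  pts <- list()
  for (a in attrs$numeric) {
    pts[[a]] <- attribute_test_points(ruleset$rules, a,
                                      ruleset$domain[[a]] %||% c(0, Inf))
  }
  for (a in attrs$categorical) {
    vals <- character(0)
    for (r in ruleset$rules) for (cn in r$conditions) {
      if (cn$attribute == a && cn$op == "eq") vals <- union(vals, cn$bound)
    }
    pts[[a]] <- vals
  }
  if (length(pts) == 0) {
    k <- length(ruleset$rules)
    return(list(exhaustive = k >= 1, mutually_exclusive = k <= 1,
                n_points = 1L))
  }
  grid <- expand.grid(pts, stringsAsFactors = FALSE)
  hits <- rep(0L, nrow(grid))
  for (r in ruleset$rules) {
    sat <- rep(TRUE, nrow(grid))
    for (cn in r$conditions) {
      sat <- sat & condition_holds(cn, grid[[cn$attribute]])
    }
    hits <- hits + as.integer(sat)
  }
  list(exhaustive = all(hits >= 1), mutually_exclusive = all(hits <= 1),
       n_points = nrow(grid))
}

# --- serialization ---------------------------------------------------------

#' Serialize a rule set to JSON or CLIPS-style text
#'
#' The JSON dialect is canonical and round-trips losslessly through
#' \code{\link{parse_rules}}. The CLIPS dialect emits one
#' \code{(defrule ...)} block per rule with one fact pattern plus test per
#' condition and an asserted \code{(conclusion "...")}; only this subset is
#' parsed back.
#'
#' @param ruleset An \code{xla_ruleset}.
#' @param dialect \code{"json"} or \code{"clips"}.
#' @return A single string.
#' @export
serialize_rules <- function(ruleset, dialect = c("json", "clips")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    rules <- lapply(ruleset$rules, function(r) {
      list(id = r$id,
           conditions = lapply(r$conditions, function(cn) {
             list(attribute = cn$attribute, op = cn$op,
                  bound = if (cn$op == "eq") cn$bound else as.numeric(cn$bound))
           }),
           conclusion = r$conclusion,
           provenance = r$provenance)
    })
    return(as.character(jsonlite::toJSON(
      list(name = ruleset$name, domain = ruleset$domain,
           exhaustive = ruleset$exhaustive,
           mutually_exclusive = ruleset$mutually_exclusive,
           rules = rules),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")))
  }
  blocks <- vapply(ruleset$rules, function(r) {
    lines <- character(0)
    for (i in seq_along(r$conditions)) {
      cn <- r$conditions[[i]]
      v <- paste0("?v", i)
      lines <- c(lines, switch(
        cn$op,
        lt = paste0("  (", cn$attribute, " ", v, ") (test (< ", v, " ",
                    format(cn$bound, digits = 15), "))"),
        ge = paste0("  (", cn$attribute, " ", v, ") (test (>= ", v, " ",
                    format(cn$bound, digits = 15), "))"),
        "in" = paste0("  (", cn$attribute, " ", v, ") (test (and (>= ", v,
                      " ", format(cn$bound[1], digits = 15), ") (< ", v, " ",
                      format(cn$bound[2], digits = 15), ")))"),
        eq = paste0("  (", cn$attribute, " \"", cn$bound, "\")")))
    }
    paste0("(defrule ", r$id, "\n",
           paste(lines, collapse = "\n"),
           if (length(lines)) "\n" else "",
           "  =>\n  (assert (conclusion \"", r$conclusion, "\")))")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), if (length(blocks)) "\n" else "")
}

#' Parse a serialized rule set
#'
#' Inverse of \code{\link{serialize_rules}} on its own output. Malformed
#' documents (including intervals with \code{low >= high}) raise an error;
#' for the CLIPS dialect the error names the offending line.
#'
#' @param text Serialized rule-set text.
#' @param dialect \code{"json"} or \code{"clips"}.
#' @return An \code{xla_ruleset}.
#' @export
parse_rules <- function(text, dialect = c("json", "clips")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    rules <- lapply(doc$rules, function(r) {
      conds <- lapply(r$conditions, function(cn) {
        condition(cn$attribute, cn$op,
                  if (cn$op == "eq") cn$bound else as.numeric(unlist(cn$bound)))
      })
      rule(r$id, conds, r$conclusion, r$provenance %||% "manual")
    })
    domain <- lapply(doc$domain, function(d) as.numeric(unlist(d)))
    return(rule_set(rules, domain = domain,
                    exhaustive = doc$exhaustive %||% NA,
                    mutually_exclusive = doc$mutually_exclusive %||% NA,
                    name = doc$name))
  }
  parse_clips(text)
}

parse_clips <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rules <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1; next }
    m <- regmatches(ln, regexec("^\\(defrule ([^ )]+)$", ln))[[1]]
    if (length(m) == 0) stop_config("CLIPS parse error at line ", i, ": ", ln)
    id <- m[2]
    i <- i + 1
    conds <- list()
    conclusion <- NULL
    while (i <= n) {
      ln <- trimws(lines[i])
      if (ln == "=>") { i <- i + 1; next }
      mc <- regmatches(ln, regexec(
        "^\\(assert \\(conclusion \"(.*)\"\\)\\)\\)$", ln))[[1]]
      if (length(mc)) { conclusion <- mc[2]; i <- i + 1; break }
      mi <- regmatches(ln, regexec(paste0(
        "^\\((\\w+) \\?v\\d+\\) \\(test \\(and \\(>= \\?v\\d+ ([-0-9.eE]+)\\)",
        " \\(< \\?v\\d+ ([-0-9.eE]+)\\)\\)\\)$"), ln))[[1]]
      if (length(mi)) {
        conds[[length(conds) + 1]] <-
          condition(mi[2], "in", c(as.numeric(mi[3]), as.numeric(mi[4])))
        i <- i + 1; next
      }
      ms <- regmatches(ln, regexec(
        "^\\((\\w+) \\?v\\d+\\) \\(test \\((<|>=) \\?v\\d+ ([-0-9.eE]+)\\)\\)$",
        ln))[[1]]
      if (length(ms)) {
        conds[[length(conds) + 1]] <-
          condition(ms[2], if (ms[3] == "<") "lt" else "ge", as.numeric(ms[4]))
        i <- i + 1; next
      }
      me <- regmatches(ln, regexec("^\\((\\w+) \"(.*)\"\\)$", ln))[[1]]
      if (length(me)) {
        conds[[length(conds) + 1]] <- condition(me[2], "eq", me[3])
        i <- i + 1; next
      }
      stop_config("CLIPS parse error at line ", i, ": ", ln)
    }
    if (is.null(conclusion)) {
      stop_config("CLIPS parse error: rule '", id, "' has no conclusion")
    }
    rules[[length(rules) + 1]] <- rule(id, conds, conclusion,
                                       provenance = "manual")
  }
  rule_set(rules)
}
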