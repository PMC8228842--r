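# Shared test helpers: independent brute-force oracles and small random
# fixtures. The oracles deliberately re-derive everything from first
# principles (table() counts, explicit loops) so they share no code with
# the implementation they check.

# Naive exhaustive split search: every attribute, every midpoint between
# consecutive distinct sorted values, Gini computed from explicit class
# proportions. Ties: first attribute in `attributes`, then lowest
# threshold.
oracle_best_split <- function(data, target, attributes) {
  y <- as.character(data[[target]])
  n <- length(y)
  gini <- function(labels) {
    p <- table(labels) / length(labels)
    1 - sum(p^2)
  }
  parent <- gini(y)
  best <- NULL
  for (a in attributes) {
    x <- data[[a]]
    vs <- sort(unique(x))
    if (length(vs) < 2) next
    for (i in seq_len(length(vs) - 1)) {
      thr <- (vs[i] + vs[i + 1]) / 2
      left <- x < thr
      gain <- parent - sum(left) / n * gini(y[left]) -
        sum(!left) / n * gini(y[!left])
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(attribute = a, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# Random classification table.
random_table <- function(n, p = 3, k = 2, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(lapply(seq_len(p), function(i) round(runif(n, 0, 10), 2)))
  names(df) <- paste0("x", seq_len(p))
  df$y <- sample(letters[seq_len(k)], n, replace = TRUE)
  df
}

# Conclusions of the disease-course knowledge base for every row of a
# processed table.
kb1_conclusions <- function(processed, catalog = threshold_catalog()) {
  apply_ruleset(load_kb("kb1_course_ig", catalog),
                processed[, c("age_ob", "igm_pct", "igg_pct", "iga_pct")])
}

# Exhaustive grid of test records over the bounds appearing in a compiled
# rule set (every bound, midpoints between consecutive bounds, one point
# beyond each side), plus n_random random records over the attribute
# domains.
equivalence_records <- function(ruleset, n_random = 10000, seed = 1) {
  attrs <- character(0)
  bounds <- list()
  for (r in ruleset$rules) for (cn in r$conditions) {
    a <- cn$attribute
    attrs <- union(attrs, a)
    bounds[[a]] <- c(bounds[[a]], unlist(cn$bound))
  }
  pts <- lapply(bounds, function(b) {
    b <- sort(unique(b[is.finite(b)]))
    lo <- min(b) - 1
    hi <- max(b) + 1
    sort(unique(c(b, lo, hi, (c(lo, b) + c(b, hi)) / 2)))
  })
  grid <- expand.grid(pts)
  set.seed(seed)
  rnd <- as.data.frame(lapply(bounds, function(b) {
    hi <- max(b[is.finite(b)], 1) * 2
    runif(n_random, 0, hi)
  }))
  rbind(grid, rnd[, names(grid), drop = FALSE])
}

# Small helper: grown tree and compiled rules must agree everywhere.
expect_tree_rules_equivalent <- function(tree, n_random = 10000, seed = 1) {
  rules <- compile_rules(tree)
  recs <- equivalence_records(rules, n_random = n_random, seed = seed)
  missing <- setdiff(tree$attributes, names(recs))
  for (a in missing) recs[[a]] <- 1  # attribute unused by any split
  expect_identical(as.character(predict(tree, recs)),
                   apply_ruleset(rules, recs))
}
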