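# Random forest of CART trees, used for attribute-importance ranking by
# mean decrease in Gini. Trees are grown on bootstrap resamples with
# mtry-subsampled candidate attributes per split.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Attributes sampled per split; default
#'   \code{floor(sqrt(p))} at build time.
#' @param seed Integer RNG seed.
#' @param bootstrap Grow each tree on a bootstrap resample (default
#'   \code{TRUE}); with \code{FALSE} every tree sees the full table.
#' @return A list of class \code{xla_forest_config}.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, seed = 1,
                          bootstrap = TRUE) {
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap)),
            class = "xla_forest_config")
}

#' Build a random forest of CART trees
#'
#' @param data Data frame (non-empty).
#' @param target Label column name.
#' @param attributes Candidate attribute names.
#' @param config A \code{\link{forest_config}}.
#' @param control Per-tree \code{\link{split_control}}; the default imposes
#'   no practical depth limit so trees grow to purity like classification
#'   forests usually do.
#' @return An object of class \code{xla_forest}: trees plus the bootstrap
#'   index sets (for out-of-bag evaluation).
#' @export
build_forest <- function(data, target, attributes, config = forest_config(),
                         control = split_control(minsplit = 2, maxdepth = 30)) {
  if (nrow(data) == 0) stop_config("cannot build a forest on an empty table")
  p <- length(attributes)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  if (mtry > p) stop_config("mtry exceeds the number of attributes")
  set.seed(config$seed)
  n <- nrow(data)
  trees <- vector("list", config$n_trees)
  inbag <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    idx <- if (config$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[t]] <- grow_tree(data[idx, , drop = FALSE], target, attributes,
                            control = control,
                            mtry = if (mtry < p) mtry else NULL)
    inbag[[t]] <- idx
  }
  structure(list(trees = trees, inbag = inbag, target = target,
                 attributes = attributes, config = config, n = n,
                 classes = trees[[1]]$classes),
            class = "xla_forest")
}

#' Majority-vote prediction from a forest
#'
#' @param object An \code{xla_forest}.
#' @param newdata Data frame of records.
#' @param ... Unused.
#' @return Factor of predicted labels (ties broken by class order).
#' @export
predict.xla_forest <- function(object, newdata, ...) {
  votes <- vapply(object$trees,
                  function(tr) as.character(predict(tr, newdata)),
                  character(nrow(newdata)))
  if (nrow(newdata) == 1) votes <- matrix(votes, nrow = 1)
  lab <- apply(votes, 1, function(v) {
    tab <- vapply(object$classes, function(cl) sum(v == cl), integer(1))
    object$classes[which.max(tab)]
  })
  factor(lab, levels = object$classes)
}

#' Out-of-bag accuracy of a forest
#'
#' @param forest An \code{xla_forest} built with bootstrapping.
#' @param data The table the forest was built on.
#' @return Fraction of rows correctly classified by the majority vote of
#'   trees whose bootstrap sample excluded the row.
#' @export
oob_accuracy <- function(forest, data) {
  n <- nrow(data)
  classes <- forest$classes
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  for (t in seq_along(forest$trees)) {
    out <- setdiff(seq_len(n), forest$inbag[[t]])
    if (length(out) == 0) next
    pred <- as.character(predict(forest$trees[[t]], data[out, , drop = FALSE]))
    for (i in seq_along(out)) {
      votes[out[i], pred[i]] <- votes[out[i], pred[i]] + 1L
    }
  }
  covered <- rowSums(votes) > 0
  pred <- classes[apply(votes[covered, , drop = FALSE], 1, which.max)]
  mean(pred == as.character(data[[forest$target]])[covered])
}

# Accumulate per-attribute weighted Gini decreases of one tree.
tree_importance <- function(tree) {
  acc <- stats::setNames(numeric(length(tree$attributes)), tree$attributes)
  walk <- function(node, total) {
    if (node$type == "leaf") return(invisible())
    g <- gini_impurity(node$counts)
    gl <- gini_impurity(node$left$counts)
    gr <- gini_impurity(node$right$counts)
    dec <- (node$n / total) *
      (g - (node$left$n / node$n) * gl - (node$right$n / node$n) * gr)
    acc[node$attribute] <<- acc[node$attribute] + dec
    walk(node$left, total)
    walk(node$right, total)
  }
  walk(tree$root, tree$root$n)
  acc
}

#' Mean-decrease-Gini attribute importance
#'
#' For every attribute, the weighted impurity decrease
#' \code{(n_node/N) * [G(node) - (nL/n) G(left) - (nR/n) G(right)]}
#' is summed over all splits using that attribute and averaged over trees.
#' Attributes never used score exactly 0.
#'
#' @param forest An \code{xla_forest} (a single \code{xla_tree} is also
#'   accepted).
#' @return Named numeric vector of non-negative importances, one entry per
#'   candidate attribute.
#' @export
gini_importance <- function(forest) {
  if (inherits(forest, "xla_tree")) return(tree_importance(forest))
  if (length(forest$trees) == 0) stop_config("empty forest")
  acc <- Reduce(`+`, lapply(forest$trees, tree_importance))
  acc / length(forest$trees)
}

#' Attribute-importance report for both severity targets
#'
#' Builds one forest per target on the processed table and tabulates
#' mean-decrease-Gini scores side by side (disease course and mutation
#' severity), the shape of a two-target importance table. Exact scores on
#' synthetic cohorts are not comparable to any published registry values —
#' only rank-order properties are meaningful.
#'
#' @param processed Processed cohort table.
#' @param attributes Candidate attributes; default: all 16 predictors, with
#'   mutation severity 0/1-encoded as a predictor for the course target.
#' @param config A \code{\link{forest_config}}.
#' @return Data frame with columns \code{attribute},
#'   \code{gini_course}, \code{gini_mutation}.
#' @export
importance_report <- function(processed, attributes = NULL,
                              config = forest_config()) {
  df <- processed
  df$mutation_num <- as.integer(df$mutation_severity == "severe")
  base <- attributes %||% setdiff(processed_columns(),
                                  c("mutation_severity", "course"))
  f1 <- build_forest(df, "course", c(base, "mutation_num"), config = config)
  imp1 <- gini_importance(f1)
  f2 <- build_forest(df, "mutation_severity", base, config = config)
  imp2 <- gini_importance(f2)
  data.frame(attribute = c(base, "mutation_num"),
             gini_course = as.numeric(imp1[c(base, "mutation_num")]),
             gini_mutation = c(as.numeric(imp2[base]), NA))
}
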