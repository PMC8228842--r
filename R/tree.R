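# CART classification trees: Gini impurity, exhaustive threshold search,
# recursive growth under minsplit/maxdepth control, prediction, accuracy,
# and stratified train/test partitioning.
#
# Conventions (fixed so output is deterministic):
#   * split rule is `attribute < threshold` -> left; a record exactly at the
#     threshold descends right;
#   * candidate thresholds are midpoints between consecutive distinct
#     sorted values;
#   * split ties break by candidate-attribute order, then lower threshold;
#   * leaf-label ties break by class-level order.

#' Split-control parameters for tree growth
#'
#' @param minsplit Minimum number of observations a node must contain for a
#'   split to be attempted (default 8).
#' @param maxdepth Maximum tree depth, root at depth 0 (default 5).
#' @return A list of class \code{xla_control}.
#' @export
split_control <- function(minsplit = 8, maxdepth = 5) {
  if (minsplit < 2) stop_config("minsplit must be >= 2")
  if (maxdepth < 1) stop_config("maxdepth must be >= 1")
  structure(list(minsplit = as.integer(minsplit),
                 maxdepth = as.integer(maxdepth)),
            class = "xla_control")
}

#' Gini impurity of a class-count vector
#'
#' @param class_counts Non-negative counts per class (named or not).
#' @return \code{1 - sum((n_k / N)^2)}; 0 for a pure node, at most
#'   \code{1 - 1/K} for K classes.
#' @examples
#' gini_impurity(c(a = 5, b = 5))  # 0.5
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop_config("class counts must be non-negative")
  n <- sum(class_counts)
  if (n == 0) stop_config("total count must be positive")
  1 - sum((class_counts / n)^2)
}

# Gini of rows of a count matrix (0 rows allowed). Internal, vectorized.
gini_rows <- function(m, n) {
  1 - rowSums((m / n)^2)
}

#' Best single split of a table by weighted Gini decrease
#'
#' Exhaustive search over every candidate attribute and every midpoint
#' between consecutive distinct sorted values, maximizing the weighted
#' impurity decrease
#' \code{G(parent) - (nL/n) G(left) - (nR/n) G(right)}.
#'
#' @param data Data frame of observations.
#' @param target Name of the label column.
#' @param attributes Candidate attribute names (numeric columns).
#' @param mtry If non-\code{NULL}, number of attributes sampled (without
#'   replacement) as candidates — used by the random forest.
#' @return \code{list(attribute, threshold, gain)}, or \code{NULL} when no
#'   split has positive gain.
#' @export
best_split <- function(data, target, attributes, mtry = NULL) {
  if (length(attributes) == 0) stop_config("no candidate attributes")
  y <- data[[target]]
  if (is.null(y)) stop_config("target column '", target, "' not in table")
  y <- factor(y, levels = canonical_classes(y))
  n <- length(y)
  k <- nlevels(y)
  if (!is.null(mtry) && mtry < length(attributes)) {
    keep <- sort(sample.int(length(attributes), mtry))
    attributes <- attributes[keep]
  }
  parent <- tabulate(y, k)
  g_parent <- gini_impurity(parent)
  tol <- 1e-12
  best <- NULL
  yi <- as.integer(y)
  for (a in attributes) {
    x <- data[[a]]
    if (is.null(x)) stop_config("attribute '", a, "' not in table")
    if (!is.numeric(x)) stop_config("attribute '", a, "' is not numeric")
    ord <- order(x)
    xs <- x[ord]
    ys <- yi[ord]
    pos <- which(diff(xs) > 0)
    if (length(pos) == 0) next
    cum <- vapply(seq_len(k), function(cl) cumsum(ys == cl), numeric(n))
    left <- cum[pos, , drop = FALSE]
    nl <- pos
    nr <- n - pos
    right <- matrix(parent, length(pos), k, byrow = TRUE) - left
    gain <- g_parent - (nl / n) * gini_rows(left, nl) -
      (nr / n) * gini_rows(right, nr)
    gmax <- max(gain)
    if (gmax <= tol) next
    i <- which(gain >= gmax - tol)[1]          # lowest threshold among ties
    if (is.null(best) || gain[i] > best$gain + tol) {
      p <- pos[i]
      best <- list(attribute = a,
                   threshold = (xs[p] + xs[p + 1]) / 2,
                   gain = gain[i])
    }
  }
  best
}

new_leaf <- function(counts, classes) {
  m <- max(counts)
  list(type = "leaf",
       label = classes[which(counts == m)[1]],
       n = sum(counts),
       counts = stats::setNames(as.integer(counts), classes))
}

grow_node <- function(data, target, attributes, control, classes, depth, mtry) {
  y <- factor(data[[target]], levels = classes)
  counts <- tabulate(y, length(classes))
  n <- nrow(data)
  if (depth >= control$maxdepth || n < control$minsplit ||
      sum(counts > 0) <= 1) {
    return(new_leaf(counts, classes))
  }
  sp <- best_split(data, target, attributes, mtry = mtry)
  if (is.null(sp)) return(new_leaf(counts, classes))
  go_left <- data[[sp$attribute]] < sp$threshold
  list(type = "split",
       attribute = sp$attribute,
       threshold = sp$threshold,
       gain = sp$gain,
       n = n,
       counts = stats::setNames(as.integer(counts), classes),
       left = grow_node(data[go_left, , drop = FALSE], target, attributes,
                        control, classes, depth + 1, mtry),
       right = grow_node(data[!go_left, , drop = FALSE], target, attributes,
                         control, classes, depth + 1, mtry))
}

#' Grow a CART classification tree
#'
#' Recursive binary splitting by \code{\link{best_split}} until a node is
#' pure, smaller than \code{minsplit}, at \code{maxdepth}, or admits no
#' positive-gain split. Leaves are labelled by majority class, ties broken
#' by class-level order.
#'
#' @inheritParams best_split
#' @param control A \code{\link{split_control}} object.
#' @param mtry Attributes sampled per split (forest use); \code{NULL} for
#'   all.
#' @return An object of class \code{xla_tree}.
#' @export
grow_tree <- function(data, target, attributes, control = split_control(),
                      mtry = NULL) {
  if (nrow(data) == 0) stop_config("cannot grow a tree on an empty table")
  missing <- setdiff(c(target, attributes), names(data))
  if (length(missing)) {
    stop_config("columns absent from table: ", paste(missing, collapse = ", "))
  }
  classes <- canonical_classes(data[[target]])
  structure(list(root = grow_node(data, target, attributes, control, classes,
                                  0L, mtry),
                 target = target,
                 attributes = attributes,
                 classes = classes,
                 control = control,
                 n = nrow(data)),
            class = "xla_tree")
}

descend <- function(node, record) {
  while (node$type == "split") {
    v <- record[[node$attribute]]
    if (is.null(v) || is.na(v)) {
      stop_config("record is missing attribute '", node$attribute, "'")
    }
    node <- if (v < node$threshold) node$left else node$right
  }
  node$label
}

#' Predict class labels with a grown tree
#'
#' @param object An \code{xla_tree}.
#' @param newdata Data frame (or single named list) of records carrying
#'   every attribute the tree references.
#' @param ... Unused.
#' @return Factor of predicted labels with the tree's class levels.
#' @export
predict.xla_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  out <- vapply(seq_len(nrow(newdata)),
                function(i) descend(object$root, newdata[i, , drop = FALSE]),
                character(1))
  factor(out, levels = object$classes)
}

#' Classification accuracy of a tree on a test table
#'
#' @param tree An \code{xla_tree}.
#' @param test Test data frame (non-empty).
#' @param target Label column name.
#' @return Fraction of test rows whose prediction equals the label.
#' @export
accuracy <- function(tree, test, target = tree$target) {
  if (nrow(test) == 0) stop_config("test set is empty")
  mean(as.character(predict(tree, test)) == as.character(test[[target]]))
}

#' Seeded stratified train/test partition
#'
#' Allocates a \code{fraction} share to the training set within every class
#' using largest-remainder rounding (per-class proportions within one
#' observation of the global fraction), with a seeded shuffle inside each
#' class.
#'
#' @param data Data frame.
#' @param target Label column name.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Integer RNG seed.
#' @return An object of class \code{xla_partition} with integer index
#'   vectors \code{$train} and \code{$test}.
#' @export
stratified_partition <- function(data, target, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop_config("fraction must be in (0, 1)")
  y <- as.character(data[[target]])
  classes <- canonical_classes(data[[target]])
  sizes <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(sizes == 0)) {
    stop_config("class with 0 rows: ", paste(classes[sizes == 0], collapse = ", "))
  }
  set.seed(seed)
  total_train <- largest_remainder(round(fraction * nrow(data)), sizes)
  train <- integer(0)
  for (i in seq_along(classes)) {
    idx <- sample(which(y == classes[i]))
    train <- c(train, idx[seq_len(total_train[i])])
  }
  train <- sort(train)
  structure(list(train = train,
                 test = setdiff(seq_len(nrow(data)), train),
                 fraction = fraction, seed = seed),
            class = "xla_partition")
}

#' @export
print.xla_tree <- function(x, ...) {
  cat("CART tree:", x$target, "~", paste(x$attributes, collapse = " + "), "\n")
  cat("n =", x$n, "; classes:", paste(x$classes, collapse = ", "), "\n")
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "* ", node$label, "  (",
          paste(node$counts, collapse = "/"), ")\n", sep = "")
    } else {
      cat(pad, node$attribute, " < ", format(node$threshold), "\n", sep = "")
      show_node(node$left, indent + 1)
      cat(pad, node$attribute, " >= ", format(node$threshold), "\n", sep = "")
      show_node(node$right, indent + 1)
    }
  }
  show_node(x$root, 0)
  invisible(x)
}

# --- JSON serialization of trees (pipeline artifacts) ----------------------

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", label = node$label, n = node$n,
         counts = as.list(node$counts))
  } else {
    list(type = "split", attribute = node$attribute,
         threshold = node$threshold, n = node$n,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

#' Serialize a tree to JSON text, and back
#' @param tree An \code{xla_tree}.
#' @param text JSON produced by \code{tree_to_json}.
#' @return \code{tree_to_json}: a JSON string; \code{tree_from_json}: an
#'   \code{xla_tree}.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(list(target = tree$target, attributes = tree$attributes,
                        classes = tree$classes, n = tree$n,
                        control = unclass(tree$control),
                        root = node_to_list(tree$root)),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

node_from_list <- function(x) {
  if (x$type == "leaf") {
    list(type = "leaf", label = x$label, n = x$n,
         counts = unlist(x$counts))
  } else {
    list(type = "split", attribute = x$attribute, threshold = x$threshold,
         n = x$n, counts = NULL,
         left = node_from_list(x$left), right = node_from_list(x$right))
  }
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ctl <- if (!is.null(x$control)) {
    split_control(x$control$minsplit, x$control$maxdepth)
  }
  structure(list(root = node_from_list(x$root), target = x$target,
                 attributes = unlist(x$attributes),
                 classes = unlist(x$classes), control = ctl, n = x$n),
            class = "xla_tree")
}
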