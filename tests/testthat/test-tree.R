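test_that("Gini impurity matches the direct formula", {
  expect_equal(gini_impurity(c(a = 10)), 0)
  expect_equal(gini_impurity(c(a = 5, b = 5)), 0.5)
  counts <- c(17, 22, 12)
  expect_equal(gini_impurity(counts), 1 - sum((counts / 51)^2))
  expect_error(gini_impurity(c(0, 0)), "positive")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("best_split finds perfect separators and refuses hopeless tables", {
  df <- data.frame(x = c(0, 0, 0, 1, 1, 1), y = c("a", "a", "a", "b", "b", "b"))
  sp <- best_split(df, "y", "x")
  expect_equal(sp$attribute, "x")
  expect_equal(sp$threshold, 0.5)
  expect_equal(sp$gain, gini_impurity(c(3, 3)))

  pure <- data.frame(x = rnorm(5), y = rep("a", 5))
  expect_null(best_split(pure, "y", "x"))
  expect_error(best_split(df, "y", character(0)), "no candidate")
})

test_that("best_split equals the brute-force oracle on random tables", {
  for (s in 1:8) {
    df <- random_table(n = 12, p = 3, k = 3, seed = s)
    got <- best_split(df, "y", c("x1", "x2", "x3"))
    want <- oracle_best_split(df, "y", c("x1", "x2", "x3"))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("tree growth respects purity, depth and minsplit stopping", {
  pure <- data.frame(x = rnorm(6), y = rep("a", 6))
  tr <- grow_tree(pure, "y", "x")
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$label, "a")

  df <- random_table(40, p = 3, k = 3, seed = 4)
  stump <- grow_tree(df, "y", c("x1", "x2", "x3"),
                     split_control(minsplit = 2, maxdepth = 1))
  depth <- function(node) {
    if (node$type == "leaf") 0 else 1 + max(depth(node$left), depth(node$right))
  }
  expect_lte(depth(stump$root), 1)

  # property: random controls never violated; impurity weakly decreases
  for (s in 1:6) {
    ctl <- split_control(minsplit = sample(2:8, 1), maxdepth = sample(1:5, 1))
    tr <- grow_tree(random_table(30, 3, 3, seed = s), "y",
                    c("x1", "x2", "x3"), ctl)
    check <- function(node, d) {
      expect_lte(d, ctl$maxdepth)
      if (node$type == "split") {
        expect_gte(node$n, ctl$minsplit)
        expect_lte(gini_impurity(node$left$counts) *
                     node$left$n / node$n +
                     gini_impurity(node$right$counts) *
                     node$right$n / node$n,
                   gini_impurity(node$counts) + 1e-12)
        check(node$left, d + 1)
        check(node$right, d + 1)
      }
    }
    check(tr$root, 0)
    # leaf counts sum to the training size
    leaf_sum <- function(node) {
      if (node$type == "leaf") sum(node$counts)
      else leaf_sum(node$left) + leaf_sum(node$right)
    }
    expect_equal(leaf_sum(tr$root), 30)
  }
  expect_error(grow_tree(df, "y", "nope"), "absent")
})

test_that("prediction descends deterministically with strict-< boundaries", {
  df <- data.frame(x = c(0, 0, 1, 1), y = c("a", "a", "b", "b"))
  tr <- grow_tree(df, "y", "x", split_control(2, 2))
  expect_equal(as.character(predict(tr, data.frame(x = 0.5))), "b")  # at threshold: right
  expect_equal(as.character(predict(tr, data.frame(x = 0.49))), "a")
  expect_error(predict(tr, data.frame(z = 1)), "missing attribute")

  # single-leaf tree labels everything identically
  leafy <- grow_tree(data.frame(x = 1:3, y = rep("a", 3)), "y", "x")
  expect_equal(as.character(predict(leafy, data.frame(x = c(-5, 99)))),
               c("a", "a"))
})

test_that("the course knowledge-base tree reproduces reference predictions", {
  tr <- kb1_course_tree()
  cases <- verification_cases("table2")
  got <- as.character(predict(tr, cases[, c("age_ob", "igm_pct", "igg_pct",
                                            "iga_pct")]))
  expect_identical(got, cases$expected)
})

test_that("accuracy counts correct predictions", {
  df <- data.frame(x = rep(1, 51),
                   y = rep(course_labels(), c(17, 22, 12)))
  leafy <- grow_tree(df[df$y == "severe", ], "y", "x")
  expect_equal(accuracy(leafy, df, "y"), 22 / 51)
  expect_error(accuracy(leafy, df[0, ], "y"), "empty")
})

test_that("stratified partitions are disjoint, covering and balanced", {
  df <- preprocess_cohort(generate_cohort(cohort_config(seed = 1)))
  part <- stratified_partition(df, "course", 0.7, seed = 1)
  expect_length(intersect(part$train, part$test), 0)
  expect_setequal(c(part$train, part$test), seq_len(51))
  for (cl in course_labels()) {
    n_cl <- sum(df$course == cl)
    n_tr <- sum(df$course[part$train] == cl)
    expect_lte(abs(n_tr - 0.7 * n_cl), 1)
  }
  expect_identical(stratified_partition(df, "course", 0.7, seed = 1),
                   stratified_partition(df, "course", 0.7, seed = 1))
  two <- data.frame(y = c("a", "a"))
  p2 <- stratified_partition(two, "y", 0.5, 1)
  expect_length(p2$train, 1)
  expect_error(stratified_partition(df, "course", 1.2, 1), "fraction")
  df$course <- factor(df$course, levels = c(course_labels(), "ghost"))
  expect_error(stratified_partition(df, "course", 0.5, 1), "0 rows")
})

test_that("an independent CART implementation agrees on separable data", {
  skip_if_not_installed("rpart")
  pr <- preprocess_cohort(generate_cohort(
    cohort_config(seed = 2, noise_level = 0, missing_fraction = 0)))
  ours <- grow_tree(pr, "course", c("igm_pct", "igg_pct", "iga_pct", "age_ob"),
                    split_control(8, 5))
  ref <- rpart::rpart(course ~ igm_pct + igg_pct + iga_pct + age_ob, pr,
                      method = "class",
                      control = rpart::rpart.control(minsplit = 8,
                                                     maxdepth = 5, cp = 0,
                                                     xval = 0))
  expect_identical(as.character(predict(ours, pr)),
                   as.character(predict(ref, pr, type = "class")))
})

test_that("trees serialize to JSON and back without changing predictions", {
  df <- random_table(30, 3, 3, seed = 9)
  tr <- grow_tree(df, "y", c("x1", "x2", "x3"), split_control(4, 4))
  back <- tree_from_json(tree_to_json(tr))
  expect_identical(as.character(predict(back, df)),
                   as.character(predict(tr, df)))
})
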