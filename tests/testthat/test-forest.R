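test_that("a one-tree forest without resampling degenerates to a single CART", {
  df <- random_table(30, 3, 3, seed = 2)
  cfg <- forest_config(n_trees = 1, mtry = 3, seed = 1, bootstrap = FALSE)
  ctl <- split_control(minsplit = 4, maxdepth = 4)
  fo <- build_forest(df, "y", c("x1", "x2", "x3"), cfg, control = ctl)
  tr <- grow_tree(df, "y", c("x1", "x2", "x3"), ctl)
  expect_identical(as.character(predict(fo, df)),
                   as.character(predict(tr, df)))
  expect_equal(gini_importance(fo), gini_importance(tr))
})

test_that("forests are reproducible and validate mtry", {
  df <- random_table(40, 4, 2, seed = 3)
  a <- build_forest(df, "y", paste0("x", 1:4), forest_config(20, seed = 7))
  b <- build_forest(df, "y", paste0("x", 1:4), forest_config(20, seed = 7))
  expect_equal(gini_importance(a), gini_importance(b))
  expect_error(build_forest(df, "y", "x1", forest_config(5, mtry = 2)),
               "mtry")
})

test_that("a single perfect splitter earns the root impurity as importance", {
  df <- data.frame(x = c(rep(0, 6), rep(1, 6)),
                   y = rep(c("a", "b"), each = 6))
  fo <- build_forest(df, "y", "x",
                     forest_config(n_trees = 1, mtry = 1, bootstrap = FALSE))
  expect_equal(unname(gini_importance(fo)["x"]), 0.5)
})

test_that("attributes never used score exactly zero importance", {
  df <- random_table(30, 2, 2, seed = 5)
  df$flat <- 1  # constant: can never split
  fo <- build_forest(df, "y", c("x1", "x2", "flat"), forest_config(30, seed = 1))
  imp <- gini_importance(fo)
  expect_equal(unname(imp["flat"]), 0)
  expect_true(all(imp >= 0))
})

test_that("out-of-bag accuracy on the synthetic cohort beats the majority rate", {
  pr <- preprocess_cohort(generate_cohort(cohort_config(seed = 1)))
  fo <- build_forest(pr, "course",
                     setdiff(processed_columns(),
                             c("mutation_severity", "course")),
                     forest_config(n_trees = 100, seed = 1))
  expect_gt(oob_accuracy(fo, pr), max(table(pr$course)) / nrow(pr))
})

test_that("laboratory attributes dominate the importance report", {
  pr <- preprocess_cohort(generate_cohort(cohort_config(seed = 3)))
  rep <- importance_report(pr, config = forest_config(n_trees = 60, seed = 3))
  expect_identical(names(rep), c("attribute", "gini_course", "gini_mutation"))
  get <- function(a, col) rep[[col]][rep$attribute == a]
  for (col in c("gini_course", "gini_mutation")) {
    expect_gt(get("igm_pct", col), get("family", col))
    expect_gt(get("btk_lib", col), get("family", col))
    expect_gt(get("igm_pct", col), get("rheumatology", col))
  }
})

test_that("an independent forest implementation ranks the same leaders", {
  skip_if_not_installed("randomForest")
  pr <- preprocess_cohort(generate_cohort(cohort_config(seed = 2)))
  attrs <- setdiff(processed_columns(), c("mutation_severity", "course"))
  ours <- gini_importance(build_forest(pr, "course", attrs,
                                       forest_config(100, seed = 2)))
  set.seed(2)
  ref <- randomForest::randomForest(x = pr[, attrs], y = pr$course,
                                    ntree = 100)
  refimp <- ref$importance[, "MeanDecreaseGini"]
  # rank agreement on the shared attribute set
  expect_gt(cor(rank(ours[attrs]), rank(refimp[attrs]),
                method = "spearman"), 0.6)
  # both implementations put the same attribute on top
  expect_identical(names(which.max(ours)), names(which.max(refimp)))
})
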