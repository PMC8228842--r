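test_that("condition constructors enforce their invariants", {
  expect_error(condition("x", "in", c(50, 20)), "low < high")
  expect_error(condition("x", "lt", c(1, 2)), "single number")
  expect_error(condition("x", "eq", 3), "label")
  ok <- condition("iga_pct", "in", c(20, 50))
  expect_s3_class(ok, "xla_condition")
})

test_that("compiling a tree yields one rule per leaf with merged intervals", {
  # complete depth-2 tree: four leaves, four rules, pairwise exclusive
  df <- data.frame(x1 = rep(c(0, 0, 1, 1), 5), x2 = rep(c(0, 1, 0, 1), 5),
                   y = rep(c("a", "b", "c", "d"), 5))
  tr <- grow_tree(df, "y", c("x1", "x2"), split_control(2, 2))
  rs <- compile_rules(tr)
  expect_length(rs$rules, 4)
  chk <- check_ruleset(rs)
  expect_true(chk$exhaustive)
  expect_true(chk$mutually_exclusive)

  # single-leaf tree: one unconditional rule
  leafy <- grow_tree(data.frame(x = 1:4, y = rep("a", 4)), "y", "x")
  one <- compile_rules(leafy)
  expect_length(one$rules, 1)
  expect_length(one$rules[[1]]$conditions, 0)

  # repeated splits on one attribute merge into a single interval
  deep <- kb2_mutation_tree()
  rs2 <- compile_rules(deep)
  per_attr_max <- max(vapply(rs2$rules, function(r) {
    max(table(vapply(r$conditions, `[[`, character(1), "attribute")))
  }, numeric(1)))
  expect_equal(per_attr_max, 1)
  igm_in <- Filter(function(cn) cn$attribute == "igm_pct" && cn$op == "in",
                   rs2$rules[[3]]$conditions)
  expect_length(igm_in, 1)
  expect_equal(igm_in[[1]]$bound, c(20, 60))
})

test_that("tree predictions equal compiled-rule inference everywhere", {
  pr <- preprocess_cohort(generate_cohort(cohort_config(seed = 4)))
  tr <- grow_tree(pr, "course", c("igm_pct", "igg_pct", "iga_pct", "age_ob"),
                  split_control(8, 5))
  expect_tree_rules_equivalent(tr, n_random = 2000, seed = 4)
  rnd <- grow_tree(random_table(40, 3, 3, seed = 8), "y",
                   c("x1", "x2", "x3"), split_control(3, 6))
  expect_tree_rules_equivalent(rnd, n_random = 2000, seed = 8)
})

test_that("JSON serialization is a lossless fixed point", {
  kb <- load_kb("kb1_course_ig")
  txt <- serialize_rules(kb, "json")
  back <- parse_rules(txt, "json")
  expect_identical(serialize_rules(back, "json"), txt)
  expect_length(back$rules, 7)
  expect_true(back$exhaustive)
  # empty ruleset round-trips too
  empty <- rule_set(list())
  expect_length(parse_rules(serialize_rules(empty, "json"), "json")$rules, 0)
  expect_error(serialize_rules(kb, "prolog"), "arg")
})

test_that("CLIPS serialization emits one defrule per rule and parses back", {
  kb <- load_kb("kb1_course_ig")
  txt <- serialize_rules(kb, "clips")
  expect_length(gregexpr("\\(defrule ", txt)[[1]], 7)
  back <- parse_rules(txt, "clips")
  expect_length(back$rules, 7)
  wm <- facts(age_ob = 19, igm_pct = 12, igg_pct = 19, iga_pct = 17)
  expect_identical(run_inference(back, wm)$conclusion,
                   run_inference(kb, wm)$conclusion)
  # categorical conditions survive the round trip
  kb4 <- load_kb("kb4_course_combined")
  back4 <- parse_rules(serialize_rules(kb4, "clips"), "clips")
  expect_identical(vapply(back4$rules[[1]]$conditions, `[[`, character(1),
                          "op")[1], "eq")
})

test_that("malformed rule documents are rejected with locations", {
  bad_json <- '{"rules": [{"id": "r1", "conditions":
    [{"attribute": "x", "op": "in", "bound": [50, 20]}],
    "conclusion": "severe"}]}'
  expect_error(parse_rules(bad_json, "json"), "low < high")
  bad_clips <- "(defrule r1\n  (x ?v1) (flurb)\n  =>\n  (assert (conclusion \"a\")))"
  expect_error(parse_rules(bad_clips, "clips"), "line 2")
})

test_that("interval-arithmetic check flags gaps and overlaps", {
  gappy <- rule_set(list(
    rule("r1", list(condition("x", "lt", 10)), "a"),
    rule("r2", list(condition("x", "ge", 20)), "b")))
  chk <- check_ruleset(gappy)
  expect_false(chk$exhaustive)
  expect_true(chk$mutually_exclusive)

  lappy <- rule_set(list(
    rule("r1", list(condition("x", "lt", 20)), "a"),
    rule("r2", list(condition("x", "lt", 10)), "b")))
  chk2 <- check_ruleset(lappy)
  expect_false(chk2$mutually_exclusive)
})
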