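# xlapipe

From a tabular X-linked agammaglobulinemia (XLA, Bruton's disease)
patient registry to a rule-based clinical expert system, as one tested,
reproducible R pipeline.

XLA is a rare primary immunodeficiency: BTK mutations leave children with
almost no B lymphocytes and very low immunoglobulins. Clinicians grade
the **disease course** (very severe / severe / less severe) and the
**mutation severity** (severe / less severe) from onset age,
immunoglobulin levels as percent of the age-specific norm, B-cell counts,
Btk expression and infection history. `xlapipe` is for biostatisticians
and clinical-informatics researchers who want that knowledge-discovery
path — data, trees, rules, inference, verification — as auditable code
rather than a one-off analysis:

* **`generate_cohort()`** — seeded synthetic cohorts in the raw
  37-attribute registry schema, with exact label marginals (51 patients;
  course 17/22/12, mutation 28/23) and feature–label structure that makes
  the severity rules recoverable. Real patient-level registries of this
  kind are unpublishable; the generator stands in for one.
* **`preprocess_cohort()`** — the 18-attribute modelling table: ages in
  months, immunoglobulins and B cells as percent of age-banded reference
  values, diseases grouped by organ system, severe/less-severe infection
  counts, median imputation of blanks.
* **`grow_tree()` / `stratified_partition()` / `accuracy()`** — CART
  classification trees with Gini impurity
  (`G = 1 − Σ p_k²`; split maximizing
  `G(node) − (n_L/n)G(left) − (n_R/n)G(right)`) under
  `minsplit`/`maxdepth` control, with deterministic tie-breaking.
* **`build_forest()` / `gini_importance()`** — random-forest
  mean-decrease-Gini attribute ranking.
* **`compile_rules()` / `serialize_rules()`** — one production rule per
  root-to-leaf path, merged into half-open intervals, provably mutually
  exclusive and exhaustive (`check_ruleset()`), exported as JSON or
  CLIPS-style `defrule` text.
* **`run_inference()` / `load_kb()` / `run_verification()`** — a small
  forward-chaining engine (working memory, agenda, specificity-first
  conflict resolution, full condition traces) plus curated severity
  knowledge bases and their reference verification tables.
* **`run_pipeline()`** — everything end to end into a run directory with
  a machine-readable manifest; byte-identical under a fixed seed.

## Worked example

Load the disease-course knowledge base, inspect its seven rules, and run
an expertise for a child with onset at 19 months, IgM 12%, IgG 19%,
IgA 17% of the age norm:

```r
library(xlapipe)

kb1 <- load_kb("kb1_course_ig")
kb1
#> Rule set 'kb1_course_ig' with 7 rules
#>   [kb1-1] IF igm_pct < 20 AND age_ob < 24 AND igg_pct < 20 THEN very severe
#>   [kb1-2] IF igm_pct < 20 AND age_ob < 24 AND igg_pct >= 20 THEN severe
#>   [kb1-3] IF igm_pct < 20 AND age_ob >= 24 THEN severe
#>   [kb1-4] IF igm_pct >= 20 AND age_ob < 24 AND iga_pct < 20 THEN severe
#>   [kb1-5] IF igm_pct >= 20 AND age_ob < 24 AND iga_pct in [20, 50) THEN less severe
#>   [kb1-6] IF igm_pct >= 20 AND age_ob < 24 AND iga_pct >= 50 THEN severe
#>   [kb1-7] IF igm_pct >= 20 AND age_ob >= 24 THEN less severe

run_inference(kb1, facts(age_ob = 19, igm_pct = 12, igg_pct = 19, iga_pct = 17))
#> Conclusion: very severe
#> Fired: kb1-1
```

Undetectable IgM (< 20% of norm) with onset before age two and
undetectable IgG is the very severe course; the fired-rule id and a full
condition trace (`$trace`) document why. Replaying the bundled reference
test table confirms the whole rule set:

```r
run_verification(kb1, verification_cases("table2"))
#> Verification: 7 / 7 cases match
```

The same works for the mutation knowledge base (`kb2_mutation_ig`,
5/5 on `verification_cases("table3")`). A full pipeline run —

```r
res <- run_pipeline("runs/r1", config = cohort_config(seed = 1))
```

— generates and preprocesses a 51-patient cohort, trains the seven
standard tree experiments (for seed 1 the immunoglobulin course model
reaches held-out accuracy 0.867 on its 15-record test set, coarse by
design at this sample size), writes each tree with its compiled JSON and
CLIPS rule files, the two-target importance report, the 12/12
verification report, and `manifest.json` with every threshold and seed in
force.

A thin command-line wrapper with `generate` / `preprocess` / `train` /
`importance` / `compile` / `infer` / `verify` / `run-all` subcommands
lives at `inst/cli/xlapipe.R`.

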