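Package: xlapipe
Title: Decision-Tree Knowledge Discovery and Rule-Based Severity Inference
    for X-Linked Agammaglobulinemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline from a tabular X-linked
    agammaglobulinemia (Bruton's disease) patient registry to a rule-based
    clinical expert system.  Provides a seeded synthetic-cohort generator
    emulating the raw 37-attribute registry schema, preprocessing to an
    18-attribute modelling table (ages in months, immunoglobulin levels as
    percent of age-specific norm, diseases grouped by organ system), CART
    classification trees grown with Gini impurity under minsplit/maxdepth
    control, random-forest mean-decrease-Gini attribute importance,
    compilation of decision trees into mutually exclusive and exhaustive
    production-rule sets (JSON and CLIPS-style serialization), a small
    forward-chaining inference engine, and curated knowledge bases for
    disease-course and mutation severity with a verification harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    randomForest,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
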