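{
  "comment": "Synthetic default age-banded reference table. Bands are half-open [min_months, max_months) and partition [0, Inf). Reference values are plausible pediatric midpoints (IgG/IgA/IgM in g/L, B cells in percent of lymphocytes); they are placeholders, not a published standard — replace with a laboratory's own table for real data.",
  "analytes": {
    "igg": {
      "min_months": [0, 6, 12, 24, 72],
      "max_months": [6, 12, 24, 72, null],
      "reference":  [4.0, 6.0, 7.0, 9.0, 10.5]
    },
    "iga": {
      "min_months": [0, 6, 12, 24, 72],
      "max_months": [6, 12, 24, 72, null],
      "reference":  [0.3, 0.5, 0.7, 1.0, 1.5]
    },
    "igm": {
      "min_months": [0, 6, 12, 24, 72],
      "max_months": [6, 12, 24, 72, null],
      "reference":  [0.5, 0.7, 0.9, 1.1, 1.2]
    },
    "b_cells": {
      "min_months": [0, 6, 12, 24, 72],
      "max_months": [6, 12, 24, 72, null],
      "reference":  [25, 24, 23, 21, 15]
    }
  }
}
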