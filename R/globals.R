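# Column names used in dplyr/ggplot2 non-standard evaluation.
utils::globalVariables(c(
  "group", "condition", "combined_pct", "frames", "id", "density",
  "same", "static", "opposite", "delta_same_pct", "delta_opposite_pct",
  "mean_pct", "ci_lo_pct", "ci_hi_pct", "reduction_pct"
))
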