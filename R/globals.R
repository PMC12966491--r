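## columns used in tidy evaluation
utils::globalVariables(c(
  "food", "g_per_day", "metabolite", "mmol_per_day", "mmol", "sample",
  "coverage", "total", "fraction", "abundance", "model_id", "n", "taxon",
  "minimum", "maximum", "mean_secretion", "qualifies",
  "total_mean_secretion", "uptake", "max_uptake", "mean_uptake", "check",
  "observed", "lower", "upper", "caution", "verdict", "reaction",
  "raw_minimum", "raw_maximum", "unbounded_min", "unbounded_max",
  "net_secretion"))
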