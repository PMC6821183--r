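#!/usr/bin/env Rscript
# Split-operon AND gates: the soft-minimum gate (luxAB vs luxCDE under two
# inducers) against the protein-protein gate (split luxA/luxB), compared by
# output dynamic range (ODR).

library(luxcircuit)

min_res <- run_scenario("min_gate", out_dir = "results", seed = 1)
pp_res <- run_scenario("pp_gate", out_dir = "results", seed = 1)

show_tt <- function(name, res) {
  tt <- res$summary$truth_table
  cat(sprintf("%s truth table (I00, I01, I10, I11): %s\n", name,
              paste(signif(unlist(tt), 4), collapse = ", ")))
  cat(sprintf("  ODR: %.4f orders of magnitude\n", res$summary$odr))
}
show_tt("MIN fuzzy lattice", min_res)
show_tt("Protein-protein gate", pp_res)
cat("Both designs separate the ON corner from every OFF corner;\n")
cat("the ODR statistic quantifies the worst-case separation.\n")
cat("Tables written under results/{min,pp}_gate_truth_table.csv\n")
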