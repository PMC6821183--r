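#!/usr/bin/env Rscript
# The crosstalk-compensating circuit: an incoherent feedforward loop where
# recA activates the reverse enzymes for every chemical while katG, via the
# delayed TetR repressor, transiently shuts the forward enzymes for H2O2 —
# making the bioluminescent peak count equal the number of chemical types.

library(luxcircuit)

res <- run_scenario("iffl", out_dir = "results", seed = 1)

for (nm in names(res$summary$peaks))
  cat(sprintf("%-10s -> %d peak(s) at t = %s min\n", nm,
              res$summary$peaks[[nm]],
              paste(res$summary$peak_times[[nm]], collapse = ", ")))
cat("One prominent peak per chemical present; with both chemicals the\n")
cat("TetR repression window separates the two peaks by a trough.\n")
cat("Tables written under results/iffl_time_courses.csv\n")
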