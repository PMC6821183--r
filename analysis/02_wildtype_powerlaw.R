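#!/usr/bin/env Rscript
# The intact luxCDABE operon as a reporter: one promoter drives all five
# genes, luciferase scales as the square of the drive and the reverse
# enzymes linearly, so the signal follows a power law with local exponent
# strictly between 1 and 2.

library(luxcircuit)

res <- run_scenario("wildtype_powerlaw", out_dir = "results", seed = 1)

cat(sprintf("Local log-log slopes over the 1e-3..1e3 drive grid: [%.4f, %.4f]\n",
            res$summary$min_slope, res$summary$max_slope))
cat(sprintf("Mid-range (0.1..10) power-law fit: exponent %.3f (R^2 = %.4f)\n",
            res$summary$midrange_exponent, res$summary$midrange_r2))
cat("The exponent approaches 2 at low drive (dimer-limited) and 1 at high\n")
cat("drive (reverse-pathway-limited); saturation is pushed out to very\n")
cat("high inputs, unlike a Michaelis-Menten reporter.\n")
cat("Tables written under results/wildtype_powerlaw_*.csv\n")
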