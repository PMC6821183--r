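#!/usr/bin/env Rscript
# Steady-state behaviour of the lux forward/reverse reaction: how the
# reverse-enzyme level programs both the detection threshold (K_deff) and
# the saturation intensity of the bioluminescent signal.

library(luxcircuit)

res <- run_scenario("fig1_sim", out_dir = "results", seed = 1)

cat("Lux reaction steady state at reverse-enzyme levels",
    paste(res$summary$E_R_levels, collapse = ", "), "\n")
cat("  detection thresholds K_deff:",
    paste(signif(res$summary$K_deff, 4), collapse = ", "), "\n")
cat("  saturation intensities:",
    paste(signif(res$summary$plateau_I, 4), collapse = ", "), "\n")
cat("Both rise together with E_R: the threshold and the plateau are\n")
cat("independently programmable through the reverse pathway.\n")
cat("Tables written under results/fig1_sim_*.csv\n")
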