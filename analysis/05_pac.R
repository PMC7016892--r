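#!/usr/bin/env Rscript
# Phase-amplitude coupling on the stable window: the GLM index between
# slow-oscillation phase and fast-gamma amplitude at every depth
# (intraregional), plus the canonical cross-regional pair (SO phase in
# cortical L4/5 at 600 um, fast-gamma amplitude in CA1 sr-lm at 1500 um).
# The injected coupling is depth-graded, so the recovered intraregional
# profile should rank hippocampal channels above cortical ones.

library(lfposc)

stable <- read_recording("scratch/session/lfp_stable_500hz.bin")
truth <- jsonlite::read_json("scratch/session/truth.json",
                             simplifyVector = TRUE)

message("intraregional SO -> fast-gamma PAC at every depth ...")
intra <- pac_matrix(stable, "so", "fast_gamma", mode = "intra")
intra$depth_um <- stable$depths[intra$amp_channel]
intra$injected_depth <- truth$pac_depth[intra$amp_channel]
write.csv(intra, "results/pac_intraregional.csv", row.names = FALSE)

cross_pairs <- data.frame(
  phase_channel = which(stable$depths == 600),   # L4/5
  amp_channel = which(stable$depths == 1500))    # CA1 sr-lm
cross <- pac_matrix(stable, "so", "fast_gamma", mode = "cross",
                    pairs = cross_pairs)
write.csv(cross, "results/pac_cross_l45_srlm.csv", row.names = FALSE)

hip <- mean(intra$index[intra$depth_um >= 1100])
ctx <- mean(intra$index[intra$depth_um < 1100])
message(sprintf("mean intraregional PAC index: hippocampus %.3f, cortex %.3f", hip, ctx))
message(sprintf("cross-regional PAC (L4/5 phase, sr-lm amplitude): %.3f",
                cross$index[1]))
message("wrote results/pac_intraregional.csv and results/pac_cross_l45_srlm.csv")
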