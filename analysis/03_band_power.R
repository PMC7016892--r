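#!/usr/bin/env Rscript
# Band-power analysis of the stable window: Welch PSD per channel (10 s
# Hann segments, 50% overlap), total power profile over depth, relative
# band powers, and the two imbalance ratios (SO/delta and Low/High).
# Writes the per-depth tables to results/.

library(lfposc)

stable <- read_recording("scratch/session/lfp_stable_500hz.bin")
psd <- compute_psd(stable)
bp <- band_powers(psd, depths = stable$depths)

tab <- cbind(
  channel = seq_len(nrow(bp$relative)),
  depth_um = stable$depths,
  total_uv2 = bp$absolute$total,
  round(bp$relative[, bp$bands], 2),
  so_delta_ratio = round(power_ratio(bp, "so", "delta"), 3),
  low_high_ratio = round(power_ratio(bp, "low", "high"), 3)
)
write.csv(tab, "results/band_power_by_depth.csv", row.names = FALSE)

seven <- tab[tab$depth_um %in% c(2100, 1900, 1500, 1200, 900, 600, 300), ]
write.csv(seven, "results/band_power_seven_depths.csv", row.names = FALSE)

message("relative power at sr-lm (1500 um): SO ",
        tab$so[tab$depth_um == 1500], "%, delta ",
        tab$delta[tab$depth_um == 1500], "%")
message("mean SO+delta share across depths: ",
        round(mean(tab$so + tab$delta), 1), "% of total power")
message("wrote results/band_power_by_depth.csv")
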