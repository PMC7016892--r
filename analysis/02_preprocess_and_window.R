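#!/usr/bin/env Rscript
# Preprocess the simulated session exactly as the acquisition pipeline
# prescribes (Gaussian comb notch at 50 Hz and harmonics, running-median
# baseline removal, order-5 zero-phase Butterworth low-pass at 190/25/10 Hz,
# decimation to 500/50/20 Hz), then select the earliest five-minute window
# during which both heart and respiration rates stay within median +/- 2 Hz
# and +/- 0.5 Hz. Writes the preprocessed stable-window LFP to scratch/ and
# the gating report to results/.

library(lfposc)

sess <- "scratch/session"
dir.create("results", showWarnings = FALSE)

rec <- read_recording(file.path(sess, "lfp.bin"))
ecg <- read_physio(file.path(sess, "ecg.bin"))
resp <- read_physio(file.path(sess, "resp.bin"))

message("preprocessing LFP ...")
lfp <- preprocess_lfp(rec)          # notch -> baseline -> 190 Hz LP -> 500 Hz
ecg_p <- preprocess_ecg(ecg)        # baseline -> 25 Hz LP -> 50 Hz
resp_p <- preprocess_resp(resp)     # baseline -> 10 Hz LP -> 20 Hz

gate <- gate_stable_window(ecg_p, resp_p, n_samples(lfp), lfp$rate)
win <- gate$window
message(sprintf("stable window: [%.1f, %.1f] s (bounds: heart %.2f-%.2f Hz, breath %.2f-%.2f Hz)",
                win$start, win$end,
                gate$bounds_ecg[1], gate$bounds_ecg[2],
                gate$bounds_resp[1], gate$bounds_resp[2]))

stable <- crop_recording(lfp, win)
write_recording(stable, "scratch/session/lfp_stable_500hz.bin")

jsonlite::write_json(
  list(window = list(start = win$start, end = win$end),
       bounds_ecg_hz = as.list(gate$bounds_ecg),
       bounds_resp_hz = as.list(gate$bounds_resp),
       stable_fraction_ecg = mean(gate$mask_ecg),
       stable_fraction_resp = mean(gate$mask_resp)),
  "results/stable_window.json", auto_unbox = TRUE, digits = NA)
message("wrote results/stable_window.json")
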