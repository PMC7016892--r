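# lfposc

Resting-state LFP analysis for laminar probes spanning cortex and
hippocampus under anesthesia: band-power imbalance, envelope-based
functional connectivity, and phase-amplitude coupling — with a synthetic
multichannel generator so every stage is verifiable against known ground
truth without animal data.

## The problem

In anesthetized mouse recordings from a linear silicon probe (24 channels,
100 µm spacing, from the dentate gyrus up to parietal cortex), slow
oscillations (SO, 0.1–1.7 Hz) dominate the spectrum and propagate from
cortex to hippocampus with lags of tens of milliseconds. Disease models
show three signatures that this package quantifies:

1. **Power imbalance.** Per channel, the Welch PSD is integrated over a
   band scheme tiling 0.1–190 Hz (SO, delta 1.7–4.7 Hz, theta, beta,
   slow/fast gamma, epsilon). Relative power is the percentage of the
   channel's total (0.1–190 Hz) power; the imbalance indices are the power
   ratios SO/delta and Low (0.1–4.7 Hz) / High (4.7–190 Hz).
2. **Envelope connectivity.** For each channel pair (i, j), the
   instantaneous SO amplitude `a_k(t) = |H[x_k](t)|` (modulus of the
   analytic signal of the band-passed trace) is cross-correlated:
   `c_ij(τ) = corr(a_i(t+τ), a_j(t))`. The maximal |c| and its signed lag
   τ* form symmetric coefficient and antisymmetric latency matrices
   (negative latency = channel i leads), averaged within and between the
   laminar regions L2/3, L4/6, CA1 and DG.
3. **Phase-amplitude coupling (PAC).** The GLM index regresses a fast
   band's amplitude on `{cos φ, sin φ, 1}` of the slow band's phase; the
   index is the coefficient of determination R² ∈ [0, 1], invariant to
   phase rotation.

Analyses run on a physiology-gated five-minute window: heartbeat and
breath events are detected on the preprocessed ECG/respiration, and the
earliest 300 s run during which both rates stay within median ± 2 Hz
(heart) and ± 0.5 Hz (breath) is selected. Preprocessing is a Gaussian
comb notch at 50 Hz and harmonics, running-median baseline removal,
zero-phase order-5 Butterworth low-pass (190/25/10 Hz), and decimation to
500/50/20 Hz. Group comparisons use Kruskal–Wallis gated at the
Šidák-adjusted level `1 − (1 − α)^(1/k)`, then pairwise Mann–Whitney
against control.

## Worked example

The numbered drivers under `analysis/` run a complete session. Simulate a
24-channel, 420 s session in which the dentate gyrus trails cortex by
68 ms, SO→fast-gamma coupling is strongest in hippocampal channels, and a
tachycardic epoch spans 40–90 s; then preprocess, gate, and analyze:

```sh
Rscript analysis/01_simulate_session.R
Rscript analysis/02_preprocess_and_window.R
Rscript analysis/03_band_power.R
Rscript analysis/04_connectivity.R
Rscript analysis/05_pac.R
Rscript analysis/06_group_stats.R
```

Output from a run of these drivers:

```
stable window: [90.2, 390.2] s (bounds: heart 3.00-7.00 Hz, breath 1.04-2.04 Hz)
relative power at sr-lm (1500 um): SO 59.44%, delta 17.7%
mean SO+delta share across depths: 77.2% of total power
cross-regional L4/6 -> DG latency: -69.4 ms (injected -68.0 ms)
mean intraregional PAC index: hippocampus 0.224, cortex 0.084
cross-regional PAC (L4/5 phase, sr-lm amplitude): 0.219
median SO/delta ratio: WT 3.19, TG 1.25 (-61%)
pairwise Mann-Whitney vs WT: U = 0, p = 0.00018 (**)
```

Reading this: the gate skipped the injected unstable epoch and started the
window at the first clean sample (90.2 s). The low bands carry ~3/4 of
total power, as they should under anesthesia. The recovered cortex→DG
latency is negative (cortex leads) and within 1.5 ms of the injected lag.
The PAC profile ranks hippocampal depths above cortical ones, matching the
injected depth-graded coupling. In the cohort comparison, halving the SO
amplitude in one group cuts its SO/delta ratio by ~61% and is flagged
`**` by the gatekept rank test. Tables land in `results/`.

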