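---
title: "Methods: band power, envelope connectivity and phase-amplitude coupling in laminar LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, envelope connectivity and phase-amplitude coupling in laminar LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models and
estimators, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical choices that shaped the implementation.

## Signal model and preprocessing

The data model is a laminar multichannel LFP (24 channels at 100 µm
spacing by convention, deepest channel first, native 10 kHz) with
time-locked ECG and respiration. Preprocessing follows the standard
anesthetized-recording chain:

1. **Gaussian comb notch.** Line noise at 50 Hz and its harmonics is
   attenuated by frequency-domain Gaussian notches of depth 1 and width
   σ = 1 Hz (default 3 harmonics, covering up to 150 Hz at the native
   rate). σ = 1 Hz is narrow enough to spare the fast-gamma and epsilon
   bands that extend to 190 Hz. The notch is applied circularly on the
   native grid: line components are stationary over the recording, so
   they map (near-)exactly onto the notched bins, while the near-unit
   gain elsewhere passes edge discontinuities through almost unchanged.
2. **Running-median baseline removal.** Window 10 s for LFP (suppresses
   drift below ~0.1 Hz while sparing the SO band, whose lower edge is
   0.1 Hz), 1 s for ECG, 5 s for respiration; window edges shrink.
3. **Zero-phase Butterworth low-pass** (order 5; 190 Hz LFP, 25 Hz ECG,
   10 Hz respiration) followed by decimation to 500/50/20 Hz.

### Zero-phase filtering in the frequency domain

All Butterworth filters are applied as real gain profiles in the
frequency domain: the gain is the *squared* single-pass magnitude
response — exactly the effective magnitude of a forward–backward
(filtfilt-style) cascade — with identically zero phase. This choice is
forced by numerics: an order-5 band-pass at 0.1–1.7 Hz on a 500 Hz grid
has a normalized lower cutoff of 4·10⁻⁴, and a time-domain IIR
realization of that design is unstable in double precision (the
forward–backward run returns NaN). Evaluating the analytic magnitude
response `|H(jω)|² = 1/(1 + ((ω² − ω₀²)/(Bω))^{2n})` on the FFT grid is
exact at any edge. Signals are extended by even reflection before the
transform so the DFT's circularity does not wrap signal onto signal; the
suite verifies the zero-lag contract, the 60 dB double-pass attenuation
at twice a low-pass cutoff, impulse-response symmetry, and agreement with
a time-domain forward–backward run on a well-conditioned design.

## Physiology-gated window selection

Heart/breath events are local maxima above `median + k·MAD`, one event
per contiguous above-threshold excursion, with a refractory period
(amplitude priority). Defaults are sized to the anesthetized mouse —
heart ~5 Hz, breathing ~1.5 Hz: ECG k = 2 with a floor of 40% of the
beat amplitude (at tachycardic rates the beat duty cycle inflates the
MAD; at low rates the MAD is noise-dominated and the floor rejects noise
crossings), refractory 80 ms (rates to ~12 Hz resolvable); respiration
k = 0.5, refractory 200 ms (a smooth quasi-sinusoidal breath trace never
exceeds a spike-oriented k = 4 threshold). Only event *times* feed the
downstream gating, so detector details do not propagate.

Rates are per inter-event interval (1/IEI, in Hz); the stability bounds
are `median ± 2 Hz` for heartbeats and `median ± 0.5 Hz` for respiration,
with a non-positive lower bound clamped to zero. A sample is stable iff
its enclosing interval's rate is in bounds, with edge samples inheriting
the nearest interval. Stable runs are then **eroded by one interval at
every transition**: an epoch that starts mid-interval leaves that
interval's rate partially offset and possibly in bounds, so without
erosion the selected window could protrude into the epoch by up to one
interval. The earliest contiguous run of the AND-ed ECG/respiration mask
of at least 300 s, trimmed to exactly 300 s, is the analysis window —
"earliest" is the deterministic tie-break.

## Spectral analysis

The PSD is a Welch average of Hann-windowed, mean-detrended periodograms
(10 s segments, 50% overlap): 0.1 Hz resolution, enough to resolve the
SO band's lower edge, and Parseval holds within ~2%. Band powers are
trapezoidal integrals of the density with linear interpolation at the
band edges, over a scheme tiling 0.1–190 Hz: SO [0.1, 1.7), delta
[1.7, 4.7), theta [4.7, 12), beta [12, 30), slow gamma [30, 45), fast
gamma [45, 90), epsilon [90, 190]. SO, delta, fast gamma and the
composites Low [0.1, 4.7) / High [4.7, 190] are fixed by the analysis
conventions for urethane anesthesia; theta/beta/slow-gamma edges complete
the tiling and are config-overridable. Because all bands are integrated
on one grid with half-open intervals, elementary relative powers sum to
100% per channel by construction. Ratios (SO/delta, Low/High) are ratios
of absolute powers; a zero denominator yields a flagged missing value.

## Envelope connectivity

Channels are band-passed (zero-phase order 5), the envelope is the
modulus of the analytic signal (computed via the one-sided spectrum with
reflection padding), and the normalized cross-correlation
`c(τ) = corr(a_i(t+τ), a_j(t))` is evaluated on the sample grid within
±500 ms for SO (±250 ms suits delta) — a range chosen to exceed the
~70 ms physiological lags with a wide margin. The maximal |c| is
reported with its signed lag; the convention "negative latency(i, j) ⇔ i
leads j" makes a cortex-leads-hippocampus configuration print a negative
cortico-hippocampal lag. |c| rather than signed c is maximized: envelope
correlations are expected positive, but the contract is explicit.

The discrete peak is refined by **parabolic interpolation** over its two
neighbours, the standard sub-sample refinement in time-delay estimation.
At 500 Hz the grid step is 2 ms while injected lags need not be grid
multiples (25 ms = 12.5 samples), so a grid-only estimator carries a
1 ms systematic floor; interpolation removes it at no cost. A
configuration switch restores the raw grid value.

Regional averages use depth ranges L2/3 = 100–400 µm, L4/6 =
500–1000 µm, CA1 = 1100–1600 µm, DG = 1700–2300 µm, consistent with the
seven named analysis depths (300–2100 µm); the fixed region order
(cortex first) keeps cross-regional latency signs coherent, and
intraregional latency is summarized as the mean absolute pair lag.

## The GLM coupling index

For phase series φ(t) (argument of the analytic signal of the slow band)
and amplitude series a(t) (envelope of the fast band), the index is the
R² of the least-squares regression of a on {cos φ, sin φ, 1}, computed
from the normal equations of the centered two-column harmonic design.
Because cos/sin span every phase offset, the index is invariant to
constant phase rotation (verified to 10⁻⁹), lies in [0, 1], and is 0 for
constant amplitude. A `pac_index = "r"` switch returns the multiple
correlation √R² for formulations that prefer it; both are monotone
transforms of the same quantity. An optional low-pass of the amplitude
series at the phase band's upper edge before regression is available but
off by default — with the default bands the envelope already varies
slowly relative to fast-gamma and the extra smoothing changes indices
only marginally. Delta-phase PAC with the fast-gamma/epsilon (45–190 Hz)
range reuses the same operation with different band arguments.

## The synthetic generator

Each channel is a sum of independent band-limited Gaussian processes —
white noise shaped by the same squared-Butterworth band responses the
analysis uses, so synthesis and analysis share band edges exactly —
plus a 1/f^a background (default a = 1, amplitude held flat below
0.1 Hz so the background carries no drift). Defaults put ~70% of total
power in the Low range (SO 0.55, delta 0.15), the share observed under
anesthesia; amplitudes are arbitrary µV-scaled units (total SD 200 µV)
since no absolute calibration is specified for this kind of recording.
The SO component of channel k is the channel-1 component delayed by an
exact fractional (FFT phase-ramp) delay, giving an antisymmetric
ground-truth lag matrix; all other components are channel-independent.
PAC is injected by multiplying the amplitude-band component by
`(1 + m·cos φ)/√(1 + m²/2)`, which preserves its variance so power
ground truth and coupling ground truth stay orthogonal; m may be given
per channel for depth-graded coupling. Ground-truth band fractions are
computed by exact periodogram binning of the generated signal (thereby
including the background's in-band share) — the true spectral content of
the realization, independent of the Welch/trapezoid estimation path.

ECG is a train of biphasic 40 ms beat complexes at the configured heart
rate — wide enough that the dominant lobe survives the 25 Hz ECG
low-pass with alignment-stable amplitude at the 50 Hz target rate —
with multiplicative cycle-to-cycle jitter (default 2%); respiration is a
rectified sine whose phase advances at the breath rate. Unstable epochs
add a configured offset to the instantaneous rate of the named trace;
their sample ranges are part of the ground truth. Identical
configuration and seed reproduce all signals bit for bit.

What the generator does **not** emulate: volume conduction and the
systematic depth profile of real laminar power, non-Gaussian and
non-stationary dynamics (up/down state alternation, burst suppression),
spike contamination, electrode drift, and realistic ECG/respiration
morphology. Passing tests therefore demonstrate that the estimators
recover known structure of the assumed signal class, not that they are
robust to everything real recordings contain.

## Validation conditions and problem sizes

The validation suite and `scripts/acceptance.R` use these conditions,
chosen once as the package's own study design:

- **Latency recovery**: 24 channels, 300 s at the 500 Hz analysis rate,
  SO lead ladder {0, 10, 25, 40, 70, 100} ms (four channels per rung),
  10 seeds; every one of the 276 pairwise latencies must fall within
  ±2 ms (one sample) of ground truth with the leader's sign negative.
  This configuration is SO-dominant with a weak spectrally flat
  background (fractions: SO 0.95, delta 0.04, background 0.01), a
  calibration-style signal: envelope-correlation peak localization error
  grows with independent in-band noise (with the realistic default 30%
  1/f background the mean error is ~9 ms, an order of magnitude above
  the grid step, because the SO envelope decorrelates over ~0.6 s and
  in-band noise jitters a peak that broad). The ladder validates the
  estimator's resolution and sign convention; robustness to realistic
  noise is a statement about precision, not correctness.
- **PAC**: oracle agreement of the normal-equations index with an
  independent `lm` fit to 10⁻⁹ on 50 randomized cases; strict
  monotonicity of the index over injected depths {0, 0.25, 0.5, 1} at
  300 s with the depth-0 index below 0.01.
- **Band power**: 300 s, three channels, full default band scheme;
  every band's relative power within ±15% (relative) of the realized
  ground-truth fraction, elementary bands summing to 100 ± 0.1%.
- **Stability gating**: 100 randomized 900 s sessions with 1–3
  non-overlapping anomalous epochs (rate offsets beyond the 0.5/2 Hz
  constants: ±0.8–1.25 Hz breath, ±2.5–4 Hz heart) in the first 570 s;
  the selected window must never intersect an epoch, and a fully stable
  session must yield the earliest window deterministically.
- **Statistics**: Kruskal–Wallis H = 7.2 on {1,2,3}/{4,5,6}/{7,8,9}
  against the direct rank-sum formula; exact Mann–Whitney equal to full
  enumeration for all group sizes ≤ 6; the omnibus false-positive rate
  of the gatekept procedure at nominal α = 0.05 (k = 1, three null
  groups of 10) within 0.05 ± 0.015 over 2000 replicates. The k = 1
  simulation isolates the nominal-level behaviour; with the study's
  k = 4 Šidák gate the familywise rate is by construction ~0.013.
- **End-to-end discrimination**: 200 two-group cohorts (10 + 10
  animals, 60 s per animal at 500 Hz, SO and delta only) with the SO
  amplitude halved in one group; the gatekept comparison must flag the
  SO/delta ratio at p < 0.05 in at least 90% of cohorts. Halving the
  amplitude quarters the SO power, so the expected ratio change is about
  −75% before accounting for the background's in-band share (~−61%
  observed).

Cohort and gating simulations generate directly at the 500 Hz analysis
rate (the decimation chain is validated separately); the single-session
drivers under `analysis/` simulate at a 1 kHz native grid and run the
full chain. These sizes keep the complete validation under ten minutes
on one core while leaving every tolerance comfortably met.

## Degenerate inputs and numerical conventions

Loaders never resample or rescale, and missing metadata is an explicit
error. All-zero signals propagate to zero spectra, zero envelopes and a
zero PAC index. Identical values across statistical groups return H = 0,
p = 1 with a warning rather than NaN. Decimation requires an integer
factor. Band integrals outside the PSD support, bands at or above
Nyquist, lags beyond half the window, and windows longer than the trace
all raise errors naming the violated precondition. The pipeline wraps
each stage so failures abort with the stage name and cause, and a fixed
seed makes a full run byte-reproducible.

## Known limitations

The envelope latency estimator reports the grid/interpolated argmax of a
single global cross-correlation; it does not model lag dispersion within
a window. The GLM index tests only first-harmonic phase dependence —
coupling concentrated in higher harmonics of φ would need an extended
design. The stability gate assumes physiological instability manifests
as rate changes; amplitude-only artifacts pass it. The generator's
stationarity means temporal non-stationarity of coupling (a hallmark of
real recordings) is untested. Native Open Ephys acquisition files are
out of scope; sessions enter through the package's container or CSV.
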