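---
title: "Methods: MEA spike detection and transcriptomic statistics in spikexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike detection and transcriptomic statistics in spikexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`spikexpr` implements the analysis chain of a four-group, two-stage brain
organoid study: HD-MEA recordings of spontaneous multi-unit activity at two
developmental ages (60 and 90 days in vitro), with and without a drug
treatment, followed by bulk RNA-seq on the same design. This vignette is the
package's own account of the methods: the models and their assumptions, the
tunable parameters, the numerical choices made where the procedure left them
open, and what the synthetic-data validation does and does not demonstrate.

## 1. Signal cleaning

A recording is a channels × samples voltage matrix in µV at a sampling
frequency `fs` (default 19,754 Hz). Two artifact classes are excised by
building a recording-wide boolean validity mask:

* **Recalibration artifacts.** HD-MEA chips recalibrate periodically
  (~every 400 ms) and inject large artificial transients. Each recalibration
  timestamp removes a symmetric border of `border = 100` samples either side
  (2·border + 1 = 201 samples ≈ 10.2 ms per event, ~2.5% of recording time at
  the default cadence). The timestamp sample itself is included in the
  excision — the symmetric reading of a "border on either side". Overlapping
  borders merge.
* **Flashes.** Samples where at least `channel_frac = 0.5` of channels exceed
  `saturation_frac = 0.9` of the saturation rail are invalidated (±`pad`).
  "Majority" and "saturated" are not quantified by the upstream acquisition
  description, so both fractions are exposed in the configuration with these
  defaults.

Invalid samples are *masked*, never zero-filled: zero-filling a 1.5 mV
artifact gap creates filter edge transients that mimic spikes. All downstream
statistics (filtering, thresholds, firing rates) consult the mask, and firing
rates divide by the *effective duration* (valid samples / fs).

## 2. Band-pass filtering

The 150–3000 Hz band-pass is a linear-phase equiripple FIR designed by the
Remez exchange algorithm and applied with group-delay compensation, per
contiguous valid segment, so output length and alignment match the input.

One numerical point deserves record. A single Remez band-pass with these
corners needs very asymmetric transition bands (here 100 Hz below, 300 Hz
above, on a 9,877 Hz Nyquist). The exchange algorithm leaves transition bands
unconstrained, and for this geometry `signal::remez()` produces designs that
peak at more than +30 dB *inside* the upper transition band — white noise
passed through such a filter comes out five times larger, and higher orders
fail to converge outright. The package therefore builds the band-pass as a
cascade of two well-conditioned designs: a 401-tap high-pass (stopband edge
50 Hz, stopband error weight 10) convolved with a 113-tap low-pass (stopband
from 3300 Hz), 513 taps in total. Verified over the full FFT grid, the
cascade is flat to ±0.4 dB across 150–3000 Hz, −52 dB at 50 Hz, and −36 dB
above 3300 Hz, with no transition peaking. Corner frequencies, section
lengths, transition widths and the stopband weight are all arguments of
`design_bandpass_fir()`.

## 3. Spike detection

Spikes are two-sided excursions beyond mean ± k·SD (k = 5) computed in a
moving window of `floor(window_ms·fs/1000)` samples (5 ms → 98 samples),
centered on the evaluated sample and truncated at segment edges; whether the
upstream analysis used a centered or trailing window is not documented, and
centered is the symmetric default. The spike time is the sample of maximum
absolute deviation within the excursion; excursions closer than
`refractory_ms = 1` merge; spikes on invalid samples are discarded. Polarity
is two-sided because extracellular spikes are predominantly but not
exclusively negative.

The plain short-window estimator, however, cannot satisfy both halves of the
detection contract (sensitivity ≥ 0.95 and FDR ≤ 0.05 at SNR 8), for two
reasons that are worth quantifying:

* **Self-contamination.** A ~1 ms biphasic spike inside its own 5 ms window
  contributes roughly 7·A²/98 to the window variance; at SNR 8 (A = 8σ) that
  inflates the windowed SD ~2.4-fold, pushing the effective threshold to
  ~12σ — above the spike peak. Detection of moderate-SNR events is then
  impossible *on average*, not just occasionally. `detect_spikes()` therefore
  excludes a ±1 ms guard interval (one spike width, matching the refractory
  distance) around the evaluated sample from the window statistics
  (`guard_ms = 1`).
* **Estimator instability.** After band-limiting to 150–3000 Hz, the 5 ms
  window holds only ~17 statistically independent noise samples, and with the
  guard even fewer; the raw windowed SD then has ~20% sampling error and its
  low excursions admit noise crossings at a measured rate near 2 events/s —
  an order of magnitude above the firing rates of interest. The windowed SD
  is therefore floored at the channel-wide robust noise scale, the
  MAD-derived SD of the valid filtered trace (`robust_floor = TRUE`), the
  standard spike-insensitive noise estimate in extracellular
  electrophysiology. The moving mean still tracks local baseline, and the
  threshold still rises where local noise genuinely increases.

Both refinements are arguments; `guard_ms = 0, robust_floor = FALSE` recovers
the plain windowed estimator, and `moving_threshold()` keeps the plain
estimator as its own default so the windowed statistic itself remains
directly testable against a per-window loop.

**Channel and organoid selection.** Channels above `max_hz = 5` (abnormal,
plausibly non-biological activity) are excluded *before* ranking — the
upstream ordering of exclusion versus top-30 selection is ambiguous, and
excluding first is the conservative choice since a 6 Hz artifact channel
would otherwise displace a genuine channel from the top 30. The remaining
channels are ranked by frequency (ties broken by ascending channel id) and
the `top_n = 30` kept. An organoid is included when the mean rate of its
selected channels is ≥ `min_mean_hz = 0.5`; the boundary sits on the included
side because the exclusion is stated as "< 0.5 Hz".

## 4. Group statistics

`unpaired_t()` implements the pooled (Student) and Welch variants and accepts
summary triplets (mean, SEM or SD, n) so published summaries can be checked
directly. Unlabelled "±" values in the source literature are read as SEM —
the reading under which the published growth comparison (1.19 ± 0.16 vs
1.27 ± 0.17, n = 5) reproduces its printed p = 0.738; the SD reading does
not. The choice is an explicit argument of `group_sample()`.

`anova_sidak()` computes the omnibus one-way F and pairwise comparisons using
the pooled within-group variance (ANOVA MSE, N − k df), Šídák-adjusted as
p_adj = 1 − (1 − p)^m (computed via `expm1` for small p). The comparison
family defaults to all six pairs among four groups because the source family
is not enumerated; `m` follows the requested set. Normality screening wraps
`shapiro.test()`. The outlier screen is a ROUT-style procedure reduced to the
one-sample location case: robust center (median) and scale (MAD-derived SD),
two-sided t p-values, Benjamini–Hochberg flagging at q = 0.01 — a screen, not
a reimplementation of the proprietary robust-regression original.

## 5. Expression filtering and DEG calling

Genes are retained when at least `min_valid = 7` of the samples exceed
`min_value = 0.1` TPM (idempotent by construction). DEGs satisfy a strict
three-way conjunction: |mean difference| > 4 (linear TPM — the matrix's
unit, the natural reading of an "absolute difference" threshold, exposed as
an argument), fold change > 2, p < 0.05. The p-value is a pooled two-tailed t
on log2(TPM + 1); the offset is configurable since only "log-transformed" is
specified upstream. Fold change is max(mean)/min(mean) with group means
floored at 0.01 TPM to avoid division by zero, and direction is carried
separately as the sign of log2 FC. No multiple-testing correction is applied
in DEG calling, mirroring the raw-p criterion it reproduces. Z-score
heatmap matrices standardize each gene to mean 0, SD 1 across samples using
the sample SD (n − 1, as `scale()`); constant genes are an error naming the
gene.

## 6. Overlap statistics and enrichment

The representation factor of an overlap x between lists of sizes n1, n2 in a
background of N genes is RF = x·N/(n1·n2), with exact hypergeometric
upper-tail p = P(X ≥ x). The background N defaults, in the pipeline, to the
number of genes surviving the expression filter. Published RFs often omit N;
`background_from_rf()` inverts the RF identity and `background_from_p()`
solves P(X ≥ x | N) = p by monotone root finding. Applied to the published
triple this reconstruction shows the two up-regulated cases sharing
N ≈ 26.3k while the down-regulated case implies N ≈ 24.7k — a documented
reconstruction of apparently different universes, not an assertion about the
original analysis.

Over-representation of a query list against a GMT collection is a per-set
hypergeometric upper tail (set memberships restricted to the background)
with Benjamini–Hochberg q-values. Pre-ranked GSEA ranks genes by
sign(log2FC)·(−log10 p) (ties broken by gene id, zero p floored at the
smallest double) and computes the weighted Kolmogorov–Smirnov running-sum ES;
the running-sum extrema are evaluated only at hit positions and just before
the next hit, which is exact and keeps permutation loops O(set size).
Significance uses *gene-set permutation* (random same-size position sets):
with n = 5 samples per group, phenotype permutation is degenerate, and the
ranking is the natural exchangeable unit. NES divides ES by the mean
magnitude of same-signed null ES; the permutation p uses the same-signed null
with +1 smoothing; FDR compares the pooled null NES distribution against the
observed NES distribution, capped at 1 — the published normalization and FDR
scheme for pre-ranked analysis.

## 7. Synthetic data: what it emulates, and what it does not

`generate_mea_recording()` produces Gaussian noise (default 10 µV SD) with
biphasic spikes — a negative half-sine lobe (~0.6 ms) followed by a smaller
positive lobe (~0.4 ms), amplitude jittered ±20%, default 80 µV peak
(SNR 8) — at Poisson times thinned to a 3 ms minimum separation, on a
configurable fraction of channels; a 1 ms square recalibration pulse on all
channels at exact multiples of 400 ms; and 5 ms rail-level saturation flashes
on a random 90% channel subset, everything clipped at the ±2048 µV rail. The
artifact waveform and flash duration are conventions (the instrument's are
undocumented); a worst-case square pulse makes excision testable.
`generate_expression_matrix()` builds log2(TPM+1) values as log-normal
baselines (location 3, scale 2) plus signature effects (default 2 log2 units)
plus Gaussian replicate noise (0.25 log2 units), with a 400-gene maturation
signature (85% up), a 40-gene stage-1 treatment signature overlapping the
maturation-up set by 80%, and a 30-gene stage-2 treatment signature
down-regulating maturation-up genes — the overlap structure the
representation-factor logic is designed to quantify. DE genes are placed on
genes above 5 TPM baseline, since threshold-based calling cannot see fold
changes of near-zero genes.

What the generators deliberately do **not** model: bursting or network
synchrony (only stationary Poisson firing), electrode drift and
non-stationary noise, spike waveform diversity or overlap (sorting is out of
scope), biophysical neuron or pharmacokinetic models, count-based RNA-seq
noise (mean–variance relationships, library-size effects), and correlated
gene modules. Passing validation therefore demonstrates that the *pipeline
logic* is correct under its stated assumptions — artifact excision excises,
thresholds are calibrated, criteria conjunctions and overlap statistics
compute what they claim — not that real recordings or libraries satisfy
those assumptions.

## 8. Problem sizes and degenerate inputs

Validation sizes are chosen so the full suite runs in minutes on one CPU
while keeping binomial error bands tight where calibration is asserted:
10–20 s recordings at 4–6 channels (≥ 100 ground-truth spikes for
sensitivity/FDR), 1,000-sample traces for brute-force oracle agreement,
5,000-gene null matrices (±3.3 binomial SDs ≈ ±0.012 around the 0.05 rate),
10,000 replicates for t-test type-I calibration, 200 random sets × 500
permutations for GSEA null calibration, and a 1,200-gene, 8-organoid
end-to-end run checked byte-for-byte for reproducibility. The end-to-end
pipeline derives every stage seed deterministically from the single
configuration seed, and each output carries the MD5 hash of the canonical
YAML serialization of its configuration.

Degenerate inputs are errors with the offending field named: invalid
generator or configuration fields, unknown configuration keys, windows
shorter than two samples, empty channel selections, groups missing from the
sample map, constant genes in z-scoring, overlaps violating
x ≤ min(n1, n2) ≤ N constraints, query genes outside the enrichment
background, and dilutions exceeding their stock.

## 9. Known limitations

Recordings are serialized as single R containers (RDS) rather than a
cross-language array format; the read/write surface validates field by field
so the container format can be swapped without touching the analysis. The
t-based DEG p-values assume approximate log-scale normality with n = 5 per
group — adequate for threshold-style calling, but shrinkage estimators
(limma/DESeq2-style) would be preferred for genome-wide inference. The
ROUT-style screen covers the one-sample location case only. GSEA uses
gene-set permutation; phenotype-permutation FDRs on larger designs are out of
scope. Representation factors treat gene lists as exchangeable draws from a
common finite universe; list-specific detectabilities are not modelled.
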