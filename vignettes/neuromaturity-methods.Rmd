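---
title: "Methods: multi-phenotypic maturation scoring, screen normalization and activity metrics"
author: "neuromaturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phenotypic maturation scoring, screen normalization and activity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay in one page

Neuronal maturation is multi-dimensional: nuclei grow and round up,
dendritic arbors elongate and branch, and cells acquire the ability to
mount a depolarization-induced immediate-early-gene (IEG) response.
The package quantifies six parameters per well from four-channel
fluorescence images — nucleus area and roundness (DAPI), total neurite
length and segment count per nucleus (MAP2), and the KCl-induced FOS⁺
and EGR-1⁺ nuclear fractions — plus synaptic SYN1/PSD95 puncta
apposition density as a screen-independent maturation readout, and
electrophysiological activity metrics (MEA spikes and network bursts,
calcium transients) as functional validation.

Mature primary rat cortical neurons at day 14 serve as the assay
benchmark: ~130 µm² nuclei with roundness index ~0.93, more than
2,500 µm of neurite per neuron, and near-universal KCl-induced IEG
responses. Immature hPSC-derived cultures sit far below these values.

## Imaging operators

**Nucleus segmentation.** DAPI is Gaussian-smoothed (σ = 2 px), globally
thresholded by Otsu's method, and touching nuclei are split by a
watershed on the distance transform (tolerance 2 px of h-maxima
suppression; ties resolved by the label propagation order of the
watershed, which is deterministic). Regions outside [40, 500] µm² are
discarded — the operational definition of an *intact* nucleus; debris
and clumps do not enter the viability count. An all-zero raster yields
an empty segmentation, not an error.

**Morphometry.** Area is pixel count × pixel-size². Roundness is the
isoperimetric quotient 4πA/P², clipped to 1, with P estimated by the
4-direction Cauchy–Crofton formula (intercept counts along rows,
columns and both diagonals). Crofton is accurate to ~1–2% on smooth
digital shapes; its known bias on long straight polygon edges (~3–5%)
is irrelevant for nuclei. The synthetic generator calibrates its
ellipse axis ratios against the *continuous* version of the same
definition (Ramanujan perimeter), so a 0.93 target renders shapes that
measure ≈ 0.93 under this estimator — the roundness scale is
self-consistent between generator and measurement.

**Neurite tracing.** MAP2 is Otsu-thresholded, nuclear regions are
removed (somata do not count toward neurite length), components smaller
than 4 px are pruned (noise specks; pruning uses 8-connected labelling),
and the mask is thinned to a 1-px skeleton (Zhang–Suen). The skeleton is
decomposed into *segments*: maximal paths between junction (degree ≥ 3)
or end (degree 1) nodes under m-adjacency (a diagonal link is used only
when no bridging orthogonal pixel exists, so staircases do not create
spurious parallel edges). Segment length is the chain length — 1 per
orthogonal step, √2 per diagonal step, times the pixel size. Isolated
loops count as one segment; isolated pixels as a zero-length segment.
Per-nucleus values are field totals divided by the nucleus count (no
per-cell assignment is attempted); with zero nuclei they are reported
missing.

**IEG scoring.** Mean channel intensity within each nuclear mask,
positive when *strictly* above threshold (FOS > 800 AFU,
EGR-1 > 1,000 AFU; a mean of exactly 1,000 is negative). Double
positivity requires both. The mean (not median) within the mask is used;
with ~300-px nuclei and additive read noise the two are
indistinguishable in practice.

**Puncta and appositions.** Scale-normalized difference-of-Gaussian blob
detection over σ ∈ [1, 3] px (4 geometric scales, 3-D local maxima,
response threshold 500 AFU, near-duplicates within 1.5 px merged),
restricted to the MAP2 mask dilated by 2 µm — the region "immediately
surrounding" neurites. A PSD95 punctum is apposed when its centroid lies
within 1 µm of a SYN1 centroid, counted at most once; density is
apposed count per 100 µm of neurite. The 1 µm radius and 2 µm dilation
are package choices (the assay definition leaves "immediately
surrounding" unquantified); both are exposed in `threshold_config()`.

## Screen statistics

The normalization pipeline follows the order *pair → b-score → z-score
→ replicate average → PCA*:

1. **Pairing.** Every well address must appear in both the stimulated
   and unstimulated plate of a replicate (orphans are an error naming
   the well). Induced IEG fractions are stimulated − unstimulated
   (negative induction is legitimate); morphology and the viable-nuclei
   count are averaged across the pair.
2. **b-score.** Per plate and parameter, a two-way median polish
   removes additive row/column artifacts; residuals are divided by
   1.4826 × median |residual|. The sweep loop runs until the largest
   absolute row/column median is below 1e-9 or 1,000 iterations. These
   are deliberately tighter than a casual choice: on random 16×24
   plates the polish needs a median of ~105 and occasionally ~500
   sweeps to stabilize, and stopping earlier leaves residuals that
   differ from the fixed point by more than the 1e-6 at which the
   package's own oracle tests compare. A zero-MAD plate returns all
   zeros. The loop is implemented directly (Rcpp) because the stopping
   rule is on the largest sweep; `stats::medpolish`'s sum-plateau
   criterion can halt while residuals are still moving, and serves
   instead as the independent cross-check in the test suite.
3. **z-score.** Per replicate and parameter, robust standardization
   against the library distribution: (x − median)/ (1.4826 × MAD).
   Robust moments were chosen over classical ones because screens are
   outlier-heavy by construction — the hits and toxic compounds are the
   outliers, and they should not set the scale. Replicate z-vectors are
   averaged per compound (which shrinks the null spread by √2 — the
   reason a DMSO population shows MAD-scaled spread ≈ 0.7 after
   averaging two replicates).
4. **Viability filter.** Excluded iff viability z < −2, strictly; a
   compound at exactly −2 is retained. With ~2,400 retained compounds a
   few borderline inert compounds inevitably cross this threshold by
   chance (the z-scale is standardized, so the ~0.2% Gaussian tail at
   −2.83 robust SDs is irreversible by any noise setting); the filter
   is judged by its recovery of the planted toxic set, not by the raw
   excluded count.
5. **PCA hits.** Covariance PCA on the compound × 6 z-matrix (already
   on a common scale — no further column scaling). PC1 is oriented so
   the FOS-fraction loading is positive ("more mature" is positive);
   other components so their largest-magnitude loading is positive,
   removing the eigen-solver's sign ambiguity. Hits are PC1 > 4,
   strictly. Cluster labels operationalize the screen's phenotypic
   classes: maturation-enhancing (PC1 > 4), maturation-inhibiting
   (PC1 < −4), non-neuronal proliferation (viability z > 2 with
   neurite z < 0), otherwise other. Components with near-zero variance
   (< 1e-10 SD) are flagged, not dropped.
6. **Single-parameter hits.** Top-5 per parameter (total neurite
   length; double-IEG induced fraction) after removing compounds
   already selected by PCA; ties broken by ascending compound id and
   flagged.
7. **Validation and dose–response.** Four parameters (nucleus area,
   roundness, neurite length, induced double-IEG fraction) divided by
   *same-plate* DMSO means — per-plate normalization shields composites
   from plate effects; the composite is their mean, so DMSO-like wells
   score 1.0. Dose trends use the Spearman correlation of well
   composites against log₁₀(dose) over the 30–10,000 nM ladder, with a
   one-sided permutation test: exhaustive when ≤ 10⁵ permutations
   (n ≤ 8 wells), otherwise 10⁴ seeded Monte-Carlo draws. A constant
   composite has ρ defined as 0 and is never flagged.

## Activity metrics

**Spikes.** Noise σ per channel is median(|x − median|)/0.6745 — the
standard robust estimator for extracellular traces, immune to the
spikes themselves. Events are negative-going crossings of 9σ, timed at
the trough, with a 2-ms refractory. Detection is invariant under
amplitude scaling, and at 9σ the Gaussian false-positive rate is
negligible (≪ 0.1/channel/min). The upstream assay used a proprietary
precise-timing detector; only the 9-SD threshold is retained here and
the detector is the package's own threshold-crossing implementation.

**Firing-rate summary.** Channels ranked by spike count in a 60-s
window; the top 1/64 of each probe (64 of 4,096; ties by channel id) is
summarized per probe and pooled — two probes yield 128 electrodes.

**Network bursts.** Population rate per 0.1-s bin = total spikes /
(channels × bin). A burst is a maximal run of bins at ≥ 1 spike s⁻¹ per
channel; bursts closer than 0.2 s are merged. The per-channel-mean
reading of the array-wide threshold is the default (`mode = "array"`
thresholds the total rate instead); bin width and merge gap are package
choices, as the original detector's binning is not public.

**Calcium.** F₀ is a running 10th percentile over a centered 60-frame
window (floored at 1 AFU); ΔF/F = (F − F₀)/F₀. An event is an upward
crossing of 3 robust SDs of the ΔF/F series lasting ≥ 2 frames, with a
2-frame merge gap. The 240-frame schedule (one frame per 5 s for
20 min) is validated on construction: a 239-frame matrix declared at
that schedule is an error, not a warning.

## What the generators emulate — and what they do not

The synthetic field renderer draws nuclei as rotated ellipses (area CV
12–15%, axis ratio solved from the target roundness), neurite arbors as
branched 8-direction persistent random walks rooted at somata (so the
generative chain length is in *exactly* the same metric as the tracer's
readout), nuclear IEG fill at responder/non-responder intensities with
responder status drawn per neuron, Gaussian puncta on neurites with a
controlled apposed fraction (apposition labels are re-derived from the
final geometry, not from the construction), 16-bit intensities,
constant background and Gaussian read noise. Screen plates are
simulated at the feature level: per-well six-parameter vectors plus
viable-nuclei counts, additive per-plate row/column artifacts, hits
elevating every maturity parameter by +6 noise-SD (IEG only under
stimulation) and toxic compounds depressing nuclei counts by 6 SD.

Not emulated: optics (no PSF, no shading, no photobleaching),
out-of-focus debris, per-cell neurite attribution, correlated
compound pharmacology (inert compounds are exactly null), non-additive
plate artifacts, electrode drift or overlapping spike waveforms, and
calcium indicator kinetics beyond a single-exponential decay. Passing
the planted-truth suites therefore demonstrates that the *analytics*
are correct and calibrated on data whose generating process is known —
not that the pipeline is robust to every artifact of real microscopy.

A deliberate density choice: screen-density fields default to 60
neurons per 1,024² field (scaled from 5,000 cells/well sampled by four
×20 fields at 0.65 µm/px). At that density a quarter of all pixels are
neurite, arbors overlap heavily, and skeleton crossings make per-cell
length systematically unattributable — exactly as in real mature
cultures. The package's tracing *benchmark* therefore uses sparse
plating (25 neurons/field, 8 fields, ≥ 200 nuclei per replicate seed),
the standard practice when per-cell neurite length must be validated;
at that density the union-loss from crossings is a few percent and the
tracer recovers ~93% of the generative 2,800 µm per neuron.

## Problem sizes and determinism

Every generator takes an explicit integer seed and restores the RNG
state afterwards; identical spec + seed give bitwise-identical rasters,
tables and files (result CSVs from two identical runs are
byte-identical, which the manifest's MD5 inventory makes checkable).
The shipped validation suites use: 20 replicate seeds × 8 fields for
parameter recovery; the full 2,688-compound duplicate screen
(16 plate-instances of 16×24) for normalization and hit selection; 100
random plates and 100 random puncta fields for oracle equivalence;
8 × 60-s traces at 12.5 kHz for spike recovery; and a 4,096-channel
spike-table simulation for burst and rate summaries. These sizes keep
the whole suite in single-digit minutes on one CPU while leaving each
statistical check comfortably powered.

## Known limitations

- Per-field segment counts at screen density are dominated by
  skeleton-crossing junctions, not biological branch points; the
  parameter is informative only *relatively* (z-scored), which is how
  the screen uses it.
- The watershed does not split heavily overlapping nuclei (> ~40%
  area overlap); the generator avoids such configurations by
  construction, and real clumps are removed by the area gate.
- Blob detection merges puncta closer than ~1.5 px; at the default
  densities this costs ~15–20% of detections in dense fields, which
  cancels in DMSO-normalized comparisons but biases absolute counts
  downward.
- The dose–response permutation test treats wells as exchangeable
  under the null; plate nesting of replicate wells is not modelled.
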