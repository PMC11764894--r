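---
title: "Multi-entropy fusion for EEG emotion recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-entropy fusion for EEG emotion recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bremtool)
```

## The problem and the model

Emotion recognition from EEG usually throws many channels and a trained
classifier at the problem. `bremtool` implements the opposite regime: a
resource-efficient pipeline that works from a *single channel* (or a single
anatomical region) and needs only *two labeled exemplars* — one positive
(high-arousal/high-valence), one negative — instead of a training set.

The pipeline has three stages.

1. **Rhythm extraction.** A 4-level discrete wavelet transform (db4 by
   default) splits the signal into five reconstructions that sum exactly
   back to the input: at 128 Hz, A4 → delta (0–4 Hz), D4 → theta (4–8),
   D3 → alpha (8–16), D2 → beta (16–32), D1 → gamma (32–64).
2. **Multi-entropy features.** On each rhythm, six complexity measures are
   computed: approximate (AE), fuzzy (FE), sample (SE), permutation (PE),
   singular-spectrum (SSE) and spectral (PSDE) entropy. The 5 × 6 result is
   the *Brain Rhythm Entropy Matrix* (BREM); fixed row order gamma → delta,
   fixed column order AE, FE, SE, PE, SSE, PSDE. Region mode concatenates
   the matrices of a region's channels horizontally (occipital: 5 × 30).
3. **Template classification.** A test BREM is compared with the positive
   and the negative template under one of four measures — dynamic time
   warping (DTW) on the row-major flattened matrix, histogram mutual
   information (MI), Spearman rank correlation (SCC), or a quantized
   Jaccard coefficient (JSC) — and takes the class of the more similar
   template. Evaluation cycles exhaustively over every (negative, positive)
   template pair (LOOCV template cycling: 16 negative × 24 positive trials
   → 384 pairs of 38 test trials each) and averages the per-pair
   accuracies, `(TP + TN) / (TP + FP + FN + TN)`.

## Numerical and design choices

**Dyadic versus nominal band edges.** The clinical rhythm boundaries
(alpha 8–13 Hz, beta 13–30 Hz) do not coincide with the dyadic splits of a
level-based filter bank (8–16, 16–32). The pipeline is deliberately
level-based, so the dyadic edges are what the decomposition actually
delivers; `band_edges` reports them honestly, and a warning fires when the
realized boundaries stray more than 25 % from the nominal ones (e.g. at
64 Hz sampling). Alpha is taken as the whole D3 band without a 13 Hz
sub-split, because the 4-level tree has no finer node there.

**Boundary handling.** Decomposition uses symmetric (half-point) signal
extension, which minimizes edge artifacts in short 5 s windows. The
transform keeps `floor((n + L - 1)/2)` coefficients per branch and is
therefore slightly expansive but *exactly* invertible; the five
reconstructions sum to the input to better than 1e-8 relative error, which
the test suite asserts for arbitrary lengths and all supported wavelets.
Gamma is capped at the Nyquist frequency. Decompositions deeper than 4
levels fold the extra low-frequency detail branches into delta so the
reconstruction identity survives.

**Entropy parameter defaults.** The source method fixes none of the
estimator parameters, so the package adopts the dominant conventions of the
nonlinear-dynamics literature and exposes every knob in `entropy_config()`:
embedding dimension `m = 2`, tolerance `r = 0.2 · SD(x)`, fuzzy exponent
`n = 2`, ordinal patterns of order 3 at delay 1, Welch spectra from
256-sample Hann segments with 50 % overlap, trajectory window `L = 10`.
Natural logarithms are used throughout, so PE is bounded by `ln(3!)` and
PSDE by the log of the number of frequency bins.

**Entropy conventions where the printed formulas are inconsistent.** Three
of the printed entropy definitions conflict with the standard estimators:
the sample-entropy ratio appears inverted (which would make the statistic
nonpositive under the usual counting), the singular-spectrum sum lacks its
leading minus sign, and fuzzy entropy appears as a bare difference of
membership sums rather than a log-ratio. In all three cases the package
implements the standard, nonnegative orientation — `-ln(φ(m+1)/φ(m))` with
self-matches excluded, `-Σ σ̃ log(σ̃ + ε)`, and `ln φ^m − ln φ^(m+1)` —
because these are the estimators the surrounding text describes
qualitatively (larger = more irregular).

**Degenerate inputs.** Constant sequences return 0 for every entropy (the
limit of each formula as variability vanishes), so an all-zero signal maps
to an all-zero BREM instead of propagating NaNs. When no length-`m+1`
template pair matches, sample entropy returns the bounded cap
`log(φ(m) · (N − m))` rather than `+Inf`, keeping the downstream matrix
finite. Ordinal-pattern ties are broken by earlier index (stable sort), so
PE is deterministic on quantized data.

**Similarity measures on a 30-entry matrix.** DTW needs a sequence, so the
matrix is flattened row-major in the canonical order (configurable via
`similarity_config()`); a fixed order makes scores reproducible. MI and JSC
need discrete values: both use equal-width binning over the *pooled* range
of the two matrices, with 5 bins by default — 30 samples cannot support a
finer histogram. The JSC set representation includes the cell position,
not the value alone, so a match means "the same rhythm–entropy cell fell in
the same level". The Jaccard formula `1 − |A∩B| / |A∪B|` is a
dissimilarity (0 = identical), and the classifier treats it as a distance —
the prose description of its range in the source is inverted, and we follow
the formula. Note that coarse binning makes exact MI/JSC ties between
structurally similar BREMs common; ties are resolved toward the positive
class and counted (`tie_count`), which mirrors the degenerate all-positive
behavior the method's authors observed for JSC.

**Evaluation protocol.** Template trials are excluded from testing only for
their own pair (38 of 40 trials tested per pair, which reproduces the
published worked example: an all-positive predictor on 15 negative + 23
positive test trials scores 23/38 = 60.53 %). Subject-level accuracy is the
mean over all template pairs, with its SD reported alongside. Grid search
over channels and non-overlapping segments (anchored at 0 s) breaks ties
deterministically: montage order first, earlier segment second. Because it
is ambiguous whether a subject-level summary should use the best segment or
average over segments, `grid_search_best()` returns both the argmax cell
and the full per-cell table, leaving the aggregation to the analyst. The ANOVA
screen is the two-group closed form (F = squared pooled t), reported
unadjusted for multiple testing, matching the source analysis.

## What the synthetic generator emulates — and what it does not

`generate_subject()` produces the *stated world* used by every stochastic
test: 128 Hz, one-minute trials, 40 trials split 24 positive / 16 negative
per subject (the published subject-S1 split). Each trial sums, over the
five dyadic bands, a band-centered sinusoid and band-limited Gaussian noise
(white noise passed through the package's own filter bank, so planted
structure aligns exactly with what the analysis extracts), plus broadband
noise. Base band amplitudes decline with frequency
(delta 20, theta 10, alpha 15, beta 8, gamma 5 arbitrary units over
broadband noise of SD 5), a crude 1/f-like profile.

Class separation is controlled by a single `effect` scale acting on two
mechanisms at once: band power (positive trials raise beta/gamma by
`1 + 0.5·effect`, negative trials raise delta/alpha — affecting PSDE/SSE)
and regularity (the sinusoidal energy fraction moves from 0.4 down to
`0.4 − 0.3·effect` for positive and up to `0.4 + 0.3·effect` for negative
trials — affecting SE/FE/AE/PE). The documented **strong preset** is
`effect = 1`; the **null preset** is `effect = 0`, under which the two
classes share one generating distribution by construction. These presets
were fixed before the acceptance thresholds were evaluated and are not
tuning knobs.

The generator does **not** emulate real EEG physiology: no 1/f spectral
continuum, no transients or artifacts, no inter-channel correlation, no
non-stationarity within a trial. A green synthetic test therefore
establishes that the *pipeline* separates classes whose band power and
regularity differ — not that any particular accuracy is attainable on real
recordings, which require the licensed study dataset.

In multi-channel subjects the effect is planted in exactly one channel
(`signal_channel`); the remaining channels draw from the null parameters.
This is what makes channel grid-search recovery a meaningful check.

## Scaled-down stochastic suites

To keep the default test run inside a desktop budget, the replicate loops
use reduced subjects: channel-recovery replicates use 12 + 8 trials of 10 s
across 3 channels (two 5 s segments), and null-calibration replicates use
12 + 8 trials of 5 s; the strong-preset accuracy check runs at the full
24 + 16 scale. The reductions change only runtime, not the statistical
question; all seeds are fixed in the test code.

## Known limitations

* Only orthogonal Daubechies wavelets (haar/db1, db2, db4) are built in;
  biorthogonal families are out of scope.
* The DWT mapping to the five rhythms requires `levels >= 4`; other depths
  fold extra details into delta rather than renaming bands.
* MI and JSC inherit the coarseness of 5-bin histograms on 30 points;
  exact ties are frequent by construction and always resolved positive.
* Reading the original study dataset's distribution files is not included;
  the text/RDS trial store plus the generator cover the test surface.
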