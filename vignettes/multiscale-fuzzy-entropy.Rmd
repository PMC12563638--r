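---
title: "Multi-scale fuzzy entropy features for EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale fuzzy entropy features for EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msentropy)
```

## The problem

A concealed-information protocol records a few seconds of EEG while a
subject truthfully acknowledges, or deceptively denies, recognizing an
item. Deception engages response inhibition and semantic control, and the
working hypothesis of entropy-based lie detection is that this changes the
*irregularity* of the signal rather than its amplitude: a single
well-chosen electrode may then suffice for classification, which matters
for portable headsets. `msentropy` implements the full feature and
evaluation stack for this setting: a fuzzy entropy estimator, two
multi-scale extensions, per-trial feature fusion, six conventional
classifiers under three cross-validation schemes, and
representative-channel selection.

## Fuzzy entropy

For a series $x_1,\dots,x_N$, overlapping pattern vectors of length $m$
are compared pairwise with the Chebyshev distance
$d_{ij} = \max_k |x_{i+k} - x_{j+k}|$. Instead of a hard threshold, each
distance is mapped to a similarity in $(0,1]$ by the exponential
membership function $\mu(d) = \exp(-d^n/r)$. With
$\phi^m$ the mean membership over all ordered pairs of distinct
$m$-dimensional vectors (outer mean over the $N-m+1$ vectors, inner mean
over the other $N-m$), fuzzy entropy is

$$\mathrm{FE}(m, r, n) = \ln \phi^m - \ln \phi^{m+1},$$

the log-loss in pattern similarity when the pattern length grows by one.
Irregular signals lose similarity quickly (high FE); regular signals do
not. Defaults are $m = 2$, $n = 2$, $r = 0.15$ in units of the series'
standard deviation — the parameterization commonly used for EEG.

Three numerical choices deserve note:

* **Tolerance in sd units.** The relative tolerance resolves to an
  absolute tolerance $r\,\sigma^n$, equivalent to evaluating the literal
  membership function on the unit-variance series. With the naive reading
  $r\,\sigma$ the exponent $d^n/r$ would scale as $c^{\,n-1}$ under
  $x \mapsto c\,x$, so the same signal would score differently in
  microvolts and millivolts. With the sd-unit reading, FE (and TSMFE and
  HMFE below) are exactly invariant under amplitude scaling and
  translation, which the test suite asserts at $10^{-10}$. User-supplied
  absolute tolerances are used verbatim.
* **Minimum length.** Both $\phi^m$ and $\phi^{m+1}$ need at least two
  vectors, so a series must have $N \ge m+2$; shorter input signals a
  typed "short series" condition that the multi-scale layer converts into
  a zero contribution.
* **Degenerate series.** When $\sigma < 10^{-12}$ and no absolute
  tolerance is given, FE is reported as 0 with a degeneracy flag rather
  than as 0/0. Values with $|\mathrm{FE}| < 10^{-14}$ are clamped to zero
  to absorb floating-point sign noise; larger negative values (possible in
  principle for pathological inputs) are reported as computed.
* **Raw embeddings.** Pattern vectors are raw slices; no local baseline is
  removed. Some older fuzzy-entropy variants subtract each window's mean —
  that behaviour is available via `baseline_removal` in
  `embed_vectors()` but is off by default.

## Time-shifted multi-scale fuzzy entropy (TSMFE)

Coarse-graining — averaging adjacent samples before re-estimating entropy —
smooths away exactly the fast structure one is trying to measure, and its
estimates degrade at coarse scales. The time-shifted construction avoids
this: at scale $k$ the series is split into the $k$ interleaved
subsequences that start at offsets $1..k$ and take every $k$-th sample.
Their index sets are disjoint and cover the series; nothing is averaged.
Each subsequence is scored with FE (tolerance resolved on the
subsequence's own standard deviation by default;
`tolerance_scope = "series"` switches to the whole-series rule for
sensitivity analyses) and the scale value is the mean of the $k$ scores.
A subsequence shorter than $m+2$, degenerate, or failing the FE
computation contributes 0, so coarse scales with a few unusable
subsequences are not distorted. The vector over scales $1..k_{\max}$
(default 10) is the TSMFE feature; scale 1 is by construction plain FE.

## Hierarchical multi-band fuzzy entropy (HMFE)

EEG rhythms live in conventional frequency bands (delta, theta, alpha,
beta), and band-specific complexity is informative. HMFE decomposes a
trial with an orthogonal multi-level discrete wavelet transform,
reconstructs each band alone in the time domain, and computes FE per band.
At 128 Hz with the default Daubechies-4 (8-tap) wavelet and level 4 the
bands are approximately A4 0–4 Hz (delta), D4 4–8 Hz (theta), D3 8–16 Hz
(alpha), D2 16–32 Hz (beta), D1 32–64 Hz — which is why those defaults
were chosen; both are configurable.

Band energies differ by orders of magnitude, so a common tolerance would
be numb in quiet bands and hypersensitive in loud ones. The band tolerance
is therefore the base tolerance rescaled by $\sigma_b/\sigma_x$ and passed
to FE as an *absolute* tolerance — the per-series rule must not be applied
a second time, or the adaptation would be undone. A near-silent band
($\sigma_b/\sigma_x < 10^{-8}$) reports FE = 0 with a flag.

The transform itself is implemented as a periodized orthogonal filter
bank. Periodization (rather than symmetric extension) keeps the transform
an orthogonal map of $\mathbb{R}^N$, so coefficient energy equals signal
energy and the $L+1$ single-band reconstructions sum back to the input at
machine precision — both properties are asserted in the tests. The cost is
that the series length must be divisible by $2^L$ (the 384-sample
reference trials support level 4); infeasible depths fail with the maximum
feasible level named.

## Features, classifiers, validation

Per trial and channel the fused vector concatenates
$[\mathrm{FE},\ \mathrm{TSMFE}_{1..k_{\max}},\
\mathrm{HMFE}_{A_L..D_1}]$ — 16 values under defaults. Multi-channel
configurations concatenate per-channel blocks in the requested order.
Extraction is per-trial independent, so no statistic leaks across
cross-validation folds; non-finite features are a hard error, never
imputed.

Six classifiers are evaluated (C1–C6): linear and RBF-kernel SVM, kNN with
k = 3 and 5, Gaussian naive Bayes, and LDA. The reference protocol does
not state hyperparameters; the package uses the common defaults (SVM cost
1, RBF width by the "scale" convention $1/(p\,\mathrm{Var}(Z))$, Euclidean
uniform-vote kNN, pooled-covariance LDA with priors from the training
labels) and exposes them. Features are z-scored with parameters fit on the
training fold only — the protocol source is silent on normalization, but
the distance-based classifiers (kNN, RBF-SVM) are scale-sensitive, so the
package standardizes by default and the switch is exposed; treat this as a
reproduction caveat.

Three validation schemes: per-trial leave-one-out within a subject (50
folds for a 50-trial subject, seed-free), stratified 10-fold within a
subject (classes dealt to folds in opposite directions so fold sizes stay
equal; seeded and reproducible), and leave-one-subject-out across subjects
(the generalization test; training rows never include the test subject).
Accuracy is the evaluation metric, appropriate because the design is
exactly balanced (equal lie and truth trials); per-subject values are kept
at full precision and rounded only for display.

A subject's *representative channel* is the single channel with the
highest accuracy; ties are broken by fixed montage order (AF3, T7, PZ, T8,
AF4) and all tied channels are logged, since the reference protocol does
not state its rule. Occurrence counts across subjects summarize which
electrodes matter. Because the published per-scheme best-channel listings
differ between schemes and the cumulative figure does not state which
combinations are summed, the package reports per-scheme counts and leaves
any summation to the caller.

## The synthetic generator

Real recordings of this protocol cannot be bundled, so the package ships a
generator that emulates the reference layout exactly: 27 subjects, two
conditions, 25 trials x 3 s per condition, 5 channels, 128 Hz. Each trial
sums three unit-variance components — a subject-specific oscillation
(alpha ~10 Hz plus theta ~6 Hz), 1/f-like noise, and broadband white
noise — with power fractions summing to one, scaled to the subject's
amplitude. The "lie" condition on the informative channels (default PZ and
T7) moves `effect_size` (default 0.4) of the power budget into the
broadband component. Total power is unchanged: amplitude carries no class
information, the class signal is purely a complexity contrast, which is
the honest way to exercise entropy features.

Two variability terms make the task realistically hard. The broadband
fraction fluctuates trial-to-trial (sd 0.08, a fixed model constant
standing in for attention/state drift), so within-subject accuracy does
not saturate. Each subject carries a persistent offset of their baseline
broadband fraction (scale `subject_sd`, default 0.15, plus relative jitter
of oscillation frequency and amplitude), so one subject's "lie" complexity
can resemble another subject's "truth" — which is what makes
cross-subject LOSOCV harder than within-subject LOOCV, as observed in real
data. All randomness derives from a single seed; regeneration is bitwise
identical and the caller's RNG state is untouched.

What the generator does *not* model: event-related potentials, volume
conduction and channel correlation, artifacts (ocular, muscle), and
non-stationarity beyond the per-trial state jitter. Passing the recovery
study therefore shows the pipeline is correct and sensitive to planted
complexity contrasts; it does not certify performance on real EEG.

## The recovery study and problem sizes

`synthetic_recovery_study()` is the package's self-check, mirroring the
reference protocol at 20 synthetic subjects: full feature extraction on
all five channels, RBF-SVM and LDA (the protocol's two best families)
under LOOCV and LOSOCV, per-subject best-channel scoring (as the published
result tables do), planted-channel recovery, and an effect-free null run
on one channel whose LOOCV accuracy must hover at chance — the leakage
alarm. Twenty subjects keeps the study at a few minutes on one core while
leaving the proportions of the reference design intact; the bundled
27-subject reference tables cover the aggregation path at full scale.

## Preprocessing and I/O

The CSV + JSON-manifest reader applies the standard preprocessing of the
reference dataset — DC removal, then a 0.5–45 Hz zero-phase band-pass —
only when the manifest marks data as raw; bundled and simulated data are
generated in-band and skip it. The band-pass is an order-4 Butterworth
high-pass cascaded with an order-8 Butterworth low-pass, each applied
forward-backward. A single high-order band-pass in transfer-function form
is numerically fragile at the very low normalized drift edge
(0.5 Hz / 64 Hz Nyquist), and an order-4 band-pass does not reach 20 dB
attenuation by 1.2x the upper edge; the cascade achieves both stability
and that attenuation contract, which the tests measure by FFT amplitude
ratio. Trials keep the full 3 s window (prompt plus stimulus) by default;
`trial_crop = c(1, 3)` drops the prompt second, since the protocol source
does not say whether it was excluded. Sample indices are 0-based with
half-open windows. EDF input is not supported — convert to CSV.

## Known limitations

* FE is O(N^2) per series; the compiled core makes the default trial
  length (384 samples) take about a millisecond, but very long series
  will be slow.
* The periodized DWT requires trial lengths divisible by 2^level.
* Published headline accuracies for this protocol were measured on a real
  dataset that the package does not download; the bundled transcriptions
  cover only the aggregation and channel-selection arithmetic.
* The wavelet family is limited to Haar/db2/db4 filter banks.
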