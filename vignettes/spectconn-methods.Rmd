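---
title: "Spectral EEG connectivity and network group comparison: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral EEG connectivity and network group comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectconn)
```

## What the package does

`spectconn` implements a two-track pipeline for comparing resting-state EEG
functional networks between two groups of subjects (here labelled *patients*
and *controls*):

1. **Scalp track** — connectivity between scalp electrodes;
2. **Nodal track** — connectivity between 17 source-space regions of interest
   spanning the default-mode (DMN), central-executive (CEN) and salience (SN)
   networks. The package consumes ROI time series directly; an inverse
   solution that produces them is deliberately out of scope, and the interface
   point (`generate_roi_cohort()` / any epochs-by-ROI recording) is where a
   real source localization would plug in.

Each track runs: preprocessing → per-epoch spectral decomposition on the
integer 1–100 Hz grid → twelve connectivity estimators → band aggregation
(delta 1–3, theta 4–7, alpha 8–13, low-beta 14–21, high-beta 22–30, gamma
31–60 Hz; the nodal track pools beta to 14–30 Hz) → proportional thresholding
at the top 20% of edge weights → graph metrics (degree, clustering
coefficient, assortativity) → group inference (pooled-variance t-tests at
configurable alpha levels: 0.0005 for scalp edge-wise maps, 0.02 for scalp
network metrics, 0.05 for nodal analysis) → ROC discriminability of a
subject-level summary score.

Because no public recordings accompany the study design this pipeline
targets, the package ships a first-class synthetic-cohort generator with
planted, known connectivity, so that every stage can be validated against
ground truth.

## The generative model

Each subject is a stable multivariate autoregressive (MVAR) process
$x_t = \sum_{r=1}^{p} A_r x_{t-r} + \varepsilon_t$, with
$\varepsilon_t \sim N(0, \sigma^2 I)$. Channel dynamics are damped order-2
resonators: a channel oscillating at $f_0$ Hz has
$a_1 = 2\rho\cos(2\pi f_0/f_s)$, $a_2 = -\rho^2$ on its own diagonal, with
pole radius $\rho = 0.95$ — the minimal model with a tunable spectral peak.
Band centers are fixed at delta 2, theta 6, alpha 10, low-beta 18, high-beta
26 and gamma 40 Hz (band midpoints rounded onto the analysis grid).
A directed coupling $j \to i$ of strength $s$ adds $s$ to $A_1[i, j]$.
`build_generating_mvar()` asserts stability (companion-matrix spectral
radius < 1) on every build and, if a requested coupling set is unstable,
scales the couplings by 0.8 per attempt (up to 25 attempts) before failing;
the attempt count is recorded in the model metadata.

Cohort defaults mirror the study design the pipeline targets: 18 patients vs
17 controls, 512 Hz sampling, 2-second epochs, 60 epochs per subject
(two minutes of retained data), unit innovation SD (amplitudes then fall in a
plausible tens-of-microvolts range).

### The planted group effect

The default patient effect couples the first four fronto-central channels
into a *mutually* (bidirectionally) coupled theta clique at nominal strength
0.35. Two design points deserve explanation:

* **Why mutual coupling.** One-way couplings between near-resonant
  oscillators act as a cascade: each hop multiplies amplitude by roughly the
  resonator gain, which is numerically explosive for cliques of any depth.
  Symmetric coupling instead splits the channels' degenerate resonator poles
  into shared network modes — strong, band-limited statistical dependence at
  bounded amplitude. The builder's stabilization brings the realized
  coefficients to the stable region, so the nominal strength is an upper
  bound, and the effect expresses itself through shared modes rather than
  raw coefficient size.
* **Why a clique.** Disjoint coupled pairs raise edge weights but plant no
  triangles; a clique raises degree *and* clustering coefficient in the
  affected channels, which is the network signature the downstream analysis
  and the subject-level score are designed to detect. The clique size (4) and
  band (theta) were calibrated once so that the default cohort shows both a
  detectable edge-wise effect at the stringent scalp alpha (0.0005) and a
  discriminative subject score (ROC AUC comfortably above 0.8), and then
  frozen.

The nodal-track default effect plants salience-network-internal couplings
(anterior insula → ACC, bilaterally) in the beta band.

### Seeds and determinism

A cohort seed determines per-subject seeds by a counter-based split
(`(seed * 10007 + i) mod (2^31 - 1)`). All randomness flows through R's RNG
(innovations are drawn in R and only the sequential filter recursion runs in
compiled code), so identical specs reproduce byte-identical data. Each epoch
is simulated independently with a burn-in of `max(10 p, 512)` samples: a pole
at radius 0.95 has a time constant of roughly 20 samples, so 512 samples
(about 1 s at 512 Hz) comfortably absorbs the start-up transient that a
shorter, order-proportional burn-in would leak into the data.

### What the generator does and does not emulate

It emulates epoched, band-limited oscillatory multichannel EEG with
controllable directed coupling and group structure. It does **not** emulate
volume conduction (channels are generated directly as MVAR series; an
optional zero-lag mixing would deliberately stress the PLV-vs-WPLI contrast),
electrode drift, eye-blink or muscle artifacts, 1/f background spectra, or
nonstationarity. Passing tests therefore demonstrate correctness of the
estimators and inference machinery on data satisfying their assumptions —
not robustness to every pathology of real recordings.

## Preprocessing

* **Filters.** Zero-phase (forward–backward) Butterworth: high-pass 0.5 Hz
  and low-pass 100 Hz of order 4, and an order-2 notch of 2 Hz width at
  50 Hz. Epochs of one recording are consecutive segments of one record, so
  the filters run on the concatenated record with odd-symmetric reflection
  padding (up to 4 s per end) and the result is re-epoched: the 0.5 Hz
  high-pass and the narrow notch settle over seconds — longer than a single
  2-s epoch — so per-epoch filtering would be dominated by edge transients.
* **Bad channels.** Two robust criteria per channel, both aimed at *noise*
  contamination: (i) log variance of the first-differenced signal —
  differencing emphasizes broadband high-frequency content (electrode noise,
  line interference, muscle) while suppressing band-limited physiological
  rhythms by orders of magnitude, so a strong theta or alpha rhythm (which is
  exactly what the group comparison studies) is not mistaken for a noisy
  channel; flagged two-sided (noisy or dead); and (ii) mean correlation with
  spatial neighbours, flagged one-sided (only decorrelated channels —
  unusually *high* neighbour correlation is not a noise signature). Each
  criterion is a robust z-score (median/MAD across channels) thresholded at
  |z| > 3. Because the across-channel spread on clean homogeneous data is
  tiny, a bare z threshold would routinely flag clean channels (the maximum
  of n z-scores exceeds 3 easily); each criterion therefore also carries a
  practical-effect floor — at least a twofold difference in differenced-signal
  variance (|Δ log var| > log 2) or a 0.2 drop in neighbour correlation —
  which clean data essentially never reaches and genuinely broken channels
  exceed by orders of magnitude.
* **Interpolation.** Flagged channels are replaced sample-wise by the
  inverse-distance-weighted mean of their clean neighbours (a convex
  combination, hence always within the neighbours' range).
* **Artifact rejection.** Epochs whose peak absolute amplitude exceeds
  150 µV (configurable) on any channel are dropped — an automated surrogate
  for visual artifact screening, which is not reproducible.

## Spectral stage

`compute_fft()` applies a single Hann taper per epoch and keeps coefficients
at the 100 integer frequencies 1–100 Hz; with 2-s epochs the native
resolution is 0.5 Hz so the integer bins are exact (other epoch lengths are
linearly interpolated). A single taper (not multitaper) keeps per-epoch phase
well defined for the phase-locking family of measures.

`fit_mvar()` estimates one coefficient set per subject by least squares
pooled across epochs — each epoch contributes its own lagged design block, no
lag crosses an epoch boundary. Order is selected by the Schwarz criterion
capped at 20 (`"auto"`), or fixed by the caller; the generator defaults make
order 3 a safe pipeline choice. `spectral_factor()` evaluates
$\bar A(f) = I - \sum_r A_r e^{-i 2\pi f r / f_s}$ and $H(f) = \bar A(f)^{-1}$
with a reciprocal-condition-number guard (1e-12); ill-conditioned frequencies
come back NaN with a warning rather than silently wrong.

## Connectivity estimators

With per-epoch coefficients $X_e$, $Y_e$ at one frequency,
$Z_e = X_e \overline{Y_e}$, $\theta_e = \arg Z_e$, $N$ epochs, and
$S_{xy} = \tfrac1N \sum_e Z_e$:

| measure | definition | range |
|---|---|---|
| CSD magnitude | $|S_{xy}|$ | ≥ 0 |
| coherence | $|S_{xy}|^2 / (S_{xx} S_{yy})$ | [0, 1] |
| imaginary coherency | $|\mathrm{Im}\,S_{xy}| / \sqrt{S_{xx} S_{yy}}$ | [0, 1] |
| power correlation | Pearson r of $|X|^2, |Y|^2$ across epochs | [−1, 1] |
| PLV | $|\tfrac1N \sum_e e^{i\theta_e}|$ | [0, 1] |
| PLI | $|\tfrac1N \sum_e \mathrm{sign}(\mathrm{Im}\,Z_e)|$ | [0, 1] |
| WPLI | $|\sum_e \mathrm{Im}\,Z_e| / \sum_e |\mathrm{Im}\,Z_e|$ | [0, 1] |
| PPC | $(N\,\mathrm{PLV}^2 - 1)/(N-1)$ | [−1, 1] |
| WPPC | $(|\sum z_e|^2 - \sum |z_e|^2)/((\sum w_e)^2 - \sum w_e^2)$, $w_e = |z_e|$ | [−1, 1] |
| PDC | $|\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2}$ | [0, 1] |
| DTF | $|H_{ij}(f)| / \sqrt{\sum_k |H_{ik}(f)|^2}$ | [0, 1] |
| Granger (Geweke) | $\ln S_{ii} / (S_{ii} - (\Sigma_{jj} - \Sigma_{ij}^2/\Sigma_{ii})|H_{ij}|^2)$ | ≥ 0 |

Directed entries follow the `[target, source]` convention. Diagonals are NaN
everywhere; the directed AR measures also retain the full normalized array
(`values_full`) because their exact normalization identities
($\sum_i \mathrm{PDC}_{ij}^2 = 1$ per column, $\sum_j \mathrm{DTF}_{ij}^2 = 1$
per row) include the self-terms. Granger causality is computed
pairwise-bivariate (each pair refitted as a 2-channel model) rather than
conditionally multivariate — PDC and DTF already carry the multivariate
directed structure, and the bivariate Geweke form is standard, transparent
and swappable. The registry counts twelve measures: the widely used ten plus
PLI and imaginary coherency as the two configurable extra slots.

Degenerate cases follow fixed conventions: WPLI with an identically zero
imaginary part (a purely zero-lag relation) is defined as 0 and flagged;
zero autospectra give NaN coherence with a warning; nonpositive Granger log
arguments are clamped to 0 with a warning.

## Networks and inference

Band aggregation is the arithmetic mean over each band's integer bins with
NaN bins excluded. Proportional thresholding ranks candidate entries (upper
triangle undirected, all ordered pairs directed), keeps
`round(fraction × candidates)` — for 128 channels and fraction 0.2 that is
round(0.2 × 8128) = 1626 edges — and binarizes. Ties at the cut break by
row-major index order, so results are bit-reproducible; NaN weights sort
last. Graphs are binarized because degree is reported as a count of
connections; weighted variants are out of scope.

Metrics: degree (in+out for directed graphs); clustering coefficient
$2t_i/(k_i(k_i-1))$ with Fagiolo's generalization on directed graphs, 0 by
convention below degree 2; Newman degree assortativity as the Pearson
correlation of end-node degrees over the edge list (both orientations;
directed graphs are measured on their undirected skeleton; regular graphs
are NaN with a warning).

Group inference is the classic pooled-variance unpaired t-test (not Welch —
available behind a flag), vectorized over units, two-sided, with the fixed
sign convention *patient minus control*. Multiplicity is handled the way the
target analysis handles it: a fixed stringent alpha per level (0.0005 /
0.02 / 0.05), not FDR machinery. Cluster identification over the
channel-by-frequency grid is descriptive connected-components labelling
(montage neighbours spatially, ±1 bin spectrally, mass = sum of |t|), not a
permutation cluster-mass test. A variance-ratio (F) comparison with
two-sided p by tail doubling is available alongside.

## Discriminability

The default subject score is the node-mean clustering coefficient of the
thresholded PDC graph in the beta band (the nodal-track headline metric;
band and statistic are configurable — the synthetic scalp cohorts use theta
to match the planted band). The ROC curve sweeps all distinct score
thresholds, AUC is the trapezoid rule (identically the normalized
Mann–Whitney U), and the reported operating point maximizes Youden's J with
ties resolved toward higher specificity — consistent with reporting a single
optimal sensitivity/specificity pair. Quartiles in the group summaries use
the linear-interpolation convention (R type 7), stated because median/IQR
values depend on it.

## Numerical and fixture choices

* Test and acceptance fixtures scale the study shape down to desk size:
  type-I calibration uses 8-channel, 5-vs-5 cohorts of 60 one-second epochs
  at 256 Hz (native 1 Hz resolution keeps integer bins exact); effect
  recovery uses the full 18-vs-17 design on a 16-channel montage. The type-I
  fixture tests band-aggregated power correlation, whose subject-level null
  values are close to Gaussian, so the pooled t's nominal level is meaningful
  at five subjects per group.
* Estimator null expectations used in tests are exact small-sample results:
  E[PLV²] = 1/N and E[coherence] ≈ 1/N under independence, PPC/WPPC unbiased
  at 0, PLV biased upward like √(π/4N).
* The EDF reader/writer covers the fixed-rate, equal-samples case the
  package emits (16-bit, one data record per epoch); files round-trip within
  one quantization step of each channel's physical range.
* The 17 ROI names are a documented stand-in set (no canonical list is
  available to reproduce): DMN (VMPFC, DMPFC, PCC, precuneus, bilateral
  IPL), CEN (bilateral DLPFC, bilateral PPC), SN (bilateral anterior insula,
  ACC, bilateral VLPFC, preSMA, dorsomedial thalamus); every ROI-accepting
  function takes an override.
* Eyes-open/eyes-closed block labels are carried as epoch annotations but
  pooled by default.

## Known limitations

* No volume-conduction forward model: scalp-level estimator behaviour under
  zero-lag mixing is exercised only by targeted unit tests (WPLI invariance
  vs PLV inflation), not by the cohort generator defaults.
* Granger causality is bivariate, not conditional; on densely coupled
  systems it can report indirect influence.
* Cluster identification is descriptive; no familywise cluster-level p-value
  is attached.
* The sLORETA inverse problem, ICA-based artifact correction and
  re-referencing schemes are out of scope by design.
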