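# spectconn

Group comparison of resting-state EEG functional networks: spectral
connectivity, graph metrics, and biomarker discriminability, in R.

## The problem

Neurodegenerative disease reorganizes the brain's functional networks before
it is visible in behaviour. Resting-state EEG is a cheap, widely available
way to look for that reorganization: statistical dependence between channels
(or between source-space regions) at specific frequencies defines a weighted
graph per subject, graph theory summarizes its topology, and group
statistics ask where patients and controls differ. `spectconn` implements
that pipeline end to end for two-group designs — a *scalp track* over
electrodes and a *nodal track* over 17 regions of interest covering the
default-mode, central-executive and salience networks — together with a
synthetic-cohort generator that plants known directed couplings, so every
stage can be validated against ground truth.

The pipeline, per subject: zero-phase filtering (0.5–100 Hz, 50 Hz notch),
statistical bad-channel handling, 2-s epochs, artifact-epoch rejection →
Hann-tapered FFT on the integer 1–100 Hz grid and MVAR fitting with spectral
factorization → twelve connectivity estimators (CSD, coherence, imaginary
coherency, power correlation, PLV, PLI, WPLI, PPC, weighted PPC, PDC, DTF,
spectral Granger causality) → band aggregation (delta/theta/alpha/low-beta/
high-beta/gamma) → top-20% proportional thresholding → degree, clustering
coefficient, assortativity. Group level: pooled-variance t-tests per edge or
metric at configurable alpha (0.0005 scalp edge maps, 0.02 scalp network,
0.05 nodal), electrode-by-frequency cluster identification, F-ratio
comparisons, and ROC analysis of a subject-level score (by default the
node-mean clustering coefficient of the thresholded PDC graph).

Key identities, implemented and tested exactly:
PDC `|Ā_ij(f)| / √Σ_k |Ā_kj(f)|²` (columns sum-square to 1),
DTF `|H_ij(f)| / √Σ_k |H_ik(f)|²` (rows sum-square to 1),
PPC `(N·PLV² − 1)/(N − 1)`, WPLI `|Σ Im Z_e| / Σ |Im Z_e|`,
Geweke spectral Granger causality from pairwise bivariate fits,
AUC ≡ normalized Mann–Whitney U.

## Worked example

Simulate a small cohort (6 patients vs 6 controls, 12 channels; patients
carry a mutually coupled fronto-central theta subnetwork on top of the
shared baseline), run the full pipeline, and look at the group results:

```r
library(spectconn)

cfg <- validate_config(list(
  cohort = list(n_patients = 6, n_controls = 6, n_channels = 12,
                epochs_per_subject = 30, epoch_len_s = 2, fs = 512),
  measures = c("csd", "coherence", "plv", "pdc"),
  score = list(measure = "pdc", band = "theta", statistic = "clustering"),
  mvar_order = 3,
  seed = 42))
out <- run_pipeline(cfg)

dplyr::count(dplyr::filter(out$edge_stats, significant), measure, band)
#>    measure   band          n
#>  1 coherence delta         6
#>  2 coherence theta         1
#>  3 csd       delta        34
#>  4 csd       theta        10
#>  5 pdc       alpha         8
#>  6 pdc       delta         6
#>  7 pdc       high_beta     1
#>  8 pdc       low_beta      4
#>  9 pdc       theta         6
#> 10 plv       delta         6
```

The planted theta couplings surface as significant edges (at the stringent
scalp alpha 0.0005) in theta and its spectral neighbourhood — a mode of
finite width has a skirt, so adjacent bands light up too, the familiar
"spread over adjacent bands" pattern of real group findings.

```r
out$group_summary
#>   group       n median     q1    q3    min   max
#> 1 patient     6  0.164 0.125  0.194 0.112  0.203
#> 2 control     6  0.114 0.0963 0.134 0.0450 0.143
attr(out$group_summary, "p_value")
#> [1] 0.03888444

out$roc
#> <roc_analysis> AUC 0.833; optimum: sens 67% / spec 100% at 0.1511
```

The subject score (theta-band PDC clustering) separates the groups: patient
median 0.164 vs control 0.114, AUC 0.83, and the Youden-optimal operating
point classifies with 67% sensitivity at 100% specificity. `autoplot()` has
methods for connectivity matrices, channel-by-frequency t-maps and ROC
curves; `tidy()`/`glance()` return tibbles for every result type.

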