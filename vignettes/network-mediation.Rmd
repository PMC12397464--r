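---
title: "From ROI time series to a mediation claim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ROI time series to a mediation claim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netmed implements the full inferential chain used in resting-state
functional-connectivity studies of brain–behaviour associations in ageing:
cleaned ROI time series are turned into weighted connectivity networks,
nodal graph metrics are averaged over a sparsity sweep, screened against
behavioural scores with covariate-adjusted rank correlations under FDR
control, and the surviving regions are tested as mediators of a
behaviour–behaviour association with a bias-corrected bootstrap. This
vignette is the package's own account of each stage: the model, the
defaults and why, the numerical choices, and what the synthetic validation
does and does not establish.

```{r setup}
library(netmed)
```

## The pipeline

The unit of analysis is a cohort of older adults, each contributing a
resting-state scan summarised as a volumes-by-ROIs matrix (90 regions of a
bilateral anatomical parcellation; 240 volumes at TR = 2 s in the emulated
design) plus behavioural scores: psychological resilience (a 0–45
hardiness scale) and processing speed (a symbol–digit substitution count),
with age, sex and education as covariates.

### 1. Signal cleaning (`clean_timeseries()`)

The per-subject chain runs in a fixed order:

1. **Initial discard** — the first 5 volumes are dropped (signal
   equilibration), 240 → 235.
2. **Framewise displacement** — Power-style FD: the L1 norm of the
   backward differences of the six realignment parameters, rotations
   converted to arc length on a 50 mm sphere. The formula choice matters
   because the 0.2 mm (inclusion) and 0.5 mm (scrubbing) thresholds used
   throughout are calibrated to this definition.
3. **Scrubbing** — each volume with FD > 0.5 mm is censored via a
   unit-impulse spike regressor, together with 1 volume before and 2
   after. Spikes enter the nuisance regression as covariates rather than
   deleting rows, which preserves the temporal grid for filtering.
4. **Nuisance regression** — white-matter, CSF and global signals plus the
   Friston-24 motion expansion (6 parameters, their differences, and both
   squares) and the spike columns, all regressed jointly against an
   intercept-augmented design. Joint (not sequential) regression avoids
   reintroducing variance removed by an earlier step.
5. **Band-pass 0.01–0.1 Hz** — a zero-phase ideal (rectangular frequency
   response) filter: demean, FFT, zero all bins outside the band,
   invert. This is the convention of the standard resting-state
   toolchains; it meets the attenuation contract exactly (in-band
   sinusoids pass unchanged on the FFT grid, out-of-band sinusoids are
   removed, DC maps to numerical zero) at the cost of some spectral
   leakage for off-grid frequencies, which is immaterial for correlation
   estimates.

Cohort-level QC (`qc_filter()`) excludes subjects with MoCA < 22, GDS > 7,
or excessive motion. The inclusion sentence the thresholds come from joins
the motion bounds ambiguously ("≤ 2 mm and ≤ 2°, or mean FD ≤ 0.2 mm"); the
default reads it conservatively as a conjunction of all three bounds, with
`motion_rule = "disjunction"` available for the alternative reading. All
bounds are inclusive at the boundary.

An undecidable ordering question — whether tissue signals were themselves
band-passed before regression — is resolved by the fixed order above
(regression first, then filtering), the more common order in the emulated
toolchain.

### 2. Networks (`correlation_matrix()`, `fisher_z()`, `sparsity_sweep()`)

Pearson correlations of the cleaned series are variance-stabilised with
Fisher's r-to-z (|r| clamped at 1 − 10⁻⁶ so degenerate columns cannot
overflow), the diagonal zeroed. Proportional thresholding keeps the
`k = round(S · n(n−1)/2)` strongest *positive* z edges at each sparsity
level `S` in 0.05, 0.10, …, 0.50; negative edges never count toward `k`.
Numerical conventions, fixed for reproducibility where the procedure is
silent:

* `k` uses round-half-away-from-zero (so S = 0.05 on 90 nodes keeps
  exactly 200 of 4005 edges);
* ties at the cut weight break by ascending (row, column) index;
* retained weights are the original z values — networks stay weighted,
  never binarised;
* if fewer than `k` positive edges exist the positive set is kept whole,
  with a warning.

Because every level keeps a prefix of the same ranking, edge sets are
nested across the sweep, which makes threshold-averaged metrics smooth in
`S` and gives the monotonicity property the tests assert.

### 3. Nodal metrics (`nodal_metrics()`, `region_metrics()`)

Weighted degree centrality is the pipeline-defining metric: the sum of edge
weights incident to a node. Nodal efficiency and betweenness centrality
are the supplementary metrics; their exact formulas are not fixed by the
source, so the package adopts the standard weighted conventions of the
connectome toolboxes: shortest-path distance under edge length `1/w`,
efficiency normalised by `n − 1` with unreachable pairs contributing zero,
betweenness unnormalised with equal-length multiplicities split
fractionally (Brandes). Whether the supplementary metrics were originally
computed on weighted or binarised networks is not stated; weighted is used
for consistency with degree. Metrics are computed per threshold, averaged
across the ten thresholds (a plain unweighted mean), and the left/right
homologue values of each target region (thalamus, hippocampus, caudate,
insula) are averaged into one bilateral value. Bilateral averaging after
threshold averaging is an arbitrary but fixed order — both operations are
linear means, so the result is order-independent.

### 4. Association screen (`roi_association_screen()`)

The screen computes a **partial Spearman correlation** per region: rank
all variables (average ranks on ties), residualise the two focal rank
vectors on an intercept plus the covariate ranks, and correlate the
residuals. This rank-then-residualise estimator is the common software
definition, and for one covariate it coincides with the first-order
partial-correlation recursion on rank correlations — which is what the
tests use as an independent oracle. The p-value uses the t approximation
with `n − 2 − k` degrees of freedom, two-sided. Sex enters as a 0/1 code;
ranking a binary preserves its grouping, and covariate ranks make the
adjustment invariant to monotone covariate recodings.

Benjamini–Hochberg adjustment is applied across exactly the screened
regions (four in the headline analysis; all 90 ROIs in the exploratory
variant). The permutation validation shuffles the *outcome only* (B =
5000 by default), keeping predictor and covariate rows aligned — the
reading of "shuffling the relationship between" the two focal variables
that preserves the covariate structure; this choice is recorded in the
output metadata. The empirical p uses the add-one estimator
`(1 + #{|ρ_b| ≥ |ρ_obs|})/(B + 1)`, which cannot return zero and is
floored at `1/(B+1)`.

### 5. Mediation (`bootstrap_indirect()`, `run_mediation_suite()`)

The mediation model is the PROCESS model-4 structure estimated by three
OLS fits (M ~ X + C; Y ~ X + M + C; Y ~ X + C), with X resilience, M a
region's threshold-averaged degree centrality, Y processing speed, and C =
{age, sex, education}. Covariates enter **all three** equations (the
PROCESS default; the source does not say). With identical covariate sets
the OLS identity `c = c′ + a·b` holds to machine precision and is asserted
at 10⁻⁸ on every fit. The education-mediator variant sets M = education
years and C = {age, sex}.

Inference on the indirect effect `a·b` uses case resampling (subjects with
replacement, the PROCESS convention), 5000 resamples by default, with a
**bias-corrected** (not accelerated) percentile interval, following the
stated method: `z₀ = Φ⁻¹(fraction of bootstrap estimates below the point
estimate)`, bounds at the `Φ(2z₀ ± z_{α/2})` bootstrap quantiles. When the
bootstrap distribution is median-centred on the estimate, `z₀ = 0` and the
interval reduces to the plain percentile interval. Degenerate
(rank-deficient) resamples are redrawn and counted; more than 10% aborts.
Whether the source's reported indirect estimates are standardised is not
stated; the default `standardize = TRUE` z-scores x, m and y before
fitting (the reported estimates' 0.08–0.22 range looks standardised), and
the flag is carried in the output so either scale can be produced.

## The synthetic cohort and its ground truth

No public data accompany the emulated study, so `simulate_cohort()`
generates cohorts in which every downstream claim has a known truth value.
The design plants the mediation **at the covariance level**: a per-subject
latent `u_i` scales the covariance rows of one bilateral target region, so
the planted effect maps directly onto degree centrality and the population
value of the mediator is analytically computable from the covariance
matrix (a property the tests exploit).

The generative chain, all effects on standardised scales:

* resilience `X_i` ~ N(28.4, 5.63²) truncated to [0, 45], rounded to the
  integer scale — the emulated cohort's observed marginal;
* latent `u_i = a·z(X_i) + ε_u` with `a = −0.5`, `sd(ε_u) = 0.8`;
* covariance modulation `d_i = 0.44 · 1.5 tanh(u_i/1.5)`: near-linear
  over typical draws, soft-clipped so that the modulated
  compound-symmetry matrix (base correlation 0.3) stays positive
  definite even for extreme `u_i` — a hard requirement, since repairing
  an indefinite matrix by shrinkage would distort the planted signal
  non-monotonically;
* processing speed `Y_i = b·u_i + c′·z(X_i) + β_age z(age) + β_edu z(edu)
  + β_sex sex + ε_y` with `b = −0.4`, `c′ = −0.05`,
  `β = (−0.2, +0.3, 0)` and `sd(ε_y) = 0.6`, mapped to the
  symbol–digit scale (mean 53.9, SD 10.7) and rounded to a non-negative
  integer;
* age uniform on 60–79, sex Bernoulli(73/101), education
  N(12.2, 4.67²) truncated at 0 — the emulated marginals;
* ROI series: stationary multivariate AR(1) (coefficient 0.3, a typical
  lag-1 autocorrelation at TR = 2 s) whose innovation covariance is the
  subject's modulated matrix; the common AR coefficient leaves the
  cross-ROI correlation structure equal to that of the innovation
  covariance;
* motion: a mean-reverting six-parameter random walk with rare large
  spikes (default per-volume probability 0.005) that produce isolated
  FD exceedances; tissue/global signals as smooth low-frequency series.

The sign structure mirrors the emulated finding: `a < 0` (higher
resilience, lower target connectivity) and `b < 0` (lower connectivity,
faster speed) give negative degree–behaviour correlations for both
behaviours and a *positive* indirect effect `a·b` with no direct effect.
Effect sizes are not reported quantities anywhere in the source; the
defaults were chosen once so that the planted effect is reliably
detectable under the study's own dimensions (n = 101, 90 ROIs, 235
analysed volumes) while remaining in the realistic range of
brain–behaviour correlations (|partial ρ| ≈ 0.3–0.6). Two constraints
shaped them, and both are measurement-theoretic rather than tuning:
estimated degree centrality is an imperfect proxy of the latent (proxy
correlation λ ≈ 0.9 at 235 band-passed volumes — the band-pass keeps only
≈ 42 of 117 frequency bins, which is the dominant noise source), and
proxy error leaks a spurious positive component `a·b(1 − λ²)/(1 − λ²a²)`
≈ +0.05 into the *observable* direct effect even when the latent direct
path is zero. Because the emulated finding is full mediation *as
observed* — a nonsignificant direct effect in the fitted model — the
default `c′ = −0.05` offsets that attenuation leak so the observable
direct effect is centred at zero. A cohort intended to test the leak
itself can simply set `path_c_prime = 0`. For the same reason the
package's inferential statement about the direct path is its
bias-corrected bootstrap interval (case resampling captures the extra
variability the measured mediator induces in c′, which the OLS standard
error understates).

What the generator does **not** emulate: voxel-level imaging artefacts,
physiological noise spectra, spatially heterogeneous connectivity (the
base covariance is compound-symmetric), scanner drift, or realistic
lifespan covariance between age and behaviour (age, sex and education are
independent of resilience by construction). Consequently, passing
end-to-end tests shows the *inferential chain* is sound — that planted
covariance effects of realistic size propagate through cleaning,
thresholding and rank-based inference to correct mediation conclusions,
and that null cohorts do not — not that the pipeline is robust to every
artefact of real fMRI.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
degree against row sums; nodal efficiency against a hand-rolled
Floyd–Warshall; betweenness against exhaustive simple-path enumeration
(n ≤ 8, where enumeration is exact and fast — it is factorial in n);
partial Spearman against the closed-form first-order recursion; the BH
step-up against its printed worked examples; confound regression against
a normal-equations solve. Calibration studies use Monte-Carlo sizes
chosen to give binding checks at reasonable runtimes: permutation type-I
error over 500 replicates of n = 101 with B = 1000; mediation coverage
and type-I over 200 replicates with 1000 bootstrap resamples (the floor
the package itself enforces for reported CIs); the end-to-end synthetic
replication over 25 master seeds at the full study dimensions with 1000
bootstrap resamples. The 5000-resample/5000-permutation defaults are what
analyses of real data should use; the calibration studies scale them down
only because they repeat the entire procedure hundreds of times.

## Known limitations

* Proportional thresholding with very few positive edges (heavily
  negative matrices) degenerates to "keep all positive edges"; the
  warning is the only guard.
* The ideal-filter band-pass assumes a regular temporal grid; scrubbed
  volumes are censored by regression, not removed, so the grid stays
  regular by construction.
* The bias-corrected interval can be unstable when the bootstrap
  distribution is heavily discrete (small n with many ties); the package
  clamps the bias fraction away from 0/1 rather than failing.
* The permutation test's outcome-shuffling preserves covariate alignment
  with the predictor; under strong covariate–outcome confounding a
  Freedman–Lane style residual permutation would be more exact. The
  simpler scheme is what the emulated analysis describes, and its type-I
  calibration is verified directly.
* `run_mediation_suite()` fits one mediator at a time; multiple-mediator
  and alternative-ordering models are out of scope.
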