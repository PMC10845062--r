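---
title: "deltacwas: models, design choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltacwas: models, design choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltacwas)
```

## The analysis model

`deltacwas` implements a longitudinal connectome-wide association study
(CWAS). The unit of analysis is the *edge*: an unordered pair of ROIs from a
parcellation that mixes a cortical functional atlas (each parcel labeled
with a resting-state network) and a subcortical set. Connectomes are raw
("unstandardized") pairwise Pearson correlations of ROI time series; an
optional Fisher z-transform exists for sensitivity analyses
(`build_connectome(..., fisher_z = TRUE)`) and defaults off, matching the
common practice of analyzing raw r for correlation-difference statistics.
Connectivity change is the arithmetic difference ΔrsFC = rsFC(TP2) −
rsFC(TP1), edge-wise.

The workhorse regression, fit independently at each of the P(P−1)/2 edges,
is

$$\mathrm{symptoms}_{TP2,i} = \beta_0 + \beta_\Delta\,\Delta\mathrm{rsFC}_{e,i}
  + \beta_b\,\mathrm{rsFC}^{TP1}_{e,i} + \beta_s\,\mathrm{sex}_i
  + \varepsilon_i .$$

Controlling for the same edge's baseline level separates "where you ended
up relative to where you started" from "where you started"; sex is a binary
covariate. Residual df is n − 4. With `standardize = TRUE` (the default)
the outcome and both continuous regressors are z-scored per edge, so
$\beta_\Delta$ is a standardized coefficient; sex stays 0/1 and its
coefficient is reported together with the coding (default: first level
alphabetically → 0). Standardization never changes t or p for slope terms
(an invariance the suite tests exactly); it only fixes the reporting scale.

Cross-sectional variants (`fit_cross_sectional`) regress the concurrent
symptom score on the rsFC level at one time point with sex only, for
compatibility with single-time-point designs.

### Row-wise FDR

Multiple-comparison control uses the Benjamini–Hochberg step-up procedure
applied *independently to each ROI row* of the connectivity matrix: for ROI
r, the P−1 raw p values of edges incident to r are adjusted together.
Consequences, implemented deliberately:

* every edge (a, b) carries **two** adjusted p values, one per endpoint
  row; there is no single "the" adjusted p of an edge;
* all per-ROI quantities — significant-edge counts
  (`count_significant`), network frequencies (`network_frequency`), hub
  scores (`hub_scores`) — read the row of the ROI being reported;
* the procedure is more liberal than connectome-wide BH and, unlike
  cluster-based corrections, it does not privilege large clusters; a small
  subcortical nucleus with a handful of true associations can reach
  significance in its own row.

Significance uses `p_adj ≤ q` (inclusive) with two-sided p throughout.
Degenerate edges (zero-variance regressor, rank-deficient design) are
flagged and carried as `NA`, never dropped, and the row's test count m
counts valid tests only. The BH step (sort, scale by m/i, cumulative
minimum from the largest p, cap at 1) is implemented in the package
(`bh_adjust`); `stats::p.adjust(method = "BH")` and a literal brute-force
transcription serve as independent oracles in the test suite.

### Cortical integration, ratio, ROC

The *cortical integration* of a subcortical seed set is the per-subject
mean of its connectivity (level or Δ) to all cortical ROIs — a scalar per
subject computed over exactly |seed set| × (number of cortical ROIs) edges.
The integration regression mirrors the edge model with the block means as
regressors:

$$\mathrm{symptoms}_{TP2} \sim \overline{\Delta\mathrm{rsFC}}_{seed}
  + \overline{\mathrm{rsFC}^{TP1}}_{seed} + \mathrm{sex} + C .$$

It is fit through `stats::lm` — a code path independent of the mass edge
engine — and the suite asserts that both engines agree to 1e−10 on a
synthetic one-edge dataset holding the integration means. Model reports
carry per-term 95% CIs (β ± t₀.₉₇₅(df)·se) and whole-model R², F and p,
with the R²–F identity asserted at construction. The seed set is
configurable (a single lateralized nucleus and a bilateral pair are both
ordinary choices); nothing is hardcoded.

`integration_ratio` forms the per-subject ratio of two seeds' integration
*levels* and correlates it with a behavioral score (Pearson by default,
Spearman by flag; df = n_valid − 2; subjects with numerically zero
denominators are flagged out rather than producing infinities).

`roc_percentile_sweep` dichotomizes the outcome at each percentile of a
grid (default 50, 55, …, 95) and computes the AUC of a per-subject score
against that labeling with the rank-based (Mann–Whitney, midranks)
estimator, which makes AUC exactly invariant under strictly monotone score
transforms. Two conventions the literature leaves open were fixed and
documented here: positives are subjects **strictly above** the percentile
threshold, and the 100th percentile (empty positive class) is reported as
an undefined row rather than an error. The default pipeline score is the
sign-aligned integration change of the seed set, not the full-model
prediction; a model-prediction score can be substituted by the caller.

### Two-group contrast

The patients-versus-controls analysis fits `rsfc ~ group + sex` (main
effects, no interaction — sex enters as a control variable only) per edge
on a single-session cohort and reports the group effect as F with 1
numerator df. For a two-level factor the Type-II F of the group term equals
the squared t of the dummy-coded OLS coefficient, which is how it is
computed; the identity is asserted against `lm` on random edges. Direction
is the sign of the patient-minus-control adjusted mean. Row-wise BH applies
unchanged. Equal-n synthetic fixtures make the Type-II choice inert but
testable; with unbalanced real data the dummy-t route *is* Type II for this
one-df term.

## The synthetic cohort generator

Real cohorts for this design are access-restricted, so validation runs on
simulated data with known truth (`simulate_cohort`). The generative model,
on the standardized scale:

* sex ~ Bernoulli(1/2); a latent sex-adjusted symptom factor r ~ N(0, 1);
* the follow-up score is
  `sym = γ(sex − 1/2) + sqrt(1 − γ²/4)·r`, which has unit variance by
  construction; γ defaults to −0.24, echoing the magnitude of the sex
  coefficient reported for painful-symptom scores at this scale;
* a planted edge with coupling $b_e$ has
  `Δ_e = σ_Δ (b_e·r + sqrt(1 − b_e²)·ε)`, null edges are pure noise
  `σ_Δ·ε`;
* baselines are a population mean connectome (within-network cortical
  edges 0.30, all other edges 0.05) plus between-subject noise
  (sd 0.10); TP2 = TP1 + Δ with σ_Δ = 0.10; all correlations are clipped
  to ±0.999 with the clip rate monitored — more than 1% clipping aborts
  with a dedicated condition instead of silently distorting the tails.

With this construction the population standardized partial coefficient
recovered by the edge model is $b_e\sqrt{1-\gamma^2/4} \approx 0.993\,b_e$
— the recovery criteria (±0.02 at b = 0.5 and b = −0.18) are met by
algebra, not tuning. The small attenuation exists because the model
standardizes the outcome by its *marginal* sd while the planted coupling is
defined against the sex-adjusted factor; it is documented rather than
hidden. `symptom_noise_sd` (default 0) mixes extra measurement noise into
the outcome and attenuates recovered couplings by 1/√(1+sd²) — useful for
robustness studies, deliberately not part of the default stated world so
that recovery criteria stay interpretable.

`integration_block_effects` inverts the block-mean algebra: planting the
same coupling b on all m seed-to-cortex edges yields an integration
coefficient `g·b/√(b² + (1−b²)/m)`; the helper solves for b given the
target coefficient, so integration-level effects can be planted exactly.
One consequence worth internalizing: an integration effect of −0.18 spread
over 48 edges puts only b ≈ −0.027 on each edge — invisible to edge-wise
testing, obvious to the block mean. The generator reproduces this
dissociation, which is precisely the argument for carrying both analyses.

Defaults: 48 cortical ROIs over 6 networks + 6 subcortical ROIs (a
desk-scale stand-in for a 256-parcel atlas + basal ganglia; full size
generates fine but is not required by tests), n = 200 subjects.

In `mode = "timeseries"` the generator first draws each subject's target
connectomes as above, projects each to the nearest valid correlation matrix
(Higham alternating projections with Dykstra correction, iteration-capped,
final eigenvalue floor at −1e−12 — implemented in
`nearest_correlation`), draws T multivariate-normal samples, and builds
connectomes from the series with the same `build_connectome` users call.
Estimates converge entrywise to the targets as T grows (asserted at
T = 5000, tolerance 0.05).

The two-group generator plants patient-minus-control mean shifts (in units
of the between-subject sd) on chosen edges; phenotypes carry only the sex
effect, so group structure lives exclusively in connectivity.

### What a green test does not establish

The generator draws independent Gaussian edge noise. Real connectome data
have correlated edges (shared ROI time series induce dependence between
edges sharing an endpoint), autocorrelated BOLD noise, site and scanner
effects, motion artifacts, and non-Gaussian tails. None of these are
modeled; green FDR-control tests therefore certify the procedure under
independence, not under arbitrary positive dependence (BH is known to be
conservative under PRDS dependence, but the simulation does not probe
that). Time-series mode adds realistic estimator noise to the connectome
step but still uses white Gaussian series. Preprocessing (motion
correction, ICA denoising, filtering) is explicitly upstream of this
package: it consumes cleaned ROI series or connectomes as given.

## Numerical and design choices

* **Edge identity**: canonical unordered pair with roi_a < roi_b, 0-based
  ids, row-major upper-triangle order; `vectorize_edges`/
  `devectorize_edges` are an exact bijection, asserted on random inputs.
  Input matrices may be asymmetric up to 1e−8 (averaged with the
  transpose); worse asymmetry errors.
* **Mass OLS**: per-edge QR (`.lm.fit`) inside a vectorized assembly; the
  test oracle is an explicit normal-equations solve. Agreement to 1e−8 on
  random instances is an acceptance criterion.
* **df bookkeeping**: df_resid = n − (k + 1) with k regressors plus
  intercept — 686 at n = 690 for the four-parameter longitudinal model.
  Printed sources sometimes also quote t(n − 1) for the same model; this
  package reports the standard residual df only.
* **Complete-case assembly**: subjects missing either time point or any
  phenotype field are dropped and logged; no imputation. Duplicate subject
  ids are an error.
* **Sex coding**: configurable two-level map; default assigns 0 to the
  alphabetically first level. The sign of the sex coefficient is
  coding-dependent and is only interpretable with the coding, which the
  manifest records.
* **Ties in ROC**: midranks; ties in BH: stable order-based step-up (ties
  share the adjusted value by the cumulative-minimum step).
* **Collinearity**: the integration model records a warning in its report
  when the design's exact condition number exceeds 1e4 instead of failing.
* **Config format**: the declarative run config is JSON (readable,
  diffable, no extra dependency); flags override keys; the manifest echoes
  every effective setting so there are no silent defaults.

## Limitations

* Hub scores and frequency tables are per-ROI scalars; projecting them
  onto volumetric atlas maps for rendering is out of scope.
* No network-based statistic or permutation maxT correction is provided;
  the row-wise BH choice is a sensitivity-oriented design decision, not a
  claim of optimality.
* The group ANOVA supports exactly two groups and one binary covariate
  plus optional extra numeric covariates via the edge-model hook; factorial
  designs beyond that are not implemented.
* Statements about *which* anatomical pathway a significant seed reflects
  are interpretation, outside the package's claims.
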