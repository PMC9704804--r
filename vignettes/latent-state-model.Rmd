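---
title: "Binary latent states and analog variability of synapse sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary latent states and analog variability of synapse sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinestates)
```

## The model

Synapse sizes between layer 2/3 pyramidal cells — measured either as
spine-head volume (µm³) or as synaptic-cleft voxel count — span two orders
of magnitude and are strongly right-skewed, so all modelling happens on
log10-transformed sizes. The core model is a two-component normal mixture
on the log scale, read as a latent-variable model: each synapse carries a
hidden binary state \(H \in \{S, L\}\) drawn by a biased coin (the mixture
weights), and conditional on the state its log10 size is normal,

\[
V \mid H = h \sim \mathcal{N}(\mu_h, \sigma_h^2), \qquad
P(H = L) = w_L .
\]

The size of a synapse therefore decomposes into a *binary* component (which
state it is in) and an *analog* component (the log-normal scatter within
the state).

For *dual connections* — directed cell pairs joined by exactly two synapses
— the model is extended to a joint distribution over the state pair
\((H_1, H_2)\), with the same two emission components shared by both
synapses. The four probabilities \((p_{SS}, p_{SL}, p_{LS}, p_{LL})\)
quantify how strongly the two latent states covary; their phi coefficient

\[
\varphi = \frac{p_{SS}\,p_{LL} - p_{SL}\,p_{LS}}
               {\sqrt{p_{1S}\,p_{1L}\,p_{2S}\,p_{2L}}}
\]

is the Pearson correlation of the two binary states. Conditional on the
states, the two sizes are assumed independent — the package's correlation
analyses exist to test exactly that assumption.

## Fitting

`fit_mixture()` maximizes the mixture likelihood by EM, initialized by
k-means with as many clusters as components. Numerical choices: the EM
stops when the relative log-likelihood change falls below `tol = 1e-8`
(2000 iterations cap); component standard deviations have a floor of
`1e-3` log10 units, and a fit whose component collapses below it is
restarted up to 5 times from perturbed inits before a degeneracy error.
Components are always reported sorted by ascending mean and labelled S, L.
The EM inner loop is compiled (Rcpp) because the bootstrap procedures below
refit the model hundreds of thousands of times.

Cleft sizes only exist above the 50-voxel detection cutoff, so cleft fits
renormalize each component over \([\log_{10} 50, \infty)\)
(`truncation_lower = log10(50)`); the truncated M-step has no closed form
and is solved numerically (an ECM step). Spine-volume fits are
untruncated.

`refit_weights()` re-estimates only the weights on a subset of synapses
(single, dual, triple connections) with the components frozen at the
all-synapse fit: under the two-state model the components are
subset-invariant while the state occupancies may shift.
`bootstrap_weight_sd()` reports the SD of the fitted small-component weight
over nonparametric resamples (default B = 200).

`fit_pair_model()` fits the dual-connection joint as a two-state chain of
length two with tied normal emissions. Chains are trained on ordered
pairs, but a dual connection's synapses have no inherent order, so every
pair enters twice, once per order. Duplication makes the mixed states
equal in expectation; residual numerical asymmetry is removed by averaging
\(p_{SL}\) and \(p_{LS}\) after EM (rather than by constrained EM — the
averaged estimate is the symmetric projection of an already symmetric
target). Tying the emissions across the two positions is likewise a
modelling choice: a single pair of S/L components describes both synapses.

## The bimodality test

A two-normal mixture can be unimodal or bimodal depending on its
parameters; with equal weights and standard deviations the density is
unimodal exactly when the means are at most \(2\sigma\) apart.
`count_modes()` counts density maxima numerically — the derivative's sign
is evaluated in log space on a fine grid between the two means, where all
stationary points must lie — so it also covers unequal weights and
standard deviations; the analytic equal-weight rule serves as a test
oracle only.

`bimodality_test()` compares the best bimodal and best unimodal fits by a
likelihood ratio. The unimodal side (`unimodal_constrained_fit()`)
maximizes the mixture likelihood subject to a single density mode, by
penalized Nelder–Mead from multiple starts (the free fit contracted to the
unimodal boundary, the single-normal fit, and perturbations of both); the
returned solution is always projected onto the feasible side, and
near-ties are resolved toward the smaller mean separation. The free side
uses a multi-start EM (k-means plus quantile-split inits, best
log-likelihood wins): mixture likelihoods are multimodal, and a single
init routinely misses weakly bimodal optima, which would degenerate the LR
at zero. When the free fit is itself unimodal the LR is 0.

Because the unimodal hypothesis is a boundary subset of the parameter
space, the asymptotic null is the boundary-corrected mixture
\(\tfrac12\delta_0 + \tfrac12\chi^2_1\): \(p = \tfrac12 P(\chi^2_1 \ge
\mathrm{LR})\) for positive LR and \(p = 1\) at LR = 0. The exact degrees
of freedom behind such boundary corrections are convention-dependent, so a
parametric bootstrap is provided as the convention-free alternative and is
the authoritative cross-check.

Two design points in the bootstrap deserve explanation:

* **Null representative.** Bootstrap replicates are drawn from the fitted
  *single normal*, the interior representative of the unimodal family, not
  from the constrained boundary fit. When the free fit is bimodal, the
  constrained fit sits exactly on the unimodal/bimodal boundary (its
  density has a flat dip); samples from such a boundary model re-fit as
  bimodal far more often than samples from an interior unimodal truth,
  which we measured to make the test severely conservative (rejection
  0.008 instead of the nominal 0.05 on single-normal nulls at n = 320).
  Drawing from the interior representative keeps the observed and
  bootstrap LR statistics exchangeable, and the measured rejection rate at
  the 0.05 level is 0.050 over 500 single-normal replicates.
* **Sequential stopping and pruning.** The bootstrap stops early once 10
  replicates have met or exceeded the observed LR (Besag–Clifford
  sequential p-value): the accept/reject decision at the 0.05 level with
  B = 199 is unchanged, and the many replicates that would only confirm a
  large p are skipped. Within a replicate, the constrained fit is skipped
  whenever a cheap upper bound on its LR — against the better of the
  single-normal fit and the free fit projected to the unimodal boundary,
  both dominated by the constrained optimum — already falls below the
  observed LR, since only the exceedance comparison matters.

## Correlation analyses

`state_conditioned_resample()` implements the conditional-independence
test: each iteration assigns every dual pair to the target state (SS or
LL) by an independent biased coin weighted by the pair's posterior
probability of that state, and records Pearson's r of the included pairs
(10,000 iterations by default; iterations with fewer than three included
pairs are redrawn so the count stays fixed). "No correlation" is
summarized by the mean and SD of the r distribution and by the one-sided
exceedance fraction \(P(r \le 0)\). Note an intrinsic attenuation: the
posterior-weighted inclusion restricts the size range, so even a genuine
within-state correlation of 0.5 appears as a resampled mean r around
0.2–0.25 — still many SDs away from the null, which is what the positive
controls assert.

`residual_correlation()` subtracts each synapse's state emission mean and
correlates the residuals. The state is assigned by MAP under the marginal
mixture given *that synapse's own size only*. Partner-blindness here is
essential: assigning states from the pair posterior feeds the partner's
size into the subtracted component through the correlated joint, which by
itself induces a spurious negative residual correlation (about −0.06 on
model-consistent data at n = 2000, where the partner-blind convention
gives +0.04 ± 0.03). Hard assignment still attenuates injected analog
correlations (misclassified synapses add ±Δµ outliers to the residuals),
so the positive controls test detection, not unbiased recovery. The
partner-dependent conventions remain available as options for comparison.

`control_pair_analysis()` draws synapse pairs sharing only one endpoint
(same presynaptic cell, different postsynaptic cells — or the converse)
from the synapses of dual connections; each eligible cell contributes one
pair per draw, and pairs sharing both endpoints are excluded by
construction and audited per draw. With 1000 draws (default) the per-draw
phi (of MAP states) and Pearson r are summarized as mean ± SD.

`distance_split_analysis()` splits dual connections at the median
inter-synapse Euclidean distance and fits the pair model per group,
probing whether latent-state correlations are confined to nearby pairs.

## The synthetic connectome

`generate_connectome()` emulates the statistical structure the analysis
assumes, so the full pipeline runs without any external data: per
connection a synapse count from the empirical multiplicity distribution
(89.1% single, 9.22% dual, …), a first latent state from the joint's
marginal, subsequent states from the conditional of the configured
symmetric joint given the previous state, sizes drawn independently per
state from the S/L components, and centroids uniform in a
250 × 140 × 90 µm³ volume. Defaults are the study conditions: the
dual-connection joint (0.490, 0.0885, 0.0885, 0.333) and the all-synapse
components S(−1.42, 0.24), L(−0.77, 0.22) in log10 µm³. Cell pools
default to about one cell per five connections, matching the study's
cell-to-connection ratio, so that control pairings have eligible cells.

Three deliberate limitations. The chain extension to connections with
three or more synapses is an extrapolation — only pairs are modelled by
the joint. Because the chain starts from the joint's marginal, the latent
marginal is identical across multiplicities: the generator reproduces the
dual-connection correlation structure but *not* the empirical enrichment
of L states with synapse count, which is a property of the real data and
not implied by the pair model. And coordinates are uniform with no
spatial model, so distance-dependent analyses on synthetic data test
invariance, not distance effects. Ground-truth states travel in
dot-prefixed columns that no analysis function reads.

`generate_mixed_population()` emulates tables pooled over axons of mixed,
unknown cell types ("orphan axons"): each connection draws one population,
and sizes come from that population's single log-normal — no latent S/L
structure, so pooling populations with distinct means smears the
distribution and bimodality should *not* be detected.

`simulate_pairs()` draws dual-connection pairs directly from a joint +
emissions specification and can inject a within-state analog correlation
as a deliberate model violation for power checks.

## Problem sizes used in the test suite

Tests mirror the study's scales where that is what is being claimed
(n = 1960 synapses, 160 dual connections, n = 320 for the bimodality
null calibration with B = 199 and 500 replicates; parameter recovery over
50 seeds) and use smaller simulations for auxiliary property checks
(20–40 replicates, a few hundred to a few thousand synapses), chosen to
keep each property's Monte-Carlo error well inside its assertion margin.

## Reproducing the study without its data

`run_full_analysis()` chains every stage — grouping, multiplicity
statistics, mixture fits and weight refits with bootstrap errors,
bimodality tests, the pair model with phi, projections, resampling and
residual checks, controls, and the distance split — from one top-level
seed that fans out deterministically to per-stage seeds, and writes a
JSON report plus CSV tables. Two runs with the same table, configuration
and seed produce byte-identical reports. Fitting the deposited synapse
tables of the original study only requires pointing
`read_synapse_table()` at them with a column-mapping sidecar; all
analyses downstream are measurement-agnostic.

## Known limitations

* Mixtures with more than two components, and non-normal emission
  families, are out of scope.
* The pair model covers chains of length two only; triples and beyond are
  analyzed solely through weight refits.
* The LR test against a single normal uses a χ²(3) reference by default;
  mixture LRTs are known to be irregular, and the parametric bootstrap in
  `lrt_vs_single(bootstrap = TRUE)` is the robust alternative.
* Phi estimated from n = 160 dual connections has a sampling SD of about
  0.095 under the study's parameters — about a third larger than the
  floor set by knowing the true states — so single-dataset phi values at
  this scale carry an uncertainty of roughly ±0.2 at two SDs.
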