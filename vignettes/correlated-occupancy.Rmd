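---
title: "Occupancy estimation with Markov-correlated detections on transect segments"
author: "occuCorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy estimation with Markov-correlated detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuCorr)
```

## The model

`occuCorr` estimates habitat occupancy from sign surveys in which each site
(a grid cell) is sampled by a single walk along a trail divided into
contiguous segments. The sampling unit design creates a specific dependence
problem: segments are spatial, not temporal, replicates, and sign left by an
animal clusters along the trail. Treating segments as independent replicates
(the standard single-season model) understates uncertainty and biases the
occupancy estimate.

The hierarchical model has three levels for site $i$ and segments
$k = 1, \dots, K$:

* **Occupancy.** $Z_i \sim \mathrm{Bernoulli}(\psi_i)$ with
  $\operatorname{logit}\psi_i = \beta_0 + \sum_j \beta_j x_{ij}$.
* **Local presence.** Within an occupied site, presence of sign on segment
  $k$, $z_{ik}$, follows a two-state Markov chain:
  $\Pr(z_{i1}=1) = \pi$, $\Pr(z_{ik}=1 \mid z_{i,k-1}=0) = \theta^0$,
  $\Pr(z_{ik}=1 \mid z_{i,k-1}=1) = \theta^1$. $\theta^1 > \theta^0$
  expresses the clustering of sign.
* **Detection.** $y_{ik} \mid z_{ik}=1 \sim \mathrm{Bernoulli}(p_{ik})$ with
  $\operatorname{logit} p_{ik} = \alpha_0 + \sum_j \alpha_j x_{ij}$, and
  $y_{ik} = 0$ deterministically when $z_{ik} = 0$ or $Z_i = 0$.

The site likelihood marginalises $z$ by the forward algorithm in $O(K)$:
with emission terms $e_k(z)$ ($e_k(1) = p_k^{y_k}(1-p_k)^{1-y_k}$,
$e_k(0) = \mathbf{1}[y_k = 0]$, and $e_k(\cdot) = 1$ for an unsurveyed
segment) the forward pass yields
$F_i = \Pr(\text{history} \mid \text{occupied})$ and

$$\Pr(y_i) = \psi_i F_i + (1-\psi_i)\,\mathbf{1}[\text{no detection observed}].$$

All probability parameters use the logit link. The total negative
log-likelihood is vectorised over sites, with per-segment rescaling of the
forward variables so that 20-segment (or much longer) transects cannot
underflow. `siteLikelihoodBruteforce()` is an exact enumeration over the
$2^K$ latent sequences, exponential in $K$, retained purely as an
independent oracle; the test suite asserts agreement with the forward
recursion to $10^{-10}$ across random parameter draws and histories, that
history probabilities sum to one, and the two analytic collapses
($\theta^0=\theta^1=\pi=1$ reduces to the standard model;
$\theta^0=\theta^1=\pi=\theta$ with constant $p$ reduces to the standard
model with $p' = \theta p$).

### The first-segment probability $\pi$

The probability that sign is locally present on the *first* segment is not
pinned down by the chain unless one assumes stationarity. We treat $\pi$ as
a free parameter on the logit scale by default, because that choice is what
reproduces the parameter counts of the model family this package mirrors
(e.g. $K = 14$ for a global six-covariate occupancy structure with three
detection covariates: $7 + 4 + \theta^0 + \theta^1 + \pi$). Two alternatives
are available in `occuSpec()`: `piMode = "stationary"` sets
$\pi = \theta^0 / (1 + \theta^0 - \theta^1)$ (the chain equilibrium, one
parameter fewer) and `piMode = "fixed"` pins it to a constant.

### Missing segments

Segments that could not be surveyed (terrain, jurisdiction, logistics) are
`NA` in the detection matrix. They contribute emission factor 1 while the
chain still transitions across them — the standard hidden-Markov convention
— rather than freezing the chain, because local presence on the ground does
not pause when the observer does. Missingness is treated as a fixed design
feature: the goodness-of-fit bootstrap conditions on the observed
missingness pattern instead of resimulating it.

## Covariate handling

Field covariates recorded per segment (termite mounds, fruit plants, the
three disturbance components) are aggregated to the site level as the
proportion of *surveyed* segments with presence. The three disturbance
indicators (humans, livestock, fire) are pooled by taking, per segment, the
maximum of the three and then averaging over surveyed segments. Pooling
before averaging keeps the disturbance score a proportion of segments (a
segment disturbed in two ways is one disturbed segment, not two); averaging
the components separately and summing was a defensible alternative and is
deliberately not offered, to keep one documented definition.

All covariates — proportions and continuous remote-sensing scores alike —
are z-scaled (sample sd, $n-1$ denominator) before modelling, so a
coefficient is the change in log-odds per 1 SD of the covariate. The
centre/scale pairs are stored in the table and are reused by
`applyScale()` when predicting at new sites, and by `unscaleCovariates()`
to recover the raw values exactly. A Pearson correlation screen over all
covariate pairs (default flag at $|r| \ge 0.5$) is reported before
modelling.

## Estimation and uncertainty

`fitOccu()` minimises the NLL with BFGS from multiple starting points:
start 1 is the zero vector on the link scale (every probability 0.5), the
rest add standard-normal jitter drawn from the user's seed. Multimodality
is a real risk in this model family, particularly when $\theta^0$ or $\pi$
drifts to a boundary, hence the default of 10 starts; simulation harnesses
in this package use 1–2 starts because the intercept-dominated
configurations they fit are well-behaved and the cost scales linearly.

The variance–covariance matrix is the inverse of a central-difference
Hessian of the NLL at the optimum (step $10^{-5}$). A fit is declared
converged when the optimiser reports success, the Hessian is positive
definite, and the numerical gradient norm is below
$10^{-4}(1 + |\mathrm{NLL}|)$ — a relative criterion, because an absolute
gradient threshold is not meaningful against finite-difference truncation
error on an NLL of magnitude several hundred. Non-positive-definite
Hessians (typically boundary optima: no detections, $\theta^0 \to 0$) mark
the fit as not converged rather than being silently pseudo-inverted, and
real-scale parameters within $10^{-4}$ of 0 or 1 are listed in
`boundaryFlags`.

Real-scale estimates (`realParameters()`, `predictPsi()`) report the
delta-method SE through the inverse-logit (matching the conventional
"estimate ± SE" presentation), while the 95% *limits* are a Wald interval
on the logit scale back-transformed to $(0,1)$. The two constructions were
compared by simulation at the package's validation conditions: symmetric
real-scale intervals undercover detection probability (about 85% observed
coverage at nominal 95%) because the availability–detection ridge makes
the sampling distribution of $\hat p$ heavily skewed, whereas the
back-transformed logit intervals hold 92–95% for every parameter. The
logit construction — also what PRESENCE-lineage software reports for real
parameters — is therefore the package's choice. Coefficient intervals
(`coefTable()`) remain symmetric Wald intervals on the link scale, which
is how coefficient tables in this literature print them. Detection
probability is reported at the
covariate means (zero on the z-scale) — a weighted average over sites is an
alternative reading of a single printed "p", and the covariate-mean
convention is the package's documented choice.

## Model selection and averaging

Model comparison uses AIC ($-2\ell + 2K$), Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ and model likelihoods
$e^{-\Delta_i/2}$; ties in AIC rank the smaller $K$ first. AICc and QAIC
are deliberately not offered (c-hat is reported by the GoF module but not
used to re-rank).

`twoStepSelection()` implements the two-step strategy used with spatial
sign surveys: first hold occupancy at the *global* structure (all candidate
covariates) and rank detection structures; then hold the best detection
structure fixed and search occupancy structures. The occupancy search is
the null model, every univariate model, and `stepwiseAdditive()` expansions
from the best univariate — a covariate is retained only if its addition
strictly decreases AIC, any amount counting as an improvement. The null
model under the *second-best* detection structure is added when step 1
produced more than one structure, since a near-tied detection model
deserves representation in the final set. Models that fail to converge are
dropped from tables with a warning rather than poisoning the ranking.
Model averaging (`modelAverage()`) spans *all* converged step-2 models, not
a ΔAIC-truncated subset; the occupancy scalar each model contributes is the
unweighted mean of its site-level $\hat\psi_i$, and the unconditional SE is
$\sum_i w_i \sqrt{\mathrm{SE}_i^2 + (\hat\theta_i - \bar\theta)^2}$,
combining within- and between-model variance.

## Goodness of fit

`pearsonChisq()` computes the MacKenzie–Bailey Pearson statistic on
detection histories: sites are grouped into cohorts sharing a missingness
pattern and covariate profile (with continuous site covariates each site is
its own cohort), each cohort's observed unique histories contribute
$(O_h - E_h)^2 / E_h$, and one pooled complement category per cohort
absorbs the unobserved probability mass. `gofBootstrap()` simulates B
datasets from the fitted model (covariates and missingness held fixed),
refits each starting from the observed MLE, and reports
$p = (1 + \#\{X^2_b \ge X^2_{obs}\})/(B+1)$ — the add-one estimator, so p
is never exactly zero — and the overdispersion factor
$\hat c = X^2_{obs} / \overline{X^2_{boot}}$. Bootstrap refits that end at
a boundary still yield a usable statistic and are kept; only optimiser
failures are discarded, and more than 20% of them aborts the procedure.
The default B of 1000 is a convention; the calibration studies in this
package run B = 100, which is sufficient to place a rejection decision at
$\alpha = 0.05$.

## What the simulator does and does not emulate

`simulateDataset()` generates data from exactly the hierarchical model
above, with defaults chosen to mirror the survey design this package grew
out of: 45 grids, 20 segments of 200 m, occupancy near 0.7, per-segment
detection near 0.25, a sticky chain ($\theta^0 = 0.3$, $\theta^1 = 0.7$,
$\pi = 0.45$), termite/fruit segment-indicator covariates with presence
probabilities 0.30/0.25, disturbance components at 0.10/0.08/0.05, and
three standard-normal remote-sensing covariates. Segment-indicator
covariates are generated independently of the detection process by default;
coefficients named after them (e.g. a `Term` effect in `alphaP`) couple
them to detection through the aggregated site-level proportion. Latent
truth (occupancy, the chain states, per-site $\psi$ and $p$) is recorded
for recovery studies.

What it does **not** emulate — and therefore what passing recovery tests do
not establish about field data: spatial autocorrelation of covariates
across the grid, the checkerboard survey geometry, sign misidentification
or decay, heterogeneity in $p$ beyond the covariate model, and
block-structured missingness beyond the simple optional "block" mode
(uniform missingness is the default).

## Problem sizes used in validation

The package's own validation studies (test suite and acceptance script)
run at: 1000 sites × 20 segments × 100 replicates for parameter recovery
(median absolute bias below 0.03 and 95% CI coverage within [0.90, 0.99]
for each real parameter); 100 meta-replicates × B = 100 at 100 sites for
goodness-of-fit calibration (rejection rate at $\alpha = 0.05$ within
[0.01, 0.10], median c-hat within (0.8, 1.25)); 1000 random draws with
$K \le 12$ for the forward-vs-enumeration check. These sizes are the
package's choices for a single-CPU validation run; the generative
parameter values are fixed by the study conditions described above and are
not tuned.

## Known limitations

* Detection covariates enter at the site level by default (`pLevel =
  "site"`); segment-level covariates are supported through `segCovs`
  matrices but are secondary and less exercised.
* Single season only: no colonisation/extinction dynamics, no multi-species
  or abundance-induced (Royle–Nichols) heterogeneity.
* Wald/delta uncertainty throughout; no profile likelihood or Bayesian
  posterior.
* The stepwise-additive search is a heuristic over the additive lattice;
  with strongly collinear covariates it can stop at a local AIC optimum —
  the collinearity screen exists precisely to keep that regime out.
* At the 45-site study scale the data carry limited information about
  $\theta^0, \theta^1, \pi$; boundary optima happen, are flagged, and
  should be read as "the chain is weakly identified here", not as point
  estimates of zero.
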