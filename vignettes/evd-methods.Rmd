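---
title: "Ecosystem vulnerability distributions: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecosystem vulnerability distributions: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regional environmental management needs to know not only how large each
stressor is at each site, but how vulnerable the local ecosystems are to
it. Vulnerability varies across a region because species assemblages and
ambient conditions vary; a nutrient level harmless in one stream may cost
another stream a substantial share of its species. `evdist` quantifies
that variation as an *ecosystem vulnerability distribution* (EVD): the
distribution, across a set of minimally disturbed reference sites, of the
stressor level at which each site is predicted to lose a chosen fraction
of its species richness. Overlaying the EVD with the regional
distribution of observed stressor levels classifies every site as
not-at-risk, at-risk or impacted, and comparing the overlays across
stressors ranks them.

The input is routine biomonitoring data: one table of environmental
measurements per site, one presence/absence table of species per site, a
list of reference sites (how those are selected — ecological judgment,
food-web metrics, stressor percentiles — is outside this package; they are
an input), and a role for every variable: stressful when it increases
(nutrients, toxic pressure), when it decreases (a habitat-quality index),
in either direction (pH), or a natural covariate that is modelled but
never treated as a stressor (drainage area).

## The model chain

**Collinearity screening.** Candidate predictors are pruned by sequential
variance-inflation-factor elimination: while any candidate has
VIF $= 1/(1-R^2) \ge 5$ (configurable), the one with the highest VIF is
removed. The paper-of-record practice in this field states the rule
without an order; highest-first removal is the standard reading and is
pinned here, with ties broken deterministically by removing the variable
later in the input order so screening is column-order invariant up to that
rule. Screening uses all modelled sites, not reference sites only, because
the species models themselves are fitted region-wide.

**Species distribution models.** Each species with at least 20 presences
(configurable) among the modelled sites — by default restricted to species
observed at reference sites — gets a logistic model of occurrence on the
standardized predictors,

$$\operatorname{logit} P(y=1) \;=\; \beta_0 + \sum_n \beta_n S_n +
\beta_n' S_n^2 ,$$

with every subset of predictors tried and a quadratic term admitted only
together with its linear term: $3^p$ candidate models per species.
Candidates are ranked by AIC; all models within two AIC units of the best
form the confidence set, and coefficients are averaged over that set with
Akaike weights $w_i \propto \exp(-\Delta_i/2)$. By default a term absent
from a model contributes zero to its average (full/shrinkage averaging);
conditional averaging is a switch. Model accuracy is summarized by
in-sample AUC (Mann–Whitney form, ties counted one half); an AUC-based
species filter exists but is off by default, reflecting its role as a
robustness check rather than a selection rule.

Standardization uses the sample mean and $n-1$ standard deviation over
the modelled sites, stored so that sweep grids and new data are projected
onto exactly the fitting scale; sweeping in native or standardized units
is therefore equivalent, which the tests verify. Fits are by iteratively
reweighted least squares (deviance change $<10^{-8}$, at most 100
iterations). Separated or non-converged candidates — flagged by a
coefficient magnitude above 15 on the standardized scale — are excluded
from the confidence set with a logged count; the intercept-only model is
always finite, so a confidence set always exists. AIC is the default
criterion; AICc is available as a switch for small samples.

**Response curves.** For each reference site and each stressor-role
variable, the stressor is swept over an evenly spaced grid between the
regional 1st and 99th percentiles (the operational reading of "excluding
extreme outliers"; configurable), extended to cover every reference
site's observed value and clipped to declared natural bounds (a toxic
pressure expressed as a fraction stays in $[0,1]$). All other variables
are held at the site's observed values. The species pool is the set of
modelled species observed at the site (or all modelled species in the
all-species variant). Expected species richness is the *sum of occurrence
probabilities* over the pool — not thresholded presences, which would give
step-like curves — and relative species richness (RSR) is that sum divided
by its value at the site's observed conditions, so RSR $=1$ at the point
of departure by construction.

**Critical levels and the EVD.** Given an impact threshold $T$ (default
5% richness loss), the critical stressor level of a site is the first
value, moving from the point of departure along the stress direction, at
which RSR crosses $1-T$, located by linear interpolation between grid
points. A curve may re-cross the threshold when optima are skewed; taking
the *first* crossing is the conservative choice and is pinned. A site
whose curve never reaches $1-T$ within the sweep range is censored at the
grid end; censored sites stay in the EVD's denominator but never count as
exceeded, so censoring can only dilute risk, not inflate it. Variables
stressful in both directions yield two EVDs (one per direction), as pH
does in practice. The EVD itself is the empirical distribution of the
uncensored critical levels across reference sites; no parametric
smoothing is applied, and the exceedance function is the step function
"fraction of reference sites whose critical level has been passed".

Two advisory flags mark stressors whose EVD should be read with care:
`low_response` when more than half the reference sites are censored (the
conductivity-like case, where opposite species responses cancel) and
`complex_response` when more than a quarter of the curves cross the
threshold at least twice (the total-nitrogen-like case). The cutoffs
(0.5, 0.25) are this package's operationalization of what is, in the
field, a judgment call; they are configurable and the flags never block
EVD emission unless every site is censored.

**Overlay and ranking.** Every regional site's observed value is projected
on the stress axis (for decrease-direction stressors, lower = more
stress) and compared with the EVD range: before it, not-at-risk; inside
it (endpoints inclusive, pinned for determinism); beyond it, impacted.
Stressors are ranked by impacted fraction, then at-risk fraction, then
name; a stressor whose regional values never reach its EVD range is "not
identified". For both-direction variables the two directional reports are
kept separate and additionally merged per site by worst case, since
practice has not settled which of the two belongs in a single ranking
figure — both outputs are emitted.

## The virtual landscape

Because real regional datasets of this kind are rarely public, the package
ships a simulator whose truth is analytic. Environmental gradients are
drawn from chosen marginals (optionally rank-correlated through a Gaussian
copula); species occurrence follows the same quadratic-logit family the
models fit — deliberately the well-specified case — written on the
standardized scale of the marginals' *theoretical* moments, so every
site's true response curve and true critical level are available in closed
form, independent of any sample. Presences are Bernoulli draws, optionally
thinned by a detection probability. Reference sites are the `n_reference`
sites with the smallest mean directional standardized stress (increase
stressors count $+z$, decrease stressors $-z$, both-direction stressors
$|z|$) — a stand-in for the ecological-status selection used with real
data, which is out of scope here.

The bundled default landscape emulates a freshwater biomonitoring region:
2000 sites, 30 species, 18 reference sites, and four gradients — a 0–100
habitat-quality index (stressor on decrease), a lognormal nutrient
concentration and a bounded toxic-pressure fraction (stressors on
increase), and a normal pH-like variable (both directions). Niche
intercepts span common to rare, so some species deliberately fall under
the 20-occurrence filter; linear responses are biased against stress and
about half the niches carry a negative quadratic term, giving unimodal
optima of varying breadth and some skew. What the simulator does *not*
emulate: spatial autocorrelation, species interactions, observation
covariance between environment and detection, and model misspecification
beyond quadratic-logit truth. Passing recovery tests on this landscape
therefore shows the chain is statistically consistent and correctly
implemented, not that real assemblages satisfy its assumptions.

## Numerical choices

- Sweep grids have 1001 points by default; with linear interpolation the
  inversion error is far below ecological precision. The truth grids of
  the simulator are ten times denser.
- The normalization invariant (RSR exactly 1 at the observed value) is
  checked by direct evaluation, not interpolation, and holds to $10^{-9}$.
- Repeated samplings of one site collapse to the per-variable median; a
  species ever observed at a site counts as present there (max), an
  assumption the data format leaves open.
- Sites missing a value in any kept predictor are dropped from fitting
  and sweeping with a logged count; reference sites hosting none of the
  modelled species are skipped with a logged message rather than aborting
  the regional analysis.
- All tabular artifacts are written with 17 significant digits, so staged
  reruns and repeated runs are byte-identical; one seed in the
  configuration governs all stochastic stages (only data synthesis is
  stochastic — fitting is deterministic).

## Problem sizes used in validation

The package's own validation (tests and the acceptance script) uses
landscapes of 200–2000 sites and 8–30 species: closed-form and oracle
checks at small $n$, coefficient and critical-level recovery at
$n = 2000$, and a 20-replicate ranking-recovery study on a two-stressor
landscape whose dominant stressor truly impacts roughly three times more
sites than the weaker one. These sizes were chosen as the smallest at
which the asymptotic claims (3-standard-error coefficient recovery, rank
correlation above 0.9) are comfortably expressed.

## Known limitations

- One stressor is varied at a time; interactions among stressors and
  among species are not modelled.
- In-sample AUC flatters model accuracy relative to cross-validation.
- The EVD inherits the reference-site selection: a different selection
  yields a different distribution, by design.
- Censoring depends on the sweep range: widening the regional quantile
  clamp can turn censored sites into finite critical levels.
- The empirical EVD is a step function; with few reference sites its
  range estimate is coarse, and the overlay classification inherits that
  coarseness.
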