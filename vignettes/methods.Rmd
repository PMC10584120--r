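---
title: "Models and methods: starvation survival, morphometrics, and carbonate chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: starvation survival, morphometrics, and carbonate chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opilioOA)
```

opilioOA implements the complete statistical analysis of a two-year,
fully crossed ocean-acidification (OA) experiment on snow crab
(*Chionoecetes opilio*) embryos and larvae: ovigerous females held at
three pH treatments (Ambient ~8.1, pH 7.8, pH 7.5) through two brooding
cycles, with larvae from each embryo treatment re-exposed to all three
pH levels in a 3 x 3 design. This vignette explains the models the
package fits, the choices behind their implementation, and what the
synthetic-data generator does and does not emulate.

## The starvation-survival model

Unfed larvae in replicate inserts (mesh-bottomed chambers, 20 larvae
each, 5 inserts per design cell) are monitored daily until death or a
7-week horizon. Cumulative mortality is modelled with a power
formulation of the logistic curve,

$$P_m(t) = \frac{1}{1 + (t/t_{50})^s},$$

where $t_{50}$ is the time to 50% mortality (LT50, days) and $s < 0$ is
a unitless slope. For negative $s$ this is exactly the CDF of a
log-logistic death-time distribution, which is what the generator draws
from and what the likelihood integrates over.

**Likelihood.** Deaths are observed daily, so a larva dying on day $d$
is interval-censored in $(d-1, d]$ and contributes
$\log[P_m(d) - P_m(d-1)]$; a larva alive at the horizon contributes
$\log[1 - P_m(49)]$. This interval (multinomial) likelihood is the
package default. A "daily-binomial" mode — each day's cumulative death
count scored against a binomial mass at $P_m(d)$ — is also provided
because survival analyses are sometimes phrased that way; its daily
terms are not independent, so it is a pseudo-likelihood kept behind a
flag for comparability, not inference. The effective sample size used
by AICc is the number of larvae (900 per year at design scale) under
the interval likelihood, and the number of insert-days under the
pseudo-likelihood; the fitted object records which.

**Factor structures and the candidate set.** $\log t_{50}$ and $s$ may
each be constant, vary with embryo treatment (E), larval treatment (L),
both additively (E+L), or freely per cell (E#L). "Varying linearly with
treatment" is implemented as factor dummy coding with Ambient as the
reference level, which reproduces the candidate set's parameter counts
exactly: K = 2, 4, 4, 6, 10 for the five $t_{50}$ structures with
constant $s$, K = 4, 4, 6, 10 for constant $t_{50}$ with varying $s$,
and K = 18 for the full-interaction model. Model ranking uses
$AICc = -2\log L + 2K + 2K(K+1)/(n-K-1)$, Akaike weights, and a
top-set flag at $\Delta AICc < 2$ (models that close are treated as
equally supported).

**Optimization.** BFGS quasi-Newton search on
$(\log t_{50}\text{-coefficients}, s\text{-coefficients})$ from a
deterministic start ($t_{50}$ at the overall empirical median death
day, $s = -3$), relative tolerance 1e-10 on the objective, with up to 5
seed-jittered restarts if the first search does not converge;
non-convergence is flagged, never silent. Interval probabilities are
floored at 1e-12 (with a warning) so that a stray parameter excursion
cannot produce $-\infty$; trial steps that under/overflow
$\exp(\log t_{50})$ are rejected inside the objective. The sign of $s$
is unconstrained — every published estimate is negative, and a fitted
$\hat s \ge 0$ triggers a validity warning instead of a bound.
All-censored cells are an error (naming the cell): $t_{50}$ is not
identifiable beyond the horizon.

## The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, at the study's design scale, from explicit seeds.

* **Death days** are continuous log-logistic draws binned to days
  (deaths observed daily means day-binning *is* the observation model)
  and censored at 49 days. Defaults reproduce the published per-cell
  best-fit parameters for each study year
  (`survival_curve_params()`), e.g. Ambient/Ambient year 1:
  $t_{50} = 6.20$ d, $s = -3.06$.
* **Larvae are i.i.d. within a cell.** The study gives no estimate of
  inter-insert overdispersion, so none is simulated by default; an
  optional log-normal insert-level effect on $t_{50}$ (`insert_sd`) is
  available for sensitivity work but off by default.
* **Morphometrics** are multivariate normal around group means with a
  shared covariance, truncated at zero by resampling (not clipping, so
  means stay unbiased at realistic noise levels where truncation is
  rare). Six larval measurements are used: carapace width (CW), lateral
  spine (LSL), dorsal spine (DSL), rostro-dorsal length (RDL), rostral
  spine (RSL), protopodite (PL), all mm.
* **Clutch outcomes** draw each female's embryo total as Poisson around
  `mean_fecundity / (1 - p_nonviable - p_unhatched)` and split it
  multinomially; Poisson is a one-parameter convenience, any count
  distribution with the right mean would serve.
* **Water series** emit daily pH/temperature and weekly DIC/TA records
  whose noise-free base is internally consistent with the carbonate
  solver.

What the generator does *not* emulate: hatch-timing asynchrony between
females, tank effects, measurement error on individual larvae beyond
the stated covariances, or embryo staging. Passing recovery tests
therefore show that the estimation machinery is correct and well
calibrated at the design's information content — not that real larvae
meet the i.i.d. log-logistic assumptions.

## Permutation multivariate statistics

Morphometric tables are z-scored per measurement (so millimetre and
square-millimetre variables weigh equally) and analysed on Euclidean
distance matrices. The permutation machinery is implemented from
scratch; vegan serves as an independent cross-check in the test suite,
never as the implementation.

* **PERMANOVA** partitions the total sum of squared distances by
  sequential projection of the Gower-centred matrix (one or two crossed
  factors); pseudo-F per term, p-values by permuting sample identities.
  With a single variable the pseudo-F reduces exactly to the classical
  ANOVA F. Permutations can be restricted to strata, which is the
  package's nesting approximation: the study's embryo analysis nests
  female within treatment, and restricting permutations within female
  (or month) approximates that design without a full nested
  partitioning, a documented scope bound rather than an asserted
  equivalence.
* **PERMDISP** embeds samples by principal coordinates, measures
  distances to group centroids (negative-eigenvalue axes subtract, the
  usual sign convention — with Euclidean input all eigenvalues are
  non-negative anyway), and permutes least-squares residuals under a
  one-way F.
* **ANOSIM** uses midranks for ties and the statistic
  $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$, so $R \in
  [-1, 1]$ with 1 at perfect separation.
* **SIMPER** (Euclidean) attributes to each variable its squared
  coordinate difference averaged over all between-group pairs, so
  contributions sum exactly to 100% of the mean squared distance. The
  software convention behind published SIMPER tables is not always
  stated; the squared-difference share is the one consistent with a
  Euclidean resemblance matrix. The per-variable percent difference is
  $100(\bar x_A - \bar x_B)/\bar x_A$, negative when the second
  treatment is larger.

P-values use the add-one convention $(b+1)/(m+1)$ with a default of
9999 permutations; instances with at most 8 samples can be enumerated
exhaustively, in which case the exact fraction is reported.

## Univariate framework

One-way and fully crossed two-way fixed-effects ANOVAs use sequential
(Type I) sums of squares, which coincide with Type III on balanced
designs; balance is reported because some females died mid-study. The
nested variant (female within treatment, crossed with month) tests
treatment over the mean square of unit-within-treatment — the
statistically defensible denominator when units, not observations, are
the replicates for treatment; whether the original analysis used this
or the residual denominator is not stated, so this is a documented
package choice. Normality is checked with Anderson-Darling (case 3,
estimated moments; via nortest) and variance homogeneity with Levene's
test centred at the group mean (via car; median centring available as
the Brown-Forsythe variant). ANOVA is robust to non-normality, so
normality failures are reported but not acted on; under
heteroscedasticity the decision rule lowers the working alpha to the
Levene p-value — a term is then called significant only if its p-value
is below the Levene p-value. Tukey's HSD provides pairwise comparisons,
with a compact letter display computed from the maximal cliques of the
not-significantly-different graph.

## Carbonate chemistry

The solver works from either measured pair: free-scale pH + DIC
(closed-form speciation) or TA + DIC (pH root-found in [4, 10] to
|dTA| < 1e-10 mol/kg; TA is strictly increasing in pH at fixed DIC so
the root is unique). Constants default to the "Lueker set" (Lueker
K1/K2, Weiss K0 and fugacity, Dickson KB and KS, Millero KW, Perez &
Fraga KF, Mucci solubilities, Lee boron), all at surface pressure with
nutrient alkalinity assumed zero — the study measured no nutrients.
Salinity is never printed in the study's tables ("ambient salinity");
the package assumes S = 32, typical of coastal Gulf of Alaska surface
water, reports it in every output, and exposes it as an argument.
Recomputed derived columns (pCO2, bicarbonate, carbonate, saturation
states) fall within the printed mean +- 1 SD of the study's chemistry
tables for all three treatments under that assumption, which also
absorbs the (unstated) choice of measured pair. pH-scale conversions
(free/total/seawater) are exact inverses of each other; speciation mass
balance holds by construction.

## Numerical and design choices, in brief

* Day numbering is 1-based; day $d$ means the interval $(d-1, d]$.
* Counts are rounded half away from zero only at the final step of the
  hatch-count estimators; intermediate arithmetic is exact.
* The three clutch percentages share one denominator (viable +
  non-viable + unhatched), so they partition 100% exactly.
* All generators are bit-reproducible given a seed and restore the
  caller's RNG state.
* Treatment labels are the verbatim strings "Ambient", "pH 7.8",
  "pH 7.5"; files are plain comma-delimited UTF-8 with YAML manifests
  carrying seeds, settings and a configuration hash.

## Problem sizes used in validation

The package's validation suite simulates at the study's design scale: 9
cells x 5 inserts x 20 larvae with a 49-day horizon. Parameter-recovery
checks use 100 simulation replicates per year (median estimates land
within ~1% of generating $t_{50}$ values, comfortably inside the 5%
acceptance band; slopes within ~2% against a 15% band, $s$ being the
more weakly identified parameter at 100 larvae per cell). Model-selection
consistency uses 25 replicates of the full 10-model comparison (the
generating full-interaction model attains essentially all Akaike weight
in over 90% of replicates). Permutation-test calibration uses 2000 null
datasets of 3 variables at 199 permutations each, where the attainable
rejection rate at $\alpha = 0.05$ is exact. Group sizes for the null
simulations follow where each test is well calibrated: PERMANOVA and
ANOSIM at 6 samples per group, PERMDISP and Levene's test at 15 per
group — the study's own morphometric sampling scale — because both are
known to run mildly liberal in very small groups.

## Known limitations

* No mixed-effects/REML alternatives, frailty terms, or Bayesian
  fitting; the candidate set is the 10 factor-structured models only.
* Multivariate dissimilarities other than Euclidean (e.g. Bray-Curtis)
  and >2-group SIMPER are out of scope, as are ordination plots.
* The full nested multifactor PERMANOVA partition is approximated by
  permutation strata, as discussed above.
* Absolute AICc values from the original experiment are not
  reproducible without the raw observations; the package's claims are
  about recovery and ranking behaviour at the design scale, and about
  in-table worked values (parameter counts, percent differences,
  carbonate chemistry) that are reproducible.
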