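---
title: "Predicting canopy green-fraction dynamics of untested genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting canopy green-fraction dynamics of untested genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

canopygp predicts the growth trajectory of crop genotypes that have never
been phenotyped, by combining a mechanistic canopy-cover curve with genomic
prediction. This vignette is the package's own account of the models it
implements, the defaults it chooses, and the limits of what its synthetic
experiments can show.

## The canopy dynamics model

UAV imagery of a field plot yields a *green fraction* (GF): the proportion
of pixels covered by green canopy. GF is linked to leaf area index through
Beer-Lambert extinction,

$$\mathrm{GF} = 1 - e^{-k\,\mathrm{LAI}},$$

with extinction coefficient $k = 0.5$, the value commonly used for soybean.
LAI itself is modelled on the growing-degree-day scale $T_d$ (cumulative
daily mean temperature above a base of 8 °C from sowing) as logistic growth
minus exponential senescence:

$$\mathrm{LAI}(T_d) = \mathrm{LAI_{amp}}\left\{\frac{1}{1 + e^{-r_g (T_d -
T_g)}} - e^{r_s (T_d - T_s)}\right\}.$$

The five parameters are the maximum LAI ($\mathrm{LAI_{amp}}$,
dimensionless), the growth rate $r_g$ and senescence rate $r_s$ (per
degree-day), the growth inflection $T_g$ and the senescence zero-crossing
$T_s$ (degree-days, $T_s > T_g$). Past $T_s$ the curve goes negative; the
package clamps LAI at zero before converting to GF, because a pixel
fraction cannot be negative.

## Two-step curve fitting

Single plots — especially drought-stressed ones — carry too little signal
to estimate all five parameters stably, so estimation is staged:

1. **Genotype-level joint fit.** All plots of a genotype within a year are
   fitted together, assuming the curve shape ($r_g, r_s, T_g, T_s$) is a
   genotype property shared across watering treatments while
   $\mathrm{LAI_{amp}}$ is plot-specific (the finest level consistent with
   exempting only the amplitude from genotype-dependence). $(T_g, T_s)$ are
   searched on a $7\times7$ lattice spanning $(300, 1200) \times (1400,
   3000)$ degree-days with inclusive endpoints (150/266.7 degree-day
   spacing); at each lattice point a Nelder-Mead simplex minimises the cost
   over the remaining parameters, log-parameterised so positivity needs no
   constraints.
2. **Per-plot refinement.** Each plot is re-fitted inside a window of
   $\pm 200$ ($T_g$) and $\pm 400$ ($T_s$) degree-days around its
   genotype's stage-1 optimum (truncated at the global ranges, same 7-point
   resolution), started from the stage-1 parameter values. The exact
   stage-1 cell is always evaluated, so refinement can never worsen the
   plot's cost beyond simplex tolerance.

The cost is weighted least squares,
$\sum_d \sum_i (y_{i,d} - \hat y_{i,d})^2 / \bar y_d$, where $\bar y_d$ is
the mean observed GF of the environment on date $d$ — measurement noise in
image-derived cover fractions is roughly proportional to the mean cover.
Dates with $\bar y_d < 10^{-4}$ are dropped from the cost: their weights
would explode and they carry no canopy information.

Numerical choices worth knowing:

* The lattice is scanned with a loose simplex (reltol $10^{-4}$, 200
  iterations) and only the winning cell is polished at full tolerance
  (reltol $10^{-8}$, up to 2000 iterations). The scan only has to rank
  basins, not resolve optima.
* The polish lets **all** parameters move, including $(T_g, T_s)$, with
  `parscale` evening out the $O(1)$ log-rate axes against the $O(10^3)$
  degree-day axes and up to two simplex restarts. The lattice provides
  global structure; the continuous polish removes the discretisation error
  that would otherwise leak from a gridded $T_g$ into compensating biases
  in $r_g$ and $\mathrm{LAI_{amp}}$. On noise-free data this recovers all
  five parameters to well under 1 %.
* Ties across lattice cells break to the lowest $(T_g, T_s)$; cells with
  $T_s \le T_g$ are skipped; simplex excursions that overflow `exp()`
  receive an effectively infinite cost rather than `NaN`.
* Parameters live inside a generous physical box ($\mathrm{LAI_{amp}} \le
  12$, rates $\le 1$ per degree-day, $T$'s within widened search ranges),
  enforced as an infinite-cost wall. This matters for identifiability, not
  just hygiene: when flights stop before senescence, a ridge opens up in
  which $T_s$ near the end of the observed window with a small $r_s$
  subtracts a near-constant from the curve and the amplitude compensates
  upward without bound — GF saturates above canopy closure, so LAI
  amplitude beyond it is unobservable. Unbounded, that ridge wrecks the
  heritability of the fitted amplitude; capped at a value soybean canopies
  never approach, it stays a local nuisance.
* Genotypes whose observations are all zero (or whose dates are all
  excluded) are flagged unfit and carry the configuration initials; plots
  with fewer than five usable observations keep their stage-1 parameters,
  flagged `genotype_joint`.

Whether stage 1 should pool plots across years as well as treatments is
not determined by the two-step description alone; the package pools within
year (one joint fit per genotype × year), since year-to-year weather acts
on the shape parameters in ways a shared fit would average away.

## Genotypic values and the genomic machinery

Per flight date (for GF) and per environment (for each curve parameter),
plot-level values are decomposed as $y = \mu + \mathrm{block} + s + e$ with
fixed block effects (sum-to-zero contrasts, so $\mu$ is the overall mean)
and i.i.d. random genotype effects, fitted with lme4; the genotypic value
is $g = \mu + \mathrm{BLUP}(s)$. Blocks are treated as fixed because the
replicate structure has very few levels; under balance the choice is
inconsequential. Without any replication the variances are unidentifiable
and the function falls back to plot means, with a warning.

Markers pass quality control (MAF $\ge 0.025$, missing rate $< 0.05$,
greedy sliding-window LD pruning at $r^2 \ge 0.95$ — window 50, step 5,
later marker dropped — then column-mean imputation). The genomic
relationship matrix is $G = XX^\top / c$ on centred, scaled codes with $c =
\mathrm{tr}(XX^\top)/n$, so the mean diagonal is 1 and heritability sits on
the standard scale; this is VanRaden-equivalent up to the normalisation
constant, which the source material leaves unspecified.

Single-trait G-BLUP ($g = m + u + \varepsilon$, $u \sim N(0, \sigma_u^2
G)$) is solved by REML on the spectral decomposition of the training-set
$G$: the profile restricted likelihood of the variance ratio is maximised
by a bounded one-dimensional search on $\log \lambda \in [\log 10^{-5},
\log 10^5]$ (61-point bracket plus golden-section refinement). This is
exact, deterministic and cannot fail to converge. Test genotypes get the
conditional mean $G_{\mathrm{test,train}} (G_{\mathrm{train}} + \lambda^{-1}
I)^{-1}(g - \hat m)$ and its conditional variance, which later feeds the
trajectory-sampling models. Genomic heritability is $h^2 = \sigma_u^2 /
(\sigma_u^2 + \sigma_\varepsilon^2)$.

## The multi-trait sampler

The multi-trait model stacks $J$ variates with genetic covariance
$K \otimes G$ and residual covariance $R \otimes I$ and is fitted by Gibbs
sampling:

* On the eigenbasis of $G$ the genetic-effect conditional decouples into
  $n$ independent $J$-dimensional normals — the update is exact and cheap
  (compiled kernel).
* $K$ and $R$ get inverse-Wishart updates with weakly informative priors
  ($J + 2$ degrees of freedom, $0.5\,I$ scale). Columns are standardised
  internally before fitting — variates live on wildly different scales
  (degree-days vs. rates per degree-day), and both the prior and the
  sampler's conditioning assume $O(1)$ variances — and all outputs are
  transformed back.
* Means get a flat-prior joint normal update.
* Missing entries of *partially* observed genotypes are imputed from the
  conditional residual normal, blockwise by missingness pattern.
* Genotypes with *no* observations (the usual test set) are not
  data-augmented at all: their effects are drawn from the conditional prior
  given the observed genotypes' effects, through $G$. Imputing phenotypes
  that carry no information would only create a slow-mixing feedback loop.
* Point predictions are Rao-Blackwellised: the chain averages the
  conditional *means* of the genetic effects rather than the draws, which
  removes pure Monte-Carlo noise from point estimates while the raw draws —
  which carry the full predictive spread — remain available for the ABC
  stage. With one variate the posterior-mean predictions then agree with
  REML G-BLUP to correlation $> 0.98$ at 3,000 iterations.

Chain defaults are 15,000 iterations, 5,000 burn-in, thinning 5 (2,000
retained draws), always seeded. The experiments in this package use shorter,
explicitly configured chains (reported with each result); chain length,
priors and burn-in are configuration, with no claim that they match any
particular published analysis.

Supporting variates for a target are ranked by $s(h^2) + s(|r|)$, where
$s(\cdot)$ scales the candidate vector to zero mean and unit variance,
$h^2$ is the candidate's genomic heritability and $r$ its correlation with
the target, both computed on the training genotypes only. Zero-variance
candidate sets get zero scores; ties break to higher $h^2$, then
lexicographic label. The standard model is eleven variates (one target plus
ten supports). For the two-step multi-trait model (TMGP), whose "target" is
the five curve parameters jointly, candidates are scored against the
strongest absolute correlation with any of the five, and six supports keep
the eleven-variate budget; both counts are configurable.

## The six prediction models

* **GP** — single-trait G-BLUP of the per-date GF genotypic values.
* **TGP** — G-BLUP of the five curve parameters, then the curve rebuilds
  the trajectory at the target environment's flight degree-days.
* **MGP** — the eleven-variate multi-trait model of the target date.
* **TMGP** — the multi-trait model over the five parameters (plus
  supports), posterior-mean parameters through the curve.
* **TGPG / TMGPG** — the "for growth" variants: parameter *distributions*
  rather than point estimates are pushed through the curve, and ABC
  rejection keeps, per genotype, the `n_keep` trajectories closest
  (Euclidean distance on the GF scale, early-period dates only) to that
  genotype's observed early-season green fractions; the prediction for all
  dates is the mean of the kept trajectories. Defaults are 60,000 samples
  and 60 kept (0.1 %); the desk-scale experiments use 6,000 and 6.

The two draw sources are deliberately asymmetric, mirroring the
point-vs-distribution distinction between the underlying models: TGPG
samples each parameter from the asymptotic predictive normal of its REML
G-BLUP (conditional mean and variance plugged in, independent across
parameters), whereas TMGPG uses the raw MCMC draws, which carry the
posterior correlation between parameters. Draws with non-positive rates or
amplitude are assigned infinite distance rather than discarded, preserving
the draw count; a genotype with no early observations gets no selection and
degrades gracefully to the posterior-mean trajectory.

## Cross-validation designs

* **CV1** — 10-fold cross-validation of genotypes; test genotypes' records
  leave the training data of *every* environment.
* **CV2** — genotype folds crossed with leave-one-environment-out: test
  genotypes' records leave only the held-out environment, and supporting
  variates may come only from the other environments. GP and TGP train on
  same-environment data alone, so their CV2 predictions equal CV1 — a
  useful internal consistency check.
* **CV3** — as CV2, but the growth cycle is split into early and late
  halves with equal observation counts (an odd count favours the early
  half), the test genotypes' early-period GF in the held-out environment
  joins the conditioning data, and accuracy is scored on late dates only.
  MGP then uses seven criterion-selected supports plus the latest three
  early flights of the held-out environment; TGPG/TMGPG condition through
  ABC.

Accuracy is the Pearson correlation between genotypic values and
predictions, computed per environment × date across the test genotypes and
then averaged. Repeats use seeds `seed`, `seed + 1`, `seed + 2`; folds are
drawn independently per scheme and repeat (re-using CV1's folds in CV2 is
an alternative the source description leaves open; independent seeded folds
are the simpler reproducible choice). The early observations that drive the
ABC step are the per-date genotypic values of the test genotype (its
block-corrected own data) rather than raw single-plot GF; this uses the
same quantity the accuracy metric is defined on and removes block effects
that the dynamics model does not represent. Model improvements are reported
as ratios of mean correlations, $(\bar r_A / \bar r_B - 1) \times 100\,\%$.

## What the synthetic generator does and does not emulate

`sim_config()` encodes the study conditions the package is tested under: a
diversity panel of 200 genotypes, 2,000 biallelic markers with U-shaped
Beta(0.5, 0.5) allele frequencies, three years × control/drought
environments, two blocks, and 16 flights evenly spaced over days 14-75
after sowing (flights begin after thinning). The panel descends from 25
founder families (each individual inherits a founder's genotype with 30 %
of markers redrawn): family relatedness is what gives the genomic
relationship matrix usable structure, as in any real diversity panel —
with fully independent genotypes $G \approx I$, genomic prediction of
unseen genotypes is impossible by construction and genetic covariances are
unidentifiable. An unstructured panel remains available
(`n_families = NULL`). Genetic values of the five
curve parameters are additive in the markers with a 5×5 genetic correlation
matrix (moderate positive correlations among $\mathrm{LAI_{amp}}$, $r_g$,
$T_g$; weak elsewhere), per-parameter heritabilities (0.8, 0.6, 0.4, 0.7,
0.4 for $\mathrm{LAI_{amp}}, r_g, r_s, T_g, T_s$ — growth-phase parameters
heritable up to 0.8, senescence parameters lower), genetic coefficients of
variation of 8-15 %, environment mean shifts (drought multiplies
$\mathrm{LAI_{amp}}$ by 0.65, $r_g$ by 0.8, $T_g$ by 0.85; a heat-stressed
year shrinks amplitude), plot-level lognormal jitter (sdlog 0.05, which is
what makes genotypic and residual variance separable in the plot model),
and additive Gaussian observation noise with s.d. equal to 5 % of the
date's mean GF, clipped to $[0, 1)$ — additive mean-proportional noise
matches the weighting rationale of the fitting cost directly, which is why
it was chosen over a logit-normal.

Deliberate limitations of the emulation, hence of what green tests prove
about real data:

* Family structure creates genome-wide relatedness but no positional
  linkage-disequilibrium map; QC's LD pruning is exercised only by
  duplicated columns in tests.
* No spatial field trends, missing flights, or segmentation artefacts;
  noise is independent across dates.
* Under the default flight window (to day 75, roughly 1,400 degree-days)
  senescence is barely observed, so $T_s$ and $r_s$ are weakly identified —
  exactly as in short-season field campaigns. Tests that check full
  five-parameter recovery therefore use an extended schedule (to day 150).
* Because drought shrinks $T_g$, the drought curve inflects *earlier* and
  can transiently sit above the control curve during canopy closure; within
  this logistic family that crossover is unavoidable if all three growth
  parameters shrink. Dominance of control over drought is therefore
  asserted season-wide and in the saturated phase, not pointwise.
* Genotype codes are sampled under Hardy-Weinberg proportions; a true
  inbred diversity panel would be nearly free of heterozygotes. The coding
  and QC paths do not depend on the heterozygosity level.

## Problem sizes used by the test suite

The packaged experiments are sized for a single CPU: curve-recovery checks
use 4-13 genotypes (noise-free and 5 %-noise scenarios, 3 seeds);
heritability recovery uses $n = 200$ with 20 replicates per level;
sampler-equivalence checks use $n = 100$ and 3,000-iteration chains; the
directional late-period experiment uses the full 200-genotype panel, five
simulation replicates, two evaluation folds of a 10-fold split, one
held-out drought environment, 6,000-draw chains and ABC keep-6. The
acceptance script re-runs the same pipeline at the 200-genotype scale and
reports its numbers as computed.

## Known limitations

* The curve family cannot represent bimodal or heat-truncated seasons; a
  poor fit shows up as high cost, not as a model switch.
* Stage-1 pooling assumes treatment-independent shape within a year; under
  strong genotype × treatment interaction in $T_g$ the stage-2 window
  ($\pm 200$ degree-days) bounds how far a plot can move back.
* The G-BLUP machinery is additive-only: no dominance or epistatic
  kernels, no pedigree fallback, no GWAS.
* ABC conditions only on early-period GF; it cannot correct a parameter
  posterior that puts no mass near the truth.
* Joint hierarchical estimation of curve and genetic effects in one model
  is out of scope; the two-step structure is the design point.
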