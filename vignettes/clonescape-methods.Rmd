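---
title: "Methods: clonality, connectivity and reproductive investment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, connectivity and reproductive investment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

`clonescape` links three bodies of data about a clonal marine plant —
diploid microsatellite genotypes, field estimates of flowering and seed
production, and a hydrodynamic picture of how propagules move — into one
question: do isolated, seed-poor meadows rely on clonal spread while
well-connected, seed-rich meadows stay genotypically diverse? This
vignette explains each model in the chain, the parameters that matter,
and the design decisions that were genuinely open.

## Clone detection and genotypic richness

A *ramet* is a sampled shoot; a *genet* is a genetic individual. Ramets
sharing an identical multilocus genotype (MLG) across all scored loci
are assigned to one genet. Matching is exact and unordered within a
locus; `missing_policy` controls whether a missing locus matches only
another missing locus (`"exact"`, the default) or anything
(`"permissive"`, assigned greedily in input order). The permissive mode
exists because microsatellite panels drop loci sporadically; it is
deliberately not a stepwise-mutation "multilocus lineage" caller, which
is out of scope.

Genotypic richness is

$$R = \frac{G - 1}{N - 1},$$

0 for a monoclonal stand, 1 when every ramet is its own genet. The
denominator is $N - 1$ (not $N$): with that convention every per-site
value in the bundled Port Phillip Bay table is reproduced exactly from
its $(N, G)$ pair (for example $N = 45, G = 9 \rightarrow 0.18$;
$N = 43, G = 40 \rightarrow 0.93$), which is the decisive check between
the two typographic readings of the formula.

Whether repeated MLGs are truly clones is assessed with
$P_{gen}$, the Hardy–Weinberg probability of the genotype
($\prod_\ell p_a p_b \cdot 2^{[a \ne b]}$), and
$P_{sex}(k, N) = \sum_{i \ge k} \binom{N}{i} P_{gen}^i (1 -
P_{gen})^{N - i}$, the probability of seeing at least $k$ copies among
$N$ independent sexual recruits. Allele frequencies for $P_{gen}$ come
from unique genets only and are not $F_{IS}$-corrected — the plain HWE
form. For MLGs shared *between* sites, frequencies are pooled over the
genets of the involved sites; a small $P_{sex}$ then argues for
between-site dispersal of vegetative fragments rather than coincident
sexual production.

## Diversity and population structure

Per-site diversity uses unique genets only (clonal resampling would
otherwise downweight rare alleles): mean alleles per locus $Na$,
observed heterozygosity $H_O$, and Nei's unbiased expected
heterozygosity

$$H_E = \frac{2n}{2n - 1}\Bigl(1 - \sum_a p_a^2\Bigr)$$

with $n$ the genets called at the locus, averaged over loci.

Differentiation is the Weir–Cockerham estimator: per locus and allele,
the variance components $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals), with
$\hat\theta = \sum a / \sum (a + b + c)$ over alleles and loci.
Monomorphic loci contribute zero components; negative estimates are
reported as computed, not truncated, so means over many estimates stay
unbiased. Pairwise significance comes from permuting genets between the
two sites (2499 permutations by default) with a Bonferroni-adjusted
α (0.05/120 ≈ 0.0004 for 16 sites); Benjamini–Hochberg is available.
The estimator is validated three ways in the test suite: an
independently coded transcription of the variance components (agreement
to 10⁻¹²), analytic limits (identical composition → θ ≈ 0; fixed
alternative alleles → θ = 1), and a Balding–Nichols calibration (mean
$\hat\theta$ within 0.02 of the generating $F$ at $F = 0.05, 0.10$).

The Mantel test correlates the off-diagonal elements of two labelled
matrices and permutes one matrix's labels jointly over rows and
columns; the default alternative is positive association (the
isolation-by-distance convention), with `"less"` available for testing
$F_{ST}$ against dispersal flow, where more exchange should mean less
differentiation. Flow matrices are asymmetric, so `symmetrize` offers
`sum` or `mean` of $x$ and $x^\top$; the choice is exposed rather than
fixed because either reading of "propagules given and received" is
defensible, and with the log transform all entries must be strictly
positive, which zero flows violate — a structural reason this
comparison is reported but not treated as a reproducible target.

## The fragment-dispersal simulator

Seed-carrying fragments are the long-distance dispersal vector for a
seagrass whose seeds themselves are negatively buoyant. The simulator
is a Lagrangian particle model over a gridded current field with the
fragment biology in four pieces:

* **Buoyancy stages.** Fragments rise for the first week
  (+0.0049 m s⁻¹), are neutral in the second, and sink thereafter
  (−0.005 m s⁻¹). The velocities are taken from drift measurements on
  a congeneric seagrass; they are stated without units in the source
  literature and interpreted here as m s⁻¹, consistent with that
  measurement context.
* **Mortality.** Weekly loss fractions 0.25, 0.50, 0.75, 1.00.
  Within weeks 1–3 the loss is applied as a constant hazard (so
  survival at day 7 is exactly 0.75); the final week declines linearly
  to zero so that no fragment outlives 28 days while dispersal can
  continue through the last week. Only the first-week loss and the
  four-week endpoint are externally specified; the linear escalation
  between them is this package's default and is configurable.
* **Settlement.** Allowed after the first 6 h whenever a fragment
  contacts the seabed inside a habitat patch. Bed contact outside
  habitat leaves the fragment resting and able to resuspend (mortality
  is defined only by age and beaching); a `bed_mortality` switch makes
  bare-seabed contact lethal instead.
* **Beaching.** Entering a land cell (or leaving the grid) removes the
  fragment.

Integration is forward Euler with bilinear spatial and linear temporal
interpolation of the hourly currents, default step 1 h, with an
optional random-walk horizontal diffusivity (default 0). The vertical
dimension is reduced from the source system's eight layers to
depth-averaged horizontal currents plus explicit particle depth — the
buoyancy life history is what matters for when a fragment can touch
the bed, and this keeps the simulator desk-scale; the `current_field`
interface accepts any field you can put on a grid, layered models
included once averaged.

Releases are uniform-random over each patch's cells at the surface.
Reproductive output is proportional to patch area, implemented by
scaling the probability matrix rows by source area into the *flow*
matrix (not by releasing more particles from large patches — equal
particle counts keep Monte-Carlo error comparable across sources).
*Relative inflow* is the column sum of flow excluding self-recruitment;
the matrix bundled with the package carries an empty diagonal, which is
why exclusion is the default.

Two scale presets exist: `"study"` (1000 fragments per patch every 3 h
over a 92-day season — the scale of the original field campaign,
roughly 736 release events) and `"desk"` (100 fragments, 12-h
releases, 30 days), the default used throughout the tests so the whole
suite runs in minutes on one CPU.

## The synthetic bay

`simulate_bay()` builds an enclosed rectangular bay: a one-cell land
border with a mouth, bathymetry deepening from 2 m at the shore to
20 m mid-bay, and a velocity field of three parts — a steady double
gyre, a spatially uniform semidiurnal tidal oscillation, and optional
white noise. The gyre is constructed so its *central-difference*
divergence vanishes exactly on the grid (the $v$ amplitude carries a
$\sin(ah)/\sin(bh)$ factor), which makes the discrete
incompressibility test sharp rather than approximate. Default current
amplitudes (0.03 m s⁻¹ gyre, 0.01 m s⁻¹ tide) keep the fastest
displacement under one 400-m cell per hourly step — the CFL-style
constraint the Euler integrator needs — and produce a realistic fate
mix at desk scale: most fragments beach or die, a few percent settle,
and the settlement matrix has nonzero off-diagonal structure. Habitat
patches are 2×2 blocks of shallow near-shore cells with nominal areas
drawn log-uniformly over 10³–10⁵ m², two orders of magnitude, so the
area-weighted flow matrix is genuinely exercised.

## Synthetic genotypes and reproductive covariates

`simulate_genotypes()` draws ancestral allele frequencies from a flat
Dirichlet per locus (allele counts uniform on 3–16, the range seen in
the bundled system), site frequencies from the Balding–Nichols model
with parameter $F$ (default 0.06, the bundled system's global
differentiation), genets under HWE within sites, and ramet counts from
a geometric clone-size law adjusted to hit each site's target $R$
exactly; increments go preferentially to already-large genets, so
dominant clones emerge naturally at low $R$, and a
`dominant_clone_fraction` can force, e.g., one genet to 55 % of
ramets. Collisions between genets are redrawn, so the realized $G$ is
exact. What this generator does *not* emulate: linkage disequilibrium,
null alleles, scoring error, somatic mutation within genets, and
spatial clone geometry within sites — so passing tests say the
estimators are correct under clean HWE island-model data, not that
they are robust to those artefacts.

`simulate_reproduction()` inverts the regression model: given each
site's $R$ and inflow it solves
$\log(\text{seed}) = (\mathrm{logit}(R) - \beta_0 - \beta_{inflow}
\log(\text{inflow})) / \beta_{seed}$, optionally jittered by lognormal
noise, and sets spathe density to seed density times lognormal noise
(reproducing the strong seed–spathe correlation seen in field data).
Noise-free, the beta regression recovers the truth to numerical
precision; with noise, recovery within 3 standard errors is a tested
property. The default truth
$(\beta_0, \beta_{seed}, \beta_{inflow}) = (-0.75, 0.21, 0.30)$ is the
log-scale fit to the bundled 15-site table, a realistic operating
point.

## Beta regression and model selection

Genotypic richness is a proportion-like quantity in $(0, 1)$, so the
site-level model is a beta law with logit-linked mean and constant
precision $\phi$:
$y_i \sim \mathrm{Beta}(\mu_i \phi, (1 - \mu_i)\phi)$,
$\mathrm{logit}(\mu_i) = x_i^\top \beta$. The fit maximizes the exact
log-likelihood with `nlminb` over $(\beta, \log\phi)$; predictors are
standardized internally for conditioning and mapped back, and standard
errors come from the observed information with the same mapping.
Responses on the boundary are squeezed with
$y' = (y(n-1) + 0.5)/n$. The reported pseudo-$R^2$ is the squared
Pearson correlation between the linear predictor and the
link-transformed response (zero for an intercept-only fit). The fit is
verified against an independent multi-start Nelder–Mead maximization of
the same likelihood and against parameter recovery on simulated data.

All-subsets selection ranks every predictor subset by
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ with $k$ counting all
estimated parameters including $\phi$, reporting ΔAICc and Akaike
weights; subsets with too few observations are skipped with a warning.
The collinearity screen drops, greedily, the member of the most
correlated pair with the larger mean absolute correlation to the rest,
at a default threshold of $|r| \ge 0.7$ — the threshold used to thin
spathe density, node degree and $H_E$ from the bundled analysis is not
published, and 0.7 is a stated assumption of this package.

**Predictor scale.** There is a genuine ambiguity in the bundled
system: the methods description says seed density and inflow were log
transformed, but the published coefficient table (seed effect printed
as `<0.001` with standard error `<0.001`, inflow 0.093 with z = 3.25)
is numerically consistent only with a raw-scale fit — refitting on raw
scales reproduces the intercept (−0.045 vs −0.035), the inflow
coefficient (0.0939) and the pseudo-$R^2$ (0.740 vs the printed 0.73),
while the log-log fit gives pseudo-$R^2 = 0.53$ and visibly different
coefficients. Both transforms are available (the formula interface
takes `log()` terms directly); the package's reproduction of the
published fit uses the raw scale, and the synthetic generator's truth
is stated on the log scale where the relationship is cleanest.

## Connectivity networks

Sites are nodes; an undirected edge joins sites whose pairwise
$F_{ST}$ is at or below the threshold (inclusive — values *above* the
threshold are removed). The conventional threshold 0.04 is the lowest
value that connects all nodes of the bundled system except its one
genuinely isolated site. Betweenness uses the Brandes convention
(fractional credit across tied shortest paths, endpoints excluded,
unnormalized) with $F_{ST}$ as edge length by default, so paths prefer
genetically similar stepping stones; edge lengths are floored at 10⁻⁹
because unconstrained $F_{ST}$ estimates can be zero or negative and
Dijkstra needs positive lengths. Recomputing degrees from the bundled
pairwise matrix at 0.04 does not reproduce every published degree
value (e.g. one site yields 10 pairs at or under the threshold against
a published degree of 8), indicating additional unpublished filtering
in the original network tool; the package therefore treats the
threshold rule as the definition and does not calibrate to those
values.

## Problem sizes and determinism

Every stochastic component takes one integer seed; the pipeline
derives fixed per-stage offsets from its global seed, and identical
configurations reproduce byte-identical outputs. The test suite runs
the simulators at reduced scale (tens of particles per release,
seasons of days, hundreds of permutations, 10–50 replicate
simulations), sizes chosen so the full suite completes in a few
minutes on a single CPU while keeping Monte-Carlo error well inside
each test's tolerance; the dispersal acceptance check uses a
100,000-fragment cohort where a ±1-percentage-point band requires it.

## Known limitations

* Clone calling is exact-match only; somatic mutation or scoring error
  splits a genet into two.
* The dispersal model is two-dimensional in its currents; vertical
  shear between layers is not represented, only stage-driven depth.
* Over-water geographic distances are accepted as a precomputed
  matrix; path-around-land computation is out of scope.
* The beta regression models constant precision; precision covariates
  and spatial autocorrelation corrections are not implemented.
* Global standardized F-statistics beyond θ (F′, G′, AMOVA) and
  percolation-based threshold selection for networks are out of scope.
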