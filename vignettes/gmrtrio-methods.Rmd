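---
title: "Methods: trio-based germline mutation rates and their comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based germline mutation rates and their comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrtrio)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not establish about real data.

## The estimation problem

A parent–offspring trio sequenced at high depth lets mutation rates be read
off directly: a de novo mutation (DNM) is a site where both parents are
confidently homozygous reference and the offspring is heterozygous. Two
systematic errors dominate naive counting. False positives come from
genotyping artefacts that mimic the de novo pattern; they are controlled by
a cascade of hard filters. False negatives come from those same filters
removing genuine mutations; they are controlled by restricting the
denominator to *callable* sites and correcting the remainder with an
explicit false-negative rate (FNR). The per-trio estimator is

$$\hat\mu_{\text{gen}} = \frac{m}{(1-\widehat{FNR})\cdot 2C},$$

with $m$ the candidate count and $C$ the callable genome; the factor 2
counts the two haploid genomes an offspring inherits.

## The filter cascade

`filter_config()` holds the thresholds. Filter 1 uses the standard GATK
site annotations (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR); filters 2–5
act on the trio: the de novo genotype pattern, an offspring allelic balance
in the closed interval [0.30, 0.70], per-individual depth strictly inside
(0.5, 2) × mean trio depth, and genotype quality of at least 60 for all
three individuals. Choices that the thresholds alone do not determine:

* **Missing annotations pass their own sub-filter.** GATK omits the
  rank-sum annotations at some sites; failing such sites would silently
  shrink the callable genome. The annotation is treated as uninformative
  instead.
* **Allelic-balance bounds are inclusive, depth bounds exclusive**, read
  directly off the interval conventions "30–70%" versus "DP > 0.5·m, DP <
  2·m".
* **Mean trio depth** is the mean of the three per-individual mean depths
  over the analysed table (a per-genome mean, not per-site), recorded
  alongside the audit trail.
* **Multi-allelic records are skipped and counted**, not guessed at.
* An optional **exclusion list** removes externally identified false
  positives (e.g. a second caller's disagreements); the package audits but
  does not re-call.

`call_dnms()` returns the candidates plus an audit table counting, per
filter, the Mendelian-violation sites it removed — the cascade is fully
reconstructable from the audit.

## Callable genome and FNR

A site is callable when a DNM occurring there *could* have been detected:
parents HomRef, all three individuals passing depth and quality. The
site-annotation filters are deliberately excluded from callable counting —
they can only be evaluated meaningfully at polymorphic sites — and enter
through the FNR instead, which has two components combined as
$1-(1-f_{\text{site}})(1-f_{\text{ab}})$ under an independence assumption:

* $f_{\text{site}}$, analytic: MQRankSum and ReadPosRankSum are rank-sum
  z-statistics, standard normal at well-behaved sites, so their loss is the
  normal tail mass outside the bounds (0.02278 for (−2, 4), 0.00270 for
  (−3, 3)); FS is a phred-scaled p-value, so P(FS > 20) = 10^−2^. These
  null distributions are a modelling choice, stated and configurable; QD,
  MQ and SOR have no comparably clean null and are assumed lossless at true
  heterozygous sites.
* $f_{\text{ab}}$, empirical: among transmitted heterozygotes (one parent
  HomRef, the other HomAlt, offspring Het) — sites whose read sampling
  mirrors a true DNM's — the fraction with offspring allele balance outside
  the window.

Intervals are Wilson score intervals on $(m, 2C)$, scaled by
$1/(1-\widehat{FNR})$; the FNR is treated as known in the interval, which
is slightly anti-conservative but matches how such corrections are usually
propagated. Species-level rates average trio rates, with a pooled-count
Wilson interval.

## Phasing and male bias

Phasing works at the level of linkage observations: a read (pair) covering
both the DNM and a nearby heterozygous site whose alleles can be traced to
exactly one parent. Reads carrying the DNM allele vote for the parent
carrying the co-occurring allele; reads carrying the other offspring
haplotype vote for the opposite parent. The conflict rule is strict — any
disagreement among informative observations leaves the mutation unphased —
because a false phase biases α directly whereas a lost phase only widens
its interval. α's confidence interval is the monotone image $p/(1-p)$ of
the Wilson interval on the paternal fraction, which keeps the reciprocity
property (swapping counts inverts the interval exactly) and yields a finite
lower bound even when no maternal mutations were observed.

Sibling sharing counts identical (chrom, pos, alt) mutations in two or more
offspring of the same parent pair; the denominator is all mutation
instances in such families and the standard error is binomial per-instance.
A per-species grouping is available via the `by` argument.

## The parental-age model

Counts are modelled as Poisson,

$$m_i \sim \text{Pois}\big((1-FNR_i)\,2C_i\, d_{s(i)}\,(a + b\,\tau_i)\big),
\qquad \tau_i = p\,\text{father}_i + (1-p)\,\text{mother}_i,$$

with an *identity* link: the biology is an additive load — mutations
already present in a newborn parent's germ line ($a$, per site) plus a
linear accumulation per year of weighted parental age ($b$). A log link
would make the intercept multiplicative and misrepresent the
"contribution at birth". Positivity is enforced during optimisation
(penalised Nelder–Mead on per-Gb-scaled parameters; standard errors from
the numerical curvature at the optimum). The weights $p$ are the
species-level paternal fractions from phasing, defaulting to 0.5 where
unknown.

Fitting is two-stage: a global $(a, b)$ with all species deviations fixed
at 1, then each $d_s$ by closed-form per-species maximum likelihood
($d_s = \sum m_i / \sum \hat\lambda_{0i}$) holding $(a, b)$. The second
stage can only increase the joint likelihood, which is asserted in the
tests. No shrinkage is applied to $d_s$; single-trio species simply carry
wide bootstrap intervals. Trios without both parental ages are excluded
from fitting but still receive modelled rates through their species.

Model fit is summarised by $r^2 = 1 - SS_{res}/SS_{tot}$ between predicted
means and observed *counts* (not rates): counts are what the likelihood
addresses, and the exposure factors vary little within a cohort.

Evaluating the fit at a species' generation time $G$ gives
$\mu_{\text{gen,mod}} = d_s(a + bG)$ and
$\mu_{\text{year,mod}} = \mu_{\text{gen,mod}}/G$ (an exact identity, tested
as such). Intervals come from a parametric bootstrap — counts resampled
from the fitted means, both stages refitted — with a fixed seed and a
configurable replicate count (default 1000).

## Spectrum statistics

Substitutions are strand-collapsed onto the A/C reference frame; CpG status
means a C followed by G (equivalently a G preceded by C before collapsing),
`NA` when the context of a C:G-origin mutation is unknown — such mutations
are excluded from CpG proportions with a reported count, never guessed.
The strong-to-weak flag marks C:G>T:A. Tests are Pearson chi-squared
without continuity correction (counts in these tables are large; Yates'
correction would only bias the statistic downward), a generic
class-versus-rest contrast for single-class comparisons, and a one-way
ANOVA on species-level mean rates across taxonomic classes.

## Comparative layer

PGLS is generalized least squares with covariance proportional to shared
branch lengths (Brownian motion). Pagel's λ is fixed at 1 by default — the
simplest defensible choice and the one that makes a star phylogeny reduce
exactly to OLS (a machine-precision test); λ can be set manually but is not
optimised. The r² compares residual quadratic forms against an
intercept-only GLS fit in the same metric, so it is invariant to global
branch-length rescaling, as are the coefficients and p-values. Regressions
are on the raw scale by default; transform the variables in the formula for
log-scale fits.

Harmonic-mean Ne over a window clips partially covered segments of the
piecewise-constant trajectory:
$H = \int_W dt \big/ \int_W dt/N_e(t)$. The harmonic mean never exceeds
the time-weighted arithmetic mean, which the tests exploit as an
invariant. `ne_from_pi()` applies the neutral-equilibrium identity
$N_e = \pi/4\mu$.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, at
two scales:

* **Site level** (`simulate_trio()`): materialised all-sites tables with
  planted DNMs (Binomial(2n, μ)), transmitted heterozygotes, error sites
  with explicit failure signatures, Poisson depth, truncated-normal
  genotype qualities, and annotations drawn from the same null
  distributions the FNR correction assumes. The default `n_sites = 2e5`
  per trio is a deliberate desk-scale choice — a vertebrate's ~2.4 Gb
  callable genome cannot sensibly be materialised row by row — so
  site-level runs exercise the calling logic, not count statistics at
  realistic rates.
* **Count level** (`simulate_cohort()`): the study-scale design — 68
  species split 36/18/8/6 across mammals, birds, fishes and reptiles, 151
  trios, callable genomes near 2.4 Gb — with counts drawn from the same
  Poisson age model the package fits (defaults a = 0.6e-8, b = 0.4e-9,
  log-normal species deviations), class-level paternal fractions implying
  male biases near 2.3/3.2/0.8/1.5, correlated log-normal parental ages
  (correlation 0.9, ~30% of trios with masked ages), a 48% phasing
  probability, 2% sibling duplication, a mutation spectrum with Ts/Tv 2.3,
  48.5% strong-to-weak and 42.4% CpG share, a random ultrametric tree
  scaled to 400 Myr, and log-normal piecewise-constant Ne histories.

Values not dictated by the cohort design above were chosen once as
field-typical: mean depth 67×, genotype quality N(85, 10) truncated to
[0, 99], transmitted-het density 1e-3 (a typical vertebrate
heterozygosity), error-site rate 1e-4, allele-balance spread 0.05. The
distribution of true offspring allele balance is not observable directly;
the Beta-spread `ab_noise` knob is an explicit stand-in.

Reads are *not* simulated; phasing evidence is generated at the level of
informative linkage observations, which exercises the same decision logic
as physical read tracing. Sibling sharing duplicates a mutation into one
sibling with probability `sibling_share_prob` q, making the expected shared
fraction 2q/(2+q).

**What passing tests show — and don't.** The synthetic cohorts verify the
estimators against known truth under the package's own noise model:
annotation nulls are exactly the distributions the FNR assumes, error modes
are planted one per site, and genotypes contain no mapping or
reference-bias structure. Passing therefore demonstrates correctness of
the decision logic and calibration under the stated model, not robustness
to the correlated artefacts of real alignments (segmental duplications,
index hopping, clipped reads); those require the audit trail and an
external cross-caller check on real data.

## Numerical choices and degenerate inputs

Tolerances and tie-breaks that matter: thresholds at exactly the cut-off
pass filter 1 (strict inequalities); an offspring with zero informative
reads fails allelic balance with an explicit reason; zero transmitted
heterozygotes make f_ab undefined and the function refuses unless a value
is supplied; an all-equal age vector makes the slope unidentifiable and the
fit refuses; a species absent from the fit receives d_s = 1 with a flag;
ultrametricity is checked to 1e-6 relative tolerance and violations warn
rather than fail (calibrated trees often carry rounding error). Wilson
intervals are computed in closed form and clamped to [0, 1].

## Problem sizes used by tests and the acceptance script

Coverage and recovery properties run at reduced but non-trivial sizes
chosen as the package's own defaults: 50 trios at 2e5 sites for end-to-end
interval coverage, 200-trio cohorts over 50 seeds for age-model recovery,
200 replicates for α coverage, 500 replicates for the PGLS Brownian null,
200 bootstrap replicates for modelled-rate intervals in the acceptance
script. The acceptance script derives every random stream from its `--seed`
argument and writes all quantities with the problem size used.

## Known limitations

Indel mutations, X/Y-specific handling and read-level simulation are out of
scope. The FNR site component inherits its null-distribution assumptions;
if an instrument's annotations deviate from them, f_site should be supplied
externally. The species deviation d_s is a point multiplier without
shrinkage, noisy for single-trio species. PGLS fixes λ = 1 rather than
estimating it, which can overstate phylogenetic signal for labile traits.
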