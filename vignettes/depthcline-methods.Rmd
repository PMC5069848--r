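---
title: "Methods: genotype-phenotype divergence along a water-depth gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-phenotype divergence along a water-depth gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthcline)
```

## The scientific problem

Deep lakes host intraspecific fish variants ("ecotypes") that differ in
morphology, buoyancy, and life history, yet often show little neutral
genetic differentiation. The question this package addresses is how to
decide, from microsatellite genotypes and phenotypic measurements of the
same individuals, (i) which grouping factor — ecotype, geographic zone, or
water-depth stratum — structures the neutral genetic variation, and (ii)
which traits diverge among those groups more than neutral drift can
explain, i.e. which traits carry a signature of divergent selection along
the depth gradient.

The pipeline combines standard population-genetic summary statistics
(allelic richness by rarefaction, unbiased heterozygosity, $F_{IS}$,
Weir–Cockerham $\theta$, Jost's $D$), hierarchical AMOVA factor ranking,
Mantel tests of isolation-by-depth and isolation-by-distance, principal
coordinates ordination of individual genotypes, and a $P_{ST}$–$F_{ST}$
comparison for quantitative traits. All stages run on a common trio of
inputs: a GenePop genotype file, a per-individual metadata table, and a
per-individual trait table.

## The synthetic-data generator

No raw data accompany the study the analysis design follows, so every
stage is validated against a generator with known ground truth.

**Genotypes.** Group allele frequencies follow the Balding–Nichols model:
per locus an ancestral frequency vector $p$ is drawn from a flat Dirichlet
over $k$ alleles ($k$ uniform on 3–25, emulating microsatellite panels),
and each group's vector from $\mathrm{Dirichlet}(p\,(1-F)/F)$, whose
expected fixation index is the target $F$. Diploid genotypes are binomial
draws from the group vector. This matches an island-model $F_{ST}$ target
analytically and runs in milliseconds, at the price of exchangeable (not
clinal) groups and no mutational realism — the generator makes no claim
about the loci's true mutation process (no SMM/IAM, no linkage). Genotypes
are exported in the 3-digit GenePop dialect. Each locus consumes its own
RNG sub-stream, so adding loci never perturbs existing ones, and the same
seed reproduces the dataset byte-for-byte.

Default study conditions, chosen once: three depth strata of 83, 217 and
71 genotyped individuals (the per-stratum genotyped sample sizes of the
motivating design), 18 loci, target $F_{ST} = 0.005$ (mid-range of the
weak pairwise differentiation the design expects, 0.002–0.012), 2%
missing calls, nominal stratum depths 40/80/120 m, and capture depths
drawn from the six net-set categories 40, 50, 80, 90, 100 and >120 m so
that the six-category Mantel stage is exercisable. Ecotype labels are
assigned independently of the genetic groups, so the AMOVA ranking has a
known right answer (stratum) and a known wrong one (ecotype).

**Traits.** Standard length $SL$ is lognormal (median 450 mm, log-sd
0.25). An allometric trait is $a\,SL^{b}\,10^{e}$ with $e$ normal on the
log10 scale; between-group shifts have variance $\sigma^2_B$ and residual
variance is $\sigma^2_W$, optionally scaled monotonically across groups
(variance trend; the increasing case emulates character release, an
intermediate peak the hybridization signature). Under a depth trend the
group effects are a deterministic monotone sequence whose sample variance
equals $\sigma^2_B$ exactly — this makes parameter-recovery experiments
well-posed, because the realized between-group variance does not fluctuate
with a 2-degree-of-freedom random draw. Weights in air and water are
constructed so that the buoyancy formula recovers the simulated buoyancy
cline exactly, and $\omega = L_{max} \times K$ holds exactly in the
emitted table. What the generator does *not* emulate: measurement error
correlated across traits, age structure, non-lognormal size distributions,
and genotype–phenotype linkage (trait divergence is imposed, not inherited
from the simulated loci). Passing tests therefore demonstrate estimator
correctness and calibration under idealized sampling, not robustness to
those real-data features.

Three YAML presets ship with the package: `neutral`,
`divergent-by-depth`, and `stabilizing`.

## Statistical choices, tolerances, and degenerate inputs

**Depth strata.** Bin edges are half-open: $[0,50)$, $[50,100]$,
$(100,\infty)$ m; the boundary depths 50 and 100 m fall in the
intermediate stratum. The source design prints the strata without edge
ownership, so this assignment is a package convention recorded in the
manifest, not an inference about intent. The ">120 m" depth category is
valued at its 120 m lower bound in the Mantel depth matrix.

**Heterozygosity.** $H_e$ uses the $2n/(2n-1)$ small-sample correction,
so it never falls below the plug-in estimate. Monomorphic loci return
$H_o = H_e = 0$ rather than an error.

**Rarefaction.** Allelic richness uses exact hypergeometric expectations
(no resampling): $A_{r,g} = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$,
computed with `lchoose` for numerical stability. Private allelic richness
uses the generalized rarefaction — the expected number of alleles present
in the focal group's $g$-gene subsample and absent from every other
group's $g$-gene subsample. Note that an allele shared at full sample size
can still look private in finite subsamples, so $PA_{r,g}$ is positive
below the full gene count and collapses to the strict private-allele count
exactly at it.

**$F_{IS}$.** Weir–Cockerham small $f$ per group; the permutation null
re-pairs alleles among individuals within the group (each locus
independently), which tests Hardy–Weinberg proportions within groups —
permuting whole genotypes would test a different null. The P-value is
two-sided on $|f|$ with the add-one rule, so it can never be smaller than
$1/(n_{perm}+1)$.

**Multiple testing.** SGoF declares significant the excess of observed
over binomially expected sub-$\alpha$ p-values, applied sequentially from
the smallest p-value; it controls the family-wise error near $\alpha$
under the null while retaining power for many weak effects. Bonferroni is
available where the original toolchain used it (Jost's $D$ across pairs).

**$\theta$ and its inference.** Weir–Cockerham variance components are
summed over alleles and loci and combined as
$\sum a / \sum (a+b+c)$. Negative estimates are reported as computed —
truncation at zero would bias a comparison across near-zero pairwise
values. Pairwise significance permutes individuals between the two groups
(one-sided); the multilocus confidence interval bootstraps loci
(percentile, 95%), and the derived standard error is the interval width
divided by 3.92 (two 1.96 normal quantiles), the same conversion used to
put $F_{ST}$ next to $P_{ST}$ on a common error scale.

**Jost's $D$.** Per-locus $D_{est}$ with the Nei–Chesser small-sample
corrections (harmonic-mean sample size, $H_o$ adjustment) and the
$r/(r-1)$ scaling. Loci are combined by the harmonic mean when all
per-locus values are positive; otherwise a clamped delta-method
approximation ($\bar D - s^2_D/\bar D$, bounded to $[\min D, \bar D]$,
returning $\bar D$ when $\bar D \le 0$) — the unclamped approximation
degenerates when $\bar D$ is near zero, which matters because the
significance null (parametric bootstrap from the pooled pair under
Hardy–Weinberg, the semantics of the cited DEMEtics tool rather than a
label permutation) lives exactly in that near-zero regime.

**AMOVA.** One level, on the squared allele-count distance (number of
allele differences between two genotypes summed over loci; ARLEQUIN's
default metric for unphased microsatellites). Loci with a missing call in
either member of a pair are skipped and the distance rescaled by
$L/L_{\mathrm{observed}}$, which keeps all individuals rather than
dropping incomplete ones. Sums of squares among and within groups are
conservation-checked on every run ($SS_A + SS_W = SS_T$). $F_{CT}$ is the
among-group variance component over the total; significance permutes whole
individuals across groups. Factor crossings use `interaction()` with empty
cells dropped, so the degrees of freedom equal the number of non-empty
cells minus one. Sources that collapse to a single non-empty group are
skipped with a warning. The ranking stage orders sources by significant
$F_{CT}$ and hands the winner to the downstream stages.

**Mantel.** Pearson correlation over the upper triangle with simultaneous
row/column permutation; for matrices of size $\le 6$ the full $n!$
permutation distribution is enumerated exactly (720 relabelings at most),
which matters because the isolation-by-depth test runs on only six depth
categories. Fewer than four points is an error — the test is undefined
there. The genetic matrix is pairwise linearized $\theta/(1-\theta)$ among
depth-category groups and the environmental matrix is the absolute depth
difference in metres; neither metric is dictated by the source design, so
both are overridable inputs. An optional outlier interpolation (replace
the entry with the largest absolute regression residual by the mean of its
row/column neighbours) ships switched off, because no objective outlier
criterion was stated where the idea originates.

**PCoA.** Classical multidimensional scaling (`stats::cmdscale`) of the
square root of the squared genotypic distance. Negative eigenvalues are
reported, percent variance is taken over positive eigenvalues only, and an
all-zero distance matrix is flagged degenerate instead of decomposed.

**Size adjustment.** Ordinary least squares of $\log_{10}(\text{trait})$
on $\log_{10}(SL)$, returning internally studentized residuals (the
common statistics-package default labelled "studentized"; an external
option exists). The log-log dialect is the default because allometry is
multiplicative; whether the regressor was logged in the original workflow
is not stated, so the choice is recorded in the run manifest. Residuals
are equivariant to unit changes of both variables. A numerically perfect
fit (residual variance below $10^{-12}\,\mathrm{var}(y)$) returns exact
zeros, since studentization is 0/0 there. Life-history traits and shape
PC scores bypass adjustment: they are not length measurements of a body
part.

**ANOVA and LSD.** Classical one-way ANOVA; Fisher's LSD uses the pooled
mean squared error with unadjusted pairwise P-values — that is what the
procedure is — gated on the omnibus test at 0.05. Singleton groups are
dropped with a warning.

**Variance profiles.** Per-group unbiased variance with percentile
bootstrap CIs (default 1000 replicates); a monotone trend is declared only
when the CIs along the depth order are pairwise disjoint in that
direction, and an intermediate-peak flag marks the hybridization-consistent
pattern. Groups under five observations get no CI.

**$P_{ST}$ and the R-matrix.** Two estimators are provided deliberately.
The variance-component estimator computes
$P_{ST} = \sigma^2_B/(\sigma^2_B + 2h^2\sigma^2_W)$ from
method-of-moments one-way components (negative $\sigma^2_B$ truncated at
zero), with a bootstrap over individuals within groups. The R-matrix
estimator standardizes traits by the pooled within-group standard
deviation, centers group means on the sample-size-weighted grand mean,
averages squared codivergence across traits, scales by $1/(2h^2)$, and
maps onto the $F_{ST}$ scale as $A/(1+A)$ with $A$ the weighted mean
diagonal. The sample-size adjustment of the original RMET program is not
published, so the package subtracts the *exact* sampling contribution of
each estimated group mean — $(1-2w_i)/n_i + \sum_j w_j^2/n_j$ on the
diagonal and the matching covariance term off it — plus a
$1/(1-\sum w_i^2)$ factor that unbiases the weighted mean of squares as a
between-group variance estimate. That algebra makes the two estimators
agree exactly in the one-trait, equal-$n$, $h^2=1$ case (an internal
cross-check in the test suite) and demonstrably reduces small-sample bias
at $n=30$ per group; exact numerical parity with RMET output is not
claimed. $D^2_{ij} = r_{ii} + r_{jj} - 2r_{ij}$, floored at zero (the
bias correction can push a tiny distance below it), with bootstrap SEs.
Heritability defaults to $h^2 = 1$, the conservative choice: it minimizes
$P_{ST}$, so selection calls err toward false negatives.

**Selection classification.** "Selection" only when the $P_{ST}$ lower
confidence limit exceeds the $F_{ST}$ upper limit; "below-neutral" for
the mirrored case; overlap is "drift"; missing limits are
"indeterminate". The method cannot distinguish heritable divergence from
environmentally induced plasticity — classification is about departure
from neutral expectation, not mechanism.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as
follows, as the package's own validation design: estimator-vs-oracle
checks on 4–10-individual hand instances at $10^{-10}$ tolerance;
type-I-error calibration of the AMOVA and $F_{IS}$ permutation tests on
1000 null datasets (three groups of 10, and one group of 30, respectively)
with 99 permutations each; Balding–Nichols recovery at $n = 200$ per
group and 18 loci over 10 seeds per target; $P_{ST}$ coverage at $n = 200$
per group over 100 seeds with 199-replicate bootstraps; and 20 seeds of
the full divergent-by-depth scenario at the default study conditions. API
defaults remain at the tool-chain-faithful 10,000 permutations and 1000
bootstrap replicates.

## Known limitations

- Balding–Nichols groups are exchangeable: the generator cannot produce a
  genuinely clinal genotype structure, so the isolation-by-depth power
  check constructs a frequency-interpolated cline separately.
- The Jost $D$ multilocus harmonic mean is dominated by the least
  differentiated loci; this is a property of the chosen combination rule,
  not a bug, and the per-locus values are available.
- AMOVA here is one-level (groups within total, plus factor crossings);
  nested three-level designs are out of scope.
- $P_{ST}$ at $h^2 = 1$ is conservative by construction; traits reported
  as "drift" may still be under selection (type-II errors).
- The missing-data rescaling in the genotypic distance assumes calls are
  missing at random across loci.

## A worked example

```{r example, eval = FALSE}
library(depthcline)
sim <- simulate_scenario("divergent-by-depth", seed = 7)
report <- run_all(sim, n_perm = 999, n_boot = 499, jost_boot = 499, seed = 7)
report
write_report_bundle(report, "depthcline-report")
```

The report bundles machine-readable analogues of the classic result
tables: the AMOVA factor ranking, the per-stratum diversity table, the
differentiation matrix ($\theta$ below the diagonal, Jost's $D$ above),
trait clines with LSD post hocs, within-group variance profiles, the
per-trait $P_{ST}$-vs-$F_{ST}$ classification, and the paired
$D^2$-vs-$F_{ST}$ comparison across stratum pairs, plus a JSON manifest
with the seed, configuration, and software versions.
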