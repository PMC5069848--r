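# depthcline

Genotype–phenotype divergence analysis along a water-depth gradient, for
population geneticists and fish ecologists working with microsatellite
panels and morphological/life-history measurements on the same
individuals. The package asks two questions of such data: **which grouping
factor structures the neutral genetic variation** (ecotype, geographic
zone, or depth stratum — ranked by hierarchical AMOVA F<sub>CT</sub>), and
**which traits diverge among those groups beyond neutral expectation**
(P<sub>ST</sub>–F<sub>ST</sub> comparison).

## What it computes

* **Diversity** (per depth stratum): mean alleles per locus *A*, rarefied
  allelic richness *A*<sub>r</sub> and private allelic richness
  *PA*<sub>r</sub> at a standardized gene count (exact hypergeometric
  expectations), observed and unbiased expected heterozygosity
  *H*<sub>o</sub>/*H*<sub>e</sub>, and Weir–Cockerham *F*<sub>IS</sub>
  with a within-group allele-permutation test; SGoF and Bonferroni
  multiple-testing corrections.
* **Differentiation**: pairwise and global Weir–Cockerham θ
  (= *F*<sub>ST</sub>) with permutation P-values and locus-bootstrap CIs
  (SE = CI width / 3.92), and Jost's *D* with a pooled-pair bootstrap
  null.
* **Structure**: one-level AMOVA on the allele-count distance with factor
  ranking by F<sub>CT</sub>; Mantel tests (exact enumeration for ≤ 6
  units) of isolation-by-depth across six depth categories and
  isolation-by-distance across sites; PCoA of individual genotypes.
* **Phenotype**: percent buoyancy
  `100 (W_air − W_water)/W_air`, allometric size adjustment by
  studentized residuals of log10(trait) on log10(SL), one-way ANOVA with
  Fisher's LSD, and within-group variance profiles over depth (character
  release / hybridization signatures).
* **Selection vs drift**: P<sub>ST</sub> = σ²<sub>B</sub>/(σ²<sub>B</sub> +
  2h²σ²<sub>W</sub>) by variance components *and* by a
  Relethford–Blangero-style R-matrix with Mahalanobis D² distances;
  traits classified *selection* when the P<sub>ST</sub> lower confidence
  limit exceeds the F<sub>ST</sub> upper limit.
* **Synthetic data**: a Balding–Nichols genotype generator plus an
  allometric trait generator with controllable between/within-group
  variance, depth trends, and variance trends, so the whole pipeline is
  testable with known ground truth (`simulate_scenario("neutral" |
  "divergent-by-depth" | "stabilizing")`).

## Worked example

```r
library(depthcline)
sim    <- simulate_scenario("divergent-by-depth", seed = 7)
report <- run_all(sim, n_perm = 199, n_boot = 199, jost_boot = 99, seed = 7)
```

The AMOVA ranking puts depth stratum on top and leaves ecotype and zone
non-significant — the data are structured by depth, not by morphology or
geography:

```
              source      Fct     P significant
             stratum 0.007268 0.005        TRUE
 ecotype and stratum 0.004924 0.005        TRUE
    zone and stratum 0.004823 0.005        TRUE
    ecotype and zone 0.002204 0.015        TRUE
                zone 0.000553 0.225       FALSE
             ecotype 0.000210 0.385       FALSE
```

Diversity is homogeneous across strata (the deep stratum has the lowest
private allelic richness), and no stratum departs from Hardy–Weinberg:

```
    group   N    A   Ar   PAr    Ho    He      Fis Fis_P
    <50 m  83 14.4 14.2 0.420 0.845 0.842 -0.00377 0.660
 50-100 m 217 15.5 14.2 0.407 0.850 0.842 -0.00919 0.135
   >100 m  71 13.9 13.9 0.195 0.824 0.834  0.01239 0.285
```

Pairwise differentiation is weak (θ below the diagonal, Jost's *D*
above; global θ = 0.0043, 95% CI 0.0030–0.0056), which is exactly the
regime where the P<sub>ST</sub>–F<sub>ST</sub> contrast is informative:

```
          <50 m 50-100 m  >100 m
<50 m    0.0000   0.0044  0.0094
50-100 m 0.0053   0.0000 -0.0055
>100 m   0.0046   0.0030  0.0000
```

The trait classification separates the simulated swimming/buoyancy cline
from the undiverged craniofacial traits:

```
            trait      Pst Pst_lower Pst_upper classification
 buoyancy_pct_adj 0.207529   0.14786    0.2761      selection
          CPD_adj 0.178981   0.12915    0.2494      selection
          PVL_adj 0.152083   0.09950    0.2138      selection
          Lmax_mm 0.095561   0.05015    0.1532      selection
          HLL_adj 0.000000   0.00000    0.0171          drift
          MXL_adj 0.000000   0.00000    0.0192          drift
          POL_adj 0.000000   0.00000    0.0185          drift
         head_PC1 0.000000   0.00000    0.0157          drift
```

A P<sub>ST</sub> lower limit of 0.148 against an F<sub>ST</sub> upper
limit of 0.0056 means the buoyancy divergence among strata is ~30 times
what drift at these sample sizes could produce.
`write_report_bundle(report, dir)` writes all tables as TSV plus a JSON
run manifest.

## The methods vignette

`vignettes/depthcline-methods.Rmd` documents the statistical choices in
detail: estimator formulas, permutation-null semantics, the rarefaction
and R-matrix algebra, what the synthetic generator does and does not
emulate, and known limitations.
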