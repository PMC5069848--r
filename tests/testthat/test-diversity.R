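test_that("allele frequencies match a brute-force tally", {
  gt <- gt_from_calls(list(rbind(c(1, 1), c(1, 2))))
  af <- allele_frequencies(gt, rep("g", 2))
  expect_equal(unname(af$g[[1]]$freq), c(0.75, 0.25))
  # larger simulated instance against an independent tally
  cfg <- synth_config(group_sizes = c(250, 250), n_loci = 4,
                      depth_per_group = c(40, 120), n_groups = 2,
                      missing_rate = 0.1, seed = 31, trait_specs = list())
  sim <- simulate_genotypes(cfg)
  af2 <- allele_frequencies(sim$genotypes, sim$frame$group)
  for (l in 1:4) {
    rows <- sim$frame$group == "G1"
    genes <- c(sim$genotypes$a1[rows, l], sim$genotypes$a2[rows, l])
    genes <- genes[!is.na(genes)]
    tal <- table(genes) / length(genes)
    expect_equal(unname(af2$G1[[l]]$freq[names(tal)]), unname(c(tal)),
                 tolerance = 1e-12)
    expect_equal(sum(af2$G1[[l]]$freq), 1, tolerance = 1e-12)
  }
})

test_that("an all-missing locus is flagged and excluded", {
  a1 <- cbind(c(1L, 2L), c(NA_integer_, NA_integer_))
  gt <- genotype_table(a1, a1)
  af <- allele_frequencies(gt, rep("g", 2))
  expect_true(af$g[[2]]$flagged)
  expect_false(af$g[[1]]$flagged)
})

test_that("heterozygosities match hand-computed values", {
  # all heterozygous (1,2) -> Ho = 1
  gt <- gt_from_calls(list(cbind(rep(1, 4), rep(2, 4))))
  h <- heterozygosities(gt, rep("g", 4))
  expect_equal(unname(h$g$Ho[1]), 1)
  # monomorphic -> Ho = He = 0
  gtm <- gt_from_calls(list(cbind(rep(2, 4), rep(2, 4))))
  hm <- heterozygosities(gtm, rep("g", 4))
  expect_equal(unname(hm$g$He[1]), 0)
  # 5-individual hand set: p = (.6,.3,.1); He = (10/9)(1-0.46) = 0.6
  gt5 <- gt_from_calls(list(rbind(c(1, 1), c(1, 2), c(2, 2), c(1, 1), c(1, 3))))
  h5 <- heterozygosities(gt5, rep("g", 5))
  expect_equal(unname(h5$g$He[1]), 0.6, tolerance = 1e-12)
  expect_equal(unname(h5$g$Ho[1]), 0.4)
  # the unbiased estimate never falls below the plug-in estimate
  expect_gte(unname(h5$g$He[1]), 0.54)
})

test_that("rarefied richness matches closed form and exhaustive enumeration", {
  # counts (5,5), g = 2: 2 (1 - C(5,2)/C(10,2)) = 14/9
  gt <- gt_from_calls(list(cbind(rep(1, 5), rep(2, 5))))
  ar <- rarefied_richness(gt, rep("g", 5), g = 2)
  expect_equal(ar[1, 1], 2 * (1 - choose(5, 2) / choose(10, 2)),
               tolerance = 1e-12)
  expect_equal(ar[1, 1], oracle_rarefy(c(5, 5), 2), tolerance = 1e-12)
  expect_equal(round(ar[1, 1], 4), 1.5556)
  # richer instance vs enumeration
  gt2 <- gt_from_calls(list(rbind(c(1, 2), c(1, 3), c(2, 2), c(3, 1))))
  ar2 <- rarefied_richness(gt2, rep("g", 4), g = 3)
  expect_equal(ar2[1, 1], oracle_rarefy(c(3, 3, 2), 3), tolerance = 1e-12)
})

test_that("rarefied richness limits: one draw, full sample, monotone in g", {
  gt <- gt_from_calls(list(rbind(c(1, 2), c(2, 3), c(1, 1), c(3, 3))))
  expect_equal(rarefied_richness(gt, rep("g", 4), g = 1)[1, 1], 1)
  full <- rarefied_richness(gt, rep("g", 4), g = 8)[1, 1]
  expect_equal(full, 3) # equals observed A at the full gene count
  ar_g <- sapply(1:8, function(g) rarefied_richness(gt, rep("g", 4), g)[1, 1])
  expect_true(all(diff(ar_g) > -1e-12))
  expect_error(rarefied_richness(gt, rep("g", 4), g = 9), "exceeds")
})

test_that("private allelic richness behaves at the full-sample limit", {
  # no strictly private allele: both groups carry exactly {1,2};
  # at g = full sample size the private richness must be zero
  gt <- gt_from_calls(list(rbind(c(1, 2), c(1, 2), c(1, 2), c(2, 1))))
  pa_full <- private_rarefied_richness(gt, c("a", "a", "b", "b"), g = 4)
  expect_equal(unname(pa_full[1, ]), c(0, 0), tolerance = 1e-12)
  # below the full sample an allele can still look private in a subsample,
  # so PAr is positive but bounded by the allele count
  pa2g <- private_rarefied_richness(gt, c("a", "a", "b", "b"), g = 2)
  expect_true(all(pa2g[1, ] >= 0 & pa2g[1, ] < 2))
  # allele 3 strictly private to group b: PAr(b) exceeds PAr(a) at any g,
  # and at full sample size it equals the private count exactly
  gt2 <- gt_from_calls(list(rbind(c(1, 2), c(1, 2), c(1, 3), c(2, 1))))
  pa2 <- private_rarefied_richness(gt2, c("a", "a", "b", "b"), g = 2)
  expect_gt(unname(pa2[1, "b"]), unname(pa2[1, "a"]))
  pa2_full <- private_rarefied_richness(gt2, c("a", "a", "b", "b"), g = 4)
  expect_equal(unname(pa2_full[1, "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(pa2_full[1, "a"]), 0, tolerance = 1e-12)
})

test_that("rarefaction agrees with Monte-Carlo subsampling", {
  counts <- c(12, 7, 4, 1)           # 24 genes = 12 diploid individuals
  g <- 8
  genes <- rep(seq_along(counts), counts)
  gt <- gt_from_calls(list(cbind(genes[1:12], genes[13:24])))
  ar <- rarefied_richness(gt, rep("g", 12), g = g)[1, 1]
  set.seed(99)
  draws <- replicate(10000, length(unique(sample(genes, g))))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(ar - mean(draws)), 3 * mc_se)
})

test_that("Fis sign tracks heterozygote excess and deficit", {
  # all heterozygotes at a 2-allele locus with p = 0.5 -> Fis < 0
  gt <- gt_from_calls(list(cbind(rep(1, 20), rep(2, 20))))
  ft <- fis_test(gt, rep("g", 20), n_perm = 99)
  expect_lt(ft$Fis, 0)
  # selfing-like inflation of homozygosity -> Fis > 0 and detected
  set.seed(12)
  n <- 200
  make_geno <- function() {
    p <- c(0.5, 0.3, 0.2)
    a1 <- sample.int(3, n, TRUE, prob = p)
    a2 <- ifelse(runif(n) < 0.5, a1, sample.int(3, n, TRUE, prob = p))
    cbind(a1, a2)
  }
  gts <- gt_from_calls(list(make_geno(), make_geno(), make_geno()))
  fts <- fis_test(gts, rep("g", n), n_perm = 199)
  expect_gt(fts$Fis, 0)
  expect_lt(fts$P, 0.05)
  # monomorphic group reported as missing
  gtm <- gt_from_calls(list(cbind(rep(1, 5), rep(1, 5))))
  expect_true(is.na(fis_test(gtm, rep("g", 5), n_perm = 9)$Fis))
})

test_that("SGoF and Bonferroni behave on the stated examples", {
  expect_equal(sum(sgof_correct(rep(0.99, 100))), 0)
  expect_equal(sum(bonferroni_correct(rep(0.99, 100))), 0)
  expect_true(sgof_correct(0.001))
  expect_true(bonferroni_correct(0.001))
  # strong signal: SGoF declares the excess of sub-alpha p-values over the
  # binomial expectation, always from the smallest p-values up
  set.seed(60)
  p <- c(rep(1e-6, 20), runif(80, 0.2, 1))
  sg <- sgof_correct(p)
  expect_gt(sum(sg), 0)
  expect_lte(sum(sg), 20)
  expect_true(all(which(sg) %in% 1:20))
  expect_false(any(sg[21:100]))
  expect_identical(sgof_correct(numeric(0)), logical(0))
})

test_that("SGoF family-wise discovery under the null is near alpha", {
  set.seed(7)
  any_disc <- replicate(400, any(sgof_correct(runif(153))))
  expect_lt(abs(mean(any_disc) - 0.05), 0.04)
})

test_that("diversity_table assembles per-group summaries coherently", {
  sim <- simulate_scenario("neutral", seed = 8)
  dt <- diversity_table(sim$genotypes, sim$frame$stratum, n_perm = 49)
  expect_equal(dt$group, levels(sim$frame$stratum))
  expect_true(all(dt$Ho >= 0 & dt$Ho <= 1))
  expect_true(all(dt$He >= 0 & dt$He <= 1))
  expect_true(all(dt$Ar <= dt$A + 1e-9))
  expect_true(all(dt$Fis >= -1 & dt$Fis <= 1))
})
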