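test_that("theta matches the brute-force component oracle on a hand set", {
  # 6 individuals, 2 loci, 2 groups
  calls <- list(rbind(c(1, 1), c(1, 2), c(2, 2), c(1, 2), c(2, 2), c(2, 2)),
                rbind(c(1, 3), c(3, 3), c(1, 1), c(3, 3), c(1, 3), c(3, 3)))
  gt <- gt_from_calls(calls)
  g <- c("a", "a", "a", "b", "b", "b")
  th <- wc_theta(gt, g)$theta
  expect_equal(th, oracle_theta(gt$a1, gt$a2, g), tolerance = 1e-10)
  # and on a larger simulated instance with three groups and missing data
  cfg <- synth_config(group_sizes = c(30, 40, 20), n_loci = 5,
                      target_fst = 0.05, missing_rate = 0.05, seed = 77,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  expect_equal(wc_theta(sim$genotypes, sim$frame$group)$theta,
               oracle_theta(sim$genotypes$a1, sim$genotypes$a2,
                            sim$frame$group),
               tolerance = 1e-10)
})

test_that("theta is invariant to allele relabeling and individual order", {
  cfg <- synth_config(group_sizes = c(25, 25), n_groups = 2,
                      depth_per_group = c(40, 120), n_loci = 4,
                      target_fst = 0.05, missing_rate = 0, seed = 13,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  th <- wc_theta(sim$genotypes, sim$frame$group)$theta
  # relabel alleles with an arbitrary injective map
  remap <- function(m) matrix(97L - m, nrow(m), ncol(m))
  gt2 <- genotype_table(remap(sim$genotypes$a1), remap(sim$genotypes$a2))
  expect_equal(wc_theta(gt2, sim$frame$group)$theta, th, tolerance = 1e-12)
  perm <- sample(50)
  gt3 <- subset_individuals(sim$genotypes, perm)
  expect_equal(wc_theta(gt3, sim$frame$group[perm])$theta, th,
               tolerance = 1e-12)
})

test_that("pairwise theta under the null is small with uniform P", {
  cfg <- synth_config(group_sizes = c(80, 80), n_groups = 2,
                      depth_per_group = c(40, 120), n_loci = 8,
                      target_fst = 0, missing_rate = 0, seed = 5,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  pf <- pairwise_fst(sim$genotypes, sim$frame$group, n_perm = 99)
  expect_lt(abs(pf$fst[1, 2]), 0.02)
  expect_gt(pf$P[1, 2], 0.05)
  expect_equal(pf$fst, t(pf$fst))
})

test_that("negative pairwise theta is reported, not truncated", {
  found_negative <- FALSE
  for (s in 1:5) {
    cfg <- synth_config(group_sizes = c(12, 12), n_groups = 2,
                        depth_per_group = c(40, 120), n_loci = 3,
                        target_fst = 0, missing_rate = 0, seed = 600 + s,
                        trait_specs = list())
    sim <- simulate_genotypes(cfg)
    th <- pairwise_fst(sim$genotypes, sim$frame$group, n_perm = 0)$fst[1, 2]
    if (th < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("CI-to-SE conversion applies the 3.92 divisor exactly", {
  expect_equal(ci_to_se(0.10, 0.30), 0.05102, tolerance = 1e-4)
  expect_equal(ci_to_se(0.2, 0.2), 0)
  lo <- runif(5); up <- lo + runif(5)
  expect_equal((up - lo) / ci_to_se(lo, up), rep(3.92, 5))
  expect_error(ci_to_se(0.3, 0.1), "below")
})

test_that("locus bootstrap produces a CI that brackets theta", {
  cfg <- synth_config(group_sizes = c(60, 60, 60), n_loci = 12,
                      target_fst = 0.05, missing_rate = 0, seed = 21,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  set.seed(1)
  ci <- fst_bootstrap_ci(sim$genotypes, sim$frame$group, n_boot = 299)
  expect_lt(ci$lower, ci$theta)
  expect_gt(ci$upper, ci$theta)
  expect_equal(ci$se, (ci$upper - ci$lower) / 3.92)
  one_locus <- genotype_table(sim$genotypes$a1[, 1, drop = FALSE],
                              sim$genotypes$a2[, 1, drop = FALSE])
  expect_error(fst_bootstrap_ci(one_locus, sim$frame$group), "two loci")
})

test_that("Jost D matches the direct Dest formula and its limits", {
  # hand set: two pops, one locus
  x1a <- c(1, 1, 2, 2, 1); x2a <- c(1, 2, 2, 2, 3)
  x1b <- c(3, 3, 1, 3, 3); x2b <- c(3, 1, 1, 3, 2)
  gt <- gt_from_calls(list(cbind(c(x1a, x1b), c(x2a, x2b))))
  g <- rep(c("a", "b"), each = 5)
  jd <- jost_d(gt, g, n_boot = 9)
  expect_equal(jd$D[1, 2],
               oracle_dest(list(x1a, x1b), list(x2a, x2b)),
               tolerance = 1e-10)
  # identical allele frequencies -> D ~ 0
  gt0 <- gt_from_calls(list(cbind(rep(c(1, 2), 40), rep(c(2, 1), 40))))
  jd0 <- jost_d(gt0, rep(c("a", "b"), 40), n_boot = 9)
  expect_lt(abs(jd0$D[1, 2]), 0.05)
  # fully disjoint alleles at large n -> D -> 1
  n <- 100
  gt1 <- gt_from_calls(list(cbind(c(rep(1, n), rep(3, n)),
                                  c(rep(2, n), rep(4, n)))))
  jd1 <- jost_d(gt1, rep(c("a", "b"), each = n), n_boot = 9)
  expect_gt(jd1$D[1, 2], 0.97)
})

test_that("Jost D bootstrap P separates structure from its absence", {
  cfg <- synth_config(group_sizes = c(60, 60), n_groups = 2,
                      depth_per_group = c(40, 120), n_loci = 6,
                      target_fst = 0.1, missing_rate = 0, seed = 3,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  set.seed(2)
  jd <- jost_d(sim$genotypes, sim$frame$group, n_boot = 99)
  expect_lt(jd$P[1, 2], 0.05)
})

test_that("AMOVA decomposition conserves variance and detects structure", {
  cfg <- synth_config(group_sizes = c(40, 40, 40), n_loci = 6,
                      target_fst = 0.1, missing_rate = 0, seed = 41,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  am <- amova(sim$genotypes, sim$frame$group, n_perm = 99)
  tab <- am$table
  expect_equal(tab$sum_sq[1] + tab$sum_sq[2], tab$sum_sq[3], tolerance = 1e-9)
  expect_equal(tab$df[1] + tab$df[2], tab$df[3])
  expect_equal(sum(tab$pct_variation[1:2]), 100, tolerance = 1e-9)
  expect_gt(am$Fct, 0)
  expect_lt(am$P, 0.05)
  expect_error(amova(sim$genotypes, rep("one", 120)), "at least two")
})

test_that("AMOVA ranking recovers the structuring factor and drops crossings",
{
  sim <- simulate_scenario("divergent-by-depth", seed = 19)
  set.seed(19)
  rk <- amova_rank(sim$genotypes, sim$frame,
                   factors = c("ecotype", "zone", "stratum"),
                   crossings = FALSE, n_perm = 99)
  fct <- setNames(rk$Fct, rk$source)
  expect_gt(fct["stratum"], fct["ecotype"])
  expect_gt(fct["stratum"], fct["zone"])
  expect_lte(rk$P[rk$source == "stratum"], 0.05)
})

test_that("Mantel: identity, exact enumeration, and vegan agreement", {
  set.seed(8)
  m <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  r <- mantel(m, m, method = "exact")
  expect_equal(r$r_m, 1)
  expect_equal(r$P, 1 / factorial(6), tolerance = 1e-12)
  # 4x4: exhaustive 24-permutation null vs a large permutation estimate
  a <- as.matrix(dist(c(1, 2, 3.5, 7)))
  b <- as.matrix(dist(c(2, 1, 4, 6.5)))
  ex <- mantel(a, b, method = "exact")
  pm <- mantel(a, b, n_perm = 49999, method = "permutation")
  expect_equal(ex$n_perm, 24)
  expect_lt(abs(ex$P - pm$P), 0.02)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ex$r_m, unname(vg$statistic), tolerance = 1e-10)
})

test_that("Mantel input contracts are enforced", {
  m3 <- as.matrix(dist(1:3))
  expect_error(mantel(m3, m3), "more than three")
  m4 <- as.matrix(dist(1:4))
  expect_error(mantel(m4, as.matrix(dist(1:5))), "equal size")
})

test_that("isolation-by-depth is detected on a clinal simulation", {
  cl <- cline_genotypes(seed = 6)
  mm <- depth_mantel_matrices(cl$gt, cl$depth_cat)
  res <- mantel(mm$depth, mm$genetic)
  expect_gt(res$r_m, 0)
  expect_lt(res$P, 0.05)
})

test_that("PCoA reconstructs Euclidean distances and flags degeneracy", {
  # Euclidean configuration: coordinates must reproduce the distances
  set.seed(3)
  cfg <- synth_config(group_sizes = c(10, 10), n_groups = 2,
                      depth_per_group = c(40, 120), n_loci = 6,
                      target_fst = 0.05, missing_rate = 0, seed = 15,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  pc <- pcoa_individuals(sim$genotypes, k = 19)
  d2 <- genotype_distance2(sim$genotypes)
  pos <- pc$eigenvalues > 1e-8
  if (pc$n_negative_eigenvalues == 0) {
    rec <- as.matrix(dist(pc$coordinates))
    expect_equal(rec^2, d2, tolerance = 1e-6, ignore_attr = TRUE)
  } else succeed("non-Euclidean matrix; reconstruction not required")
  # identical individuals -> degenerate ordination flagged
  gti <- gt_from_calls(list(cbind(rep(1, 4), rep(2, 4))))
  expect_warning(pci <- pcoa_individuals(gti), "degenerate")
  expect_true(pci$degenerate)
})

test_that("unstructured genotypes give a diffuse ordination", {
  cfg <- synth_config(group_sizes = c(70, 70, 70), target_fst = 0,
                      missing_rate = 0, seed = 27, trait_specs = list())
  sim <- simulate_genotypes(cfg)
  pc <- pcoa_individuals(sim$genotypes)
  expect_lt(pc$pct_variance[1], 10)
  expect_lt(pc$pct_variance[2], 10)
})
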