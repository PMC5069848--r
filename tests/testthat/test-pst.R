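test_that("Pst follows the defining variance ratio", {
  set.seed(1)
  # sigma2_B = sigma2_W, h2 = 1 -> Pst = 1/3; built with exact group shifts
  cfg <- synth_config(group_sizes = c(200, 200, 200), seed = 51,
                      trait_specs = list(
                        trait_spec("y", base = 0, sigma2_between = 1,
                                   sigma2_within = 1,
                                   depth_trend = "increasing")))
  sim <- simulate_genotypes(cfg)
  tr <- simulate_traits(cfg, sim$frame)
  p <- pst_variance_components(tr$y, sim$frame$group, n_boot = 299)
  expect_gt(1 / 3, p$lower)
  expect_lt(1 / 3, p$upper)
  expect_lt(abs(p$Pst - 1 / 3), 0.1)
  # sigma2_B = 0 -> Pst = 0 (truncated at the boundary)
  p0 <- pst_variance_components(rnorm(300), rep(c("a", "b", "c"), 100),
                                n_boot = 49)
  expect_lt(p0$Pst, 0.05)
  # h2 scales the denominator: lower h2 -> higher Pst
  p_low_h2 <- pst_variance_components(tr$y, sim$frame$group, h2 = 0.5,
                                      n_boot = 9)
  expect_gt(p_low_h2$Pst, p$Pst)
})

test_that("Pst is invariant to affine transformation of the trait", {
  set.seed(2)
  x <- rnorm(150, rep(c(0, 1, 2), each = 50), 1)
  g <- rep(c("a", "b", "c"), each = 50)
  p1 <- pst_variance_components(x, g, n_boot = 9)
  p2 <- pst_variance_components(5 * x - 100, g, n_boot = 9)
  expect_equal(p1$Pst, p2$Pst, tolerance = 1e-12)
})

test_that("R-matrix vanishes when group means are equal", {
  base <- c(1.2, 3.4, 5.6, 7.8, 9.1)
  x <- rep(base, 3)
  g <- rep(c("a", "b", "c"), each = 5)
  rm0 <- r_matrix(matrix(x, ncol = 1), g, sample_size_correction = FALSE,
                  n_boot = 9)
  expect_equal(unname(rm0$R), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(unname(rm0$D2), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(rm0$global_Pst, 0)
})

test_that("two-group D2 matches a direct Mahalanobis computation", {
  set.seed(3)
  x <- rnorm(80, rep(c(0, 1.5), each = 40), 1)
  g <- rep(c("a", "b"), each = 40)
  rmx <- r_matrix(matrix(x, ncol = 1), g, sample_size_correction = FALSE,
                  n_boot = 9)
  m <- tapply(x, g, mean)
  s2 <- (sum((x[1:40] - m[1])^2) + sum((x[41:80] - m[2])^2)) / (80 - 2)
  maha <- (m[1] - m[2])^2 / s2
  A <- sum(c(0.5, 0.5) * rmx$rii)
  expect_equal(unname(rmx$D2[1, 2] * (1 + A / (1 - A))), unname(maha),
               tolerance = 1e-9)
})

test_that("R-matrix global Pst equals variance-component Pst (equal n, h2=1)",
{
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(120, rep(rnorm(3, 0, 1), each = 40), 1)
    g <- rep(c("a", "b", "c"), each = 40)
    pvc <- pst_variance_components(x, g, n_boot = 2)
    rmx <- r_matrix(matrix(x, ncol = 1), g, n_boot = 2)
    expect_equal(rmx$global_Pst, pvc$Pst, tolerance = 1e-6)
    # weighted mean of rii equals the global Pst (construction invariant)
    expect_equal(sum(rep(1 / 3, 3) * rmx$rii), rmx$global_Pst,
                 tolerance = 1e-9)
  }
})

test_that("sample-size correction reduces small-sample bias of global Pst", {
  # neutral traits: true between-group divergence zero at 30 per group
  set.seed(5)
  est <- replicate(200, {
    x <- rnorm(90)
    g <- rep(c("a", "b", "c"), each = 30)
    c(corr = r_matrix(matrix(x, ncol = 1), g, n_boot = 2)$global_Pst,
      raw = r_matrix(matrix(x, ncol = 1), g, sample_size_correction = FALSE,
                     n_boot = 2)$global_Pst)
  })
  bias_corr <- abs(mean(est["corr", ]) - 0)
  bias_raw <- abs(mean(est["raw", ]) - 0)
  expect_lt(bias_corr, bias_raw)
})

test_that("selection classification applies the CI rule", {
  tab <- data.frame(trait = c("t1", "t2", "t3", "t4"),
                    Pst = c(0.30, 0.03, 0.001, 0.2),
                    lower = c(0.20, 0.00, 0.0005, NA),
                    upper = c(0.40, 0.06, 0.002, 0.3))
  out <- classify_selection(tab, fst_lower = 0.003, fst_upper = 0.05)
  expect_equal(out$classification,
               c("selection", "drift", "below-neutral", "indeterminate"))
})

test_that("neutral simulations rarely classify selection", {
  set.seed(6)
  n_sel <- 0
  for (s in 1:40) {
    cfg <- synth_config(group_sizes = c(60, 60, 60), n_loci = 8,
                        target_fst = 0.005, missing_rate = 0, seed = 7000 + s,
                        trait_specs = list(
                          trait_spec("y", base = 0, sigma2_between = 0,
                                     sigma2_within = 1)))
    sim <- simulate_genotypes(cfg)
    tr <- simulate_traits(cfg, sim$frame)
    fci <- fst_bootstrap_ci(sim$genotypes, sim$frame$group, n_boot = 99)
    p <- pst_variance_components(tr$y, sim$frame$group, n_boot = 99)
    if (!is.na(p$lower) && p$lower > fci$upper) n_sel <- n_sel + 1
  }
  expect_lte(n_sel / 40, 0.1)
})

test_that("D2 across depth pairs reflects the geometry of the cline", {
  set.seed(7)
  g <- factor(rep(c("S1", "S2", "S3"), each = 100),
              levels = c("S1", "S2", "S3"))
  cline <- rnorm(300, rep(c(0, 1, 2), each = 100), 1)   # linear cline
  flat <- rnorm(300)
  traits <- data.frame(cline = cline, flat = flat)
  cfg <- synth_config(group_sizes = c(100, 100, 100), n_loci = 6,
                      target_fst = 0.01, missing_rate = 0, seed = 71,
                      trait_specs = list())
  sim <- simulate_genotypes(cfg)
  gt <- sim$genotypes
  lv <- levels(factor(sim$frame$group))
  pf <- pairwise_fst(gt, g, n_perm = 0)
  tab <- d2_vs_depth(traits, g, pf, c("S1", "S2", "S3"), n_boot = 9)
  cl <- tab[tab$trait == "cline", ]
  expect_gt(cl$D2[cl$pair == "S1 vs S3"], cl$D2[cl$pair == "S1 vs S2"])
  expect_true(all(cl$monotone_increase))
  fl <- tab[tab$trait == "flat", ]
  expect_true(all(fl$D2 < 0.15))
})
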