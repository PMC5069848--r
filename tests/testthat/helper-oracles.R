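# Independent brute-force oracles, written as literal loop translations of
# the defining formulas (no shared code with the package internals).

# Weir & Cockerham (1984) theta by explicit per-locus, per-allele loops on
# raw allele vectors.
oracle_theta <- function(a1, a2, grouping) {
  grouping <- factor(grouping)
  num <- den <- 0
  for (l in seq_len(ncol(a1))) {
    keep <- !is.na(a1[, l])
    g <- droplevels(grouping[keep])
    x1 <- a1[keep, l]; x2 <- a2[keep, l]
    pops <- levels(g)
    r <- length(pops)
    if (r < 2) next
    ni <- sapply(pops, function(pp) sum(g == pp))
    if (mean(ni) <= 1) next
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in unique(c(x1, x2))) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        in_pop <- g == pops[k]
        p_i[k] <- (sum(x1[in_pop] == al) + sum(x2[in_pop] == al)) / (2 * ni[k])
        h_i[k] <- sum((x1[in_pop] == al) != (x2[in_pop] == al)) / ni[k]
      }
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# expected distinct alleles in g genes by exhaustive enumeration of all
# gene subsets (tiny inputs only)
oracle_rarefy <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# Jost Dest for one locus evaluated directly from tallied frequencies
oracle_dest <- function(x1_by_pop, x2_by_pop) {
  r <- length(x1_by_pop)
  ni <- sapply(x1_by_pop, length)
  alleles <- unique(unlist(c(x1_by_pop, x2_by_pop)))
  p <- t(sapply(seq_len(r), function(i)
    sapply(alleles, function(al)
      (sum(x1_by_pop[[i]] == al) + sum(x2_by_pop[[i]] == al)) / (2 * ni[i]))))
  ho <- sapply(seq_len(r), function(i) mean(x1_by_pop[[i]] != x2_by_pop[[i]]))
  ntilde <- r / sum(1 / ni)
  hs_hat <- ntilde / (ntilde - 1) *
    (mean(1 - rowSums(p^2)) - mean(ho) / (2 * ntilde))
  ht_hat <- 1 - sum(colMeans(p)^2) + hs_hat / (2 * ntilde * r)
  (ht_hat - hs_hat) / (1 - hs_hat) * r / (r - 1)
}

# internally studentized residuals of y ~ x via explicit hat-matrix algebra
oracle_studentized <- function(y, x) {
  X <- cbind(1, x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  e <- as.vector((diag(length(y)) - H) %*% y)
  s2 <- sum(e^2) / (length(y) - 2)
  e / sqrt(s2 * (1 - diag(H)))
}

# one-way ANOVA F from the between/within mean-square ratio
oracle_anova_F <- function(x, g) {
  g <- factor(g)
  N <- length(x); G <- nlevels(g)
  m <- tapply(x, g, mean); n <- tapply(x, g, length)
  msb <- sum(n * (m - mean(x))^2) / (G - 1)
  msw <- sum((x - m[g])^2) / (N - G)
  msb / msw
}

# genotype_table from explicit allele vectors (test convenience)
gt_from_calls <- function(calls, loci = NULL) {
  # calls: list per locus of 2-column matrices of allele codes
  a1 <- sapply(calls, function(m) m[, 1])
  a2 <- sapply(calls, function(m) m[, 2])
  genotype_table(a1, a2, loci = loci)
}

# monotone genetic cline over depth categories: endpoint allele frequency
# vectors drawn per locus, intermediate categories linear mixtures, so
# pairwise divergence grows with depth separation
cline_genotypes <- function(depths = c(40, 50, 80, 90, 100, 125),
                            n_per = 40, n_loci = 12, k = 6,
                            spread = 0.35, seed = 1) {
  set.seed(seed)
  tfrac <- (depths - min(depths)) / diff(range(depths))
  n <- n_per * length(depths)
  a1 <- a2 <- matrix(NA_integer_, n, n_loci)
  for (l in seq_len(n_loci)) {
    pa <- stats::rgamma(k, 1); pa <- pa / sum(pa)
    pb <- pa * exp(stats::rnorm(k, 0, spread)); pb <- pb / sum(pb)
    for (d in seq_along(depths)) {
      p <- (1 - tfrac[d]) * pa + tfrac[d] * pb
      rows <- (d - 1) * n_per + seq_len(n_per)
      a1[rows, l] <- sample.int(k, n_per, TRUE, prob = p)
      a2[rows, l] <- sample.int(k, n_per, TRUE, prob = p)
    }
  }
  list(gt = genotype_table(a1, a2),
       depth_cat = depth_category(rep(depths, each = n_per)))
}
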