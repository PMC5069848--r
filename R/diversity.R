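#' Per-group, per-locus allele frequencies
#'
#' Missing calls are excluded pairwise per locus. A locus with no observed
#' call in a group is flagged and excluded from multilocus summaries.
#'
#' @param gt A [genotype_table].
#' @param grouping Factor of group membership, one entry per individual.
#' @return A list per group (named by level) of lists per locus with elements
#'   `freq` (named frequency vector summing to 1), `n_genes` (observed gene
#'   count), and `flagged` (TRUE when the locus has no data in the group).
#' @export
allele_frequencies <- function(gt, grouping) {
  grouping <- factor(grouping)
  stopifnot(length(grouping) == n_individuals(gt))
  cm <- allele_count_matrices(gt)
  out <- lapply(levels(grouping), function(lev) {
    rows <- which(grouping == lev)
    lapply(seq_along(cm), function(l) {
      m <- cm[[l]][rows, , drop = FALSE]
      counts <- colSums(m, na.rm = TRUE)
      genes <- sum(counts)
      if (genes == 0)
        return(list(freq = counts, n_genes = 0L, flagged = TRUE))
      list(freq = counts / genes, n_genes = as.integer(genes), flagged = FALSE)
    })
  })
  names(out) <- levels(grouping)
  out
}

#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of heterozygous individuals among those genotyped;
#' `He` is expected heterozygosity with the small-sample correction
#' `2n/(2n - 1) * (1 - sum p^2)` where `n` is the number of genotyped
#' individuals. Monomorphic loci give `Ho = He = 0`.
#'
#' @inheritParams allele_frequencies
#' @return A list per group with matrices `Ho`, `He` (loci in rows) and
#'   multilocus means `Ho_mean`, `He_mean` over non-flagged loci.
#' @export
heterozygosities <- function(gt, grouping) {
  grouping <- factor(grouping)
  stopifnot(length(grouping) == n_individuals(gt))
  L <- n_loci(gt)
  out <- lapply(levels(grouping), function(lev) {
    rows <- which(grouping == lev)
    a1 <- gt$a1[rows, , drop = FALSE]
    a2 <- gt$a2[rows, , drop = FALSE]
    Ho <- He <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      ok <- !is.na(a1[, l])
      n <- sum(ok)
      if (n == 0) next
      Ho[l] <- mean(a1[ok, l] != a2[ok, l])
      p <- table(c(a1[ok, l], a2[ok, l])) / (2 * n)
      He[l] <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
    }
    names(Ho) <- names(He) <- gt$loci
    list(Ho = Ho, He = He,
         Ho_mean = mean(Ho, na.rm = TRUE), He_mean = mean(He, na.rm = TRUE))
  })
  names(out) <- levels(grouping)
  out
}

# Expected number of distinct alleles in g genes drawn without replacement
# from counts N_a (total N): sum_a [1 - C(N - N_a, g)/C(N, g)].
rarefy_counts <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction size g = ", g, " exceeds available genes (", N, ")")
  # lchoose is stable for large N
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' genes, computed from exact hypergeometric expectations (the HP-RARE
#' formulas), per locus and group.
#'
#' @inheritParams allele_frequencies
#' @param g Standardized gene count; must not exceed the smallest observed
#'   per-locus gene count across groups.
#' @return A matrix (loci x groups) of `Ar_g` values.
#' @export
rarefied_richness <- function(gt, grouping, g) {
  grouping <- factor(grouping)
  af <- allele_frequencies(gt, grouping)
  L <- n_loci(gt)
  out <- matrix(NA_real_, L, length(af), dimnames = list(gt$loci, names(af)))
  for (gl in seq_along(af)) for (l in seq_len(L)) {
    fl <- af[[gl]][[l]]
    if (fl$flagged) next
    counts <- round(fl$freq * fl$n_genes)
    out[l, gl] <- rarefy_counts(counts, g)
  }
  out
}

#' Rarefied private allelic richness
#'
#' Generalized private-allele rarefaction: the expected number of alleles
#' that appear in a subsample of `g` genes from the focal group and in none
#' of the other groups' subsamples of `g` genes each.
#'
#' @inheritParams rarefied_richness
#' @return A matrix (loci x groups) of `PAr_g` values.
#' @export
private_rarefied_richness <- function(gt, grouping, g) {
  grouping <- factor(grouping)
  af <- allele_frequencies(gt, grouping)
  G <- length(af)
  L <- n_loci(gt)
  # per group/locus: named allele count vectors aligned on the union
  out <- matrix(NA_real_, L, G, dimnames = list(gt$loci, names(af)))
  for (l in seq_len(L)) {
    alleles <- unique(unlist(lapply(af, function(gl) names(gl[[l]]$freq))))
    if (!length(alleles)) next
    cnt <- sapply(seq_len(G), function(i) {
      fl <- af[[i]][[l]]
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      if (!fl$flagged) v[names(fl$freq)] <- round(fl$freq * fl$n_genes)
      v
    })
    cnt <- matrix(cnt, ncol = G, dimnames = list(alleles, names(af)))
    Ntot <- colSums(cnt)
    if (any(Ntot > 0 & Ntot < g)) next  # g not attainable at this locus
    for (i in seq_len(G)) {
      if (Ntot[i] == 0) next
      pres_i <- 1 - exp(lchoose(Ntot[i] - cnt[, i], g) - lchoose(Ntot[i], g))
      abs_other <- rep(1, length(alleles))
      for (j in seq_len(G)[-i]) {
        if (Ntot[j] == 0) next
        abs_other <- abs_other *
          exp(lchoose(Ntot[j] - cnt[, j], g) - lchoose(Ntot[j], g))
      }
      out[l, i] <- sum(pres_i * abs_other)
    }
  }
  out
}

# Weir & Cockerham's within-population inbreeding coefficient (small f) for a
# single group, summed over alleles and loci: f = 1 - sum(c) / sum(b + c).
fis_single_group <- function(a1, a2) {
  sb <- sc <- 0
  for (l in seq_len(ncol(a1))) {
    ok <- !is.na(a1[, l])
    n <- sum(ok)
    if (n < 2) next
    x1 <- a1[ok, l]; x2 <- a2[ok, l]
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    for (al in alleles) {
      p <- (sum(x1 == al) + sum(x2 == al)) / (2 * n)
      h <- mean((x1 == al) != (x2 == al))
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      sb <- sb + b
      sc <- sc + h / 2
    }
  }
  if (sb + sc <= 0) return(NA_real_)
  1 - sc / (sb + sc)
}

#' Fis with a within-group allele permutation test
#'
#' Weir-Cockerham small-f per group, with a null distribution built by
#' permuting alleles among individuals within the group (each locus
#' independently), which tests Hardy-Weinberg proportions within groups.
#' Two-sided P: `(#{|f*| >= |f|} + 1) / (n_perm + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param n_perm Number of permutations (default 10000).
#' @return A data.frame with one row per group: `group`, `n`, `Fis`, `P`.
#'   Monomorphic groups give `Fis = NA`, `P = NA`.
#' @export
fis_test <- function(gt, grouping, n_perm = 10000) {
  grouping <- factor(grouping)
  stopifnot(length(grouping) == n_individuals(gt))
  res <- lapply(levels(grouping), function(lev) {
    rows <- which(grouping == lev)
    if (length(rows) < 2)
      return(data.frame(group = lev, n = length(rows), Fis = NA_real_, P = NA_real_))
    a1 <- gt$a1[rows, , drop = FALSE]
    a2 <- gt$a2[rows, , drop = FALSE]
    f_obs <- fis_single_group(a1, a2)
    if (is.na(f_obs))
      return(data.frame(group = lev, n = length(rows), Fis = NA_real_, P = NA_real_))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p1 <- a1; p2 <- a2
      for (l in seq_len(ncol(a1))) {
        ok <- which(!is.na(a1[, l]))
        genes <- sample(c(a1[ok, l], a2[ok, l]))
        p1[ok, l] <- genes[seq_along(ok)]
        p2[ok, l] <- genes[length(ok) + seq_along(ok)]
      }
      f_b <- fis_single_group(p1, p2)
      if (!is.na(f_b) && abs(f_b) >= abs(f_obs)) hits <- hits + 1L
    }
    data.frame(group = lev, n = length(rows), Fis = f_obs,
               P = (hits + 1) / (n_perm + 1))
  })
  do.call(rbind, res)
}

#' Multiple-testing corrections: SGoF and Bonferroni
#'
#' `sgof_correct()` implements the sequential goodness-of-fit metatest: with
#' `R` p-values at or below `alpha` among `n`, it declares significant the
#' `k` smallest p-values, where `k` is the number of counts `c` in `1..R`
#' whose one-sided binomial tail probability `P(Binom(n, alpha) >= c)` is at
#' or below `alpha` (equivalently, the test is applied sequentially,
#' decrementing the significant count while it remains an improbable excess).
#' `bonferroni_correct()` declares `p <= alpha / n`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return A logical vector marking significant tests (empty input gives an
#'   empty vector).
#' @export
sgof_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (n == 0L) return(logical(0))
  R <- sum(p <= alpha)
  if (R == 0L) return(rep(FALSE, n))
  tails <- stats::pbinom(seq_len(R) - 1L, n, alpha, lower.tail = FALSE)
  k <- sum(tails <= alpha + 1e-12)
  sig <- rep(FALSE, n)
  if (k > 0) sig[order(p)[seq_len(k)]] <- TRUE
  sig
}

#' @rdname sgof_correct
#' @export
bonferroni_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) == 0L) return(logical(0))
  p <= alpha / length(p)
}

#' Per-group diversity summary table
#'
#' Mean alleles per locus (`A`), rarefied allelic richness (`Ar_g`), private
#' allelic richness (`PAr_g`), observed and unbiased expected heterozygosity,
#' and Fis with permutation P, per group.
#'
#' @inheritParams fis_test
#' @param g Rarefaction gene count; defaults to the largest feasible value
#'   (smallest observed per-locus gene count over groups and loci).
#' @return A data.frame with one row per group.
#' @export
diversity_table <- function(gt, grouping, g = NULL, n_perm = 10000) {
  grouping <- factor(grouping)
  af <- allele_frequencies(gt, grouping)
  if (is.null(g)) {
    genes <- unlist(lapply(af, function(gl)
      vapply(gl, function(x) x$n_genes, 0L)))
    g <- min(genes[genes > 0])
  }
  A <- vapply(af, function(gl)
    mean(vapply(gl, function(x) if (x$flagged) NA_real_ else sum(x$freq > 0), 0),
         na.rm = TRUE), 0)
  Ar <- colMeans(rarefied_richness(gt, grouping, g), na.rm = TRUE)
  PAr <- colMeans(private_rarefied_richness(gt, grouping, g), na.rm = TRUE)
  het <- heterozygosities(gt, grouping)
  fis <- fis_test(gt, grouping, n_perm = n_perm)
  data.frame(
    group = names(af),
    N = as.integer(table(grouping)),
    A = A,
    Ar = Ar,
    PAr = PAr,
    Ho = vapply(het, function(h) h$Ho_mean, 0),
    He = vapply(het, function(h) h$He_mean, 0),
    Fis = fis$Fis,
    Fis_P = fis$P,
    rarefaction_g = g,
    row.names = NULL
  )
}
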