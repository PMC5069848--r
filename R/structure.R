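# Weir & Cockerham (1984) variance components per locus, summed over
# alleles: a (among populations), b (among individuals within populations),
# c (within individuals). theta = sum(a) / sum(a + b + c).
wc_components <- function(cm, grouping) {
  grouping <- factor(grouping)
  per_locus <- lapply(cm, function(m) {
    obs <- !is.na(m[, 1L])
    if (!any(obs)) return(c(a = 0, abc = 0))
    g <- droplevels(grouping[obs])
    m <- m[obs, , drop = FALSE]
    ni <- as.vector(table(g))
    r <- length(ni)
    if (r < 2 || any(ni < 1)) return(c(a = 0, abc = 0))
    nbar <- mean(ni)
    if (nbar <= 1) return(c(a = 0, abc = 0))
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    csum <- rowsum(m, g)                      # r x k allele counts
    p <- csum / (2 * ni)
    h <- rowsum((m == 1L) + 0, g) / ni        # heterozygote freq per allele
    pbar <- colSums(ni * p) / (r * nbar)
    s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(ni * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = sum(a), abc = sum(a + b + cc))
  })
  do.call(rbind, per_locus)
}

#' Multilocus Weir-Cockerham theta
#'
#' The variance-component Fst estimator: per-locus components are summed over
#' alleles and loci and combined as `sum(a) / sum(a + b + c)`. Negative
#' estimates are reported as computed, not truncated.
#'
#' @param gt A [genotype_table].
#' @param grouping Factor of group membership.
#' @return A list with `theta` (multilocus), `theta_by_locus`, and the
#'   per-locus component matrix `components` (columns `a`, `abc`).
#' @export
wc_theta <- function(gt, grouping) {
  stopifnot(length(grouping) == n_individuals(gt))
  comp <- wc_components(allele_count_matrices(gt), grouping)
  rownames(comp) <- gt$loci
  theta_l <- ifelse(comp[, "abc"] != 0, comp[, "a"] / comp[, "abc"], NA_real_)
  denom <- sum(comp[, "abc"])
  list(theta = if (denom != 0) sum(comp[, "a"]) / denom else NA_real_,
       theta_by_locus = theta_l,
       components = comp)
}

#' Pairwise Fst with permutation tests
#'
#' Weir-Cockerham theta for every pair of groups; significance by permuting
#' individuals between the two groups of a pair (one-sided:
#' `P = (#{theta* >= theta} + 1) / (n_perm + 1)`).
#'
#' @inheritParams wc_theta
#' @param n_perm Number of permutations (default 10000).
#' @return A list with symmetric matrices `fst` and `P` (diagonal zero and
#'   NA respectively). Pairs where every locus is monomorphic give NA.
#' @export
pairwise_fst <- function(gt, grouping, n_perm = 10000) {
  grouping <- factor(grouping)
  stopifnot(length(grouping) == n_individuals(gt))
  levs <- levels(grouping)
  if (length(levs) < 2) stop("need at least two groups")
  cm <- allele_count_matrices(gt)
  G <- length(levs)
  fst <- matrix(0, G, G, dimnames = list(levs, levs))
  P <- matrix(NA_real_, G, G, dimnames = list(levs, levs))
  theta_of <- function(rows, lab) {
    sub <- lapply(cm, function(m) m[rows, , drop = FALSE])
    comp <- wc_components(sub, lab)
    denom <- sum(comp[, "abc"])
    if (denom != 0) sum(comp[, "a"]) / denom else NA_real_
  }
  for (i in seq_len(G - 1)) for (j in seq(i + 1, G)) {
    rows <- which(grouping %in% levs[c(i, j)])
    lab <- droplevels(grouping[rows])
    obs <- theta_of(rows, lab)
    fst[i, j] <- fst[j, i] <- obs
    if (is.na(obs)) next
    hits <- 0L
    for (b in seq_len(n_perm)) {
      tb <- theta_of(rows, sample(lab))
      if (!is.na(tb) && tb >= obs) hits <- hits + 1L
    }
    P[i, j] <- P[j, i] <- (hits + 1) / (n_perm + 1)
  }
  list(fst = fst, P = P)
}

#' Locus-bootstrap confidence interval for multilocus theta
#'
#' Percentile interval over resampled loci, with the derived standard error
#' `SE = (upper - lower) / 3.92`.
#'
#' @inheritParams wc_theta
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return A list with `theta`, `lower`, `upper`, `se`, `n_boot`.
#' @export
fst_bootstrap_ci <- function(gt, grouping, n_boot = 1000, conf = 0.95) {
  if (n_loci(gt) < 2)
    stop("locus bootstrap requires at least two loci")
  comp <- wc_components(allele_count_matrices(gt), factor(grouping))
  L <- nrow(comp)
  obs <- sum(comp[, "a"]) / sum(comp[, "abc"])
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(L, L, replace = TRUE)
    den <- sum(comp[idx, "abc"])
    if (den != 0) sum(comp[idx, "a"]) / den else NA_real_
  }, 0)
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(theta = obs, lower = qs[1], upper = qs[2],
       se = ci_to_se(qs[1], qs[2]), n_boot = n_boot)
}

#' Convert a 95% confidence interval to a standard error
#'
#' `SE = (upper - lower) / 3.92`, i.e. the CI width divided by two 1.96
#' normal quantiles.
#'
#' @param lower,upper Confidence limits.
#' @return The implied standard error.
#' @examples
#' ci_to_se(0.10, 0.30) # 0.05102
#' @export
ci_to_se <- function(lower, upper) {
  if (any(upper < lower)) stop("upper limit below lower limit")
  (upper - lower) / 3.92
}

# Jost's Dest for one locus from per-population allele counts (r x k),
# sample sizes (individuals) and observed heterozygosities, with the
# Nei-Chesser small-sample corrections and the r/(r-1) scaling.
dest_locus <- function(counts, n_ind, ho) {
  keep <- rowSums(counts) > 0 & n_ind > 0
  counts <- counts[keep, , drop = FALSE]
  n_ind <- n_ind[keep]
  ho <- ho[keep]
  r <- nrow(counts)
  if (r < 2) return(NA_real_)
  p <- counts / rowSums(counts)
  ntilde <- r / sum(1 / n_ind)                 # harmonic mean sample size
  hs_plug <- mean(1 - rowSums(p^2))
  ho_bar <- mean(ho)
  hs <- ntilde / (ntilde - 1) * (hs_plug - ho_bar / (2 * ntilde))
  pbar <- colMeans(p)
  ht_plug <- 1 - sum(pbar^2)
  ht <- ht_plug + hs / (2 * ntilde * r)
  if (1 - hs <= 0) return(NA_real_)
  (ht - hs) / (1 - hs) * r / (r - 1)
}

# harmonic-mean combination across loci; delta-method fallback when some
# per-locus values are non-positive (the harmonic mean is undefined there),
# clamped to [min(d), mean(d)] because var/mean degenerates near zero
combine_dest <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  if (all(d > 0)) return(1 / mean(1 / d))
  m <- mean(d)
  if (m <= 0) return(m)
  max(min(m - stats::var(d) / m, m), min(d))
}

# per-locus Dest for a set of groups defined by `grouping`
dest_by_locus <- function(gt, grouping) {
  grouping <- factor(grouping)
  vapply(seq_len(n_loci(gt)), function(l) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    ok <- !is.na(a1)
    g <- droplevels(grouping[ok])
    if (nlevels(g) < 2) return(NA_real_)
    x1 <- a1[ok]; x2 <- a2[ok]
    alleles <- sort(unique(c(x1, x2)))
    counts <- rowsum(outer(x1, alleles, "==") + outer(x2, alleles, "==") + 0, g)
    n_ind <- as.vector(table(g))
    ho <- as.vector(rowsum((x1 != x2) + 0, g)) / n_ind
    dest_locus(counts, n_ind, ho)
  }, 0)
}

#' Pairwise Jost's D with bootstrap significance
#'
#' Dest (the effective-allele differentiation measure) per locus with
#' small-sample corrections, combined across loci by the harmonic mean. The
#' null distribution is built by parametric bootstrap from the pooled pair:
#' genotypes are redrawn in Hardy-Weinberg proportions from the pooled
#' allele frequencies, so `P = (#{D* >= D} + 1) / (n_boot + 1)`. A
#' Bonferroni flag across pairs is included.
#'
#' @inheritParams wc_theta
#' @param n_boot Number of bootstrap resamplings (default 10000).
#' @param alpha Level for the Bonferroni flag (default 0.05).
#' @return A list with matrices `D`, `P`, and `significant_bonferroni`.
#' @export
jost_d <- function(gt, grouping, n_boot = 10000, alpha = 0.05) {
  grouping <- factor(grouping)
  stopifnot(length(grouping) == n_individuals(gt))
  levs <- levels(grouping)
  if (length(levs) < 2) stop("need at least two groups")
  G <- length(levs)
  D <- matrix(0, G, G, dimnames = list(levs, levs))
  P <- matrix(NA_real_, G, G, dimnames = list(levs, levs))
  L <- n_loci(gt)
  for (i in seq_len(G - 1)) for (j in seq(i + 1, G)) {
    rows <- which(grouping %in% levs[c(i, j)])
    sub <- subset_individuals(gt, rows)
    lab <- droplevels(grouping[rows])
    d_obs <- combine_dest(dest_by_locus(sub, lab))
    D[i, j] <- D[j, i] <- d_obs
    if (is.na(d_obs)) next
    # pooled allele frequencies per locus for the null
    pooled <- lapply(seq_len(L), function(l) {
      x <- c(sub$a1[, l], sub$a2[, l])
      x <- x[!is.na(x)]
      if (!length(x)) return(NULL)
      tab <- table(x)
      list(alleles = as.integer(names(tab)), p = as.vector(tab) / sum(tab))
    })
    n1 <- sum(lab == levs[i]); n2 <- sum(lab == levs[j])
    hits <- 0L
    for (b in seq_len(n_boot)) {
      d_l <- vapply(seq_len(L), function(l) {
        pl <- pooled[[l]]
        if (is.null(pl) || length(pl$alleles) < 2) return(NA_real_)
        k <- length(pl$alleles)
        draw <- function(n) {
          g1 <- sample.int(k, n, replace = TRUE, prob = pl$p)
          g2 <- sample.int(k, n, replace = TRUE, prob = pl$p)
          list(counts = tabulate(g1, k) + tabulate(g2, k),
               ho = mean(g1 != g2))
        }
        s1 <- draw(n1); s2 <- draw(n2)
        dest_locus(rbind(s1$counts, s2$counts), c(n1, n2), c(s1$ho, s2$ho))
      }, 0)
      db <- combine_dest(d_l)
      if (!is.na(db) && db >= d_obs) hits <- hits + 1L
    }
    P[i, j] <- P[j, i] <- (hits + 1) / (n_boot + 1)
  }
  npair <- n_pairs(G)
  sig <- !is.na(P) & P <= alpha / npair
  diag(sig) <- NA
  list(D = D, P = P, significant_bonferroni = sig)
}

#' One-level AMOVA on genotypic distances
#'
#' Analysis of molecular variance partitioning total allelic variance among
#' and within groups, on the squared allele-count distance of
#' [genotype_distance2()]. `Fct = sigma2_among / sigma2_total`; significance
#' by permuting whole individuals across groups.
#'
#' @param gt A [genotype_table], or a precomputed squared-distance matrix.
#' @param grouping Factor of group membership (use `interaction()` for
#'   factor crossings; empty cells are dropped).
#' @param n_perm Number of permutations (default 10000).
#' @return A list of class `amova_result` with elements `table` (source,
#'   d.f., sum of squares, variance component, percent of variation), `Fct`,
#'   and `P`.
#' @export
amova <- function(gt, grouping, n_perm = 10000) {
  d2 <- if (inherits(gt, "genotype_table")) genotype_distance2(gt) else as.matrix(gt)
  grouping <- droplevels(factor(grouping))
  N <- nrow(d2)
  stopifnot(length(grouping) == N)
  G <- nlevels(grouping)
  if (G < 2) stop("AMOVA needs at least two non-empty groups")
  decompose <- function(g) {
    ss_total <- sum(d2) / (2 * N)   # sum over i<j of d2 / N
    ss_within <- 0
    ni <- as.vector(table(g))
    for (lev in levels(g)) {
      rows <- which(g == lev)
      ss_within <- ss_within + sum(d2[rows, rows]) / (2 * length(rows))
    }
    ss_among <- ss_total - ss_within
    df_among <- nlevels(g) - 1
    df_within <- N - nlevels(g)
    ms_within <- ss_within / df_within
    n0 <- (N - sum(ni^2) / N) / df_among
    sigma_among <- (ss_among / df_among - ms_within) / n0
    sigma_within <- ms_within
    tot <- sigma_among + sigma_within
    list(ss = c(ss_among, ss_within, ss_total),
         df = c(df_among, df_within, N - 1),
         sigma = c(sigma_among, sigma_within),
         fct = if (tot != 0) sigma_among / tot else NA_real_)
  }
  obs <- decompose(grouping)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    fb <- decompose(sample(grouping))$fct
    if (!is.na(fb) && fb >= obs$fct) hits <- hits + 1L
  }
  P <- (hits + 1) / (n_perm + 1)
  tot <- sum(obs$sigma)
  tab <- data.frame(
    source = c("Among groups", "Within groups", "Total"),
    df = obs$df,
    sum_sq = obs$ss,
    variance = c(obs$sigma, tot),
    pct_variation = c(100 * obs$sigma / tot, 100)
  )
  structure(list(table = tab, Fct = obs$fct, P = P, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Fct = %.4f, P = %.4g (%d permutations)\n", x$Fct, x$P, x$n_perm))
  invisible(x)
}

#' Rank grouping factors by AMOVA Fct
#'
#' Runs a one-level AMOVA for each candidate factor and (optionally) each
#' two-way crossing, then orders sources by significant Fct — the
#' factor-ranking step that decides which grouping drives downstream
#' analyses. Sources that collapse to a single non-empty group are skipped
#' with a warning.
#'
#' @param gt A [genotype_table].
#' @param frame Sample frame (data.frame) holding the factor columns.
#' @param factors Character vector of factor column names.
#' @param crossings Include all two-way factor crossings (default TRUE).
#' @param n_perm Permutations per AMOVA.
#' @param alpha Significance level for the ranking (default 0.05).
#' @return A data.frame ordered by decreasing Fct among significant sources
#'   first, with columns `source`, `Fct`, `df`, `sum_sq`, `variance`,
#'   `pct_variation`, `P`, `significant`.
#' @export
amova_rank <- function(gt, frame, factors = c("ecotype", "zone", "stratum"),
                       crossings = TRUE, n_perm = 10000, alpha = 0.05) {
  d2 <- genotype_distance2(gt)
  sources <- stats::setNames(as.list(factors), factors)
  if (crossings && length(factors) > 1) {
    for (pair in utils::combn(factors, 2, simplify = FALSE))
      sources[[paste(pair, collapse = " and ")]] <- pair
  }
  rows <- lapply(names(sources), function(nm) {
    cols <- sources[[nm]]
    g <- droplevels(interaction(frame[cols], drop = TRUE, sep = ":"))
    if (nlevels(g) < 2) {
      warning("source '", nm, "' has a single non-empty group; skipped")
      return(NULL)
    }
    res <- amova(d2, g, n_perm = n_perm)
    data.frame(source = nm, Fct = res$Fct,
               df = res$table$df[1], sum_sq = res$table$sum_sq[1],
               variance = res$table$variance[1],
               pct_variation = res$table$pct_variation[1], P = res$P)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$P <= alpha
  out[order(-out$significant, -out$Fct), , drop = FALSE]
}

# all permutations of 1..n as rows (n <= 7 kept sane: 5040 rows)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangle, with
#' significance by simultaneous row/column permutation of one matrix.
#' For matrices of size 6 or smaller the permutation distribution is
#' enumerated exactly. One-sided P (positive association).
#'
#' @param dist_a,dist_b Square symmetric matrices with matching labels.
#' @param n_perm Number of permutations (default 9999; ignored under exact
#'   enumeration).
#' @param method `"auto"` (exact for n <= 6), `"exact"`, or `"permutation"`.
#' @return A list of class `mantel_result` with `r_m`, `P`, `n_perm`,
#'   `method`, `n`.
#' @export
mantel <- function(dist_a, dist_b, n_perm = 9999,
                   method = c("auto", "exact", "permutation")) {
  method <- match.arg(method)
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  n <- nrow(a)
  if (n < 4) stop("Mantel test requires more than three points")
  if (!all(dim(a) == c(n, n)) || !all(dim(b) == c(n, n)))
    stop("matrices must be square and of equal size")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !all(rownames(a) == rownames(b)))
    stop("matrix labels disagree")
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], b[ut])
  if (method == "auto") method <- if (n <= 6) "exact" else "permutation"
  if (method == "exact") {
    pm <- perms(n)
    rs <- apply(pm, 1L, function(ix) {
      bp <- b[ix, ix]
      stats::cor(a[ut], bp[ut])
    })
    P <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(pm)
  } else {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      ix <- sample.int(n)
      bp <- b[ix, ix]
      if (stats::cor(a[ut], bp[ut]) >= r_obs - 1e-12) hits <- hits + 1L
    }
    P <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r_m = r_obs, P = P, n_perm = n_used, method = method, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (n = %d, %s): r_m = %.3f, P = %.4g\n",
              x$n, x$method, x$r_m, x$P))
  invisible(x)
}

#' Build the depth-category matrices for the isolation-by-depth Mantel test
#'
#' Genetic matrix: pairwise linearized theta, `theta / (1 - theta)`, among
#' the depth-category groups. Depth matrix: absolute difference in metres
#' between category depths (the `>120 m` category counts as 120 m). An
#' optional outlier interpolation replaces the most outlying genetic entry
#' (largest absolute residual from the genetic-on-depth regression over the
#' upper triangle) and its symmetric twin by the mean of the remaining
#' entries sharing a row or column with it.
#'
#' @param gt A [genotype_table].
#' @param depth_cat Factor of depth-category membership per individual.
#' @param interpolate_outlier Apply the outlier replacement (default FALSE).
#' @return A list with `genetic` and `depth` matrices ready for [mantel()].
#' @export
depth_mantel_matrices <- function(gt, depth_cat, interpolate_outlier = FALSE) {
  depth_cat <- droplevels(factor(depth_cat))
  levs <- levels(depth_cat)
  if (length(levs) < 4)
    stop("Mantel test requires more than three depth categories")
  pf <- pairwise_fst(gt, depth_cat, n_perm = 0)
  theta <- pf$fst
  gen <- theta / (1 - theta)
  diag(gen) <- 0
  metres <- depth_category_metres(levs)
  if (anyNA(metres)) metres <- as.numeric(gsub("[^0-9.]", "", levs))
  dep <- abs(outer(metres, metres, "-"))
  dimnames(dep) <- dimnames(gen)
  if (interpolate_outlier) {
    ut <- which(upper.tri(gen), arr.ind = TRUE)
    fit <- stats::lm(gen[upper.tri(gen)] ~ dep[upper.tri(dep)])
    res <- stats::rstandard(fit)
    worst <- ut[which.max(abs(res)), ]
    i <- worst[1]; j <- worst[2]
    neighbours <- c(gen[i, -c(i, j)], gen[-c(i, j), j])
    gen[i, j] <- gen[j, i] <- mean(neighbours)
  }
  list(genetic = gen, depth = dep)
}

#' Principal coordinates analysis of individual genotypes
#'
#' Double-centers the squared allele-count genotypic distance and
#' eigendecomposes it (classical multidimensional scaling). Negative
#' eigenvalues are reported; percent variance is taken over positive
#' eigenvalues only.
#'
#' @param gt A [genotype_table].
#' @param k Number of axes to return (default `min(n - 1, 10)`).
#' @return A list with `coordinates`, `eigenvalues`, `pct_variance`,
#'   `n_negative_eigenvalues`, and `degenerate` (TRUE when all distances
#'   are zero).
#' @export
pcoa_individuals <- function(gt, k = NULL) {
  n <- n_individuals(gt)
  if (n < 3) stop("PCoA needs at least three individuals")
  d2 <- genotype_distance2(gt)
  if (all(d2 == 0)) {
    warning("all genotypic distances are zero; ordination is degenerate")
    return(list(coordinates = matrix(0, n, 1, dimnames = list(gt$ids, "Axis1")),
                eigenvalues = 0, pct_variance = NA_real_,
                n_negative_eigenvalues = 0L, degenerate = TRUE))
  }
  if (is.null(k)) k <- min(n - 1L, 10L)
  mds <- stats::cmdscale(sqrt(d2), k = k, eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-8]
  got <- ncol(mds$points)
  colnames(mds$points) <- paste0("Axis", seq_len(got))
  list(coordinates = mds$points,
       eigenvalues = mds$eig,
       pct_variance = 100 * mds$eig[seq_len(got)] / sum(pos),
       n_negative_eigenvalues = sum(mds$eig < -1e-8),
       degenerate = FALSE)
}
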