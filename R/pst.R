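# One-way random-effects variance components by the method of moments:
# sigma2_within = MSW, sigma2_between = (MSB - MSW)/n0 truncated at zero.
one_way_vc <- function(x, g) {
  g <- droplevels(factor(g))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  ni <- as.vector(table(g))
  G <- length(ni)
  N <- sum(ni)
  if (G < 2 || any(ni < 1)) return(c(s2b = NA_real_, s2w = NA_real_))
  m <- tapply(x, g, mean)
  grand <- mean(x)
  msb <- sum(ni * (m - grand)^2) / (G - 1)
  msw <- sum((x - m[g])^2) / (N - G)
  n0 <- (N - sum(ni^2) / N) / (G - 1)
  c(s2b = max(0, (msb - msw) / n0), s2w = msw)
}

#' Pst from one-way variance components
#'
#' `Pst = sigma2_B / (sigma2_B + 2 h2 sigma2_W)`, the phenotypic analogue of
#' Fst, from method-of-moments one-way variance components (negative
#' between-group components truncated at zero). The bootstrap resamples
#' individuals within groups (group sizes preserved) and returns a
#' percentile confidence interval.
#'
#' @param trait Numeric (size-adjusted) trait values.
#' @param grouping Factor of group membership (>= 2 groups).
#' @param h2 Heritability scalar in (0, 1], default 1.0 (conservative: at
#'   h2 = 1 Pst is smallest, so selection calls are prone to false
#'   negatives, not false positives).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `pst_result` with `Pst`, `lower`, `upper`,
#'   `sigma2_between`, `sigma2_within`, `h2`. Both components zero gives NA.
#' @export
pst_variance_components <- function(trait, grouping, h2 = 1.0, n_boot = 1000,
                                    conf = 0.95) {
  stopifnot(h2 > 0, h2 <= 1)
  grouping <- factor(grouping)
  ok <- !is.na(trait) & !is.na(grouping)
  trait <- trait[ok]; grouping <- droplevels(grouping[ok])
  if (nlevels(grouping) < 2) stop("need at least two groups")
  vc <- one_way_vc(trait, grouping)
  pst_of <- function(v) {
    tot <- v["s2b"] + 2 * h2 * v["s2w"]
    if (is.na(tot) || tot == 0) return(NA_real_)
    unname(v["s2b"] / tot)
  }
  est <- pst_of(vc)
  idx_by_group <- split(seq_along(trait), grouping)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(idx_by_group, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    pst_of(one_way_vc(trait[idx], grouping[idx]))
  }, 0)
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(Pst = est, lower = ci[1], upper = ci[2],
                 sigma2_between = unname(vc["s2b"]),
                 sigma2_within = unname(vc["s2w"]),
                 h2 = h2, n_boot = n_boot),
            class = "pst_result")
}

#' @export
print.pst_result <- function(x, ...) {
  cat(sprintf("Pst = %.4f (95%% CI %.4f-%.4f), h2 = %g\n",
              x$Pst, x$lower, x$upper, x$h2))
  invisible(x)
}

# core of the R-matrix estimator, operating on a numeric trait matrix
# (columns standardized internally) and a grouping factor
r_matrix_core <- function(X, g, h2, sample_size_correction) {
  g <- droplevels(factor(g))
  ni <- as.vector(table(g))
  G <- length(ni)
  N <- sum(ni)
  t_n <- ncol(X)
  w <- ni / N
  # pooled within-group variance per trait (the Mahalanobis scale)
  M <- apply(X, 2, function(col) tapply(col, g, mean))
  M <- matrix(M, nrow = G)
  s2 <- vapply(seq_len(t_n), function(k)
    sum((X[, k] - M[as.integer(g), k])^2) / (N - G), 0)
  if (any(s2 <= 0)) return(NULL)
  Ms <- sweep(M, 2, sqrt(s2), "/")
  grand <- colSums(w * Ms)
  Mc <- sweep(Ms, 2, grand, "-")
  C <- Mc %*% t(Mc) / t_n
  if (sample_size_correction) {
    sw <- sum(w^2 / ni)
    Tmat <- outer(-w / ni, -w / ni, "+") + sw
    diag(Tmat) <- (1 - 2 * w) / ni + sw
    C <- C - Tmat
  }
  # unbias the weighted mean of squares as an estimate of the
  # between-group variance (factor 1/(1 - sum w^2))
  C <- C / (1 - sum(w^2))
  R0 <- C / (2 * h2)
  A <- max(0, sum(w * diag(R0)))
  R <- R0 / (1 + A)
  D2 <- outer(diag(R), diag(R), "+") - 2 * R
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  dimnames(R) <- dimnames(D2) <- list(levels(g), levels(g))
  list(R = R, D2 = D2, global_Pst = A / (1 + A))
}

#' R-matrix estimate of among-group phenotypic divergence
#'
#' Relethford-Blangero style relationship matrix from (size-adjusted) trait
#' group means: traits are standardized by the pooled within-group standard
#' deviation, group means are centered on the sample-size-weighted grand
#' mean, the mean squared codivergence across traits is scaled by
#' `1/(2 h2)` and renormalized so that the sample-size-weighted mean of the
#' diagonal `r_ii` equals the global Pst on the Fst scale,
#' `global_Pst = A / (1 + A)` with `A = sum(w_i r_ii)`. The sample-size
#' correction subtracts the exact sampling contribution of each group mean
#' (`(1 - 2 w_i)/n_i + sum w_j^2/n_j` on the diagonal, with the matching
#' covariance term off-diagonal). `D2_ij = r_ii + r_jj - 2 r_ij` is the
#' Mahalanobis-type squared distance between group means; its SE comes from
#' a bootstrap over individuals within groups.
#'
#' @param traits Numeric matrix or data.frame of trait values (individuals x
#'   traits), already size-adjusted where appropriate.
#' @param grouping Factor of group membership; all groups need >= 2 members.
#' @param h2 Heritability scalar (default 1.0).
#' @param sample_size_correction Apply the diagonal/off-diagonal sampling
#'   correction (default TRUE).
#' @param n_boot Bootstrap replicates for SEs (default 1000).
#' @param conf Confidence level for the global Pst interval (default 0.95).
#' @return A list of class `rmatrix_result`: `R`, `rii`, `D2`, `D2_se`,
#'   `global_Pst`, `global_Pst_ci`, `h2`, `sample_size_correction`.
#' @export
r_matrix <- function(traits, grouping, h2 = 1.0, sample_size_correction = TRUE,
                     n_boot = 1000, conf = 0.95) {
  stopifnot(h2 > 0, h2 <= 1)
  X <- as.matrix(traits)
  storage.mode(X) <- "double"
  grouping <- factor(grouping)
  ok <- stats::complete.cases(X) & !is.na(grouping)
  X <- X[ok, , drop = FALSE]
  g <- droplevels(grouping[ok])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two individuals")
  est <- r_matrix_core(X, g, h2, sample_size_correction)
  if (is.null(est)) stop("a trait has zero pooled within-group variance")
  idx_by_group <- split(seq_len(nrow(X)), g)
  G <- nlevels(g)
  boot_d2 <- array(NA_real_, c(G, G, n_boot))
  boot_glob <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_group, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    eb <- r_matrix_core(X[idx, , drop = FALSE], g[idx], h2,
                        sample_size_correction)
    if (is.null(eb)) next
    boot_d2[, , b] <- eb$D2
    boot_glob[b] <- eb$global_Pst
  }
  D2_se <- apply(boot_d2, c(1, 2), stats::sd, na.rm = TRUE)
  dimnames(D2_se) <- dimnames(est$D2)
  ci <- stats::quantile(boot_glob, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(R = est$R, rii = diag(est$R), D2 = est$D2, D2_se = D2_se,
                 global_Pst = est$global_Pst, global_Pst_ci = ci,
                 h2 = h2, sample_size_correction = sample_size_correction,
                 n_boot = n_boot),
            class = "rmatrix_result")
}

#' @export
print.rmatrix_result <- function(x, ...) {
  cat(sprintf("R-matrix over %d groups: global Pst = %.4f (95%% CI %.4f-%.4f)\n",
              nrow(x$R), x$global_Pst, x$global_Pst_ci[1], x$global_Pst_ci[2]))
  invisible(x)
}

#' Classify traits as selection- or drift-consistent from Pst vs Fst
#'
#' Per trait: `selection` when the Pst lower confidence limit exceeds the
#' Fst upper confidence limit; `below-neutral` when the Pst upper limit is
#' below the Fst lower limit; `drift` when the intervals overlap;
#' `indeterminate` when a limit is missing. At h2 = 1 the classification is
#' conservative (prone to type-II, not type-I, errors).
#'
#' @param pst_results Named list of [pst_variance_components()] results (or
#'   a data.frame with columns `trait`, `Pst`, `lower`, `upper`).
#' @param fst_lower,fst_upper Confidence limits of the neutral Fst.
#' @return A data.frame: `trait`, `Pst`, `Pst_lower`, `Pst_upper`,
#'   `Fst_lower`, `Fst_upper`, `classification`.
#' @export
classify_selection <- function(pst_results, fst_lower, fst_upper) {
  if (is.data.frame(pst_results)) {
    tab <- pst_results
  } else {
    tab <- do.call(rbind, lapply(names(pst_results), function(nm) {
      p <- pst_results[[nm]]
      data.frame(trait = nm, Pst = p$Pst, lower = p$lower, upper = p$upper)
    }))
  }
  cls <- vapply(seq_len(nrow(tab)), function(i) {
    lo <- tab$lower[i]; up <- tab$upper[i]
    if (is.na(lo) || is.na(up) || is.na(fst_lower) || is.na(fst_upper))
      return("indeterminate")
    if (lo > fst_upper) return("selection")
    if (up < fst_lower) return("below-neutral")
    "drift"
  }, "")
  data.frame(trait = tab$trait, Pst = tab$Pst,
             Pst_lower = tab$lower, Pst_upper = tab$upper,
             Fst_lower = fst_lower, Fst_upper = fst_upper,
             classification = cls)
}

#' Paired comparison of phenotypic D2 and genetic Fst across depth strata
#'
#' For each trait, the Mahalanobis `D2` between each ordered stratum pair is
#' compared with the corresponding pairwise Fst. The monotone flag marks
#' traits whose divergence grows with depth separation (the endpoint pair
#' exceeding both adjacent pairs).
#'
#' @param traits Data.frame/matrix of (size-adjusted) traits, or a named
#'   list mapping trait name to a single-trait [r_matrix()] result.
#' @param grouping Factor of stratum membership (used when `traits` holds
#'   raw columns).
#' @param fst Pairwise Fst list from [pairwise_fst()] (matrices `fst`, `P`).
#' @param stratum_order Stratum levels from shallow to deep (length 3).
#' @param h2,n_boot Passed to [r_matrix()] when fitting per-trait.
#' @return A data.frame with one row per trait and pair: `trait`, `pair`,
#'   `D2`, `D2_se`, `Fst`, `Fst_P`, `monotone_increase`.
#' @export
d2_vs_depth <- function(traits, grouping = NULL, fst, stratum_order,
                        h2 = 1.0, n_boot = 1000) {
  if (length(stratum_order) != 3) stop("expected three ordered strata")
  if (!is.list(traits) || is.data.frame(traits)) {
    X <- as.data.frame(traits)
    rmats <- lapply(X, function(col)
      r_matrix(matrix(col, ncol = 1), grouping, h2 = h2, n_boot = n_boot))
    names(rmats) <- names(X)
  } else rmats <- traits
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  out <- do.call(rbind, lapply(names(rmats), function(nm) {
    rm <- rmats[[nm]]
    d2v <- vapply(pairs, function(p)
      rm$D2[stratum_order[p[1]], stratum_order[p[2]]], 0)
    rows <- do.call(rbind, lapply(seq_along(pairs), function(k) {
      p <- pairs[[k]]
      data.frame(
        trait = nm,
        pair = paste(stratum_order[p[1]], "vs", stratum_order[p[2]]),
        D2 = d2v[k],
        D2_se = rm$D2_se[stratum_order[p[1]], stratum_order[p[2]]],
        Fst = fst$fst[stratum_order[p[1]], stratum_order[p[2]]],
        Fst_P = fst$P[stratum_order[p[1]], stratum_order[p[2]]])
    }))
    rows$monotone_increase <- d2v[3] > d2v[1] & d2v[3] > d2v[2]
    rows
  }))
  rownames(out) <- NULL
  out
}
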