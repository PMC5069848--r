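#' Percent buoyancy
#'
#' `100 * (weight_air - weight_water) / weight_air`. Values above 100
#' (negative in-water weight) are permitted with a warning.
#'
#' @param weight_air,weight_water Weights of the fish measured in air and in
#'   water (same units).
#' @return Percent buoyancy.
#' @examples
#' compute_buoyancy(100, 5) # 95
#' @export
compute_buoyancy <- function(weight_air, weight_water) {
  if (any(weight_air <= 0, na.rm = TRUE))
    stop("weight in air must be positive")
  out <- 100 * (weight_air - weight_water) / weight_air
  if (any(out > 100, na.rm = TRUE))
    warning("buoyancy above 100% (negative in-water weight) for ",
            sum(out > 100, na.rm = TRUE), " observation(s)")
  out
}

#' Allometric size adjustment by studentized residuals
#'
#' Regresses `log10(trait)` on `log10(SL)` (ordinary least squares; the
#' log-log dialect is the default because allometry is multiplicative) and
#' returns studentized residuals as the size-adjusted variable. Internal
#' studentization is the default; set `external = TRUE` for leave-one-out
#' studentization.
#'
#' @param trait Strictly positive trait measurements.
#' @param SL Strictly positive standard lengths.
#' @param log_SL Log10-transform the regressor as well (default TRUE).
#' @param external Use externally studentized residuals (default FALSE).
#' @param ids Optional ids used in error messages.
#' @return Numeric vector of studentized residuals (NA where inputs are NA).
#' @export
size_adjust <- function(trait, SL, log_SL = TRUE, external = FALSE, ids = NULL) {
  if (length(trait) != length(SL)) stop("trait and SL lengths differ")
  if (is.null(ids)) ids <- seq_along(trait)
  ok <- !is.na(trait) & !is.na(SL)
  bad <- ok & (trait <= 0 | SL <= 0)
  if (any(bad))
    stop("non-positive measurement(s) for id(s): ",
         paste(ids[bad], collapse = ", "))
  if (sum(ok) < 3) stop("need at least 3 complete observations")
  y <- log10(trait[ok])
  x <- if (log_SL) log10(SL[ok]) else SL[ok]
  fit <- stats::lm(y ~ x)
  if (stats::sigma(fit)^2 <= 1e-12 * max(stats::var(y), .Machine$double.eps)) {
    # numerically perfect allometry: studentization degenerates to 0/0
    res <- rep(0, sum(ok))
  } else {
    res <- if (external) stats::rstudent(fit) else stats::rstandard(fit)
    res[!is.finite(res)] <- 0
  }
  out <- rep(NA_real_, length(trait))
  out[ok] <- res
  out
}

#' One-way ANOVA with Fisher's LSD post hoc tests
#'
#' Classical one-way ANOVA followed by pairwise least-significant-difference
#' t-tests using the pooled mean squared error, with unadjusted P-values
#' (that is what Fisher's LSD is), gated on the omnibus test at `alpha`.
#' Singleton groups are dropped with a warning.
#'
#' @param trait Numeric response.
#' @param grouping Factor of group membership.
#' @param alpha Omnibus gate level (default 0.05).
#' @param conf Confidence level for group-mean CIs (default 0.95).
#' @return A list of class `anova_lsd` with `F`, `df_between`, `df_within`,
#'   `P`, `group_means` (mean, n, CI per group), and `lsd` (pairwise mean
#'   differences with P; NULL when the omnibus test is not significant).
#' @export
anova_lsd <- function(trait, grouping, alpha = 0.05, conf = 0.95) {
  grouping <- factor(grouping)
  ok <- !is.na(trait) & !is.na(grouping)
  trait <- trait[ok]
  grouping <- droplevels(grouping[ok])
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    warning("dropping singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- grouping %in% names(sizes)[sizes >= 2]
    trait <- trait[keep]
    grouping <- droplevels(grouping[keep])
    sizes <- table(grouping)
  }
  G <- nlevels(grouping)
  if (G < 2) stop("need at least two groups with two or more observations")
  fit <- stats::lm(trait ~ grouping)
  av <- stats::anova(fit)
  F_stat <- av$`F value`[1]
  P <- av$`Pr(>F)`[1]
  dfw <- av$Df[2]
  mse <- av$`Mean Sq`[2]
  means <- tapply(trait, grouping, mean)
  tcrit <- stats::qt(1 - (1 - conf) / 2, dfw)
  gm <- data.frame(group = levels(grouping), n = as.vector(sizes),
                   mean = as.vector(means),
                   lower = as.vector(means) - tcrit * sqrt(mse / sizes),
                   upper = as.vector(means) + tcrit * sqrt(mse / sizes))
  lsd <- NULL
  if (!is.na(P) && P <= alpha) {
    pairs <- utils::combn(levels(grouping), 2, simplify = FALSE)
    lsd <- do.call(rbind, lapply(pairs, function(pr) {
      d <- means[pr[1]] - means[pr[2]]
      se <- sqrt(mse * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
      tval <- d / se
      data.frame(group_1 = pr[1], group_2 = pr[2], diff = unname(d),
                 t = unname(tval),
                 P = unname(2 * stats::pt(-abs(tval), dfw)))
    }))
    rownames(lsd) <- NULL
  }
  structure(list(F = F_stat, df_between = av$Df[1], df_within = dfw, P = P,
                 group_means = gm, lsd = lsd),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, P = %.4g\n",
              x$df_between, x$df_within, x$F, x$P))
  if (!is.null(x$lsd)) {
    cat("Fisher's LSD pairwise comparisons:\n")
    print(x$lsd, row.names = FALSE)
  } else cat("(omnibus test not significant; LSD suppressed)\n")
  invisible(x)
}

#' Within-group variance profile along a depth order
#'
#' Per-group unbiased variance with percentile bootstrap confidence
#' intervals, and a trend classification over the depth order:
#' `increasing`/`decreasing` only when CIs along the order are pairwise
#' non-overlapping in that direction (character release reads as increasing
#' variance with depth); an `intermediate_peak` flag marks the
#' hybridization-consistent pattern (middle group's CI above and disjoint
#' from both ends).
#'
#' @param trait Numeric (typically size-adjusted) trait.
#' @param grouping Factor of group membership.
#' @param depth_order Character vector of group levels from shallow to deep.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `variance_profile` with a per-group table
#'   (`variance`, `lower`, `upper`, `n`), `trend`, and `intermediate_peak`.
#' @export
variance_profile <- function(trait, grouping, depth_order, n_boot = 1000,
                             conf = 0.95) {
  grouping <- factor(grouping)
  if (length(depth_order) < 3) stop("need at least three depth-ordered groups")
  if (!all(depth_order %in% levels(grouping)))
    stop("depth_order contains unknown group levels")
  qlo <- (1 - conf) / 2
  rows <- lapply(depth_order, function(lev) {
    x <- trait[grouping == lev & !is.na(trait)]
    n <- length(x)
    v <- if (n >= 2) stats::var(x) else NA_real_
    if (n >= 5) {
      boot <- vapply(seq_len(n_boot), function(b)
        stats::var(sample(x, n, replace = TRUE)), 0)
      ci <- stats::quantile(boot, c(qlo, 1 - qlo), names = FALSE)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(group = lev, n = n, variance = v, lower = ci[1], upper = ci[2])
  })
  tab <- do.call(rbind, rows)
  disjoint_up <- function(i, j) !is.na(tab$upper[i]) && !is.na(tab$lower[j]) &&
    tab$upper[i] < tab$lower[j]
  k <- nrow(tab)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  inc <- all(vapply(pairs, function(p) disjoint_up(p[1], p[2]), TRUE))
  dec <- all(vapply(pairs, function(p) disjoint_up(p[2], p[1]), TRUE))
  trend <- if (inc) "increasing" else if (dec) "decreasing" else "none"
  mid <- seq_len(k)[-c(1, k)]
  peak <- any(vapply(mid, function(m)
    disjoint_up(1, m) && disjoint_up(k, m), TRUE))
  structure(list(table = tab, trend = trend, intermediate_peak = peak,
                 conf = conf, n_boot = n_boot),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("trend over depth:", x$trend,
      if (x$intermediate_peak) "(intermediate peak: hybridization-consistent)" else "",
      "\n")
  invisible(x)
}
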