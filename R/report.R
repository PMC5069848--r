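#' Percentage with render-time rounding
#'
#' `round(100 * n / total, digits)`; full precision belongs in JSON outputs,
#' one decimal in rendered tables.
#'
#' @param n,total Counts.
#' @param digits Decimal places (default 1).
#' @return Percentage.
#' @examples
#' percent(319, 592) # 53.9
#' @export
percent <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

#' Ecotype-by-stratum composition summary
#'
#' Counts and percentages of each ecotype overall and within each depth
#' stratum, one decimal at render time.
#'
#' @param frame Sample frame with `ecotype` and `stratum` columns.
#' @return A data.frame: one row per ecotype x (overall + stratum) cell with
#'   `n`, `total`, `pct`.
#' @export
composition_summary <- function(frame) {
  stopifnot(nrow(frame) > 0)
  eco <- factor(frame$ecotype)
  strat <- factor(frame$stratum)
  blocks <- c(list(overall = rep(TRUE, nrow(frame))),
              stats::setNames(lapply(levels(strat), function(s) strat == s),
                              levels(strat)))
  out <- do.call(rbind, lapply(names(blocks), function(bn) {
    sel <- blocks[[bn]]
    tot <- sum(sel)
    cnt <- table(eco[sel])
    data.frame(scope = bn, ecotype = names(cnt), n = as.vector(cnt),
               total = tot, pct = percent(as.vector(cnt), tot))
  }))
  rownames(out) <- NULL
  out
}

#' Run the full divergence pipeline
#'
#' Executes diversity -> AMOVA factor ranking -> differentiation (pairwise
#' theta, locus-bootstrap CI, Jost's D) -> isolation-by-depth Mantel and
#' individual PCoA -> trait ANOVA/LSD and variance profiles -> Pst-Fst
#' classification and D2-vs-depth comparison. The top-ranked AMOVA factor
#' determines the grouping used downstream (falling back to `stratum` when
#' no factor is significant).
#'
#' @param data A list with `genotypes` ([genotype_table]), `frame` (sample
#'   frame), `traits` (trait table with `_adj` columns; missing adjusted
#'   columns are added), e.g. the output of [simulate_scenario()].
#' @param factors Candidate grouping factors for the AMOVA ranking.
#' @param rarefy_g Rarefaction gene count (default: largest feasible).
#' @param n_perm Permutations for AMOVA/Fst/Fis (default 10000).
#' @param n_boot Bootstrap replicates for CIs (default 1000).
#' @param jost_boot Bootstrap resamplings for Jost's D P-values
#'   (default 1000).
#' @param h2 Heritability used in Pst and the R-matrix (default 1.0).
#' @param exclude_zone Optional zone label(s) removed before analysis (the
#'   replication preset excludes a zone whose sampling confounds zone with
#'   depth); default none.
#' @param exclude_loci Optional locus names removed before analysis (e.g. a
#'   null-allele or low-diversity filter list); default none.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `depthcline_report`: `composition`,
#'   `table1_amova`, `table2_diversity`, `table3_differentiation` (theta
#'   below the diagonal, D above), `fst_ci`, `mantel`, `pcoa_pct_variance`,
#'   `fig4_clines`, `variance_profiles`, `fig5_pst_fst`, `fig6_d2`,
#'   `grouping_factor`, `manifest`.
#' @export
run_all <- function(data, factors = c("ecotype", "zone", "stratum"),
                    rarefy_g = NULL, n_perm = 10000, n_boot = 1000,
                    jost_boot = 1000, h2 = 1.0,
                    exclude_zone = NULL, exclude_loci = NULL, seed = 1L) {
  gt <- data$genotypes
  frame <- data$frame
  traits <- data$traits
  stopifnot(inherits(gt, "genotype_table"),
            all(frame$individual_id == gt$ids))
  set.seed(seed)
  if (!is.null(exclude_zone)) {
    keep <- !(as.character(frame$zone) %in% exclude_zone)
    gt <- subset_individuals(gt, which(keep))
    frame <- droplevels(frame[keep, , drop = FALSE])
    if (!is.null(traits)) traits <- traits[keep, , drop = FALSE]
  }
  if (!is.null(exclude_loci)) {
    keep_l <- !(gt$loci %in% exclude_loci)
    gt <- genotype_table(gt$a1[, keep_l, drop = FALSE],
                         gt$a2[, keep_l, drop = FALSE],
                         ids = gt$ids, loci = gt$loci[keep_l])
  }
  message("stage: composition")
  composition <- composition_summary(frame)

  message("stage: diversity")
  table2 <- diversity_table(gt, frame$stratum, g = rarefy_g, n_perm = n_perm)

  message("stage: AMOVA factor ranking")
  table1 <- amova_rank(gt, frame, factors = factors, n_perm = n_perm)
  top <- if (any(table1$significant)) table1$source[1] else "stratum"
  if (!top %in% names(frame)) top <- "stratum"  # a crossing cannot group downstream
  grouping <- droplevels(factor(frame[[top]]))

  message("stage: differentiation (grouping by ", top, ")")
  pf <- pairwise_fst(gt, grouping, n_perm = n_perm)
  jd <- jost_d(gt, grouping, n_boot = jost_boot)
  table3 <- pf$fst
  table3[upper.tri(table3)] <- jd$D[upper.tri(jd$D)]
  fst_ci <- fst_bootstrap_ci(gt, grouping, n_boot = n_boot)

  message("stage: Mantel / PCoA")
  mant <- tryCatch({
    mm <- depth_mantel_matrices(gt, frame$depth_category)
    mantel(mm$depth, mm$genetic, n_perm = min(n_perm, 9999))
  }, error = function(e) {
    warning("Mantel stage skipped: ", conditionMessage(e))
    NULL
  })
  pc <- pcoa_individuals(gt)

  fig4 <- variance_profiles <- pst_list <- NULL
  fig5 <- fig6 <- NULL
  if (!is.null(traits)) {
    adj_cols <- grep("_adj$", names(traits), value = TRUE)
    if (!length(adj_cols)) {
      traits <- size_adjust_table(traits)
      adj_cols <- grep("_adj$", names(traits), value = TRUE)
    }
    # life-history and shape traits enter raw (they are not length
    # measurements of a body part)
    raw_cols <- intersect(c("Lmax_mm", "omega_mm_per_yr", "K_per_yr",
                            "body_PC1", "head_PC1"), names(traits))
    pheno_cols <- c(adj_cols, raw_cols)
    message("stage: phenotype clines")
    fig4 <- do.call(rbind, lapply(pheno_cols, function(tc) {
      a <- anova_lsd(traits[[tc]], grouping)
      cbind(trait = tc, a$group_means,
            F = a$F, P = a$P)
    }))
    depth_order <- levels(grouping)
    variance_profiles <- lapply(stats::setNames(pheno_cols, pheno_cols),
                                function(tc)
      variance_profile(traits[[tc]], grouping, depth_order, n_boot = n_boot))
    message("stage: Pst-Fst")
    pst_list <- lapply(stats::setNames(pheno_cols, pheno_cols), function(tc)
      pst_variance_components(traits[[tc]], grouping, h2 = h2,
                              n_boot = n_boot))
    fig5 <- classify_selection(pst_list, fst_ci$lower, fst_ci$upper)
    fig5$Fst <- fst_ci$theta
    fig5$Fst_se <- fst_ci$se
    if (length(depth_order) == 3)
      fig6 <- d2_vs_depth(traits[, pheno_cols, drop = FALSE], grouping,
                          pf, depth_order, h2 = h2, n_boot = n_boot)
  }
  manifest <- run_manifest(
    config = list(factors = factors, rarefy_g = table2$rarefaction_g[1],
                  n_perm = n_perm, n_boot = n_boot, jost_boot = jost_boot,
                  h2 = h2, grouping_factor = top,
                  exclude_zone = exclude_zone, exclude_loci = exclude_loci),
    seed = seed)
  structure(list(composition = composition, table1_amova = table1,
                 table2_diversity = table2,
                 table3_differentiation = table3,
                 fst_P = pf$P, jost_P = jd$P, fst_ci = fst_ci,
                 mantel = mant, pcoa_pct_variance = pc$pct_variance,
                 fig4_clines = fig4, variance_profiles = variance_profiles,
                 fig5_pst_fst = fig5, fig6_d2 = fig6,
                 grouping_factor = top, manifest = manifest),
            class = "depthcline_report")
}

#' @export
print.depthcline_report <- function(x, ...) {
  cat("depthcline report; grouping factor:", x$grouping_factor, "\n")
  cat("\nAMOVA factor ranking:\n")
  print(x$table1_amova, row.names = FALSE)
  cat("\nDiversity by stratum:\n")
  print(x$table2_diversity, row.names = FALSE)
  if (!is.null(x$mantel)) print(x$mantel)
  if (!is.null(x$fig5_pst_fst)) {
    cat("\nPst-Fst classification:\n")
    print(x$fig5_pst_fst[, c("trait", "Pst", "classification")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' TSV tables mirroring the report's components plus a JSON manifest.
#'
#' @param report A `depthcline_report` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = is.matrix(x) ||
                         !is.null(rownames(x)) && is.matrix(x))
  }
  wtsv(report$table1_amova, "table1_amova.tsv")
  wtsv(report$table2_diversity, "table2_diversity.tsv")
  utils::write.table(report$table3_differentiation,
                     file.path(dir, "table3_differentiation.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wtsv(report$composition, "composition.tsv")
  wtsv(report$fig4_clines, "fig4_clines.tsv")
  wtsv(report$fig5_pst_fst, "fig5_pst_fst.tsv")
  wtsv(report$fig6_d2, "fig6_d2.tsv")
  write_manifest(report$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
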