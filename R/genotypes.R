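#' Diploid multilocus genotype table
#'
#' The central genotype container: two integer matrices (`a1`, `a2`) of
#' allele codes, one row per individual and one column per locus, with `NA`
#' marking missing calls. Allele codes are positive integers; within a call
#' either both alleles are present or both are missing.
#'
#' @param a1,a2 Integer matrices of allele codes (individuals x loci).
#' @param ids Character vector of unique individual identifiers.
#' @param loci Character vector of locus names.
#' @return An object of class `genotype_table` with elements `ids`, `loci`,
#'   `a1`, `a2`.
#' @examples
#' gt <- genotype_table(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 2L), 2, 1),
#'                      ids = c("f1", "f2"), loci = "Sfo001")
#' n_individuals(gt)
#' @export
genotype_table <- function(a1, a2, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (ncol(a1) < 1L) stop("at least one locus is required")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("duplicated individual ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) != nrow(a1) || length(loci) != ncol(a1))
    stop("ids/loci lengths do not match the allele matrices")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls (one allele NA) at ",
         sum(half), " cell(s); both alleles must be present or both missing")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$ids), length(x$loci), 100 * miss))
  invisible(x)
}

#' @rdname genotype_table
#' @param gt A `genotype_table`.
#' @export
n_individuals <- function(gt) length(gt$ids)

#' @rdname genotype_table
#' @export
n_loci <- function(gt) length(gt$loci)

#' Subset a genotype table by individuals
#'
#' @param gt A `genotype_table`.
#' @param keep Logical, integer, or character index of individuals to keep.
#' @return A `genotype_table` restricted to the selected individuals.
#' @export
subset_individuals <- function(gt, keep) {
  if (is.character(keep)) keep <- match(keep, gt$ids)
  genotype_table(gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE],
                 ids = gt$ids[keep], loci = gt$loci)
}

# Per-locus allele-count matrices: for locus l, an n x k integer matrix of
# copies (0/1/2) of each observed allele carried by each individual; rows
# with missing calls are NA. Most statistics downstream are linear in these.
allele_count_matrices <- function(gt) {
  lapply(seq_along(gt$loci), function(l) {
    a1 <- gt$a1[, l]
    a2 <- gt$a2[, l]
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    k <- length(alleles)
    m <- matrix(0L, nrow = length(a1), ncol = k,
                dimnames = list(gt$ids, as.character(alleles)))
    if (k == 0L) return(m)
    i1 <- match(a1, alleles)
    i2 <- match(a2, alleles)
    ok <- which(!is.na(i1))
    m[cbind(ok, i1[ok])] <- m[cbind(ok, i1[ok])] + 1L
    m[cbind(ok, i2[ok])] <- m[cbind(ok, i2[ok])] + 1L
    m[is.na(a1), ] <- NA_integer_
    m
  })
}

#' Pairwise genotypic distance between individuals
#'
#' Squared genotypic distance as the number of allele differences summed over
#' loci: per locus the count-vector L1 distance divided by two, i.e. 0 for an
#' identical genotype, 1 for one shared allele, 2 for none. This is the
#' allele-count metric used for AMOVA on unphased microsatellites and for
#' individual-level ordination. Loci with a missing call in either individual
#' are skipped and the sum rescaled by `n_loci / n_observed_loci`.
#'
#' @param gt A `genotype_table`.
#' @return A symmetric numeric matrix of squared distances with zero diagonal.
#' @export
genotype_distance2 <- function(gt) {
  n <- n_individuals(gt)
  cm <- allele_count_matrices(gt)
  d2 <- matrix(0, n, n, dimnames = list(gt$ids, gt$ids))
  used <- matrix(0, n, n)
  for (m in cm) {
    obs <- !is.na(m[, 1L])
    dl <- matrix(0, n, n)
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      v[!obs] <- 0L
      dl <- dl + abs(outer(v, v, "-"))
    }
    pair_ok <- outer(obs, obs, "&")
    d2 <- d2 + (dl / 2) * pair_ok
    used <- used + pair_ok
  }
  if (any(used == 0 & upper.tri(used)))
    warning("some individual pairs share no observed locus; distance set to NA")
  scale <- ifelse(used > 0, length(cm) / used, NA_real_)
  out <- d2 * scale
  diag(out) <- 0
  out
}

#' Number of unordered pairs
#'
#' Convenience for locus-pair summaries: `n * (n - 1) / 2`.
#'
#' @param n Non-negative integer count.
#' @return Number of unordered pairs among `n` items.
#' @examples
#' n_pairs(18) # 153 locus pairs for an 18-locus panel
#' @export
n_pairs <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}
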