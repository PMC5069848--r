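#' Read a GenePop genotype file
#'
#' Parses the 2- and 3-digit diploid GenePop dialects. Allele code "00"/"000"
#' denotes a missing allele; a call is treated as missing when either allele
#' is zero. `POP` blocks are returned as a provisional grouping factor.
#'
#' @param path Path to a `.gen` file.
#' @return A list with `genotypes` (a [genotype_table]) and `pop` (factor of
#'   POP-block membership, one entry per individual).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a GenePop file (fewer than 3 lines)")
  body <- lines[-1L]                      # first line is a free title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("no POP line found")
  header <- body[seq_len(pop_idx[1L] - 1L)]
  # locus names: one per line, or a single comma-separated line
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0L) stop("no locus names before first POP")

  ids <- character()
  pop <- integer()
  rows1 <- list()
  rows2 <- list()
  digits <- NA_integer_
  pop_no <- 0L
  for (i in seq(pop_idx[1L], length(body))) {
    line <- body[i]
    lineno <- i + 1L
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) < 2L)
      stop("line ", lineno, ": expected 'id , genotypes'")
    id <- trimws(parts[1L])
    gstr <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
    if (length(gstr) != L)
      stop("line ", lineno, ": ", length(gstr), " genotypes for ", L, " loci")
    w <- unique(nchar(gstr))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("line ", lineno, ": genotype strings must be uniformly 4 or 6 ",
           "characters (2- or 3-digit alleles); got widths ",
           paste(w, collapse = ","))
    d <- w / 2L
    if (is.na(digits)) digits <- d
    if (d != digits)
      stop("line ", lineno, ": mixed 2- and 3-digit dialects")
    a1 <- as.integer(substr(gstr, 1L, d))
    a2 <- as.integer(substr(gstr, d + 1L, 2L * d))
    if (anyNA(a1) || anyNA(a2))
      stop("line ", lineno, ": non-numeric allele codes")
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    ids <- c(ids, id)
    pop <- c(pop, pop_no)
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
  }
  if (anyDuplicated(ids))
    stop("duplicated individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- genotype_table(do.call(rbind, rows1), do.call(rbind, rows2),
                       ids = ids, loci = loci)
  list(genotypes = gt, pop = factor(paste0("pop", pop)))
}

#' Write a GenePop genotype file
#'
#' @param gt A [genotype_table].
#' @param path Output path.
#' @param pop Optional grouping; one POP block is written per level (in level
#'   order). Default: a single block.
#' @param digits Allele-code width, 2 or 3 (default 3).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, pop = NULL, digits = 3L,
                          title = "depthcline export") {
  stopifnot(digits %in% c(2L, 3L))
  maxcode <- suppressWarnings(max(gt$a1, gt$a2, na.rm = TRUE))
  if (is.finite(maxcode) && maxcode >= 10^digits)
    stop("allele code ", maxcode, " does not fit in ", digits, " digits")
  if (is.null(pop)) pop <- factor(rep("all", n_individuals(gt)))
  pop <- factor(pop)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  out <- c(title, gt$loci)
  for (lev in levels(pop)) {
    rows <- which(pop == lev)
    if (!length(rows)) next
    out <- c(out, "POP")
    g1 <- fmt(gt$a1[rows, , drop = FALSE])
    g2 <- fmt(gt$a2[rows, , drop = FALSE])
    dim(g1) <- dim(g2) <- c(length(rows), n_loci(gt))
    geno <- matrix(paste0(g1, g2), nrow = length(rows))
    out <- c(out, paste(gt$ids[rows], ",", apply(geno, 1L, paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Depth strata and depth categories
#'
#' Capture depths are binned into three strata — shallow (`<50 m`),
#' intermediate (`50-100 m`), deep (`>100 m`) — with half-open edges
#' `[0,50)`, `[50,100]`, `(100,Inf)`: boundary depths of exactly 50 and
#' 100 m fall in the intermediate stratum. `depth_category()` snaps a depth
#' to the six net-set categories (40, 50, 80, 90, 100, >120 m) used by the
#' Mantel stage.
#'
#' @param depth_m Numeric capture depth in metres.
#' @return `assign_stratum`: a factor with levels `<50 m`, `50-100 m`,
#'   `>100 m`. `depth_category`: a factor with the six category labels.
#' @examples
#' assign_stratum(c(40, 50, 75, 100, 120))
#' @export
assign_stratum <- function(depth_m) {
  stopifnot(all(depth_m >= 0, na.rm = TRUE))
  cut(depth_m, breaks = c(-Inf, 50, 100, Inf), right = FALSE,
      labels = c("<50 m", "50-100 m", ">100 m")) |>
    (\(s) {
      # right=FALSE puts 100 in the deep bin; the rule assigns 100 to the
      # middle stratum, so fix the single boundary value up.
      s[which(depth_m == 100)] <- "50-100 m"
      s
    })()
}

#' @rdname assign_stratum
#' @export
depth_category <- function(depth_m) {
  cuts <- c(40, 50, 80, 90, 100, 120)
  labs <- c("40 m", "50 m", "80 m", "90 m", "100 m", ">120 m")
  idx <- vapply(depth_m, function(d) {
    if (is.na(d)) return(NA_integer_)
    if (d > 120) return(6L)
    which.min(abs(cuts - d))
  }, integer(1))
  factor(labs[idx], levels = labs)
}

#' Numeric depth of the six depth categories
#'
#' The `>120 m` category is assigned its lower bound, 120 m.
#'
#' @param cat Factor or character of depth-category labels.
#' @return Numeric metres.
#' @export
depth_category_metres <- function(cat) {
  map <- c("40 m" = 40, "50 m" = 50, "80 m" = 80, "90 m" = 90,
           "100 m" = 100, ">120 m" = 120)
  unname(map[as.character(cat)])
}

ECOTYPES <- c("lean", "humper", "siscowet", "redfin")

#' Read and validate the per-individual metadata table
#'
#' Required columns: `individual_id`, `ecotype`, `zone`, `capture_depth_m`,
#' `site_id`, `site_lon`, `site_lat`. `stratum` and `depth_category` are
#' derived from capture depth if absent and checked for consistency if
#' present.
#'
#' @param path CSV path.
#' @param genotype_ids Optional character vector: ids that must all be
#'   present in the metadata (typically `gt$ids`).
#' @return A validated `data.frame` (the sample frame).
#' @export
read_sample_metadata <- function(path, genotype_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_frame(df, genotype_ids = genotype_ids)
}

#' @rdname read_sample_metadata
#' @param frame A data.frame to validate in place of a file.
#' @export
validate_sample_frame <- function(frame, genotype_ids = NULL) {
  req <- c("individual_id", "ecotype", "zone", "capture_depth_m",
           "site_id", "site_lon", "site_lat")
  missing_cols <- setdiff(req, names(frame))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(frame$individual_id))
    stop("duplicated individual ids in metadata")
  bad_eco <- setdiff(unique(frame$ecotype), ECOTYPES)
  if (length(bad_eco))
    stop("unknown ecotype label(s): ", paste(bad_eco, collapse = ", "),
         " (expected ", paste(ECOTYPES, collapse = "/"), ")")
  frame$ecotype <- factor(frame$ecotype, levels = ECOTYPES)
  frame$zone <- factor(frame$zone)
  derived <- assign_stratum(frame$capture_depth_m)
  if ("stratum" %in% names(frame)) {
    if (!all(as.character(frame$stratum) == as.character(derived)))
      stop("stratum column inconsistent with capture_depth_m")
    frame$stratum <- factor(as.character(frame$stratum), levels = levels(derived))
  } else frame$stratum <- derived
  if (!"depth_category" %in% names(frame))
    frame$depth_category <- depth_category(frame$capture_depth_m)
  else
    frame$depth_category <- factor(as.character(frame$depth_category),
                                   levels = levels(depth_category(40)))
  if (!is.null(genotype_ids)) {
    orphan <- setdiff(genotype_ids, frame$individual_id)
    if (length(orphan))
      stop("individuals genotyped but absent from metadata: ",
           paste(orphan, collapse = ", "))
    frame <- frame[match(genotype_ids, frame$individual_id), , drop = FALSE]
    rownames(frame) <- NULL
  }
  frame
}

#' Read the per-individual trait table
#'
#' Checks positivity of standard length and the exact life-history identity
#' `omega_mm_per_yr = Lmax_mm * K_per_yr` where all three are present.
#'
#' @param path CSV path.
#' @param ids Optional character vector giving the required individual order.
#' @return A validated `data.frame`.
#' @export
read_trait_table <- function(path, ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(df, ids = ids)
}

#' @rdname read_trait_table
#' @param traits A data.frame to validate in place of a file.
#' @export
validate_trait_table <- function(traits, ids = NULL) {
  if (!"individual_id" %in% names(traits))
    stop("trait table missing individual_id column")
  if ("SL_mm" %in% names(traits) && any(traits$SL_mm <= 0, na.rm = TRUE))
    stop("non-positive standard length for id(s): ",
         paste(traits$individual_id[which(traits$SL_mm <= 0)], collapse = ", "))
  lh <- c("omega_mm_per_yr", "Lmax_mm", "K_per_yr")
  if (all(lh %in% names(traits))) {
    ok <- is.na(traits$omega_mm_per_yr) | is.na(traits$Lmax_mm) |
      is.na(traits$K_per_yr) |
      abs(traits$omega_mm_per_yr - traits$Lmax_mm * traits$K_per_yr) <
        1e-6 * pmax(1, abs(traits$omega_mm_per_yr))
    if (!all(ok))
      stop("omega_mm_per_yr != Lmax_mm * K_per_yr for id(s): ",
           paste(traits$individual_id[!ok], collapse = ", "))
  }
  if (!is.null(ids)) {
    orphan <- setdiff(ids, traits$individual_id)
    if (length(orphan))
      stop("individuals absent from trait table: ",
           paste(orphan, collapse = ", "))
    traits <- traits[match(ids, traits$individual_id), , drop = FALSE]
    rownames(traits) <- NULL
  }
  traits
}

#' Great-circle distance matrix between sites
#'
#' @param lon,lat Numeric decimal degrees, one entry per site.
#' @param labels Optional site labels.
#' @return Symmetric matrix of distances in kilometres.
#' @export
site_distance_km <- function(lon, lat, labels = NULL) {
  pts <- cbind(lon, lat)
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- geosphere::distGeo(pts[i, ], pts) / 1000
  d <- (d + t(d)) / 2  # distGeo is symmetric up to rounding
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  d
}

#' Run manifest
#'
#' A JSON-serialisable record of configuration, seed, and software versions
#' that accompanies every result bundle.
#'
#' @param config A list of run parameters (stored verbatim).
#' @param seed The integer seed in force.
#' @param inputs Optional named character vector of input file paths;
#'   checksums (md5) are recorded for files that exist.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seed = NA_integer_, inputs = NULL) {
  checksums <- NULL
  if (!is.null(inputs)) {
    existing <- inputs[file.exists(inputs)]
    checksums <- vapply(existing, function(p) unname(tools::md5sum(p)), "")
  }
  structure(list(
    package = "depthcline",
    version = as.character(utils::packageVersion("depthcline")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = as.list(checksums)
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
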