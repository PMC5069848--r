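#' Trait specification for the synthetic generator
#'
#' Declares how one trait is simulated: its location (`base`), between- and
#' within-group variance on the simulated scale, heritability, allometric
#' exponent (`NA` for traits that do not scale with body size; allometric
#' traits are generated as `base * SL^b * 10^e`, so the variances apply on
#' the log10 scale), a monotone group-mean trend over depth, and a monotone
#' within-group variance trend (increasing variance with depth emulates
#' character release; an intermediate peak can be requested for
#' hybridization scenarios).
#'
#' @param name Trait name (column name in the emitted table).
#' @param base Location: multiplicative coefficient for allometric traits,
#'   additive mean otherwise.
#' @param sigma2_between Variance of group means (>= 0).
#' @param sigma2_within Within-group residual variance (>= 0).
#' @param heritability_h2 Heritability in (0, 1].
#' @param allometric_exponent Scaling exponent `b` (NA = non-allometric).
#' @param depth_trend One of `"none"`, `"increasing"`, `"decreasing"`.
#' @param variance_trend One of `"none"`, `"increasing"`, `"decreasing"`,
#'   `"intermediate_peak"`.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, base, sigma2_between = 0, sigma2_within = 1,
                       heritability_h2 = 1.0, allometric_exponent = NA_real_,
                       depth_trend = c("none", "increasing", "decreasing"),
                       variance_trend = c("none", "increasing", "decreasing",
                                          "intermediate_peak")) {
  depth_trend <- match.arg(depth_trend)
  variance_trend <- match.arg(variance_trend)
  stopifnot(sigma2_between >= 0, sigma2_within >= 0,
            heritability_h2 > 0, heritability_h2 <= 1)
  structure(list(name = name, base = base,
                 sigma2_between = sigma2_between,
                 sigma2_within = sigma2_within,
                 heritability_h2 = heritability_h2,
                 allometric_exponent = allometric_exponent,
                 depth_trend = depth_trend, variance_trend = variance_trend),
            class = "trait_spec")
}

#' Default trait roster for the three simulation profiles
#'
#' `divergent`: depth clines in buoyancy (increasing), caudal peduncle
#' depth/length, pelvic fin length, body shape PC1, asymptotic length and
#' early growth rate (decreasing), an increasing-variance trend in pelvic
#' fin length, and no divergence in the craniofacial traits. `neutral`: all
#' between-group variances zero, no trends. `stabilizing`: no trends and
#' halved within-group variances.
#'
#' @param profile One of `"divergent"`, `"neutral"`, `"stabilizing"`.
#' @return A named list of [trait_spec()] objects.
#' @export
default_trait_specs <- function(profile = c("divergent", "neutral",
                                            "stabilizing")) {
  profile <- match.arg(profile)
  lin <- function(name, a, b, s2b, trend, vtrend = "none")
    trait_spec(name, base = a, sigma2_between = s2b, sigma2_within = 0.002,
               allometric_exponent = b, depth_trend = trend,
               variance_trend = vtrend)
  specs <- list(
    buoyancy = trait_spec("buoyancy", base = 94, sigma2_between = 1.0,
                          sigma2_within = 1.5, depth_trend = "increasing"),
    CPD = lin("CPD", 0.10, 1.05, 0.0010, "decreasing"),
    CPL = lin("CPL", 0.15, 1.00, 0.0006, "decreasing"),
    HLL = lin("HLL", 0.25, 0.98, 0, "none"),
    MXL = lin("MXL", 0.10, 1.02, 0, "none"),
    OOL = lin("OOL", 0.06, 0.90, 0, "none"),
    PCL = lin("PCL", 0.15, 1.00, 0.0003, "decreasing"),
    PVL = lin("PVL", 0.13, 1.00, 0.0008, "decreasing", "increasing"),
    POL = lin("POL", 0.07, 1.00, 0, "none"),
    body_PC1 = trait_spec("body_PC1", base = 0, sigma2_between = 0.3,
                          sigma2_within = 1, depth_trend = "decreasing"),
    head_PC1 = trait_spec("head_PC1", base = 0, sigma2_between = 0,
                          sigma2_within = 1),
    t0_yr = trait_spec("t0_yr", base = 0.35, sigma2_between = 0,
                       sigma2_within = 0.0025),
    L0_mm = trait_spec("L0_mm", base = 21.7, sigma2_between = 0,
                       sigma2_within = 1),
    K_per_yr = trait_spec("K_per_yr", base = 0.18, sigma2_between = 1e-4,
                          sigma2_within = 4e-4, depth_trend = "decreasing"),
    Lmax_mm = trait_spec("Lmax_mm", base = 700, sigma2_between = 900,
                         sigma2_within = 2500, depth_trend = "decreasing")
  )
  if (profile == "neutral") {
    specs <- lapply(specs, function(s) {
      s$sigma2_between <- 0
      s$depth_trend <- "none"
      s$variance_trend <- "none"
      s
    })
  } else if (profile == "stabilizing") {
    specs <- lapply(specs, function(s) {
      s$sigma2_between <- 0
      s$depth_trend <- "none"
      s$variance_trend <- "none"
      s$sigma2_within <- s$sigma2_within / 2
      s
    })
  }
  specs
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions: three depth strata with genotyped
#' sample sizes 83/217/71, 18 microsatellite loci with 3-25 alleles, weak
#' differentiation (target Fst 0.005), nominal stratum depths 40/80/120 m,
#' 2% missing calls.
#'
#' @param n_groups Number of groups (depth strata).
#' @param group_sizes Individuals per group (all >= 2).
#' @param n_loci Number of loci.
#' @param alleles_per_locus Single count or `c(min, max)` range.
#' @param target_fst Balding-Nichols target Fst in `[0, 0.5]`.
#' @param depth_per_group Nominal depth (m) per group.
#' @param trait_specs Named list of [trait_spec()]s.
#' @param missing_rate Fraction of genotype calls masked, in `[0, 0.5]`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 3, group_sizes = c(83, 217, 71),
                         n_loci = 18, alleles_per_locus = c(3, 25),
                         target_fst = 0.005,
                         depth_per_group = c(40, 80, 120),
                         trait_specs = default_trait_specs("divergent"),
                         missing_rate = 0.02, seed = 1L) {
  stopifnot(length(group_sizes) == n_groups, all(group_sizes >= 2),
            target_fst >= 0, target_fst <= 0.5,
            missing_rate >= 0, missing_rate <= 0.5,
            length(depth_per_group) == n_groups,
            n_loci >= 1)
  if (length(alleles_per_locus) == 1)
    alleles_per_locus <- rep(alleles_per_locus, 2)
  stopifnot(alleles_per_locus[1] >= 2,
            alleles_per_locus[2] >= alleles_per_locus[1])
  structure(list(n_groups = n_groups, group_sizes = as.integer(group_sizes),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 target_fst = target_fst,
                 depth_per_group = depth_per_group,
                 trait_specs = trait_specs,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))  # pathological alpha ~ 0
  x / sum(x)
}

# per-locus RNG sub-stream: changing n_loci leaves earlier loci unchanged
locus_seed <- function(seed, l, offset = 0L) {
  (as.integer(seed) + 7919L * l + offset) %% 2147483629L
}

#' Simulate structured microsatellite genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies per locus are drawn from a flat Dirichlet;
#' group frequencies from a Dirichlet with concentration
#' `p (1 - Fst) / Fst` (for `target_fst = 0` all groups share the ancestral
#' vector); diploid genotypes are drawn binomially per individual; calls are
#' masked at `missing_rate`. Each locus uses its own RNG sub-stream, so the
#' same seed gives identical loci regardless of how many are generated.
#'
#' @param config A [synth_config()].
#' @return A list with `genotypes` (a [genotype_table]) and `frame` (sample
#'   frame data.frame with ecotype, zone, stratum, capture depth, depth
#'   category, site id and coordinates). Ecotype and zone are assigned
#'   independently of the genetic groups.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  G <- config$n_groups
  ni <- config$group_sizes
  N <- sum(ni)
  group <- factor(rep(seq_len(G), ni))
  fst <- config$target_fst
  a1 <- a2 <- matrix(NA_integer_, N, config$n_loci)
  for (l in seq_len(config$n_loci)) {
    set.seed(locus_seed(config$seed, l))
    k <- if (config$alleles_per_locus[1] == config$alleles_per_locus[2])
      config$alleles_per_locus[1]
    else sample(seq(config$alleles_per_locus[1], config$alleles_per_locus[2]), 1)
    p0 <- rdirichlet1(rep(1, k))
    for (g in seq_len(G)) {
      pg <- if (fst == 0) p0 else rdirichlet1(p0 * (1 - fst) / fst)
      rows <- which(group == g)
      a1[rows, l] <- sample.int(k, length(rows), replace = TRUE, prob = pg)
      a2[rows, l] <- sample.int(k, length(rows), replace = TRUE, prob = pg)
    }
  }
  set.seed(locus_seed(config$seed, 0L, offset = 104729L))
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(N * config$n_loci) < config$missing_rate,
                   N, config$n_loci)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  ids <- sprintf("fish%04d", seq_len(N))
  loci <- sprintf("loc%02d", seq_len(config$n_loci))
  gt <- genotype_table(a1, a2, ids = ids, loci = loci)

  # metadata: capture depths drawn from the six net-set categories
  # compatible with each group's stratum
  strat <- assign_stratum(config$depth_per_group)
  cat_choices <- list("<50 m" = 40, "50-100 m" = c(50, 80, 90, 100),
                      ">100 m" = 125)
  depth <- unlist(lapply(seq_len(G), function(g) {
    ch <- cat_choices[[as.character(strat[g])]]
    sample(rep(ch, 2), ni[g], replace = TRUE)
  }))
  n_sites <- 20
  site_lon <- stats::runif(n_sites, -89.2, -88.4)
  site_lat <- stats::runif(n_sites, 47.8, 48.2)
  site_zone <- rep_len(1:3, n_sites)
  site <- sample.int(n_sites, N, replace = TRUE)
  frame <- data.frame(
    individual_id = ids,
    group = paste0("G", group),
    ecotype = sample(ECOTYPES, N, replace = TRUE,
                     prob = c(0.239, 0.121, 0.539, 0.101)),
    zone = paste0("zone", site_zone[site]),
    capture_depth_m = depth,
    stratum = assign_stratum(depth),
    depth_category = depth_category(depth),
    site_id = paste0("site", site),
    site_lon = site_lon[site],
    site_lat = site_lat[site]
  )
  frame <- validate_sample_frame(frame, genotype_ids = ids)
  list(genotypes = gt, frame = frame)
}

# monotone group effects with (sample) variance s2b across groups, oriented
# by trend; "none" draws iid normal effects
group_effects <- function(G, s2b, trend, depth) {
  if (s2b == 0) return(rep(0, G))
  if (trend == "none") return(stats::rnorm(G, 0, sqrt(s2b)))
  d <- seq(-1, 1, length.out = G)
  eff <- d * sqrt(s2b / stats::var(d))
  eff <- eff[rank(depth, ties.method = "first")]
  if (trend == "decreasing") eff <- -eff
  eff
}

variance_multipliers <- function(G, vtrend) {
  switch(vtrend,
         none = rep(1, G),
         increasing = seq(0.4, 1.6, length.out = G),
         decreasing = seq(1.6, 0.4, length.out = G),
         intermediate_peak = {
           m <- rep(0.5, G)
           m[ceiling(G / 2)] <- 2
           m
         })
}

#' Simulate the per-individual trait table
#'
#' Standard length is drawn lognormally; allometric traits as
#' `base * SL^b * 10^e` with group-mean shifts of variance `sigma2_between`
#' (monotone over depth under a trend) and residual variance `sigma2_within`
#' (scaled per group under a variance trend) on the log10 scale;
#' non-allometric traits additively on their own scale. Weights in air and
#' water are generated so that [compute_buoyancy()] recovers the simulated
#' buoyancy exactly, and `omega_mm_per_yr = Lmax_mm * K_per_yr` holds
#' exactly.
#'
#' @param config A [synth_config()].
#' @param frame The sample frame from [simulate_genotypes()] (its `group`
#'   labels and sizes must match the config).
#' @return A trait data.frame; the per-trait true group effects are attached
#'   as `attr(, "truth")`.
#' @export
simulate_traits <- function(config, frame) {
  stopifnot(inherits(config, "synth_config"))
  group <- factor(frame$group)
  G <- nlevels(group)
  if (G != config$n_groups ||
      !all(as.vector(table(group)) == config$group_sizes))
    stop("frame group labels do not match the config")
  trends <- vapply(config$trait_specs, function(s) s$depth_trend, "")
  if (any(trends != "none") && is.unsorted(config$depth_per_group) &&
      is.unsorted(rev(config$depth_per_group)))
    stop("depth_per_group must be monotone when a depth trend is requested")
  set.seed(locus_seed(config$seed, 0L, offset = 224737L))
  N <- nrow(frame)
  gi <- as.integer(group)
  SL <- stats::rlnorm(N, log(450), 0.25)
  out <- data.frame(individual_id = frame$individual_id, SL_mm = SL)
  truth <- list()
  for (s in config$trait_specs) {
    eff <- group_effects(G, s$sigma2_between, s$depth_trend,
                         config$depth_per_group)
    mult <- variance_multipliers(G, s$variance_trend)
    e <- stats::rnorm(N, 0, sqrt(s$sigma2_within * mult[gi]))
    val <- if (!is.na(s$allometric_exponent)) {
      s$base * SL^s$allometric_exponent * 10^(eff[gi] + e)
    } else {
      s$base + eff[gi] + e
    }
    truth[[s$name]] <- list(group_effects = eff,
                            variance_multipliers = mult, spec = s)
    out[[s$name]] <- val
  }
  if ("buoyancy" %in% names(out)) {
    b <- pmin(out$buoyancy, 99.9)
    wa <- 1e-5 * SL^3 * 10^stats::rnorm(N, 0, 0.02)
    out$weight_air_g <- wa
    out$weight_water_g <- wa * (1 - b / 100)
    out$buoyancy_pct <- compute_buoyancy(out$weight_air_g, out$weight_water_g)
    out$buoyancy <- NULL
  }
  if (all(c("Lmax_mm", "K_per_yr") %in% names(out))) {
    out$Lmax_mm <- pmax(out$Lmax_mm, 100)
    out$K_per_yr <- pmax(out$K_per_yr, 0.01)
    out$omega_mm_per_yr <- out$Lmax_mm * out$K_per_yr
  }
  attr(out, "truth") <- truth
  out
}

#' Add size-adjusted columns to a trait table
#'
#' Applies [size_adjust()] to each named trait against `SL_mm`, appending
#' `<trait>_adj` columns. Life-history traits and shape PC scores are not
#' length measurements and are left unadjusted by default.
#'
#' @param traits Trait data.frame with an `SL_mm` column.
#' @param which_traits Columns to adjust; default: the eight linear traits
#'   and percent buoyancy (those present).
#' @return The trait table with `_adj` columns appended.
#' @export
size_adjust_table <- function(traits,
                              which_traits = c("buoyancy_pct", "CPD", "CPL",
                                               "HLL", "MXL", "OOL", "PCL",
                                               "PVL", "POL")) {
  which_traits <- intersect(which_traits, names(traits))
  for (tr in which_traits)
    traits[[paste0(tr, "_adj")]] <- size_adjust(traits[[tr]], traits$SL_mm,
                                                ids = traits$individual_id)
  traits
}

#' Scenario presets
#'
#' Named YAML presets shipped with the package: `neutral` (no genetic or
#' phenotypic structure), `divergent-by-depth` (weak genetic structure by
#' stratum, clinal traits), `stabilizing` (no between-group divergence,
#' reduced within-group variance).
#'
#' @param scenario Scenario name or a path to a YAML file.
#' @param seed Integer seed.
#' @return `scenario_config()`: a [synth_config()]. `simulate_scenario()`:
#'   a list with `genotypes`, `frame`, `traits` (size-adjusted), `config`.
#' @export
scenario_config <- function(scenario = "divergent-by-depth", seed = 1L) {
  path <- if (file.exists(scenario)) scenario else
    system.file("extdata", "scenarios", paste0(scenario, ".yaml"),
                package = "depthcline")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario: ", scenario)
  y <- yaml::read_yaml(path)
  specs <- default_trait_specs(y$trait_profile %||% "divergent")
  for (nm in names(y$trait_overrides %||% list())) {
    ov <- y$trait_overrides[[nm]]
    for (field in names(ov)) specs[[nm]][[field]] <- ov[[field]]
  }
  synth_config(
    n_groups = length(y$group_sizes),
    group_sizes = unlist(y$group_sizes),
    n_loci = y$n_loci,
    alleles_per_locus = unlist(y$alleles_per_locus),
    target_fst = y$target_fst,
    depth_per_group = unlist(y$depth_per_group),
    trait_specs = specs,
    missing_rate = y$missing_rate,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname scenario_config
#' @export
simulate_scenario <- function(scenario = "divergent-by-depth", seed = 1L) {
  config <- scenario_config(scenario, seed = seed)
  sim <- simulate_genotypes(config)
  traits <- simulate_traits(config, sim$frame)
  traits <- size_adjust_table(traits)
  list(genotypes = sim$genotypes, frame = sim$frame, traits = traits,
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the GenePop genotype file (POP blocks by group), the metadata CSV,
#' and the trait CSV.
#'
#' @param sim Output of [simulate_scenario()] or [simulate_genotypes()] plus
#'   traits.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genepop = file.path(dir, "genotypes.gen"),
             metadata = file.path(dir, "metadata.csv"),
             traits = file.path(dir, "traits.csv"))
  write_genepop(sim$genotypes, paths["genepop"], pop = factor(sim$frame$group))
  utils::write.csv(sim$frame, paths["metadata"], row.names = FALSE)
  if (!is.null(sim$traits)) {
    tr <- sim$traits
    attr(tr, "truth") <- NULL
    utils::write.csv(tr, paths["traits"], row.names = FALSE)
  }
  invisible(paths)
}
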