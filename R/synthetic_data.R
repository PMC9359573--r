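#' Noise model for simulated dual-probe CT readings
#'
#' Describes how delta-CT values scatter around the three genotype cluster
#' centres for one species, and how often probes fail. The assay reads two
#' competing probes; a homozygote's off-allele probe either crosses the
#' threshold late (cross-reaction) or never crosses at all (dropout), in
#' which case the final cycle number is substituted downstream.
#'
#' @param species_label Species name the model applies to.
#' @param cluster_centers Three strictly increasing delta-CT cluster centres
#'   (cycles), ordered FF < LF < LL.
#' @param cluster_sd Within-cluster standard deviation (cycles), > 0.
#' @param base_ct CT of a matched, amplifying probe (cycles, in `[10, 35]`).
#' @param base_sd Specimen-to-specimen spread of `base_ct` (cycles); shifts
#'   both probes of a specimen equally, so it never alters delta-CT.
#' @param dropout_prob Probability the off-allele probe of a homozygote
#'   produces no CT at all.
#' @param no_amp_prob Probability both probes fail (no amplification).
#' @param ct_max Final cycle number (default 40).
#' @return A `noise_model` object.
#' @export
noise_model <- function(species_label, cluster_centers, cluster_sd,
                        base_ct = 25, base_sd = 1, dropout_prob = 0,
                        no_amp_prob = 0, ct_max = 40) {
  stopifnot(is.character(species_label), length(species_label) == 1L,
            is.numeric(cluster_centers), length(cluster_centers) == 3L)
  if (any(diff(cluster_centers) <= 0))
    stop("cluster_centers must be strictly increasing (FF < LF < LL)")
  if (!is.numeric(cluster_sd) || cluster_sd <= 0)
    stop("cluster_sd must be > 0")
  if (base_ct < 10 || base_ct > 35)
    stop("base_ct must lie in [10, 35]")
  for (p in c(dropout_prob, no_amp_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(species_label = species_label,
                 cluster_centers = setNames(as.numeric(cluster_centers),
                                            c("FF", "LF", "LL")),
                 cluster_sd = cluster_sd, base_ct = base_ct,
                 base_sd = base_sd, dropout_prob = dropout_prob,
                 no_amp_prob = no_amp_prob, ct_max = ct_max),
            class = "noise_model")
}

#' Default per-species noise models
#'
#' Cluster centres are the published per-species 3-means centres. The
#' within-cluster spread is not published and is set once from the magnitude
#' of the published ANOVA F statistics; the off-probe dropout probability is
#' nonzero only where probe separation is large, and the no-amplification
#' probability matches the published 4% failure rate.
#'
#' @inheritParams kdr_cluster_centers
#' @return A `noise_model` object.
#' @export
default_noise_model <- function(species = c("Cx. pipiens", "Cx. tarsalis")) {
  species <- match.arg(species)
  switch(species,
    "Cx. pipiens"  = noise_model(species, kdr_cluster_centers(species),
                                 cluster_sd = 0.8, base_ct = 25,
                                 dropout_prob = 0.05, no_amp_prob = 0.04),
    "Cx. tarsalis" = noise_model(species, kdr_cluster_centers(species),
                                 cluster_sd = 0.5, base_ct = 25,
                                 dropout_prob = 0, no_amp_prob = 0.04))
}

#' Cohort specification for simulated field surveys
#'
#' @param strata Data frame with columns `species`, `region`, `land_use`,
#'   `n`, `p_LL`, `p_LF`, `p_FF`. Each row is one sampling stratum; the
#'   genotype probabilities of each row must sum to 1.
#' @param sf_prob Fraction of specimens drawn as LF that are truly SF
#'   (the L1014S-bearing heterozygote the dual-probe assay reports as LF).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(strata, sf_prob = 0, seed = 1L) {
  req <- c("species", "region", "land_use", "n", "p_LL", "p_LF", "p_FF")
  if (!all(req %in% names(strata)))
    stop("strata must have columns: ", paste(req, collapse = ", "))
  if (!all(strata$region %in% REGIONS))
    stop("region must be one of: ", paste(REGIONS, collapse = ", "))
  if (!all(strata$land_use %in% LAND_USES))
    stop("land_use must be one of: ", paste(LAND_USES, collapse = ", "))
  if (any(strata$n < 0) || any(strata$n != round(strata$n)))
    stop("n must be a nonnegative integer")
  probs <- as.matrix(strata[, c("p_LL", "p_LF", "p_FF")])
  if (any(probs < 0) || any(probs > 1))
    stop("genotype probabilities must lie in [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("genotype probabilities must sum to 1 within 1e-9")
  if (sf_prob < 0 || sf_prob > 1) stop("sf_prob must lie in [0, 1]")
  structure(list(strata = as.data.frame(strata), sf_prob = sf_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort emulating the published field survey
#'
#' Stratum sizes reproduce the published per-species totals; the regional
#' split and resistance-allele frequencies follow the published per-region
#' estimates, with genotype proportions in Hardy-Weinberg ratios at each
#' stratum's allele frequency. Each stratum is tied to synthetic trap
#' coordinates inside the corresponding region.
#'
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
default_cohort_spec <- function(seed = 1L) {
  hw <- function(f) c(p_LL = (1 - f)^2, p_LF = 2 * f * (1 - f), p_FF = f^2)
  strata <- rbind(
    data.frame(species = "Cx. erythrothorax", region = "bayside",
               land_use = "wildlife", n = 126, t(hw(0))),
    data.frame(species = "Cx. pipiens", region = "bayside",
               land_use = "urban", n = 359, t(hw(0.375))),
    data.frame(species = "Cx. pipiens", region = "inland",
               land_use = "agriculture", n = 385, t(hw(0.749))),
    data.frame(species = "Cx. tarsalis", region = "bayside",
               land_use = "wildlife", n = 268, t(hw(0.084))),
    data.frame(species = "Cx. tarsalis", region = "inland",
               land_use = "agriculture", n = 239, t(hw(0.230))))
  cohort_spec(strata, sf_prob = 0, seed = seed)
}

# Synthetic trap-site anchors per region (decimal degrees, Alameda-like).
region_anchor <- function(region) {
  switch(region, bayside = c(lat = 37.72, lon = -122.20),
         inland = c(lat = 37.70, lon = -121.78))
}

#' Simulate specimens for a cohort
#'
#' Draws, per stratum, exactly `n` specimens with categorical true genotypes
#' and stratum labels, relabels a fraction `sf_prob` of the drawn LF
#' specimens as SF, and attaches two synthetic trap sites per stratum.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `specimen_id`, `species`, `region`,
#'   `land_use`, `site_id`, `latitude`, `longitude`, `true_genotype`.
#' @export
simulate_specimens <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    out <- vector("list", nrow(spec$strata))
    for (i in seq_len(nrow(spec$strata))) {
      row <- spec$strata[i, ]
      n <- row$n
      if (n == 0) next
      geno <- sample(GENOTYPES, n, replace = TRUE,
                     prob = c(row$p_LL, row$p_LF, row$p_FF))
      if (spec$sf_prob > 0) {
        is_lf <- geno == "LF"
        flip <- is_lf & runif(n) < spec$sf_prob
        geno[flip] <- "SF"
      }
      anchor <- region_anchor(row$region)
      # two sites per stratum, ~0.4 km apart (exercises 1-km merging)
      sites <- data.frame(
        site_id = sprintf("S%02d_%d", i, 1:2),
        latitude = anchor["lat"] + c(0, 0.0036) + 0.02 * (i - 1),
        longitude = anchor["lon"] + c(0, 0))
      pick <- sample(1:2, n, replace = TRUE)
      out[[i]] <- data.frame(
        specimen_id = sprintf("SP%02d_%04d", i, seq_len(n)),
        species = row$species, region = row$region, land_use = row$land_use,
        site_id = sites$site_id[pick],
        latitude = sites$latitude[pick], longitude = sites$longitude[pick],
        true_genotype = geno, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# One specimen's probe pair given its true genotype; uses the current RNG
# stream. SF is drawn from the LF distribution: the two probes cannot see
# the serine allele, so the assay reads SF as LF.
simulate_ct_pair_one <- function(genotype, model) {
  if (!genotype %in% GENOTYPES_EXT) stop("unknown genotype: ", genotype)
  if (runif(1) < model$no_amp_prob)
    return(c(ct_tta = NA_real_, ct_ttt = NA_real_))
  b <- rnorm(1, model$base_ct, model$base_sd)
  cc <- model$cluster_centers
  clip <- function(ct) if (is.na(ct) || ct > model$ct_max) NA_real_ else ct
  if (genotype == "LL") {
    d <- rnorm(1, cc[["LL"]], model$cluster_sd)
    ttt <- if (runif(1) < model$dropout_prob) NA_real_ else clip(b + d)
    c(ct_tta = b, ct_ttt = ttt)
  } else if (genotype == "FF") {
    d <- rnorm(1, cc[["FF"]], model$cluster_sd)
    tta <- if (runif(1) < model$dropout_prob) NA_real_ else clip(b - d)
    c(ct_tta = tta, ct_ttt = b)
  } else { # LF or SF
    d <- rnorm(1, cc[["LF"]], model$cluster_sd)
    c(ct_tta = b - d / 2, ct_ttt = b + d / 2)
  }
}

#' Simulate a dual-probe CT pair
#'
#' Draws the FAM (TTA, wild-type) and HEX (TTT, mutant) probe CTs for
#' specimens of known genotype. The matched probe amplifies near the model's
#' `base_ct`; a homozygote's off-allele probe amplifies `|centre|` cycles
#' later, drops out with probability `dropout_prob`, or is censored at the
#' final cycle (returned as absent; the delta-CT computation substitutes the
#' final cycle number). Heterozygotes split the delta symmetrically across
#' the two probes. Uses the current RNG stream; seed control belongs to the
#' plate-level generator.
#'
#' @param genotypes Character vector of true genotypes (LL/LF/FF/SF).
#' @param model A [noise_model()].
#' @return Data frame with columns `ct_tta`, `ct_ttt` (NA = no CT).
#' @export
simulate_ct_pair <- function(genotypes, model) {
  stopifnot(inherits(model, "noise_model"))
  pairs <- t(vapply(genotypes, simulate_ct_pair_one, numeric(2),
                    model = model, USE.NAMES = FALSE))
  data.frame(ct_tta = pairs[, 1], ct_ttt = pairs[, 2])
}

#' Simulate a qPCR plate for a simulated cohort
#'
#' Applies the species-matched noise model to every specimen and returns
#' well readings ready for [call_genotypes()].
#'
#' @param specimens Output of [simulate_specimens()].
#' @param models Named list of [noise_model()] objects keyed by species
#'   label; defaults cover Cx. pipiens and Cx. tarsalis, and any species
#'   whose label is absent falls back to the Cx. tarsalis-like model (small
#'   probe separation).
#' @param seed Integer seed.
#' @return Data frame with `specimen_id`, `species`, `well`, `ct_tta`,
#'   `ct_ttt`.
#' @export
simulate_plate <- function(specimens, models = NULL, seed = 1L) {
  if (is.null(models))
    models <- list("Cx. pipiens" = default_noise_model("Cx. pipiens"),
                   "Cx. tarsalis" = default_noise_model("Cx. tarsalis"))
  withr::with_seed(as.integer(seed), {
    fallback <- models[["Cx. tarsalis"]] %||% models[[1]]
    ct <- data.frame(ct_tta = rep(NA_real_, nrow(specimens)),
                     ct_ttt = NA_real_)
    for (sp in unique(specimens$species)) {
      idx <- which(specimens$species == sp)
      m <- models[[sp]] %||% fallback
      ct[idx, ] <- simulate_ct_pair(specimens$true_genotype[idx], m)
    }
    data.frame(specimen_id = specimens$specimen_id,
               species = specimens$species,
               well = sprintf("W%04d", seq_len(nrow(specimens))),
               ct_tta = ct$ct_tta, ct_ttt = ct$ct_ttt,
               stringsAsFactors = FALSE)
  })
}

#' Bottle-bioassay specification
#'
#' @param strain Strain label.
#' @param insecticide Insecticide label.
#' @param n_bottles Number of replicate bottles (positive integer).
#' @param n_per_bottle Mosquitoes per bottle (integer in `[21, 23]`).
#' @param time_grid Observation times in minutes (15-min grid up to 120).
#' @param slope Knockdown line slope (percent per minute).
#' @param intercept Knockdown line intercept (percent). Predicted knockdown
#'   percent is clamped to `[0, 100]`.
#' @param seed Integer seed.
#' @return A `bioassay_spec` object.
#' @export
bioassay_spec <- function(strain, insecticide, n_bottles = 3,
                          n_per_bottle = 22,
                          time_grid = seq(15, 120, by = 15),
                          slope, intercept, seed = 1L) {
  stopifnot(n_bottles >= 1, n_per_bottle >= 21, n_per_bottle <= 23)
  if (length(time_grid) < 1 || any(diff(time_grid) != 15) ||
      max(time_grid) > 120)
    stop("time_grid must be a 15-min grid up to 120 min")
  structure(list(strain = strain, insecticide = insecticide,
                 n_bottles = as.integer(n_bottles),
                 n_per_bottle = as.integer(n_per_bottle),
                 time_grid = time_grid, slope = slope, intercept = intercept,
                 seed = as.integer(seed)),
            class = "bioassay_spec")
}

#' Simulate a CDC bottle bioassay
#'
#' Each mosquito's knockdown time is drawn by inverting the clamped linear
#' cumulative-knockdown curve `clamp(slope * t + intercept, 0, 100)`: a
#' uniform draw on (0, 100) is mapped to the first grid time whose expected
#' cumulative knockdown percent reaches it (never, for draws above the
#' 120-min prediction). Cumulative counts are therefore nondecreasing and
#' the expected knockdown percent at each grid time equals the clamped line.
#'
#' @param spec A [bioassay_spec()].
#' @return Data frame with columns `strain`, `insecticide`, `bottle`,
#'   `n_total`, `time_min`, `n_down` (cumulative).
#' @export
simulate_bioassay <- function(spec) {
  stopifnot(inherits(spec, "bioassay_spec"))
  expected <- pmin(pmax(spec$slope * spec$time_grid + spec$intercept, 0), 100)
  withr::with_seed(spec$seed, {
    rows <- vector("list", spec$n_bottles)
    for (b in seq_len(spec$n_bottles)) {
      u <- runif(spec$n_per_bottle, 0, 100)
      n_down <- vapply(expected, function(e) sum(u <= e), integer(1))
      rows[[b]] <- data.frame(strain = spec$strain,
                              insecticide = spec$insecticide, bottle = b,
                              n_total = spec$n_per_bottle,
                              time_min = spec$time_grid, n_down = n_down,
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Simulate Sanger-style reference genotype calls
#'
#' The reference equals the true genotype (Sanger sequencing resolves the SF
#' class the probe assay cannot) except for an `error_rate` fraction of
#' specimens perturbed to a uniformly chosen different genotype.
#'
#' @param truth Character vector of true genotypes (LL/LF/FF/SF).
#' @param error_rate Per-specimen error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of reference genotypes, same length as `truth`.
#' @export
simulate_reference_calls <- function(truth, error_rate = 0, seed = 1L) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  stopifnot(all(truth %in% GENOTYPES_EXT))
  withr::with_seed(as.integer(seed), {
    ref <- truth
    err <- runif(length(truth)) < error_rate
    for (i in which(err))
      ref[i] <- sample(setdiff(GENOTYPES_EXT, truth[i]), 1)
    ref
  })
}
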