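#' Run configuration for the end-to-end pipeline
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param cohort A [cohort_spec()] (defaults to the published-survey-like
#'   cohort).
#' @param models Named list of per-species [noise_model()]s (NULL = package
#'   defaults).
#' @param method Calling method passed to [call_genotypes()].
#' @param cutoff_cycle QC cutoff cycle.
#' @param ct_max Final cycle number.
#' @param merge_radius_km Trap-site merge radius (km).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param verbose Log per-stage record counts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, cohort = NULL, models = NULL,
                       method = "cluster", cutoff_cycle = 30, ct_max = 40,
                       merge_radius_km = 1.0, out_dir = NULL,
                       verbose = FALSE) {
  stopifnot(merge_radius_km > 0, cutoff_cycle > 0, cutoff_cycle <= 40)
  seed <- as.integer(seed)
  cohort <- cohort %||% default_cohort_spec(seed = seed)
  structure(list(seed = seed, cohort = cohort, models = models,
                 method = method, cutoff_cycle = cutoff_cycle,
                 ct_max = ct_max, merge_radius_km = merge_radius_km,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

count_table_by <- function(calls_meta, by) {
  keep <- calls_meta$genotype %in% GENOTYPES
  sub <- calls_meta[keep, , drop = FALSE]
  tab <- table(sub[[by]], factor(sub$genotype, levels = GENOTYPES))
  data.frame(stratum_type = by, stratum = rownames(tab),
             n_LL = as.integer(tab[, "LL"]), n_LF = as.integer(tab[, "LF"]),
             n_FF = as.integer(tab[, "FF"]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full simulate-call-summarise pipeline
#'
#' Simulates a cohort and its qPCR plate, calls genotypes, joins specimen
#' metadata, merges trap sites within the configured radius, tabulates
#' genotype counts by species, region, land use and site cluster, estimates
#' resistance allele frequencies per stratum, and fits unadjusted
#' proportional-odds models for species and region (species with no
#' resistant alleles observed are excluded from the models, as separation
#' leaves their odds unidentified). Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `specimens`, `plate`, `calls`,
#'   `count_tables`, `allele_frequencies`, `site_clusters`, `models`,
#'   `report`; artifacts are also written under `out_dir` when set.
#' @export
pipeline_run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  specimens <- simulate_specimens(config$cohort)
  if (is.null(specimens) || nrow(specimens) == 0)
    stop("empty cohort: nothing to simulate")
  log_msg("simulated %d specimens in %d strata", nrow(specimens),
          nrow(config$cohort$strata))

  plate <- simulate_plate(specimens, models = config$models,
                          seed = config$seed + 1000L)
  log_msg("simulated plate: %d wells", nrow(plate))

  calls <- call_genotypes(plate, method = config$method,
                          cutoff_cycle = config$cutoff_cycle,
                          ct_max = config$ct_max, seed = config$seed + 2000L)
  log_msg("calls: %d rows (%d excluded)", nrow(calls),
          sum(calls$genotype == "EXCLUDED"))

  meta_cols <- c("specimen_id", "region", "land_use", "site_id",
                 "latitude", "longitude", "true_genotype")
  calls_meta <- merge(calls, specimens[, meta_cols], by = "specimen_id")

  sites <- unique(specimens[, c("site_id", "latitude", "longitude")])
  site_clusters <- merge_sites(sites, config$merge_radius_km)
  calls_meta <- merge(calls_meta, site_clusters, by = "site_id")
  log_msg("merged %d sites into %d clusters", nrow(site_clusters),
          length(unique(site_clusters$cluster_id)))

  count_tables <- rbind(count_table_by(calls_meta, "species"),
                        count_table_by(calls_meta, "region"),
                        count_table_by(calls_meta, "land_use"),
                        count_table_by(calls_meta, "cluster_id"))
  freqs <- allele_frequency_table(count_tables)

  # unadjusted proportional-odds fits; drop strata with no resistant alleles
  species_counts <- freqs[freqs$stratum_type == "species" & freqs$f > 0, ]
  fits <- list()
  if (nrow(species_counts) >= 2) {
    sp <- species_counts
    names(sp)[names(sp) == "stratum"] <- "species"
    fits$species <- fit_proportional_odds(sp, "species")
  }
  resistant_species <- species_counts$stratum
  region_sub <- calls_meta[calls_meta$species %in% resistant_species, ]
  region_counts <- count_table_by(region_sub, "region")
  if (nrow(region_counts) >= 2 && all(rowSums(region_counts[, 3:5]) > 0)) {
    rg <- region_counts
    names(rg)[names(rg) == "stratum"] <- "region"
    fits$region <- fit_proportional_odds(rg, "region",
                                         ref = c(region = "bayside"))
  }

  report <- list(
    seed = config$seed,
    n_specimens = nrow(specimens),
    n_excluded = sum(calls$genotype == "EXCLUDED"),
    exclusion_fraction = mean(calls$genotype == "EXCLUDED"),
    allele_frequencies = freqs,
    odds_ratios = lapply(fits, `[[`, "odds_ratios"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_plate_csv(plate, p("plate.csv"))
    write_metadata_csv(specimens, p("metadata.csv"))
    write_calls_csv(calls, p("calls.csv"))
    write.csv(freqs, p("allele_frequencies.csv"), row.names = FALSE)
    write_report_json(report, p("report.json"))
    log_msg("artifacts written to %s", config$out_dir)
  }

  invisible(list(specimens = specimens, plate = plate, calls = calls,
                 count_tables = count_tables, allele_frequencies = freqs,
                 site_clusters = site_clusters, models = fits,
                 report = report))
}
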