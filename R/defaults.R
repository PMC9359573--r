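#' Primers and probes of the Culex RTkdr assay
#'
#' Returns the published oligo set for the dual-probe allelic-discrimination
#' assay at the L1014F kdr locus: two forward primers (one placed upstream
#' for sequencing), one reverse primer, and the two allele-specific probes.
#' Probe sequences are stripped of reporter/quencher chemistry annotations;
#' the reporter dye (FAM for the TTA/leucine probe, HEX for the
#' TTT/phenylalanine probe) is kept as a label.
#'
#' @return A data frame with columns `name`, `role`
#'   (`forward`/`reverse`/`probe`), `bases` and `reporter`.
#' @export
#' @examples
#' kdr_oligos()
kdr_oligos <- function() {
  path <- system.file("extdata", "rtkdr_oligos.csv", package = "culexkdr",
                      mustWork = TRUE)
  read_oligos_csv(path)
}

#' Published per-species delta-CT cluster centres
#'
#' Final 3-means cluster centres (cycles) of the delta-CT distribution for
#' the two extensively validated species, ordered FF < LF < LL.
#'
#' @param species `"Cx. pipiens"` or `"Cx. tarsalis"`.
#' @return Numeric vector of three ascending centres, named FF/LF/LL.
#' @export
kdr_cluster_centers <- function(species = c("Cx. pipiens", "Cx. tarsalis")) {
  species <- match.arg(species)
  centers <- switch(species,
    "Cx. pipiens"  = c(-13.212, -0.871, 12.691),
    "Cx. tarsalis" = c(-2.944, -0.089, 3.107))
  names(centers) <- c("FF", "LF", "LL")
  centers
}

#' Species-specific delta-CT decision bands
#'
#' Published delta-CT bands for direct threshold calling. Values outside
#' every band (the gaps the published bands leave open) are called
#' `UNDETERMINED`, mirroring the manual-review step of the assay protocol.
#' The extreme-negative band is interpreted as the FF (homozygous resistant)
#' band, consistent with the sign of the delta-CT statistic (mutant-probe CT
#' minus wild-type-probe CT) and with the cluster-centre ordering.
#'
#' @param species `"Cx. pipiens"` or `"Cx. tarsalis"`.
#' @return A `threshold_bands` object (see [threshold_bands()]).
#' @export
kdr_threshold_bands <- function(species = c("Cx. pipiens", "Cx. tarsalis")) {
  species <- match.arg(species)
  switch(species,
    "Cx. pipiens"  = threshold_bands(species, ff_max = -4.0, lf_low = -2.0,
                                     lf_high = 4.9, ll_min = 5.0),
    "Cx. tarsalis" = threshold_bands(species, ff_max = -2.0, lf_low = -1.0,
                                     lf_high = 1.0, ll_min = 2.0))
}

# Default band set used by call_genotypes(). Cx. erythrothorax borrows the
# Cx. tarsalis bands: its amplicon is identical across the assay region and
# its delta-CT values resemble the tarsalis LL cluster.
default_band_set <- function() {
  list("Cx. pipiens" = kdr_threshold_bands("Cx. pipiens"),
       "Cx. tarsalis" = kdr_threshold_bands("Cx. tarsalis"),
       "Cx. erythrothorax" = threshold_bands("Cx. erythrothorax",
                                             ff_max = -2.0, lf_low = -1.0,
                                             lf_high = 1.0, ll_min = 2.0))
}

#' Published bottle-bioassay knockdown regression lines
#'
#' Knockdown-percent-versus-time regression lines (percent per minute and
#' intercept percent) for the susceptible KNWR and resistant Conaway
#' Cx. tarsalis strains exposed to permethrin or deltamethrin.
#'
#' @return Data frame with columns `strain`, `insecticide`, `slope`,
#'   `intercept`.
#' @export
kdr_bioassay_lines <- function() {
  data.frame(
    strain      = c("KNWR", "Conaway", "KNWR", "Conaway"),
    insecticide = c("deltamethrin", "deltamethrin", "permethrin", "permethrin"),
    slope       = c(1.785, 0.1977, 1.818, 0.0870),
    intercept   = c(-6.627, -4.588, -1.553, -2.156),
    stringsAsFactors = FALSE)
}

#' Published Alameda County survey genotype counts
#'
#' Genotype counts (LL/LF/FF) by species, geographic region and land-use
#' stratum from the published Alameda County field survey. These marginal
#' tables are the substrate for allele-frequency and ordinal-regression
#' examples.
#'
#' @param stratum_type Optional filter: `"species"`, `"region"` or
#'   `"land_use"`.
#' @return Data frame with columns `stratum_type`, `stratum`, `n_LL`,
#'   `n_LF`, `n_FF`.
#' @export
survey_genotype_counts <- function(stratum_type = NULL) {
  path <- system.file("extdata", "alameda_survey_counts.csv",
                      package = "culexkdr", mustWork = TRUE)
  counts <- read_genotype_counts_csv(path)
  if (!is.null(stratum_type)) {
    stratum_type <- match.arg(stratum_type, c("species", "region", "land_use"))
    counts <- counts[counts$stratum_type == stratum_type, , drop = FALSE]
    rownames(counts) <- NULL
  }
  counts
}

#' Published Conaway-strain bioassay genotype table
#'
#' Cross-classification of Conaway-strain mosquitoes from the bottle
#' bioassays by insecticide, 120-min knockdown status and kdr genotype
#' (including the SF class detectable only by Sanger sequencing).
#'
#' @return Data frame with columns `insecticide`, `knockdown`, `LL`, `LF`,
#'   `FF`, `SF`.
#' @export
bioassay_genotype_counts <- function() {
  path <- system.file("extdata", "conaway_bioassay_genotypes.csv",
                      package = "culexkdr", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("insecticide", "knockdown", "LL", "LF", "FF", "SF") %in%
                  names(tab)))
  tab
}
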