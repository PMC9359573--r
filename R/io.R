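# CSV dialects shared by the generators and the analysis stages. All
# writers quote text fields (RFC-4180 style); readers accept quoted or bare
# fields and treat an empty CT cell as an absent CT, never as zero.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
}

parse_ct <- function(x, column, path) {
  x[is.na(x)] <- ""
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  nz <- nzchar(x)
  val <- suppressWarnings(as.numeric(x[nz]))
  if (anyNA(val)) {
    bad <- which(nz)[is.na(val)]
    stop("file '", path, "', column ", column, ": non-numeric CT at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (any(val <= 0 | val > 40))
    stop("file '", path, "', column ", column, ": CT values must lie in (0, 40]")
  out[nz] <- val
  out
}

#' Read a qPCR plate CSV
#'
#' Expected columns: `specimen_id`, `species`, `ct_fam`, `ct_hex` (optional
#' `well`). The FAM channel reports the wild-type (TTA) probe and the HEX
#' channel the mutant (TTT) probe; empty CT cells mean the probe never
#' crossed threshold. Duplicate specimen ids are a hard error.
#'
#' @param path CSV path.
#' @return Data frame with `specimen_id`, `species`, `well`, `ct_tta`,
#'   `ct_ttt`.
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  require_columns(df, c("specimen_id", "species", "ct_fam", "ct_hex"), path)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup) > 0)
    stop("file '", path, "': duplicate specimen id(s): ",
         paste(unique(dup), collapse = ", "))
  data.frame(specimen_id = df$specimen_id, species = df$species,
             well = if ("well" %in% names(df)) df$well else NA_character_,
             ct_tta = parse_ct(df$ct_fam, "ct_fam", path),
             ct_ttt = parse_ct(df$ct_hex, "ct_hex", path),
             stringsAsFactors = FALSE)
}

#' Write a qPCR plate CSV
#' @param readings Data frame with `specimen_id`, `species`, `well`,
#'   `ct_tta`, `ct_ttt`.
#' @param path Output path.
#' @export
write_plate_csv <- function(readings, path) {
  out <- data.frame(specimen_id = readings$specimen_id,
                    species = readings$species,
                    well = readings$well %||% NA_character_,
                    ct_fam = readings$ct_tta, ct_hex = readings$ct_ttt)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a specimen metadata CSV
#'
#' Expected columns: `specimen_id`, `site_id`, `latitude`, `longitude`,
#' `region`, `land_use` (extra columns are kept). Region and land-use values
#' are validated against their closed vocabularies.
#'
#' @param path CSV path.
#' @return Data frame of specimen metadata.
#' @export
read_metadata_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("specimen_id", "site_id", "latitude", "longitude",
                        "region", "land_use"), path)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup) > 0)
    stop("file '", path, "': duplicate specimen id(s): ",
         paste(unique(dup), collapse = ", "))
  bad_region <- setdiff(unique(df$region), REGIONS)
  if (length(bad_region) > 0)
    stop("file '", path, "': unknown region value(s): ",
         paste(bad_region, collapse = ", "))
  bad_lu <- setdiff(unique(df$land_use), LAND_USES)
  if (length(bad_lu) > 0)
    stop("file '", path, "': unknown land_use value(s): ",
         paste(bad_lu, collapse = ", "))
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("file '", path, "': coordinates out of range")
  df
}

#' Write specimen metadata CSV
#' @param specimens Data frame with the metadata columns.
#' @param path Output path.
#' @export
write_metadata_csv <- function(specimens, path) {
  cols <- intersect(c("specimen_id", "species", "site_id", "latitude",
                      "longitude", "region", "land_use", "true_genotype"),
                    names(specimens))
  write.csv(specimens[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write and read genotype calls CSV
#' @param calls Calls data frame from [call_genotypes()].
#' @param path Output path.
#' @export
write_calls_csv <- function(calls, path) {
  write.csv(calls, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_calls_csv
#' @export
read_calls_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  require_columns(df, c("specimen_id", "genotype"), path)
  bad <- setdiff(unique(df$genotype), CALL_LEVELS)
  if (length(bad) > 0)
    stop("file '", path, "': unknown genotype value(s): ",
         paste(bad, collapse = ", "))
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Read a genotype count table CSV
#'
#' Expected columns: `n_LL`, `n_LF`, `n_FF` plus any stratum label columns.
#'
#' @param path CSV path.
#' @return Data frame of counts.
#' @export
read_genotype_counts_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("n_LL", "n_LF", "n_FF"), path)
  for (col in c("n_LL", "n_LF", "n_FF"))
    if (any(df[[col]] < 0) || any(df[[col]] != round(df[[col]])))
      stop("file '", path, "': ", col, " must be nonnegative integers")
  df
}

#' Read and write bioassay CSVs
#'
#' Columns: `strain`, `insecticide`, `bottle`, `n_total`, `time_min`,
#' `n_down` (cumulative knockdown count).
#'
#' @param path CSV path.
#' @return Data frame of bioassay records.
#' @export
read_bioassay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("strain", "insecticide", "bottle", "n_total",
                        "time_min", "n_down"), path)
  if (any(df$n_down < 0) || any(df$n_down > df$n_total))
    stop("file '", path, "': n_down must lie in [0, n_total]")
  key <- interaction(df$strain, df$insecticide, df$bottle, drop = TRUE)
  for (k in levels(key)) {
    sub <- df[key == k, ]
    sub <- sub[order(sub$time_min), ]
    if (is.unsorted(sub$n_down))
      stop("file '", path, "': cumulative counts decrease over time for ", k)
  }
  df
}

#' @rdname read_bioassay_csv
#' @param records Bioassay data frame.
#' @export
write_bioassay_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an oligo set CSV
#'
#' Columns: `name`, `role`, `sequence` and optional `reporter`. Sequences
#' are stripped of chemistry annotations via [oligo()].
#'
#' @param path CSV path.
#' @return Data frame with `name`, `role`, `bases`, `reporter`.
#' @export
read_oligos_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  require_columns(df, c("name", "role", "sequence"), path)
  parsed <- lapply(seq_len(nrow(df)), function(i)
    oligo(df$name[i], df$sequence[i], df$role[i],
          reporter = if ("reporter" %in% names(df) && !is.na(df$reporter[i]))
            df$reporter[i] else NULL))
  data.frame(name = vapply(parsed, `[[`, "", "name"),
             role = vapply(parsed, `[[`, "", "role"),
             bases = vapply(parsed, `[[`, "", "bases"),
             reporter = vapply(parsed, function(o) o$reporter %||% NA_character_,
                               NA_character_),
             stringsAsFactors = FALSE)
}

#' Write the statistics report as JSON
#'
#' @param report Named list (nested lists/data frames are serialised).
#' @param path Output path.
#' @param schema_version Schema tag embedded in the file.
#' @export
write_report_json <- function(report, path, schema_version = "1.0") {
  report <- c(list(schema_version = schema_version), report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
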