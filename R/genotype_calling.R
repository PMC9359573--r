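#' Delta-CT statistic with final-cycle fallback
#'
#' The genotype statistic of the dual-probe assay: the mutant (TTT, HEX)
#' probe's CT minus the wild-type (TTA, FAM) probe's CT. A probe that never
#' crossed threshold contributes the final cycle number (`ct_max`) and is
#' flagged; if neither probe amplified the specimen is flagged
#' `no_amplification` and delta-CT is undefined.
#'
#' @param readings Data frame with numeric columns `ct_tta` and `ct_ttt`
#'   (NA = no CT).
#' @param ct_max Final cycle number substituted for an absent CT.
#' @return The input with added columns `delta_ct`, `tta_substituted_40`,
#'   `ttt_substituted_40`, `no_amplification`.
#' @export
#' @examples
#' compute_delta_ct(data.frame(ct_tta = c(20, 25, NA), ct_ttt = c(NA, 25, 22)))
compute_delta_ct <- function(readings, ct_max = 40) {
  stopifnot(all(c("ct_tta", "ct_ttt") %in% names(readings)))
  tta <- readings$ct_tta
  ttt <- readings$ct_ttt
  no_amp <- is.na(tta) & is.na(ttt)
  out <- readings
  out$tta_substituted_40 <- is.na(tta) & !no_amp
  out$ttt_substituted_40 <- is.na(ttt) & !no_amp
  out$no_amplification <- no_amp
  tta[out$tta_substituted_40] <- ct_max
  ttt[out$ttt_substituted_40] <- ct_max
  out$delta_ct <- ifelse(no_amp, NA_real_, ttt - tta)
  out
}

#' Quality-control filter on late or absent amplification
#'
#' A specimen is excluded when every probe CT it produced exceeds the cutoff
#' cycle, or when neither probe amplified.
#'
#' @param readings Data frame with `ct_tta`, `ct_ttt`.
#' @param cutoff_cycle Exclusion cutoff (cycles).
#' @return List with `kept` and `excluded` data frames and
#'   `exclusion_fraction`.
#' @export
qc_filter <- function(readings, cutoff_cycle = 30) {
  stopifnot(cutoff_cycle > 0, cutoff_cycle <= 40)
  late <- function(ct) is.na(ct) | ct > cutoff_cycle
  drop <- late(readings$ct_tta) & late(readings$ct_ttt)
  list(kept = readings[!drop, , drop = FALSE],
       excluded = readings[drop, , drop = FALSE],
       exclusion_fraction = mean(drop))
}

#' One-dimensional k-means clustering (Lloyd's algorithm)
#'
#' Lloyd's algorithm on scalar data, initialised at the `(2i - 1) / 2k`
#' quantiles and at `restarts` additional seeded random draws of k distinct
#' values; the solution with the lowest within-cluster sum of squares is
#' kept. Convergence is declared when assignments stop changing; if the
#' iteration cap is reached first a warning is raised. Points equidistant
#' from two centres go to the lower-indexed (smaller-centre) cluster.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of clusters.
#' @param max_iter Iteration cap per start.
#' @param restarts Number of random restarts in addition to the quantile
#'   initialisation.
#' @param seed Integer seed for the random restarts.
#' @return A `cluster_model`: list with ascending `centers`, `assignments`
#'   (cluster index per value, 1 = lowest centre), `sizes`, `wss`,
#'   `iterations`, `converged`.
#' @export
kmeans_1d <- function(values, k = 3, max_iter = 10, restarts = 10, seed = 1L) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  uniq <- unique(values)
  if (length(uniq) < k)
    stop("need at least k = ", k, " distinct values, got ", length(uniq))

  assign_nearest <- function(v, centers) {
    d <- abs(outer(v, centers, "-"))
    max.col(-d, ties.method = "first")  # tie -> lower-indexed centre
  }
  lloyd <- function(centers0) {
    centers <- sort(centers0)
    assign_prev <- rep(0L, length(values))
    iterations <- 0L
    converged <- FALSE
    repeat {
      assign_cur <- assign_nearest(values, centers)
      if (identical(assign_cur, assign_prev)) { converged <- TRUE; break }
      if (iterations >= max_iter) break
      iterations <- iterations + 1L
      assign_prev <- assign_cur
      for (j in seq_len(k)) {
        member <- values[assign_cur == j]
        if (length(member) > 0) centers[j] <- mean(member)
        else { # re-seed an empty cluster at the worst-fit point
          far <- which.max(abs(values - centers[assign_cur]))
          centers[j] <- values[far]
        }
      }
      ord <- order(centers)
      centers <- centers[ord]
    }
    wss <- sum((values - centers[assign_cur])^2)
    list(centers = centers, assignments = assign_cur, wss = wss,
         iterations = iterations, converged = converged)
  }

  starts <- list(quantile(values, probs = (2 * seq_len(k) - 1) / (2 * k),
                          names = FALSE, type = 7))
  if (restarts > 0) {
    starts <- c(starts, withr::with_seed(as.integer(seed), {
      lapply(seq_len(restarts), function(i) sample(uniq, k))
    }))
  }
  fits <- lapply(starts, lloyd)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "wss"))]]
  if (!best$converged)
    warning("kmeans_1d: iteration cap (", max_iter,
            ") reached before assignment stability")
  # relabel so cluster 1 has the lowest centre
  ord <- order(best$centers)
  relabel <- match(seq_len(k), ord)
  structure(list(centers = best$centers[ord],
                 assignments = relabel[best$assignments],
                 sizes = tabulate(relabel[best$assignments], k),
                 wss = best$wss, iterations = best$iterations,
                 converged = best$converged),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", length(x$centers), "centers:",
      paste(signif(x$centers, 6), collapse = ", "),
      sprintf("(wss %.4g, %d iterations, %s)\n", x$wss, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Genotype calls from a fitted cluster model
#'
#' Maps the three clusters by centre order to genotypes: lowest delta-CT
#' centre is FF (mutant probe early), middle is LF, highest is LL. A value
#' exactly midway between two centres is assigned to the lower cluster and
#' flagged `tie_midpoint`.
#'
#' @param model A 3-cluster [kmeans_1d()] fit.
#' @param delta_cts Delta-CT values the model was fitted to (same order as
#'   `model$assignments`).
#' @param specimen_id Optional specimen identifiers.
#' @return Data frame of genotype calls (`specimen_id`, `delta_ct`,
#'   `genotype`, `method`, `cluster_index`, `flags`).
#' @export
calls_from_clusters <- function(model, delta_cts, specimen_id = NULL) {
  stopifnot(inherits(model, "cluster_model"), length(model$centers) == 3)
  if (any(!is.finite(model$centers))) stop("non-finite cluster centre")
  stopifnot(length(delta_cts) == length(model$assignments))
  genos <- c("FF", "LF", "LL")[model$assignments]
  mid <- vapply(delta_cts, function(v) {
    d <- abs(v - model$centers)
    sum(d == min(d)) > 1
  }, logical(1))
  data.frame(
    specimen_id = specimen_id %||% seq_along(delta_cts),
    delta_ct = delta_cts, genotype = genos, method = "cluster",
    cluster_index = model$assignments,
    flags = ifelse(mid, "tie_midpoint", ""),
    stringsAsFactors = FALSE)
}

#' Species-specific delta-CT threshold bands
#'
#' @param species_label Species the bands apply to.
#' @param ff_max Delta-CT below which the call is FF.
#' @param lf_low,lf_high Closed LF band.
#' @param ll_min Delta-CT above which the call is LL.
#' @return A `threshold_bands` object. Bands must satisfy
#'   `ff_max <= lf_low <= lf_high <= ll_min`; values falling in the gaps the
#'   bands leave open are called UNDETERMINED.
#' @export
threshold_bands <- function(species_label, ff_max, lf_low, lf_high, ll_min) {
  if (!(ff_max <= lf_low && lf_low <= lf_high && lf_high <= ll_min))
    stop("inverted bands: require ff_max <= lf_low <= lf_high <= ll_min")
  structure(list(species_label = species_label, ff_max = ff_max,
                 lf_low = lf_low, lf_high = lf_high, ll_min = ll_min),
            class = "threshold_bands")
}

#' Genotype calls from threshold bands
#'
#' Delta-CT above `ll_min` is LL, below `ff_max` is FF, inside
#' `[lf_low, lf_high]` is LF; values in the gaps between bands are
#' UNDETERMINED and flagged `in_band_gap` (they correspond to the manual
#' review step of the bench protocol).
#'
#' @param delta_cts Numeric delta-CT values.
#' @param bands A [threshold_bands()] object.
#' @param specimen_id Optional specimen identifiers.
#' @return Data frame of genotype calls.
#' @export
calls_from_thresholds <- function(delta_cts, bands, specimen_id = NULL) {
  stopifnot(inherits(bands, "threshold_bands"))
  geno <- ifelse(delta_cts > bands$ll_min, "LL",
          ifelse(delta_cts < bands$ff_max, "FF",
          ifelse(delta_cts >= bands$lf_low & delta_cts <= bands$lf_high,
                 "LF", "UNDETERMINED")))
  data.frame(
    specimen_id = specimen_id %||% seq_along(delta_cts),
    delta_ct = delta_cts, genotype = geno, method = "threshold",
    cluster_index = NA_integer_,
    flags = ifelse(geno == "UNDETERMINED", "in_band_gap", ""),
    stringsAsFactors = FALSE)
}

#' Call genotypes from plate readings
#'
#' Full calling pipeline for one plate: QC exclusion of specimens with no or
#' late amplification, delta-CT computation with final-cycle fallback, and
#' per-species genotype assignment by 3-means clustering and/or published
#' threshold bands. Species without published bands are called by cluster
#' only.
#'
#' @param readings Plate data frame (`specimen_id`, `species`, `ct_tta`,
#'   `ct_ttt`).
#' @param method `"cluster"`, `"threshold"` or `"both"` (both returns one
#'   row per specimen and method).
#' @param bands Named list of [threshold_bands()] keyed by species; defaults
#'   to the published per-species bands.
#' @param cutoff_cycle QC cutoff cycle.
#' @param ct_max Final cycle number.
#' @param seed Seed for the k-means restarts.
#' @param min_center_gap Minimum separation (cycles) between adjacent fitted
#'   cluster centres for a 3-means solution to be accepted as three genotype
#'   clusters. A species whose specimens span fewer than three genotypes
#'   (e.g. a monomorphic population) produces artificially close centres;
#'   such species fall back to their threshold bands when available, and
#'   otherwise raise an error rather than reporting fabricated clusters.
#' @return Data frame with columns `specimen_id`, `species`, `delta_ct`,
#'   `genotype` (LL/LF/FF/UNDETERMINED/EXCLUDED), `method`, `flags`.
#' @export
call_genotypes <- function(readings, method = c("cluster", "threshold", "both"),
                           bands = NULL, cutoff_cycle = 30, ct_max = 40,
                           seed = 1L, min_center_gap = 1.5) {
  method <- match.arg(method)
  stopifnot(all(c("specimen_id", "species", "ct_tta", "ct_ttt") %in%
                  names(readings)))
  if (is.null(bands)) bands <- default_band_set()
  qc <- qc_filter(readings, cutoff_cycle)
  excluded <- NULL
  if (nrow(qc$excluded) > 0)
    excluded <- data.frame(specimen_id = qc$excluded$specimen_id,
                           species = qc$excluded$species,
                           delta_ct = NA_real_, genotype = "EXCLUDED",
                           method = "qc", flags = "no_amplification",
                           stringsAsFactors = FALSE)
  kept <- compute_delta_ct(qc$kept, ct_max)
  sub_flags <- ifelse(kept$tta_substituted_40, "tta_substituted_40",
               ifelse(kept$ttt_substituted_40, "ttt_substituted_40", ""))
  methods <- if (method == "both") c("cluster", "threshold") else method
  out <- list()
  for (sp in unique(kept$species)) {
    idx <- which(kept$species == sp)
    for (m in methods) {
      calls <- if (m == "cluster") {
        model <- kmeans_1d(kept$delta_ct[idx], k = 3, seed = seed)
        if (min(diff(model$centers)) < min_center_gap) {
          # fewer than three genotype clusters present in this species
          if (is.null(bands[[sp]]))
            stop("species '", sp, "': 3-means centres are separated by ",
                 "less than ", min_center_gap, " cycles and no threshold ",
                 "bands are available")
          calls_from_thresholds(kept$delta_ct[idx], bands[[sp]],
                                kept$specimen_id[idx])
        } else {
          calls_from_clusters(model, kept$delta_ct[idx],
                              kept$specimen_id[idx])
        }
      } else {
        if (is.null(bands[[sp]])) next  # no published bands: cluster only
        calls_from_thresholds(kept$delta_ct[idx], bands[[sp]],
                              kept$specimen_id[idx])
      }
      calls$species <- sp
      calls$flags <- ifelse(nzchar(sub_flags[idx]) & nzchar(calls$flags),
                            paste(sub_flags[idx], calls$flags, sep = ";"),
                            paste0(sub_flags[idx], calls$flags))
      out[[length(out) + 1]] <-
        calls[, c("specimen_id", "species", "delta_ct", "genotype",
                  "method", "flags")]
    }
  }
  res <- do.call(rbind, c(out, list(excluded)))
  rownames(res) <- NULL
  res
}

#' One-way ANOVA of delta-CT by assigned genotype
#'
#' Standard one-way fixed-effects decomposition, testing whether delta-CT
#' differs among the assigned genotype groups.
#'
#' @param delta_cts Numeric delta-CT values.
#' @param genotypes Group labels (same length).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_delta_by_genotype <- function(delta_cts, genotypes) {
  keep <- !is.na(delta_cts) & !is.na(genotypes)
  delta_cts <- delta_cts[keep]
  genotypes <- factor(genotypes[keep])
  if (nlevels(genotypes) < 2) stop("need at least two genotype groups")
  ft <- oneway.test(delta_cts ~ genotypes, var.equal = TRUE)
  list(F = unname(ft$statistic), df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]), p = unname(ft$p.value))
}
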