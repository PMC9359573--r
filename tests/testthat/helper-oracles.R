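# Independent oracles used to cross-check the implementation. These are
# deliberately naive (exhaustive window scans, full partition enumeration,
# closed forms) and share no code with the functions they check.

# Hamming window scan over both strands of a template, pure string ops.
brute_binding_sites <- function(template, oligo, max_mismatch) {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  tc <- strsplit(template, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") oligo else rc(oligo)
    pc <- strsplit(pat, "")[[1]]
    L <- length(pc)
    for (i in seq_len(length(tc) - L + 1)) {
      mm <- sum(tc[i:(i + L - 1)] != pc)
      if (mm <= max_mismatch)
        hits[[length(hits) + 1]] <- data.frame(start = i, end = i + L - 1,
                                               strand = strand,
                                               mismatches = mm)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatches, out$start), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Optimal k-partition of 1-D data: in one dimension the minimum-WSS
# partition is contiguous in sorted order, so enumerate all contiguous
# splits of the sorted values.
kmeans_1d_oracle_wss <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  best <- Inf
  for (cut in cuts) {
    bounds <- c(0, cut, n)
    wss <- 0
    for (j in seq_len(k)) {
      seg <- v[(bounds[j] + 1):bounds[j + 1]]
      wss <- wss + sum((seg - mean(seg))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Two-sided Fisher p for a 2x2 table from the hypergeometric closed form.
fisher_2x2_oracle <- function(m) {
  stopifnot(all(dim(m) == c(2, 2)))
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimum probe mismatch over both strands via Biostrings counting,
# independent of the package's own window scan.
probe_min_mismatch_oracle <- function(amplicon, probe) {
  p <- Biostrings::DNAString(probe)
  a <- Biostrings::DNAString(amplicon)
  arc <- Biostrings::reverseComplement(a)
  for (k in 0:nchar(probe)) {
    if (Biostrings::countPattern(p, a, max.mismatch = k) +
        Biostrings::countPattern(p, arc, max.mismatch = k) > 0)
      return(k)
  }
  nchar(probe)
}

# Simulated specimens + plate at given centres, returning truth and calls.
simulate_and_call <- function(n_per_geno, model, seed = 1L,
                              method = "cluster") {
  truth <- rep(c("LL", "LF", "FF"), each = n_per_geno)
  ct <- withr::with_seed(seed, simulate_ct_pair(truth, model))
  readings <- data.frame(specimen_id = sprintf("S%04d", seq_along(truth)),
                         species = model$species_label,
                         ct_tta = ct$ct_tta, ct_ttt = ct$ct_ttt)
  calls <- call_genotypes(readings, method = method, seed = seed)
  list(truth = data.frame(specimen_id = readings$specimen_id,
                          genotype = truth), calls = calls)
}

# Draw grouped ordinal counts from the proportional-odds model.
simulate_po_counts <- function(alpha, beta, n_per_group) {
  pr <- function(eta) {
    cum <- c(plogis(alpha - eta), 1)
    diff(c(0, cum))
  }
  y0 <- stats::rmultinom(1, n_per_group, pr(0))
  y1 <- stats::rmultinom(1, n_per_group, pr(beta))
  data.frame(x = c("a", "b"), n_LL = c(y0[1], y1[1]),
             n_LF = c(y0[2], y1[2]), n_FF = c(y0[3], y1[3]))
}
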