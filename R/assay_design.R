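#' Construct an oligo
#'
#' Primer or probe with chemistry annotations stripped to pure bases:
#' reporter-dye prefixes (e.g. `FAM-`, `HEX-`), internal quencher tags such
#' as `/ZEN/`, 3' quencher codes (e.g. `3IABkFQ`) and whitespace/hyphens are
#' removed at parse time; the reporter, if any, is kept as a plain label.
#'
#' @param name Oligo name.
#' @param bases Sequence, possibly annotated; must reduce to A/C/G/T.
#' @param role One of `"forward"`, `"reverse"`, `"probe"`.
#' @param reporter Optional reporter label (e.g. `"FAM"`).
#' @return An `oligo` object (list with `name`, `bases`, `role`, `reporter`).
#' @export
#' @examples
#' oligo("RTkdr_TTA", "FAM-GGTTAAGTA/ZEN/CGACTAAGTTTCCTATCACTAC-3IABkFQ",
#'       "probe", reporter = "FAM")
oligo <- function(name, bases, role = c("forward", "reverse", "probe"),
                  reporter = NULL) {
  role <- match.arg(role)
  seq <- toupper(bases)
  if (is.null(reporter)) {
    m <- regmatches(seq, regexpr("^(FAM|HEX|VIC|CY5|TEX)(?=-)", seq, perl = TRUE))
    if (length(m) == 1 && nzchar(m)) reporter <- m
  }
  seq <- sub("^(FAM|HEX|VIC|CY5|TEX)-", "", seq)
  seq <- gsub("/[A-Z0-9]+/", "", seq)          # internal quenchers, /ZEN/ etc.
  seq <- sub("-?3[A-Z0-9]+$", "", seq)         # 3' quencher codes
  seq <- gsub("[-[:space:]]", "", seq)
  if (!nzchar(seq)) stop("oligo '", name, "': empty sequence")
  if (grepl("[^ACGT]", seq))
    stop("oligo '", name, "': non-ACGT bases after stripping annotations: ", seq)
  structure(list(name = name, bases = seq, role = role, reporter = reporter),
            class = "oligo")
}

as_dna <- function(x) {
  if (inherits(x, "DNAString")) return(x)
  if (inherits(x, "oligo")) return(Biostrings::DNAString(x$bases))
  if (inherits(x, "amplicon_result")) return(Biostrings::DNAString(x$bases))
  Biostrings::DNAString(toupper(as.character(x)))
}

oligo_bases <- function(x) as.character(as_dna(x))

#' Reverse complement of a DNA string
#' @param x Character, `DNAString` or `oligo`.
#' @return Character reverse complement.
#' @export
revcomp <- function(x) as.character(Biostrings::reverseComplement(as_dna(x)))

#' Find oligo binding sites on a template
#'
#' Scans both strands of the template for windows within `max_mismatch`
#' Hamming mismatches of the oligo. A minus-strand hit means the oligo
#' matches the reverse complement of the reported window (i.e. the oligo
#' anneals to the plus strand shown). Ambiguous template bases (N) count as
#' mismatches. Coordinates are 1-based inclusive on the plus strand.
#'
#' @param template Character or `DNAString` (or named list with `bases`).
#' @param oligo An [oligo()] or plain sequence.
#' @param max_mismatch Maximum Hamming mismatches allowed (no indels).
#' @return Data frame with columns `start`, `end`, `strand` (`"+"`/`"-"`),
#'   `mismatches`, sorted by (mismatches, start).
#' @export
find_binding_site <- function(template, oligo, max_mismatch = 0) {
  tmpl <- as_dna(if (is.list(template) && !is.null(template$bases))
    template$bases else template)
  olg <- as_dna(oligo)
  if (length(tmpl) == 0 || length(olg) == 0)
    stop("empty template or oligo")
  if (length(olg) > length(tmpl))
    stop("oligo longer than template")
  hit_one <- function(pattern, strand) {
    v <- Biostrings::matchPattern(pattern, tmpl, max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(v) == 0)
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0)))
    starts <- Biostrings::start(v)
    mm <- Biostrings::neditStartingAt(pattern, tmpl, starting.at = starts,
                                      with.indels = FALSE, fixed = TRUE)
    data.frame(start = starts, end = Biostrings::end(v), strand = strand,
               mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_one(olg, "+"),
                hit_one(Biostrings::reverseComplement(olg), "-"))
  hits <- hits[hits$mismatches <= max_mismatch, , drop = FALSE]
  hits <- hits[order(hits$mismatches, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' In-silico PCR
#'
#' Pairs forward-primer plus-strand sites with reverse-primer minus-strand
#' sites downstream of them (and the mirrored orientation on the minus
#' strand) and extracts the amplicon, which spans both primer footprints.
#' When several products are possible the shortest is returned; all are
#' listed in the `products` field. Failure to amplify is an explicit status,
#' not an error, and single-primer binding is reported distinctly.
#'
#' @param template Character/`DNAString`, or a list with `id` and `bases`.
#' @param fwd,rev Forward and reverse [oligo()]s (or plain sequences).
#' @param max_mismatch Maximum mismatches tolerated per primer site.
#' @return An `amplicon_result`: list with `template_id`, `status`
#'   (`"amplified"`, `"no_amplification"`, `"fwd_only"`, `"rev_only"`),
#'   and, when amplified, `start`, `end` (1-based inclusive, plus strand),
#'   `length`, `bases` (oriented to begin with the forward-primer match),
#'   `orientation` (`"+"` if the forward primer sits on the plus strand),
#'   `fwd_mismatches`, `rev_mismatches`, and a `products` data frame.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0) {
  id <- if (is.list(template) && !is.null(template$id)) template$id else NA_character_
  tmpl <- as_dna(if (is.list(template) && !is.null(template$bases))
    template$bases else template)
  fh <- find_binding_site(tmpl, fwd, max_mismatch)
  rh <- find_binding_site(tmpl, rev, max_mismatch)
  prods <- list()
  # forward on +, reverse on -, reverse footprint downstream
  for (i in which(fh$strand == "+")) for (j in which(rh$strand == "-")) {
    if (rh$start[j] > fh$end[i])
      prods[[length(prods) + 1]] <- data.frame(
        start = fh$start[i], end = rh$end[j], orientation = "+",
        fwd_mismatches = fh$mismatches[i], rev_mismatches = rh$mismatches[j])
  }
  # mirrored: forward on -, reverse on +, reverse footprint upstream
  for (i in which(fh$strand == "-")) for (j in which(rh$strand == "+")) {
    if (rh$end[j] < fh$start[i])
      prods[[length(prods) + 1]] <- data.frame(
        start = rh$start[j], end = fh$end[i], orientation = "-",
        fwd_mismatches = fh$mismatches[i], rev_mismatches = rh$mismatches[j])
  }
  base <- list(template_id = id, products = NULL)
  if (length(prods) == 0) {
    status <- if (nrow(fh) > 0 && nrow(rh) == 0) "fwd_only"
    else if (nrow(rh) > 0 && nrow(fh) == 0) "rev_only"
    else "no_amplification"
    return(structure(c(base, list(status = status)), class = "amplicon_result"))
  }
  products <- do.call(rbind, prods)
  products$length <- products$end - products$start + 1L
  products <- products[order(products$length, products$start), , drop = FALSE]
  rownames(products) <- NULL
  best <- products[1, ]
  window <- Biostrings::subseq(tmpl, best$start, best$end)
  bases <- if (best$orientation == "+") as.character(window)
  else as.character(Biostrings::reverseComplement(window))
  structure(list(template_id = id, status = "amplified",
                 start = best$start, end = best$end, length = best$length,
                 bases = bases, orientation = best$orientation,
                 fwd_mismatches = best$fwd_mismatches,
                 rev_mismatches = best$rev_mismatches,
                 products = products),
            class = "amplicon_result")
}

#' @export
print.amplicon_result <- function(x, ...) {
  cat("<amplicon_result>", x$template_id %||% "", "status:", x$status, "\n")
  if (identical(x$status, "amplified"))
    cat(sprintf("  %d bp at %d..%d (%s strand), primer mismatches %d/%d\n",
                x$length, x$start, x$end, x$orientation,
                x$fwd_mismatches, x$rev_mismatches))
  invisible(x)
}

#' Minimum probe mismatch count over an amplicon
#'
#' Minimum Hamming distance between the probe and any window of the
#' amplicon, on either strand (probes may be antisense).
#'
#' @param amplicon An `amplicon_result` or plain sequence.
#' @param probe An [oligo()] or plain sequence.
#' @return Nonnegative integer mismatch count.
#' @export
probe_mismatch_count <- function(amplicon, probe) {
  amp <- oligo_bases(amplicon)
  prb <- oligo_bases(probe)
  if (nchar(prb) > nchar(amp)) stop("probe longer than amplicon")
  pc <- strsplit(prb, "")[[1]]
  L <- length(pc)
  best <- L
  for (s in c(amp, revcomp(amp))) {
    sc <- strsplit(s, "")[[1]]
    for (i in seq_len(length(sc) - L + 1)) {
      d <- sum(sc[i:(i + L - 1)] != pc)
      if (d < best) best <- d
    }
  }
  as.integer(best)
}

#' Percent identity of two sequences
#'
#' Global pairwise alignment (match +1, mismatch 0, linear gap penalty 1 per
#' position, for anchoring only); identity is matches over alignment
#' columns, in percent. With these scores, equal-length inputs align without
#' spurious gaps, so identity is 100 exactly when the strings are equal.
#'
#' @param a,b Character sequences (or `DNAString`/`oligo`).
#' @return Real in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  sa <- oligo_bases(a); sb <- oligo_bases(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty input")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  100 * Biostrings::nmatch(aln) / nchar(p)
}

#' Anchor describing where the 1014 codon sits in the amplicon
#'
#' The codon is located via the conserved flank immediately 5' of it on the
#' sense (mRNA) strand; for the RTkdr assay this flank is the reverse
#' complement of the probes' shared 3' arm.
#'
#' @param flank Conserved sense-strand sequence immediately preceding the
#'   codon.
#' @return List with `flank`.
#' @export
kdr_codon_anchor <- function(flank = "GTAGTGATAGGAAAC") list(flank = flank)

#' Read the 1014 genotype from an amplicon sequence
#'
#' Locates the codon by exact match to the conserved anchor flank on either
#' strand and interprets the codon (IUPAC codes allowed): third position `A`
#' is the leucine (TTA) allele, `T` the phenylalanine (TTT) allele, `W`
#' (A/T) a leucine/phenylalanine heterozygote; a serine-bearing codon (C, or
#' pyrimidine ambiguity, at the variable positions) is reported as the
#' SF class; anything else is `ambiguous`.
#'
#' @param amplicon An `amplicon_result` or plain sequence.
#' @param codon_anchor Anchor from [kdr_codon_anchor()].
#' @return One of `"LL"`, `"FF"`, `"LF"`, `"SF"`, `"ambiguous"`.
#' @export
genotype_from_sequence <- function(amplicon, codon_anchor = kdr_codon_anchor()) {
  for (s in c(oligo_bases(amplicon), revcomp(amplicon))) {
    pos <- regexpr(codon_anchor$flank, s, fixed = TRUE)
    if (pos > 0) {
      codon <- substr(s, pos + nchar(codon_anchor$flank),
                      pos + nchar(codon_anchor$flank) + 2L)
      if (nchar(codon) < 3) stop("anchor found but codon truncated")
      p1 <- substr(codon, 1, 1); p2 <- substr(codon, 2, 2)
      p3 <- substr(codon, 3, 3)
      if (p1 != "T") return("ambiguous")
      if (p2 %in% c("C", "Y")) return("SF")
      if (p2 != "T") return("ambiguous")
      return(switch(p3, A = "LL", T = "FF", W = "LF", C = "SF", "ambiguous"))
    }
  }
  stop("codon anchor not found in amplicon")
}

# Building blocks of the synthetic Vgsc cDNA templates: real assay oligos
# embedded in fixed random spacers chosen so each oligo has a unique binding
# site at <= 2 mismatches. Coordinates below are relative to the amplicon
# produced by RTSeq_Fwd + RTkdr_Rev (373 bp).
.synth <- list(
  s_left  = "CTAGCCTCGCAGGTGGCTACGGGTTCCCTTCGTCCCAACA",
  s1      = paste0("GATTATCAGGTATCACTGTACTAAGCGAGACGAACATCTCGGAGTATGTAAGGTAGG",
                   "GGCTTGAATGCAGTGACCGTTATTTCAGCTACCAGGGCATAAAACGGCGTGCATCCA",
                   "AGCGTTGGCCCCATTAGTACCGTATGAAAGTTTCCTTTGCGACGCCGATGTCGACCA",
                   "TAAGCGTCGCGGTGATATGTTTTTAAAAAACTAAAGCCCTGACTTGTTT"),
  s2      = "AGGGGATACAGGGACCGAGGAAGTAAGAAG",
  s3      = "GATGTATTAGTTCCAGACATTCTGCGAAGTCC",
  s_right = "CGGGAGACACTTGATAGGCAACCTTCTGAATATGCGTAGC",
  # transitions applied for the divergent (Cx. pipiens-like) variant:
  # 13 spacer positions plus 2 in the probe arm 3' of the codon
  mut_pos = c(35L, 60L, 85L, 110L, 135L, 160L, 185L, 210L, 265L, 280L,
              310L, 317L, 325L, 335L, 345L))

#' Synthetic Vgsc cDNA template
#'
#' Builds a synthetic (not GenBank-derived) cDNA template that embeds the
#' published RTkdr primer and probe binding sites with the stated assay
#' geometry: the sequencing forward primer and the reverse primer delimit a
#' 373-bp product containing the 1014 codon. Variants emulate the
#' cross-species structure reported for the assay: `"reference"` and
#' `"conserved_flanks"` are identical across the amplicon (the latter
#' differs only outside it, like the fully conserved sister species), while
#' `"divergent"` carries ~4% substitutions across the amplicon including
#' exactly two under the probe footprint, with all primer sites intact.
#'
#' @param codon The 1014 codon on the sense strand (e.g. `"TTA"`, `"TTT"`,
#'   `"TTW"`).
#' @param variant Template variant (see above).
#' @return List with `id`, `bases`, `description` (a `template_seq`).
#' @export
synthetic_vgsc_template <- function(codon = "TTA",
                                    variant = c("reference",
                                                "conserved_flanks",
                                                "divergent")) {
  variant <- match.arg(variant)
  stopifnot(nchar(codon) == 3)
  codon <- toupper(codon)
  oligos <- kdr_oligos()
  seqs <- setNames(oligos$bases, oligos$name)
  amp <- paste0(seqs[["RTSeq_Fwd"]], .synth$s1, seqs[["RTkdr_Fwd"]],
                .synth$s2, "GTAGTGATAGGAAAC", codon, "GTCGTACTTAACC",
                .synth$s3, revcomp(seqs[["RTkdr_Rev"]]))
  if (variant == "divergent") {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    ch <- strsplit(amp, "")[[1]]
    ch[.synth$mut_pos] <- transition[ch[.synth$mut_pos]]
    amp <- paste(ch, collapse = "")
  }
  flanks <- switch(variant,
    conserved_flanks = list(chartr("ACGT", "TGCA", .synth$s_left),
                            chartr("ACGT", "TGCA", .synth$s_right)),
    list(.synth$s_left, .synth$s_right))
  list(id = paste0("SYNTH_VGSC_", variant, "_", codon),
       bases = paste0(flanks[[1]], amp, flanks[[2]]),
       description = paste("synthetic Vgsc cDNA template,", variant,
                           "variant, 1014 codon", codon))
}

#' Evaluate the assay oligo set against a set of templates
#'
#' For each template: runs in-silico PCR with the sequencing forward primer
#' and the assay reverse primer, counts the minimum probe mismatches of both
#' allele probes over the amplicon, computes amplicon percent identity to
#' the first (reference) template's amplicon, and reads the 1014 genotype
#' from the amplicon sequence.
#'
#' @param templates A named character vector of sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param oligos Oligo data frame as returned by [kdr_oligos()] /
#'   [read_oligos_csv()].
#' @param max_mismatch Primer mismatch tolerance.
#' @param fwd_name,rev_name Names of the primer pair used for the product.
#' @return Data frame with one row per template: `template_id`, `status`,
#'   `amplicon_length`, `fwd_mismatches`, `rev_mismatches`,
#'   `probe_tta_mismatches`, `probe_ttt_mismatches`,
#'   `identity_to_reference`, `genotype`.
#' @export
assay_eval <- function(templates, oligos = kdr_oligos(), max_mismatch = 2,
                       fwd_name = "RTSeq_Fwd", rev_name = "RTkdr_Rev") {
  tset <- read_templates(templates)
  seqs <- setNames(oligos$bases, oligos$name)
  fwd <- seqs[[fwd_name]]; rev <- seqs[[rev_name]]
  probes <- oligos[oligos$role == "probe", , drop = FALSE]
  ref_amp <- NULL
  rows <- vector("list", length(tset))
  for (i in seq_along(tset)) {
    res <- in_silico_pcr(list(id = names(tset)[i], bases = tset[[i]]),
                         fwd, rev, max_mismatch)
    row <- data.frame(template_id = names(tset)[i], status = res$status,
                      amplicon_length = NA_integer_,
                      fwd_mismatches = NA_integer_,
                      rev_mismatches = NA_integer_,
                      probe_tta_mismatches = NA_integer_,
                      probe_ttt_mismatches = NA_integer_,
                      identity_to_reference = NA_real_,
                      genotype = NA_character_, stringsAsFactors = FALSE)
    if (identical(res$status, "amplified")) {
      row$amplicon_length <- res$length
      row$fwd_mismatches <- res$fwd_mismatches
      row$rev_mismatches <- res$rev_mismatches
      mm <- vapply(probes$bases, function(p) probe_mismatch_count(res, p),
                   integer(1))
      tta <- grep("TTA", probes$name)[1]; ttt <- grep("TTT", probes$name)[1]
      row$probe_tta_mismatches <- mm[[tta]]
      row$probe_ttt_mismatches <- mm[[ttt]]
      if (is.null(ref_amp)) ref_amp <- res$bases
      row$identity_to_reference <- percent_identity(res$bases, ref_amp)
      row$genotype <- tryCatch(genotype_from_sequence(res),
                               error = function(e) NA_character_)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Accepts FASTA path, DNAStringSet, named character vector or list of
# template_seq lists; returns a named character vector.
read_templates <- function(templates) {
  if (is.character(templates) && length(templates) == 1 &&
      file.exists(templates)) {
    set <- Biostrings::readDNAStringSet(templates)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  if (inherits(templates, "DNAStringSet")) {
    seqs <- as.character(templates)
    names(seqs) <- sub("\\s.*$", "", names(templates))
    return(seqs)
  }
  if (is.list(templates))
    return(setNames(vapply(templates, `[[`, "", "bases"),
                    vapply(templates, `[[`, "", "id")))
  if (is.character(templates)) {
    if (is.null(names(templates)))
      names(templates) <- paste0("template_", seq_along(templates))
    return(templates)
  }
  stop("unsupported template input")
}
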