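#' Resistance allele frequency from genotype counts
#'
#' Frequency of the resistance (F/phenylalanine) allele among `2N` allele
#' draws: `f = (2 n_FF + n_LF) / (2 N)`. The standard error is the binomial
#' SE on the `2N` allele draws, `sqrt(f (1 - f) / (2 N))`. Counts are
#' accessed by name to rule out positional mix-ups.
#'
#' @param n_LL,n_LF,n_FF Nonnegative integer genotype counts.
#' @return An `allele_frequency` list: `f`, `se`, `n_individuals`.
#' @export
#' @examples
#' allele_frequency(n_LL = 208, n_LF = 226, n_FF = 310)
allele_frequency <- function(n_LL, n_LF, n_FF) {
  counts <- c(n_LL = n_LL, n_LF = n_LF, n_FF = n_FF)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  N <- sum(counts)
  if (N == 0) stop("empty stratum: N = 0")
  f <- (2 * n_FF + n_LF) / (2 * N)
  structure(list(f = f, se = sqrt(f * (1 - f) / (2 * N)),
                 n_individuals = as.integer(N)),
            class = "allele_frequency")
}

#' @export
print.allele_frequency <- function(x, ...) {
  cat(sprintf("F(FF,LF) = %.4f +/- %.4f (N = %d)\n", x$f, x$se,
              x$n_individuals))
  invisible(x)
}

#' Allele frequencies for a table of genotype counts
#'
#' @param counts Data frame with columns `n_LL`, `n_LF`, `n_FF` and any
#'   stratum label columns.
#' @return The input with added columns `N`, `f`, `se`.
#' @export
allele_frequency_table <- function(counts) {
  stopifnot(all(c("n_LL", "n_LF", "n_FF") %in% names(counts)))
  est <- lapply(seq_len(nrow(counts)), function(i)
    allele_frequency(n_LL = counts$n_LL[i], n_LF = counts$n_LF[i],
                     n_FF = counts$n_FF[i]))
  counts$N <- vapply(est, `[[`, integer(1), "n_individuals")
  counts$f <- vapply(est, `[[`, numeric(1), "f")
  counts$se <- vapply(est, `[[`, numeric(1), "se")
  counts
}

#' Concordance between two call sets
#'
#' Matches calls by specimen id, removes specimens EXCLUDED (or NA) in
#' either set, and reports agreement with a confusion matrix.
#'
#' @param calls_a,calls_b Data frames with `specimen_id` and `genotype`
#'   columns (or character vectors of equal length, matched by position).
#' @return List with `n_total` (shared ids), `n_valid` (after exclusions),
#'   `n_concordant`, `percent`, and `confusion` (a table, rows = set A).
#' @export
concordance <- function(calls_a, calls_b) {
  norm <- function(x, who) {
    if (is.data.frame(x)) {
      stopifnot(all(c("specimen_id", "genotype") %in% names(x)))
      data.frame(specimen_id = x$specimen_id, genotype = x$genotype,
                 stringsAsFactors = FALSE)
    } else data.frame(specimen_id = seq_along(x), genotype = as.character(x),
                      stringsAsFactors = FALSE)
  }
  a <- norm(calls_a); b <- norm(calls_b)
  m <- merge(a, b, by = "specimen_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared specimen ids")
  valid <- !(m$genotype_a %in% "EXCLUDED") & !(m$genotype_b %in% "EXCLUDED") &
    !is.na(m$genotype_a) & !is.na(m$genotype_b)
  mv <- m[valid, , drop = FALSE]
  n_conc <- sum(mv$genotype_a == mv$genotype_b)
  list(n_total = nrow(m), n_valid = nrow(mv), n_concordant = n_conc,
       percent = 100 * n_conc / nrow(mv),
       confusion = table(A = mv$genotype_a, B = mv$genotype_b))
}

# log point probability of a table given margins (hypergeometric extension)
log_table_prob <- function(tab, lr, lc, lN) {
  lr + lc - lN - sum(lgamma(tab + 1))
}

#' Fisher's exact test for r x c tables
#'
#' Exhaustive enumeration of all tables sharing the observed margins;
#' the two-sided p-value is the total conditional probability of tables
#' whose point probability does not exceed the observed one (with a small
#' relative slack of 1e-7 for floating-point ties, matching common
#' implementations). All-zero rows and columns are dropped first. When the
#' number of tables would exceed `budget`, a seeded Monte-Carlo estimate
#' over tables drawn from the conditional distribution (Patefield's
#' algorithm) is returned instead with `method = "monte_carlo"`.
#'
#' @param table Matrix of nonnegative integer counts.
#' @param budget Maximum number of tables to enumerate.
#' @param mc_reps Monte-Carlo replicates used beyond the budget.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List with `p`, `method` (`"exact"` or `"monte_carlo"`), and for
#'   the exact method `n_tables` and `total_prob` (enumeration check; sums
#'   to 1).
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(1, 11, 9, 3), nrow = 2))
fisher_exact_rxc <- function(table, budget = 1e7, mc_reps = 1e5, seed = 1L) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least two nonzero rows and columns")
  r <- rowSums(m); cs <- colSums(m); N <- sum(m)
  lr <- sum(lgamma(r + 1)); lc <- sum(lgamma(cs + 1)); lN <- lgamma(N + 1)
  lp_obs <- log_table_prob(m, lr, lc, lN)
  slack <- 1e-7

  n_tables <- 0L
  p_sum <- 0
  total <- 0
  over_budget <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  tab <- matrix(0L, nr, nc)
  # enumerate row by row, cell by cell, with feasibility bounds
  recurse <- function(i, j, row_left, col_left) {
    if (over_budget) return()
    if (i > nr) {
      n_tables <<- n_tables + 1L
      if (n_tables > budget) { over_budget <<- TRUE; return() }
      lp <- log_table_prob(tab, lr, lc, lN)
      pr <- exp(lp)
      total <<- total + pr
      if (lp <= lp_obs + slack) p_sum <<- p_sum + pr
      return()
    }
    if (j > nc) { recurse(i + 1L, 1L, r[i + 1L], col_left); return() }
    if (j == nc) {       # last cell of the row is forced
      v <- row_left
      if (v > col_left[j]) return()
      tab[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      if (i == nr && any(cl != 0)) { tab[i, j] <<- 0L; return() }
      recurse(i + 1L, 1L, if (i < nr) r[i + 1L] else 0L, cl)
      tab[i, j] <<- 0L
      return()
    }
    rest_cap <- sum(col_left[(j + 1L):nc])
    lo <- max(0L, row_left - rest_cap)
    hi <- min(row_left, col_left[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      tab[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
    tab[i, j] <<- 0L
  }
  recurse(1L, 1L, r[1L], cs)

  if (over_budget) {
    p <- withr::with_seed(as.integer(seed), {
      sims <- r2dtable(mc_reps, r, cs)
      hits <- vapply(sims, function(t)
        log_table_prob(t, lr, lc, lN) <= lp_obs + slack, logical(1))
      (1 + sum(hits)) / (mc_reps + 1)
    })
    return(list(p = p, method = "monte_carlo", mc_reps = mc_reps))
  }
  list(p = min(p_sum, 1), method = "exact", n_tables = n_tables,
       total_prob = total)
}

#' Knockdown-versus-time regression line
#'
#' Ordinary least squares of cumulative knockdown percent on time in
#' minutes, pooled across bottles.
#'
#' @param records Bioassay data frame with columns `time_min` and either
#'   `pct_down` or (`n_down`, `n_total`).
#' @return A `regression_line`: `slope` (percent/min), `intercept`
#'   (percent), `r_squared`, `residual_ss`, `slope_se`, `n`.
#' @export
knockdown_regression <- function(records) {
  stopifnot("time_min" %in% names(records))
  pct <- if ("pct_down" %in% names(records)) records$pct_down
  else 100 * records$n_down / records$n_total
  t <- records$time_min
  if (length(unique(t)) < 2) stop("need at least two distinct timepoints")
  fit <- lm(pct ~ t)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate input
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residual_ss = sum(fit$residuals^2),
                 slope_se = sm$coefficients[2, 2],
                 n = length(t)),
            class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("y = %.4g * t %+.4g  (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Test for equal knockdown slopes (ANCOVA)
#'
#' Compares the common-slope model `y ~ t + group` against separate slopes
#' `y ~ t * group` by the extra-sum-of-squares F test:
#' `F = (SSE_common - SSE_separate) / (SSE_separate / (n - 4))` on
#' `(1, n - 4)` degrees of freedom for two groups.
#'
#' @param records Data frame with `time_min`, knockdown percent (`pct_down`
#'   or `n_down`/`n_total`) and a `group` column with exactly two levels.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
ancova_slopes <- function(records) {
  stopifnot(all(c("time_min", "group") %in% names(records)))
  pct <- if ("pct_down" %in% names(records)) records$pct_down
  else 100 * records$n_down / records$n_total
  g <- factor(records$group)
  if (nlevels(g) != 2) stop("ancova_slopes compares exactly two groups")
  t <- records$time_min
  full <- lm(pct ~ t * g)
  reduced <- lm(pct ~ t + g)
  sse_f <- sum(full$residuals^2)
  sse_r <- sum(reduced$residuals^2)
  scale <- sum(pct^2) + 1
  if (sse_f < 1e-18 * scale) sse_f <- 0     # numerically perfect fit
  if (sse_r < 1e-18 * scale) sse_r <- 0
  df2 <- length(pct) - 4
  Fst <- if (sse_f == 0 && sse_r == 0) 0    # e.g. exactly parallel lines
  else ((sse_r - sse_f) / 1) / (sse_f / df2)
  list(F = Fst, df1 = 1, df2 = df2, p = pf(Fst, 1, df2, lower.tail = FALSE))
}

# Pooled knockdown proportion of one strain/insecticide at a given time.
knockdown_proportion <- function(records, at_minute) {
  rows <- records[records$time_min == at_minute, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("no observations at ", at_minute, " min")
  sum(rows$n_down) / sum(rows$n_total)
}

#' Resistance ratio at a fixed time point
#'
#' Ratio of the reference (susceptible) strain's pooled knockdown proportion
#' to the test (candidate-resistant) strain's, conventionally read at the
#' 45-min time point when average knockdown is below 100%. The resistant
#' strain sits in the denominator, so larger ratios mean more resistance.
#'
#' @param reference,test Bioassay data frames (columns `time_min`, `n_down`,
#'   `n_total`) for the reference and test strains.
#' @param at_minute Time point in minutes.
#' @return Positive real (or `Inf` with a warning when the test strain shows
#'   zero knockdown).
#' @export
resistance_ratio <- function(reference, test, at_minute = 45) {
  p_ref <- knockdown_proportion(reference, at_minute)
  p_test <- knockdown_proportion(test, at_minute)
  if (p_test == 0) {
    warning("test strain shows zero knockdown at ", at_minute,
            " min; resistance ratio is infinite")
    return(Inf)
  }
  p_ref / p_test
}

#' CDC 120-minute resistance classification
#'
#' A population is classified as suspected resistant when knockdown at 120
#' minutes is below 90%, susceptible otherwise.
#'
#' @param knockdown_at_120 Proportion knocked down at 120 min, in `[0, 1]`.
#' @return `"resistant_suspected"` or `"susceptible"`.
#' @export
classify_cdc_resistance <- function(knockdown_at_120) {
  if (any(knockdown_at_120 < 0) || any(knockdown_at_120 > 1))
    stop("knockdown proportion must lie in [0, 1]")
  ifelse(knockdown_at_120 < 0.90, "resistant_suspected", "susceptible")
}
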