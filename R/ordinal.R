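#' Proportional-odds (cumulative-logit) ordinal regression
#'
#' Maximum-likelihood fit of the proportional-odds model
#' `logit P(Y <= j | x) = alpha_j - x' beta` for an ordered outcome
#' (here LL < LF < FF, so positive `beta` shifts mass toward the resistant
#' genotypes and `exp(beta) > 1` is the odds ratio of being in a more
#' resistant category). Data are grouped: one row per covariate pattern with
#' counts per outcome category. Fitting is by Newton-type ascent on the
#' multinomial log-likelihood with the analytic score; the observed
#' information (used both for the steps and for the Wald covariance) is
#' obtained by central finite differences of the score. Convergence is
#' declared when the largest score component falls below `1e-8` or the
#' relative log-likelihood change falls below `1e-10`; divergence or
#' separation leaves `converged = FALSE` rather than returning silently.
#'
#' @param counts Data frame holding one row per covariate pattern, with the
#'   outcome counts in columns `n_LL`, `n_LF`, `n_FF` (or the columns named
#'   in `outcome_cols`, ordered from lowest to highest category) and the
#'   covariates in the columns named by `covariates`.
#' @param covariates Character vector of covariate column names; each is
#'   treated as a factor with its first level (or the level given in `ref`)
#'   as the reference, coded by treatment contrasts.
#' @param ref Optional named character vector of reference levels.
#' @param outcome_cols Names of the ordered outcome count columns.
#' @param max_iter Iteration cap.
#' @return An `ordinal_fit`: `cutpoints` (ascending `alpha_j`),
#'   `coefficients` (`beta`), `vcov`, `odds_ratios` (data frame with OR,
#'   95% Wald CI and two-sided normal-reference p-values), `loglik`,
#'   `iterations`, `converged`, `n`.
#' @export
#' @examples
#' counts <- data.frame(species = c("Cx. tarsalis", "Cx. pipiens"),
#'                      n_LL = c(401, 208), n_LF = c(57, 226),
#'                      n_FF = c(49, 310))
#' fit <- fit_proportional_odds(counts, "species",
#'                              ref = c(species = "Cx. tarsalis"))
#' fit$odds_ratios
fit_proportional_odds <- function(counts, covariates,
                                  ref = NULL,
                                  outcome_cols = c("n_LL", "n_LF", "n_FF"),
                                  max_iter = 100L) {
  stopifnot(length(covariates) >= 1,
            all(covariates %in% names(counts)),
            all(outcome_cols %in% names(counts)))
  Y <- as.matrix(counts[, outcome_cols, drop = FALSE])
  if (any(Y < 0) || any(Y != round(Y))) stop("counts must be nonnegative integers")
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  J <- ncol(Y)
  if (J < 2) stop("need at least two outcome categories")

  fac <- lapply(covariates, function(v) {
    f <- factor(counts[[v]][keep])
    if (!is.null(ref) && v %in% names(ref)) f <- stats::relevel(f, ref[[v]])
    if (nlevels(f) < 2) stop("covariate '", v, "' has a single observed level")
    f
  })
  names(fac) <- covariates
  mf <- as.data.frame(fac)
  X <- stats::model.matrix(~ ., data = mf)[, -1, drop = FALSE]
  p <- ncol(X)

  # theta = (alpha_1 < ... < alpha_{J-1}, beta_1..beta_p)
  loglik <- function(theta) {
    alpha <- theta[seq_len(J - 1)]
    if (is.unsorted(alpha, strictly = TRUE)) return(-Inf)
    eta <- drop(X %*% theta[J:(J - 1 + p)])
    cum <- cbind(0, plogis(outer(-eta, alpha, "+")), 1)
    pr <- cum[, -1, drop = FALSE] - cum[, -(J + 1), drop = FALSE]
    if (any(pr[Y > 0] <= 0)) return(-Inf)
    sum(Y * log(pmax(pr, .Machine$double.xmin)))
  }
  score <- function(theta) {
    alpha <- theta[seq_len(J - 1)]
    eta <- drop(X %*% theta[J:(J - 1 + p)])
    Fm <- plogis(outer(-eta, alpha, "+"))            # n x (J-1)
    fm <- Fm * (1 - Fm)                              # logistic density values
    cum <- cbind(0, Fm, 1)
    pr <- cum[, -1, drop = FALSE] - cum[, -(J + 1), drop = FALSE]
    pr <- pmax(pr, .Machine$double.xmin)
    W <- Y / pr                                      # n x J
    g_alpha <- vapply(seq_len(J - 1), function(m) {
      sum(fm[, m] * (W[, m] - W[, m + 1]))
    }, numeric(1))
    # d eta terms: dp_ij/dbeta = -(f_j - f_{j-1}) x_i
    fmat <- cbind(0, fm, 0)
    dpe <- fmat[, -1, drop = FALSE] - fmat[, -(J + 1), drop = FALSE]
    g_beta <- drop(t(X) %*% rowSums(W * (-dpe)))
    c(g_alpha, g_beta)
  }
  info <- function(theta) { # observed information = -Hessian, by central FD
    q <- length(theta)
    H <- matrix(0, q, q)
    h <- pmax(1e-6, 1e-6 * abs(theta))
    for (i in seq_len(q)) {
      up <- theta; up[i] <- up[i] + h[i]
      dn <- theta; dn[i] <- dn[i] - h[i]
      H[, i] <- (score(up) - score(dn)) / (2 * h[i])
    }
    -(H + t(H)) / 2
  }

  # start: marginal cumulative logits, beta = 0
  marg <- colSums(Y) / sum(Y)
  theta <- c(qlogis(cumsum(marg)[seq_len(J - 1)]), rep(0, p))
  ll <- loglik(theta)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    g <- score(theta)
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    I <- info(theta)
    step <- tryCatch(solve(I, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    new_ll <- -Inf
    lambda <- 1
    while (lambda >= 1 / 1024) {       # step halving keeps ascent + ordering
      cand <- theta + lambda * step
      new_ll <- loglik(cand)
      if (is.finite(new_ll) && new_ll >= ll - 1e-12) break
      lambda <- lambda / 2
    }
    if (!is.finite(new_ll)) break
    improved <- new_ll - ll
    theta <- theta + lambda * step
    ll <- new_ll
    if (abs(improved) < 1e-10 * (abs(ll) + 1e-10)) {
      converged <- max(abs(score(theta))) < 1e-6
      break
    }
  }

  I <- info(theta)
  V <- tryCatch(solve(I), error = function(e) matrix(NA_real_, length(theta),
                                                     length(theta)))
  nm <- c(paste0("cut_", seq_len(J - 1)), colnames(X))
  dimnames(V) <- list(nm, nm)
  beta <- setNames(theta[J:(J - 1 + p)], colnames(X))
  se <- sqrt(diag(V))[J:(J - 1 + p)]
  or <- data.frame(term = colnames(X), estimate = beta, se = se,
                   odds_ratio = exp(beta),
                   ci_low = exp(beta - 1.96 * se),
                   ci_high = exp(beta + 1.96 * se),
                   p_value = 2 * pnorm(-abs(beta / se)),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cutpoints = setNames(theta[seq_len(J - 1)],
                                      paste0("cut_", seq_len(J - 1))),
                 coefficients = beta, vcov = V, odds_ratios = or,
                 loglik = ll, iterations = iterations, converged = converged,
                 n = sum(Y)),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("<ordinal_fit> proportional-odds model, n =", x$n,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("cutpoints:", paste(signif(x$cutpoints, 6), collapse = ", "), "\n")
  print(transform(x$odds_ratios,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  odds_ratio = signif(odds_ratio, 4),
                  ci_low = signif(ci_low, 4), ci_high = signif(ci_high, 4),
                  p_value = signif(p_value, 3)))
  invisible(x)
}
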