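test_that("allele frequency follows the gene-counting formula with binomial SE", {
  est <- allele_frequency(n_LL = 208, n_LF = 226, n_FF = 310)
  expect_equal(est$f, (2 * 310 + 226) / (2 * 744))
  expect_equal(round(est$f, 2), 0.57)
  expect_equal(est$se, sqrt(est$f * (1 - est$f) / (2 * 744)))
  expect_equal(allele_frequency(n_LL = 126, n_LF = 0, n_FF = 0)$f, 0)
  expect_equal(allele_frequency(n_LL = 0, n_LF = 0, n_FF = 50)$f, 1)
  expect_error(allele_frequency(n_LL = 0, n_LF = 0, n_FF = 0), "N = 0")
  expect_error(allele_frequency(n_LL = -1, n_LF = 1, n_FF = 1), "nonnegative")

  # equals the mean per-individual resistance-allele dosage / 2
  dosage <- rep(c(0, 1, 2), c(208, 226, 310))
  expect_equal(est$f, mean(dosage) / 2)
})

test_that("concordance reproduces the published validation arithmetic", {
  a <- data.frame(specimen_id = 1:10, genotype = rep("LL", 10))
  expect_equal(concordance(a, a)$percent, 100)

  # 190 shared calls, one discordant: accuracy above 99%
  b <- data.frame(specimen_id = 1:190,
                  genotype = rep(c("LL", "LF", "FF"), length.out = 190))
  c1 <- b; c1$genotype[7] <- "FF"
  res <- concordance(b, c1)
  expect_equal(res$n_concordant, 189)
  expect_equal(res$percent, 100 * 189 / 190)
  expect_gt(res$percent, 99)

  # 75 specimens, 3 excluded, 3 discordant: 69/72 = 96%
  x <- data.frame(specimen_id = 1:75,
                  genotype = c(rep("LL", 72), rep("EXCLUDED", 3)))
  y <- x; y$genotype[1:3] <- "LF"; y$genotype[73:75] <- "LL"
  res2 <- concordance(x, y)
  expect_equal(res2$n_valid, 72)
  expect_equal(res2$n_concordant, 69)
  expect_equal(round(res2$percent), 96)
  expect_equal(res2$confusion["LL", "LF"], 3)
  expect_error(concordance(data.frame(specimen_id = 1, genotype = "LL"),
                           data.frame(specimen_id = 2, genotype = "LL")),
               "no shared")
})

test_that("exact Fisher test matches the hypergeometric closed form and fisher.test", {
  m <- matrix(c(1, 11, 9, 3), nrow = 2)
  res <- fisher_exact_rxc(m)
  expect_equal(res$method, "exact")
  expect_equal(res$p, fisher_2x2_oracle(m), tolerance = 1e-12)
  expect_equal(res$p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  expect_equal(res$total_prob, 1, tolerance = 1e-9)

  prop <- rbind(c(10, 5, 15), c(20, 10, 30))   # proportional rows
  expect_equal(fisher_exact_rxc(prop)$p, 1, tolerance = 1e-9)

  for (seed in 1:4) {
    m3 <- withr::with_seed(seed, matrix(rpois(12, 2), nrow = 3))
    m3 <- m3 + 1   # avoid degenerate all-zero margins
    res3 <- fisher_exact_rxc(m3)
    expect_equal(res3$p, stats::fisher.test(m3)$p.value, tolerance = 1e-9)
    expect_equal(res3$total_prob, 1, tolerance = 1e-9)
  }
})

test_that("bioassay genotype-by-knockdown association is computed from the fixture", {
  tab <- bioassay_genotype_counts()
  perm <- as.matrix(tab[tab$insecticide == "permethrin",
                        c("LL", "LF", "FF", "SF")])
  res_p <- fisher_exact_rxc(perm)
  expect_equal(res_p$p, stats::fisher.test(perm)$p.value, tolerance = 1e-9)
  expect_equal(round(res_p$p, 3), 0.138)   # published permethrin association

  delta <- as.matrix(tab[tab$insecticide == "deltamethrin",
                         c("LL", "LF", "FF", "SF")])
  res_d <- fisher_exact_rxc(delta)         # all-zero LL column dropped inside
  expect_equal(res_d$p, stats::fisher.test(delta[, colSums(delta) > 0])$p.value,
               tolerance = 1e-9)
  expect_lt(res_d$p, 0.05)                 # significant association

  # knocked-down permethrin mosquitoes: FF share 60%
  kd <- tab[tab$insecticide == "permethrin" & tab$knockdown == "yes", ]
  expect_equal(100 * kd$FF / sum(kd[, c("LL", "LF", "FF", "SF")]), 60)
})

test_that("Monte-Carlo fallback engages beyond the enumeration budget", {
  m <- matrix(c(8, 12, 14, 6, 9, 11), nrow = 2, byrow = TRUE)
  exact <- fisher_exact_rxc(m)
  mc <- fisher_exact_rxc(m, budget = 10, mc_reps = 20000, seed = 4)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p - exact$p), 0.02)
  expect_identical(mc, fisher_exact_rxc(m, budget = 10, mc_reps = 20000,
                                        seed = 4))
})

test_that("knockdown regression reproduces exact and hand-computed lines", {
  t <- 0:10
  exact <- knockdown_regression(data.frame(time_min = t, pct_down = 2 * t + 1))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  three <- knockdown_regression(data.frame(time_min = c(0, 1, 2),
                                           pct_down = c(0, 1, 4)))
  expect_equal(three$slope, 2, tolerance = 1e-12)     # normal equations
  expect_equal(three$intercept, -1 / 3, tolerance = 1e-12)
  expect_error(knockdown_regression(data.frame(time_min = c(5, 5),
                                               pct_down = c(1, 2))),
               "distinct timepoints")
})

test_that("ancova_slopes matches the nested-model oracle", {
  # identical groups: no slope difference
  d0 <- data.frame(time_min = rep(1:6, 2), pct_down = rep(c(1, 3, 4, 6, 9, 11), 2),
                   group = rep(c("a", "b"), each = 6))
  r0 <- ancova_slopes(d0)
  expect_equal(r0$F, 0, tolerance = 1e-9)
  expect_equal(r0$p, 1, tolerance = 1e-9)

  # exactly parallel noiseless lines
  dp <- data.frame(time_min = rep(1:6, 2),
                   pct_down = c(2 * (1:6) + 1, 2 * (1:6) + 8),
                   group = rep(c("a", "b"), each = 6))
  expect_equal(ancova_slopes(dp)$F, 0)

  # constructed noisy data against the anova() nested-model comparison
  d <- withr::with_seed(12, data.frame(
    time_min = rep(seq(15, 120, 15), 4),
    pct_down = c(1.8 * rep(seq(15, 120, 15), 2) + rnorm(16, 0, 5),
                 0.2 * rep(seq(15, 120, 15), 2) + rnorm(16, 0, 5)),
    group = rep(c("a", "b"), each = 16)))
  res <- ancova_slopes(d)
  full <- lm(pct_down ~ time_min * group, data = d)
  reduced <- lm(pct_down ~ time_min + group, data = d)
  oracle <- anova(reduced, full)
  expect_equal(res$F, oracle$F[2], tolerance = 1e-9)
  expect_equal(res$p, oracle$`Pr(>F)`[2], tolerance = 1e-9)
  expect_equal(res$df2, nrow(d) - 4)
})

test_that("resistance ratio and CDC classification follow their definitions", {
  mk <- function(n_down, n_total = 100) data.frame(time_min = 45,
                                                   n_down = n_down,
                                                   n_total = n_total)
  expect_equal(resistance_ratio(mk(30), mk(30)), 1)
  expect_equal(resistance_ratio(mk(90), mk(30)), 3)
  # fully knocked-down reference vs a barely responding strain: 1/p scale
  expect_equal(resistance_ratio(mk(100), mk(2, 110)), 55)
  expect_warning(rr <- resistance_ratio(mk(90), mk(0)), "infinite")
  expect_identical(rr, Inf)

  expect_equal(classify_cdc_resistance(0.15), "resistant_suspected")
  expect_equal(classify_cdc_resistance(1.00), "susceptible")
  expect_equal(classify_cdc_resistance(0.90), "susceptible")  # boundary
  expect_error(classify_cdc_resistance(1.2), "\\[0, 1\\]")
})

test_that("simulated bioassays reproduce the published resistance contrasts", {
  lines <- kdr_bioassay_lines()
  recs <- lapply(seq_len(nrow(lines)), function(i)
    simulate_bioassay(bioassay_spec(lines$strain[i], lines$insecticide[i],
                                    n_bottles = 20, slope = lines$slope[i],
                                    intercept = lines$intercept[i],
                                    seed = 100 + i)))
  names(recs) <- paste(lines$strain, lines$insecticide)
  # susceptible strain: full knockdown by 120 min; resistant: well below 90%
  p120 <- function(r) sum(r$n_down[r$time_min == 120]) /
    sum(r$n_total[r$time_min == 120])
  expect_equal(classify_cdc_resistance(p120(recs[["KNWR permethrin"]])),
               "susceptible")
  expect_equal(classify_cdc_resistance(p120(recs[["Conaway permethrin"]])),
               "resistant_suspected")
  expect_equal(classify_cdc_resistance(p120(recs[["Conaway deltamethrin"]])),
               "resistant_suspected")
  # resistance ratio at 45 min is far above 1 for both insecticides
  rr_perm <- resistance_ratio(recs[["KNWR permethrin"]],
                              recs[["Conaway permethrin"]])
  rr_delt <- resistance_ratio(recs[["KNWR deltamethrin"]],
                              recs[["Conaway deltamethrin"]])
  expect_gt(rr_perm, 10)
  expect_gt(rr_delt, 10)
})
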