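---
title: "Methods: dual-probe RT-qPCR kdr genotyping and resistance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-probe RT-qPCR kdr genotyping and resistance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culexkdr)
```

# The problem

Pyrethroid insecticides kill mosquitoes by holding voltage-gated sodium
channels (*Vgsc*) open; the L1014F substitution in the channel (the
"knockdown resistance", *kdr*, mutation) reduces that effect. Surveillance
programmes genotype field-collected *Culex* mosquitoes at codon 1014 to
track where resistance alleles are spreading. The assay this package models
is an allelic-discrimination RT-qPCR on cDNA: two competing TaqMan probes —
a FAM-labelled probe matching the wild-type leucine codon (TTA) and a
HEX-labelled probe matching the mutant phenylalanine codon (TTT) — run in
one reaction, and which probe amplifies earlier reveals the genotype.

`culexkdr` implements the complete downstream analysis: the delta-CT
genotype statistic and its calling rules, in-silico evaluation of the
oligo set against cDNA templates, allele-frequency and association
statistics, bottle-bioassay metrics, and geographic aggregation — plus a
seeded synthetic-data generator so the whole pipeline is testable without
instrument exports.

# The delta-CT statistic and genotype calling

For each specimen the statistic is

$$\Delta C_T = C_T(\text{TTT probe}) - C_T(\text{TTA probe}),$$

with the final cycle number (40) substituted when a probe never crosses
threshold (`compute_delta_ct()` flags every substitution). Homozygous
wild-type (LL) specimens amplify the TTA probe early and the TTT probe late
or never, so $\Delta C_T$ is large and positive; FF mirrors this; balanced
amplification ($\Delta C_T \approx 0$) indicates a heterozygote. Specimens
whose every observed CT exceeds 30 cycles, or that never amplify, are
excluded by `qc_filter()` before calling.

Two calling methods are provided:

* **Cluster calling** (`kmeans_1d()` + `calls_from_clusters()`): Lloyd's
  3-means on the per-species $\Delta C_T$ values, initialised at the
  $(2i-1)/2k$ quantiles plus seeded random restarts, best
  within-cluster sum of squares kept. Clusters map to genotypes by centre
  order (lowest = FF, middle = LF, highest = LL). In one dimension the
  optimal partition is contiguous in sorted order, and the test suite
  verifies the fitted solution against an exhaustive contiguous-partition
  search for small inputs.
* **Threshold calling** (`calls_from_thresholds()`): the published
  per-species decision bands. For *Cx. pipiens*: $\Delta C_T > 5.0$ is LL,
  $-2.0 \le \Delta C_T \le 4.9$ is LF, $\Delta C_T < -4.0$ is FF; for
  *Cx. tarsalis*: $> 2.0$, $[-1.0, 1.0]$, and $< -2.0$ respectively. The
  published bands leave gaps (for *Cx. pipiens*, $(-4.0, -2.0)$ and
  $(4.9, 5.0]$); values in a gap are returned as `UNDETERMINED` with an
  `in_band_gap` flag rather than silently snapped to the nearest band,
  mirroring the manual review step of the bench protocol. The extreme
  negative band is interpreted as FF: the sign convention of the statistic
  forces it, and the published cluster centres confirm it.

Two judgement calls deserve a note. First, the published band text labels
both the extreme-negative and the middle band "LF"; we treat that as a
typographical slip and assign the extreme-negative band to FF. Second,
3-means clustering is only meaningful when three genotype clusters are
actually present. A monomorphic population (every *Cx. erythrothorax*
observed was LL) still yields three fitted centres, but they sit within the
noise of a single cluster. `call_genotypes()` therefore rejects a cluster
solution whose adjacent centres are closer than `min_center_gap` (default
1.5 cycles, i.e. roughly two to three within-cluster standard deviations)
and falls back to the species' threshold bands. *Cx. erythrothorax* ships
with the *Cx. tarsalis* bands for this purpose: its amplicon is identical
across the assay region and its $\Delta C_T$ values resemble the tarsalis
LL cluster.

# In-silico assay evaluation

`find_binding_site()` scans both strands of a cDNA template for windows
within a Hamming tolerance of an oligo (ambiguous template bases count as
mismatches — the conservative reading). `in_silico_pcr()` pairs a
plus-strand forward site with a downstream minus-strand reverse site (or
the mirrored orientation), returns the shortest product when several are
possible, and reports "no amplification", forward-only and reverse-only
binding as explicit outcomes rather than errors. `percent_identity()` uses
a global alignment with match $+1$, mismatch $0$ and a linear gap penalty
of $1$ per position — the gap penalty exists only to anchor the alignment,
so equal-length inputs align gap-free and identity is 100 exactly when the
strings are equal. `genotype_from_sequence()` locates the 1014 codon via
its conserved 5' flank and interprets IUPAC codes: third-position A is the
leucine allele, T the phenylalanine allele, W a heterozygote, and a
serine-bearing codon is reported as the SF class.

The sequencing forward primer is paired with the assay *reverse* primer to
produce the 373-bp sequencing product. The protocol text names the second
forward primer as the partner, but two forward-orientation oligos cannot
prime a product; we treat that as a typo and log it as an open question.

Because GenBank downloads are deliberately outside the test path, the
package ships synthetic cDNA templates (`synthetic_vgsc_template()`, and a
FASTA fixture whose records are named `SYNTH_*`) that embed the real
published oligo sequences in fixed random spacers with the real product
geometry: a 373-bp product, a variant identical across the amplicon but
divergent outside it, and a divergent variant carrying ~4% substitutions
including exactly two under the probe footprint. These reproduce the
*structure* of the published cross-species comparison; `assay_eval()`
accepts any user-supplied FASTA of real accessions for the genuine article.

# Resistance statistics

**Allele frequency.** `allele_frequency()` computes
$F_{(FF,LF)} = (2 N_{FF} + N_{LF}) / 2N$ by exact integer arithmetic,
rounding only for display. The standard error is binomial on the $2N$
allele draws, $\sqrt{F(1-F)/2N}$ — the source material never states its SE
formula, and this convention matches the magnitudes it prints.

**Proportional-odds regression.** `fit_proportional_odds()` fits
$\mathrm{logit}\, P(Y \le j) = \alpha_j - x^\top\beta$ for the ordered
outcome LL < LF < FF, so $e^{\beta} > 1$ means greater odds of the
resistant genotypes. The fit is an own Newton-type maximiser of the grouped
multinomial likelihood: the score is analytic, and the observed information
is obtained by central finite differences of that score (adequate to ~1e-7
for the handful of parameters involved, and verified against an
independent reference implementation in the tests). Step halving preserves
ascent and the ordering of the cutpoints; convergence requires the largest
score component below $10^{-8}$ or a relative log-likelihood change below
$10^{-10}$. Separation is reported via `converged = FALSE` (or an exploding
interval), never silently. Confidence intervals are Wald,
$\exp(\beta \pm 1.96\,\mathrm{SE})$, and p-values compare $\beta/SE$ to a
standard normal, matching the source analysis; no profile likelihood and no
multiple-testing correction are applied, again matching it. Reference
levels are *Cx. tarsalis*, bayside and wildlife.

The single-covariate region and land-use fits exclude the monomorphic
species by subtracting its 126 all-LL bayside wildlife specimens from the
printed marginals, because the published models were fit only to
*Cx. pipiens* and *Cx. tarsalis* data even though the printed region and
land-use margins include all species.

**Fisher's exact test.** `fisher_exact_rxc()` enumerates every table with
the observed margins (recursively, with feasibility bounds), computes each
table's conditional probability from log-factorials, and sums the
probabilities of tables no more probable than the observed one — with a
relative slack of $1+10^{-7}$ for floating-point ties, the same rule the
classical implementations use, so the dual-route test against an
independent implementation compares like with like. The enumerated
probabilities must total 1 (a test asserts this to $10^{-9}$). Beyond a
configurable table budget the function switches to a seeded Monte-Carlo
estimate over Patefield-sampled tables and says so in its return value.

**Bioassay metrics.** `knockdown_regression()` is ordinary least squares of
cumulative knockdown percent on time; `ancova_slopes()` tests slope
equality between two strains by the extra-sum-of-squares F statistic
$F = (SSE_{common} - SSE_{separate})/(SSE_{separate}/(n-4))$;
`resistance_ratio()` is the susceptible strain's pooled knockdown
proportion over the test strain's at 45 minutes (resistant strain in the
denominator, so large is resistant); `classify_cdc_resistance()` applies
the 90%-at-120-minutes rule, with exactly 90% classed susceptible.

# The synthetic-data generator

The generator exists so every downstream stage can be tested end to end
with data whose truth is known. What it emulates, and the values chosen:

* **Delta-CT structure** (`noise_model()`): per-species Gaussian clusters
  at the published 3-means centres (−13.212, −0.871, 12.691 cycles for
  *Cx. pipiens*; −2.944, −0.089, 3.107 for *Cx. tarsalis*). The
  within-cluster spread is not published; defaults of 0.8 cycles
  (*Cx. pipiens*) and 0.5 (*Cx. tarsalis*) were chosen once from the
  magnitude of the published ANOVA F statistics (an F near 23,600 on 264
  specimens with those centres implies a within-group mean square well
  below 1). A matched probe amplifies near `base_ct` (default 25 cycles,
  with a specimen-level spread that cancels out of delta-CT); a
  homozygote's off-allele probe amplifies $|centre|$ cycles later, is
  censored at cycle 40, or drops out entirely with probability
  `dropout_prob` (default 0.05 for the widely separated *Cx. pipiens*
  probes, 0 for *Cx. tarsalis*, whose probes cross-react). Both probes fail
  with probability 0.04, the published assay-failure rate. SF specimens are
  drawn from the LF distribution because the two probes cannot see the
  serine allele.
* **Cohorts** (`cohort_spec()`, `default_cohort_spec()`): stratum sizes
  reproduce the published per-species totals (126 / 507 / 744), regional
  splits are solved from the published per-region allele frequencies
  (0.375/0.749 for *Cx. pipiens* bayside/inland; 0.084/0.230 for
  *Cx. tarsalis*), and genotypes within a stratum follow Hardy-Weinberg
  proportions at the stratum frequency. Hardy-Weinberg is a modelling
  choice — the real survey's genotype mix need not be in equilibrium — so
  tests compare allele frequencies, which the choice preserves, not
  genotype counts.
* **Bioassays** (`simulate_bioassay()`): each mosquito's knockdown time is
  drawn by inverting the clamped published knockdown-versus-time lines
  (e.g. 1.818 %/min − 1.553 for the susceptible strain under permethrin),
  binned to the 15-minute observation grid; cumulative counts are monotone
  by construction and their expectation equals the clamped line.
* **Reference genotypes** (`simulate_reference_calls()`): Sanger-style
  truth (SF visible) with a uniform error fraction.

What it does **not** emulate: amplification-efficiency kinetics, plate
spatial effects, probe competition, species misidentification, or
departure from Hardy-Weinberg within strata. Passing tests therefore
demonstrate the statistical machinery is correct under the stated
generative model, not that the assay performs on any particular bench.

# Geographic aggregation

`merge_sites()` combines trap sites within 1 km by single linkage:
haversine distances on a sphere of radius 6371.0088 km, sites joined at
$\le$ radius, connected components as clusters. The source protocol says
only "within 1 km of each other"; single linkage is the maximal
(transitive) reading and is an explicit choice here, not inferred intent.
Cluster names are the lexicographically smallest member id, making the
output invariant to input order.

# Numerical choices and degenerate inputs

* k-means ties (a value equidistant from two centres) go to the
  lower-indexed cluster and are flagged; an emptied cluster is re-seeded at
  the worst-fitted point; hitting the 10-iteration cap without assignment
  stability warns rather than failing.
* The proportional-odds information matrix uses finite differences of the
  analytic score with step $\max(10^{-6}, 10^{-6}|\theta|)$.
* Exact-zero residual sums of squares in the ANCOVA are detected with a
  relative tolerance of $10^{-18}$ so that noiseless parallel lines give
  exactly $F = 0$ instead of a 0/0.
* CT values parse from CSV with empty cells meaning "no CT", never zero;
  duplicate specimen ids and out-of-range values are hard errors naming
  the offender.
* A zero test-strain knockdown proportion makes the resistance ratio
  infinite, with a warning, rather than an error.

# Problem sizes used in the tests

The shipped tests simulate at the scales the method was characterised at:
264 and 360 delta-CT values for the per-species cluster recovery checks,
~1,400 specimens for the end-to-end survey pipeline, 500 replicates for
the Wald-interval coverage check, and n ≤ 20 for the exhaustive
contiguous-partition cross-check of the clusterer. These sizes make the
whole suite run in about a minute on a single core while keeping the
binomial error bars tight enough for 3-standard-error assertions.

# Known limitations

* The assay (and hence the simulator and caller) cannot distinguish SF
  from LF heterozygotes; only sequencing-style reference calls can.
* Threshold calling inherits the published bands verbatim, including their
  gaps and their asymmetry; the probe-swap symmetry that holds for cluster
  calling holds for thresholds only with symmetric bands.
* Adjusted (multi-covariate) odds ratios require the per-specimen
  cross-classification of species, region and land use, which was never
  published; the model machinery accepts multiple covariates, but the
  package makes no claim to reproduce the published adjusted estimates.
* The published unadjusted region odds ratio could not be reproduced from
  the printed marginal counts (the fit gives 3.69 with either this
  package's MLE or the standard reference implementation); the package
  reports what the stated inputs yield.

```{r example}
# a compact end-to-end run
res <- pipeline_run(run_config(seed = 1))
subset(res$allele_frequencies, stratum_type == "species")
res$models$species$odds_ratios
```
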