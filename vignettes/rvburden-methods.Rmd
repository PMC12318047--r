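---
title: "Methods: stratified rare-variant burden meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified rare-variant burden meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The model

`rvburden` tests, per gene and per collapsing class, whether cases carry
more ultra-rare qualifying variants than controls, across samples grouped
into ancestry × platform strata, and augments the case-control evidence
with de novo mutation counts from trios.

**Variant classes.** Collapsing classes are total functions over
(consequence, MPC): `PTV_only`; `PTV_plus_MPCgt3` (PTV or missense with
MPC > 3); `PTV_plus_MPCgt2`; `MPCgt2_only`; `synonymous` (negative
control); `MPC_2_3`. MPC thresholds are strict — a missense variant at
exactly MPC 2.0 or 3.0 falls *below* the `> 2` / `> 3` cut. Missense
records must carry an MPC score; classes containing missense variants are
only defined over genes annotated as having at least one possible missense
variant above the cut.

**Rarity.** A variant qualifies when its minor allele count is at most the
cap (default 5) both in the analysed cohort — all strata pooled — and in
the external reference panel. A *singleton* has cohort MAC 1 and reference
count 0; the reference cap of the rarity filter and the absence rule of the
singleton definition are independent parameters. Multi-allelic sites are
represented as one record per alternate allele, because MAC and consequence
are allele-level properties.

**Stratified burden test.** For gene g and class c, each stratum
contributes a 2×2 table of carrier counts (an individual counts once per
gene × class however many qualifying variants they carry; in the ultra-rare
regime carrier and allele counting coincide almost surely, and carrier
counting keeps table rows independent individuals). The test statistic is
the Cochran–Mantel–Haenszel chi-square with 1 df,

$$X^2 = \frac{\big(\,\lvert \sum_k a_k - \sum_k E[a_k]\rvert - \tfrac12\big)^2}
             {\sum_k \mathrm{Var}(a_k)},$$

with hypergeometric moments $E[a_k] = n_{1k} m_{1k}/n_k$ and
$\mathrm{Var}(a_k) = n_{1k} n_{0k} m_{1k} m_{0k}/(n_k^2 (n_k - 1))$. The ½
subtraction is the standard continuity correction, applied inside the
squared numerator and floored at zero; the two-sided p-value is the upper
chi-square tail, making the test direction-agnostic. The common odds ratio
is Mantel–Haenszel, $\hat{OR} = \sum_k (a_k d_k/n_k) / \sum_k (b_k
c_k/n_k)$, with a 95% CI from the Robins–Breslow–Greenland variance of
$\log \hat{OR}$ (the CI method is a package choice; Wald on the RBG scale
is the field default). Strata with a zero margin on either axis carry no
information and are skipped rather than pseudo-counted — pseudo-counts
would bias $\hat{OR}$. For X non-PAR genes, configured strata are split
into male and female tables; males are counted by genotype presence, not
doubled hemizygous dosage.

**Inclusion rules.** To limit type-I error from variants confined to one
small stratum, a gene × class test runs only when carriers appear in at
least two strata or in the designated largest stratum. Genes associated
with age-related clonal haematopoiesis (TET2, DNMT3A, ASXL1) are excluded.
Excluded tests still count toward the multiplicity total — the decision not
to look is still a test.

**De novo evidence and meta-analysis.** Per-gene de novo enrichment across
all trios is the exact one-sided Poisson tail $P(X \ge \mathrm{obs} \mid
\lambda)$; this closed form reproduces the published worked value
$P(X \ge 3 \mid 0.069) = 5.2\times10^{-5}$ exactly. When the case-control
p-value passes the gate (default $p < 0.01$) and a de novo record exists,
the meta p is Fisher's combination, the upper $\chi^2_4$ tail of
$-2(\ln p_{cc} + \ln p_{dn})$. Because combining with an uninformative
$p_{dn} = 1$ still pays the 4-df penalty ($\mathrm{fisher}(p, 1) > p$), the
reported final statistic is $\min(p_{cc}, p_{meta})$, with ties reported as
case-control for provenance. Both the case-control scan and the
meta-analysed genes enter the multiplicity ledger; the exome-wide threshold
is $\alpha / n_{total}$. With the published per-class gene counts
(18,318 + 2,034 + 4,991 + 4,991 case-control tests, 340 meta tests) this
yields 30,674 tests and a threshold of $1.63\times10^{-6}$.

**De novo class matching.** Gene annotations carry expected de novo rates
for two atomic classes only — PTV and missense MPC > 2 (this mirrors the
granularity of published trio rate tables). Test classes map onto them as:
`PTV_only` → PTV; `MPCgt2_only`, `MPC_2_3` → missense; both `PTV_plus_*`
classes → PTV + missense summed. For `PTV_plus_MPCgt3` the missense rate is
therefore the MPC > 2 rate, a deliberate mild overcount (MPC > 3 variants
are a subset); with expected rates of a few hundredths this changes the
Poisson tail negligibly and only for gated genes. An expectation of exactly
0 with a positive observed count has no defined rate ratio: the gene is
reported with the gate closed rather than given an artificial p-value.

**FDR.** Q-values are Benjamini–Hochberg step-up with an explicit
denominator. The default denominator is the *full* ledger total rather than
the number of p-values supplied — the conservative reading when q-values
are interpreted within the whole testing frame; `fdr_denominator =
"meta_genes"` gives textbook BH over the listed genes. The source analysis
does not state its denominator, so the choice is exposed and recorded.

**Locus-restricted correction.** For genes inside a CNV critical region,
`subset_bonferroni()` multiplies the final p by the number of gene tests at
that locus (capped at 1), reproducing the published single-gene-locus
example (p = 0.00029, n = 3 → 0.00087).

**Gene-set enrichment.** Case status is regressed on the per-sample count
of qualifying variants in a set, with intercept, the first PCs, sex (0/1)
and the exome-wide rare-variant burden as covariates. The likelihood is
penalized by the Jeffreys prior, $\ell(\beta) + \tfrac12 \log \det
I(\beta)$, which keeps estimates finite under the complete or
quasi-complete separation that sparse burdens routinely produce. Newton
iterations with step-halving (up to 10 halvings) stop at relative
penalized-likelihood change ≤ 1e−8 or score max-norm ≤ 1e−6, max 50
iterations. The burden p-value is the penalized likelihood-ratio test with
the tested coefficient *constrained to zero under the full-model penalty* —
fitting a reduced design with a smaller information matrix instead is a
tempting shortcut that we measured to inflate type-I error several-fold, so
the constrained construction is load-bearing. Wald p-values are available
as an option. The 95% CI is Wald on the log-odds scale, exponentiated;
profile-likelihood CIs are deliberately not implemented. Covariates are
used unstandardized (the penalized LRT is invariant to affine rescaling).

## The synthetic world

The generator exists because the genotype data this analysis was designed
for are controlled-access; it reproduces the *statistical structure* the
method assumes, so that calibration and power claims are testable offline.

Per stratum, each individual carries a qualifying variant of each atomic
class (`PTV`, `missense_gt3`, `missense_2_3`, `synonymous`) in each gene as
an independent Bernoulli event: controls at `baseline_carrier_rate`, cases
at the probability whose odds are the planted odds ratio times the baseline
odds (1 unless the gene × class is planted). One carrier event becomes one
variant record with cohort MAC 1; reference-panel MACs are categorical —
90% in 0..5 with 0 most likely, 10% in 6..10 so the rarity filter does real
work — independent of phenotype, so filtering attenuates power slightly but
cannot bias the odds ratio. MPC scores are drawn uniform within the
simulated bin. PCs are standard normal with zero true effect; sex is
Bernoulli(½); the exome-wide burden covariate is counted from the emitted
records (a confounding mode adds a stratum-correlated shift to exercise
covariate adjustment). De novo counts are Poisson(λ × enrichment) per gene
and atomic class, with λ stored as the expectation.

Default parameters, chosen once as a realistic stated world and not
revisited: three unequal strata of (2000, 2000), (1500, 2000), (1000, 1500)
cases/controls; `baseline_carrier_rate` 0.01 (per-gene per-class carrier
fractions of ~1% match ultra-rare qualifying-variant carrier counts at
cohort scale); constrained fraction 0.17 (≈ 3,051 constrained of ~18,000
tested genes); possible-variant flag rates 0.11 (MPC > 3, nested) and 0.27
(MPC > 2), mirroring the published per-class gene counts relative to all
genes; per-gene per-class de novo λ 0.05 across 3,444 trios, the magnitude
of published per-gene expectations (e.g. 0.069); 10 PCs.

What a green test does **not** establish: the generator has no
depth-of-coverage differences between cases and controls (the real analogue
produced a synonymous-singleton imbalance), no relatedness, no within-
stratum structure, no genotyping error, and carrier events are independent
across genes. Null calibration and power results transfer to real data only
to the extent those artefacts are handled upstream.

## Numerical choices and scale effects

- The CMH statistic for a single stratum equals the classical Pearson score
  chi-square times $(n-1)/n$ — the exact finite-sample identity; tests
  assert it exhaustively over all 2×2 tables with margins ≤ 12.
- The continuity correction is conservative on every input
  ($p_{corrected} \ge p_{uncorrected}$) and its effect scales like
  $\tfrac12 / \mathrm{sd}(\sum a_k)$. At small per-gene carrier counts this
  visibly depresses the null p-value distribution; uniformity (KS at
  α = 0.01) is asserted at a cohort scale — 3 strata of 5,000/15,000,
  carrier rate 0.015, i.e. several hundred carriers per gene — comparable
  in spirit to the ~132,000-sample cohort the method was built for, where
  the correction is second-order.
- Degenerate directions are flagged, not errored: all carriers in cases
  gives $\hat{OR} = \infty$ with a finite p; no informative stratum gives
  an untestable result distinct from an error.
- BH q-values enforce step-up monotonicity by cumulative minima from the
  largest rank; q-values are capped at 1.
- Seeds: every simulation entry point takes one integer seed; sub-streams
  (panel, case-control arm, trios) use fixed offsets so a study is
  reproducible byte-for-byte.

## Design decisions that were genuinely open

- **Carrier vs allele counting** in the 2×2 tables: carrier counting is the
  default (independence of rows); the config records the mode.
- **CI method** for the MH odds ratio: RBG Wald; the source does not state
  its method.
- **BH denominator**: full ledger total by default (see above).
- **Firth p-values**: penalized LRT over Wald, standard practice under
  sparse counts.
- **Per-allele representation** of multi-nucleotide/compound events: how
  such events were collapsed before MAC counting is not stated anywhere we
  could follow; per-allele is the cleanest convention and is declared in
  the interchange format.

## Worked check

```{r worked}
poisson_denovo_test(3, 0.069)
fisher_combine(2.2e-3, poisson_denovo_test(3, 0.069))
build_ledger(30334, 340)
```
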