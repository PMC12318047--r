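#' @title De novo enrichment, Fisher meta-analysis and multiplicity control
#' @name denovo_meta
#' @description
#' Gene-based de novo coding-variant enrichment is the exact one-sided
#' Poisson tail against a per-gene mutation-rate expectation. Genes whose
#' case-control burden p-value passes a gate (default 0.01) are meta-analysed
#' with the de novo p-value by Fisher's combined probability test
#' (chi-square, 4 df). The final per-gene statistic is the minimum of the
#' case-control-only and meta p-values; both tests enter the multiplicity
#' ledger, giving the exome-wide Bonferroni threshold, and q-values come from
#' Benjamini-Hochberg with a configurable denominator.
NULL

#' One-sided Poisson enrichment test for de novo counts
#'
#' `p = P(X >= observed)` for `X ~ Poisson(expected)`. With `observed = 0`
#' the p-value is 1. An expectation of exactly 0 with a positive observed
#' count has no defined rate ratio and returns NA (callers treat the meta
#' gate as closed).
#'
#' @param observed non-negative integer count across all trios.
#' @param expected expected count lambda (>= 0).
#' @return p-value in (0, 1], or NA when `expected == 0 && observed > 0`.
#' @export
poisson_denovo_test <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0))
    stop("observed and expected de novo counts must be non-negative")
  if (any(observed != floor(observed))) stop("observed must be integer")
  p <- stats::ppois(observed - 1, expected, lower.tail = FALSE)
  p[expected == 0 & observed > 0] <- NA_real_
  p[observed == 0] <- 1
  p
}

#' Fisher's combined probability test for two p-values
#'
#' Upper tail of chi-square(4 df) at `-2 (ln p1 + ln p2)`. Combining with
#' p = 1 still pays the 4-df penalty, so `fisher_combine(p, 1) > p` for
#' p < 1; the minimum-P reporting rule exists for exactly this reason.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p1, p2) {
  if (any(!is.finite(c(p1, p2))) || any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    stop("p-values must lie in (0, 1]")
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Gated meta-analysis and minimum-P final statistic for one gene
#'
#' When the case-control p-value passes the gate (default `< 0.01`) and a de
#' novo record is available, the meta p is the Fisher combination of the
#' case-control p with the Poisson de novo p, and the final p is the minimum
#' of the two; otherwise the meta p is absent and the final p is the
#' case-control p. Ties go to the case-control test for provenance.
#'
#' @param p_cc case-control p-value in (0, 1].
#' @param observed,expected de novo count and expectation, or NULL for a gene
#'   without a de novo record.
#' @param gate meta-analysis gate on `p_cc` (default 0.01).
#' @return List: `p_denovo` (NA if not computed), `p_meta` (NA if the gate is
#'   closed), `p_final`, `provenance` (`"case_control"` or `"meta"`).
#' @export
final_gene_p <- function(p_cc, observed = NULL, expected = NULL, gate = 0.01) {
  if (!is.finite(p_cc) || p_cc <= 0 || p_cc > 1)
    stop("p_cc must lie in (0, 1]")
  out <- list(p_denovo = NA_real_, p_meta = NA_real_, p_final = p_cc,
              provenance = "case_control")
  if (p_cc < gate && !is.null(observed) && !is.null(expected)) {
    p_dn <- poisson_denovo_test(observed, expected)
    out$p_denovo <- p_dn
    if (is.finite(p_dn)) {  # lambda = 0 with observed > 0 keeps gate closed
      out$p_meta <- fisher_combine(p_cc, p_dn)
      if (out$p_meta < p_cc) {
        out$p_final <- out$p_meta
        out$provenance <- "meta"
      }
    }
  }
  out
}

#' Multiplicity ledger and exome-wide Bonferroni threshold
#'
#' Every counted case-control test plus every meta-analysed gene is one test;
#' the exome-wide significance threshold is `alpha / n_total`.
#'
#' @param n_cc_tests counted case-control tests.
#' @param n_meta_tests meta-analysed genes.
#' @param alpha family-wise error rate (default 0.05).
#' @return List of class `multiplicity_ledger`: `n_cc_tests`, `n_meta_tests`,
#'   `n_total`, `alpha`, `bonferroni_threshold`.
#' @export
build_ledger <- function(n_cc_tests, n_meta_tests, alpha = 0.05) {
  if (n_cc_tests < 0 || n_meta_tests < 0) stop("test counts must be >= 0")
  n_total <- n_cc_tests + n_meta_tests
  if (n_total == 0) stop("configuration error: total test count is zero")
  out <- list(n_cc_tests = as.integer(n_cc_tests),
              n_meta_tests = as.integer(n_meta_tests),
              n_total = as.integer(n_total), alpha = alpha,
              bonferroni_threshold = alpha / n_total)
  class(out) <- "multiplicity_ledger"
  out
}

#' @export
print.multiplicity_ledger <- function(x, ...) {
  cat(sprintf(
    "%d case-control + %d meta tests = %d total; Bonferroni P < %.3g (alpha = %g)\n",
    x$n_cc_tests, x$n_meta_tests, x$n_total, x$bonferroni_threshold, x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg q-values with an explicit denominator
#'
#' Step-up BH where the denominator `m` is the total number of tests in the
#' frame (which may exceed the number of p-values supplied, e.g. when
#' q-values are reported only for meta-analysed genes but the full scan
#' counted more tests). With `m = length(p)` this is textbook BH.
#'
#' @param p_finals p-values in (0, 1].
#' @param m denominator, `>= length(p_finals)`.
#' @return q-values in the input order, capped at 1.
#' @export
fdr_qvalues <- function(p_finals, m = length(p_finals)) {
  k <- length(p_finals)
  if (!k) return(numeric(0))
  if (m < k) stop("configuration error: BH denominator m < number of p-values")
  if (any(!is.finite(p_finals)) || any(p_finals <= 0) || any(p_finals > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(p_finals)
  q <- p_finals[o] * m / seq_len(k)
  q <- rev(cummin(rev(q)))       # enforce step-up monotonicity
  q <- pmin(q, 1)
  out <- numeric(k)
  out[o] <- q
  out
}

#' Locus-restricted Bonferroni correction
#'
#' For genes inside a CNV critical region, the p-value is corrected for the
#' number of gene tests at that locus only: `p_corrected = min(1, p * n)`.
#'
#' @param p_finals named numeric vector, gene -> final p.
#' @param locus_genes character vector of genes in the locus; all must be
#'   present in `p_finals`.
#' @return Named vector of corrected p-values over `locus_genes`.
#' @export
subset_bonferroni <- function(p_finals, locus_genes) {
  if (!length(locus_genes)) stop("locus_genes must be non-empty")
  unknown <- setdiff(locus_genes, names(p_finals))
  if (length(unknown))
    stop("gene(s) not present in results: ", paste(unknown, collapse = ", "))
  stats::setNames(pmin(1, p_finals[locus_genes] * length(locus_genes)),
                  locus_genes)
}

# de novo atomic classes matched to each test class
denovo_classes_for <- function(class) {
  switch(class,
    PTV_only        = "PTV",
    PTV_plus_MPCgt3 = , PTV_plus_MPCgt2 = c("PTV", "missense_gt2"),
    MPCgt2_only     = , MPC_2_3 = "missense_gt2",
    character(0))
}

#' Attach de novo meta-analysis, Bonferroni and FDR flags to a burden scan
#'
#' For every testable (gene, class) row with `p_cc` below the gate, looks up
#' the matching de novo record (summing atomic PTV / missense MPC>2 counts
#' and expectations as required by the class), computes the Poisson de novo
#' p, the Fisher meta p and the minimum-P final statistic, then builds the
#' multiplicity ledger and flags exome-wide (Bonferroni) and FDR < 5%
#' significance.
#'
#' @param scan result of [run_burden_scan()].
#' @param denovo `data.table` with `gene_id`, `variant_class`
#'   (`PTV` | `missense_gt2`), `observed`, `expected`; or NULL for no trios.
#' @param gate meta gate on `p_cc` (default 0.01).
#' @param alpha family-wise / FDR level (default 0.05).
#' @param fdr_denominator `"ledger_total"` (BH over the full test count,
#'   default) or `"meta_genes"` (BH over the tested p-values only).
#' @return List: `results` (scan plus `dn_observed`, `dn_expected`,
#'   `p_denovo`, `p_meta`, `p_final`, `provenance`, `q_value`,
#'   `exome_wide_significant`, `fdr5_significant`) and `ledger`.
#' @export
run_meta <- function(scan, denovo = NULL, gate = 0.01, alpha = 0.05,
                     fdr_denominator = c("ledger_total", "meta_genes")) {
  fdr_denominator <- match.arg(fdr_denominator)
  res <- data.table::copy(data.table::as.data.table(scan))
  n <- nrow(res)
  res$dn_observed <- NA_integer_; res$dn_expected <- NA_real_
  res$p_denovo <- NA_real_; res$p_meta <- NA_real_
  res$p_final <- res$p_cc
  res$provenance <- ifelse(is.na(res$p_cc), NA_character_, "case_control")
  n_meta <- 0L
  for (i in seq_len(n)) {
    p_cc <- res$p_cc[i]
    if (is.na(p_cc) || p_cc >= gate || is.null(denovo)) next
    cls <- denovo_classes_for(res$variant_class[i])
    dn <- denovo[denovo$gene_id == res$gene_id[i] &
                 denovo$variant_class %in% cls, , drop = FALSE]
    if (!nrow(dn)) next
    obs <- sum(dn$observed); exp <- sum(dn$expected)
    f <- final_gene_p(p_cc, obs, exp, gate = gate)
    res$dn_observed[i] <- as.integer(obs); res$dn_expected[i] <- exp
    res$p_denovo[i] <- f$p_denovo; res$p_meta[i] <- f$p_meta
    res$p_final[i] <- f$p_final; res$provenance[i] <- f$provenance
    if (is.finite(f$p_meta)) n_meta <- n_meta + 1L
  }
  ledger <- build_ledger(n_cc_tests = sum(res$counted),
                         n_meta_tests = n_meta, alpha = alpha)
  tested <- which(is.finite(res$p_final))
  res$q_value <- NA_real_
  if (length(tested)) {
    m <- if (fdr_denominator == "ledger_total") ledger$n_total else length(tested)
    res$q_value[tested] <- fdr_qvalues(res$p_final[tested], m = m)
  }
  res$exome_wide_significant <- is.finite(res$p_final) &
    res$p_final < ledger$bonferroni_threshold
  res$fdr5_significant <- is.finite(res$q_value) & res$q_value < 0.05
  list(results = res[], ledger = ledger)
}
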