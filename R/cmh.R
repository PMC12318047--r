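#' @title Stratified Cochran-Mantel-Haenszel burden testing
#' @name burden_cmh
#' @description
#' Per-gene carrier burden is tested across ancestry x platform strata with
#' the Cochran-Mantel-Haenszel chi-square (1 df, optional continuity
#' correction), the Mantel-Haenszel common odds ratio, and a 95% confidence
#' interval from the Robins-Breslow-Greenland variance of its logarithm.
#' Individuals are counted as carriers (>= 1 qualifying variant in the gene,
#' counted once) rather than by allele; in the ultra-rare regime the two
#' conventions coincide almost everywhere and carrier counting keeps rows of
#' the 2x2 tables independent individuals.
NULL

#' Build per-stratum 2x2 carrier tables for one gene and class
#'
#' A sample is a carrier if it carries at least one qualifying variant of the
#' class in the gene. One table is produced per stratum; for X (non-PAR)
#' genes each stratum listed in `sex_split_strata` contributes two tables
#' (male and female) instead, since carrier rates differ by sex there.
#'
#' @param gene gene id.
#' @param class test class, one of [variant_classes()].
#' @param variants variant table, already restricted by the rarity filter.
#' @param samples sample table (`sample_id`, `phenotype`, `stratum`, `sex`).
#' @param sex_split_strata strata to split by sex for X non-PAR genes.
#' @param x_gene is the gene X non-PAR? (default: inferred from the records'
#'   `chrom_category`, FALSE when the gene has no records).
#' @return `data.table` with columns `stratum`, `sex` (NA unless split),
#'   `a` (case carriers), `b` (case non-carriers), `c` (control carriers),
#'   `d` (control non-carriers).
#' @export
build_tables <- function(gene, class, variants, samples,
                         sex_split_strata = character(), x_gene = NULL) {
  v <- variants[variants$gene_id == gene, , drop = FALSE]
  keep <- if (nrow(v)) class_membership(v, class) else logical(0)
  v <- v[keep, , drop = FALSE]
  if (is.null(x_gene))
    x_gene <- nrow(v) > 0 && any(v$chrom_category == "X_nonPAR")
  carriers <- unique(expand_carriers(v)$sample_id)
  unknown <- setdiff(carriers, samples$sample_id)
  if (length(unknown))
    stop("carrier id(s) with no sample record: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  s <- data.table::as.data.table(samples)
  s$carrier <- s$sample_id %in% carriers
  split_sex <- x_gene & s$stratum %in% sex_split_strata
  s$cell_sex <- ifelse(split_sex, s$sex, NA_character_)
  carrier <- phenotype <- NULL  # NSE columns, silence R CMD check
  agg <- s[, list(
    a = sum(carrier & phenotype == "case"),
    b = sum(!carrier & phenotype == "case"),
    c = sum(carrier & phenotype == "control"),
    d = sum(!carrier & phenotype == "control")),
    by = c("stratum", "cell_sex")]
  data.table::setnames(agg, "cell_sex", "sex")
  data.table::setorderv(agg, c("stratum", "sex"))
  agg[]
}

#' Gene-level test inclusion rule
#'
#' A gene x class test is run only when: the gene is not excluded as a
#' clonal-haematopoiesis gene; for missense-containing classes the gene has
#' at least one possible missense variant above the class's MPC cut; and
#' carriers are observed in at least two strata or in the designated largest
#' stratum. Excluded tests still count toward the multiplicity total.
#'
#' @param gene gene id.
#' @param class test class.
#' @param tables from [build_tables()] (all strata present, even empty ones).
#' @param annotation one-row gene annotation (see [simulate_gene_panel()]).
#' @param largest_stratum label of the largest (reference) stratum.
#' @return Logical scalar.
#' @export
gene_is_testable <- function(gene, class, tables, annotation,
                             largest_stratum) {
  if (!largest_stratum %in% tables$stratum)
    stop("largest_stratum '", largest_stratum,
         "' is not among the table strata")
  if (isTRUE(annotation$excluded_clonal_haem)) return(FALSE)
  if (class %in% c("PTV_plus_MPCgt3") && !isTRUE(annotation$has_possible_mpc_gt3))
    return(FALSE)
  if (class %in% c("PTV_plus_MPCgt2", "MPCgt2_only", "MPC_2_3") &&
      !isTRUE(annotation$has_possible_mpc_gt2))
    return(FALSE)
  carriers <- tables$a + tables$c
  strata_with <- unique(tables$stratum[carriers > 0])
  length(strata_with) >= 2L ||
    any(carriers[tables$stratum == largest_stratum] > 0)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' The statistic is `(|sum a_k - sum E a_k| - 1/2 [continuity])^2 / sum V_k`
#' with the hypergeometric mean `E a_k = n1k m1k / nk` and variance
#' `V_k = n1k n0k m1k m0k / (nk^2 (nk - 1))` per stratum; the two-sided
#' p-value is the chi-square(1 df) upper tail, so the test is
#' direction-agnostic. The Mantel-Haenszel common odds ratio is
#' `sum(a_k d_k / n_k) / sum(b_k c_k / n_k)` and its 95% CI uses the
#' Robins-Breslow-Greenland variance of the log odds ratio. Strata with a
#' zero margin on either axis carry no information and are skipped (excluded
#' from `n_informative_strata`).
#'
#' @param tables `data.table`/`data.frame` with columns `a`, `b`, `c`, `d`.
#' @param continuity apply the 1/2 continuity correction (default TRUE).
#' @return Object of class `cmh_result`: `statistic`, `p_two_sided`, `or_mh`
#'   (possibly `Inf` or 0 in degenerate directions), `ci95` (lower, upper),
#'   `n_informative_strata`, and `testable` (FALSE when no stratum is
#'   informative, in which case p is NA).
#' @export
cmh_test <- function(tables, continuity = TRUE) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  if (any(c(a, b, cc, d) < 0)) stop("negative cell count")
  n1 <- a + b; n0 <- cc + d          # case / control totals
  m1 <- a + cc; m0 <- b + d          # carrier / non-carrier totals
  n <- n1 + n0
  info <- n1 > 0 & n0 > 0 & m1 > 0 & m0 > 0
  res <- list(statistic = NA_real_, p_two_sided = NA_real_,
              or_mh = NA_real_, ci95 = c(NA_real_, NA_real_),
              n_informative_strata = sum(info), testable = any(info))
  class(res) <- "cmh_result"
  if (!any(info)) return(res)
  a <- a[info]; b <- b[info]; cc <- cc[info]; d <- d[info]
  n1 <- n1[info]; n0 <- n0[info]; m1 <- m1[info]; m0 <- m0[info]; n <- n[info]

  e <- n1 * m1 / n
  v <- n1 * n0 * m1 * m0 / (n^2 * (n - 1))
  dev <- abs(sum(a) - sum(e))
  if (continuity) dev <- max(0, dev - 0.5)
  stat <- if (sum(v) > 0) dev^2 / sum(v) else 0
  res$statistic <- stat
  res$p_two_sided <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  num <- sum(a * d / n)
  den <- sum(b * cc / n)
  res$or_mh <- if (den > 0) num / den else if (num > 0) Inf else NA_real_

  # Robins-Breslow-Greenland variance of log(or_mh)
  if (den > 0 && num > 0) {
    P <- (a + d) / n; Q <- (b + cc) / n
    R <- a * d / n;   S <- b * cc / n
    var_log <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
    hw <- stats::qnorm(0.975) * sqrt(var_log)
    res$ci95 <- exp(log(res$or_mh) + c(-hw, hw))
  } else if (is.infinite(res$or_mh)) {
    res$ci95 <- c(NA_real_, Inf)
  } else if (identical(res$or_mh, 0)) {
    res$ci95 <- c(0, NA_real_)
  }
  res
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf(
    "CMH: chi2(1) = %.4g, p = %.4g, OR_MH = %.4g (95%% CI %.4g-%.4g), %d informative strata\n",
    x$statistic, x$p_two_sided, x$or_mh, x$ci95[1], x$ci95[2],
    x$n_informative_strata))
  invisible(x)
}

# Vectorized CMH over G genes sharing one stratification.
# A, C: G x K case-/control-carrier count matrices; n1, n0: per-cell sample
# totals. Same arithmetic as cmh_test(), computed for all genes at once.
.cmh_vectorized <- function(A, C, n1, n0, continuity = TRUE) {
  G <- nrow(A); K <- ncol(A)
  storage.mode(A) <- "double"; storage.mode(C) <- "double"
  N1 <- matrix(as.numeric(n1), G, K, byrow = TRUE)
  N0 <- matrix(as.numeric(n0), G, K, byrow = TRUE)
  B <- N1 - A; D <- N0 - C
  M1 <- A + C; M0 <- B + D
  N <- N1 + N0
  info <- N1 > 0 & N0 > 0 & M1 > 0 & M0 > 0
  E <- ifelse(info, N1 * M1 / N, 0)
  V <- ifelse(info, N1 * N0 * M1 * M0 / (N^2 * (N - 1)), 0)
  sumV <- rowSums(V)
  dev <- abs(rowSums(ifelse(info, A, 0)) - rowSums(E))
  if (continuity) dev <- pmax(0, dev - 0.5)
  stat <- ifelse(sumV > 0, dev^2 / sumV, 0)
  num <- rowSums(ifelse(info, A * D / N, 0))
  den <- rowSums(ifelse(info, B * C / N, 0))
  or <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  # Robins-Breslow-Greenland variance of log(or)
  P <- ifelse(info, (A + D) / N, 0); Q <- ifelse(info, (B + C) / N, 0)
  R <- ifelse(info, A * D / N, 0);   S <- ifelse(info, B * C / N, 0)
  sR <- rowSums(R); sS <- rowSums(S)
  var_log <- rowSums(P * R) / (2 * sR^2) +
    rowSums(P * S + Q * R) / (2 * sR * sS) + rowSums(Q * S) / (2 * sS^2)
  hw <- stats::qnorm(0.975) * sqrt(var_log)
  ok <- is.finite(or) & or > 0 & is.finite(hw)
  ci_lo <- ifelse(ok, exp(log(or) - hw), ifelse(is.infinite(or), NA_real_, 0))
  ci_hi <- ifelse(ok, exp(log(or) + hw), ifelse(is.infinite(or), Inf, NA_real_))
  ci_lo[!ok & !is.infinite(or) & (!is.finite(or) | or != 0)] <- NA_real_
  any_info <- rowSums(info) > 0
  list(statistic = ifelse(any_info, stat, NA_real_),
       p = ifelse(any_info, stats::pchisq(stat, 1, lower.tail = FALSE), NA_real_),
       or = ifelse(any_info, or, NA_real_),
       ci_lo = ifelse(any_info, ci_lo, NA_real_),
       ci_hi = ifelse(any_info, ci_hi, NA_real_),
       n_info = rowSums(info))
}

# carrier-count matrices (case, control) of dim n_genes x n_cells for one
# class, over the gene ids in `gene_ids` and the stratification in `cells`
# (a data.table keyed by cell label with n1/n0 totals).
.carrier_matrices <- function(gene_ids, class, variants, samples, cells,
                              cell_of_sample) {
  keep <- if (nrow(variants)) class_membership(variants, class) else logical(0)
  vv <- variants[keep, , drop = FALSE]
  A <- matrix(0L, length(gene_ids), nrow(cells),
              dimnames = list(gene_ids, cells$cell))
  C <- A
  if (nrow(vv)) {
    cc <- expand_carriers(vv)
    cc$gene_id <- vv$gene_id[cc$variant_row]
    unknown <- setdiff(unique(cc$sample_id), samples$sample_id)
    if (length(unknown))
      stop("carrier id(s) with no sample record: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    cc <- unique(cc[, c("gene_id", "sample_id")])
    cc <- cc[cc$gene_id %in% gene_ids, , drop = FALSE]
    if (nrow(cc)) {
      idx <- match(cc$sample_id, samples$sample_id)
      cc$cell <- cell_of_sample[idx]
      cc$pheno <- samples$phenotype[idx]
      tab <- cc[, list(n = .N), by = c("gene_id", "cell", "pheno")]
      icase <- tab$pheno == "case"
      A[cbind(match(tab$gene_id[icase], gene_ids),
              match(tab$cell[icase], cells$cell))] <- tab$n[icase]
      C[cbind(match(tab$gene_id[!icase], gene_ids),
              match(tab$cell[!icase], cells$cell))] <- tab$n[!icase]
    }
  }
  list(A = A, C = C)
}

#' Scan all genes and classes with the stratified burden test
#'
#' Computes, for every (gene, class) pair for which the class is defined on
#' the gene (missense classes only over genes carrying the corresponding
#' possible-variant flag), the stratified CMH test, Mantel-Haenszel odds
#' ratio and RBG confidence interval. The arithmetic is identical to
#' [build_tables()] + [cmh_test()] (which remain the single-gene reference
#' path) but is vectorized across genes. Untestable pairs (per
#' [gene_is_testable()]) are reported with NA statistics but are still
#' counted tests for the multiplicity ledger.
#'
#' @param study list with `variants`, `samples`, `genes` (e.g. from
#'   [simulate_study()]); variants should already pass the rarity filter.
#' @param classes test classes to scan (default [default_scan_classes()]).
#' @param largest_stratum reference stratum label; default: the stratum with
#'   the most samples.
#' @param continuity continuity correction flag passed to [cmh_test()].
#' @param sex_split_strata strata split by sex for X non-PAR genes.
#' @return `data.table` with one row per counted test: `gene_id`,
#'   `variant_class`, `counted`, `testable`, `n_informative_strata`, `or_mh`,
#'   `ci_lo`, `ci_hi`, `p_cc`.
#' @export
run_burden_scan <- function(study, classes = default_scan_classes(),
                            largest_stratum = NULL, continuity = TRUE,
                            sex_split_strata = character()) {
  variants <- study$variants; samples <- study$samples; genes <- study$genes
  if (is.null(largest_stratum)) {
    tab <- sort(table(samples$stratum), decreasing = TRUE)
    largest_stratum <- names(tab)[1]
  }
  if (!nrow(variants))
    warning("no variant records: burden scan is empty of carriers")
  if (!largest_stratum %in% samples$stratum)
    stop("largest_stratum '", largest_stratum,
         "' is not among the sample strata")
  samples <- data.table::as.data.table(samples)

  # two stratification layouts: plain strata, and sex-split strata (X genes)
  pheno <- NULL  # NSE column
  make_cells <- function(cell_of_sample) {
    d <- data.table::data.table(cell = cell_of_sample,
                                pheno = samples$phenotype)
    cells <- d[, list(n1 = sum(pheno == "case"),
                      n0 = sum(pheno == "control")), by = "cell"]
    data.table::setorderv(cells, "cell")
    cells
  }
  plain_cell <- samples$stratum
  split_cell <- ifelse(samples$stratum %in% sex_split_strata,
                       paste0(samples$stratum, "|", samples$sex),
                       samples$stratum)
  is_x <- genes$chrom_category == "X_nonPAR"

  out <- vector("list", 0L)
  for (cl in classes) {
    defined <- switch(cl,
      PTV_plus_MPCgt3 = genes$has_possible_mpc_gt3,
      PTV_plus_MPCgt2 = , MPCgt2_only = , MPC_2_3 = genes$has_possible_mpc_gt2,
      rep(TRUE, nrow(genes)))
    for (layout in c("plain", "split")) {
      gmask <- defined & (if (layout == "plain") !is_x else is_x)
      if (layout == "split" && !length(sex_split_strata)) gmask <- defined & is_x
      if (!any(gmask)) next
      cell_of_sample <- if (layout == "plain") plain_cell else split_cell
      cells <- make_cells(cell_of_sample)
      gid <- genes$gene_id[gmask]
      mats <- .carrier_matrices(gid, cl, variants, samples, cells,
                                cell_of_sample)
      r <- .cmh_vectorized(mats$A, mats$C, cells$n1, cells$n0,
                           continuity = continuity)
      # inclusion rule: >= 2 strata with carriers (base stratum labels), or
      # carriers in the largest stratum; plus exclusion + possible flags
      carr <- mats$A + mats$C
      base <- sub("\\|.*$", "", cells$cell)
      n_strata_with <- vapply(seq_len(nrow(carr)), function(i)
        length(unique(base[carr[i, ] > 0])), 0L)
      in_largest_cols <- base == largest_stratum
      in_largest <- rowSums(carr[, in_largest_cols, drop = FALSE]) > 0
      testable <- !genes$excluded_clonal_haem[gmask] &
        (n_strata_with >= 2L | in_largest)
      row <- data.table::data.table(
        gene_id = gid, variant_class = cl, counted = TRUE,
        testable = testable,
        n_informative_strata = ifelse(testable, r$n_info, NA_integer_),
        or_mh = ifelse(testable, r$or, NA_real_),
        ci_lo = ifelse(testable, r$ci_lo, NA_real_),
        ci_hi = ifelse(testable, r$ci_hi, NA_real_),
        p_cc = ifelse(testable, r$p, NA_real_))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- data.table::rbindlist(out)
  # keep the panel's gene order within each class
  res[order(match(res$variant_class, classes),
            match(res$gene_id, genes$gene_id))]
}
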