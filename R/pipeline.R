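#' Analysis configuration for a gene-discovery run
#'
#' Collects every threshold of the discovery pipeline: the ultra-rare MAC
#' cap, the meta-analysis gate on the case-control p-value, the family-wise
#' alpha, the classes scanned, carrier-vs-allele counting, the BH
#' denominator convention and the seed.
#'
#' @param mac_cap ultra-rare MAC cap (default 5).
#' @param meta_gate gate on `p_cc` for the de novo meta-analysis (default
#'   0.01).
#' @param alpha significance level (default 0.05).
#' @param largest_stratum reference stratum for the inclusion rule; NULL
#'   means the largest stratum by sample count.
#' @param classes test classes to scan.
#' @param carrier_mode `"carrier"` (default; one count per individual per
#'   gene) or `"allele"` (reserved; only carrier counting is implemented,
#'   the ultra-rare regime makes the two essentially identical).
#' @param fdr_denominator `"ledger_total"` or `"meta_genes"`, see
#'   [run_meta()].
#' @param continuity CMH continuity correction (default TRUE).
#' @param sex_split_strata strata split by sex for X non-PAR genes.
#' @param seed integer seed for any simulation steps.
#' @return List of class `study_config`.
#' @export
study_config <- function(mac_cap = 5L, meta_gate = 0.01, alpha = 0.05,
                         largest_stratum = NULL,
                         classes = default_scan_classes(),
                         carrier_mode = c("carrier", "allele"),
                         fdr_denominator = c("ledger_total", "meta_genes"),
                         continuity = TRUE,
                         sex_split_strata = character(), seed = 1L) {
  carrier_mode <- match.arg(carrier_mode)
  fdr_denominator <- match.arg(fdr_denominator)
  if (mac_cap < 1L) stop("mac_cap must be >= 1")
  if (meta_gate <= 0 || meta_gate >= 1) stop("meta_gate must lie in (0, 1)")
  structure(list(mac_cap = as.integer(mac_cap), meta_gate = meta_gate,
                 alpha = alpha, largest_stratum = largest_stratum,
                 classes = classes, carrier_mode = carrier_mode,
                 fdr_denominator = fdr_denominator, continuity = continuity,
                 sex_split_strata = sex_split_strata,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Kolmogorov-Smirnov uniformity check for null p-values
#'
#' Compares a set of p-values (typically the synonymous-class burden scan,
#' which carries no signal by construction) against Uniform(0, 1).
#'
#' @param p_values numeric vector, at least 100 values.
#' @param alpha rejection level for the verdict (default 0.01).
#' @return List: `ks_statistic`, `ks_p`, `n`, `pass`.
#' @export
qq_null_check <- function(p_values, alpha = 0.01) {
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) < 100L)
    stop("need at least 100 p-values for the null check (got ",
         length(p_values), ")")
  ks <- suppressWarnings(stats::ks.test(p_values, "punif"))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       n = length(p_values), pass = ks$p.value > alpha)
}

#' Run the full gene-discovery pipeline on a study
#'
#' Filters variants by the ultra-rare MAC cap, scans every gene x class with
#' the stratified CMH burden test, gates the de novo Fisher meta-analysis,
#' builds the multiplicity ledger, attaches q-values and significance flags,
#' runs any gene-set Firth tests, and performs the synonymous-class null
#' calibration check. Filter counts are logged via `message()`.
#'
#' @param study list with `variants`, `samples`, `genes`, optionally
#'   `denovo` (from [simulate_study()] or [read_study()]).
#' @param config a [study_config()].
#' @param genesets optional list of [geneset_spec()] objects.
#' @return List of class `discovery_run`: `results`, `ledger`, `genesets`,
#'   `qq_synonymous` (p-values + KS verdict, when computable), `counts`.
#' @export
run_discovery <- function(study, config = study_config(), genesets = NULL) {
  v <- study$variants
  n_in <- nrow(v)
  keep <- if (n_in) passes_rare_filter(v, mac_cap = config$mac_cap) else logical(0)
  v <- v[keep, , drop = FALSE]
  message("variants in: ", n_in, "; passing MAC <= ", config$mac_cap,
          " rarity filter: ", nrow(v))
  fstudy <- study
  fstudy$variants <- v

  scan <- run_burden_scan(fstudy, classes = config$classes,
                          largest_stratum = config$largest_stratum,
                          continuity = config$continuity,
                          sex_split_strata = config$sex_split_strata)
  for (cl in config$classes)
    message("class ", cl, ": ",
            sum(scan$variant_class == cl & scan$testable), " testable of ",
            sum(scan$variant_class == cl), " counted gene tests")
  meta <- run_meta(scan, denovo = study$denovo, gate = config$meta_gate,
                   alpha = config$alpha,
                   fdr_denominator = config$fdr_denominator)
  message("meta-analysed genes: ", meta$ledger$n_meta_tests,
          "; total tests: ", meta$ledger$n_total,
          "; Bonferroni threshold: ",
          signif(meta$ledger$bonferroni_threshold, 3))

  gs <- NULL
  if (!is.null(genesets)) {
    gs <- data.table::rbindlist(lapply(genesets, function(spec) {
      r <- geneset_test(fstudy, spec)
      data.table::data.table(set_name = r$set_name, or_burden = r$or_burden,
                             ci_lo = r$ci95[1], ci_hi = r$ci95[2],
                             p_burden = r$p_burden, converged = r$converged,
                             n_carriers = r$n_carriers)
    }))
  }

  qq <- NULL
  syn_scan <- tryCatch({
    s <- run_burden_scan(fstudy, classes = "synonymous",
                         largest_stratum = config$largest_stratum,
                         continuity = config$continuity,
                         sex_split_strata = config$sex_split_strata)
    s$p_cc[s$testable & is.finite(s$p_cc)]
  }, warning = function(w) numeric(0), error = function(e) numeric(0))
  if (length(syn_scan) >= 100L)
    qq <- c(qq_null_check(syn_scan), list(p_values = syn_scan))

  structure(list(results = meta$results, ledger = meta$ledger,
                 genesets = gs, qq_synonymous = qq,
                 counts = list(variants_in = n_in,
                               variants_pass = nrow(v))),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("Gene-discovery run:", nrow(x$results), "counted tests;")
  cat(" exome-wide significant:", sum(x$results$exome_wide_significant),
      "; FDR<5%:", sum(x$results$fdr5_significant), "\n")
  print(x$ledger)
  invisible(x)
}

# format p columns to >= 6 significant digits for TSV output
.fmt_results <- function(res) {
  out <- data.table::copy(data.table::as.data.table(res))
  for (col in intersect(c("or_mh", "ci_lo", "ci_hi", "p_cc", "p_denovo",
                          "p_meta", "p_final", "q_value", "dn_expected",
                          "p_burden", "or_burden"), names(out)))
    data.table::set(out, j = col,
                    value = ifelse(is.finite(out[[col]]),
                                   sprintf("%.6g", out[[col]]), "NA"))
  out
}

#' Run the pipeline from files and write result tables
#'
#' Reads a study directory (or simulates one when the config says so), runs
#' [run_discovery()], and writes `gene_results.tsv`, `ledger.tsv`,
#' `geneset_results.tsv` (when sets are given) and `qq_synonymous.tsv` to
#' the output directory. P-values are written with 6 significant digits.
#'
#' @param study_dir directory with study TSVs (see [read_study()]).
#' @param out_dir output directory.
#' @param config a [study_config()].
#' @param genesets_path optional genesets.tsv path.
#' @return The [run_discovery()] result, invisibly.
#' @export
run_pipeline <- function(study_dir, out_dir, config = study_config(),
                         genesets_path = NULL) {
  study <- read_study(study_dir)
  genesets <- if (!is.null(genesets_path)) read_genesets(genesets_path)
  run <- run_discovery(study, config = config, genesets = genesets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(.fmt_results(run$results),
                     file.path(out_dir, "gene_results.tsv"), sep = "\t")
  led <- run$ledger
  data.table::fwrite(data.table::data.table(
    n_cc_tests = led$n_cc_tests, n_meta_tests = led$n_meta_tests,
    n_total = led$n_total, alpha = led$alpha,
    bonferroni_threshold = sprintf("%.6g", led$bonferroni_threshold)),
    file.path(out_dir, "ledger.tsv"), sep = "\t")
  if (!is.null(run$genesets))
    data.table::fwrite(.fmt_results(run$genesets),
                       file.path(out_dir, "geneset_results.tsv"), sep = "\t")
  if (!is.null(run$qq_synonymous))
    data.table::fwrite(data.table::data.table(
      p_cc = sprintf("%.6g", run$qq_synonymous$p_values)),
      file.path(out_dir, "qq_synonymous.tsv"), sep = "\t")
  invisible(run)
}
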