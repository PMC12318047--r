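#' Simulation configuration for a synthetic exome study
#'
#' Describes a complete case-control + trio exome study with planted risk
#' genes. Carrier events are independent Bernoulli draws per individual per
#' gene per atomic consequence class (at most one qualifying variant per
#' individual per gene per class): in the ultra-rare regime the multi-hit
#' probability is negligible and this keeps the 2x2 carrier tables exact.
#'
#' @param n_strata number of ancestry x platform strata.
#' @param stratum_sizes list of `c(n_cases, n_controls)` pairs, one per
#'   stratum. Default: three unequal strata (2000,2000), (1500,2000),
#'   (1000,1500).
#' @param n_genes number of genes in the panel.
#' @param frac_constrained fraction of genes with pLI >= 0.9 (default 0.17,
#'   roughly the constrained share of the tested exome).
#' @param risk_genes `data.frame` with columns `gene_index`, `variant_class`
#'   (a test class, see [variant_classes()]) and `odds_ratio` (> 0), or NULL.
#' @param baseline_carrier_rate per-gene per-atomic-class probability that a
#'   control carries a qualifying variant (default 0.01).
#' @param n_trios number of proband-parent trios (bookkeeping; expected de
#'   novo counts are already expressed across all trios).
#' @param denovo_rate_per_gene_class expected de novo count lambda per gene
#'   per atomic class across all trios (default 0.05).
#' @param denovo_enrichment multiplicative factor applied to lambda in risk
#'   genes for the de novo class matching the planted test class.
#' @param n_pcs number of principal components simulated per sample.
#' @param seed integer seed; a fixed seed reproduces the study exactly.
#' @param frac_mac_ref_gt5 fraction of variant records given a reference-panel
#'   MAC > 5, to exercise the rarity filter (default 0.1).
#' @param frac_x_genes fraction of genes placed on X (non-PAR).
#' @param atomic_classes atomic consequence classes to simulate; subset of
#'   `c("PTV", "missense_gt3", "missense_2_3", "synonymous")`.
#' @param confound_burden if TRUE, adds a stratum-correlated shift to the
#'   exome-wide burden covariate (to exercise covariate adjustment).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_strata = 3L,
                       stratum_sizes = list(c(2000L, 2000L), c(1500L, 2000L),
                                            c(1000L, 1500L)),
                       n_genes = 200L,
                       frac_constrained = 0.17,
                       risk_genes = NULL,
                       baseline_carrier_rate = 0.01,
                       n_trios = 3444L,
                       denovo_rate_per_gene_class = 0.05,
                       denovo_enrichment = 1,
                       n_pcs = 10L,
                       seed = 1L,
                       frac_mac_ref_gt5 = 0.1,
                       frac_x_genes = 0,
                       atomic_classes = c("PTV", "missense_gt3",
                                          "missense_2_3", "synonymous"),
                       confound_burden = FALSE) {
  cfg <- list(n_strata = as.integer(n_strata), stratum_sizes = stratum_sizes,
              n_genes = as.integer(n_genes),
              frac_constrained = frac_constrained, risk_genes = risk_genes,
              baseline_carrier_rate = baseline_carrier_rate,
              n_trios = as.integer(n_trios),
              denovo_rate_per_gene_class = denovo_rate_per_gene_class,
              denovo_enrichment = denovo_enrichment,
              n_pcs = as.integer(n_pcs), seed = as.integer(seed),
              frac_mac_ref_gt5 = frac_mac_ref_gt5,
              frac_x_genes = frac_x_genes,
              atomic_classes = atomic_classes,
              confound_burden = confound_burden)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  sz <- vapply(x$stratum_sizes, function(s) paste(s, collapse = "/"), "")
  cat("sim_config:", x$n_genes, "genes,", x$n_strata,
      "strata (cases/controls:", paste(sz, collapse = ", "), "),",
      if (is.null(x$risk_genes)) 0L else nrow(x$risk_genes),
      "risk genes, seed", x$seed, "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  err <- function(field, why) stop("invalid sim_config field '", field, "': ",
                                   why, call. = FALSE)
  if (!is.finite(cfg$n_genes) || cfg$n_genes < 1L) err("n_genes", "must be >= 1")
  if (!is.finite(cfg$n_strata) || cfg$n_strata < 1L) err("n_strata", "must be >= 1")
  if (length(cfg$stratum_sizes) != cfg$n_strata)
    err("stratum_sizes", "must have exactly n_strata entries")
  ok <- vapply(cfg$stratum_sizes,
               function(s) length(s) == 2L && all(is.finite(s)) && all(s > 0),
               TRUE)
  if (!all(ok)) err("stratum_sizes", "entries must be positive (cases, controls) pairs")
  for (f in c("frac_constrained", "baseline_carrier_rate", "frac_mac_ref_gt5",
              "frac_x_genes")) {
    x <- cfg[[f]]
    if (!is.finite(x) || x < 0 || x > 1) err(f, "must lie in [0, 1]")
  }
  if (!is.finite(cfg$denovo_rate_per_gene_class) ||
      cfg$denovo_rate_per_gene_class < 0)
    err("denovo_rate_per_gene_class", "lambda must be >= 0")
  if (!is.finite(cfg$denovo_enrichment) || cfg$denovo_enrichment <= 0)
    err("denovo_enrichment", "must be > 0")
  if (cfg$n_trios < 0L) err("n_trios", "must be >= 0")
  if (cfg$n_pcs < 0L) err("n_pcs", "must be >= 0")
  bad <- setdiff(cfg$atomic_classes,
                 c("PTV", "missense_gt3", "missense_2_3", "synonymous"))
  if (length(bad)) err("atomic_classes", paste("unknown:", paste(bad, collapse = ", ")))
  if (!is.null(cfg$risk_genes)) {
    rg <- cfg$risk_genes
    need <- c("gene_index", "variant_class", "odds_ratio")
    if (!all(need %in% names(rg)))
      err("risk_genes", "needs columns gene_index, variant_class, odds_ratio")
    if (any(rg$odds_ratio <= 0)) err("risk_genes", "odds_ratio must be > 0")
    if (any(rg$gene_index < 1L | rg$gene_index > cfg$n_genes))
      err("risk_genes", "gene_index out of range")
    bad <- setdiff(rg$variant_class, variant_classes())
    if (length(bad)) err("risk_genes", paste("unknown class:", paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

# Atomic simulation classes -> VariantRecord consequence + MPC sampler.
.atomic_meta <- list(
  PTV          = list(consequence = "PTV", mpc = function(n) rep(NA_real_, n)),
  missense_gt3 = list(consequence = "missense", mpc = function(n) stats::runif(n, 3.05, 5)),
  missense_2_3 = list(consequence = "missense", mpc = function(n) stats::runif(n, 2.05, 3)),
  synonymous   = list(consequence = "synonymous", mpc = function(n) rep(NA_real_, n)))

# Which atomic classes a planted test class touches.
atomic_for_class <- function(class) {
  switch(class,
    PTV_only        = "PTV",
    PTV_plus_MPCgt3 = c("PTV", "missense_gt3"),
    PTV_plus_MPCgt2 = c("PTV", "missense_gt3", "missense_2_3"),
    MPCgt2_only     = c("missense_gt3", "missense_2_3"),
    MPC_2_3         = "missense_2_3",
    synonymous      = "synonymous",
    stop("unknown variant class: ", class))
}

#' Simulate a gene annotation panel
#'
#' Draws pLI values so that exactly `round(n_genes * frac_constrained)` genes
#' are constrained (pLI >= 0.9), assigns possible-variant flags for the
#' MPC > 3 and MPC > 2 missense classes (marginal rates ~0.11 and ~0.27,
#' mirroring the tested-exome proportions, with the > 3 flag nested in > 2),
#' and per-gene per-class expected de novo rates. When `n_genes >= 3` and
#' `name_clonal_haem = TRUE`, the first three genes are labelled TET2, DNMT3A
#' and ASXL1 and flagged for clonal-haematopoiesis exclusion.
#'
#' @param cfg a [sim_config()].
#' @param name_clonal_haem label three genes for exclusion testing.
#' @return `data.table` of gene annotations.
#' @export
simulate_gene_panel <- function(cfg, name_clonal_haem = FALSE) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  n_con <- round(n * cfg$frac_constrained)
  constrained <- rep(FALSE, n)
  if (n_con > 0) constrained[sample.int(n, n_con)] <- TRUE
  pli <- ifelse(constrained, stats::runif(n, 0.9, 1), stats::runif(n, 0, 0.899))
  gt3 <- stats::runif(n) < 0.111
  gt2 <- gt3 | (stats::runif(n) < 0.18)
  n_x <- round(n * cfg$frac_x_genes)
  chrom <- rep("autosomal_or_PAR", n)
  if (n_x > 0) chrom[sample.int(n, n_x)] <- "X_nonPAR"
  excl <- rep(FALSE, n)
  if (name_clonal_haem && n >= 3L) {
    gene_id[1:3] <- c("TET2", "DNMT3A", "ASXL1")
    excl[1:3] <- TRUE
  }
  data.table::data.table(
    gene_id = gene_id, pli = pli, constrained = constrained,
    has_possible_mpc_gt3 = gt3, has_possible_mpc_gt2 = gt2,
    lambda_ptv = rep(cfg$denovo_rate_per_gene_class, n),
    lambda_mis_gt2 = rep(cfg$denovo_rate_per_gene_class, n),
    chrom_category = chrom, excluded_clonal_haem = excl,
    cnv_locus = NA_character_)
}

# Case carrier probability for a planted odds ratio against baseline p0.
.case_rate <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Simulate the case-control arm of a synthetic study
#'
#' Per stratum, each control carries a qualifying variant of atomic class `a`
#' in gene `g` with probability `baseline_carrier_rate`; cases carry with the
#' probability whose odds are the planted odds ratio times the baseline odds
#' (1 for non-risk genes). Each carrier event is emitted as one variant
#' record with cohort MAC 1 (per-allele representation) and a reference-panel
#' MAC drawn categorically: 90% in 0..5 (0 most likely), 10% in 6..10 so the
#' rarity filter is exercised. Principal components are standard normal; the
#' exome-wide rare-variant burden is counted from the emitted records.
#'
#' @param cfg a [sim_config()].
#' @param panel gene panel from [simulate_gene_panel()].
#' @return List with elements `variants`, `samples`, `genes`, `truth`.
#' @export
simulate_case_control <- function(cfg, panel) {
  validate_sim_config(cfg)
  stopifnot(nrow(panel) == cfg$n_genes)
  # planted OR lookup: gene x atomic class -> OR
  or_map <- new.env(parent = emptyenv())
  truth <- list()
  if (!is.null(cfg$risk_genes)) {
    for (i in seq_len(nrow(cfg$risk_genes))) {
      gi <- cfg$risk_genes$gene_index[i]
      cl <- cfg$risk_genes$variant_class[i]
      or <- cfg$risk_genes$odds_ratio[i]
      if (grepl("MPCgt3", cl) && !panel$has_possible_mpc_gt3[gi])
        stop("invalid sim_config field 'risk_genes': gene ", panel$gene_id[gi],
             " lacks the possible MPC>3 flag required by class ", cl)
      if (grepl("gt2|2_3", cl) && !panel$has_possible_mpc_gt2[gi])
        stop("invalid sim_config field 'risk_genes': gene ", panel$gene_id[gi],
             " lacks the possible MPC>2 flag required by class ", cl)
      for (a in atomic_for_class(cl))
        assign(paste0(gi, ".", a), or, envir = or_map)
      truth[[panel$gene_id[gi]]] <- list(variant_class = cl, odds_ratio = or)
    }
  }
  set.seed(cfg$seed + 1L)

  # samples
  samp <- list()
  for (s in seq_len(cfg$n_strata)) {
    nc <- cfg$stratum_sizes[[s]][1]
    nt <- cfg$stratum_sizes[[s]][2]
    samp[[s]] <- data.table::data.table(
      sample_id = c(sprintf("S%d_case_%05d", s, seq_len(nc)),
                    sprintf("S%d_ctrl_%05d", s, seq_len(nt))),
      phenotype = rep(c("case", "control"), c(nc, nt)),
      stratum = sprintf("stratum%d", s))
  }
  samples <- data.table::rbindlist(samp)
  n_samp <- nrow(samples)
  samples$sex <- ifelse(stats::runif(n_samp) < 0.5, "male", "female")
  if (cfg$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n_samp * cfg$n_pcs), n_samp, cfg$n_pcs)
    colnames(pcs) <- sprintf("pc%d", seq_len(cfg$n_pcs))
    samples <- cbind(samples, data.table::as.data.table(pcs))
  }

  # carrier events, one Bernoulli per (gene, atomic class, sample)
  p0 <- cfg$baseline_carrier_rate
  recs <- vector("list", 0L)
  if (p0 > 0) {
    is_case <- samples$phenotype == "case"
    for (a in cfg$atomic_classes) {
      meta <- .atomic_meta[[a]]
      for (gi in seq_len(cfg$n_genes)) {
        or <- mget(paste0(gi, ".", a), envir = or_map,
                   ifnotfound = 1)[[1]]
        p1 <- if (or == 1) p0 else .case_rate(p0, or)
        pr <- ifelse(is_case, p1, p0)
        hit <- stats::runif(n_samp) < pr
        k <- sum(hit)
        if (!k) next
        recs[[length(recs) + 1L]] <- data.table::data.table(
          gene_id = panel$gene_id[gi],
          carrier_ids = samples$sample_id[hit],
          consequence = meta$consequence,
          mpc = meta$mpc(k),
          chrom_category = panel$chrom_category[gi],
          mac_internal = 1L,
          mac_reference = 0L)  # drawn below
      }
    }
  }
  variants <- if (length(recs)) data.table::rbindlist(recs) else
    variant_table(character(), character(), character(), numeric(),
                  character(), integer(), integer())
  if (nrow(variants)) {
    # reference-panel MAC: 0 weighted highest within 0..5; 10% exceed the cap
    low <- sample(0:5, nrow(variants), replace = TRUE,
                  prob = c(0.55, rep(0.09, 5)) / 1.0)
    high <- sample(6:10, nrow(variants), replace = TRUE)
    gt5 <- stats::runif(nrow(variants)) < cfg$frac_mac_ref_gt5
    variants$mac_reference <- ifelse(gt5, high, low)
    validate_variants(variants)
  }

  burden <- exome_wide_burden(samples, variants)
  samples$exome_burden <- as.integer(burden[samples$sample_id])
  if (cfg$confound_burden) {
    shift <- as.integer(factor(samples$stratum)) - 1L
    samples$exome_burden <- samples$exome_burden + shift
  }
  list(variants = variants, samples = samples, genes = panel, truth = truth)
}

#' Simulate trio de novo counts
#'
#' For every gene and atomic de novo class (`PTV`, `missense_gt2`), draws the
#' observed count across all trios as Poisson(lambda x enrichment) when the
#' gene is a planted risk gene whose class touches that de novo class, and
#' Poisson(lambda) otherwise. The `expected` column stores lambda.
#'
#' @param cfg a [sim_config()].
#' @param panel gene panel from [simulate_gene_panel()].
#' @return `data.table` with columns `gene_id`, `variant_class`
#'   (`PTV` | `missense_gt2`), `observed`, `expected`.
#' @export
simulate_trios <- function(cfg, panel) {
  validate_sim_config(cfg)
  if (any(panel$lambda_ptv < 0) || any(panel$lambda_mis_gt2 < 0))
    stop("invalid sim_config field 'denovo_rate_per_gene_class': lambda must be >= 0")
  set.seed(cfg$seed + 2L)
  enr_ptv <- rep(1, cfg$n_genes)
  enr_mis <- rep(1, cfg$n_genes)
  if (!is.null(cfg$risk_genes)) {
    for (i in seq_len(nrow(cfg$risk_genes))) {
      gi <- cfg$risk_genes$gene_index[i]
      at <- atomic_for_class(cfg$risk_genes$variant_class[i])
      if ("PTV" %in% at) enr_ptv[gi] <- cfg$denovo_enrichment
      if (any(c("missense_gt3", "missense_2_3") %in% at))
        enr_mis[gi] <- cfg$denovo_enrichment
    }
  }
  data.table::data.table(
    gene_id = rep(panel$gene_id, 2L),
    variant_class = rep(c("PTV", "missense_gt2"), each = cfg$n_genes),
    observed = c(stats::rpois(cfg$n_genes, panel$lambda_ptv * enr_ptv),
                 stats::rpois(cfg$n_genes, panel$lambda_mis_gt2 * enr_mis)),
    expected = c(panel$lambda_ptv, panel$lambda_mis_gt2))
}

#' Simulate a complete synthetic exome study
#'
#' Convenience wrapper: gene panel + case-control arm + trio de novo counts.
#'
#' @param cfg a [sim_config()].
#' @param name_clonal_haem see [simulate_gene_panel()].
#' @return List with `variants`, `samples`, `genes`, `denovo`, `truth`.
#' @export
simulate_study <- function(cfg, name_clonal_haem = FALSE) {
  panel <- simulate_gene_panel(cfg, name_clonal_haem = name_clonal_haem)
  cc <- simulate_case_control(cfg, panel)
  cc$denovo <- simulate_trios(cfg, panel)
  cc
}
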