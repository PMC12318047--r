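#' @title Variant-class taxonomy and ultra-rare filters
#' @name variant_model
#' @description
#' The data model for rare-coding-variant burden analysis. Variants are
#' tabular records (one row per alternate allele) carrying the gene, the
#' carrier sample ids, a consequence (`PTV`, `missense`, `synonymous`,
#' `other`), an MPC deleteriousness score for missense alleles, a chromosome
#' category, and two minor allele counts: `mac_internal` over the analysed
#' cases + controls (all strata pooled) and `mac_reference` in an external
#' reference panel of population controls.
#'
#' Test classes collapse variants for per-gene burden tests. MPC thresholds
#' are strict: a missense allele with MPC exactly 2 (or 3) falls below the
#' `> 2` (`> 3`) cut.
NULL

#' Test classes for per-gene burden scans
#'
#' The six collapsing classes: `PTV_only` (protein-truncating variants),
#' `PTV_plus_MPCgt3` (PTVs plus missense with MPC > 3), `PTV_plus_MPCgt2`,
#' `MPCgt2_only` (missense MPC > 2 alone), `synonymous` (the null-calibration
#' class), and `MPC_2_3` (missense with 2 < MPC <= 3).
#'
#' @return Character vector of class names.
#' @export
variant_classes <- function() {
  c("PTV_only", "PTV_plus_MPCgt3", "PTV_plus_MPCgt2", "MPCgt2_only",
    "synonymous", "MPC_2_3")
}

#' The four classes scanned by default in a gene-discovery run
#' @return Character vector.
#' @export
default_scan_classes <- function() {
  c("PTV_only", "PTV_plus_MPCgt3", "PTV_plus_MPCgt2", "MPCgt2_only")
}

.consequences <- c("PTV", "missense", "synonymous", "other")
.chrom_categories <- c("autosomal_or_PAR", "X_nonPAR")

#' Construct a variant table
#'
#' Builds and validates the canonical variant `data.table`. `carrier_ids` is
#' a character vector of comma-separated sample ids (one string per variant).
#'
#' @param gene_id character.
#' @param carrier_ids character, comma-separated sample ids per variant.
#' @param consequence character, one of `PTV`, `missense`, `synonymous`,
#'   `other`.
#' @param mpc numeric, `NA` allowed only for non-missense records.
#' @param chrom_category `"autosomal_or_PAR"` or `"X_nonPAR"`.
#' @param mac_internal integer >= 1, allele count in the analysed cohort.
#' @param mac_reference integer >= 0, allele count in the reference panel.
#' @return A `data.table` with one row per variant record.
#' @export
variant_table <- function(gene_id, carrier_ids, consequence, mpc,
                          chrom_category, mac_internal, mac_reference) {
  v <- data.table::data.table(
    gene_id = as.character(gene_id),
    carrier_ids = as.character(carrier_ids),
    consequence = as.character(consequence),
    mpc = as.numeric(mpc),
    chrom_category = as.character(chrom_category),
    mac_internal = as.integer(mac_internal),
    mac_reference = as.integer(mac_reference))
  validate_variants(v)
  v
}

#' Validate a variant table
#'
#' @param v variant `data.table` (see [variant_table()]).
#' @return `v`, invisibly, after checks.
#' @export
validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  need <- c("gene_id", "carrier_ids", "consequence", "mpc", "chrom_category",
            "mac_internal", "mac_reference")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(v$consequence), .consequences)
  if (length(bad))
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(v$chrom_category), .chrom_categories)
  if (length(bad))
    stop("unknown chrom_category value(s): ", paste(bad, collapse = ", "))
  if (any(v$mac_internal < 1L, na.rm = TRUE) || anyNA(v$mac_internal))
    stop("mac_internal must be an integer >= 1 for every record")
  if (any(v$mac_reference < 0L, na.rm = TRUE) || anyNA(v$mac_reference))
    stop("mac_reference must be a non-negative integer for every record")
  i <- which(v$consequence == "missense" & !is.finite(v$mpc))
  if (length(i))
    stop("missense record(s) without an MPC score at row(s): ",
         paste(utils::head(i, 5L), collapse = ", "))
  invisible(v)
}

#' Class membership of a variant record
#'
#' Total function over (consequence, MPC): `PTV_only` iff PTV;
#' `PTV_plus_MPCgt3` iff PTV or missense with MPC > 3; `PTV_plus_MPCgt2` iff
#' PTV or missense with MPC > 2; `MPCgt2_only` iff missense with MPC > 2;
#' `synonymous` iff synonymous; `MPC_2_3` iff missense with 2 < MPC <= 3.
#' All MPC comparisons are strict at the lower cut.
#'
#' @param v variant table (any number of rows).
#' @param class one of [variant_classes()].
#' @return Logical vector, one entry per record.
#' @export
class_membership <- function(v, class) {
  class <- match.arg(class, variant_classes())
  i <- which(v$consequence == "missense" & !is.finite(v$mpc))
  if (length(i))
    stop("missense record(s) without an MPC score at row(s): ",
         paste(utils::head(i, 5L), collapse = ", "))
  cons <- v$consequence
  mpc <- v$mpc
  is_ptv <- cons == "PTV"
  is_mis <- cons == "missense"
  switch(class,
    PTV_only        = is_ptv,
    PTV_plus_MPCgt3 = is_ptv | (is_mis & mpc > 3),
    PTV_plus_MPCgt2 = is_ptv | (is_mis & mpc > 2),
    MPCgt2_only     = is_mis & mpc > 2,
    synonymous      = cons == "synonymous",
    MPC_2_3         = is_mis & mpc > 2 & mpc <= 3)
}

#' Ultra-rare filter: MAC at or below a cap in cohort and reference panel
#'
#' A variant passes when `mac_internal <= mac_cap` (allele count in all
#' analysed cases and controls) and `mac_reference <= mac_cap` (count in the
#' external reference panel). The default cap of 5 is the conventional
#' ultra-rare threshold at this cohort scale.
#'
#' @param v variant table.
#' @param mac_cap integer >= 1.
#' @return Logical vector per record.
#' @export
passes_rare_filter <- function(v, mac_cap = 5L) {
  if (mac_cap < 1L) stop("mac_cap must be >= 1")
  if (any(v$mac_internal < 0L) || any(v$mac_reference < 0L))
    stop("negative minor allele count")
  v$mac_internal <= mac_cap & v$mac_reference <= mac_cap
}

#' Singleton filter: cohort MAC = 1 and absent from the reference panel
#'
#' @param v variant table.
#' @return Logical vector per record.
#' @export
is_singleton <- function(v) {
  if (any(v$mac_internal < 0L) || any(v$mac_reference < 0L))
    stop("negative minor allele count")
  v$mac_internal == 1L & v$mac_reference == 0L
}

# Expand comma-separated carrier strings into (row, sample_id) long form.
expand_carriers <- function(v) {
  ids <- strsplit(v$carrier_ids, ",", fixed = TRUE)
  n <- lengths(ids)
  data.table::data.table(
    variant_row = rep.int(seq_len(nrow(v)), n),
    sample_id = trimws(unlist(ids, use.names = FALSE)))
}

#' Per-sample exome-wide burden of qualifying variants
#'
#' Counts, for every sample, the number of variant carriages passing a
#' predicate across all genes. The sum over samples equals the number of
#' qualifying (variant, carrier) pairs.
#'
#' @param samples sample table with a `sample_id` column.
#' @param variants variant table.
#' @param filter logical vector per variant record, or a function mapping the
#'   variant table to one (default: the MAC <= 5 rarity filter).
#' @return Named integer vector over all `samples$sample_id` (zeros included).
#' @export
exome_wide_burden <- function(samples, variants,
                              filter = function(v) passes_rare_filter(v)) {
  keep <- if (is.function(filter)) filter(variants) else as.logical(filter)
  stopifnot(length(keep) == nrow(variants))
  out <- integer(nrow(samples))
  names(out) <- samples$sample_id
  if (!nrow(variants) || !any(keep)) return(out)
  cc <- expand_carriers(variants[keep, , drop = FALSE])
  unknown <- setdiff(unique(cc$sample_id), samples$sample_id)
  if (length(unknown))
    stop("carrier id(s) absent from sample table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  tab <- table(cc$sample_id)
  out[names(tab)] <- as.integer(tab)
  out
}
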