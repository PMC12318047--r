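#' @title Tabular study input/output
#' @name study_io
#' @description
#' Plain-text interchange formats: `variants.tsv` (one row per alternate
#' allele, carriers comma-separated, `.` for a missing MPC), `samples.tsv`
#' (phenotype, stratum, sex, `pc1..pcN`, `exome_burden`), `genes.tsv`
#' (pLI, possible-variant flags, de novo lambdas, exclusion flags, CNV
#' locus), `denovo.tsv` (observed and expected de novo counts per gene and
#' atomic class) and `genesets.tsv` (long format). All tab-separated with
#' headers.
NULL

.fail_row <- function(path, what, rows) {
  stop(path, ": ", what, " at data row(s) ",
       paste(utils::head(rows, 5L), collapse = ", "))
}

#' Read a variants.tsv file
#' @param path file path.
#' @return Validated variant `data.table` (see [variant_table()]).
#' @export
read_variants <- function(path) {
  v <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = "sample_ids"))
  need <- c("gene_id", "sample_ids", "consequence", "mpc", "chrom_category",
            "mac_internal", "mac_reference")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  data.table::setnames(v, "sample_ids", "carrier_ids")
  if (is.character(v$mpc)) {
    mpc <- suppressWarnings(as.numeric(ifelse(v$mpc == ".", NA, v$mpc)))
    bad <- which(!is.finite(mpc) & !v$mpc %in% ".")
    if (length(bad)) .fail_row(path, "malformed mpc value", bad)
    v$mpc <- mpc
  }
  for (col in c("mac_internal", "mac_reference")) {
    x <- suppressWarnings(as.integer(v[[col]]))
    bad <- which(is.na(x))
    if (length(bad)) .fail_row(path, paste("malformed", col), bad)
    data.table::set(v, j = col, value = x)
  }
  validate_variants(v)
  v
}

#' Write a variants.tsv file
#' @param variants variant table.
#' @param path output path.
#' @export
write_variants <- function(variants, path) {
  out <- data.table::copy(data.table::as.data.table(variants))
  data.table::setnames(out, "carrier_ids", "sample_ids")
  out$mpc <- ifelse(is.finite(out$mpc), format(out$mpc, digits = 7), ".")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a samples.tsv file
#' @param path file path.
#' @return Sample `data.table`.
#' @export
read_samples <- function(path) {
  s <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "phenotype", "stratum", "sex")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!s$phenotype %in% c("case", "control"))
  if (length(bad)) .fail_row(path, "phenotype must be case|control", bad)
  bad <- which(!s$sex %in% c("male", "female"))
  if (length(bad)) .fail_row(path, "sex must be male|female", bad)
  bad <- which(is.na(s$stratum) | s$stratum == "")
  if (length(bad)) .fail_row(path, "empty stratum", bad)
  s
}

#' Write a samples.tsv file
#' @param samples sample table.
#' @param path output path.
#' @export
write_samples <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' Read a genes.tsv annotation file
#' @param path file path.
#' @return Gene annotation `data.table` with a derived `constrained` column.
#' @export
read_genes <- function(path) {
  g <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "pli", "has_possible_mpc_gt3", "has_possible_mpc_gt2",
            "lambda_ptv", "lambda_mis_gt2", "chrom_category",
            "excluded_clonal_haem")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (!"cnv_locus" %in% names(g)) g$cnv_locus <- NA_character_
  g$cnv_locus[g$cnv_locus %in% c("", ".")] <- NA_character_
  for (col in c("has_possible_mpc_gt3", "has_possible_mpc_gt2",
                "excluded_clonal_haem"))
    data.table::set(g, j = col, value = as.logical(g[[col]]))
  g$constrained <- g$pli >= 0.9
  g
}

#' Write a genes.tsv annotation file
#' @param genes gene annotation table.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  out <- data.table::copy(data.table::as.data.table(genes))
  out$constrained <- NULL
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a denovo.tsv file (gene_id, variant_class, observed, expected)
#' @param path file path.
#' @return De novo `data.table`.
#' @export
read_denovo <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "variant_class", "observed", "expected")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(d$observed < 0 | !is.finite(d$expected) | d$expected < 0)
  if (length(bad)) .fail_row(path, "invalid de novo counts", bad)
  d
}

#' Read a genesets.tsv file (set_name, gene_id, variant_class, filter)
#' @param path file path.
#' @return List of [geneset_spec()] objects.
#' @export
read_genesets <- function(path) {
  g <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("set_name", "gene_id", "variant_class", "filter")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(g, g$set_name), function(gg) {
    filt <- unique(gg$filter)
    cls <- unique(gg$variant_class)
    if (length(filt) != 1L || length(cls) != 1L)
      stop(path, ": set '", gg$set_name[1],
           "' mixes filters or variant classes")
    geneset_spec(gg$set_name[1], gg$gene_id,
                 variant_class = cls,
                 filter = if (filt == "singleton") "singleton" else "mac_cap",
                 mac_cap = if (grepl("^mac", filt)) {
                   n <- suppressWarnings(as.integer(sub("^mac", "", filt)))
                   if (is.na(n)) 5L else n
                 } else 5L)
  })
}

#' Write a simulated study to a directory of TSV files
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variants(study$variants, file.path(dir, "variants.tsv"))
  write_samples(study$samples, file.path(dir, "samples.tsv"))
  write_genes(study$genes, file.path(dir, "genes.tsv"))
  if (!is.null(study$denovo))
    data.table::fwrite(study$denovo, file.path(dir, "denovo.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir directory containing variants.tsv, samples.tsv, genes.tsv and
#'   optionally denovo.tsv.
#' @return List with `variants`, `samples`, `genes`, `denovo`.
#' @export
read_study <- function(dir) {
  dn <- file.path(dir, "denovo.tsv")
  list(variants = read_variants(file.path(dir, "variants.tsv")),
       samples = read_samples(file.path(dir, "samples.tsv")),
       genes = read_genes(file.path(dir, "genes.tsv")),
       denovo = if (file.exists(dn)) read_denovo(dn) else NULL)
}

#' Ingest variant records from a VCF
#'
#' Reads sites and genotypes from a VCF whose INFO field carries `GENE`,
#' `CSQ_CLASS` (PTV | missense | synonymous | other) and `MPC`, and converts
#' them to the variant table. The cohort MAC is counted from the genotypes;
#' the reference-panel MAC is taken from INFO key `MAC_REF` (0 if absent).
#' Requires the VariantAnnotation package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param chrom_category category assigned to all records (default
#'   autosomal/PAR).
#' @return Variant `data.table`.
#' @export
read_vcf_variants <- function(path, chrom_category = "autosomal_or_PAR") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF ingestion requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop(path, ": VCF has no GT genotypes")
  n_alt <- apply(gt, 1:2, function(g) if (is.na(g) || g %in% c(".", "./.")) 0L
                 else sum(strsplit(g, "[/|]")[[1]] == "1"))
  carriers <- apply(n_alt, 1L, function(r)
    paste(colnames(gt)[r > 0], collapse = ","))
  mac_ref <- if ("MAC_REF" %in% names(info)) as.integer(info$MAC_REF) else
    rep(0L, nrow(gt))
  v <- data.table::data.table(
    gene_id = as.character(info$GENE),
    carrier_ids = carriers,
    consequence = as.character(info$CSQ_CLASS),
    mpc = if ("MPC" %in% names(info)) as.numeric(info$MPC) else NA_real_,
    chrom_category = chrom_category,
    mac_internal = as.integer(rowSums(n_alt)),
    mac_reference = mac_ref)
  v <- v[v$mac_internal >= 1L, , drop = FALSE]
  validate_variants(v)
  v
}

#' Read a flat key-value configuration file
#'
#' Accepts either a JSON object or flat `key: value` / `key = value` lines
#' (comments with `#`). Scalars are auto-typed (logical, numeric, string);
#' comma-separated values become vectors.
#'
#' @param path config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  joined <- trimws(paste(txt, collapse = "\n"))
  if (startsWith(joined, "{")) return(jsonlite::fromJSON(joined))
  out <- list()
  for (ln in txt) {
    ln <- sub("#.*$", "", ln)
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop(path, ": malformed config line: ", ln)
    val <- trimws(m[3])
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    typed <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(typed)) typed
      else if (all(tolower(vals) %in% c("true", "false")))
        tolower(vals) == "true"
      else vals
    out[[m[2]]] <- parsed
  }
  out
}
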