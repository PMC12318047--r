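# shared fixture builders (all generated in code; no data files)

# a minimal variant record row
vrec <- function(gene = "G1", carriers = "s1", consequence = "PTV",
                 mpc = NA_real_, chrom = "autosomal_or_PAR",
                 mac_int = 1L, mac_ref = 0L) {
  variant_table(gene, carriers, consequence, mpc, chrom, mac_int, mac_ref)
}

# a tiny two-stratum sample table: n1 cases / n0 controls per stratum
tiny_samples <- function(n1 = c(4L, 3L), n0 = c(4L, 3L)) {
  rows <- list()
  for (s in seq_along(n1)) {
    rows[[s]] <- data.table::data.table(
      sample_id = c(sprintf("S%d_case_%d", s, seq_len(n1[s])),
                    sprintf("S%d_ctrl_%d", s, seq_len(n0[s]))),
      phenotype = rep(c("case", "control"), c(n1[s], n0[s])),
      stratum = sprintf("stratum%d", s),
      sex = "female")
  }
  data.table::rbindlist(rows)
}

# stratified 2x2 tables in the cmh_test() input layout
make_tables <- function(a, b, c, d) {
  data.table::data.table(stratum = sprintf("s%d", seq_along(a)),
                         sex = NA_character_, a = a, b = b, c = c, d = d)
}

# small default simulation for fast end-to-end tests
small_sim_config <- function(..., baseline_carrier_rate = 0.03) {
  sim_config(n_strata = 2L, stratum_sizes = list(c(300L, 300L), c(200L, 300L)),
             n_genes = 25L, baseline_carrier_rate = baseline_carrier_rate, ...)
}

# minimal single-sample VCF text for ingestion tests
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Class\">",
    "##INFO=<ID=MPC,Number=1,Type=Float,Description=\"MPC\">",
    "##INFO=<ID=MAC_REF,Number=1,Type=Integer,Description=\"Reference MAC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampA", "sampB", "sampC", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", "PASS",
          "GENE=G1;CSQ_CLASS=PTV;MAC_REF=0", "GT", "0/1", "0/0", "0/0",
          sep = "\t"),
    paste("1", "200", ".", "G", "C", ".", "PASS",
          "GENE=G2;CSQ_CLASS=missense;MPC=2.5;MAC_REF=3", "GT", "0/1", "1/1",
          "0/0", sep = "\t"),
    paste("1", "300", ".", "T", "A", ".", "PASS",
          "GENE=G3;CSQ_CLASS=synonymous;MAC_REF=0", "GT", "0/0", "0/0", "0/0",
          sep = "\t")), path)
  path
}
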