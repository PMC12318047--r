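# consequence-class taxonomy, MAC filters, burden counting, table I/O

test_that("class membership follows the strict-MPC truth table", {
  # hand-evaluated truth table over the MPC boundary grid
  mis <- vrec(consequence = "missense",
              mpc = c(1.9, 2.0, 2.1, 3.0, 3.1),
              carriers = sprintf("s%d", 1:5))
  expect_equal(class_membership(mis, "MPCgt2_only"),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(class_membership(mis, "PTV_plus_MPCgt2"),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(class_membership(mis, "PTV_plus_MPCgt3"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(class_membership(mis, "MPC_2_3"),
               c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(class_membership(mis, "PTV_only"), rep(FALSE, 5))
  expect_equal(class_membership(mis, "synonymous"), rep(FALSE, 5))

  # a damaging missense (3.2) joins every MPC class above its score
  hot <- vrec(consequence = "missense", mpc = 3.2)
  for (cl in c("PTV_plus_MPCgt3", "PTV_plus_MPCgt2", "MPCgt2_only"))
    expect_true(class_membership(hot, cl))
  expect_false(class_membership(hot, "PTV_only"))
  expect_false(class_membership(hot, "MPC_2_3"))

  # PTVs need no MPC and join the PTV-containing classes only
  ptv <- vrec(consequence = "PTV")
  expect_true(class_membership(ptv, "PTV_only"))
  expect_true(class_membership(ptv, "PTV_plus_MPCgt3"))
  expect_true(class_membership(ptv, "PTV_plus_MPCgt2"))
  expect_false(class_membership(ptv, "MPCgt2_only"))
})

test_that("missense without an MPC score is a data error", {
  bad <- data.table::data.table(
    gene_id = "G1", carrier_ids = "s1", consequence = "missense",
    mpc = NA_real_, chrom_category = "autosomal_or_PAR",
    mac_internal = 1L, mac_reference = 0L)
  expect_error(class_membership(bad, "MPCgt2_only"), "MPC")
  expect_error(validate_variants(bad), "MPC")
})

test_that("class lattice: damaging classes nest as expected", {
  set.seed(71)
  n <- 400
  cons <- sample(c("PTV", "missense", "synonymous", "other"), n, replace = TRUE)
  mpc <- ifelse(cons == "missense", runif(n, 0, 5), NA_real_)
  v <- vrec(carriers = sprintf("s%d", 1:n), consequence = cons, mpc = mpc)
  m_gt2o <- class_membership(v, "MPCgt2_only")
  m_p2 <- class_membership(v, "PTV_plus_MPCgt2")
  m_p3 <- class_membership(v, "PTV_plus_MPCgt3")
  m_ptv <- class_membership(v, "PTV_only")
  m_23 <- class_membership(v, "MPC_2_3")
  expect_true(all(!m_gt2o | m_p2))        # MPCgt2_only subset of PTV+MPC>2
  expect_true(all(!m_p3 | m_p2))          # PTV+MPC>3 subset of PTV+MPC>2
  # PTV, MPC 2-3 and missense MPC>3 partition the PTV+MPC>2 members
  m_mis3 <- cons == "missense" & mpc > 3
  expect_equal(m_p2, m_ptv | m_23 | m_mis3)
  expect_equal(as.integer(m_p2), as.integer(m_ptv) + as.integer(m_23) +
                 as.integer(m_mis3))      # disjoint union
})

test_that("rarity filter is inclusive at the cap and two-sided", {
  v <- vrec(carriers = sprintf("s%d", 1:3),
            mac_int = c(5L, 6L, 1L), mac_ref = c(5L, 0L, 6L))
  expect_equal(passes_rare_filter(v), c(TRUE, FALSE, FALSE))
  expect_equal(passes_rare_filter(v, mac_cap = 6L), c(TRUE, TRUE, TRUE))
  expect_error(passes_rare_filter(v, mac_cap = 0L), "mac_cap")
})

test_that("singleton means cohort MAC 1 and reference-panel absence", {
  v <- vrec(carriers = sprintf("s%d", 1:3),
            mac_int = c(1L, 1L, 2L), mac_ref = c(0L, 1L, 0L))
  expect_equal(is_singleton(v), c(TRUE, FALSE, FALSE))
  # singleton implies rare for any cap >= 1
  for (cap in c(1L, 3L, 5L))
    expect_true(all(!is_singleton(v) | passes_rare_filter(v, cap)))
})

test_that("filters are pure and order-independent", {
  set.seed(72)
  v <- vrec(carriers = sprintf("s%d", 1:50),
            mac_int = sample(1:8, 50, TRUE), mac_ref = sample(0:8, 50, TRUE))
  perm <- sample.int(50)
  expect_equal(passes_rare_filter(v)[perm],
               passes_rare_filter(v[perm, , drop = FALSE]))
  expect_equal(is_singleton(v)[perm], is_singleton(v[perm, , drop = FALSE]))
})

test_that("exome-wide burden equals a brute-force recount", {
  samples <- tiny_samples(c(5L, 4L), c(5L, 4L))
  expect_equal(sum(exome_wide_burden(samples, vrec()[0, ])), 0L)

  v <- vrec(gene = c("G1", "G2"),
            carriers = c("S1_case_1,S1_ctrl_2", "S1_case_1"),
            consequence = "PTV", mac_int = c(2L, 1L))
  b <- exome_wide_burden(samples, v)
  expect_equal(unname(b["S1_case_1"]), 2L)
  expect_equal(unname(b["S1_ctrl_2"]), 1L)
  expect_equal(sum(b), 3L)

  # random study: total burden = qualifying (variant, carrier) pairs
  set.seed(73)
  st <- simulate_study(small_sim_config(seed = 41L))
  keep <- passes_rare_filter(st$variants)
  b <- exome_wide_burden(st$samples, st$variants)
  recount <- 0L
  for (i in which(keep))
    recount <- recount +
      length(strsplit(st$variants$carrier_ids[i], ",")[[1]])
  expect_equal(sum(b), recount)

  # unknown carrier id is a data error
  v2 <- vrec(carriers = "nobody")
  expect_error(exome_wide_burden(samples, v2), "nobody")
})

test_that("study TSV round trip preserves the tables", {
  st <- simulate_study(small_sim_config(seed = 42L))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$variants$gene_id, st$variants$gene_id)
  expect_equal(back$variants$mpc, st$variants$mpc, tolerance = 1e-6)
  expect_equal(back$variants$mac_reference, st$variants$mac_reference)
  expect_equal(back$samples$sample_id, st$samples$sample_id)
  expect_equal(back$samples$exome_burden, st$samples$exome_burden)
  expect_equal(back$genes$gene_id, st$genes$gene_id)
  expect_equal(back$genes$constrained, st$genes$constrained)
  expect_equal(back$denovo$observed, st$denovo$observed)
})

test_that("malformed TSV rows fail with the offending row named", {
  dir <- withr::local_tempdir()
  st <- simulate_study(small_sim_config(seed = 43L))
  write_study(st, dir)
  path <- file.path(dir, "variants.tsv")
  lines <- readLines(path)
  lines[3] <- sub("\t[0-9]+\t[0-9]+$", "\tnot_a_number\t0", lines[3])
  writeLines(lines, path)
  expect_error(read_variants(path), "row")
})

test_that("VCF ingestion recovers genes, carriers and MACs", {
  skip_if_not_installed("VariantAnnotation")
  path <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"))
  v <- suppressWarnings(read_vcf_variants(path))
  expect_equal(nrow(v), 2L)  # the no-carrier site is dropped
  expect_equal(v$gene_id, c("G1", "G2"))
  expect_equal(v$mac_internal, c(1L, 3L))  # het + (het + hom alt)
  expect_equal(v$carrier_ids, c("sampA", "sampA,sampB"))
  expect_equal(v$mpc, c(NA, 2.5))
  expect_equal(v$mac_reference, c(0L, 3L))
})
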