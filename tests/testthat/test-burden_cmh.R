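# stratified 2x2 construction and the CMH test

test_that("build_tables matches a brute-force carrier recount", {
  set.seed(61)
  st <- simulate_study(small_sim_config(seed = 61L))
  keep <- passes_rare_filter(st$variants)
  v <- st$variants[keep, , drop = FALSE]
  for (g in sample(st$genes$gene_id, 5)) {
    tabs <- build_tables(g, "PTV_only", v, st$samples)
    # brute force: loop over samples, ask if each carries a PTV in g
    vv <- v[v$gene_id == g & v$consequence == "PTV", ]
    carr <- unique(unlist(strsplit(vv$carrier_ids, ",")))
    for (srt in unique(st$samples$stratum)) {
      ss <- st$samples[st$samples$stratum == srt, ]
      a <- sum(ss$phenotype == "case" & ss$sample_id %in% carr)
      c_ <- sum(ss$phenotype == "control" & ss$sample_id %in% carr)
      row <- tabs[tabs$stratum == srt, ]
      expect_equal(row$a, a)
      expect_equal(row$c, c_)
      expect_equal(row$a + row$b, sum(ss$phenotype == "case"))
      expect_equal(row$c + row$d, sum(ss$phenotype == "control"))
    }
  }
  # carriers only in stratum 1 still yields one table per stratum
  samples <- tiny_samples()
  v1 <- vrec(carriers = "S1_case_1")
  tabs <- build_tables("G1", "PTV_only", v1, samples)
  expect_equal(nrow(tabs), 2L)
  expect_equal(tabs$a[tabs$stratum == "stratum2"], 0L)
  expect_error(build_tables("G1", "PTV_only", vrec(carriers = "ghost"),
                            samples), "ghost")
})

test_that("X non-PAR genes split configured strata by sex", {
  samples <- tiny_samples(c(6L, 4L), c(6L, 4L))
  samples$sex <- rep(c("male", "female"), length.out = nrow(samples))
  v <- vrec(carriers = "S1_case_1", chrom = "X_nonPAR")
  tabs <- build_tables("G1", "PTV_only", v, samples,
                       sex_split_strata = "stratum1")
  s1 <- tabs[tabs$stratum == "stratum1", ]
  expect_equal(nrow(s1), 2L)                      # male + female tables
  expect_equal(sum(s1$a + s1$b), 6L)              # case totals partition
  expect_equal(nrow(tabs[tabs$stratum == "stratum2", ]), 1L)
})

test_that("single-stratum CMH reduces to the classical score chi-square", {
  tabs <- make_tables(10, 990, 2, 998)
  r <- cmh_test(tabs, continuity = FALSE)
  # closed-form score statistic n(ad - bc)^2 / (n1 n0 m1 m0)
  n <- 2000
  oracle <- n * (10 * 998 - 990 * 2)^2 / (1000 * 1000 * 12 * 1988)
  # the CMH variance uses n-1; the classical score test uses n
  expect_equal(r$statistic * n / (n - 1), oracle, tolerance = 1e-12)
  expect_equal(r$or_mh, (10 * 998) / (990 * 2), tolerance = 1e-12)
  expect_equal(r$p_two_sided,
               pchisq(r$statistic, 1, lower.tail = FALSE))
})

test_that("cmh_test agrees with mantelhaen.test on random strata", {
  set.seed(62)
  for (i in 1:8) {
    k <- sample(2:4, 1)  # k = 1 is covered by the closed-form test above
    tabs <- make_tables(a = sample(0:15, k, TRUE), b = sample(50:200, k, TRUE),
                        c = sample(0:15, k, TRUE), d = sample(50:200, k, TRUE))
    arr <- array(0, c(2, 2, k))
    for (j in 1:k)
      arr[, , j] <- matrix(c(tabs$a[j], tabs$b[j], tabs$c[j], tabs$d[j]),
                           2, byrow = TRUE)
    for (corr in c(TRUE, FALSE)) {
      mine <- cmh_test(tabs, continuity = corr)
      if (!mine$testable || mine$n_informative_strata == 0) next
      ref <- mantelhaen.test(arr, correct = corr)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
      expect_equal(mine$or_mh, unname(ref$estimate), tolerance = 1e-10)
    }
  }
})

test_that("degenerate and symmetric tables behave as documented", {
  # perfect symmetry: OR 1, statistic 0 before correction
  sym <- make_tables(c(5, 5), c(95, 95), c(5, 5), c(95, 95))
  r <- cmh_test(sym, continuity = FALSE)
  expect_equal(r$or_mh, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1)

  # all carriers in cases: infinite OR flag, finite p
  onesided <- make_tables(4, 96, 0, 100)
  r2 <- cmh_test(onesided)
  expect_identical(r2$or_mh, Inf)
  expect_identical(r2$ci95[2], Inf)
  expect_true(is.finite(r2$p_two_sided) && r2$p_two_sided < 1)

  # no informative stratum: flagged untestable, not an error
  r3 <- cmh_test(make_tables(0, 100, 0, 100))
  expect_false(r3$testable)
  expect_true(is.na(r3$p_two_sided))

  expect_error(cmh_test(make_tables(-1, 10, 2, 10)), "negative")
})

test_that("continuity correction is conservative and order is irrelevant", {
  set.seed(63)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    tabs <- make_tables(a = sample(0:10, k, TRUE), b = sample(20:80, k, TRUE),
                        c = sample(0:10, k, TRUE), d = sample(20:80, k, TRUE))
    r_c <- cmh_test(tabs, continuity = TRUE)
    r_n <- cmh_test(tabs, continuity = FALSE)
    if (!r_c$testable) next
    expect_gte(r_c$p_two_sided, r_n$p_two_sided)
    if (k > 1) {
      perm <- cmh_test(tabs[sample.int(k), ], continuity = TRUE)
      expect_equal(perm$statistic, r_c$statistic)
      expect_equal(perm$or_mh, r_c$or_mh)
      expect_equal(perm$ci95, r_c$ci95)
    }
  }
})

test_that("within-stratum label permutation yields uniform p-values", {
  set.seed(64)
  n1 <- c(2000, 1600); n0 <- c(2000, 2400); ncar <- c(400, 300)
  ps <- replicate(800, {
    a <- c(rhyper(1, n1[1], n0[1], ncar[1]), rhyper(1, n1[2], n0[2], ncar[2]))
    tabs <- make_tables(a, n1 - a, ncar - a, n0 - (ncar - a))
    cmh_test(tabs, continuity = FALSE)$p_two_sided
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("inclusion rule honours strata, largest stratum and exclusions", {
  samples <- tiny_samples()
  ann <- data.table::data.table(gene_id = "G1", excluded_clonal_haem = FALSE,
                                has_possible_mpc_gt3 = TRUE,
                                has_possible_mpc_gt2 = TRUE)
  # carriers in one non-largest stratum only -> not testable
  one <- make_tables(c(0, 2), c(4, 1), c(0, 0), c(4, 3))
  one$stratum <- c("stratum1", "stratum2")
  expect_false(gene_is_testable("G1", "PTV_only", one, ann, "stratum1"))
  # carriers only in the largest stratum -> testable
  expect_true(gene_is_testable("G1", "PTV_only", one, ann, "stratum2"))
  # carriers in two strata -> testable regardless
  two <- make_tables(c(1, 2), c(3, 1), c(0, 0), c(4, 3))
  two$stratum <- c("stratum1", "stratum2")
  expect_true(gene_is_testable("G1", "PTV_only", two, ann, "stratum1"))
  # clonal-haematopoiesis exclusion dominates
  annx <- data.table::copy(ann); annx$excluded_clonal_haem <- TRUE
  expect_false(gene_is_testable("TET2", "PTV_only", two, annx, "stratum1"))
  # missense classes need the possible-variant flag
  annf <- data.table::copy(ann); annf$has_possible_mpc_gt3 <- FALSE
  expect_false(gene_is_testable("G1", "PTV_plus_MPCgt3", two, annf, "stratum1"))
  expect_true(gene_is_testable("G1", "PTV_plus_MPCgt2", two, annf, "stratum1"))
  expect_error(gene_is_testable("G1", "PTV_only", two, ann, "nowhere"),
               "largest_stratum")
})

test_that("burden scan counts tests per class over defined genes", {
  st <- simulate_study(small_sim_config(seed = 65L))
  st$genes$has_possible_mpc_gt3 <- TRUE
  st$genes$has_possible_mpc_gt2 <- TRUE
  keep <- passes_rare_filter(st$variants)
  st$variants <- st$variants[keep, , drop = FALSE]
  scan <- run_burden_scan(st)
  expect_equal(nrow(scan), 4L * nrow(st$genes))
  expect_true(all(scan$counted))

  # vectorized scan equals the per-gene reference path
  for (i in sample(which(scan$testable), 8)) {
    tabs <- build_tables(scan$gene_id[i], scan$variant_class[i],
                         st$variants, st$samples)
    ref <- cmh_test(tabs)
    expect_equal(scan$p_cc[i], ref$p_two_sided)
    expect_equal(scan$or_mh[i], ref$or_mh)
    expect_equal(scan$ci_lo[i], unname(ref$ci95[1]))
    expect_equal(scan$ci_hi[i], unname(ref$ci95[2]))
  }

  # an empty study warns and yields no carrier-backed tests
  empty <- simulate_study(small_sim_config(seed = 65L,
                                           baseline_carrier_rate = 0))
  expect_warning(scan0 <- run_burden_scan(empty), "no variant records")
  expect_true(all(!scan0$testable))
})
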