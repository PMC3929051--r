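test_that("call-rate filter removes exactly the planted bad samples/markers", {
  set.seed(42)
  n <- 100; m <- 500
  dosage <- matrix(rbinom(n * m, 2, 0.5), n, m)
  bad_s <- sample(n, 3)
  bad_m <- sample(m, 7)
  for (i in bad_s) dosage[i, sample(m, 20)] <- NA_integer_   # cr 0.96
  for (j in bad_m) dosage[sample(setdiff(seq_len(n), bad_s), 10), j] <- NA_integer_
  gm <- genotype_matrix(dosage, rep(c("a", "b"), length.out = n))
  out <- call_rate_filter(gm, qc_thresholds())
  st <- attr(out, "qc_step")
  # independent recount of missingness
  exp_s <- rownames(gm$dosage)[rowMeans(is.na(dosage)) > 0.01]
  exp_m <- gm$map$marker_id[colMeans(is.na(dosage)) > 0.01]
  expect_setequal(st$removed_sample_ids, exp_s)
  expect_setequal(st$removed_marker_ids, exp_m)
  expect_true(all(rownames(gm$dosage)[bad_s] %in% st$removed_sample_ids))

  clean <- genotype_matrix(matrix(1L, 4, 4), rep("a", 4))
  out2 <- call_rate_filter(clean)
  expect_identical(out2$dosage, clean$dosage)
})

test_that("MAF filter removes low-MAF and monomorphic markers exactly", {
  # dosages [0,0,0,1]: freq 1/8 = 0.125, retained at 0.05
  gm <- genotype_matrix(cbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L), c(1L, 1L, 2L, 0L)),
                        rep("a", 4))
  out <- maf_filter(gm, 0.05)
  expect_identical(attr(out, "qc_step")$removed_marker_ids, gm$map$marker_id[2])
  expect_identical(ncol(out$dosage), 2L)

  # planted low-MAF markers in a random panel, frequency recount oracle
  set.seed(7)
  n <- 60; m <- 400
  freqs <- runif(m, 0.2, 0.8)
  low <- sample(m, 50)
  freqs[low] <- runif(50, 0.001, 0.03)
  dosage <- matrix(rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  gm2 <- genotype_matrix(dosage, rep("a", n))
  out2 <- maf_filter(gm2, 0.05)
  f_hat <- colMeans(dosage) / 2
  expected_drop <- gm2$map$marker_id[pmin(f_hat, 1 - f_hat) < 0.05]
  expect_setequal(attr(out2, "qc_step")$removed_marker_ids, expected_drop)
})

test_that("heterozygosity outlier filter flags the contaminated sample only", {
  set.seed(11)
  n <- 100; m <- 2000
  dosage <- matrix(rbinom(n * m, 2, 0.5), n, m)        # h ~ 0.5
  dosage[1, ] <- rep(c(1L, 1L, 1L, 1L, 0L), m / 5)     # h = 0.8, far outlier
  gm <- genotype_matrix(dosage, rep("a", n))
  out <- heterozygosity_outlier_filter(gm, het_fdr = 0.01)
  st <- attr(out, "qc_step")
  # independent recomputation: robust-z upper-tail p + BH
  h <- rowMeans(dosage == 1L)
  p <- pnorm(h, median(h), mad(h), lower.tail = FALSE)
  expect_setequal(st$removed_sample_ids, rownames(gm$dosage)[bh_oracle(p, 0.01)])
  expect_true(rownames(gm$dosage)[1] %in% st$removed_sample_ids)

  # all-equal heterozygosity: degenerate scale, step skipped with warning
  same <- genotype_matrix(matrix(1L, 12, 10), rep("a", 12))
  expect_warning(out2 <- heterozygosity_outlier_filter(same), "degenerate")
  expect_identical(nrow(out2$dosage), 12L)
})

test_that("BH rejection matches the brute-force max-k rule", {
  # p = [0.001, 0.008, 0.04, 0.9]: at q = 0.01 only p_(1) <= 1*0.01/4 holds
  # (0.008 > 2*0.01/4), so one rejection; at q = 0.05 the first two reject
  expect_identical(bh_reject(c(0.001, 0.008, 0.04, 0.9), 0.01),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(bh_reject(c(0.001, 0.008, 0.04, 0.9), 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_reject(p, q), bh_oracle(p, q))
  }
})

test_that("HWE exact test equals the enumeration oracle and its invariances", {
  expect_identical(hwe_exact_test(5, 0, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), hwe_enum_oracle(1, 0, 1))
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 6, 0), hwe_enum_oracle(0, 6, 0))
  # all configurations with n <= 6 here (acceptance covers n <= 10)
  for (n in 1:6) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      p <- hwe_exact_test(n0, n1, n2)
      expect_equal(p, hwe_enum_oracle(n0, n1, n2), tolerance = 1e-12)
      expect_equal(p, hwe_exact_test(n2, n1, n0))  # allele relabeling
      expect_true(p > 0 && p <= 1)
    }
  }
})

test_that("within-breed HWE filter removes planted disequilibrium markers", {
  sim <- small_panel(n_breeds = 3, n_per_breed = 50, n_chr = 3,
                     markers_per_chr = 100, missing_rate = 0,
                     seed = 21, n_hwe_violating_markers = 20)
  gm <- sim$genotypes
  out <- hwe_filter_within_breeds(gm, 0.01)
  removed <- attr(out, "qc_step")$removed_marker_ids
  planted <- gm$map$marker_id[sim$truth$hwe_violating]
  expect_true(all(planted %in% removed))   # all-het in one breed, n = 50
  # false-removal rate of clean markers near per-breed type-I at alpha = 0.01
  clean <- setdiff(gm$map$marker_id, planted)
  fpr <- mean(clean %in% removed)
  expect_lt(fpr, 3 * 0.01)  # 3 breeds x conservative exact test

  # a marker in perfect HWE proportions everywhere is retained
  perfect <- genotype_matrix(
    matrix(rep(c(rep(0L, 5), rep(1L, 10), rep(2L, 5)), 2), 40, 1),
    rep(c("x", "y"), each = 20)
  )
  kept <- hwe_filter_within_breeds(perfect, 0.01)
  expect_identical(ncol(kept$dosage), 1L)
})

test_that("full QC cascade: order, second-pass interaction, idempotence", {
  # engineered fixture: sample s01 passes call rate in pass 1 (1/100 missing)
  # but fails in pass 2 after 20 monomorphic markers are MAF-dropped
  set.seed(31)
  n <- 20; m <- 100
  base <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))  # perfect HWE at p = 0.5
  dosage <- vapply(seq_len(m), function(j) sample(base), integer(n))
  mono <- sample(m, 20)
  dosage[, mono] <- 0L
  poly <- setdiff(seq_len(m), mono)
  dosage[1, poly[1]] <- NA_integer_   # 99/100 calls in pass 1, 79/80 in pass 2
  gm <- genotype_matrix(dosage, rep("herd", n))
  # marker call-rate threshold relaxed so the single missing call does not
  # remove the marker itself at this desk scale (19/20 calls)
  th <- qc_thresholds(min_call_rate_marker = 0.9)
  res <- suppressWarnings(run_qc_pipeline(gm, th))
  tab <- qc_report_table(res$report)
  expect_identical(tab$step[1:3], c("autosome_map_restriction", "call_rate", "maf"))
  expect_identical(tab$markers_removed[tab$step == "maf"], 20L)
  expect_identical(tab$samples_removed[tab$step == "call_rate"], 0L)
  expect_identical(tab$samples_removed[tab$step == "call_rate_pass2"], 1L)
  expect_false("sample0001" %in% rownames(res$genotypes$dosage))

  # report removals reconcile with initial - final dimensions
  expect_identical(res$report$initial_dim[1] - sum(tab$samples_removed),
                   res$report$final_dim[1])
  expect_identical(res$report$initial_dim[2] - sum(tab$markers_removed),
                   res$report$final_dim[2])

  # clean data: the pipeline is a fixed point of itself (second check removes 0)
  sim <- small_panel(n_breeds = 3, n_per_breed = 40, n_chr = 3,
                     markers_per_chr = 80, missing_rate = 0, seed = 32)
  r1 <- run_qc_pipeline(sim$genotypes)
  t1 <- qc_report_table(r1$report)
  expect_identical(t1$samples_removed[t1$step == "call_rate_pass2"], 0L)
  expect_identical(t1$markers_removed[t1$step == "maf_pass2"], 0L)
  r2 <- run_qc_pipeline(r1$genotypes)
  expect_identical(r2$genotypes$dosage, r1$genotypes$dosage)
  expect_identical(sum(qc_report_table(r2$report)$markers_removed), 0L)
})
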