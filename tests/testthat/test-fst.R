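test_that("nei_chesser_locus matches the straight-line oracle", {
  # worked two-population table
  gc <- rbind(c(30, 40, 30), c(10, 40, 50))
  res <- nei_chesser_locus(gc)
  ora <- nc_oracle(gc)
  for (f in c("H_O", "H_S", "H_T", "fst")) {
    expect_equal(res[[f]], ora[[f]], tolerance = 1e-12)
  }
  # random tables (acceptance runs 1,000; this is the unit-scale check)
  set.seed(101)
  for (i in 1:200) {
    gc <- random_count_table()
    res <- nei_chesser_locus(gc)
    ora <- nc_oracle(gc)
    expect_equal(res$fst, ora$fst, tolerance = 1e-12)
    # note: H_S can slightly exceed H_T for undifferentiated tables — the
    # corrected estimator is unbiased, hence fst is allowed to be negative
    expect_lte(res$fst, 1)
    expect_lte(res$n_tilde, mean(res$n_i) + 1e-12)
    expect_true(res$H_O >= 0 && res$H_O <= 1)
  }
})

test_that("fixation and symmetry limits behave exactly", {
  # opposite fixation: H_O = H_S = 0, H_T = 0.5, fst = 1
  res <- nei_chesser_locus(rbind(c(50, 0, 0), c(0, 0, 50)))
  expect_identical(res$H_O, 0)
  expect_identical(res$H_S, 0)
  expect_equal(res$H_T, 0.5)
  expect_equal(res$fst, 1.0)
  # identical genotype counts: fst ~ 0, small negative allowed
  res2 <- nei_chesser_locus(rbind(c(30, 40, 30), c(30, 40, 30)))
  expect_lt(abs(res2$fst), 0.02)
  expect_lt(res2$fst, 1e-12)  # exactly non-positive by symmetry
})

test_that("allele-label invariance and degenerate inputs", {
  set.seed(102)
  for (i in 1:50) {
    gc <- random_count_table()
    flipped <- gc[, 3:1]
    expect_equal(nei_chesser_locus(gc)$fst, nei_chesser_locus(flipped)$fst,
                 tolerance = 1e-12)
  }
  # monomorphic overall: H_T = 0 -> NaN
  expect_true(is.nan(nei_chesser_locus(rbind(c(10, 0, 0), c(20, 0, 0)))$fst))
  # empty subpopulation dropped with warning
  expect_warning(res <- nei_chesser_locus(rbind(c(10, 5, 5), c(0, 0, 0), c(5, 5, 10))),
                 "dropped")
  expect_identical(res$s, 2L)
  expect_error(nei_chesser_locus(rbind(c(10, 5, 5), c(0, 0, 0))), "at least 2")
})

test_that("fst_profile matches per-locus calls and handles groupings", {
  sim <- small_panel(n_breeds = 3, n_per_breed = 15, n_chr = 2,
                     markers_per_chr = 30, missing_rate = 0.05, seed = 103)
  gm <- sim$genotypes
  prof <- fst_profile(gm)
  expect_length(prof, ncol(gm$dosage))
  # spot-check five loci against the single-locus entry point
  for (j in c(1, 7, 20, 41, 60)) {
    gc <- t(vapply(levels(gm$breed), function(b) {
      dj <- gm$dosage[gm$breed == b, j]
      c(sum(dj == 0, na.rm = TRUE), sum(dj == 1, na.rm = TRUE), sum(dj == 2, na.rm = TRUE))
    }, numeric(3)))
    expect_equal(unname(prof[j]), nei_chesser_locus(gc)$fst, tolerance = 1e-12)
  }
  expect_error(fst_profile(gm, rep("one", nrow(gm$dosage))), "at least 2")
  # NaN only at monomorphic loci
  mono <- colSums(gm$dosage, na.rm = TRUE) == 0 |
    colSums(2L - gm$dosage, na.rm = TRUE) == 0
  expect_identical(unname(is.nan(prof)), unname(mono))
})

test_that("one-vs-rest profiles: 2-breed symmetry, breed-specific signal, size guard", {
  sim <- small_panel(n_breeds = 2, n_per_breed = 30, n_chr = 2,
                     markers_per_chr = 40, missing_rate = 0, seed = 104)
  prof <- one_vs_rest_profiles(sim$genotypes)
  expect_equal(prof[[1]], prof[[2]], tolerance = 1e-12)

  # a divergent locus carried by breed1 only shows up in breed1's contrast
  blocks <- list(selected_block(1, 17, 8, F_selected = 0.6, affected_breeds = 1))
  sim2 <- small_panel(n_breeds = 4, n_per_breed = 40, n_chr = 2,
                      markers_per_chr = 48, F = 0.03, missing_rate = 0,
                      seed = 105, selected_blocks = blocks)
  ovr <- one_vs_rest_profiles(sim2$genotypes)
  sel <- sim2$truth$selected
  focal_gap <- mean(ovr$breed1[sel], na.rm = TRUE) - mean(ovr$breed1[!sel], na.rm = TRUE)
  other_gap <- mean(ovr$breed3[sel], na.rm = TRUE) - mean(ovr$breed3[!sel], na.rm = TRUE)
  expect_gt(focal_gap, 5 * max(other_gap, 0.01))

  tiny <- subset_genotypes(sim$genotypes, samples = c(1, 31:60))
  expect_error(one_vs_rest_profiles(tiny), "fewer than 2")
})

test_that("window_average semantics: groups, sliding, chromosome containment", {
  map4 <- data.frame(marker_id = paste0("m", 1:4), chromosome = "1",
                     position_bp = c(100L, 200L, 300L, 400L),
                     allele_a = "A", allele_b = "C")
  v <- c(0.1, 0.2, 0.3, 0.4)
  grp <- window_average(v, map4, width = 2, mode = "groups")
  expect_equal(grp$mean_fst, c(0.15, 0.35))
  sld <- window_average(v, map4, width = 2, mode = "sliding")
  expect_equal(sld$mean_fst, c(0.15, 0.25, 0.35))

  # constant vector: every window mean equals the constant
  map10 <- data.frame(marker_id = paste0("c", 1:10), chromosome = rep(c("1", "2"), each = 5),
                      position_bp = rep(1:5 * 10L, 2), allele_a = "A", allele_b = "C")
  cst <- window_average(rep(0.1, 10), map10, width = 3, mode = "groups")
  expect_true(all(cst$mean_fst == 0.1))

  # windows never span chromosomes: 2 chromosomes x 5 markers, width 8
  win <- window_average(seq(0.01, 0.10, by = 0.01), map10, width = 8, mode = "groups")
  expect_identical(nrow(win), 2L)
  expect_identical(win$chromosome, c("1", "2"))
  expect_identical(win$n_markers, c(5L, 5L))

  # remainder rule: 10 markers width 4 -> remainder 2 >= ceiling(4/2), kept
  map_c1 <- data.frame(marker_id = paste0("r", 1:10), chromosome = "1",
                       position_bp = 1:10 * 10L, allele_a = "A", allele_b = "C")
  wr <- window_average(1:10 / 10, map_c1, width = 4, mode = "groups")
  expect_identical(wr$n_markers, c(4L, 4L, 2L))
  # 10 markers width 7 -> remainder 3 >= ceiling(7/2)? no (3 < 4), merged
  wr2 <- window_average(1:10 / 10, map_c1, width = 7, mode = "groups")
  expect_identical(wr2$n_markers, 10L)
  # 11 markers width 6 -> remainder 5 >= 3, kept
  map_c2 <- rbind(map_c1, data.frame(marker_id = "r11", chromosome = "1",
                                     position_bp = 110L, allele_a = "A", allele_b = "C"))
  wr3 <- window_average(1:11 / 10, map_c2, width = 6, mode = "groups")
  expect_identical(wr3$n_markers, c(6L, 5L))

  # NaN policy: excluded from means, all-NaN window dropped; the trailing
  # single marker (< ceiling(3/2)) merges into the third block
  v2 <- c(NaN, 0.2, 0.4, NaN, NaN, NaN, 0.5, 0.1, 0.3, NaN)
  wn <- window_average(v2, map_c1, width = 3, mode = "groups")
  expect_equal(wn$mean_fst, c(0.3, 0.3))
  expect_identical(wn$window, c(1L, 3L))  # window 2 (all NaN) dropped

  # width 1 sliding is the identity on finite entries
  w1 <- window_average(v2, map_c1, width = 1, mode = "sliding")
  expect_equal(w1$mean_fst, v2[is.finite(v2)])
})

test_that("quantile thresholds use linear order-statistic interpolation", {
  th <- quantile_thresholds(1:100, 0.01, 0.99)
  expect_equal(unname(th), c(1.99, 99.01))
  same <- quantile_thresholds(rep(0.3, 10))
  expect_equal(unname(same), c(0.3, 0.3))
  expect_error(quantile_thresholds(1:10, 0.9, 0.1), "q_low")
})

test_that("outlier regions merge consecutive windows and respect injection", {
  # synthetic window table: outliers at group indices 4,5,6 and 20
  sim <- small_panel(n_breeds = 2, n_per_breed = 20, n_chr = 1,
                     markers_per_chr = 50, missing_rate = 0, seed = 106)
  scan <- fst_scan(sim$genotypes, width = 2, mode = "groups")
  scan$windows$outlier_high <- scan$windows$window %in% c(4, 5, 6, 20)
  reg <- call_outlier_regions(scan)
  expect_identical(nrow(reg), 2L)
  expect_identical(reg$n_windows, c(3L, 1L))
  scan$windows$outlier_high <- rep(FALSE, nrow(scan$windows))
  expect_identical(nrow(call_outlier_regions(scan)), 0L)

  # injected divergent block recovered as one covering region
  blocks <- list(selected_block(2, 25, 8, F_selected = 0.5, affected_breeds = 1:3))
  sim2 <- small_panel(n_breeds = 3, n_per_breed = 40, n_chr = 4,
                      markers_per_chr = 64, F = 0.05, missing_rate = 0,
                      seed = 107, selected_blocks = blocks)
  scan2 <- fst_scan(sim2$genotypes, width = 8, mode = "groups")
  reg2 <- call_outlier_regions(scan2)
  sel_pos <- sim2$genotypes$map$position_bp[sim2$truth$selected]
  on_chr2 <- reg2[reg2$chromosome == "2", ]
  expect_gte(nrow(on_chr2), 1L)
  expect_true(any(on_chr2$start_bp <= min(sel_pos) & on_chr2$end_bp >= max(sel_pos)))
})

test_that("region annotation follows BED half-open convention", {
  regions <- data.frame(chromosome = "6", start_bp = 37000001L, end_bp = 38760000L,
                        n_windows = 1L, n_markers = 8L, max_fst = 0.3, mean_fst = 0.2)
  genes <- data.frame(chrom = "6", start = 37500000L, end = 38100000L, name = "KIT_like")
  ann <- annotate_regions(regions, genes)
  expect_identical(ann$overlaps, "KIT_like")
  # adjacent but not overlapping under half-open coordinates
  adj <- data.frame(chrom = "6", start = 38760000L, end = 39000000L, name = "next_gene")
  expect_identical(annotate_regions(regions, adj)$overlaps, "")
  before <- data.frame(chrom = "6", start = 36000000L, end = 37000000L, name = "prev_gene")
  expect_identical(annotate_regions(regions, before)$overlaps, "")

  # randomized intervals match brute-force all-pairs overlap
  set.seed(108)
  regs <- data.frame(chromosome = sample(c("1", "2"), 30, TRUE),
                     start_bp = sample(1e6, 30), n_windows = 1L, n_markers = 1L,
                     max_fst = 0, mean_fst = 0)
  regs$end_bp <- regs$start_bp + sample(1e5, 30)
  ivs <- data.frame(chrom = sample(c("1", "2"), 40, TRUE), start = sample(1e6, 40))
  ivs$end <- ivs$start + sample(1e5, 40)
  ivs$name <- paste0("g", 1:40)
  ann2 <- annotate_regions(regs, ivs)
  for (i in seq_len(nrow(regs))) {
    hits <- character(0)
    for (j in seq_len(nrow(ivs))) {
      if (regs$chromosome[i] == ivs$chrom[j] &&
          max(regs$start_bp[i] - 1, ivs$start[j]) < min(regs$end_bp[i], ivs$end[j])) {
        hits <- c(hits, ivs$name[j])
      }
    }
    expect_identical(ann2$overlaps[i], paste(hits, collapse = ","))
  }
})

test_that("permuting breed labels destroys injected outliers", {
  blocks <- list(selected_block(1, 33, 8, F_selected = 0.5, affected_breeds = 1:3))
  sim <- small_panel(n_breeds = 3, n_per_breed = 30, n_chr = 3,
                     markers_per_chr = 64, F = 0.05, missing_rate = 0,
                     seed = 109, selected_blocks = blocks)
  gm <- sim$genotypes
  scan <- fst_scan(gm, width = 8, mode = "groups")
  first_sel <- gm$map$marker_id[sim$truth$selected][1]
  in_window <- vapply(strsplit(scan$windows$marker_ids, ","),
                      function(ids) first_sel %in% ids, logical(1))
  expect_true(any(scan$windows$outlier_high & in_window))
  set.seed(110)
  perm <- sample(levels(gm$breed)[as.integer(gm$breed)])
  scan_p <- fst_scan(gm, perm, width = 8, mode = "groups")
  # with labels broken, at most ~1% of windows exceed the empirical 99%
  # threshold by construction, and the injected block is no longer extreme
  expect_lte(sum(scan_p$windows$outlier_high),
             ceiling(0.011 * nrow(scan_p$windows)))
  in_window_p <- vapply(strsplit(scan_p$windows$marker_ids, ","),
                        function(ids) first_sel %in% ids, logical(1))
  expect_false(any(scan_p$windows$outlier_high & in_window_p))
})

test_that("global multi-locus GST recovers the drift closed form", {
  sim <- small_panel(n_breeds = 4, n_per_breed = 40, n_chr = 4,
                     markers_per_chr = 250, F = 0.1, missing_rate = 0, seed = 111)
  expected <- 0.1 * (1 - 1 / 4) / (1 - 0.1 / 4)
  expect_equal(global_fst(sim$genotypes), expected, tolerance = 0.12)
  expect_lt(abs(global_fst(sim$genotypes) - expected), 0.01)
})
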