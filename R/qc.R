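#' Quality-control thresholds
#'
#' Container for the filter cascade thresholds. Defaults follow common chip
#' QC practice for dense bovine panels: 99% call rate for both samples and
#' markers, 5% minimum minor allele frequency, 1% FDR for heterozygosity
#' outliers and a per-test P < 0.01 for the within-breed Hardy-Weinberg
#' exact test.
#'
#' @param min_call_rate_sample,min_call_rate_marker minimum fraction of
#'   non-missing calls for a sample / marker.
#' @param min_maf minimum pooled minor allele frequency.
#' @param het_fdr Benjamini-Hochberg FDR level for high-heterozygosity
#'   sample outliers.
#' @param hwe_alpha per-test P threshold for the within-breed HWE test.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate_sample = 0.99,
                          min_call_rate_marker = 0.99,
                          min_maf = 0.05,
                          het_fdr = 0.01,
                          hwe_alpha = 0.01) {
  th <- list(
    min_call_rate_sample = min_call_rate_sample,
    min_call_rate_marker = min_call_rate_marker,
    min_maf = min_maf, het_fdr = het_fdr, hwe_alpha = hwe_alpha
  )
  if (any(unlist(th) <= 0 | unlist(th) > 1)) stop("all thresholds must lie in (0, 1]")
  structure(th, class = "qc_thresholds")
}

qc_step <- function(name, gm_before, gm_after, removed_samples, removed_markers) {
  list(
    step = name,
    samples_removed = length(removed_samples),
    markers_removed = length(removed_markers),
    removed_sample_ids = removed_samples,
    removed_marker_ids = removed_markers
  )
}

#' Call-rate filter for samples and markers
#'
#' Sample and marker call rates (fraction of non-missing calls) are computed
#' simultaneously on the input panel, then every sample and marker below its
#' threshold is removed in a single symmetric step. Computing both on the
#' unfiltered panel makes the result independent of an arbitrary
#' sample-first/marker-first ordering.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return filtered `genotype_matrix` with attribute `"qc_step"`.
#' @export
call_rate_filter <- function(gm, thresholds = qc_thresholds()) {
  obs <- !is.na(gm$dosage)
  cr_sample <- rowMeans(obs)
  cr_marker <- colMeans(obs)
  drop_s <- cr_sample < thresholds$min_call_rate_sample
  drop_m <- cr_marker < thresholds$min_call_rate_marker
  out <- gm
  if (any(drop_s) || any(drop_m)) {
    out <- subset_genotypes(gm, samples = which(!drop_s), markers = which(!drop_m))
  }
  attr(out, "qc_step") <- qc_step("call_rate", gm, out,
                                  rownames(gm$dosage)[drop_s],
                                  gm$map$marker_id[drop_m])
  out
}

#' Pooled minor-allele-frequency filter
#'
#' Allele frequencies are computed over all non-missing genotypes pooled
#' across breeds (filters are applied before any breed separation). Markers
#' with MAF below `min_maf` are removed; monomorphic markers are always
#' removed.
#'
#' @inheritParams call_rate_filter
#' @param min_maf minimum minor allele frequency.
#' @return filtered `genotype_matrix` with attribute `"qc_step"`.
#' @export
maf_filter <- function(gm, min_maf = 0.05) {
  d <- gm$dosage
  nn <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * pmax(nn, 1L))
  maf <- pmin(f, 1 - f)
  drop <- nn == 0L | maf < min_maf | maf == 0
  out <- gm
  if (any(drop)) out <- subset_genotypes(gm, markers = which(!drop))
  attr(out, "qc_step") <- qc_step("maf", gm, out, character(0),
                                  gm$map$marker_id[drop])
  out
}

#' High-heterozygosity sample outlier filter
#'
#' Samples with abnormally *high* observed autosomal heterozygosity (a
#' classic signature of DNA contamination) are removed. Per-sample observed
#' heterozygosity `h_i` is the fraction of heterozygous calls among
#' non-missing genotypes; upper-tail p-values come from a normal model with
#' robust centre and scale (median and MAD of the `h_i`), and
#' Benjamini-Hochberg is applied at level `het_fdr`.
#'
#' @inheritParams call_rate_filter
#' @param het_fdr FDR level.
#' @param centre,scale robust location/scale functions (defaults
#'   [stats::median()] and [stats::mad()]).
#' @return filtered `genotype_matrix` with attribute `"qc_step"`.
#' @export
heterozygosity_outlier_filter <- function(gm, het_fdr = 0.01,
                                          centre = stats::median,
                                          scale = stats::mad) {
  d <- gm$dosage
  if (nrow(d) < 10L) stop("heterozygosity outlier filter needs at least 10 samples")
  h <- rowSums(d == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(d)), 1L)
  mu <- centre(h)
  s <- scale(h)
  if (s == 0) {
    warning("degenerate heterozygosity distribution (zero scale); step skipped")
    out <- gm
    attr(out, "qc_step") <- qc_step("heterozygosity", gm, out, character(0), character(0))
    return(out)
  }
  p <- stats::pnorm(h, mean = mu, sd = s, lower.tail = FALSE)
  drop <- bh_reject(p, het_fdr)
  out <- gm
  if (any(drop)) out <- subset_genotypes(gm, samples = which(!drop))
  attr(out, "qc_step") <- qc_step("heterozygosity", gm, out,
                                  rownames(gm$dosage)[drop], character(0))
  out
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up FDR procedure: reject the `k` smallest p-values where `k` is the
#' largest index with `p_(k) <= k q / m`.
#'
#' @param p vector of p-values.
#' @param q FDR level.
#' @return logical vector, `TRUE` where rejected.
#' @export
bh_reject <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for a biallelic marker from genotype counts,
#' conditioning on the observed allele counts: the p-value is the sum of
#' probabilities of every heterozygote count (with the same allele totals)
#' whose probability does not exceed that of the observed configuration.
#' Monomorphic input returns 1. All arguments are vectorized.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  ln <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), ln)
  n_Aa <- rep_len(as.integer(n_Aa), ln)
  n_aa <- rep_len(as.integer(n_aa), ln)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop("genotype counts must be non-negative")
  vapply(seq_len(ln), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  n1 <- min(nA, na)          # rarer allele count
  if (n1 == 0L) return(1.0)  # monomorphic
  # heterozygote counts share the parity of n1 and cannot exceed n1
  hets <- seq.int(n1 %% 2L, n1, by = 2L)
  # P(h) = n! 2^h n1! n2! / ( ((n1-h)/2)! h! ((n2-h)/2)! (2n)! ), valid while
  # both homozygote counts are non-negative
  hom1 <- (n1 - hets) / 2
  hom2 <- (2L * n - n1 - hets) / 2
  ok <- hom2 >= 0
  hets <- hets[ok]; hom1 <- hom1[ok]; hom2 <- hom2[ok]
  logp <- lfactorial(n) + hets * log(2) + lfactorial(n1) + lfactorial(2L * n - n1) -
    lfactorial(hom1) - lfactorial(hets) - lfactorial(hom2) - lfactorial(2L * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1.0, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Within-breed Hardy-Weinberg filter
#'
#' Runs [hwe_exact_test()] for every marker within every breed separately;
#' a marker is removed when it is out of HWE (p below `hwe_alpha`) in at
#' least one breed.
#'
#' @inheritParams call_rate_filter
#' @param hwe_alpha per-test P threshold.
#' @return filtered `genotype_matrix` with attribute `"qc_step"`; the step
#'   also records the per-marker minimum p-value in `attr(,"hwe_min_p")`.
#' @export
hwe_filter_within_breeds <- function(gm, hwe_alpha = 0.01) {
  d <- gm$dosage
  min_p <- rep(1.0, ncol(d))
  for (b in levels(gm$breed)) {
    db <- d[gm$breed == b, , drop = FALSE]
    if (nrow(db) < 2L) next
    n0 <- colSums(db == 0L, na.rm = TRUE)
    n1 <- colSums(db == 1L, na.rm = TRUE)
    n2 <- colSums(db == 2L, na.rm = TRUE)
    nonempty <- (n0 + n1 + n2) >= 1L
    p <- rep(1.0, ncol(d))
    p[nonempty] <- hwe_exact_test(n0[nonempty], n1[nonempty], n2[nonempty])
    min_p <- pmin(min_p, p)
  }
  drop <- min_p < hwe_alpha
  out <- gm
  if (any(drop)) out <- subset_genotypes(gm, markers = which(!drop))
  attr(out, "qc_step") <- qc_step("hwe_within_breeds", gm, out, character(0),
                                  gm$map$marker_id[drop])
  attr(out, "hwe_min_p") <- min_p
  out
}

#' Run the full two-pass QC cascade
#'
#' Executes, in order: autosome/complete-map restriction, call-rate filter
#' (samples and markers), pooled MAF filter, high-heterozygosity outlier
#' removal, within-breed HWE filter — then pools the filtered data and
#' repeats the first-pass criteria (call rate, MAF) once more. On clean
#' data the second pass removes nothing, and the whole pipeline is a fixed
#' point of itself.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param autosome_labels passed to [restrict_autosomes()].
#' @return list with elements `genotypes` (the filtered panel) and `report`
#'   (a `qc_report`: per-step removal counts and ids plus final dimensions).
#' @export
run_qc_pipeline <- function(gm, thresholds = qc_thresholds(),
                            autosome_labels = as.character(1:29)) {
  steps <- list()
  push <- function(g, name = NULL) {
    st <- attr(g, "qc_step")
    if (!is.null(name)) st$step <- name
    steps[[length(steps) + 1L]] <<- st
    attr(g, "qc_step") <- NULL
    g
  }
  g <- restrict_autosomes(gm, autosome_labels)
  rep0 <- attr(g, "removal_report")
  steps[[1L]] <- qc_step("autosome_map_restriction", gm, g, character(0), rep0$removed_ids)
  attr(g, "removal_report") <- NULL

  g <- push(call_rate_filter(g, thresholds))
  g <- push(maf_filter(g, thresholds$min_maf))
  g <- push(heterozygosity_outlier_filter(g, thresholds$het_fdr))
  g <- push(hwe_filter_within_breeds(g, thresholds$hwe_alpha))
  # second pass on the pooled filtered data
  g <- push(call_rate_filter(g, thresholds), "call_rate_pass2")
  g <- push(maf_filter(g, thresholds$min_maf), "maf_pass2")

  report <- structure(
    list(
      steps = steps,
      initial_dim = dim_genotypes(gm),
      final_dim = dim_genotypes(g),
      thresholds = thresholds
    ),
    class = "qc_report"
  )
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  initial: %d samples x %d markers\n", x$initial_dim[1], x$initial_dim[2]))
  for (st in x$steps) {
    cat(sprintf("  %-26s -%4d samples, -%5d markers\n",
                st$step, st$samples_removed, st$markers_removed))
  }
  cat(sprintf("  final:   %d samples x %d markers\n", x$final_dim[1], x$final_dim[2]))
  invisible(x)
}

#' Tabulate a QC report
#'
#' @param report a `qc_report` from [run_qc_pipeline()].
#' @return `data.frame` with columns `step`, `samples_removed`,
#'   `markers_removed`.
#' @export
qc_report_table <- function(report) {
  data.frame(
    step = vapply(report$steps, `[[`, character(1), "step"),
    samples_removed = vapply(report$steps, `[[`, integer(1), "samples_removed"),
    markers_removed = vapply(report$steps, `[[`, integer(1), "markers_removed"),
    stringsAsFactors = FALSE
  )
}

#' Write a QC report to TSV
#'
#' Writes the per-step table and, alongside it, a per-id exclusion list.
#'
#' @param report a `qc_report`.
#' @param path output TSV path; the exclusion list goes to
#'   `<path>.exclusions.tsv`.
#' @return invisibly, the report table.
#' @export
write_qc_report <- function(report, path) {
  tab <- qc_report_table(report)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  excl <- do.call(rbind, lapply(report$steps, function(st) {
    rbind(
      if (length(st$removed_sample_ids))
        data.frame(step = st$step, type = "sample", id = st$removed_sample_ids),
      if (length(st$removed_marker_ids))
        data.frame(step = st$step, type = "marker", id = st$removed_marker_ids)
    )
  }))
  if (is.null(excl)) excl <- data.frame(step = character(0), type = character(0), id = character(0))
  utils::write.table(excl, paste0(path, ".exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
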