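#' Per-locus multi-population fixation index (Nei-Chesser estimator)
#'
#' Sample-size-corrected estimator of GST from genotype counts in `s`
#' subpopulations. With per-subpopulation non-missing counts `n_i`, harmonic
#' mean `n~ = s / sum(1/n_i)`, allele-B frequencies `x_i` and their
#' unweighted mean `x` over subpopulations:
#'
#' \deqn{\hat H_O = \mathrm{mean}_i\, h_i \quad (h_i = \textrm{observed het.})}
#' \deqn{\hat H_S = \frac{\tilde n}{\tilde n - 1}\Big[1 - \mathrm{mean}_i \sum_k x_{ki}^2 - \frac{\hat H_O}{2\tilde n}\Big]}
#' \deqn{\hat H_T = 1 - \sum_k \bar x_k^2 + \frac{\hat H_S}{\tilde n s} - \frac{\hat H_O}{2 \tilde n s}}
#' \deqn{F_{ST} = (\hat H_T - \hat H_S)/\hat H_T}
#'
#' Each subpopulation gets equal weight regardless of its size ("fixed
#' effects" sampling: the breeds, not a random draw of breeds, are the
#' target of inference). The estimator is unbiased and can be slightly
#' negative at undifferentiated loci. Markers monomorphic overall
#' (`H_T = 0`) have an undefined index, returned as `NaN`.
#'
#' @param genotype_counts matrix with one row per subpopulation and columns
#'   `(n0, n1, n2)`: counts of samples carrying 0, 1 and 2 copies of
#'   allele B.
#' @return list of class `fst_components` with elements `s`, `n_i`,
#'   `n_tilde`, `x_i`, `x_bar`, `H_O`, `H_S`, `H_T`, `fst`.
#' @export
nei_chesser_locus <- function(genotype_counts) {
  gc <- as.matrix(genotype_counts)
  if (ncol(gc) != 3L) stop("genotype_counts must have columns (n0, n1, n2)")
  n_i <- rowSums(gc)
  if (any(n_i == 0)) {
    warning(sprintf("%d subpopulation(s) with no data dropped", sum(n_i == 0)))
    gc <- gc[n_i > 0, , drop = FALSE]
    n_i <- rowSums(gc)
  }
  s <- nrow(gc)
  if (s < 2L) stop("at least 2 subpopulations with data required")
  comp <- nei_chesser_core(
    n = matrix(n_i, nrow = s),
    het = matrix(gc[, 2], nrow = s),
    x = matrix((gc[, 2] + 2 * gc[, 3]) / (2 * n_i), nrow = s)
  )
  structure(
    list(
      s = s, n_i = as.numeric(n_i), n_tilde = comp$n_tilde[1],
      x_i = (gc[, 2] + 2 * gc[, 3]) / (2 * n_i), x_bar = comp$x_bar[1],
      H_O = comp$H_O[1], H_S = comp$H_S[1], H_T = comp$H_T[1], fst = comp$fst[1]
    ),
    class = "fst_components"
  )
}

# Vectorized Nei-Chesser core over loci. Arguments are s x L matrices of
# per-subpopulation non-missing counts (n), heterozygote counts (het) and
# allele-B frequencies (x); NA rows mark subpopulations absent at a locus.
nei_chesser_core <- function(n, het, x) {
  s_l <- colSums(!is.na(n))
  n_tilde <- s_l / colSums(1 / n, na.rm = TRUE)
  H_O <- colMeans(het / n, na.rm = TRUE)
  hs_naive <- 1 - colMeans(x^2 + (1 - x)^2, na.rm = TRUE)
  H_S <- n_tilde / (n_tilde - 1) * (hs_naive - H_O / (2 * n_tilde))
  x_bar <- colMeans(x, na.rm = TRUE)
  H_T <- 1 - (x_bar^2 + (1 - x_bar)^2) + H_S / (n_tilde * s_l) - H_O / (2 * n_tilde * s_l)
  fst <- ifelse(abs(H_T) < 1e-12, NaN, (H_T - H_S) / H_T)
  fst[s_l < 2] <- NaN
  list(s = s_l, n_tilde = n_tilde, x_bar = x_bar,
       H_O = H_O, H_S = H_S, H_T = H_T, fst = fst)
}

#' Per-marker fixation index profile
#'
#' Applies the Nei-Chesser estimator to every marker, in map order, for a
#' given grouping of samples into subpopulations.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping factor (or coercible) of subpopulation labels, one per
#'   sample; defaults to the breed labels. `NA` samples are excluded.
#' @return numeric vector of per-marker fst values, `NaN` at markers
#'   monomorphic overall (or with fewer than 2 populated subpopulations),
#'   named by marker id.
#' @export
fst_profile <- function(gm, grouping = gm$breed) {
  grouping <- factor(grouping)
  if (length(grouping) != nrow(gm$dosage)) stop("grouping must label every sample")
  grouping <- droplevels(grouping)
  if (nlevels(grouping) < 2L) stop("at least 2 subpopulations required")
  d <- gm$dosage
  s <- nlevels(grouping)
  L <- ncol(d)
  n <- het <- x <- matrix(NA_real_, s, L)
  for (i in seq_len(s)) {
    di <- d[which(grouping == levels(grouping)[i]), , drop = FALSE]
    ni <- colSums(!is.na(di))
    n[i, ] <- ifelse(ni == 0, NA_real_, ni)
    het[i, ] <- colSums(di == 1L, na.rm = TRUE)
    x[i, ] <- colSums(di, na.rm = TRUE) / (2 * ni)
  }
  fst <- nei_chesser_core(n, het, x)$fst
  names(fst) <- gm$map$marker_id
  fst
}

#' Per-marker diversity components for a grouping
#'
#' Like [fst_profile()] but returns the full per-marker Nei-Chesser
#' component vectors, for genome-wide summaries.
#'
#' @inheritParams fst_profile
#' @return list of per-marker vectors `H_O`, `H_S`, `H_T`, `fst` and the
#'   per-marker populated subpopulation count `s`.
#' @export
fst_components_profile <- function(gm, grouping = gm$breed) {
  grouping <- droplevels(factor(grouping))
  if (length(grouping) != nrow(gm$dosage)) stop("grouping must label every sample")
  if (nlevels(grouping) < 2L) stop("at least 2 subpopulations required")
  d <- gm$dosage
  s <- nlevels(grouping)
  L <- ncol(d)
  n <- het <- x <- matrix(NA_real_, s, L)
  for (i in seq_len(s)) {
    di <- d[which(grouping == levels(grouping)[i]), , drop = FALSE]
    ni <- colSums(!is.na(di))
    n[i, ] <- ifelse(ni == 0, NA_real_, ni)
    het[i, ] <- colSums(di == 1L, na.rm = TRUE)
    x[i, ] <- colSums(di, na.rm = TRUE) / (2 * ni)
  }
  comp <- nei_chesser_core(n, het, x)
  lapply(comp[c("H_O", "H_S", "H_T", "fst", "s")], `names<-`, gm$map$marker_id)
}

#' Genome-wide multi-locus fixation index
#'
#' Overall GST in the tradition of multi-locus diversity analysis: the
#' per-locus corrected diversities are averaged across markers first and
#' the index is taken as the ratio of averages,
#' `(mean(H_T) - mean(H_S)) / mean(H_T)`. Unlike the mean of per-locus
#' ratios this is free of ratio (Jensen) bias, so under a Balding-Nichols
#' world with `s` equal breeds and drift `F` it recovers the closed form
#' `F (1 - 1/s) / (1 - F/s)`.
#'
#' @inheritParams fst_profile
#' @return single numeric value.
#' @export
global_fst <- function(gm, grouping = gm$breed) {
  comp <- fst_components_profile(gm, grouping)
  ok <- is.finite(comp$H_T) & is.finite(comp$H_S)
  (mean(comp$H_T[ok]) - mean(comp$H_S[ok])) / mean(comp$H_T[ok])
}

#' One-breed-versus-rest fixation index profiles
#'
#' For each breed, computes a two-subpopulation scan contrasting the focal
#' breed against all remaining breeds pooled into a single subpopulation —
#' the contrast used to attribute a selection signature to the breed that
#' drives it.
#'
#' @param gm a [genotype_matrix()] with at least 2 breeds.
#' @return named list, one per breed, of per-marker fst vectors.
#' @export
one_vs_rest_profiles <- function(gm) {
  breeds <- levels(gm$breed)
  if (length(breeds) < 2L) stop("at least 2 breeds required")
  sizes <- tabulate(gm$breed)
  if (any(sizes < 2L)) {
    stop(sprintf("breed %s has fewer than 2 samples; focal contrast undefined",
                 breeds[which(sizes < 2L)[1]]))
  }
  out <- lapply(breeds, function(b) {
    grouping <- ifelse(gm$breed == b, b, "rest")
    fst_profile(gm, grouping)
  })
  names(out) <- breeds
  out
}

#' Average a per-marker statistic in SNP windows
#'
#' Windows never span chromosome boundaries. `NaN` loci (monomorphic
#' overall) are kept in windows but excluded from the window mean; a window
#' whose members are all `NaN` is dropped.
#'
#' Two window semantics are supported. `"groups"` partitions each
#' chromosome's markers into consecutive non-overlapping blocks of `width`
#' SNPs; a trailing remainder block is kept as its own window when it has at
#' least `ceiling(width/2)` markers and merged into the previous block
#' otherwise. `"sliding"` yields one full-width window per start position
#' (step 1).
#'
#' @param fst_vector per-marker values, in map order.
#' @param map marker map (`chromosome`, `position_bp`, `marker_id`).
#' @param width window size in SNPs.
#' @param mode `"groups"` (default, genome scans) or `"sliding"`
#'   (single-chromosome views, typically `width = 3`).
#' @return `data.frame` with one row per window: `chromosome`, `start_bp`,
#'   `end_bp`, `center_bp`, `n_markers`, `n_finite`, `mean_fst`,
#'   `marker_ids` (comma-separated), `window` (index within chromosome).
#' @export
window_average <- function(fst_vector, map, width = 8L,
                           mode = c("groups", "sliding")) {
  mode <- match.arg(mode)
  if (width < 1L) stop("width must be >= 1")
  if (length(fst_vector) != nrow(map)) stop("fst_vector does not match map")
  res <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    m <- length(idx)
    if (mode == "groups") {
      n_full <- m %/% width
      rem <- m %% width
      if (n_full == 0L) {
        grp <- rep(1L, m)
      } else {
        grp <- rep(seq_len(n_full), each = width)
        if (rem > 0L) {
          grp <- c(grp, rep(if (rem >= ceiling(width / 2)) n_full + 1L else n_full, rem))
        }
      }
      ends <- cumsum(rle(grp)$lengths)
      starts <- c(1L, ends[-length(ends)] + 1L)
    } else {
      if (m < width) next
      starts <- seq_len(m - width + 1L)
      ends <- starts + width - 1L
    }
    for (w in seq_along(starts)) {
      sel <- idx[starts[w]:ends[w]]
      vals <- fst_vector[sel]
      finite <- is.finite(vals)
      if (!any(finite)) next
      res[[length(res) + 1L]] <- data.frame(
        chromosome = chr,
        start_bp = min(map$position_bp[sel]),
        end_bp = max(map$position_bp[sel]),
        center_bp = (min(map$position_bp[sel]) + max(map$position_bp[sel])) / 2,
        n_markers = length(sel),
        n_finite = sum(finite),
        mean_fst = mean(vals[finite]),
        marker_ids = paste(map$marker_id[sel], collapse = ","),
        window = w,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), center_bp = numeric(0),
                      n_markers = integer(0), n_finite = integer(0),
                      mean_fst = numeric(0), marker_ids = character(0),
                      window = integer(0)))
  }
  do.call(rbind, res)
}

#' Empirical quantile thresholds for window means
#'
#' Linear interpolation between order statistics (type-7 empirical
#' quantiles), computed genome-wide over all windows of a scan so that a
#' single pair of horizontal threshold lines applies to every chromosome.
#'
#' @param window_means numeric vector of window means (non-finite dropped).
#' @param q_low,q_high quantile levels (defaults 0.01 and 0.99).
#' @return named numeric vector `c(t_low, t_high)`.
#' @export
quantile_thresholds <- function(window_means, q_low = 0.01, q_high = 0.99) {
  if (q_low > q_high) stop("q_low must not exceed q_high")
  v <- window_means[is.finite(window_means)]
  if (length(v) < 2L) stop("at least 2 finite window means required")
  th <- stats::quantile(v, c(q_low, q_high), names = FALSE, type = 7)
  c(t_low = th[1], t_high = th[2])
}

#' Run a windowed fixation-index genome scan
#'
#' Convenience wrapper: per-marker profile, window averaging, genome-wide
#' quantile thresholds and outlier flags in one object.
#'
#' @inheritParams fst_profile
#' @inheritParams window_average
#' @param q_low,q_high quantile levels for the outlier thresholds.
#' @return list of class `scan_result`: `windows` (with logical columns
#'   `outlier_high`, `outlier_low`), `thresholds`, `fst` (per-marker
#'   vector), `width`, `mode`, `grouping_levels`.
#' @export
fst_scan <- function(gm, grouping = gm$breed, width = 8L,
                     mode = c("groups", "sliding"),
                     q_low = 0.01, q_high = 0.99) {
  mode <- match.arg(mode)
  fst <- fst_profile(gm, grouping)
  win <- window_average(fst, gm$map, width, mode)
  th <- quantile_thresholds(win$mean_fst, q_low, q_high)
  win$outlier_high <- win$mean_fst > th["t_high"]
  win$outlier_low <- win$mean_fst < th["t_low"]
  structure(
    list(windows = win, thresholds = th, fst = fst, width = width,
         mode = mode, grouping_levels = levels(droplevels(factor(grouping)))),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "fst scan: %d windows (width %d, %s) over %d markers; thresholds [%.4f, %.4f]; %d high / %d low outlier windows\n",
    nrow(x$windows), x$width, x$mode, length(x$fst),
    x$thresholds["t_low"], x$thresholds["t_high"],
    sum(x$windows$outlier_high), sum(x$windows$outlier_low)
  ))
  invisible(x)
}

#' Merge outlier windows into candidate regions
#'
#' Consecutive outlier windows on the same chromosome (adjacent window
#' indices) are merged into a single region — the unit reported as a
#' putative selection signature.
#'
#' @param scan a `scan_result` from [fst_scan()].
#' @param direction `"high"` (default: divergent selection candidates) or
#'   `"low"` (balancing-selection candidates below the lower quantile).
#' @return `data.frame` with one row per region: `chromosome`, `start_bp`,
#'   `end_bp`, `n_windows`, `n_markers`, `max_fst`, `mean_fst`.
#' @export
call_outlier_regions <- function(scan, direction = c("high", "low")) {
  direction <- match.arg(direction)
  win <- scan$windows
  flag <- if (direction == "high") win$outlier_high else win$outlier_low
  empty <- data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_windows = integer(0),
                      n_markers = integer(0), max_fst = numeric(0),
                      mean_fst = numeric(0))
  if (!any(flag)) return(empty)
  w <- win[flag, , drop = FALSE]
  # group consecutive window indices per chromosome
  run_id <- cumsum(c(TRUE, !(w$chromosome[-1] == w$chromosome[-nrow(w)] &
                               w$window[-1] == w$window[-nrow(w)] + 1L)))
  out <- lapply(split(seq_len(nrow(w)), run_id), function(ii) {
    data.frame(
      chromosome = w$chromosome[ii[1]],
      start_bp = min(w$start_bp[ii]),
      end_bp = max(w$end_bp[ii]),
      n_windows = length(ii),
      n_markers = sum(w$n_markers[ii]),
      max_fst = max(w$mean_fst[ii]),
      mean_fst = mean(w$mean_fst[ii]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate regions with overlapping named intervals
#'
#' Overlap test against a BED-style interval table (0-based, half-open).
#' Region coordinates are 1-based inclusive bp (map convention) and are
#' converted to BED convention for the test, so a gene ending exactly where
#' a region starts does not count as overlapping.
#'
#' @param regions region table from [call_outlier_regions()].
#' @param intervals either a path to a BED file (chrom, start, end, name;
#'   tab-separated, no header) or a `data.frame` with those columns.
#' @return `regions` with an added `overlaps` column (comma-separated
#'   interval names, `""` if none).
#' @export
annotate_regions <- function(regions, intervals) {
  if (is.character(intervals)) {
    intervals <- utils::read.table(intervals, sep = "\t", header = FALSE,
                                   col.names = c("chrom", "start", "end", "name"),
                                   colClasses = c("character", "integer", "integer", "character"))
  }
  regions$overlaps <- vapply(seq_len(nrow(regions)), function(i) {
    r0 <- regions$start_bp[i] - 1L  # to 0-based half-open
    r1 <- regions$end_bp[i]
    hit <- intervals$chrom == as.character(regions$chromosome[i]) &
      intervals$start < r1 & r0 < intervals$end
    paste(intervals$name[hit], collapse = ",")
  }, character(1))
  regions
}

#' Write scan outputs as TSV (and regions additionally as BED)
#'
#' @param scan a `scan_result`.
#' @param map the marker map used for the scan.
#' @param prefix output path prefix; writes `<prefix>.fst.tsv`,
#'   `<prefix>.windows.tsv`, `<prefix>.regions.tsv`, `<prefix>.regions.bed`.
#' @return invisibly, the region table.
#' @export
write_scan <- function(scan, map, prefix) {
  fst_tab <- data.frame(chromosome = map$chromosome, position_bp = map$position_bp,
                        marker_id = map$marker_id, fst = unname(scan$fst))
  utils::write.table(fst_tab, paste0(prefix, ".fst.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scan$windows, paste0(prefix, ".windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  regions <- call_outlier_regions(scan)
  utils::write.table(regions, paste0(prefix, ".regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = regions$chromosome, start = regions$start_bp - 1L,
                    end = regions$end_bp,
                    name = sprintf("region%03d", seq_len(nrow(regions))))
  utils::write.table(bed, paste0(prefix, ".regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(regions)
}
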