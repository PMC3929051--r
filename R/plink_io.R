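#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the classic PLINK text pair into a [genotype_matrix()]. The family
#' ID column of the `.ped` file is interpreted as the breed label, the common
#' convention for multi-breed chip panels. `"0 0"` allele pairs become
#' missing dosages. For each marker, `allele_b` (the counted allele) is the
#' lexicographically later of the observed alleles, so dosage coding does not
#' depend on file ordering; both alleles are recorded in the map.
#'
#' @param ped_path path to the `.ped` file: 6 mandatory columns
#'   (FID IID PAT MAT SEX PHENO) followed by two allele columns per marker.
#' @param map_path path to the `.map` file: 4 whitespace-separated columns
#'   (chromosome, marker id, genetic position, bp position).
#' @return a [genotype_matrix()].
#' @seealso [write_plink_text()]
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4L)) {
    stop(sprintf("map format error at line %d: expected 4 columns, found %d",
                 which(nf != 4L)[1], nf[nf != 4L][1]))
  }
  map_tok <- do.call(rbind, map_tok)
  m <- nrow(map_tok)
  map <- data.frame(
    marker_id = map_tok[, 2],
    chromosome = map_tok[, 1],
    position_bp = suppressWarnings(as.integer(map_tok[, 4])),
    allele_a = "0", allele_b = "0",
    stringsAsFactors = FALSE
  )

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (length(ped_lines) == 0L) stop("ped file is empty")
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(ped_tok)
  expected <- 6L + 2L * m
  if (any(nf != expected)) {
    i <- which(nf != expected)[1]
    stop(sprintf("ped format error at line %d: expected %d fields (6 + 2 x %d markers), found %d",
                 i, expected, m, nf[i]))
  }
  ped_tok <- do.call(rbind, ped_tok)
  n <- nrow(ped_tok)
  breed <- ped_tok[, 1]
  sample_ids <- ped_tok[, 2]
  a1 <- ped_tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped_tok[, 6L + 2L * seq_len(m), drop = FALSE]
  ok <- c("A", "C", "G", "T", "0")
  bad <- !(a1 %in% ok) | !(a2 %in% ok)
  if (any(bad)) {
    i <- which(rowSums(matrix(bad, n)) > 0)[1]
    stop(sprintf("ped format error at line %d: allele character outside {A,C,G,T,0}", i))
  }
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing)) {
    i <- which(rowSums(matrix(half_missing, n)) > 0)[1]
    stop(sprintf("ped format error at line %d: half-missing genotype", i))
  }

  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L) {
      stop(sprintf("marker %s is not biallelic (alleles %s)",
                   map$marker_id[j], paste(alleles, collapse = "/")))
    }
    if (length(alleles) == 0L) next  # all missing; dosage stays NA
    if (length(alleles) == 1L) {
      # single observed allele: count it as allele_a, dosage 0 everywhere
      map$allele_a[j] <- alleles[1]
      miss <- a1[, j] == "0"
      dosage[, j] <- ifelse(miss, NA_integer_, 0L)
    } else {
      map$allele_a[j] <- alleles[1]
      map$allele_b[j] <- alleles[2]
      cnt <- (a1[, j] == alleles[2]) + (a2[, j] == alleles[2])
      cnt[a1[, j] == "0"] <- NA_integer_
      dosage[, j] <- as.integer(cnt)
    }
  }
  genotype_matrix(dosage, breed, map, sample_ids = sample_ids)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]: round trips are lossless on dosage, breed
#' labels, chromosome and position. Missing dosages are written as `"0 0"`.
#' Markers whose alleles were never observed (allele codes `"0"`) are written
#' with placeholder alleles `A`/`B` replaced by `"0 0"` only for missing
#' cells, so information content is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, `c(ped_path, map_path)`.
#' @export
write_plink_text <- function(gm, ped_path, map_path) {
  validate_genotype_matrix(gm)
  d <- gm$dosage
  if (nrow(d) == 0L || ncol(d) == 0L) stop("cannot write an empty genotype matrix")
  map <- gm$map
  writeLines(sprintf("%s\t%s\t0\t%d", map$chromosome, map$marker_id,
                     ifelse(is.na(map$position_bp), 0L, map$position_bp)),
             map_path)
  m <- ncol(d)
  n <- nrow(d)
  # per-marker genotype strings indexed by dosage
  ped_cols <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    a <- map$allele_a[j]
    b <- map$allele_b[j]
    if (a == "0" && b == "0") a <- "A"  # never-observed marker, arbitrary code
    code <- c(paste(a, a), paste(a, b), paste(b, b))
    g <- d[, j]
    ped_cols[!is.na(g), j] <- code[g[!is.na(g)] + 1L]
  }
  lines <- paste(
    as.character(gm$breed), rownames(d), "0", "0", "0", "-9",
    apply(ped_cols, 1L, paste, collapse = " ")
  )
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Canonicalize allele labels of a genotype matrix
#'
#' Puts every marker into the labeling that [read_plink_text()] produces:
#' when both alleles are observed, `allele_b` (the counted allele) is the
#' lexicographically later one; when a single allele is observed it is
#' recorded as `allele_a` and the dosage is 0; an entirely missing marker is
#' left untouched. Dosages are flipped (`2 - d`) where the labels swap.
#'
#' A PLINK text pair stores genotypes as bases only, so absolute allele
#' labels of monomorphic markers cannot survive a write/read cycle; on the
#' canonical form the cycle is the exact identity
#' (`read(write(gm)) == canonicalize(gm)`), and every frequency-based
#' statistic in the package is invariant to the relabeling.
#'
#' @param gm a [genotype_matrix()].
#' @return the canonicalized `genotype_matrix`.
#' @export
canonicalize_alleles <- function(gm) {
  d <- gm$dosage
  map <- gm$map
  for (j in seq_len(ncol(d))) {
    v <- d[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) next
    has_a <- any(obs < 2L)
    has_b <- any(obs > 0L)
    a <- map$allele_a[j]
    b <- map$allele_b[j]
    if (has_a && has_b) {
      if (a != "0" && b != "0" && a > b) {       # enforce lexicographic order
        d[, j] <- 2L - v
        map$allele_a[j] <- b
        map$allele_b[j] <- a
      }
    } else if (has_b && !has_a) {                # only allele_b observed
      d[, j] <- ifelse(is.na(v), NA_integer_, 0L)
      map$allele_a[j] <- b
      map$allele_b[j] <- "0"
    } else {                                     # only allele_a observed
      map$allele_b[j] <- "0"
    }
  }
  gm$dosage <- d
  gm$map <- map
  gm
}

#' Restrict a panel to mapped autosomal markers
#'
#' Drops markers whose chromosome label is not in `autosome_labels` (for
#' cattle, `"1".."29"`; the X chromosome and unplaced contigs are excluded)
#' and markers with unknown physical position (`position_bp` missing or
#' `<= 0`). This is the first editing step of the analysis workflow.
#'
#' @param gm a [genotype_matrix()].
#' @param autosome_labels chromosome labels to keep (default `"1".."29"`).
#' @return the filtered `genotype_matrix` with attribute `"removal_report"`,
#'   a list with counts `non_autosome` and `no_map` and the removed ids.
#' @export
restrict_autosomes <- function(gm, autosome_labels = as.character(1:29)) {
  validate_genotype_matrix(gm)
  map <- gm$map
  not_auto <- !(map$chromosome %in% autosome_labels)
  no_map <- !not_auto & (is.na(map$position_bp) | map$position_bp <= 0L)
  keep <- !not_auto & !no_map
  if (!any(keep)) stop("empty panel: no mapped autosomal markers left")
  report <- list(
    non_autosome = sum(not_auto), no_map = sum(no_map),
    removed_ids = map$marker_id[!keep], retained = sum(keep)
  )
  out <- if (all(keep)) gm else subset_genotypes(gm, markers = which(keep))
  attr(out, "removal_report") <- report
  out
}
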