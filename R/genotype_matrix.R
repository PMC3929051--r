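#' Construct a genotype matrix object
#'
#' The central data container of the package: a samples x markers diploid
#' dosage matrix together with per-sample breed labels and a marker map.
#' Dosages count copies of `allele_b` at each marker, so values are 0, 1, 2
#' or `NA` for a missing call.
#'
#' @param dosage integer matrix (samples x markers) with values in
#'   `{0, 1, 2, NA}`. Row names are taken as sample ids if `sample_ids` is
#'   not given; column names must match `map$marker_id` when present.
#' @param breed character or factor of breed labels, one per sample.
#' @param map marker map `data.frame` with columns `marker_id`,
#'   `chromosome` (character labels; autosomes `"1".."29"` for cattle, `"X"`
#'   permitted on input), `position_bp` (1-based physical position; `0` or
#'   `NA` means unknown) and single-character `allele_a`/`allele_b`
#'   (`"0"` = unknown). Created with sensible defaults if omitted.
#' @param sample_ids optional character vector of sample identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `breed` (factor) and `map`.
#'
#' @details Within each chromosome the map must be sorted by non-decreasing
#'   `position_bp`; marker ids must be unique. These invariants are enforced
#'   at construction so that downstream window operations can rely on them.
#' @export
genotype_matrix <- function(dosage, breed, map = NULL, sample_ids = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(n))
  }
  if (length(sample_ids) != n) stop("sample_ids length does not match dosage rows")
  rownames(dosage) <- sample_ids
  if (is.null(map)) {
    map <- data.frame(
      marker_id = if (is.null(colnames(dosage))) sprintf("snp%05d", seq_len(m)) else colnames(dosage),
      chromosome = "1",
      position_bp = as.integer(seq_len(m)),
      allele_a = "A", allele_b = "B",
      stringsAsFactors = FALSE
    )
  }
  colnames(dosage) <- map$marker_id
  if (length(breed) != n) stop("breed labels must be given for every sample")
  gm <- structure(
    list(dosage = dosage, breed = factor(as.character(breed)), map = map),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants of a [genotype_matrix()]: dosage values
#' in `{0,1,2,NA}`, matching dimensions, unique marker ids, per-sample breed
#' labels and a map sorted by position within each chromosome.
#'
#' @param gm object to validate.
#' @return `gm`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_genotype_matrix <- function(gm) {
  if (!inherits(gm, "genotype_matrix")) stop("not a genotype_matrix")
  d <- gm$dosage
  if (ncol(d) != nrow(gm$map)) stop("dosage columns do not match map length")
  if (length(gm$breed) != nrow(d)) stop("breed labels do not match samples")
  bad <- !(d %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values outside {0,1,2,NA}")
  map <- gm$map
  need <- c("marker_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(need %in% names(map))) stop("map lacks required columns")
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids in map")
  for (chr in unique(map$chromosome)) {
    pos <- map$position_bp[map$chromosome == chr]
    pos <- pos[!is.na(pos)]
    if (is.unsorted(pos)) stop(sprintf("map not sorted by position on chromosome %s", chr))
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers, %d breeds, %d chromosomes\n",
    nrow(x$dosage), ncol(x$dosage), nlevels(x$breed),
    length(unique(x$map$chromosome))
  ))
  cat(sprintf(
    "  missing calls: %.3f%%; breeds: %s\n",
    100 * mean(is.na(x$dosage)),
    paste(sprintf("%s(%d)", levels(x$breed), tabulate(x$breed)), collapse = ", ")
  ))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples logical/integer/character index of samples to keep.
#' @param markers logical/integer/character index of markers to keep.
#' @param ... unused.
#' @return the subset `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL, ...) {
  d <- x$dosage
  breed <- x$breed
  map <- x$map
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    breed <- breed[samples]
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker_id)
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty panel after subsetting")
  genotype_matrix(d, droplevels(breed), map)
}

#' Number of samples and markers
#' @param gm a [genotype_matrix()].
#' @return integer vector `c(samples, markers)`.
#' @export
dim_genotypes <- function(gm) c(nrow(gm$dosage), ncol(gm$dosage))
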