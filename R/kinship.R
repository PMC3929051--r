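#' Genomic kinship matrix
#'
#' Frequency-standardized kinship estimated directly from genotypes:
#' \deqn{k_{ij} = \frac{1}{L_{ij}} \sum_l \frac{(x_{il} - 2\hat p_l)(x_{jl} - 2\hat p_l)}{4 \hat p_l (1 - \hat p_l)}}
#' with `p_l` the pooled allele-B frequency and the sum over markers where
#' both genotypes are non-missing (pairwise-complete `L_ij`). Monomorphic
#' markers carry no information and are skipped. Under random mating the
#' expected self-kinship is `0.5 (1 + F_i)`, i.e. about 0.5 for outbred
#' samples, which is what makes the companion distance `d = 0.5 - k`
#' vanish on the diagonal.
#'
#' @param gm a [genotype_matrix()].
#' @return list of class `kinship_matrix`: `k` (symmetric samples x samples
#'   matrix), `sample_ids`, `n_markers_used` (polymorphic marker count).
#' @export
genomic_kinship <- function(gm) {
  d <- gm$dosage
  if (nrow(d) < 2L) stop("at least 2 samples required")
  nn <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(nn, 1L))
  poly <- nn > 0L & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic marker available")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  y <- sweep(d, 2L, 2 * p, `-`) / rep(sqrt(4 * p * (1 - p)), each = nrow(d))
  obs <- !is.na(y)
  y[!obs] <- 0
  L <- tcrossprod(obs * 1)        # pairwise-complete marker counts
  if (any(L == 0)) {
    ij <- which(L == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no non-missing marker",
                 rownames(d)[ij[1]], rownames(d)[ij[2]]))
  }
  k <- tcrossprod(y) / L
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(d), rownames(d))
  structure(
    list(k = k, sample_ids = rownames(d), n_markers_used = sum(poly)),
    class = "kinship_matrix"
  )
}

#' Kinship-derived distance matrix
#'
#' Elementwise `d_ij = 0.5 - k_ij`. No clamping is applied: pairs more
#' related than half-sibs of outbreds (`k > 0.5`, e.g. duplicates or highly
#' inbred relatives) produce negative entries, which are preserved and
#' counted in the `"n_negative"` attribute.
#'
#' @param km a `kinship_matrix` from [genomic_kinship()] (or a plain
#'   symmetric matrix of kinship coefficients).
#' @return numeric distance matrix with attribute `n_negative`.
#' @export
kinship_to_distance <- function(km) {
  k <- if (inherits(km, "kinship_matrix")) km$k else as.matrix(km)
  d <- 0.5 - k
  neg <- sum(d[upper.tri(d)] < 0)
  if (neg > 0) message(sprintf("%d pair(s) with negative distance (k > 0.5) preserved", neg))
  attr(d, "n_negative") <- neg
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared-distance matrix, `B = -J D^2 J / 2` with
#' `J = I - 11'/n`, eigendecomposes `B` and returns the top eigenvectors
#' scaled by the square roots of their (positive) eigenvalues. Negative
#' eigenvalues — arising when the input is not exactly Euclidean — are
#' dropped and counted. The sign of each component is fixed by making its
#' first nonzero loading positive, so output is deterministic across
#' platforms.
#'
#' @param distance_matrix square symmetric matrix; small asymmetries are
#'   symmetrized and a nonzero diagonal is reset to zero, each with a
#'   warning.
#' @param n_components number of components to return (default 3); silently
#'   truncated to the number of positive eigenvalues, with a warning.
#' @return list of class `embedding_result`: `coordinates` (samples x
#'   components, columns `C1`, `C2`, ...), `eigenvalues` (all, decreasing),
#'   `n_negative_eigenvalues`.
#' @export
classical_mds <- function(distance_matrix, n_components = 3L) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) warning("asymmetric distance matrix symmetrized")
  D <- (D + t(D)) / 2
  if (any(diag(D) != 0)) {
    warning("nonzero diagonal reset to zero")
    diag(D) <- 0
  }
  n <- nrow(D)
  D2 <- D^2
  # double centering without forming J explicitly
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rm_, `+`) + mean(D2))
  e <- eigen(B, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  n_neg <- sum(e$values < -tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, n_components,
                     dimnames = list(rownames(D), paste0("C", seq_len(n_components))))
    return(structure(list(coordinates = coords, eigenvalues = e$values,
                          n_negative_eigenvalues = n_neg),
                     class = "embedding_result"))
  }
  if (n_components > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); components truncated", length(pos)))
    n_components <- length(pos)
  }
  keep <- pos[seq_len(n_components)]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
  # deterministic sign: first nonzero loading of each component positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(D), paste0("C", seq_len(ncol(coords))))
  structure(
    list(coordinates = coords, eigenvalues = e$values,
         n_negative_eigenvalues = n_neg),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  ev <- x$eigenvalues[x$eigenvalues > 0]
  cat(sprintf(
    "classical MDS embedding: %d points x %d components; top eigenvalue share %.1f%%; %d negative eigenvalue(s) dropped\n",
    nrow(x$coordinates), ncol(x$coordinates),
    100 * ev[1] / sum(ev), x$n_negative_eigenvalues
  ))
  invisible(x)
}

#' Cluster centres and centre-to-centre distances in an embedding
#'
#' Per-group centroid coordinates, all pairwise Euclidean centre distances
#' and each centre's distance to the global centre of mass of the points
#' (approximately the origin, by double centering).
#'
#' @param embedding an `embedding_result` from [classical_mds()] (or a
#'   coordinates matrix).
#' @param labels grouping factor, one per embedded point (e.g. breed).
#' @return list with `centres` (groups x components matrix),
#'   `centre_distances` (long `data.frame`: `from`, `to`, `distance`; `to`
#'   is `"<centre_of_mass>"` for distances to the global centre), and
#'   `centre_of_mass`.
#' @export
cluster_geometry <- function(embedding, labels) {
  xy <- if (inherits(embedding, "embedding_result")) embedding$coordinates else as.matrix(embedding)
  labels <- factor(labels)
  if (length(labels) != nrow(xy)) stop("labels must match embedded points")
  centres <- do.call(rbind, lapply(levels(labels), function(g) {
    colMeans(xy[labels == g, , drop = FALSE])
  }))
  rownames(centres) <- levels(labels)
  com <- colMeans(xy)
  if (nlevels(labels) >= 2L) {
    pairs <- utils::combn(levels(labels), 2)
    dists <- data.frame(
      from = pairs[1, ], to = pairs[2, ],
      distance = apply(pairs, 2L, function(p) {
        sqrt(sum((centres[p[1], ] - centres[p[2], ])^2))
      }),
      stringsAsFactors = FALSE
    )
  } else {
    dists <- data.frame(from = character(0), to = character(0),
                        distance = numeric(0), stringsAsFactors = FALSE)
  }
  to_com <- data.frame(
    from = levels(labels), to = "<centre_of_mass>",
    distance = sqrt(rowSums(sweep(centres, 2L, com, `-`)^2)),
    stringsAsFactors = FALSE
  )
  rownames(to_com) <- NULL
  list(centres = centres, centre_distances = rbind(dists, to_com),
       centre_of_mass = com)
}

#' Write kinship / embedding outputs as TSV
#'
#' @param km a `kinship_matrix`.
#' @param embedding an `embedding_result`.
#' @param breed per-sample labels.
#' @param prefix output path prefix.
#' @return invisibly `NULL`.
#' @export
write_kinship_mds <- function(km, embedding, breed, prefix) {
  utils::write.table(cbind(sample = km$sample_ids, as.data.frame(km$k)),
                     paste0(prefix, ".kinship.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emb <- data.frame(sample = rownames(embedding$coordinates),
                    breed = as.character(breed),
                    embedding$coordinates, check.names = FALSE)
  utils::write.table(emb, paste0(prefix, ".mds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  geom <- cluster_geometry(embedding, breed)
  utils::write.table(geom$centre_distances, paste0(prefix, ".centre_distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
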