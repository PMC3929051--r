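#' Fit the admixture model by Gibbs sampling
#'
#' Model-based clustering of individuals into `K` ancestral populations.
#' Each of the two allele copies of every genotype carries a latent cluster
#' assignment; the sampler alternates (i) categorical draws of the
#' assignments proportional to `q_ik p_kl` (or `q_ik (1 - p_kl)` for the
#' other allele), (ii) Beta-posterior draws of the cluster allele
#' frequencies `P` under a Uniform(0,1) prior, and (iii) Dirichlet-posterior
#' draws of the membership rows `Q` under a symmetric Dirichlet(`alpha`)
#' prior. Allele frequencies are independent across clusters (no correlated-
#' frequency prior).
#'
#' The model log-probability of the data is estimated from the sampling-
#' phase log-likelihood trace as `lnP(D) = mean(ll) - var(ll)/2`, the
#' harness statistic consumed by [evanno_delta_k()].
#'
#' @param gm a [genotype_matrix()] (QC'd dosages; missing values are skipped
#'   in the likelihood).
#' @param K number of clusters (`1 <= K <=` samples).
#' @param n_burnin,n_sweeps burn-in and sampling sweep counts. Full-scale
#'   analyses typically use 5000/10000; desk-scale tests 200/800.
#' @param seed integer seed; fits are bit-identical for identical
#'   `(seed, data, K)`.
#' @param alpha_prior symmetric Dirichlet concentration for `Q` (default 1).
#' @return list of class `admixture_fit`: `K`, `Q` (posterior-mean
#'   memberships, rows sum to 1), `P` (posterior-mean cluster allele
#'   frequencies), `lnP_D`, `ll_trace`, `n_burnin`, `n_sweeps`, `seed`,
#'   `alpha_prior`.
#' @export
gibbs_admixture <- function(gm, K, n_burnin = 5000L, n_sweeps = 10000L,
                            seed = 1L, alpha_prior = 1.0) {
  d <- gm$dosage
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(d)) stop("K exceeds the number of samples")
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1")
  set.seed(seed)
  res <- gibbs_admixture_cpp(d, as.integer(K), as.integer(n_burnin),
                             as.integer(n_sweeps), alpha_prior)
  ll <- res$ll_trace
  lnP_D <- mean(ll) - stats::var(ll) / 2
  if (n_sweeps == 1L) lnP_D <- ll[1]
  Q <- res$Q
  dimnames(Q) <- list(rownames(d), paste0("q", seq_len(K)))
  P <- res$P
  dimnames(P) <- list(paste0("cluster", seq_len(K)), colnames(d))
  structure(
    list(K = K, Q = Q, P = P, lnP_D = lnP_D, ll_trace = ll,
         n_burnin = n_burnin, n_sweeps = n_sweeps, seed = seed,
         alpha_prior = alpha_prior),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, %d samples x %d markers, lnP(D) = %.2f (%d burn-in + %d sweeps, seed %d)\n",
              x$K, nrow(x$Q), ncol(x$P), x$lnP_D, x$n_burnin, x$n_sweeps, x$seed))
  invisible(x)
}

#' Multi-run admixture harness
#'
#' Independent seeded fits for every `(K, run)` combination, collecting the
#' `lnP(D)` grid that the Evanno criterion needs. At least 2 runs per K are
#' required (the across-run standard deviation is undefined otherwise).
#'
#' @inheritParams gibbs_admixture
#' @param K_range integer vector of K values (e.g. `2:5`).
#' @param n_runs independent runs per K (default 5).
#' @param base_seed integer; run seeds are derived deterministically as
#'   `base_seed + 1000*K + run` unless `seeds` is given.
#' @param seeds optional `|K_range| x n_runs` matrix of seeds.
#' @param keep_fits keep the full fits (memory-heavy) or only the grid.
#' @return list of class `multi_run_result`: `table` (`data.frame` with
#'   columns `K`, `run`, `seed`, `lnP_D`), `fits` (list or `NULL`),
#'   run settings.
#' @export
multi_run <- function(gm, K_range = 2:5, n_runs = 5L, n_burnin = 5000L,
                      n_sweeps = 10000L, base_seed = 1L, seeds = NULL,
                      alpha_prior = 1.0, keep_fits = FALSE) {
  if (n_runs < 2L) stop("n_runs must be >= 2 (across-run sd undefined otherwise)")
  if (is.null(seeds)) {
    seeds <- outer(K_range, seq_len(n_runs),
                   function(K, r) as.integer(base_seed + 1000L * K + r))
  }
  seeds <- matrix(as.integer(seeds), length(K_range), n_runs)
  rows <- list()
  fits <- if (keep_fits) list() else NULL
  for (ki in seq_along(K_range)) {
    for (r in seq_len(n_runs)) {
      fit <- gibbs_admixture(gm, K_range[ki], n_burnin, n_sweeps,
                             seed = seeds[ki, r], alpha_prior = alpha_prior)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K_range[ki], run = r, seed = seeds[ki, r], lnP_D = fit$lnP_D
      )
      if (keep_fits) fits[[sprintf("K%d_run%d", K_range[ki], r)]] <- fit
    }
  }
  structure(
    list(table = do.call(rbind, rows), fits = fits, K_range = K_range,
         n_runs = n_runs, n_burnin = n_burnin, n_sweeps = n_sweeps),
    class = "multi_run_result"
  )
}

#' Evanno delta-K model-choice statistic
#'
#' From per-K multi-run `lnP(D)` values `L(K)`, computes per-K run means
#' `m(K)` and standard deviations `s(K)` and the second-difference
#' statistic
#' \deqn{\Delta K = \frac{|m(K+1) - 2\,m(K) + m(K-1)|}{s(K)}}
#' defined only for interior K (both neighbours needed). The K with the
#' largest finite delta-K estimates the number of clusters. A zero
#' across-run sd leaves that K's delta-K undefined (`NA`, flagged with a
#' warning).
#'
#' @param table `data.frame` with columns `K`, `lnP_D` (one row per run),
#'   or a `multi_run_result` from [multi_run()].
#' @return list of class `delta_k_table`: `summary` (`data.frame`: `K`,
#'   `n_runs`, `mean_lnP_D`, `sd_lnP_D`, `delta_k`), `best_K`.
#' @export
evanno_delta_k <- function(table) {
  if (inherits(table, "multi_run_result")) table <- table$table
  if (!all(c("K", "lnP_D") %in% names(table))) stop("table needs columns K and lnP_D")
  Ks <- sort(unique(table$K))
  if (length(Ks) < 3L) stop("at least 3 consecutive K values required")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  m <- vapply(Ks, function(k) mean(table$lnP_D[table$K == k]), numeric(1))
  s <- vapply(Ks, function(k) stats::sd(table$lnP_D[table$K == k]), numeric(1))
  nr <- vapply(Ks, function(k) sum(table$K == k), integer(1))
  if (any(nr < 2L)) stop("at least 2 runs per K required")
  dk <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1L, length(Ks))]) {
    if (s[i] == 0) {
      warning(sprintf("sd of lnP(D) is zero at K = %d; delta-K undefined", Ks[i]))
      next
    }
    dk[i] <- abs(m[i + 1L] - 2 * m[i] + m[i - 1L]) / s[i]
  }
  best_K <- if (all(is.na(dk))) NA_integer_ else Ks[which.max(dk)]
  structure(
    list(
      summary = data.frame(K = Ks, n_runs = nr, mean_lnP_D = m,
                           sd_lnP_D = s, delta_k = dk),
      best_K = best_K
    ),
    class = "delta_k_table"
  )
}

#' @export
print.delta_k_table <- function(x, ...) {
  cat("Evanno delta-K table\n")
  print(format(x$summary, digits = 6), row.names = FALSE)
  cat(sprintf("best K (argmax delta-K): %s\n", x$best_K))
  invisible(x)
}

#' Align cluster labels across admixture runs
#'
#' Gibbs fits are identified only up to a permutation of cluster labels
#' ("label switching"). This aligns every fit to the first one by a greedy
#' best-permutation match on Q-column correlation: repeatedly pair the most
#' correlated remaining (reference, candidate) column pair. The permutation
#' is applied to both `Q` and `P`.
#'
#' @param fits list of `admixture_fit` objects sharing `K` and samples.
#' @return list of aligned fits (the first is returned unchanged).
#' @export
align_q_across_runs <- function(fits) {
  if (length(fits) < 2L) return(fits)
  K <- fits[[1]]$K
  if (any(vapply(fits, `[[`, numeric(1), "K") != K)) stop("fits must share K")
  ref <- fits[[1]]$Q
  out <- fits
  for (f in seq_along(fits)[-1L]) {
    Q <- fits[[f]]$Q
    if (nrow(Q) != nrow(ref)) stop("fits must share samples")
    cc <- suppressWarnings(stats::cor(ref, Q))
    cc[!is.finite(cc)] <- -Inf
    perm <- integer(K)  # perm[j] = candidate column assigned to reference j
    avail_r <- avail_c <- rep(TRUE, K)
    for (step in seq_len(K)) {
      sub <- cc
      sub[!avail_r, ] <- -Inf
      sub[, !avail_c] <- -Inf
      ij <- arrayInd(which.max(sub), dim(sub))
      perm[ij[1]] <- ij[2]
      avail_r[ij[1]] <- FALSE
      avail_c[ij[2]] <- FALSE
    }
    out[[f]]$Q <- Q[, perm, drop = FALSE]
    colnames(out[[f]]$Q) <- colnames(ref)
    out[[f]]$P <- fits[[f]]$P[perm, , drop = FALSE]
    rownames(out[[f]]$P) <- rownames(fits[[1]]$P)
  }
  out
}

#' Write a Q matrix as TSV
#'
#' @param fit an `admixture_fit`.
#' @param breed per-sample labels.
#' @param path output path.
#' @return invisibly, the written `data.frame`.
#' @export
write_q_matrix <- function(fit, breed, path) {
  tab <- data.frame(sample = rownames(fit$Q), breed = as.character(breed),
                    fit$Q, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
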