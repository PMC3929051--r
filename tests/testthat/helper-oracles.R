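# Independent oracles used across the suite. Each is a deliberately naive,
# straight-line computation kept separate from the package's code paths.

# Nei-Chesser corrected-diversity estimator, transcribed formula by formula
# for a single locus from per-subpopulation genotype counts (n0, n1, n2).
nc_oracle <- function(gc) {
  gc <- as.matrix(gc)
  n_i <- rowSums(gc)
  s <- nrow(gc)
  n_tilde <- s / sum(1 / n_i)
  x <- (gc[, 2] + 2 * gc[, 3]) / (2 * n_i)
  H_O <- mean(gc[, 2] / n_i)
  hs_naive <- 1 - mean(x^2 + (1 - x)^2)
  H_S <- n_tilde / (n_tilde - 1) * (hs_naive - H_O / (2 * n_tilde))
  xb <- mean(x)
  H_T <- 1 - (xb^2 + (1 - xb)^2) + H_S / (n_tilde * s) - H_O / (2 * n_tilde * s)
  list(H_O = H_O, H_S = H_S, H_T = H_T, fst = (H_T - H_S) / H_T)
}

# random genotype-count table: s subpopulations, counts n0/n1/n2
random_count_table <- function(s_range = 2:6, n_range = 2:200) {
  s <- sample(s_range, 1)
  t(vapply(seq_len(s), function(i) {
    n <- sample(n_range, 1)
    as.numeric(stats::rmultinom(1, n, runif(3)))
  }, numeric(3)))
}

# Hardy-Weinberg exact test by full enumeration: place the nA copies of the
# rarer allele into the 2n ordered gamete slots in every possible way
# (uniform by exchangeability), pair consecutive slots into individuals and
# tabulate heterozygote counts.
.hwe_enum_cache <- new.env(parent = emptyenv())
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2L * n0 + n1
  nr <- min(nA, 2L * n - nA)
  if (nr == 0L) return(1.0)
  key <- paste(n, nr)
  if (is.null(.hwe_enum_cache[[key]])) {
    comb <- utils::combn(2L * n, nr)
    slots <- matrix(FALSE, 2L * n, ncol(comb))
    slots[cbind(as.vector(comb), rep(seq_len(ncol(comb)), each = nr))] <- TRUE
    hets <- colSums(slots[seq(1, 2 * n, 2), , drop = FALSE] !=
                      slots[seq(2, 2 * n, 2), , drop = FALSE])
    .hwe_enum_cache[[key]] <- tabulate(hets + 1L, nbins = n + 1L) / ncol(comb)
  }
  pr <- .hwe_enum_cache[[key]]
  p_obs <- pr[n1 + 1L]
  sum(pr[pr > 0 & pr <= p_obs * (1 + 1e-10)])
}

# Benjamini-Hochberg by explicit scan over all candidate cutoffs
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= q * k / m) kmax <- k
  rej <- logical(m)
  if (kmax > 0L) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

# residual after optimally rotating/reflecting (no scaling) X onto Y
procrustes_residual <- function(X, Y) {
  k <- max(ncol(X), ncol(Y))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  Xc <- scale(pad(X), scale = FALSE)
  Yc <- scale(pad(Y), scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  sqrt(sum((Yc - Xc %*% (s$u %*% t(s$v)))^2))
}

# admixture-model data log-likelihood given (Q, P): allele copies
# independent, genotype ~ Binomial(2, u) with u = sum_k q_ik p_kl
admix_loglik <- function(dosage, Q, P) {
  u <- Q %*% P
  u <- pmin(pmax(u, 1e-300), 1 - 1e-12)
  ll <- ifelse(dosage == 0L, 2 * log(1 - u),
               ifelse(dosage == 2L, 2 * log(u), log(2) + log(u) + log(1 - u)))
  sum(ll[!is.na(dosage)])
}

# closed-form mean/variance of the K=1 log-likelihood trace: allele
# frequencies are drawn i.i.d. from their exact Beta(1+a, 1+b) posteriors,
# so E[ll] and Var[ll] follow from digamma/trigamma moments of log-Beta.
k1_lnpd_oracle <- function(dosage, n_sweeps) {
  a <- colSums(dosage, na.rm = TRUE)
  nn <- colSums(!is.na(dosage))
  b <- 2 * nn - a
  const <- sum(dosage == 1L, na.rm = TRUE) * log(2)
  tot <- 2 + a + b
  mu <- sum(a * (digamma(1 + a) - digamma(tot)) +
              b * (digamma(1 + b) - digamma(tot))) + const
  v <- sum(a^2 * (trigamma(1 + a) - trigamma(tot)) +
             b^2 * (trigamma(1 + b) - trigamma(tot)) -
             2 * a * b * trigamma(tot))
  list(lnP_D = mu - v / 2,
       se = sqrt(v / n_sweeps + v^2 / (2 * (n_sweeps - 1))))
}

# small drifted panel for generic tests
small_panel <- function(n_breeds = 3, n_per_breed = 20, n_chr = 3,
                        markers_per_chr = 40, F = 0.1, missing_rate = 0.01,
                        seed = 1, ...) {
  simulate_panel(simulation_config(
    n_breeds = n_breeds, n_per_breed = n_per_breed, n_chromosomes = n_chr,
    n_markers_per_chromosome = markers_per_chr, F_background = F,
    missing_rate = missing_rate, seed = seed, ...
  ))
}
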