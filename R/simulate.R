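#' Simulation configuration for a chip-style multi-breed panel
#'
#' Describes a Balding-Nichols world: an ancestral population with allele
#' frequencies `p_l ~ Uniform(maf_floor, 1 - maf_floor)`, from which each
#' breed drifts with parameter `F` so that breed frequencies follow
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. "Selected" blocks of consecutive SNPs
#' use a larger `F_selected` in the affected breeds only, emulating
#' breed-specific selection signatures. Genotypes are drawn in HWE within
#' breed, except for a configurable number of markers forced to
#' all-heterozygote calls in one breed (maximally detectable HWE
#' violations). Defaults emulate a 50K-chip bovine panel at desk scale:
#' 29 autosomes, 51 kb marker spacing, five breeds of unequal size (the
#' sizes are the published five-breed cohort scaled down ~14x), drift
#' F = 0.1 (cattle-breed-level differentiation), 0.5% missing calls.
#'
#' @param n_breeds number of breeds.
#' @param n_per_breed integer vector of breed sizes (recycled if scalar).
#' @param n_chromosomes,n_markers_per_chromosome panel geometry.
#' @param chrom_length_bp chromosome length; default gives 51 kb spacing.
#' @param F_background drift parameter, scalar or per-breed vector.
#' @param selected_blocks list of [selected_block()] specifications.
#' @param maf_floor lower bound of the ancestral frequency distribution.
#' @param missing_rate i.i.d. missing-call probability.
#' @param n_hwe_violating_markers markers forced out of HWE in one breed.
#' @param admixture_alpha Dirichlet concentration for [simulate_admixed()]
#'   (`NULL` for pure-breed panels).
#' @param breed_names optional breed labels.
#' @param seed RNG seed: identical configs give bit-identical panels.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_breeds = 5L,
                              n_per_breed = c(54L, 64L, 23L, 33L, 35L),
                              n_chromosomes = 29L,
                              n_markers_per_chromosome = 70L,
                              chrom_length_bp = 51000L * n_markers_per_chromosome,
                              F_background = 0.1,
                              selected_blocks = list(),
                              maf_floor = 0.05,
                              missing_rate = 0.005,
                              n_hwe_violating_markers = 0L,
                              admixture_alpha = NULL,
                              breed_names = paste0("breed", seq_len(n_breeds)),
                              seed = 1L) {
  n_per_breed <- rep_len(as.integer(n_per_breed), n_breeds)
  F_background <- rep_len(F_background, n_breeds)
  if (any(F_background <= 0 | F_background >= 1)) stop("F must lie in (0, 1)")
  if (maf_floor < 0 || maf_floor >= 0.5) stop("maf_floor must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  cfg <- structure(
    list(
      n_breeds = as.integer(n_breeds), n_per_breed = n_per_breed,
      n_chromosomes = as.integer(n_chromosomes),
      n_markers_per_chromosome = as.integer(n_markers_per_chromosome),
      chrom_length_bp = as.integer(chrom_length_bp),
      F_background = F_background, selected_blocks = selected_blocks,
      maf_floor = maf_floor, missing_rate = missing_rate,
      n_hwe_violating_markers = as.integer(n_hwe_violating_markers),
      admixture_alpha = admixture_alpha,
      breed_names = breed_names, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
  for (blk in cfg$selected_blocks) {
    if (blk$start_index < 1L ||
        blk$start_index + blk$n_snps - 1L > cfg$n_markers_per_chromosome)
      stop("selected block exceeds chromosome bounds")
    if (blk$chromosome < 1L || blk$chromosome > cfg$n_chromosomes)
      stop("selected block on nonexistent chromosome")
  }
  cfg
}

#' Specify a selected SNP block
#'
#' @param chromosome chromosome index (1-based).
#' @param start_index index of the first SNP of the block on that
#'   chromosome (1-based).
#' @param n_snps block length in SNPs.
#' @param F_selected drift parameter inside the block for affected breeds.
#' @param affected_breeds indices of the breeds that carry the signature
#'   (default: breed 1).
#' @return a list usable in `simulation_config(selected_blocks = ...)`.
#' @export
selected_block <- function(chromosome, start_index, n_snps, F_selected,
                           affected_breeds = 1L) {
  list(chromosome = as.integer(chromosome), start_index = as.integer(start_index),
       n_snps = as.integer(n_snps), F_selected = F_selected,
       affected_breeds = as.integer(affected_breeds))
}

sim_map <- function(cfg) {
  L <- cfg$n_chromosomes * cfg$n_markers_per_chromosome
  spacing <- cfg$chrom_length_bp %/% cfg$n_markers_per_chromosome
  data.frame(
    marker_id = sprintf("snp%05d", seq_len(L)),
    chromosome = as.character(rep(seq_len(cfg$n_chromosomes),
                                  each = cfg$n_markers_per_chromosome)),
    position_bp = as.integer(rep(spacing * seq_len(cfg$n_markers_per_chromosome),
                                 cfg$n_chromosomes)),
    allele_a = "A", allele_b = "C",
    stringsAsFactors = FALSE
  )
}

# per-(breed, locus) drift parameters and the selected-locus flag
sim_F_matrix <- function(cfg) {
  L <- cfg$n_chromosomes * cfg$n_markers_per_chromosome
  Fm <- matrix(rep(cfg$F_background, L), cfg$n_breeds, L)
  selected <- logical(L)
  for (blk in cfg$selected_blocks) {
    off <- (blk$chromosome - 1L) * cfg$n_markers_per_chromosome
    idx <- off + blk$start_index + seq_len(blk$n_snps) - 1L
    Fm[blk$affected_breeds, idx] <- blk$F_selected
    selected[idx] <- TRUE
  }
  list(F = Fm, selected = selected)
}

#' Simulate a multi-breed genotype panel (Balding-Nichols model)
#'
#' Draws ancestral frequencies, drifts them independently into each breed,
#' and samples diploid genotypes in HWE within breed, then applies the
#' configured HWE violations and missingness. Marker positions are evenly
#' spaced. Fully reproducible from `config$seed`.
#'
#' Under this model with `s` equal-sized breeds and common drift `F`, the
#' expected Nei-Chesser fixation index is `F (1 - 1/s) / (1 - F/s)` — a
#' closed form the test-suite uses as an analytic oracle.
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (list:
#'   `ancestral_freq`, `breed_freq` (breeds x markers), `selected` (logical
#'   per marker), `hwe_violating` (logical per marker), `hwe_violating_breed`
#'   (index or `NA`), `breed` per sample).
#' @export
simulate_panel <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  L <- nrow(map)
  n <- sum(cfg$n_per_breed)
  fm <- sim_F_matrix(cfg)

  p_anc <- stats::runif(L, cfg$maf_floor, 1 - cfg$maf_floor)
  breed_freq <- matrix(NA_real_, cfg$n_breeds, L)
  for (i in seq_len(cfg$n_breeds)) {
    Fv <- fm$F[i, ]
    breed_freq[i, ] <- stats::rbeta(L, p_anc * (1 - Fv) / Fv,
                                    (1 - p_anc) * (1 - Fv) / Fv)
  }
  # guard against numerically degenerate Beta draws
  breed_freq <- pmin(pmax(breed_freq, 0), 1)

  breed <- rep(cfg$breed_names, cfg$n_per_breed)
  dosage <- matrix(NA_integer_, n, L)
  row0 <- 0L
  for (i in seq_len(cfg$n_breeds)) {
    ni <- cfg$n_per_breed[i]
    dosage[row0 + seq_len(ni), ] <- matrix(
      stats::rbinom(ni * L, 2L, rep(breed_freq[i, ], each = ni)), ni, L
    )
    row0 <- row0 + ni
  }

  hwe_violating <- logical(L)
  hwe_breed <- rep(NA_integer_, L)
  if (cfg$n_hwe_violating_markers > 0L) {
    candidates <- which(!fm$selected)
    viol <- sample(candidates, min(cfg$n_hwe_violating_markers, length(candidates)))
    hwe_violating[viol] <- TRUE
    for (l in viol) {
      b <- sample.int(cfg$n_breeds, 1L)
      hwe_breed[l] <- b
      rows <- which(breed == cfg$breed_names[b])
      dosage[rows, l] <- 1L  # forced heterozygote excess
    }
  }

  if (cfg$missing_rate > 0) {
    miss <- stats::runif(n * L) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }

  sample_ids <- sprintf("%s_%03d", breed, unlist(lapply(cfg$n_per_breed, seq_len)))
  gm <- genotype_matrix(dosage, breed, map, sample_ids = sample_ids)
  truth <- list(
    ancestral_freq = p_anc, breed_freq = breed_freq,
    selected = fm$selected, hwe_violating = hwe_violating,
    hwe_violating_breed = hwe_breed, breed = breed
  )
  list(genotypes = gm, truth = truth)
}

#' Simulate an admixed panel
#'
#' Like [simulate_panel()], but each sample draws its membership vector
#' `Q ~ Dirichlet(alpha, ..., alpha)` over the breeds (ancestral clusters)
#' and every allele copy independently picks a source breed with
#' probability `q_k` before being drawn `Bernoulli(p_kl)`. Small `alpha`
#' concentrates samples near the simplex vertices (nearly pure ancestry);
#' large `alpha` makes everyone uniformly admixed.
#'
#' @param config a [simulation_config()] with `admixture_alpha` set.
#' @return list with `genotypes` and `truth` (including the per-sample
#'   `Q` matrix). Breed labels are assigned by each sample's majority
#'   ancestry component.
#' @export
simulate_admixed <- function(config) {
  cfg <- config
  if (is.null(cfg$admixture_alpha)) stop("admixture_alpha must be set")
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  L <- nrow(map)
  n <- sum(cfg$n_per_breed)
  K <- cfg$n_breeds
  fm <- sim_F_matrix(cfg)

  p_anc <- stats::runif(L, cfg$maf_floor, 1 - cfg$maf_floor)
  breed_freq <- matrix(NA_real_, K, L)
  for (i in seq_len(K)) {
    Fv <- fm$F[i, ]
    breed_freq[i, ] <- stats::rbeta(L, p_anc * (1 - Fv) / Fv,
                                    (1 - p_anc) * (1 - Fv) / Fv)
  }
  breed_freq <- pmin(pmax(breed_freq, 0), 1)

  g <- matrix(stats::rgamma(n * K, cfg$admixture_alpha, 1), n, K)
  Q <- g / rowSums(g)
  dosage <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    src1 <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
    src2 <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
    p1 <- breed_freq[cbind(src1, seq_len(L))]
    p2 <- breed_freq[cbind(src2, seq_len(L))]
    dosage[i, ] <- (stats::runif(L) < p1) + (stats::runif(L) < p2)
  }
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(n * L) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }
  breed <- cfg$breed_names[max.col(Q)]
  sample_ids <- sprintf("adm_%04d", seq_len(n))
  gm <- genotype_matrix(dosage, breed, map, sample_ids = sample_ids)
  list(
    genotypes = gm,
    truth = list(ancestral_freq = p_anc, breed_freq = breed_freq, Q = Q,
                 selected = fm$selected, breed = breed)
  )
}
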