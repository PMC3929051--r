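---
title: "breedscan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breedscan: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

breedscan analyses dense SNP-chip genotypes from several livestock breeds
to answer two questions: *where* in the genome have breeds diverged more
than drift alone explains (selection signatures), and *how* are the breeds
structured as populations (kinship geometry and model-based clustering).
This vignette documents the statistical models, every tunable that matters,
the numerical conventions, and what the synthetic-data tests do and do not
establish.

## The data model

A `genotype_matrix` holds a samples × markers dosage matrix counting copies
of `allele_b` (values 0/1/2, `NA` = missing call), per-sample breed labels,
and a marker map (chromosome label, 1-based bp position, both alleles).
Marker ids are unique and maps are position-sorted within chromosome by
construction. PLINK text (`.ped`/`.map`) is the interchange format; the
family-ID column carries the breed. Because a `.ped` stores bases only,
absolute allele labels of monomorphic markers cannot survive a write/read
cycle; `canonicalize_alleles()` defines the fixed point (allele_b = the
lexicographically later *observed* allele), the round trip is exact on that
canonical form, and every downstream statistic is invariant to the
relabeling, which is tested.

## Quality control

The cascade mirrors standard chip QC for multi-breed sire panels and runs
in a fixed order, twice:

1. **Autosome/complete-map restriction** — only markers on autosomes
   ("1".."29" for cattle) with a known position (`bp > 0`) are kept.
2. **Call rate** (default 0.99 for both samples and markers). Both rates
   are computed on the *unfiltered* panel and failing samples and markers
   are removed in one symmetric step. Sequential alternatives
   (samples-first or markers-first) give different counts; the symmetric
   rule is order-free and therefore reproducible from the report alone.
3. **MAF** (default 0.05), pooled across breeds, since filtering precedes
   any breed separation; monomorphic markers are always removed.
4. **Heterozygosity outliers** (default FDR 0.01). Only abnormally *high*
   observed heterozygosity is flagged (the contamination signature).
   The reference procedure is cited in the QC literature without formulas,
   so breedscan declares its own: upper-tail p-values from a normal model
   with robust centre/scale (median and MAD, both replaceable via
   arguments), then Benjamini–Hochberg. A zero MAD (degenerate,
   all-equal heterozygosity) skips the step with a warning rather than
   dividing by zero.
5. **Within-breed HWE** (default per-test P < 0.01): the exact test runs
   separately in every breed and a marker is dropped when it fails in at
   least one breed. The exact (Wigginton-style) test is the default
   because it is enumerable — the test-suite oracle enumerates all
   C(2n, nA) allele placements for n ≤ 10 — and conservative
   (measured type-I ≈ 0.009 at α = 0.01, n = 100).
6. **Second pass**: the pooled filtered data re-enter the call-rate and
   MAF filters. On clean data this removes nothing and the whole pipeline
   is a fixed point of itself; the two-pass design exists because marker
   removal can push a borderline sample below the call-rate threshold
   (and vice versa), which the suite demonstrates with an engineered
   fixture.

Missing genotypes are excluded from every count and never imputed.

## The fixation-index scan

### Per-locus estimator

For `s` subpopulations with non-missing sample counts `n_i`, allele-B
frequencies `x_i`, harmonic mean `ñ = s / Σ(1/n_i)` and observed
heterozygosities averaged as `H_O`:

    H_S = ñ/(ñ−1) · [ 1 − mean_i Σ_k x_ki² − H_O/(2ñ) ]
    H_T = 1 − Σ_k x̄_k² + H_S/(ñs) − H_O/(2ñs)
    Fst = (H_T − H_S) / H_T

with `x̄_k` the *unweighted* mean frequency over subpopulations — every
breed counts equally regardless of size, the "fixed effects" sampling view
appropriate when the sampled sires essentially *are* the breed rather than
a random draw from it. The corrected estimator is unbiased, so per-locus
values can be slightly negative at undifferentiated loci; consequently
`H_S` may exceed `H_T` there (a point sometimes mis-stated as an
invariant). Loci monomorphic overall have `H_T = 0` and an undefined
index, returned as `NaN`; subpopulations with no data at a locus are
dropped and `s` decremented, with `NaN` when fewer than two remain.

Two summaries exist deliberately: `fst_profile()` returns per-locus ratios
(what gets windowed and plotted), while `global_fst()` averages `H_S` and
`H_T` across loci first and returns the ratio of averages. The latter is
the multi-locus GST tradition and is free of ratio (Jensen) bias: under
the Balding–Nichols generator it recovers the closed form
`F(1−1/s)/(1−F/s)` to ±0.001 at F up to 0.3, where the mean of per-locus
ratios is off by ~0.03.

### Windows, thresholds, regions

Selection leaves signatures across *adjacent* markers, so per-locus values
are averaged in SNP windows that never span chromosome boundaries. Two
semantics are provided because genome-scan practice uses both:
`"groups"` (default, width 8) partitions each chromosome into consecutive
non-overlapping blocks — a trailing remainder is kept as its own window
when it has at least `⌈width/2⌉` markers and merged into the previous
block otherwise (a declared convention; any fixed rule works, but it must
be fixed) — and `"sliding"` (step 1, typically width 3) for
single-chromosome views. `NaN` loci stay in their window but are excluded
from the mean; an all-`NaN` window is dropped rather than zero-filled, so
peaks are not diluted.

Outlier thresholds are the empirical 1% and 99% quantiles (type-7 linear
interpolation) of *all* window means of the scan, genome-wide — one pair
of horizontal lines for the whole genome, not per-chromosome thresholds.
Consecutive outlier windows merge into regions; regions are reported in
1-based inclusive bp and converted to 0-based half-open BED only inside
the interval annotator, whose gene intervals must simply be on the same
genome build as the map (the package is build-agnostic).

One-vs-rest contrasts (`one_vs_rest_profiles()`) attribute a signature to
the breed driving it: the focal breed versus the other breeds *pooled into
a single subpopulation* (s = 2). The alternative — an s-breed scan with
focal weighting — is noted but not implemented. A focal breed of fewer
than 2 samples is refused (the `ñ/(ñ−1)` correction has a pole at 1).

## Kinship and multidimensional scaling

Genomic kinship is the frequency-standardized estimator

    k_ij = (1/L_ij) Σ_l (x_il − 2p̂_l)(x_jl − 2p̂_l) / (4 p̂_l(1−p̂_l))

over pooled frequencies `p̂_l`, skipping monomorphic markers, with
pairwise-complete marker sets `L_ij` under missingness (uses all data; an
exact-reproducibility alternative would be global deletion, not needed
here). This is the variant whose self-kinship is `½(1+F_i)` — about 0.5
for outbred samples — which is exactly what makes the companion distance
`d_ij = 0.5 − k_ij` vanish on the diagonal. The distance is *not*
clamped: pairs with k > 0.5 (duplicates, close inbred relatives) yield
negative entries, preserved and counted, because silently truncating them
would hide data problems.

Classical (Torgerson) MDS double-centers the squared distances,
`B = −½ J D² J`, and eigendecomposes `B`. Numerical conventions: small
asymmetries are symmetrized and a nonzero diagonal (expected here, since
`0.5 − k_ii ≈ −F/2`) is reset to zero, each with a warning; negative
eigenvalues — the signature of non-Euclidean input — are dropped and
counted; requesting more components than positive eigenvalues truncates
with a warning; each component's sign is fixed by making its first
nonzero loading positive so embeddings are platform-deterministic.
Cluster geometry (per-breed centroids, all pairwise centre distances, and
distances to the global centre of mass) is computed in the embedded
3-component space, matching how such plots are read; distances in full
space would differ and are not reported.

## Admixture model and the number of clusters

The Gibbs sampler implements the standard admixture model: each of the
two allele copies of every genotype carries a latent cluster assignment
drawn ∝ `q_ik p_kl` (or `q_ik(1−p_kl)`), cluster allele frequencies get a
Uniform(0,1) prior and Beta posterior draws, membership rows a symmetric
Dirichlet(α) prior (α = 1 by default, fixed, exposed in the API — not
estimated). Allele frequencies are *independent* across clusters: the
correlated-frequency ("F-model") prior of the reference software is
substantial extra machinery and is explicitly out of scope; cluster
recovery is instead validated against generator truth (mean |Q − truth| ≈
0.03 at F = 0.3 with 500 loci and 40 samples per population).

The model log-probability is estimated from the sampling-phase
log-likelihood trace as `lnP(D) = mean(ll) − var(ll)/2`, the statistic the
ΔK criterion consumes. Full-scale runs use 5,000 burn-in + 10,000 sweeps;
desk-scale tests use 200 + 800, which the recovery checks show is ample at
these panel sizes. Fits are bit-identical for identical (seed, data, K):
the C++ core draws exclusively from R's RNG stream.

The Evanno statistic is

    ΔK = | m(L(K+1)) − 2 m(L(K)) + m(L(K−1)) | / s(L(K))

where `m` and `s` are the mean and standard deviation of `lnP(D)` over
the independent runs at each K. The second difference is taken of the
*per-K run means* (the published phrasing is ambiguous between that and
pairing runs arbitrarily; the two coincide in expectation and the per-K
mean reading is fixed here). ΔK exists only for interior K, needs ≥ 2
runs per K (5 by default; the original description mentions 10-run means
while reporting 5 performed runs — run count is a parameter, not a
constant), and a zero across-run sd leaves ΔK undefined with a warning
rather than infinite. Label switching across runs is resolved by
`align_q_across_runs()`, a greedy best-correlation column matching that
recovers arbitrary permutations exactly (verified exhaustively for
K ≤ 3).

## The synthetic-data generator

`simulate_panel()` states the world the tests live in: ancestral
frequencies `p ~ Uniform(maf_floor, 1 − maf_floor)`; each breed drifts
independently, `p_i ~ Beta(p(1−F)/F, (1−p)(1−F)/F)` (Balding–Nichols);
genotypes are drawn in HWE within breed; "selected" blocks of consecutive
SNPs use a larger F in the affected breeds only, emulating breed-specific
signatures; HWE violations are forced all-heterozygote calls in one
breed (unambiguous and maximally detectable); missingness is i.i.d.
Defaults emulate a bovine 50K chip at desk scale: 29 autosomes, 51 kb
uniform spacing, five breeds of unequal size (the published five-breed
cohort proportions scaled down ~14×), F = 0.1 — breed-level
differentiation — a 0.05 MAF floor and 0.5% missing calls.

Balding–Nichols was chosen because its expected GST has the closed form
`F(1−1/s)/(1−F/s)`, giving the pipeline an *analytic* acceptance surface.
What the generator does **not** emulate: linkage disequilibrium (loci are
independent; real chips have block-wise LD, so real window means are more
correlated than simulated ones), realistic recombination/spacing maps
(spacing is uniform; only window containment is exercised), informative
missingness, genotyping batch effects, and pedigree structure within
breeds. A green test therefore establishes correctness of the estimators
and machinery under the stated model — not that a particular biological
dataset would yield particular peaks.

`simulate_admixed()` adds per-sample `Q ~ Dirichlet(α·1_K)` with every
allele copy drawn from a breed chosen by `Q`; α → 0 gives near-vertex
(pure) individuals, large α uniform admixture.

## Pipeline, reproducibility, degenerate inputs

`run_pipeline()` executes simulate/read → QC → scans (named groupings
plus one-vs-rest) → kinship/MDS/geometry → admixture/ΔK, writing every
table as TSV (regions also as BED) plus a per-stage report stamped with a
config hash and the seed. Outputs are pure functions of (config, seed);
the determinism check diffs two complete runs byte for byte. Every stage
error aborts with the stage name while preserving partial outputs.

Degenerate-input conventions, collected: monomorphic loci → `NaN` Fst,
skipped in kinship; empty subpopulation at a locus → dropped, `s`
decremented; `H_T = 0` → `NaN`; zero-MAD heterozygosity → step skipped;
sample pairs with no shared non-missing marker → error naming the pair;
`q_low > q_high` → error; all markers removed at any QC stage → "empty
panel" error; K exceeding the sample count → error; fewer than 2 runs per
K or fewer than 3 consecutive K values → error.

## Known limitations

- No LD-aware or haplotype statistics (iHS, XP-EHH) — per-locus GST and
  window means only, with empirical quantiles rather than significance
  tests (none are defined for this scan).
- The admixture module omits the correlated-frequency prior, the linkage
  model and informative priors; at strong divergence this matters little
  (validated), at weak divergence the correlated model is more sensitive.
- The interval annotator is a generic overlap reporter; it does not ship
  gene coordinates and knows nothing about genome builds.
- PLINK binary (`.bed`) input is not implemented; text `.ped`/`.map` is
  the normative dialect at package scale.
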