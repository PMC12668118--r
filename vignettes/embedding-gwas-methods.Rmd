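---
title: "Methods: contrastive embedding phenotypes and multivariate GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive embedding phenotypes and multivariate GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`embgwas` implements a pipeline for genetic analysis of image-derived
phenotypes: a neural encoder summarizes each image as a fixed-length feature
vector; contrastive training aligns that latent space with chronological age;
per-participant embeddings (eye-averaged, PCA-reduced, rank-normalized) become
a K-dimensional phenotype for a multivariate GWAS; significant variants are
grouped into independent loci by LD clumping; and trait-associated directions
in embedding space are extracted with a ridge-BLUP mixed model and linearly
interpolated between extreme-tail endpoints.

Real fundus-imaging cohorts are access-restricted, so the package ships a
seeded synthetic cohort generator that reproduces the statistical structure
the methods need to be exercised against: LD-structured genotypes,
high-dimensional features carrying a nonlinear age signal, planted sparse
genetic effects, paired left/right observations, and disease labels from a
logistic liability.

## The synthetic cohort: what it emulates, what it does not

`synth_config()` states the world once; every draw is a deterministic
function of the config and its seed.

* **Genotypes.** Two haplotypes per participant from a first-order Markov
  copying process: the allele at variant $j$ copies variant $j-1$ with
  probability `ld_decay`, else is a fresh Bernoulli draw at that variant's
  frequency. At equal frequencies the adjacent-dosage correlation is
  approximately `ld_decay`, giving tunable block-like $r^2$ for the clumping
  tests. Frequencies are uniform on `maf_range` (default 0.05–0.45; the
  upper bound is kept strictly below 0.5 so "minor" is well defined).
* **Features.** Per image, $f = W\phi(\mathrm{age}) + \sum_v g_v e_v +
  \varepsilon$ with $\phi$ a standardized cubic polynomial basis (so the age
  signal is genuinely nonlinear and contrastive alignment has something to
  straighten), $W$ a seeded Gaussian loading matrix scaled to unit per-feature
  signal variance, $g_v$ standardized dosages of the causal variants, $e_v$
  planted per-dimension effects of size `effect_size` on `effect_dims`
  random dimensions, and i.i.d. Gaussian noise per image (`noise_sd`,
  default 1 — comparable to the per-feature age signal, which is what makes
  denoising by contrastive alignment measurable). Both images of a
  participant share all systematic terms.
* **Disease.** A logistic liability in standardized age and the projection
  of the systematic features onto a random unit `trait_direction`, with the
  intercept solved to hit a configurable prevalence (default 10%, a
  realistic ocular-disease ballpark for a mid-life cohort).
* **Not emulated.** Population structure, relatedness, admixture,
  imputation quality, realistic human LD maps, and registry-based
  time-to-event labels. A green test here establishes the statistical
  machinery, not robustness to confounding that the generator never creates.

Defaults (500 participants, 1000 variants, 256 raw features, ages 40–70,
80% two-eyed) are desk-scale stand-ins chosen once; acceptance-grade checks
state their own sizes explicitly.

## Contrastive alignment (Rank-N-Contrast)

For a batch with representations $z_i$ and labels $y_i$, every ordered pair
$(i, j)$, $j \ne i$, is an anchor/positive pair with candidate set
$S_{ij} = \{k \ne i : |y_i - y_k| \ge |y_i - y_j|\}$, and

$$\ell_{ij} = -\log \frac{\exp(s_{ij}/\tau)}{\sum_{k \in S_{ij}}
\exp(s_{ik}/\tau)}, \qquad s_{ik} = -\lVert z_i - z_k \rVert_2 ,$$

averaged over all pairs. The positive always belongs to its own candidate
set, so every term — and the loss — is nonnegative, and a batch of two is
exactly zero. The loss depends on representations only through pairwise
distances, hence is invariant to rigid translations. We implement the
canonical symmetric-candidate form; descriptions phrased as "among all
younger samples, the closest" are read as a paraphrase of the same
objective, and an age-asymmetric candidate set is deliberately *not* the
default because the symmetric form is the published objective for
regression-aware contrastive learning.

**Encoder and optimizer.** This environment has no GPU deep-learning stack
for R, and the loss itself is the contribution, so the desk-scale encoder is
a hand-written MLP (input → 128 → 64, ReLU, linear output used directly as
the representation) trained with a hand-written AdamW on analytic gradients
of the loss; the gradient is verified against central finite differences in
the test suite (max abs error ~1e-10). Desk-scale defaults: temperature
$\tau = 2$ (the canonical default; the temperature is otherwise unstated in
the motivating work), learning rate 1e-3, weight decay 1e-4, batch 64, up to
60 epochs, early stopping on the validation loss with patience 10. The
full-scale fundus setting (learning rate 5e-6, weight decay 1e-5, batch 64)
is preserved as `train_config_fullscale()` for documentation; a freshly
initialized small MLP needs the larger step size. No data augmentation at
desk scale: augmentation policies are image-specific, and the synthetic
features support optional Gaussian jitter at most.

**Splits.** `make_split_plan()` assigns *participants* to 5 folds;
within a fold, 72% of the cohort trains, 8% drives early stopping, 20%
tests. All images of one participant share a split, so eyes never straddle
partitions.

**Probing protocol.** Embedding quality is measured by ridge probes: a
closed-form SVD ridge path (penalty chosen by internal 5-fold CV, grid
including $\lambda = 0$) for age MAE, and `cv.glmnet` ridge logistic
regression (AUC over 20 random 80/20 splits, paired t-tests for
comparisons) for disease. The linear probe is closed-form rather than
coordinate-descent because the exact-affine sanity case (MAE $\le$ 1e-6)
sits below iterative solver tolerances. One protocol subtlety: the encoder
is trained on fold 1, so probe comparisons are evaluated **on fold 1 only**.
Folds 2–5 place fold-1 training participants in their test partitions, and
an encoder can memorize training labels into its representation — in a
permuted-label control this manufactured an apparent ~16% gain that
disappears under the fold-1-only protocol.

## Embedding phenotypes

Per-image features are averaged within participant (left/right eye),
reduced by centered PCA (component signs fixed so the largest-magnitude
loading is positive, making the decomposition deterministic), and each
retained component is rank-transformed to normal quantiles,
$\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties. The fixed order —
average eyes → PCA → rank-INT → association — holds the phenotype definition
identical across all tests; PCA is fitted once on the full analysis cohort.
Sample ordering is canonicalized (sorted ids) so tie handling cannot depend
on input order. Full scale retains 40 components; desk-scale tests use
5–16 so that all moments are well estimated at their sample sizes.

One contract conflict is resolved here: a two-value input `(5, 5)` is
*all-equal*, and the degenerate-column error takes precedence over the
tie-symmetry example; tie symmetry is exercised on `(5, 5, 9)` instead.

The covariate builder produces intercept, centered age, sex (0/1), age²,
sex×age, sex×age² (age is centered *before* squaring to limit
collinearity), optional genetic PCs, and one-hot batch columns with the
first level dropped; rank-deficient designs are rejected naming the
collinear columns.

## Multivariate association

With covariates $C$ (residual projector $M$), rank-normalized phenotypes
$Y \in \mathbb{R}^{N \times K}$, and dosages $g$ (missing values
mean-imputed per variant, MAF computed after imputation, default filter
MAF ≥ 1%):

* **Null model** (fitted once): $B_0$ by least squares,
  $\hat\Sigma = E^\top E/(N - \mathrm{rank}\,C)$ from null residuals.
* **Score test:** $\hat\beta = (g^\top M Y)/(g^\top M g)$ and
  $\lambda = (g^\top M g)\, \hat\beta \hat\Sigma^{-1} \hat\beta^\top
  \sim \chi^2_K$ under the null. $\lambda$ is invariant to invertible
  re-mixing of the phenotype columns and to rescaling of $g$; effects are
  reported per dosage unit (no genotype standardization — only the reporting
  convention is affected).
* **Refined test:** "partial optimization under the alternative" is
  implemented as one post-hoc ML re-estimation of the residual covariance
  and a Gaussian likelihood-ratio statistic
  $N(\log\det S_0 - \log\det S_1)$ on $K$ df; `n_iter = 0` reduces exactly
  to the score test, and the two agree asymptotically on null simulations —
  that agreement is itself a test.
* **Univariate baseline:** each dimension is tested with the $K=1$ score
  test and per-variant p-values are combined with the aggregated Cauchy
  test, $T = \tfrac1K \sum_k \tan((0.5 - p_k)\pi)$,
  $p = 0.5 - \arctan(T)/\pi$ (equal weights; no weighting is specified
  anywhere, and equal weights keep $T$ exactly standard Cauchy under
  independent uniform inputs). P-values exactly 0 or 1 are clipped to
  machine-safe bounds with a warning; tail p-values are computed from the
  log survival function of $\chi^2_K$ to avoid underflow.
* **Calibration:** `permutation_null()` permutes genotype sample indices —
  phenotypes and covariates stay aligned with each other, so one null model
  serves every permutation — and reports empirical type-I error, genomic
  inflation $\lambda_{GC} = \mathrm{median}(\lambda)/\mathrm{median}
  (\chi^2_K)$, KS distance to Uniform(0,1), and QQ data.
* **Burden mode:** gene-level burden scores (an input; their construction
  is upstream of this package) pass through the identical machinery with no
  MAF filter; constant vectors are flagged with `p = NA`.

In the dense-effect regime the joint test concentrates the signal where the
per-dimension tests each stay under their own multiple-testing burden; in a
sparse regime (one of 40 dimensions) the Cauchy baseline is competitive.
The acceptance comparison uses effects on 5 of K = 10 dimensions with
per-dimension effect 0.15 at n = 500 — a regime scan at design time placed
this inside "per-dimension power low, joint power high", and it was frozen
before the comparison was run in anger.

## Locus discovery

Greedy clumping: repeatedly take the unclaimed significant variant
(P < 5e-8 by default) with the smallest p-value as a lead — ties broken by
(chrom, pos) — and claim every unclaimed variant within the window whose
sample LD with the lead is $r^2 \ge 0.1$, significant or not (the purpose is
independence of the leads, so LD partners are absorbed regardless of their
own p). LD is squared Pearson correlation of mean-imputed dosages on the
GWAS samples themselves. "5 Mb window" is ambiguous between total span and
distance-from-index; the default reads it as total span (±2.5 Mb), and
`window_convention = "index"` gives PLINK's ±window behavior.

## Trait axes

The axis model is $t = C\beta + Xu + \varepsilon$ with isotropic
$u \sim N(0, \sigma^2_u I_K)$ — the standard ridge-BLUP reading of
"embeddings as random effects". REML is profiled over the single ratio
$\gamma = \sigma^2_u/\sigma^2_e$ (coarse log-grid then 1-d refinement,
tolerance 1e-6), with all matrix work in $K \times K$ space via Woodbury
identities. Binary traits are fitted on the 0/1 scale, matching the
practice of applying one linear mixed model form to age, disease codes and
genotypes alike. Leave-one-out random-effect scores
$s_i = X_i \hat u^{(-i)}$ use the exact rank-one downdate of the Henderson
system at fixed variance components (no per-sample REML refit; the
brute-force oracle in the tests uses the same convention). Extreme-tail
endpoints are means over the bottom/top $\lceil qN \rceil$ samples by score
(q = 0.001 at full scale, 0.05 at desk scale where 0.1% tails would be
single noisy samples; ties broken by sample id), and
$x(\alpha) = (1-\alpha)x_{\mathrm{low}} + \alpha x_{\mathrm{high}}$ is exact
at its endpoints. Extrapolation beyond [0, 1] sits behind an explicit flag.

**Recovery-report pullback.** Mapping the embedding-space axis
$x_{\mathrm{high}} - x_{\mathrm{low}}$ back to raw feature space through the
PCA rotation alone recovers the *covariance-distorted* direction: if the
trait is $\mathrm{dir}^\top f$, the extreme-tail mean difference is
proportional to the embedding covariance times the regression weights. The
report therefore divides component $k$ by the score standard deviation
(whitened/rank-normalized embeddings) or variance (raw scores) before
rotating back — the trait-gradient pullback. The recovery benchmark runs at
D = K = 16: a scan at design time showed that with many low-variance
components (D = 32+) estimation noise in the whitened tail components caps
the achievable cosine below the 0.9 benchmark regardless of seed, i.e. the
limit is information, not implementation. Recovery also requires the
whitened embedding: on raw-variance PC scores a random planted direction is
unrecoverable (cosine 0.1–0.3) because the age-signal anisotropy dominates
the tail means. Binary disease labels attenuate recovery further and are
not the benchmark trait; the benchmark uses the continuous projection of
the averaged features on the planted direction.

## Numerical and degenerate-input policy

* Residual covariances are Cholesky-factored; non-positive-definite or
  scale-degenerate (exact covariate fit) cases raise an error suggesting
  fewer components or ridge jitter rather than limping on.
* Monomorphic / covariate-collinear dosages give flagged records with
  `p = NA`, never a crash mid-scan.
* All package randomness flows through one seed via named substreams, and
  the caller's RNG state is always restored; identical config + seed gives
  bit-identical artifacts (asserted byte-for-byte in the pipeline tests).
* Internal CV folds of the probes are seeded per split so that comparing an
  embedding set against itself is exactly a tie.

## Known limitations

* The generator's genetics-to-feature map is linear and additive; it is an
  assumption for testing, not a claim about retinal biology.
* No relatedness or mixed-model correction in the GWAS: the synthetic
  cohort is unrelated and homogeneous by construction.
* The refined test brackets, rather than reproduces, an unpublished
  partial-optimization scheme; score and refined tests are cross-validated
  against each other on null simulations.
* Image decoding (generative synthesis along interpolated axes) is out of
  scope; the axis tables are the terminal artifact.
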