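#' Synthetic cohort configuration
#'
#' Bundles every tunable of the synthetic cohort generator: genotypes with a
#' first-order Markov LD structure, per-image features carrying a nonlinear
#' chronological-age signal plus planted genetic effects, and binary disease
#' labels from a logistic liability. Identical config + seed gives
#' bit-identical output.
#'
#' @param n_participants number of participants.
#' @param p_both_eyes probability a participant contributes two images.
#' @param n_variants number of simulated variants.
#' @param maf_range length-2 vector (low, high) of allele frequencies;
#'   `0 < low <= high < 0.5`.
#' @param ld_decay probability in `[0, 1)` that a haplotype copies its left
#'   neighbour's allele state (first-order Markov copying; adjacent-variant
#'   dosage correlation is approximately `ld_decay` at equal frequencies).
#' @param n_raw_features raw feature dimension D per image.
#' @param age_range length-2 vector (min, max) age in years.
#' @param n_causal_variants number of variants with planted feature effects.
#' @param effect_dims number of feature dimensions each causal variant loads on.
#' @param effect_size per-dimension effect of one standardized dosage unit.
#' @param noise_sd standard deviation of per-image Gaussian feature noise.
#' @param missing_rate optional uniform genotype missingness rate (default 0).
#' @param prevalence target disease prevalence of the logistic liability.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_participants = 500L,
                         p_both_eyes = 0.8,
                         n_variants = 1000L,
                         maf_range = c(0.05, 0.45),
                         ld_decay = 0.9,
                         n_raw_features = 256L,
                         age_range = c(40, 70),
                         n_causal_variants = 20L,
                         effect_dims = 5L,
                         effect_size = 0.25,
                         noise_sd = 1,
                         missing_rate = 0,
                         prevalence = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    p_both_eyes = check_prob(p_both_eyes, "p_both_eyes"),
    n_variants = check_count(n_variants, "n_variants"),
    maf_range = as.numeric(maf_range),
    ld_decay = check_prob(ld_decay, "ld_decay", hi = 1, hi_open = TRUE),
    n_raw_features = check_count(n_raw_features, "n_raw_features"),
    age_range = as.numeric(age_range),
    n_causal_variants = check_count(n_causal_variants, "n_causal_variants", min = 0L),
    effect_dims = check_count(effect_dims, "effect_dims", min = 0L),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    missing_rate = check_prob(missing_rate, "missing_rate", hi = 1, hi_open = TRUE),
    prevalence = check_prob(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[1] > cfg$maf_range[2] || cfg$maf_range[2] >= 0.5) {
    stop("maf_range must satisfy 0 < low <= high < 0.5", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    stop("age_range must be (min, max) with min < max", call. = FALSE)
  }
  if (cfg$n_causal_variants > cfg$n_variants) {
    stop("n_causal_variants cannot exceed n_variants", call. = FALSE)
  }
  if (cfg$effect_dims > cfg$n_raw_features) {
    stop("effect_dims cannot exceed n_raw_features", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Construct a genotype matrix object
#'
#' @param dosage numeric samples x variants matrix with entries in `[0, 2]`
#'   (NA = missing).
#' @param variants data.frame with columns chrom, pos, id, ref, alt.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, variants, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(variants))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(dosage)))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]", call. = FALSE)
  dimnames(dosage) <- list(sample_ids, variants$id)
  structure(list(dosage = dosage, variants = as.data.frame(variants),
                 sample_ids = as.character(sample_ids)),
            class = "genotypes")
}

#' @method print genotypes
#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate genotypes with block-like LD
#'
#' Draws two haplotypes per participant under a first-order Markov copying
#' process: the allele at variant j copies the allele at variant j-1 with
#' probability `ld_decay`, and is otherwise a fresh Bernoulli draw at that
#' variant's allele frequency. Dosage is the haplotype sum, so entries lie in
#' \{0, 1, 2\}. Variants sit on one synthetic chromosome at evenly spaced
#' positions (10 kb apart).
#'
#' @param config a [synth_config()].
#' @return A [genotypes] object with `config$n_variants` variants.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  p <- config$n_variants
  with_seed(substream_seed(config$seed, "genotypes"), {
    maf <- runif(p, config$maf_range[1], config$maf_range[2])
    sim_hap <- function() {
      h <- matrix(0L, n, p)
      h[, 1] <- rbinom(n, 1L, maf[1])
      if (p > 1L) for (j in 2:p) {
        copy <- runif(n) < config$ld_decay
        fresh <- rbinom(n, 1L, maf[j])
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      }
      h
    }
    dosage <- sim_hap() + sim_hap()
    if (config$missing_rate > 0) {
      dosage[runif(length(dosage)) < config$missing_rate] <- NA
    }
    variants <- data.frame(
      chrom = "chrS1",
      pos = seq_len(p) * 10000L,
      id = sprintf("var%05d", seq_len(p)),
      ref = "A", alt = "G",
      maf = pmin(maf, 1 - maf),
      stringsAsFactors = FALSE
    )
    genotypes(dosage, variants, sprintf("S%05d", seq_len(n)))
  })
}

# Standardized cubic polynomial basis of age: the fixed smooth nonlinearity
# the encoder has to straighten.
age_basis <- function(age) {
  a <- age - mean(age)
  phi <- cbind(a, a^2, a^3)
  scale(phi, center = TRUE, scale = apply(phi, 2, sd))
}

#' Simulate per-image features, ages and disease labels for a genotyped cohort
#'
#' Per-image raw features are `f = W phi(age) + sum_v g_v e_v + noise`, with
#' `phi` a standardized cubic polynomial basis of age, `W` a seeded random
#' loading matrix, `g_v` the standardized dosage of causal variant v, `e_v`
#' that variant's planted effect vector, and independent Gaussian noise per
#' image. Participants with two images share all systematic terms. Disease
#' labels come from a logistic liability in standardized age and the
#' projection of the systematic features onto a random unit `trait_direction`,
#' with the intercept solved to hit `config$prevalence`.
#'
#' @param config a [synth_config()].
#' @param geno a [genotypes] object with `config$n_participants` samples.
#' @return list with elements `features` (class `feature_matrix`: per-image
#'   matrix plus participant map) and `truth` (class `synth_truth`: causal ids,
#'   effect matrix, ages, sex, trait direction, disease labels).
#' @export
simulate_cohort <- function(config, geno) {
  stopifnot(inherits(config, "synth_config"), inherits(geno, "genotypes"))
  n <- config$n_participants
  if (nrow(geno$dosage) != n) {
    stop("genotype sample count does not match config$n_participants", call. = FALSE)
  }
  D <- config$n_raw_features
  with_seed(substream_seed(config$seed, "cohort"), {
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- rbinom(n, 1L, 0.5)
    phi <- age_basis(age)
    W <- matrix(rnorm(D * 3L, sd = 1 / sqrt(3)), nrow = D)

    effect_matrix <- matrix(0, config$n_variants, D,
                            dimnames = list(geno$variants$id, NULL))
    causal_ids <- character(0)
    genetic <- matrix(0, n, D)
    if (config$n_causal_variants > 0L && config$effect_dims > 0L) {
      causal_idx <- sort(sample.int(config$n_variants, config$n_causal_variants))
      causal_ids <- geno$variants$id[causal_idx]
      for (v in causal_idx) {
        dims <- sample.int(D, config$effect_dims)
        effect_matrix[v, dims] <- config$effect_size *
          sample(c(-1, 1), config$effect_dims, replace = TRUE)
      }
      g <- geno$dosage[, causal_idx, drop = FALSE]
      g[is.na(g)] <- matrix(colMeans(g, na.rm = TRUE), nrow(g), ncol(g),
                            byrow = TRUE)[is.na(g)]
      g_std <- scale(g)
      g_std[, apply(g, 2, sd) == 0] <- 0
      genetic <- g_std %*% effect_matrix[causal_idx, , drop = FALSE]
    }
    systematic <- phi %*% t(W) + genetic

    two_eyes <- runif(n) < config$p_both_eyes
    eye_of <- function(i) if (two_eyes[i]) c("L", "R") else "L"
    participant <- rep(geno$sample_ids, times = 1L + two_eyes)
    eye <- unlist(lapply(seq_len(n), eye_of), use.names = FALSE)
    idx <- match(participant, geno$sample_ids)
    values <- systematic[idx, , drop = FALSE]
    if (config$noise_sd > 0) {
      values <- values + matrix(rnorm(length(values), sd = config$noise_sd),
                                nrow(values))
    }
    rownames(values) <- paste0(participant, "_", eye)

    trait_direction <- rnorm(D)
    trait_direction <- trait_direction / sqrt(sum(trait_direction^2))
    proj <- as.numeric(systematic %*% trait_direction)
    eta_raw <- 0.5 * as.numeric(scale(age)) + 1.5 * as.numeric(scale(proj))
    b0 <- uniroot(function(b) mean(plogis(b + eta_raw)) - config$prevalence,
                  c(-30, 30))$root
    disease <- rbinom(n, 1L, plogis(b0 + eta_raw))

    features <- structure(
      list(values = values, image_ids = rownames(values),
           participant = participant, eye = eye),
      class = "feature_matrix")
    truth <- structure(
      list(causal_variant_ids = causal_ids,
           effect_matrix = effect_matrix,
           age = stats::setNames(age, geno$sample_ids),
           sex = stats::setNames(sex, geno$sample_ids),
           trait_direction = trait_direction,
           disease_labels = stats::setNames(disease, geno$sample_ids),
           liability_intercept = b0),
      class = "synth_truth")
    list(features = features, truth = truth)
  })
}

#' @method print feature_matrix
#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d images x %d features from %d participants\n",
              nrow(x$values), ncol(x$values), length(unique(x$participant))))
  invisible(x)
}
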