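test_that("config validation enforces the stated invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(synth_config(maf_range = c(0.2, 0.5)), "maf_range")
  expect_error(synth_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(synth_config(ld_decay = 1), "ld_decay")
  expect_error(synth_config(n_participants = 0), "n_participants")
  expect_error(synth_config(n_causal_variants = 50, n_variants = 10),
               "n_causal_variants")
  expect_error(synth_config(age_range = c(70, 40)), "age_range")
})

test_that("genotype simulation is deterministic and bounded", {
  cfg <- synth_config(n_participants = 60, n_variants = 40, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosage %in% 0:2))
  expect_false(identical(
    g1$dosage, simulate_genotypes(synth_config(n_participants = 60,
                                               n_variants = 40,
                                               seed = 10))$dosage))
  # variant metadata: single synthetic chromosome, evenly spaced positions
  expect_length(unique(g1$variants$chrom), 1L)
  expect_true(all(diff(g1$variants$pos) == diff(g1$variants$pos)[1]))
})

test_that("empirical allele frequencies hit the configured MAF", {
  cfg <- synth_config(n_participants = 2000, n_variants = 20,
                      maf_range = c(0.3, 0.3), ld_decay = 0, seed = 4)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$dosage) / 2
  half <- qnorm(0.995) * sqrt(0.3 * 0.7 / (2 * 2000))
  expect_true(all(abs(freq - 0.3) < half))
})

test_that("ld_decay controls adjacent-variant correlation", {
  # independence case
  cfg0 <- synth_config(n_participants = 2000, n_variants = 30,
                       maf_range = c(0.3, 0.3), ld_decay = 0, seed = 21)
  g0 <- simulate_genotypes(cfg0)
  r0 <- vapply(1:29, function(j) abs(cor(g0$dosage[, j], g0$dosage[, j + 1])), 0)
  expect_lt(mean(r0), 0.05)
  # strong copying: empirical adjacent r^2 from the copying process, several seeds
  r2s <- vapply(1:5, function(s) {
    cfg <- synth_config(n_participants = 2000, n_variants = 30,
                        maf_range = c(0.3, 0.3), ld_decay = 0.95, seed = s)
    g <- simulate_genotypes(cfg)
    mean(vapply(1:29, function(j) cor(g$dosage[, j], g$dosage[, j + 1])^2, 0))
  }, 0)
  expect_gt(mean(r2s), 0.5)
})

test_that("missingness flag produces the configured NA rate", {
  cfg <- synth_config(n_participants = 400, n_variants = 50,
                      missing_rate = 0.1, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_gt(mean(is.na(g$dosage)), 0.08)
  expect_lt(mean(is.na(g$dosage)), 0.12)
})

test_that("zero noise with both eyes gives identical left/right rows", {
  cfg <- synth_config(n_participants = 40, n_variants = 20, noise_sd = 0,
                      p_both_eyes = 1, n_raw_features = 8, seed = 3)
  ch <- simulate_cohort(cfg, simulate_genotypes(cfg))
  f <- ch$features
  for (id in unique(f$participant)) {
    rows <- f$values[f$participant == id, , drop = FALSE]
    expect_equal(rows[1, ], rows[2, ], tolerance = 1e-12)
  }
})

test_that("truth object satisfies its invariants", {
  ch <- tiny_cohort()
  expect_equal(sqrt(sum(ch$truth$trait_direction^2)), 1, tolerance = 1e-12)
  noncausal <- setdiff(rownames(ch$truth$effect_matrix),
                       ch$truth$causal_variant_ids)
  expect_true(all(ch$truth$effect_matrix[noncausal, ] == 0))
  expect_true(all(ch$truth$disease_labels %in% 0:1))
  expect_error(simulate_cohort(ch$cfg,
                               simulate_genotypes(synth_config(n_participants = 10,
                                                               seed = 1))),
               "sample count")
})

test_that("planted effects are recoverable by per-dimension OLS", {
  cfg <- synth_config(n_participants = 2000, n_variants = 50,
                      n_raw_features = 12, n_causal_variants = 2,
                      effect_dims = 3, effect_size = 0.5, noise_sd = 1,
                      ld_decay = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  ch <- simulate_cohort(cfg, g)
  avg <- average_eyes(ch$features)
  cv <- ch$truth$causal_variant_ids[1]
  dim1 <- which(ch$truth$effect_matrix[cv, ] != 0)[1]
  gs <- drop(scale(g$dosage[, cv]))
  fit <- summary(lm(avg[, dim1] ~ gs))$coefficients
  expect_lt(abs(fit["gs", "Estimate"] - ch$truth$effect_matrix[cv, dim1]),
            3 * fit["gs", "Std. Error"])
})

test_that("effect_size = 0 plants nothing", {
  cfg <- synth_config(n_participants = 500, n_variants = 30,
                      n_raw_features = 10, n_causal_variants = 5,
                      effect_dims = 3, effect_size = 0, noise_sd = 1,
                      ld_decay = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  ch <- simulate_cohort(cfg, g)
  expect_true(all(ch$truth$effect_matrix == 0))
  avg <- average_eyes(ch$features)
  # per-dim OLS t-statistics on "causal" variants behave like null
  tstats <- unlist(lapply(ch$truth$causal_variant_ids, function(v) {
    gs <- drop(scale(g$dosage[, v]))
    vapply(1:5, function(d) summary(lm(avg[, d] ~ gs))$coefficients[2, 3], 0)
  }))
  expect_lt(mean(abs(tstats) > 2), 0.2)
})

test_that("disease prevalence tracks the configured target", {
  cfg <- synth_config(n_participants = 2000, n_variants = 20,
                      n_raw_features = 10, prevalence = 0.1, seed = 12)
  ch <- simulate_cohort(cfg, simulate_genotypes(cfg))
  expect_gt(mean(ch$truth$disease_labels), 0.06)
  expect_lt(mean(ch$truth$disease_labels), 0.14)
})
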