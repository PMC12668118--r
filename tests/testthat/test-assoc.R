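test_that("fit_null matches the OLS oracle and rejects degenerate fits", {
  set.seed(12)
  # K = 1, N = 10 toy: residual variance with denominator N - rank(C)
  C <- cbind(1, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.3, 13.9, 16.2, 18.0, 20.1)
  null <- fit_null(matrix(y), C)
  fit <- lm(y ~ C - 1)
  expect_equal(drop(null$Sigma), sum(residuals(fit)^2) / (10 - 2),
               tolerance = 1e-12)
  expect_equal(drop(null$B0), unname(coef(fit)), tolerance = 1e-10)
  # Y exactly in the covariate span: non-PD error path
  B <- matrix(rnorm(4), 2, 2)
  expect_error(fit_null(C %*% B, C), "positive definite")
  # too few residual df
  expect_error(fit_null(matrix(rnorm(5 * 4), 5), matrix(1, 5, 1)),
               "too few samples")
})

test_that("null residual covariance concentrates (law of large numbers)", {
  set.seed(13)
  Y <- matrix(rnorm(5000 * 5), 5000)
  null <- fit_null(Y, matrix(1, 5000, 1))
  expect_lt(max(abs(null$Sigma - diag(5))), 0.05)
})

test_that("test_score matches brute-force GLS on random small instances", {
  set.seed(14)
  for (rep in 1:20) {
    N <- sample(8:20, 1)
    K <- sample(1:3, 1)
    C <- cbind(1, matrix(rnorm(N), N, 1))
    Y <- matrix(rnorm(N * K), N)
    g <- rbinom(N, 2, 0.4)
    if (sd(g) == 0) g[1] <- g[1] + 1
    null <- fit_null(Y, C)
    rec <- test_score(null, g)
    oracle <- brute_gls(Y, C, g)
    expect_equal(rec$beta, oracle$beta, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(rec$stat, oracle$stat, tolerance = 1e-8)
  }
})

test_that("K = 1 equals the classical univariate score statistic", {
  set.seed(15)
  N <- 40
  C <- cbind(1, rnorm(N))
  y <- rnorm(N)
  g <- rbinom(N, 2, 0.3)
  null <- fit_null(matrix(y), C)
  rec <- test_score(null, g)
  M <- diag(N) - C %*% solve(crossprod(C)) %*% t(C)
  gr <- drop(M %*% g); yr <- drop(M %*% y)
  s0 <- sum(yr^2) / (N - 2)
  expect_equal(rec$stat, sum(gr * yr)^2 / (sum(gr^2) * s0), tolerance = 1e-10)
})

test_that("exact null geometry yields a zero statistic", {
  set.seed(16)
  N <- 30; K <- 2
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * K), N)
  null <- fit_null(Y, C)
  g <- rnorm(N)
  gr <- residualize(g, C)
  # remove the components along the residualized phenotype columns
  g_orth <- drop(gr - null$E %*% solve(crossprod(null$E), crossprod(null$E, gr)))
  rec <- test_score(null, g_orth)
  expect_equal(unname(rec$beta), rep(0, K), tolerance = 1e-8)
  expect_equal(rec$stat, 0, tolerance = 1e-8)
  expect_equal(rec$p, 1, tolerance = 1e-8)
})

test_that("monomorphic or covariate-collinear dosages are flagged", {
  set.seed(17)
  N <- 25
  C <- cbind(1, rnorm(N))
  null <- fit_null(matrix(rnorm(N * 2), N), C)
  rec <- test_score(null, rep(2, N))
  expect_identical(rec$flag, "monomorphic/collinear")
  expect_true(is.na(rec$p))
  rec2 <- test_score(null, drop(C %*% c(1, 2)))
  expect_identical(rec2$flag, "monomorphic/collinear")
})

test_that("the statistic is invariant to phenotype remixing and dosage scale", {
  set.seed(18)
  N <- 60; K <- 4
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * K), N)
  g <- rbinom(N, 2, 0.3)
  stat0 <- test_score(fit_null(Y, C), g)$stat
  for (rep in 1:5) {
    A <- matrix(rnorm(K * K), K)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(K * K), K)
    stat_mix <- test_score(fit_null(Y %*% A, C), g)$stat
    expect_equal(stat_mix, stat0, tolerance = 1e-8)
  }
  expect_equal(test_score(fit_null(Y, C), 3.7 * g)$stat, stat0,
               tolerance = 1e-10)
})

test_that("test_refined reduces to, and agrees with, the score test", {
  set.seed(19)
  N <- 300; K <- 3
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * K), N)
  g <- rbinom(N, 2, 0.3)
  null <- fit_null(Y, C)
  r0 <- test_refined(null, g, n_iter = 0)
  rs <- test_score(null, g)
  expect_identical(r0$stat, rs$stat)
  r1 <- test_refined(null, g, n_iter = 1)
  expect_equal(r1$beta, rs$beta, tolerance = 1e-12)   # beta free of Sigma
  expect_equal(r1$stat, rs$stat, tolerance = 0.05)     # asymptotic agreement
  # planted strong effect: both tests certain, identical effect estimate
  Y2 <- Y; Y2[, 1] <- Y2[, 1] + 0.8 * g
  null2 <- fit_null(Y2, C)
  p_s <- test_score(null2, g)$p
  p_r <- test_refined(null2, g)$p
  expect_lt(p_s, 1e-8)
  expect_lt(p_r, 1e-8)
})

test_that("refined test is calibrated on null simulations", {
  set.seed(20)
  N <- 2000; K <- 5
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * K), N)
  null <- fit_null(Y, C)
  ps <- vapply(1:400, function(i) {
    test_refined(null, rbinom(N, 2, 0.3))$p
  }, 0)
  band <- 2.58 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(ps < 0.05) - 0.05), band + 0.01)
})

test_that("run_gwas filters by MAF and finds planted signals", {
  cohort <- tiny_cohort()
  emb <- rank_inverse_normal(fit_pca(average_eyes(cohort$features), 5)$scores)
  rownames(emb) <- sort(cohort$geno$sample_ids)
  C <- build_covariates(cohort$truth$age, cohort$truth$sex)
  expect_error(suppressMessages(run_gwas(cohort$geno, emb, C, maf_min = 0.49)),
               "zero variants")
  gw <- suppressMessages(run_gwas(cohort$geno, emb, C, maf_min = 0.01))
  expect_true(all(gw$MAF >= 0.01))
  expect_true(all(gw$DF == 5))
  expect_true(all(gw$CHI2 >= 0))
  expect_true(all(gw$P > 0 & gw$P <= 1))
  # strongest signal sits at (or in LD with) a planted causal variant
  lead <- gw$ID[which.min(gw$P)]
  lead_pos <- cohort$geno$variants$pos[match(lead, cohort$geno$variants$id)]
  causal_pos <- cohort$geno$variants$pos[
    match(cohort$truth$causal_variant_ids, cohort$geno$variants$id)]
  expect_lt(min(abs(causal_pos - lead_pos)), 100000)
})

test_that("missing dosages are mean-imputed before testing", {
  set.seed(21)
  N <- 100
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * 2), N)
  null <- fit_null(Y, C)
  g <- rbinom(N, 2, 0.4)
  g_na <- g; g_na[1:5] <- NA
  g_imp <- g; g_imp[1:5] <- mean(g[-(1:5)])
  expect_equal(test_score(null, g_na)$stat, test_score(null, g_imp)$stat,
               tolerance = 1e-12)
  expect_equal(test_score(null, g_na)$callrate, 0.95)
})

test_that("acat_combine matches its closed form", {
  expect_equal(acat_combine(rep(0.5, 7)), 0.5, tolerance = 1e-12)
  expect_equal(acat_combine(0.137), 0.137, tolerance = 1e-12)  # K = 1 identity
  p3 <- c(0.01, 0.2, 0.9)
  expect_equal(acat_combine(p3), brute_acat(p3), tolerance = 1e-12)
  expect_warning(out <- acat_combine(c(0, 0.5)), "clipped")
  expect_gt(out, 0)
  expect_error(acat_combine(c(0.5, 1.2)), "0, 1")
})

test_that("univariate + ACAT baseline agrees with the K = 1 path", {
  cohort <- tiny_cohort()
  emb <- rank_inverse_normal(fit_pca(average_eyes(cohort$features), 1)$scores)
  rownames(emb) <- sort(cohort$geno$sample_ids)
  C <- build_covariates(cohort$truth$age, cohort$truth$sex)
  gw <- suppressMessages(run_gwas(cohort$geno, emb, C))
  ac <- test_univariate_acat(cohort$geno, emb, C)
  expect_equal(ac$P_ACAT, gw$P, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("permutation null is calibrated and identity-consistent", {
  set.seed(22)
  cfg <- synth_config(n_participants = 300, n_variants = 200,
                      n_raw_features = 12, n_causal_variants = 0,
                      ld_decay = 0.5, seed = 23)
  g <- simulate_genotypes(cfg)
  ch <- simulate_cohort(cfg, g)
  emb <- rank_inverse_normal(fit_pca(average_eyes(ch$features), 5)$scores)
  rownames(emb) <- sort(g$sample_ids)
  C <- build_covariates(ch$truth$age, ch$truth$sex)
  # identity permutation reproduces the unpermuted scan
  gw <- suppressMessages(run_gwas(g, emb, C))
  pid <- permutation_null(g, emb, C, n_perm = 1, seed = 1, identity = TRUE)
  expect_equal(drop(pid$stat), gw$CHI2, tolerance = 1e-10, ignore_attr = TRUE)
  # calibration
  pn <- permutation_null(g, emb, C, n_perm = 25, seed = 2)
  expect_gt(pn$ks_p, 0.01)
  m <- length(pn$p)
  band <- 2 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(pn$empirical_alpha[["alpha_0.05"]] - 0.05), band + 0.01)
})

test_that("burden testing reuses the variant machinery", {
  set.seed(24)
  N <- 250; K <- 3
  C <- cbind(1, rnorm(N))
  Y <- matrix(rnorm(N * K), N)
  g <- rbinom(N, 2, 0.3)
  null <- fit_null(Y, C)
  burden <- rbind(asgeno = g, const = rep(1, N),
                  planted = residualize(Y, C)[, 1] + rnorm(N, sd = 0.1))
  out <- test_burden(burden, Y, C)
  expect_equal(out$CHI2[1], test_score(null, g)$stat, tolerance = 1e-10)
  expect_true(is.na(out$P[2]))
  expect_identical(out$FLAG[2], "constant/collinear")
  expect_lt(out$P[3], 1e-8)
  # null burden scores give uniform p
  nullb <- matrix(rnorm(500 * N), 500, N)
  pz <- test_burden(nullb, Y, C)$P
  expect_gt(suppressWarnings(ks.test(pz, "punif"))$p.value, 0.01)
})
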