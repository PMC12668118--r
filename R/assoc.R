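# Multivariate association engine: each variant (or gene burden score) is
# tested against the K-dimensional embedding phenotype with a chi-squared
# statistic on K degrees of freedom, with residual trait covariance
# estimated once under the null. A univariate + Cauchy-aggregation baseline
# and permutation-based calibration diagnostics live here too.

#' Fit the multivariate null model
#'
#' Least-squares regression of the K-column phenotype on the covariates;
#' residual covariance `Sigma = E'E / (N - rank(C))` is estimated once here
#' and reused for every variant test.
#'
#' @param Y numeric N x K phenotype matrix (typically rank-normalized
#'   embedding components).
#' @param C covariate design from [build_covariates()] (full column rank).
#' @return list of class `null_model`: coefficients `B0`, residuals `E`,
#'   covariance `Sigma` and its inverse, the covariate QR, `N`, `rank_C`, `K`.
#' @export
fit_null <- function(Y, C) {
  Y <- as.matrix(Y); C <- as.matrix(C)
  N <- nrow(Y); K <- ncol(Y)
  if (nrow(C) != N) stop("Y and C must be row-aligned", call. = FALSE)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("rank-deficient covariate design", call. = FALSE)
  if (N <= qrC$rank + K) {
    stop("too few samples: need N > rank(C) + K residual degrees of freedom",
         call. = FALSE)
  }
  B0 <- qr.coef(qrC, Y)
  E <- Y - qr.fitted(qrC, Y)
  Sigma <- crossprod(E) / (N - qrC$rank)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  scale_y <- max(mean(Y^2), .Machine$double.xmin)
  if (is.null(ch) || max(diag(Sigma)) <= 1e-12 * scale_y ||
      min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    stop("residual covariance is not positive definite; phenotype columns ",
         "are (nearly) collinear with the covariates - consider dropping ",
         "components or adding ridge jitter", call. = FALSE)
  }
  structure(list(B0 = B0, E = E, Sigma = Sigma,
                 Sigma_inv = chol2inv(ch), Sigma_chol = ch,
                 qrC = qrC, N = N, rank_C = qrC$rank, K = K,
                 sample_ids = rownames(Y)),
            class = "null_model")
}

# Per-column mean imputation of missing dosages.
mean_impute <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2]]
  G
}

# Vectorized score statistics for a dosage matrix (samples x variants).
# Returns per-variant beta (variants x K), statistic, gtg.
score_stats_matrix <- function(null, G) {
  G <- mean_impute(as.matrix(G))
  Gr <- G - qr.fitted(null$qrC, G)
  gtg <- colSums(Gr^2)
  B <- crossprod(Gr, null$E)            # variants x K, = g_r' Y_r
  ok <- gtg > null$N * .Machine$double.eps^0.75
  beta <- B / ifelse(gtg > 0, gtg, 1)
  stat <- rowSums((beta %*% null$Sigma_inv) * beta) * gtg
  stat[!ok] <- NA_real_
  beta[!ok, ] <- NA_real_
  list(beta = beta, stat = stat, gtg = gtg, ok = ok)
}

chisq_logp <- function(stat, df) {
  pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
}

assoc_record <- function(id, beta, stat, df, maf, callrate, flag = NA_character_) {
  logp <- if (is.na(stat)) NA_real_ else chisq_logp(stat, df)
  structure(list(id = id, beta = beta, stat = stat, df = df,
                 p = if (is.na(stat)) NA_real_ else exp(logp),
                 log10p = if (is.na(stat)) NA_real_ else logp / log(10),
                 maf = maf, callrate = callrate, flag = flag),
            class = "assoc_record")
}

#' Score test of one dosage vector against the multivariate phenotype
#'
#' With `M` the residual projector of the covariates,
#' `beta = (g'M Y) / (g'M g)` and `lambda = (g'M g) * beta Sigma^-1 beta'`,
#' referred to a chi-squared distribution on K degrees of freedom. Missing
#' dosages are mean-imputed first.
#'
#' @param null a fitted [fit_null()] model.
#' @param g numeric dosage vector (length N; NA = missing).
#' @param id identifier carried into the record.
#' @return list of class `assoc_record`: `beta` (length K), `stat`, `df`,
#'   `p`, `log10p`, `maf`, `callrate`, `flag`.
#' @export
test_score <- function(null, g, id = "g") {
  g <- as.numeric(g)
  if (length(g) != null$N) stop("dosage length must equal N", call. = FALSE)
  callrate <- mean(!is.na(g))
  f <- mean(g, na.rm = TRUE) / 2
  maf <- min(f, 1 - f)
  res <- score_stats_matrix(null, matrix(g, ncol = 1))
  if (!res$ok[1]) {
    return(assoc_record(id, rep(NA_real_, null$K), NA_real_, null$K, maf,
                        callrate, flag = "monomorphic/collinear"))
  }
  assoc_record(id, drop(res$beta), res$stat[1], null$K, maf, callrate)
}

#' Refined test with one-step covariance re-estimation
#'
#' After the null-covariance effect estimate, re-estimates the residual
#' covariance from alternative-model residuals once (`n_iter = 1`) and
#' reports the Gaussian likelihood-ratio statistic
#' `N * (log det S0 - log det S1)` on K degrees of freedom, where `S0`/`S1`
#' are the ML residual covariances under null and alternative. `n_iter = 0`
#' reduces exactly to [test_score()]. The effect vector does not depend on
#' the covariance, so `beta` is identical between the two.
#'
#' @inheritParams test_score
#' @param n_iter 0 (pure score test) or 1 (one covariance re-estimation).
#' @return an `assoc_record`.
#' @export
test_refined <- function(null, g, id = "g", n_iter = 1L) {
  if (n_iter == 0L) return(test_score(null, g, id))
  rec <- test_score(null, g, id)
  if (!is.na(rec$flag)) return(rec)
  g <- mean_impute(matrix(as.numeric(g), ncol = 1))
  gr <- g - qr.fitted(null$qrC, g)
  E1 <- null$E - gr %*% matrix(rec$beta, nrow = 1)
  S0 <- crossprod(null$E) / null$N
  S1 <- crossprod(E1) / null$N
  logdet <- function(S) 2 * sum(log(diag(chol(S))))
  stat <- null$N * (logdet(S0) - logdet(S1))
  assoc_record(id, rec$beta, max(stat, 0), null$K, rec$maf, rec$callrate)
}

#' Genomic inflation factor
#'
#' Ratio of the median observed chi-squared statistic to the null median of
#' a chi-squared on `df` degrees of freedom; ~1 indicates calibration.
#'
#' @param stat vector of chi-squared statistics.
#' @param df degrees of freedom.
#' @return scalar lambda_GC.
#' @export
genomic_lambda <- function(stat, df) {
  median(stat, na.rm = TRUE) / qchisq(0.5, df)
}

#' Genome-wide multivariate association scan
#'
#' Mean-imputes missing dosages, filters variants at `maf >= maf_min`
#' (MAF computed after imputation), fits the null model once, and tests each
#' retained variant.
#'
#' @param geno a [genotypes] object.
#' @param Y N x K phenotype matrix, rows aligned with (or named by) the
#'   genotype samples.
#' @param C covariate design matrix.
#' @param maf_min minor-allele-frequency threshold (default 0.01).
#' @param mode `"score"` (default) or `"refined"`.
#' @return data.frame of class `gwas_result` with columns CHR, POS, ID, REF,
#'   ALT, MAF, N, DF, CHI2, P; per-dimension effects in `attr(, "beta")`;
#'   `attr(, "lambda_gc")` the genomic inflation factor;
#'   `attr(, "n_excluded")` the MAF-filter count.
#' @export
run_gwas <- function(geno, Y, C, maf_min = 0.01, mode = c("score", "refined")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "genotypes"))
  Y <- as.matrix(Y)
  if (!is.null(rownames(Y)) && !identical(rownames(Y), geno$sample_ids)) {
    if (!all(geno$sample_ids %in% rownames(Y))) {
      stop("phenotype rows do not cover the genotype samples", call. = FALSE)
    }
    Y <- Y[geno$sample_ids, , drop = FALSE]
    C <- as.matrix(C)[geno$sample_ids, , drop = FALSE]
  }
  G <- mean_impute(geno$dosage)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= maf_min
  if (!any(keep)) stop("zero variants retained after MAF filter", call. = FALSE)
  null <- fit_null(Y, C)
  Gk <- G[, keep, drop = FALSE]
  if (mode == "score") {
    res <- score_stats_matrix(null, Gk)
    stat <- res$stat
    beta <- res$beta
  } else {
    recs <- lapply(seq_len(ncol(Gk)), function(j) {
      test_refined(null, Gk[, j], id = colnames(Gk)[j])
    })
    stat <- vapply(recs, `[[`, 0, "stat")
    beta <- do.call(rbind, lapply(recs, `[[`, "beta"))
  }
  v <- geno$variants[keep, , drop = FALSE]
  out <- data.frame(CHR = v$chrom, POS = v$pos, ID = v$id, REF = v$ref,
                    ALT = v$alt, MAF = maf[keep], N = null$N, DF = null$K,
                    CHI2 = stat, P = exp(chisq_logp(stat, null$K)),
                    stringsAsFactors = FALSE)
  rownames(beta) <- v$id
  attr(out, "beta") <- beta
  attr(out, "lambda_gc") <- genomic_lambda(stat, null$K)
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("gwas_result", class(out))
  message(sprintf("tested %d variants (%d excluded at MAF < %g); lambda_GC = %.3f",
                  nrow(out), sum(!keep), maf_min, attr(out, "lambda_gc")))
  out
}

#' Aggregated Cauchy combination of p-values
#'
#' `T = sum_k w_k tan((0.5 - p_k) pi) / sum_k w_k` with equal weights by
#' default; the combined p-value is `0.5 - atan(T) / pi`. Robust to
#' dependence between the component tests. P-values exactly 0 or 1 are
#' clipped to machine-safe bounds with a warning.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param weights optional nonnegative weights (default equal).
#' @return combined p-value in (0, 1).
#' @export
acat_combine <- function(p, weights = NULL) {
  p <- as.numeric(p)
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p == 0 | p == 1)) {
    warning("p-values exactly 0 or 1 clipped to machine-safe bounds")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  w <- weights %||% rep(1 / length(p), length(p))
  stopifnot(length(w) == length(p), all(w >= 0), sum(w) > 0)
  Tstat <- sum(w * tan((0.5 - p) * pi)) / sum(w)
  min(max(0.5 - atan(Tstat) / pi, 1e-300), 1 - 1e-16)
}

#' Univariate baseline with Cauchy aggregation
#'
#' Tests each phenotype dimension independently with the K = 1 score test
#' and combines the per-dimension p-values per variant with
#' [acat_combine()] (equal weights).
#'
#' @inheritParams run_gwas
#' @return data.frame with ID, MAF and combined `P_ACAT`; per-dimension
#'   p-values in `attr(, "p_per_dim")`.
#' @export
test_univariate_acat <- function(geno, Y, C, maf_min = 0.01) {
  stopifnot(inherits(geno, "genotypes"))
  Y <- as.matrix(Y)
  G <- mean_impute(geno$dosage)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= maf_min
  if (!any(keep)) stop("zero variants retained after MAF filter", call. = FALSE)
  null <- fit_null(Y, C)
  Gk <- G[, keep, drop = FALSE]
  Gr <- Gk - qr.fitted(null$qrC, Gk)
  gtg <- colSums(Gr^2)
  num <- crossprod(Gr, null$E)^2          # variants x K: (g_r' y_k)^2
  sig0 <- colSums(null$E^2) / (null$N - null$rank_C)
  stat1 <- sweep(num, 2, sig0, "/") / gtg # univariate score statistics
  p_dim <- exp(pchisq(stat1, 1, lower.tail = FALSE, log.p = TRUE))
  p_acat <- apply(p_dim, 1, acat_combine)
  out <- data.frame(ID = geno$variants$id[keep], MAF = maf[keep],
                    P_ACAT = p_acat, stringsAsFactors = FALSE)
  rownames(p_dim) <- out$ID
  attr(out, "p_per_dim") <- p_dim
  out
}

#' Permutation-based null calibration
#'
#' Permutes the sample indices of the genotype matrix (the phenotype and
#' covariates stay aligned with each other, so the null model is identical
#' across permutations), recomputes the multivariate statistic for every
#' retained variant, and summarizes calibration: empirical type-I error on a
#' standard alpha grid, a Kolmogorov-Smirnov test of the permuted p-values
#' against Uniform(0, 1), genomic inflation, and QQ-plot data.
#'
#' @inheritParams run_gwas
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param identity force the identity permutation (diagnostic; statistics
#'   then equal the unpermuted run).
#' @param alpha_grid type-I error levels to report.
#' @return list of class `perm_null`: `stat` (matrix variants x n_perm),
#'   `p`, `empirical_alpha`, `ks_p`, `lambda_gc`, `qq` (expected/observed
#'   -log10 p).
#' @export
permutation_null <- function(geno, Y, C, n_perm = 100L, seed = 1L,
                             maf_min = 0.01, identity = FALSE,
                             alpha_grid = c(0.05, 0.01, 0.001)) {
  n_perm <- check_count(n_perm, "n_perm")
  stopifnot(inherits(geno, "genotypes"))
  Y <- as.matrix(Y)
  G <- mean_impute(geno$dosage)
  f <- colMeans(G) / 2
  keep <- pmin(f, 1 - f) >= maf_min
  if (!any(keep)) stop("zero variants retained after MAF filter", call. = FALSE)
  G <- G[, keep, drop = FALSE]
  null <- fit_null(Y, C)
  stat <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(b) {
      perm <- if (identity) seq_len(null$N) else sample.int(null$N)
      score_stats_matrix(null, G[perm, , drop = FALSE])$stat
    }, numeric(ncol(G)))
  })
  stat <- matrix(stat, ncol = n_perm)
  p <- exp(chisq_logp(stat, null$K))
  pv <- as.vector(p)
  emp <- vapply(alpha_grid, function(a) mean(pv < a), 0)
  names(emp) <- paste0("alpha_", alpha_grid)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  m <- length(pv)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sort(pv)))
  structure(list(stat = stat, p = p, empirical_alpha = emp,
                 ks_p = ks$p.value, lambda_gc = genomic_lambda(stat, null$K),
                 df = null$K, qq = qq),
            class = "perm_null")
}

#' Gene-level burden association
#'
#' Applies the identical multivariate machinery with a real-valued gene
#' burden score in place of the dosage vector; no MAF filter applies.
#' Constant burden vectors yield a flagged record with `p = NA`.
#'
#' @param burden genes x samples numeric matrix (rownames = gene ids).
#' @param Y,C as in [run_gwas()].
#' @return data.frame with GENE, CHI2, DF, P plus `attr(, "beta")`.
#' @export
test_burden <- function(burden, Y, C) {
  burden <- as.matrix(burden)
  null <- fit_null(as.matrix(Y), C)
  if (ncol(burden) != null$N) stop("burden must be genes x samples", call. = FALSE)
  res <- score_stats_matrix(null, t(burden))
  out <- data.frame(GENE = rownames(burden) %||% paste0("gene", seq_len(nrow(burden))),
                    CHI2 = res$stat, DF = null$K,
                    P = exp(chisq_logp(res$stat, null$K)),
                    FLAG = ifelse(res$ok, NA_character_, "constant/collinear"),
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- res$beta
  out
}
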