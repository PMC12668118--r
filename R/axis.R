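# Trait-axis construction: a ridge-BLUP linear mixed model with the
# embedding as random effects, leave-one-out random-effect predictions,
# extreme-quantile mean embeddings and linear interpolation between them.

#' Fit a trait-axis mixed model
#'
#' Model: `t = C beta + X u + e`, with `u ~ N(0, sigma2_u I_K)` and
#' `e ~ N(0, sigma2_e I_N)` — the standard ridge-BLUP reading of
#' "embeddings as random effects". Variance components are estimated by
#' restricted maximum likelihood profiled over the single variance ratio
#' `gamma = sigma2_u / sigma2_e` (coarse log-grid search then local
#' refinement, tolerance 1e-6 on log-gamma); `u` is the BLUP at the REML
#' optimum. Binary traits are fitted on the 0/1 scale.
#'
#' @param trait numeric response vector (length N).
#' @param X N x K embedding matrix (the random-effect design).
#' @param C covariate design matrix (fixed effects, with intercept).
#' @return list of class `axis_model`: `sigma2_u`, `sigma2_e`, `gamma`,
#'   `beta` (fixed effects), `u_hat` (length K), `fitted`, `reml` (profile
#'   value at the optimum).
#' @export
fit_axis <- function(trait, X, C) {
  t_ <- as.numeric(trait)
  X <- as.matrix(X); C <- as.matrix(C)
  N <- length(t_); K <- ncol(X)
  stopifnot(nrow(X) == N, nrow(C) == N)
  if (sd(t_) == 0) stop("zero-variance trait", call. = FALSE)
  p <- qr(C)$rank
  if (p < ncol(C)) stop("rank-deficient fixed-effect design", call. = FALSE)
  XtX <- crossprod(X)
  d2 <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  d2 <- pmax(d2, 0)

  # Woodbury: W(gamma) = (I + gamma X X')^{-1} = I - gamma X (I + gamma X'X)^{-1} X'
  prof <- function(log_gamma) {
    g <- exp(log_gamma)
    Minv <- solve(diag(K) + g * XtX)
    Wmul <- function(v) v - g * (X %*% (Minv %*% crossprod(X, v)))
    WC <- Wmul(C); Wt <- Wmul(t_)
    CtWC <- crossprod(C, WC)
    beta <- solve(CtWC, crossprod(C, Wt))
    r <- t_ - C %*% beta
    quad <- sum(r * Wmul(r))
    s2e <- quad / (N - p)
    ll <- -0.5 * ((N - p) * (log(s2e) + 1) + sum(log1p(g * d2)) +
                    determinant(CtWC, logarithm = TRUE)$modulus[1])
    list(ll = as.numeric(ll), beta = beta, s2e = s2e, r = r,
         Wr = Wmul(r), gamma = g)
  }
  grid <- seq(-14, 12, length.out = 40)
  lls <- vapply(grid, function(lg) prof(lg)$ll, 0)
  i <- which.max(lls)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(function(lg) prof(lg)$ll, c(lo, hi), maximum = TRUE,
                  tol = 1e-6)
  if (!is.finite(opt$objective)) {
    stop("REML did not converge; try rescaling the trait or a coarser grid",
         call. = FALSE)
  }
  best <- prof(opt$maximum)
  u_hat <- best$gamma * crossprod(X, best$Wr)
  structure(list(sigma2_u = best$gamma * best$s2e, sigma2_e = best$s2e,
                 gamma = best$gamma, beta = drop(best$beta),
                 u_hat = drop(u_hat),
                 fitted = drop(C %*% best$beta + X %*% u_hat),
                 reml = best$ll, N = N, K = K),
            class = "axis_model")
}

#' Leave-one-out random-effect scores
#'
#' `score_i = X_i u_hat^(-i)`: the random-effect prediction for sample i with
#' sample i excluded from the fit, at the variance components of the full
#' fit (no per-sample REML refit). Computed by the closed-form rank-one
#' downdate of the penalized least-squares (Henderson) system, which agrees
#' exactly with explicit drop-one refits at the same variance ratio.
#'
#' @param model a fitted [fit_axis()] model.
#' @param trait,X,C the data the model was fitted on.
#' @return numeric length-N score vector.
#' @export
loo_scores <- function(model, trait, X, C) {
  t_ <- as.numeric(trait)
  X <- as.matrix(X); C <- as.matrix(C)
  N <- length(t_); K <- ncol(X); p <- ncol(C)
  delta <- 1 / model$gamma          # ridge penalty sigma2_e / sigma2_u
  A <- cbind(C, X)
  Pen <- diag(c(rep(0, p), rep(delta, K)))
  G <- solve(crossprod(A) + Pen)
  theta <- G %*% crossprod(A, t_)
  yhat <- drop(A %*% theta)
  h <- rowSums((A %*% G) * A)       # leverages of the joint smoother
  if (any(h >= 1 - 1e-10)) {
    stop("exact interpolation, LOO undefined (leverage ~ 1)", call. = FALSE)
  }
  u_idx <- (p + 1L):(p + K)
  u_hat <- theta[u_idx]
  # u^(-i) = u - G_u a_i (t_i - yhat_i) / (1 - h_ii)
  Gu_a <- A %*% t(G[u_idx, , drop = FALSE])   # N x K: rows = (G_u a_i)'
  drop(X %*% u_hat) - rowSums(X * Gu_a) * (t_ - yhat) / (1 - h)
}

#' Extreme-quantile mean embeddings
#'
#' Mean embedding over the bottom and top `ceiling(q * N)` samples ranked by
#' score; ties at the cut are broken by sample-id (row-name) order.
#'
#' @param X N x K embedding matrix (rownames = sample ids).
#' @param scores numeric length-N ranking scores (e.g. [loo_scores()]).
#' @param q tail fraction in (0, 0.5); default 0.001 (the bottom/top 0.1%).
#' @return list: `x_low`, `x_high` (length-K means), `n_tail`,
#'   `low_ids`, `high_ids`.
#' @export
extreme_means <- function(X, scores, q = 0.001) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(length(scores) == N)
  check_prob(q, "q", lo_open = TRUE, hi = 0.5, hi_open = TRUE)
  m <- ceiling(q * N)
  if (q * N < 1) {
    stop(sprintf("q * N = %.3f < 1: no sample falls in a %.3g tail; use a larger q",
                 q * N, q), call. = FALSE)
  }
  ids <- rownames(X) %||% sprintf("row%06d", seq_len(N))
  if (max(scores) == min(scores)) {
    warning("constant scores: extreme sets drawn by sample-id order only (degenerate)")
  }
  lo <- order(scores, ids)[seq_len(m)]
  hi <- order(-scores, ids)[seq_len(m)]
  list(x_low = colMeans(X[lo, , drop = FALSE]),
       x_high = colMeans(X[hi, , drop = FALSE]),
       n_tail = m, low_ids = ids[lo], high_ids = ids[hi])
}

#' Interpolate between two endpoint embeddings
#'
#' `x(alpha) = (1 - alpha) x_low + alpha x_high`; exact at the endpoints.
#'
#' @param x_low,x_high numeric endpoint embeddings of equal length.
#' @param alpha numeric value(s) in `[0, 1]`.
#' @param allow_extrapolation permit alpha outside `[0, 1]`.
#' @return for scalar `alpha` a vector; otherwise a matrix with one row per
#'   alpha.
#' @export
interpolate_embeddings <- function(x_low, x_high, alpha,
                                   allow_extrapolation = FALSE) {
  stopifnot(length(x_low) == length(x_high))
  if (!allow_extrapolation && any(alpha < 0 | alpha > 1)) {
    stop("alpha outside [0, 1]; set allow_extrapolation = TRUE to extrapolate",
         call. = FALSE)
  }
  out <- t(vapply(alpha, function(a) (1 - a) * x_low + a * x_high,
                  numeric(length(x_low))))
  if (length(alpha) == 1L) drop(out) else out
}

#' Fit a full trait axis: model, LOO scores and endpoints
#'
#' Convenience wrapper running [fit_axis()], [loo_scores()] and
#' [extreme_means()] in sequence.
#'
#' @inheritParams fit_axis
#' @param q tail fraction for [extreme_means()].
#' @return the `axis_model` augmented with `loo`, `x_low`, `x_high`, `q`.
#' @export
build_axis <- function(trait, X, C, q = 0.001) {
  model <- fit_axis(trait, X, C)
  model$loo <- loo_scores(model, trait, X, C)
  ex <- extreme_means(X, model$loo, q)
  model$x_low <- ex$x_low
  model$x_high <- ex$x_high
  model$q <- q
  model
}

#' Planted-axis recovery report
#'
#' For a synthetic cohort with a planted trait direction: maps the
#' embedding-space axis `x_high - x_low` back into raw feature space and
#' reports its absolute cosine similarity with the planted unit direction.
#'
#' The pullback treats the axis as a trait gradient. If the trait is a
#' linear functional `dir' f` of the raw features, the extreme-tail mean
#' difference in embedding space is (up to scale) the embedding covariance
#' times the per-component regression weights, so inverting the embedding
#' map requires undoing the per-component scale: component k of the axis is
#' divided by the standard deviation (rank-normalized / whitened embeddings,
#' the default) or the variance (raw PC scores) of score k before rotating
#' back. Rotating back without this rescaling recovers the covariance-
#' distorted direction, not the planted one.
#'
#' @param axis a [build_axis()] result (or any list with `x_low`, `x_high`).
#' @param pca the [fit_pca()] projection used to build the embeddings.
#' @param truth a `synth_truth` from [simulate_cohort()].
#' @param embedding_scale `"whitened"` when the axis was fitted on
#'   rank-normalized (unit-variance) components, `"scores"` for raw PC
#'   scores.
#' @return list: `cosine` (absolute value), `axis_raw` (unit vector in raw
#'   feature space).
#' @export
axis_recovery_report <- function(axis, pca, truth,
                                 embedding_scale = c("whitened", "scores")) {
  embedding_scale <- match.arg(embedding_scale)
  s <- apply(pca$scores, 2, sd)
  pw <- if (embedding_scale == "whitened") 1 else 2
  v <- drop(pca$rotation %*% ((axis$x_high - axis$x_low) / s^pw))
  v <- v / sqrt(sum(v^2))
  list(cosine = abs(sum(v * truth$trait_direction)), axis_raw = v)
}
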