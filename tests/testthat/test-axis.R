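test_that("fit_axis recovers planted random-effect weights", {
  set.seed(25)
  n <- 600; K <- 8
  X <- matrix(rnorm(n * K), n)
  C <- cbind(rep(1, n))
  u <- rnorm(K)
  m <- fit_axis(drop(X %*% u), X, C)          # noiseless
  expect_gt(cor(m$u_hat, u), 0.99)
  expect_gte(m$sigma2_u, 0)
  expect_gt(m$sigma2_e, 0)
  expect_error(fit_axis(rep(1, n), X, C), "zero-variance")
})

test_that("a trait independent of the embedding shrinks u to zero", {
  set.seed(26)
  n <- 300; K <- 6
  C <- cbind(rep(1, n))
  norms <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * K), n)
    m <- fit_axis(rnorm(n), X, C)
    sqrt(sum(m$u_hat^2))
  }, 0)
  expect_lt(max(norms), 0.15)   # well below the unit scale of the trait
})

test_that("K = 1 matches a direct one-parameter REML grid oracle", {
  set.seed(27)
  n <- 60
  X <- matrix(rnorm(n), n)
  C <- cbind(1, rnorm(n))
  tr <- drop(C %*% c(1, 0.3) + X * 0.8 + rnorm(n, sd = 0.6))
  m <- fit_axis(tr, X, C)
  # oracle: explicit N x N REML profile over log-gamma
  reml <- function(lg) {
    g <- exp(lg)
    V <- g * tcrossprod(X) + diag(n)
    Vi <- solve(V)
    beta <- solve(t(C) %*% Vi %*% C, t(C) %*% Vi %*% tr)
    r <- tr - C %*% beta
    s2e <- drop(t(r) %*% Vi %*% r) / (n - 2)
    -0.5 * ((n - 2) * (log(s2e) + 1) + determinant(V)$modulus[1] +
              determinant(t(C) %*% Vi %*% C)$modulus[1])
  }
  grid <- seq(-14, 12, length.out = 200)
  vals <- vapply(grid, reml, 0)
  i <- which.max(vals)
  opt <- optimize(reml, grid[c(i - 1, i + 1)], maximum = TRUE, tol = 1e-8)
  expect_equal(log(m$gamma), opt$maximum, tolerance = 1e-4)
  expect_equal(m$reml, opt$objective, tolerance = 1e-6)
})

test_that("closed-form LOO equals explicit drop-one refits", {
  set.seed(28)
  n <- 100; K <- 5
  X <- matrix(rnorm(n * K), n)
  C <- cbind(1, rnorm(n))
  u <- rnorm(K)
  tr <- drop(C %*% c(2, 0.5) + X %*% u + rnorm(n, sd = 0.7))
  m <- fit_axis(tr, X, C)
  loo <- loo_scores(m, tr, X, C)
  delta <- 1 / m$gamma
  brute <- vapply(seq_len(n), function(i) {
    A <- cbind(C, X)[-i, , drop = FALSE]
    P <- diag(c(0, 0, rep(delta, K)))
    th <- solve(crossprod(A) + P, crossprod(A, tr[-i]))
    sum(X[i, ] * th[3:(2 + K)])
  }, 0)
  expect_lt(max(abs(loo - brute)), 1e-8)
})

test_that("LOO respects null rows and exchangeability", {
  set.seed(29)
  n <- 60; K <- 4
  X <- matrix(rnorm(n * K), n)
  X[7, ] <- 0
  X[20, ] <- X[21, ]                       # duplicated pair
  C <- cbind(rep(1, n))
  tr <- drop(X %*% rnorm(K) + rnorm(n, sd = 0.5))
  tr[21] <- tr[20]
  m <- fit_axis(tr, X, C)
  loo <- loo_scores(m, tr, X, C)
  expect_equal(loo[7], 0, tolerance = 1e-12)
  expect_equal(loo[20], loo[21], tolerance = 1e-10)
})

test_that("extreme_means implements ceiling tails with id tie-breaks", {
  set.seed(30)
  X <- matrix(rnorm(1000 * 3), 1000,
              dimnames = list(sprintf("P%04d", 1:1000), NULL))
  sc <- rnorm(1000)
  ex <- extreme_means(X, sc, q = 0.001)
  expect_identical(ex$n_tail, 1)
  expect_equal(ex$x_low, X[which.min(sc), ], ignore_attr = TRUE)
  expect_equal(ex$x_high, X[which.max(sc), ], ignore_attr = TRUE)
  # invariance under strictly monotone transforms of the scores
  ex2 <- extreme_means(X, qlogis(pnorm(sc)), q = 0.01)
  expect_identical(extreme_means(X, sc, q = 0.01), ex2)
  # scores equal to a coordinate: that coordinate separates the tails most
  ex3 <- extreme_means(X, X[, 1], q = 0.05)
  gap <- (ex3$x_high - ex3$x_low) / apply(X, 2, sd)
  expect_identical(which.max(abs(gap)), 1L)
  # degenerate and too-small tails
  expect_warning(extreme_means(X, rep(1, 1000), q = 0.01), "constant scores")
  expect_error(extreme_means(X[1:100, ], sc[1:100], q = 0.001), "larger q")
})

test_that("interpolation is exact at endpoints and linear", {
  x_lo <- c(0.3, -1.2, 5)
  x_hi <- c(2, 4, -1)
  expect_identical(interpolate_embeddings(x_lo, x_hi, 0), x_lo)
  expect_identical(interpolate_embeddings(x_lo, x_hi, 1), x_hi)
  expect_equal(interpolate_embeddings(c(0, 0), c(2, 4), 0.5), c(1, 2))
  # linearity: x(a1) + x(a2) = x(a1 + a2) + x(0)
  a1 <- 0.2; a2 <- 0.35
  expect_equal(interpolate_embeddings(x_lo, x_hi, a1) +
                 interpolate_embeddings(x_lo, x_hi, a2),
               interpolate_embeddings(x_lo, x_hi, a1 + a2) + x_lo,
               tolerance = 1e-12)
  expect_error(interpolate_embeddings(x_lo, x_hi, 1.2), "alpha")
  expect_equal(interpolate_embeddings(x_lo, x_hi, 1.5,
                                      allow_extrapolation = TRUE),
               x_lo + 1.5 * (x_hi - x_lo), tolerance = 1e-12)
})

test_that("an axis aligned with PC1 is recovered on PC1", {
  set.seed(31)
  n <- 500
  # dominant variance along a known direction
  base <- matrix(rnorm(n * 6, sd = 0.3), n)
  base[, 1] <- rnorm(n, sd = 3)
  rot <- qr.Q(qr(matrix(rnorm(36), 6)))
  raw <- base %*% t(rot)
  rownames(raw) <- sprintf("P%04d", 1:n)
  pca <- fit_pca(raw, 6)
  X <- rank_inverse_normal(pca$scores)
  rownames(X) <- rownames(raw)
  C <- cbind(rep(1, n))
  tr <- pca$scores[, 1] + rnorm(n, sd = 0.3)
  ax <- build_axis(tr, X, C, q = 0.05)
  w <- abs(ax$x_high - ax$x_low)
  expect_identical(unname(which.max(w)), 1L)
})
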