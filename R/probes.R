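# Linear probing of frozen embeddings: how much age / disease signal do they
# carry? Ridge with internal CV, mirroring standard probing protocols.

# Closed-form ridge path via SVD; lambda chosen by internal k-fold CV on MAE
# (regression). lambda = 0 is included so an exact linear relationship is
# recovered exactly (glmnet's coordinate-descent tolerance would blur it).
ridge_cv_fit <- function(X, y, lambdas = c(0, 10^seq(-6, 8, length.out = 29)),
                         nfolds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fit_one <- function(Xtr, ytr) {
    ctr <- colMeans(Xtr); my <- mean(ytr)
    Xc <- sweep(Xtr, 2, ctr)
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d) * 1e-12
    list(ctr = ctr, my = my, sv = sv, pos = pos, ytr = ytr - my)
  }
  coef_at <- function(f, lam) {
    d <- f$sv$d[f$pos]
    shrink <- d / (d^2 + lam)
    f$sv$v[, f$pos, drop = FALSE] %*%
      (shrink * crossprod(f$sv$u[, f$pos, drop = FALSE], f$ytr))
  }
  pred_at <- function(f, lam, Xn) {
    drop(sweep(as.matrix(Xn), 2, f$ctr) %*% coef_at(f, lam)) + f$my
  }
  folds <- with_seed(substream_seed(seed, "ridge-cv"),
                     sample(rep_len(seq_len(nfolds), n)))
  cv_err <- sapply(lambdas, function(lam) {
    mean(vapply(seq_len(nfolds), function(k) {
      f <- fit_one(X[folds != k, , drop = FALSE], y[folds != k])
      mean(abs(pred_at(f, lam, X[folds == k, , drop = FALSE]) - y[folds == k]))
    }, 0))
  })
  lam <- lambdas[which.min(cv_err)]
  f <- fit_one(X, y)
  list(lambda = lam, predict = function(Xn) pred_at(f, lam, Xn))
}

#' Linear ridge probe for age
#'
#' Trains a ridge regression (internal cross-validated penalty, closed-form
#' SVD path) on the train+early-stop partitions of each fold of a
#' [make_split_plan()] and reports held-out mean absolute error per fold.
#'
#' @param embeddings matrix with one row per participant, rownames =
#'   participant ids.
#' @param ages numeric vector named by participant id.
#' @param splits a [make_split_plan()] over the same participants.
#' @param seed seed for the internal CV fold draw.
#' @param folds which folds to evaluate (default all). When probing an
#'   encoder trained on one fold, restrict to that fold: the other folds'
#'   test partitions contain the encoder's training participants.
#' @return list: `mae_per_fold`, `mean`, `sd`.
#' @export
linear_probe_age <- function(embeddings, ages, splits, seed = 1L,
                             folds = seq_along(splits$folds)) {
  embeddings <- as.matrix(embeddings)
  ids <- rownames(embeddings)
  if (is.null(ids)) stop("embeddings must have participant rownames", call. = FALSE)
  y <- ages[ids]
  if (anyNA(y)) stop("ages missing for some embedding rows", call. = FALSE)
  if (sd(y) == 0) stop("degenerate target: age is constant", call. = FALSE)
  mae <- vapply(folds, function(f) {
    part <- splits$folds[[f]]
    tr <- ids %in% c(part$train, part$val)
    te <- ids %in% part$test
    fit <- ridge_cv_fit(embeddings[tr, , drop = FALSE], y[tr], seed = seed + f)
    mean(abs(fit$predict(embeddings[te, , drop = FALSE]) - y[te]))
  }, 0)
  list(mae_per_fold = mae, mean = mean(mae),
       sd = if (length(mae) > 1L) sd(mae) else NA_real_)
}

# Rank-based AUC (Mann-Whitney).
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ridge logistic probe for a binary label
#'
#' Trains ridge logistic regression (glmnet, five-fold internal CV) on random
#' 80/20 train/test splits and reports the held-out AUC per split.
#'
#' @param embeddings matrix, one row per participant (rownames = ids).
#' @param labels 0/1 vector named by participant id (or aligned with rows).
#' @param n_splits number of random splits (default 20).
#' @param seed integer seed controlling the splits.
#' @param train_frac training fraction per split.
#' @param on_single_class `"resample"` (redraw a split whose train or test
#'   set is single-class) or `"error"`.
#' @return list: `auc_per_split`, `mean`, `sem`, `splits` (test indices, for
#'   paired comparisons).
#' @export
logistic_probe_disease <- function(embeddings, labels, n_splits = 20L,
                                   seed = 1L, train_frac = 0.8,
                                   on_single_class = c("resample", "error")) {
  on_single_class <- match.arg(on_single_class)
  embeddings <- as.matrix(embeddings)
  y <- if (!is.null(names(labels)) && !is.null(rownames(embeddings))) {
    as.integer(labels[rownames(embeddings)])
  } else as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  n <- nrow(embeddings)
  draws <- with_seed(substream_seed(seed, "probe-splits"), {
    out <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      for (try in seq_len(100L)) {
        tr <- sample.int(n, round(train_frac * n))
        if (length(unique(y[tr])) == 2L && length(unique(y[-tr])) == 2L) break
        if (on_single_class == "error") stop("single-class split", call. = FALSE)
      }
      out[[s]] <- tr
    }
    out
  })
  aucs <- vapply(seq_len(n_splits), function(s) {
    tr <- draws[[s]]
    # internal CV folds seeded per split so identical inputs give identical fits
    with_seed(substream_seed(seed, paste0("probe-cv-", s)), {
      fit <- glmnet::cv.glmnet(embeddings[tr, , drop = FALSE], y[tr],
                               family = "binomial", alpha = 0, nfolds = 5)
      p <- predict(fit, embeddings[-tr, , drop = FALSE], s = "lambda.min",
                   type = "response")
      auc_score(drop(p), y[-tr])
    })
  }, 0)
  list(auc_per_split = aucs, mean = mean(aucs),
       sem = sd(aucs) / sqrt(n_splits), splits = draws)
}

#' Paired comparison of two embedding sets by probe AUC
#'
#' Runs [logistic_probe_disease()] for both embedding sets on identical
#' splits (same seed) and compares per-split AUCs with a paired t-test.
#'
#' @param emb_a,emb_b embedding matrices over the same participants.
#' @param labels binary labels.
#' @param n_splits,seed as in [logistic_probe_disease()].
#' @return list: `auc_a`, `auc_b`, `mean_diff`, `p_value`.
#' @export
compare_probe_auc <- function(emb_a, emb_b, labels, n_splits = 20L, seed = 1L) {
  pa <- logistic_probe_disease(emb_a, labels, n_splits, seed)
  pb <- logistic_probe_disease(emb_b, labels, n_splits, seed)
  d <- pa$auc_per_split - pb$auc_per_split
  p <- if (sd(d) == 0) 1 else t.test(pa$auc_per_split, pb$auc_per_split,
                                     paired = TRUE)$p.value
  list(auc_a = pa, auc_b = pb, mean_diff = mean(d), p_value = p)
}
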