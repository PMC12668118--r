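#' Rank-N-Contrast loss
#'
#' Contrastive objective for regression: within a batch, for anchor i and
#' positive j the candidate set is every other sample at least as
#' label-distant from i as j is, `S_ij = {k != i : |y_i - y_k| >= |y_i - y_j|}`.
#' Similarity is negative Euclidean distance. The per-pair loss is
#' `-log( exp(s_ij / tau) / sum_{k in S_ij} exp(s_ik / tau) )` and the total
#' is the mean over all ordered anchor/positive pairs. Since the positive is
#' always its own candidate, every per-pair term is nonnegative, hence so is
#' the loss. Minimizing it orders the latent space by the label.
#'
#' @param representations numeric B x d matrix of encoder outputs.
#' @param labels numeric length-B vector (e.g. chronological age in years).
#' @param temperature positive softmax temperature `tau` (default 2).
#' @return Nonnegative scalar loss.
#' @export
rnc_loss <- function(representations, labels, temperature = 2) {
  rnc_eval(representations, labels, temperature, grad = FALSE)$loss
}

#' Rank-N-Contrast loss and gradient
#'
#' As [rnc_loss()], but also returns the analytic gradient of the loss with
#' respect to the representations (B x d), used by the training loop.
#'
#' @inheritParams rnc_loss
#' @param grad compute the gradient as well?
#' @return list with `loss` and (if requested) `grad`.
#' @export
rnc_eval <- function(representations, labels, temperature = 2, grad = TRUE) {
  Z <- as.matrix(representations)
  y <- as.numeric(labels)
  B <- nrow(Z)
  if (B < 2L) stop("batch too small: need at least 2 samples", call. = FALSE)
  if (length(y) != B) stop("one label per representation row required", call. = FALSE)
  if (!all(is.finite(Z))) stop("non-finite representations", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite labels", call. = FALSE)
  if (!(is.numeric(temperature) && length(temperature) == 1L && temperature > 0)) {
    stop("temperature must be a positive scalar", call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(Z))        # Euclidean distances
  smat <- -dmat / temperature              # scaled similarities
  total <- 0
  C <- if (grad) matrix(0, B, B) else NULL # C[i,k] = dLoss/d smat_raw[i,k]
  for (i in seq_len(B)) {
    cand <- setdiff(seq_len(B), i)
    lab_d <- abs(y[i] - y[cand])
    o <- order(lab_d)
    sd_s <- lab_d[o]
    ss <- smat[i, cand][o]
    M <- length(cand)
    # suffix log-sum-exp over candidates sorted by label distance
    L <- numeric(M)
    L[M] <- ss[M]
    if (M > 1L) for (m in (M - 1L):1L) {
      mx <- max(ss[m], L[m + 1L])
      L[m] <- mx + log(exp(ss[m] - mx) + exp(L[m + 1L] - mx))
    }
    start <- vapply(sd_s, function(t) sum(sd_s < t), 0L) + 1L
    total <- total + sum(-ss + L[start])
    if (grad) {
      for (m in seq_len(M)) {
        rng <- start[m]:M
        w <- exp(ss[rng] - L[start[m]])
        kk <- cand[o[rng]]
        C[i, kk] <- C[i, kk] + w
        C[i, cand[o[m]]] <- C[i, cand[o[m]]] - 1
      }
    }
  }
  n_pairs <- B * (B - 1L)
  out <- list(loss = max(total / n_pairs, 0))
  if (grad) {
    C <- C / (n_pairs * temperature)
    # ds/dz through s = -||z_i - z_k||: grad_i = sum_k (A+A')[i,k] (z_k - z_i)
    A <- C / dmat
    A[!is.finite(A)] <- 0
    Msym <- A + t(A)
    out$grad <- Msym %*% Z - rowSums(Msym) * Z
  }
  out
}

#' Training configuration for the contrastive encoder
#'
#' Desk-scale defaults for training a small MLP encoder with AdamW on
#' tabular features. The full-scale fundus-image setting uses learning rate
#' 5e-6, weight decay 1e-5 and batch size 64 with a vision-transformer
#' backbone; see [train_config_fullscale()]. Desk-scale training of a freshly
#' initialized MLP needs a much larger learning rate.
#'
#' @param temperature RnC softmax temperature.
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param hidden hidden layer widths of the MLP encoder.
#' @param seed integer seed for initialization and batch shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(temperature = 2, learning_rate = 1e-3,
                         weight_decay = 1e-4, batch_size = 64L,
                         max_epochs = 60L, patience = 10L,
                         hidden = c(128L, 64L), seed = 1L) {
  stopifnot(temperature > 0, learning_rate > 0, weight_decay >= 0)
  structure(list(temperature = temperature, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = check_count(batch_size, "batch_size", 2L),
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 patience = check_count(patience, "patience"),
                 hidden = as.integer(hidden),
                 seed = check_count(seed, "seed", 0L)),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_fullscale <- function() {
  train_config(learning_rate = 5e-6, weight_decay = 1e-5, batch_size = 64L)
}

#' Group-aware cross-validation split plan
#'
#' Assigns participants (not images) to `n_folds` test folds and, within each
#' fold, splits the remaining participants into training and early-stopping
#' partitions. All images of one participant always share a split. Default
#' fractions are 72% train / 8% early-stop / 20% test of the cohort.
#'
#' @param participants character vector of participant ids (unique).
#' @param n_folds number of cross-validation folds.
#' @param fractions named vector `c(train=, val=, test=)` summing to 1;
#'   `test` must equal `1 / n_folds`.
#' @param seed integer seed.
#' @return list of class `split_plan`: per fold, `train`, `val` and `test`
#'   participant id vectors.
#' @export
make_split_plan <- function(participants, n_folds = 5L,
                            fractions = c(train = 0.72, val = 0.08, test = 0.20),
                            seed = 1L) {
  participants <- unique(as.character(participants))
  n_folds <- check_count(n_folds, "n_folds", 2L)
  if (abs(sum(fractions) - 1) > 1e-8 ||
      abs(fractions[["test"]] - 1 / n_folds) > 1e-8) {
    stop("fractions must sum to 1 with test = 1/n_folds", call. = FALSE)
  }
  with_seed(substream_seed(seed, "splits"), {
    n <- length(participants)
    fold_of <- sample(rep_len(seq_len(n_folds), n))
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- participants[fold_of == f]
      rest <- participants[fold_of != f]
      n_val <- round(length(rest) * fractions[["val"]] /
                       (fractions[["train"]] + fractions[["val"]]))
      val <- sample(rest, n_val)
      list(train = setdiff(rest, val), val = val, test = test)
    })
    structure(list(folds = folds, participants = participants,
                   fractions = fractions, seed = seed),
              class = "split_plan")
  })
}

# ---- MLP encoder -----------------------------------------------------------

#' Initialize a small MLP encoder
#'
#' Fully connected `d_in -> hidden[1] -> hidden[2]` network with ReLU after
#' the first layer; the (linear) second-layer output is the representation.
#' He-scaled Gaussian initialization.
#'
#' @param d_in input feature dimension.
#' @param hidden integer vector of the two layer widths.
#' @param seed integer seed.
#' @return list of class `mlp_encoder` (weights plus input standardization
#'   slots, filled in by [train_encoder()]).
#' @export
encoder_init <- function(d_in, hidden = c(128L, 64L), seed = 1L) {
  stopifnot(length(hidden) == 2L)
  with_seed(substream_seed(seed, "encoder-init"), {
    structure(list(
      W1 = matrix(rnorm(d_in * hidden[1], sd = sqrt(2 / d_in)), d_in, hidden[1]),
      b1 = numeric(hidden[1]),
      W2 = matrix(rnorm(hidden[1] * hidden[2], sd = sqrt(2 / hidden[1])),
                  hidden[1], hidden[2]),
      b2 = numeric(hidden[2]),
      center = NULL, scale = NULL),
      class = "mlp_encoder")
  })
}

encoder_standardize <- function(enc, X) {
  if (is.null(enc$center)) return(X)
  sweep(sweep(X, 2, enc$center), 2, enc$scale, "/")
}

#' Encode features with an MLP encoder
#'
#' @param enc an `mlp_encoder`.
#' @param X numeric matrix, rows = samples (raw feature scale; any input
#'   standardization learned during training is applied internally).
#' @return representation matrix, rows aligned with `X`.
#' @export
encode <- function(enc, X) {
  encoder_forward(enc, encoder_standardize(enc, as.matrix(X)))$Z
}

encoder_forward <- function(enc, X) {
  A1p <- sweep(X %*% enc$W1, 2, enc$b1, "+")
  A1 <- pmax(A1p, 0)
  Z <- sweep(A1 %*% enc$W2, 2, enc$b2, "+")
  list(Z = Z, A1 = A1, A1p = A1p, X = X)
}

encoder_backward <- function(enc, fwd, dZ) {
  gW2 <- crossprod(fwd$A1, dZ)
  gb2 <- colSums(dZ)
  dA1 <- (dZ %*% t(enc$W2)) * (fwd$A1p > 0)
  gW1 <- crossprod(fwd$X, dA1)
  gb1 <- colSums(dA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adamw_step <- function(par, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (nm %in% c("W1", "W2")) wd * par[[nm]] else 0
    par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(par = par, state = state)
}

#' Train the MLP encoder with the Rank-N-Contrast objective
#'
#' Minimizes [rnc_loss()] over the training partition of one fold of a
#' group-aware [make_split_plan()] using AdamW, early-stopping on the
#' validation (early-stop) partition's loss. Inputs are standardized using
#' training-partition statistics; the standardization travels with the
#' returned encoder so [encode()] accepts raw features.
#'
#' @param features a `feature_matrix` (see [simulate_cohort()]) or a plain
#'   matrix with one row per image.
#' @param ages numeric vector of ages, named by participant id (or one per
#'   feature row when `groups` is given explicitly).
#' @param groups participant id per feature row; defaults to the
#'   `feature_matrix` participant map.
#' @param config a [train_config()].
#' @param splits a [make_split_plan()] over the participants.
#' @param fold which fold of the plan to train on (default 1).
#' @return list of class `rnc_fit`: `encoder` (best-validation weights),
#'   `log` (data.frame epoch/train_loss/val_loss), `config`, `fold`.
#' @export
train_encoder <- function(features, ages, groups = NULL,
                          config = train_config(), splits, fold = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (is.null(groups)) {
    if (!inherits(features, "feature_matrix")) {
      stop("groups required when features is a plain matrix", call. = FALSE)
    }
    groups <- features$participant
  }
  if (length(groups) != nrow(X)) stop("one group per feature row required", call. = FALSE)
  y <- if (!is.null(names(ages))) unname(ages[groups]) else as.numeric(ages)
  if (length(y) != nrow(X) || anyNA(y)) {
    stop("could not align one age per feature row", call. = FALSE)
  }
  part <- splits$folds[[fold]]
  tr <- which(groups %in% part$train)
  va <- which(groups %in% part$val)
  if (length(tr) < 2L || length(va) < 2L) stop("empty split", call. = FALSE)

  ctr <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  enc <- encoder_init(ncol(X), config$hidden, config$seed)
  enc$center <- ctr; enc$scale <- scl
  state <- list(t = 0L,
                m = lapply(enc[c("W1", "b1", "W2", "b2")], function(p) p * 0),
                v = lapply(enc[c("W1", "b1", "W2", "b2")], function(p) p * 0))
  batch_loss <- function(idx) {
    rnc_loss(encoder_forward(enc, Xs[idx, , drop = FALSE])$Z, y[idx],
             config$temperature)
  }
  eval_partition <- function(idx, cap = 512L) {
    idx <- idx[seq_len(min(length(idx), cap))]
    batch_loss(idx)
  }
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(val = Inf, enc = enc, epoch = 0L)
  with_seed(substream_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      starts <- seq(1L, length(ord), by = config$batch_size)
      ep_losses <- numeric(0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        if (length(idx) < 2L) next
        fwd <- encoder_forward(enc, Xs[idx, , drop = FALSE])
        ev <- rnc_eval(fwd$Z, y[idx], config$temperature)
        if (!is.finite(ev$loss)) stop("NaN loss during training", call. = FALSE)
        grads <- encoder_backward(enc, fwd, ev$grad)
        upd <- adamw_step(enc[c("W1", "b1", "W2", "b2")], grads, state,
                          config$learning_rate, config$weight_decay)
        enc[c("W1", "b1", "W2", "b2")] <- upd$par
        state <- upd$state
        ep_losses <- c(ep_losses, ev$loss)
      }
      vl <- eval_partition(va)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(ep_losses),
                                   val_loss = vl))
      if (vl < best$val - 1e-8) best <- list(val = vl, enc = enc, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
  })
  structure(list(encoder = best$enc, log = log, config = config, fold = fold),
            class = "rnc_fit")
}
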