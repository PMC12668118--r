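# From per-image features to per-participant GWAS-ready phenotypes:
# eye averaging -> PCA -> rank-based inverse normal transform, plus the
# covariate design and residualization used by the association null model.

#' Average per-image features within participant
#'
#' One output row per participant: the arithmetic mean of that participant's
#' image rows (left/right eye). Single-image participants pass through
#' unchanged. Output rows are sorted by participant id — the package's
#' canonical sample ordering.
#'
#' @param features a `feature_matrix` or plain matrix of per-image rows.
#' @param participant_map participant id per image row (defaults to the
#'   `feature_matrix` map).
#' @return matrix with one row per participant, rownames = participant ids.
#' @export
average_eyes <- function(features, participant_map = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (is.null(participant_map)) {
    if (!inherits(features, "feature_matrix")) {
      stop("participant_map required for a plain matrix", call. = FALSE)
    }
    participant_map <- features$participant
  }
  if (length(participant_map) != nrow(X)) {
    stop("one participant id per image row required", call. = FALSE)
  }
  ids <- sort(unique(as.character(participant_map)))
  out <- rowsum(X, group = as.character(participant_map), reorder = TRUE) /
    as.vector(table(factor(participant_map, levels = ids)))
  rownames(out) <- ids
  out
}

#' Fit a centered PCA for dimensionality reduction
#'
#' Components are ordered by decreasing explained variance; each component's
#' sign is fixed so its largest-magnitude loading is positive, making the
#' decomposition deterministic. The returned projection is reusable on new
#' samples via [apply_pca()].
#'
#' @param x matrix, rows = samples.
#' @param n_components number of components to retain (default 40).
#' @return list of class `pca_projection`: `center`, `rotation` (D x K),
#'   `scores` (N x K), `explained_variance_ratio`.
#' @export
fit_pca <- function(x, n_components = 40L) {
  x <- as.matrix(x)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stop("n_components exceeds min(N - 1, D)", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(k) {
    sign(rot[which.max(abs(rot[, k])), k])
  }, 0)
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(x, 2, pr$center) %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(n_components))
  structure(list(center = pr$center, rotation = rot, scores = scores,
                 explained_variance_ratio = pr$sdev^2 / sum(pr$sdev^2)),
            class = "pca_projection")
}

#' @rdname fit_pca
#' @param pca a fitted `pca_projection`.
#' @export
apply_pca <- function(pca, x) {
  sweep(as.matrix(x), 2, pca$center) %*% pca$rotation
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their ranks,
#' `qnorm((rank - 0.5) / n)`, with ties receiving average ranks. Strictly
#' monotone over untied values, so any strictly monotone transform of the
#' input yields identical output. Applied column-wise when given a matrix.
#'
#' @param values numeric vector or matrix (columns transformed independently).
#' @return transformed vector/matrix of the same shape.
#' @export
rank_inverse_normal <- function(values) {
  if (is.matrix(values)) {
    out <- apply(values, 2, rank_inverse_normal)
    dimnames(out) <- dimnames(values)
    return(out)
  }
  v <- as.numeric(values)
  n <- length(v)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite values", call. = FALSE)
  if (max(v) == min(v)) stop("degenerate column: all values equal", call. = FALSE)
  qnorm((rank(v, ties.method = "average") - 0.5) / n)
}

#' Build the covariate design matrix
#'
#' Intercept, centered age, sex (0/1), age-squared and sex-by-age interaction
#' terms (matching the standard imaging-GWAS covariate list), optional
#' genetic principal components, and one-hot columns (first level dropped)
#' for any categorical batch factors. Age is centered before squaring to
#' limit collinearity. Rank-deficient designs are rejected with the
#' offending columns named.
#'
#' @param age numeric vector (years), named by sample id.
#' @param sex 0/1 vector.
#' @param genetic_pcs optional matrix of genetic principal components.
#' @param batch optional data.frame of categorical covariates.
#' @param sample_ids sample ids (default from `names(age)`).
#' @return numeric design matrix of class `covariate_matrix`, full column
#'   rank, rownames = sample ids.
#' @export
build_covariates <- function(age, sex, genetic_pcs = NULL, batch = NULL,
                             sample_ids = names(age)) {
  n <- length(age)
  stopifnot(length(sex) == n)
  a <- age - mean(age)
  C <- cbind(intercept = 1, age = a, sex = as.numeric(sex), age2 = a^2,
             sex_age = as.numeric(sex) * a, sex_age2 = as.numeric(sex) * a^2)
  if (!is.null(genetic_pcs)) {
    gp <- as.matrix(genetic_pcs)
    colnames(gp) <- colnames(gp) %||% paste0("gPC", seq_len(ncol(gp)))
    C <- cbind(C, gp)
  }
  if (!is.null(batch)) {
    for (nm in names(batch)) {
      f <- factor(batch[[nm]])
      if (nlevels(f) > 1L) {
        oh <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(oh) <- paste0(nm, "_", levels(f)[-1])
        C <- cbind(C, oh)
      }
    }
  }
  if (!is.null(sample_ids)) rownames(C) <- sample_ids
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(C) <- c("covariate_matrix", class(C))
  C
}

#' Residualize a matrix on covariates
#'
#' Returns `(I - C (C'C)^-1 C') Y`: the projection of each column of `Y`
#' onto the orthogonal complement of the covariate column space.
#'
#' @param Y numeric matrix (or vector), rows aligned with `C`.
#' @param C full-column-rank covariate matrix.
#' @return residual matrix of the same shape as `Y`.
#' @export
residualize <- function(Y, C) {
  Y <- as.matrix(Y)
  C <- as.matrix(C)
  if (nrow(Y) != nrow(C)) stop("Y and C must be row-aligned", call. = FALSE)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad %||% "(unnamed)", collapse = ", "), call. = FALSE)
  }
  Y - qr.fitted(qrC, Y)
}
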