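# End-to-end pipeline: simulate/ingest -> train/probe -> embed -> associate
# (multivariate + univariate baseline) -> clump -> trait axis, with a
# reproducibility manifest. Every stage is a thin call into the library;
# all randomness flows from the single config seed via named substreams.

#' Pipeline configuration
#'
#' Strictly validated nested configuration for [run_pipeline()]. Unknown
#' keys are rejected; the seed is mandatory (no wall-clock defaults).
#'
#' @param seed global integer seed.
#' @param synth list of [synth_config()] overrides.
#' @param train list: `enabled`, plus [train_config()] overrides.
#' @param embedding list: `n_components`, `rank_int` (logical).
#' @param assoc list: `mode` ("score"/"refined"), `maf_min`, `n_perm`.
#' @param clump list: `p_threshold`, `r2_threshold`, `window_bp`,
#'   `window_convention`.
#' @param axis list: `q`, `alphas`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            synth = list(),
                            train = list(enabled = TRUE),
                            embedding = list(n_components = 10L, rank_int = TRUE),
                            assoc = list(mode = "score", maf_min = 0.01,
                                         n_perm = 20L),
                            clump = list(p_threshold = 5e-8, r2_threshold = 0.1,
                                         window_bp = 5e6,
                                         window_convention = "span"),
                            axis = list(q = 0.05, alphas = c(0, 0.25, 0.5, 0.75, 1))) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  defaults <- list(
    train = list(enabled = TRUE),
    embedding = list(n_components = 10L, rank_int = TRUE),
    assoc = list(mode = "score", maf_min = 0.01, n_perm = 20L),
    clump = list(p_threshold = 5e-8, r2_threshold = 0.1, window_bp = 5e6,
                 window_convention = "span"),
    axis = list(q = 0.05, alphas = c(0, 0.25, 0.5, 0.75, 1)))
  merge_strict <- function(base, user, where) {
    bad <- setdiff(names(user), names(base))
    if (length(bad)) stop("unknown config keys in ", where, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    utils::modifyList(base, user)
  }
  tr_defaults <- c(defaults$train["enabled"],
                   unclass(train_config())[c("temperature", "learning_rate",
                                             "weight_decay", "batch_size",
                                             "max_epochs", "patience", "hidden")])
  synth_defaults <- unclass(synth_config())
  synth_defaults$seed <- NULL
  bad_synth <- setdiff(names(synth), names(synth_defaults))
  if (length(bad_synth)) stop("unknown config keys in synth: ",
                              paste(bad_synth, collapse = ", "), call. = FALSE)
  cfg <- list(
    seed = check_count(seed, "seed", 0L),
    synth = utils::modifyList(synth_defaults, synth),
    train = merge_strict(tr_defaults, train, "train"),
    embedding = merge_strict(defaults$embedding, embedding, "embedding"),
    assoc = merge_strict(defaults$assoc, assoc, "assoc"),
    clump = merge_strict(defaults$clump, clump, "clump"),
    axis = merge_strict(defaults$axis, axis, "axis"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] structure (top-level
#'   keys seed/synth/train/embedding/assoc/clump/axis).
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "synth", "train", "embedding", "assoc", "clump", "axis")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown top-level config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(y$seed)) stop("seed is mandatory", call. = FALSE)
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_pipeline_config()].
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates genotypes and features, optionally trains the contrastive
#' encoder and encodes images (otherwise raw features are used), builds
#' per-participant embeddings (eye averaging, PCA, optional rank-based
#' inverse normal transform), runs the multivariate scan plus the univariate
#' ACAT baseline, clumps loci, runs a small permutation-calibration report,
#' fits the disease trait axis, and writes all artifacts under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results (`geno`, `cohort`,
#'   `embeddings`, `gwas`, `acat`, `loci`, `perm`, `axis`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  scfg <- stage("simulate", do.call(synth_config,
                                    c(config$synth, list(seed = config$seed))))
  geno <- stage("simulate", simulate_genotypes(scfg))
  cohort <- stage("simulate", simulate_cohort(scfg, geno))
  stage("simulate", write_dosage_tsv(geno, file.path(out_dir, "dosages.tsv")))
  stage("simulate", write_sample_table(
    data.frame(sample_id = geno$sample_ids,
               age = unname(cohort$truth$age),
               sex = unname(cohort$truth$sex),
               disease = unname(cohort$truth$disease_labels)),
    file.path(out_dir, "phenotypes.tsv")))

  feats <- cohort$features
  img_values <- feats$values
  if (isTRUE(config$train$enabled)) {
    tcfg <- do.call(train_config, c(
      config$train[setdiff(names(config$train), "enabled")],
      list(seed = substream_seed(config$seed, "train-stage"))))
    splits <- make_split_plan(unique(feats$participant), seed = config$seed)
    fit <- stage("train", train_encoder(feats, cohort$truth$age,
                                        config = tcfg, splits = splits))
    data.table::fwrite(fit$log, file.path(out_dir, "training_log.tsv"),
                       sep = "\t")
    img_values <- stage("train", encode(fit$encoder, feats$values))
    rownames(img_values) <- rownames(feats$values)
  }

  per_part <- stage("embed", average_eyes(img_values, feats$participant))
  pca <- stage("embed", fit_pca(per_part, config$embedding$n_components))
  emb <- pca$scores
  if (isTRUE(config$embedding$rank_int)) emb <- rank_inverse_normal(emb)
  rownames(emb) <- rownames(per_part)
  stage("embed", write_sample_table(emb, file.path(out_dir, "embeddings.tsv")))

  C <- stage("assoc", build_covariates(cohort$truth$age, cohort$truth$sex))
  gwas <- stage("assoc", run_gwas(geno, emb, C, maf_min = config$assoc$maf_min,
                                  mode = config$assoc$mode))
  data.table::fwrite(gwas, file.path(out_dir, "sumstats.tsv"), sep = "\t")
  acat <- stage("assoc", test_univariate_acat(geno, emb, C,
                                              maf_min = config$assoc$maf_min))
  data.table::fwrite(acat, file.path(out_dir, "sumstats_univariate.tsv"),
                     sep = "\t")
  perm <- stage("assoc", permutation_null(
    geno, emb, C, n_perm = config$assoc$n_perm,
    seed = substream_seed(config$seed, "perm-stage"),
    maf_min = config$assoc$maf_min))
  data.table::fwrite(perm$qq, file.path(out_dir, "calibration_qq.tsv"),
                     sep = "\t")

  loci <- stage("clump", clump_loci(
    gwas, geno, p_threshold = config$clump$p_threshold,
    r2_threshold = config$clump$r2_threshold,
    window_bp = config$clump$window_bp,
    window_convention = config$clump$window_convention))
  data.table::fwrite(loci, file.path(out_dir, "loci.tsv"), sep = "\t")

  ax <- stage("axis", build_axis(cohort$truth$disease_labels, emb, C,
                                 q = config$axis$q))
  interp <- interpolate_embeddings(ax$x_low, ax$x_high, config$axis$alphas)
  interp <- if (is.matrix(interp)) interp else matrix(interp, nrow = 1)
  axis_tab <- data.frame(alpha = config$axis$alphas, interp)
  names(axis_tab) <- c("alpha", colnames(emb))
  data.table::fwrite(axis_tab, file.path(out_dir, "axis.tsv"), sep = "\t")

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    outputs = c("dosages.tsv", "phenotypes.tsv", "embeddings.tsv",
                "sumstats.tsv", "sumstats_univariate.tsv",
                "calibration_qq.tsv", "loci.tsv", "axis.tsv"),
    n_loci = nrow(loci),
    lambda_gc = attr(gwas, "lambda_gc"),
    perm_ks_p = perm$ks_p)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(geno = geno, cohort = cohort, embeddings = emb, pca = pca,
                 gwas = gwas, acat = acat, loci = loci, perm = perm,
                 axis = ax, manifest = manifest))
}
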