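# File I/O: VCF (via VariantAnnotation) and the package's TSV dialects for
# dosages, features, embeddings, covariates and traits.

#' Read genotype dosages from a VCF
#'
#' Dosages come from the DS FORMAT field when present, otherwise from GT
#' allele counts (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./.` -> missing).
#' Positions are 1-based as in the VCF. Multi-allelic records are rejected
#' by default or dropped with a warning.
#'
#' @param path path to a (plain or bgzipped) VCF file.
#' @param multiallelic `"reject"` (default) or `"drop"`.
#' @return a [genotypes] object (missing genotypes stay NA; no imputation at
#'   read time).
#' @export
read_vcf_dosages <- function(path, multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) == 0L) stop("VCF has zero samples", call. = FALSE)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    if (multiallelic == "reject") {
      stop("multi-allelic records present; set multiallelic = \"drop\" to skip them",
           call. = FALSE)
    }
    warning(sum(n_alt != 1L), " multi-allelic records dropped")
    vcf <- vcf[n_alt == 1L]
    alt <- VariantAnnotation::alt(vcf)
  }
  gmats <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gmats)) {
    dos <- gmats$DS            # variants x samples
    storage.mode(dos) <- "double"
  } else if ("GT" %in% names(gmats)) {
    gt <- gmats$GT
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
               "1|0" = 1, "1/1" = 2, "1|1" = 2)
    dos[] <- known[gt]
    bad <- !(gt %in% c(names(known), "./.", ".|.", "."))
    if (any(bad)) {
      stop("malformed GT values, e.g. record ", which(rowSums(bad) > 0)[1],
           call. = FALSE)
    }
  } else {
    stop("VCF carries neither DS nor GT", call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    id = names(rr) %||% sprintf("var%05d", seq_along(rr)),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  genotypes(t(dos), variants, colnames(dos))
}

#' Write genotypes to a VCF (GT field)
#'
#' Integer dosages map to GT (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, NA ->
#' `./.`). Non-integer dosages cannot be represented as GT; use
#' [write_dosage_tsv()] for those.
#'
#' @param geno a [genotypes] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(geno, path) {
  stopifnot(inherits(geno, "genotypes"))
  d <- geno$dosage
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE)) {
    stop("non-integer dosages cannot be written as GT; use write_dosage_tsv()",
         call. = FALSE)
  }
  gt_of <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_of[round(d[ok]) + 1L]
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read/write the dosage TSV dialect
#'
#' Rows are variants: columns `chrom, pos, id, ref, alt`, then one numeric
#' dosage column per sample (header row carries sample ids; NA = missing).
#'
#' @param path file path.
#' @return [read_dosage_tsv()]: a [genotypes] object.
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta_cols <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(meta_cols %in% names(dt))) {
    stop("dosage TSV must start with columns: ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(names(dt), meta_cols)
  if (length(samples) == 0L) stop("dosage TSV has zero sample columns", call. = FALSE)
  dos <- t(as.matrix(dt[, samples, with = FALSE]))
  genotypes(dos, as.data.frame(dt[, meta_cols, with = FALSE]), samples)
}

#' @rdname read_dosage_tsv
#' @param geno a [genotypes] object.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotypes"))
  v <- geno$variants[c("chrom", "pos", "id", "ref", "alt")]
  dt <- data.table::data.table(v, t(geno$dosage))
  data.table::setnames(dt, c(names(v), geno$sample_ids))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read/write sample-indexed TSV tables
#'
#' TSV with a header row; the first column is `sample_id`. Duplicate sample
#' ids are an error. Writing emits columns in the given order; a matrix is
#' written with its rownames as `sample_id`.
#'
#' @param path file path.
#' @return [read_sample_table()]: data.frame with a `sample_id` column.
#' @export
read_sample_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (names(df)[1] != "sample_id") {
    stop("first column must be sample_id", call. = FALSE)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicated sample ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_sample_table
#' @param x data.frame (first column `sample_id`) or matrix with rownames.
#' @export
write_sample_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(sample_id = rownames(x), as.data.frame(x),
                    check.names = FALSE)
  }
  stopifnot(names(x)[1] == "sample_id")
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Align several sample-indexed objects on their common ids
#'
#' Errors if the id sets differ, naming the unmatched ids; otherwise returns
#' the objects reordered to sorted common ids (the package's canonical
#' ordering).
#'
#' @param ... named objects: data.frames with `sample_id` or matrices/vectors
#'   with names/rownames.
#' @return named list of aligned objects.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  ids_of <- function(o) {
    if (is.data.frame(o)) o$sample_id
    else if (is.matrix(o)) rownames(o)
    else names(o)
  }
  all_ids <- lapply(objs, ids_of)
  common <- sort(Reduce(intersect, all_ids))
  extra <- sort(unique(unlist(lapply(all_ids, setdiff, y = common))))
  if (length(extra)) {
    stop("unmatched sample ids across inputs: ",
         paste(head(extra, 10), collapse = ", "),
         if (length(extra) > 10) " ..." else "", call. = FALSE)
  }
  if (length(common) == 0L) stop("no overlapping sample ids", call. = FALSE)
  lapply(objs, function(o) {
    if (is.data.frame(o)) o[match(common, o$sample_id), , drop = FALSE]
    else if (is.matrix(o)) o[common, , drop = FALSE]
    else o[common]
  })
}
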