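# Greedy LD clumping of GWAS summary statistics against cohort genotypes.

#' Squared Pearson correlation between two dosage vectors
#'
#' Sample LD (r^2) on mean-imputed dosages; invariant to allele flips.
#'
#' @param g1,g2 numeric dosage vectors of equal length (NA = missing).
#' @return r^2 in `[0, 1]`.
#' @export
compute_r2 <- function(g1, g2) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) != length(g2)) stop("dosage vectors differ in length", call. = FALSE)
  if (anyNA(g1)) g1[is.na(g1)] <- mean(g1, na.rm = TRUE)
  if (anyNA(g2)) g2[is.na(g2)] <- mean(g2, na.rm = TRUE)
  if (sd(g1) == 0 || sd(g2) == 0) stop("monomorphic dosage vector", call. = FALSE)
  cor(g1, g2)^2
}

#' Greedy LD clumping into independent loci
#'
#' Repeatedly takes the unclaimed significant variant with the smallest
#' p-value as a lead and claims every unclaimed variant (significant or not)
#' within the window whose LD with the lead is `r^2 >= r2_threshold`.
#' Iterates until no significant unclaimed variant remains. Ties in p are
#' broken by (chrom, pos). By the construction, any two leads within window
#' distance have `r^2 <` the threshold.
#'
#' @param records data.frame with columns ID, CHR, POS, P (e.g. a
#'   [run_gwas()] result; a `P_ACAT` column is accepted as P).
#' @param geno the [genotypes] the scan was run on (LD is computed on the
#'   same samples).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold LD threshold (default 0.1).
#' @param window_bp clumping window in base pairs (default 5e6).
#' @param window_convention `"span"` (default): the window is the total span,
#'   i.e. +/- `window_bp / 2` around the lead; `"index"`: +/- `window_bp`
#'   from the lead (the PLINK distance-from-index convention).
#' @return data.frame of class `locus_table`, one row per locus, sorted by
#'   lead p ascending: LEAD_ID, CHR, POS, P, N_CLUMPED, CLUMPED_IDS
#'   (semicolon-joined). Empty (zero rows) when nothing is significant.
#' @export
clump_loci <- function(records, geno, p_threshold = 5e-8, r2_threshold = 0.1,
                       window_bp = 5e6,
                       window_convention = c("span", "index")) {
  window_convention <- match.arg(window_convention)
  stopifnot(inherits(geno, "genotypes"))
  rec <- as.data.frame(records)
  if (!"P" %in% names(rec) && "P_ACAT" %in% names(rec)) rec$P <- rec$P_ACAT
  if (!all(c("ID", "P") %in% names(rec))) {
    stop("records need ID and P columns", call. = FALSE)
  }
  vmap <- geno$variants
  idx <- match(rec$ID, vmap$id)
  if (anyNA(idx)) stop("records contain ids absent from the genotypes", call. = FALSE)
  rec$CHR <- vmap$chrom[idx]
  rec$POS <- vmap$pos[idx]
  half <- if (window_convention == "span") window_bp / 2 else window_bp
  G <- mean_impute(geno$dosage[, idx, drop = FALSE])

  unclaimed <- rep(TRUE, nrow(rec))
  ord <- order(rec$P, rec$CHR, rec$POS)   # deterministic tie-break
  loci <- list()
  repeat {
    cand <- ord[unclaimed[ord] & !is.na(rec$P[ord]) & rec$P[ord] < p_threshold]
    if (length(cand) == 0L) break
    lead <- cand[1L]
    unclaimed[lead] <- FALSE
    inwin <- which(unclaimed & rec$CHR == rec$CHR[lead] &
                     abs(rec$POS - rec$POS[lead]) <= half)
    claimed <- integer(0)
    if (length(inwin)) {
      glead <- G[, lead]
      if (sd(glead) > 0) {
        r2 <- suppressWarnings(cor(glead, G[, inwin, drop = FALSE]))^2
        r2[is.na(r2)] <- 0
        claimed <- inwin[r2 >= r2_threshold]
        unclaimed[claimed] <- FALSE
      }
    }
    loci[[length(loci) + 1L]] <- data.frame(
      LEAD_ID = rec$ID[lead], CHR = rec$CHR[lead], POS = rec$POS[lead],
      P = rec$P[lead], N_CLUMPED = length(claimed),
      CLUMPED_IDS = paste(rec$ID[claimed], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(LEAD_ID = character(), CHR = character(), POS = integer(),
               P = numeric(), N_CLUMPED = integer(), CLUMPED_IDS = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$P, out$CHR, out$POS), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_table", class(out))
  out
}
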