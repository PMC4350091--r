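#' Genotype matrix with per-site annotation
#'
#' The central container passed between the calling and association
#' stages: a sites x samples matrix of minor-allele dosages (0, 1, 2 or
#' `NA` for missing) together with a per-site annotation table (variant
#' id, gene, functional class, combined-cohort minor-allele frequency)
#' and optionally per-sample sequencing depths of the same shape.
#'
#' @param dosage integer matrix, variants in rows, samples in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variants data frame with one row per variant: columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `class` (one of `non-silent`, `silent`, `UTR`). A `maf` column is
#'   recomputed unless supplied.
#' @param samples character vector of sample ids (column names).
#' @param depth optional numeric matrix of per-sample read depths,
#'   same dimensions as `dosage`.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, variants, samples = colnames(dosage),
                            depth = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosage)))
  if (nrow(dosage) != nrow(variants))
    stopf("dosage has %d rows but variants has %d", nrow(dosage),
          nrow(variants))
  if (length(samples) != ncol(dosage))
    stopf("length(samples) != ncol(dosage)")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stopf("dosages must be 0, 1, 2 or NA")
  need <- c("id", "gene", "class")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stopf("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  badc <- !variants$class %in% c("non-silent", "silent", "UTR")
  if (any(badc))
    stopf("unknown variant class(es): %s",
          paste(unique(variants$class[badc]), collapse = ", "))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(dosage)))
      stopf("depth and dosage dimensions differ")
  }
  dimnames(dosage) <- list(variants$id, samples)
  if (is.null(variants$maf)) variants$maf <- compute_maf(dosage)
  structure(list(dosage = dosage, variants = as.data.frame(variants),
                 samples = as.character(samples), depth = depth),
            class = "genotype_matrix")
}

#' Combined-cohort minor-allele frequency per site
#'
#' MAF is computed over non-missing genotypes of the whole cohort
#' (cases + controls), the convention used for the rare /
#' low-frequency / common stratification.
#'
#' @param dosage dosage matrix (variants x samples).
#' @return numeric vector of per-site MAF in [0, 0.5] (sites where the
#'   labelled minor allele exceeds frequency 0.5 are folded).
#' @export
compute_maf <- function(dosage) {
  n_ok <- rowSums(!is.na(dosage))
  ac <- rowSums(dosage, na.rm = TRUE)
  maf <- ifelse(n_ok > 0, ac / (2 * n_ok), 0)
  pmin(maf, 1 - maf)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d variants x %d samples (%d genes; %.1f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$gene)),
    100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over variants.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_variants <- function(gm, keep) {
  genotype_matrix(gm$dosage[keep, , drop = FALSE],
                  gm$variants[keep, , drop = FALSE],
                  gm$samples,
                  if (!is.null(gm$depth)) gm$depth[keep, , drop = FALSE])
}

## qualifying-variant mask for a class / MAF-stratum combination
qualifying_idx <- function(gm, stratum = c("rare", "rare_lowfreq"),
                           class = c("non-silent", "UTR", "silent", "any")) {
  stratum <- match.arg(stratum)
  class <- match.arg(class)
  lab <- vapply(gm$variants$maf, classify_maf, character(1))
  in_stratum <- if (stratum == "rare") lab == "rare"
                else lab %in% c("rare", "low-frequency")
  in_class <- if (class == "any") rep(TRUE, nrow(gm$variants))
              else gm$variants$class == class
  which(in_stratum & in_class & gm$variants$maf > 0)
}
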