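# VCF interchange: the calling stage writes VCF 4.2 with GT/DP/GQ, the
# association stages read it back (via VariantAnnotation) alongside the
# annotation and phenotype sidecars.

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one bi-allelic SNV record per variant with per-sample GT and
#' (when depths are available) DP fields. Missing genotypes become
#' `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text `.vcf`).
#' @param info optional data frame aligned with the variants whose
#'   columns are written as INFO `key=value` pairs (e.g. `AF`, `LRT`).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(gm, path, info = NULL) {
  v <- gm$variants
  has_dp <- !is.null(gm$depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rvburden",
    '##INFO=<ID=AF,Number=1,Type=Float,Description="EM allele frequency">',
    '##INFO=<ID=LRT,Number=1,Type=Float,Description="2x log likelihood ratio">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- gm$dosage[i, ]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    if (has_dp) gt <- paste0(gt, ":", gm$depth[i, ])
    inf <- "."
    if (!is.null(info)) {
      inf <- paste(sprintf("%s=%s", names(info),
                           vapply(info[i, , drop = FALSE], format,
                                  character(1))),
                   collapse = ";")
    }
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
            "PASS", inf, if (has_dp) "GT:DP" else "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into dosage and depth matrices
#'
#' Parses bi-allelic SNV records (via `VariantAnnotation::readVcf`);
#' multi-allelic or non-SNV records are dropped with a counted warning.
#' Missing or half-called GT fields become missing dosages.
#'
#' @param path path to a VCF file.
#' @return list: `dosage` (variants x samples, 0/1/2/NA), `depth`
#'   (same shape, or `NULL` when the VCF has no DP), `variants`
#'   (data frame `id`, `chrom`, `pos`, `ref`, `alt`), `samples`,
#'   `n_skipped`.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  n_alt <- S4Vectors::elementNROWS(alt)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(alt[n_alt == 1L]))
  snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) &
    nchar(alt1) == 1L & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d multi-allelic or non-SNV record(s)",
                    n_skipped))
  gt <- VariantAnnotation::geno(vcf)$GT[snv, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  depth <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    depth <- VariantAnnotation::geno(vcf)$DP[snv, , drop = FALSE]
    storage.mode(depth) <- "integer"
  }
  variants <- data.frame(
    id = names(rr)[snv],
    chrom = as.character(GenomicRanges::seqnames(rr))[snv],
    pos = GenomicRanges::start(rr)[snv],
    ref = ref[snv], alt = alt1[snv], stringsAsFactors = FALSE)
  list(dosage = dosage, depth = depth, variants = variants,
       samples = colnames(gt), n_skipped = n_skipped)
}

#' Read an annotation sidecar TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `class`, and
#' optionally `id`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_annotation <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("annotation file lacks column(s): %s",
          paste(miss, collapse = ", "))
  if (is.null(df$id))
    df$id <- sprintf("%s:%d_%s/%s", df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Assemble a genotype matrix from VCF + annotation + phenotypes
#'
#' @param vcf_path,anno_path,pheno_path input files.
#' @return list `gm` (a [genotype_matrix()]), `cohort` (a [cohort()]).
#' @export
load_cohort_data <- function(vcf_path, anno_path, pheno_path) {
  vc <- read_vcf(vcf_path)
  anno <- read_annotation(anno_path)
  ch <- read_phenotypes(pheno_path)
  missing_ph <- setdiff(vc$samples, ch$sample)
  if (length(missing_ph))
    stopf("samples in VCF but not in phenotype file: %s",
          paste(utils::head(missing_ph, 5), collapse = ", "))
  ch <- ch[match(vc$samples, ch$sample), ]
  class(ch) <- c("cohort", "data.frame")
  idx <- match(vc$variants$id, anno$id)
  if (anyNA(idx))
    stopf("annotation missing for %d variant(s), e.g. %s",
          sum(is.na(idx)), vc$variants$id[which(is.na(idx))[1]])
  v <- cbind(vc$variants,
             anno[idx, c("gene", "class"), drop = FALSE])
  gm <- genotype_matrix(vc$dosage, v, vc$samples, depth = vc$depth)
  list(gm = gm, cohort = ch)
}

#' Read a gene-set file
#'
#' Same layout as pathway files: `set_name TAB gene TAB gene ...`; a
#' file may hold several sets.
#'
#' @param path file path.
#' @return named list of gene vectors.
#' @export
read_gene_sets <- function(path) read_pathways(path)
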