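# End-to-end orchestration: simulate (or load) -> call -> differential
# QC -> single-marker tests -> gene-based tests -> gene-set aggregation
# -> pathway enrichment, with per-stage logs and a run manifest.

#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one validated object:
#' the likelihood-ratio site-calling cutoff (24 on 2 x log-LR), the
#' per-sample depth mask (8x), the filter/differential-QC alpha
#' (1e-5), the MAF stratum bounds (1% / 5%), the nominal-association
#' alpha (0.05), the single-marker permutation count (10,000) and the
#' adaptive-permutation controls.
#'
#' @param lrt_threshold,min_depth,filter_alpha calling-stage settings.
#' @param maf_rare,maf_lowfreq stratum bounds.
#' @param nominal_alpha gene-level nominal threshold.
#' @param permutations fixed permutation count for single-marker tests.
#' @param r_stop,B_max adaptive-permutation controls for gene tests.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lrt_threshold = 24, min_depth = 8L,
                            filter_alpha = 1e-5, maf_rare = 0.01,
                            maf_lowfreq = 0.05, nominal_alpha = 0.05,
                            permutations = 10000L, r_stop = 10L,
                            B_max = 1e5L, seed = 1L) {
  cfg <- list(lrt_threshold = check_number(lrt_threshold, "lrt_threshold",
                                           min = 0, open_min = TRUE),
              min_depth = check_count(min_depth, "min_depth", 0L),
              filter_alpha = check_number(filter_alpha, "filter_alpha",
                                          min = 0, max = 1, open_min = TRUE),
              maf_rare = check_number(maf_rare, "maf_rare", min = 0,
                                      max = 0.5, open_min = TRUE),
              maf_lowfreq = check_number(maf_lowfreq, "maf_lowfreq",
                                         min = maf_rare, max = 0.5),
              nominal_alpha = check_number(nominal_alpha, "nominal_alpha",
                                           min = 0, max = 1,
                                           open_min = TRUE),
              permutations = check_count(permutations, "permutations", 1L),
              r_stop = check_count(r_stop, "r_stop", 1L),
              B_max = check_count(B_max, "B_max", 1L),
              seed = check_count(seed, "seed"))
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#' @param cfg a [pipeline_config()].
#' @param path JSON path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored config.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis on pipeline input files
#'
#' Stages, in order: load reads (if given) and call variants, otherwise
#' load the VCF; differential QC; single-marker association for
#' MAF >= 1% variants; gene-based burden tests for rare non-silent
#' variants; nominal-gene flagging; gene-set aggregation with Fisher
#' burden tests and the loci ratio R; pathway enrichment with BH FDR.
#' Every stage appends a log record (counts in/out, seed) and the run
#' ends with a JSON manifest.
#'
#' @param vcf,anno,pheno,gene_sets,pathways input file paths (`reads`
#'   replaces `vcf` to start from the calling stage; `pathways` may be
#'   `NULL` to skip enrichment).
#' @param reads optional read-summary TSV (from
#'   [write_simulated_cohort()]).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param single_marker_B permutations for the single-marker stage
#'   (kept configurable because 10,000 per variant is slow on large
#'   simulated panels).
#' @param min_pathway_genes pathway size floor for enrichment.
#' @return invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(vcf = NULL, anno, pheno, gene_sets,
                         pathways = NULL, reads = NULL,
                         out_dir = tempfile("rvburden_run_"),
                         config = pipeline_config(),
                         single_marker_B = 1000L,
                         min_pathway_genes = 10L) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(vcf, anno, pheno, gene_sets, pathways, reads))
    if (!file.exists(p)) stopf("input file does not exist: %s", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(); stages <- character(0)
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
    stages <<- c(stages, stage)
  }

  anno_df <- read_annotation(anno)
  ch <- read_phenotypes(pheno)

  if (!is.null(reads)) {
    rd <- read_site_reads(reads)
    calls <- call_variants(rd, samples = ch$sample,
                           min_depth = config$min_depth,
                           lrt_threshold = config$lrt_threshold,
                           filter_alpha = config$filter_alpha)
    gm <- calls_to_genotype_matrix(calls, anno_df)
    note("calling", sites_in = nrow(calls$info),
         called = sum(calls$info$called), passed = sum(calls$info$pass))
    write_vcf(gm, file.path(out_dir, "called.vcf"),
              info = data.frame(
                AF = calls$info$p_hat[calls$info$pass],
                LRT = calls$info$lrt[calls$info$pass]))
  } else {
    if (is.null(vcf)) stopf("either 'vcf' or 'reads' must be given")
    dat <- load_cohort_data(vcf, anno, pheno)
    gm <- dat$gm; ch <- dat$cohort
    note("load", variants = nrow(gm$dosage), samples = ncol(gm$dosage))
  }
  ch <- ch[match(gm$samples, ch$sample), ]
  class(ch) <- c("cohort", "data.frame")

  qc <- differential_qc(gm, ch, config$filter_alpha)
  gm_qc <- subset_variants(gm, !qc$removed)
  note("differential_qc", removed = sum(qc$removed),
       retained = sum(!qc$removed))

  sm <- single_marker_scan(gm_qc, ch, B = single_marker_B,
                           qc_alpha = config$filter_alpha,
                           seed = derive_seed(config$seed, "single_marker"))
  if (nrow(sm))
    data.table::fwrite(sm, file.path(out_dir, "single_marker.tsv"),
                       sep = "\t")
  note("single_marker", tested = if (nrow(sm)) sum(!sm$qc_removed) else 0L,
       B = single_marker_B)

  gb <- gene_burden_scan(gm_qc, ch, stratum = "rare", class = "non-silent",
                         r_stop = config$r_stop, B_max = config$B_max,
                         seed = derive_seed(config$seed, "gene_burden"))
  if (nrow(gb))
    data.table::fwrite(gb, file.path(out_dir, "gene_burden.tsv"),
                       sep = "\t")
  note("gene_burden", genes_tested = nrow(gb))

  nominal <- flag_nominal(gb, config$nominal_alpha)
  note("nominal", n_nominal = length(nominal))

  sets <- read_gene_sets(gene_sets)
  set_reports <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], unique(gm_qc$variants$gene))
    if (!length(genes)) return(NULL)
    rep <- geneset_burden_report(gm_qc, genes, ch, stratum = "rare",
                                 class = "non-silent")
    data.table::fwrite(as.data.frame(rep$table),
                       file.path(out_dir, paste0("aggregate_", nm, ".tsv")),
                       sep = "\t")
    rep
  })
  names(set_reports) <- names(sets)
  note("aggregate", sets = length(set_reports))

  enr <- NULL
  if (!is.null(pathways)) {
    pw <- read_pathways(pathways)
    enr <- enrichment_report(unique(gm_qc$variants$gene), nominal, pw,
                             min_genes = min_pathway_genes)
    if (nrow(enr))
      data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t")
    note("enrichment", pathways_tested = nrow(enr))
  }

  manifest <- list(package = "rvburden",
                   version = as.character(utils::packageVersion("rvburden")),
                   seed = config$seed, stages = stages, log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(gm = gm_qc, cohort = ch, qc = qc, single_marker = sm,
                 gene_burden = gb, nominal = nominal,
                 gene_sets = set_reports, enrichment = enr,
                 manifest = manifest, out_dir = out_dir))
}
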