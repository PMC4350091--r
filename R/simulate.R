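#' Simulation configuration for a synthetic case-control cohort
#'
#' Defaults emulate the targeted-sequencing study design the package is
#' built around: 757 cases and 709 fertile controls, ~650 genes, a
#' heavily rare-skewed site-frequency spectrum (>85% of variant sites
#' with MAF < 1%, >90% with MAF < 5%), and a configurable excess of
#' rare non-silent alleles in a designated risk gene set acting through
#' a logistic carrier model.
#'
#' @param n_cases,n_controls group sizes.
#' @param genes data frame with columns `gene`, `n_sites`, and class-mix
#'   proportions `p_nonsilent`, `p_silent`, `p_utr` (summing to 1 per
#'   gene). Default: `n_genes` genes of `sites_per_gene` sites with a
#'   60/25/15 non-silent/silent/UTR mix.
#' @param n_genes,sites_per_gene used only to build the default `genes`.
#' @param risk_gene_set character vector of risk gene names (subset of
#'   `genes$gene`). Default: the first 8 genes.
#' @param carrier_odds_ratio disease odds multiplier for carrying at
#'   least one rare non-silent allele in a risk gene.
#' @param maf_shape1,maf_shape2 Beta parameters of the MAF spectrum
#'   (truncated to (0, 0.5]); the defaults (0.1, 20) give ~88% of sites
#'   below 1% and ~98% below 5% MAF.
#' @param maf_point optional point mass: if non-`NULL` every site gets
#'   this MAF (degenerate spectrum, mainly for testing).
#' @param baseline_prev baseline disease probability for non-carriers in
#'   the logistic disease model.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param base_error_rate per-read base miscall probability, in (0, 0.5).
#' @param age_range integer ages are drawn uniformly in this range.
#' @param seed master seed; every stream is derived from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_cases = 757, n_controls = 709,
                       genes = NULL, n_genes = 650, sites_per_gene = 12,
                       risk_gene_set = NULL,
                       carrier_odds_ratio = 1.9,
                       maf_shape1 = 0.1, maf_shape2 = 20,
                       maf_point = NULL,
                       baseline_prev = 0.1,
                       mean_depth = 30, base_error_rate = 0.005,
                       age_range = c(22L, 45L), seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases", min = 1L)
  n_controls <- check_count(n_controls, "n_controls", min = 1L)
  check_number(carrier_odds_ratio, "carrier_odds_ratio", min = 0,
               open_min = TRUE)
  check_number(base_error_rate, "base_error_rate", min = 0, max = 0.5,
               open_min = TRUE, open_max = TRUE)
  check_number(mean_depth, "mean_depth", min = 0, open_min = TRUE)
  check_number(baseline_prev, "baseline_prev", min = 0, max = 1,
               open_min = TRUE, open_max = TRUE)
  if (is.null(genes)) {
    n_genes <- check_count(n_genes, "n_genes", min = 1L)
    genes <- data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
                        n_sites = sites_per_gene,
                        p_nonsilent = 0.60, p_silent = 0.25, p_utr = 0.15)
  }
  need <- c("gene", "n_sites", "p_nonsilent", "p_silent", "p_utr")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stopf("gene table lacks column(s): %s", paste(miss, collapse = ", "))
  mix <- genes$p_nonsilent + genes$p_silent + genes$p_utr
  if (any(abs(mix - 1) > 1e-8))
    stopf("class-mix proportions must sum to 1 for every gene")
  if (is.null(risk_gene_set))
    risk_gene_set <- utils::head(genes$gene, 8L)
  extra <- setdiff(risk_gene_set, genes$gene)
  if (length(extra))
    stopf("risk_gene_set contains unknown gene(s): %s",
          paste(extra, collapse = ", "))
  if (!is.null(maf_point))
    check_number(maf_point, "maf_point", min = 0, max = 0.5,
                 open_min = TRUE)
  if (maf_shape1 <= 0 || maf_shape2 <= 0)
    stopf("invalid MAF spectrum parameters: shapes must be positive")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 genes = genes, risk_gene_set = as.character(risk_gene_set),
                 carrier_odds_ratio = carrier_odds_ratio,
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
                 maf_point = maf_point, baseline_prev = baseline_prev,
                 mean_depth = mean_depth,
                 base_error_rate = base_error_rate,
                 age_range = as.integer(age_range),
                 seed = check_count(seed, "seed")),
            class = "sim_config")
}

#' Draw a rare-skewed site-frequency spectrum
#'
#' Minor-allele frequencies are drawn from a Beta(`shape1`, `shape2`)
#' distribution truncated to (0, 0.5]. With the default parameters the
#' expected fraction of sites with MAF < 1% is about 0.88 and with
#' MAF < 5% about 0.98, reproducing the rare-dominated spectrum of a
#' targeted resequencing screen.
#'
#' @param n_sites number of sites.
#' @param shape1,shape2 Beta parameters.
#' @param point optional point mass in (0, 0.5]; overrides the Beta.
#' @param seed integer seed.
#' @return numeric vector of `n_sites` MAFs in (0, 0.5].
#' @export
simulate_spectrum <- function(n_sites, shape1 = 0.1, shape2 = 20,
                              point = NULL, seed = 1L) {
  n_sites <- check_count(n_sites, "n_sites")
  if (n_sites == 0L) return(numeric(0))
  if (!is.null(point)) {
    check_number(point, "point", min = 0, max = 0.5, open_min = TRUE)
    return(rep(point, n_sites))
  }
  if (shape1 <= 0 || shape2 <= 0)
    stopf("invalid MAF spectrum parameters: shapes must be positive")
  with_seed(seed, {
    # inverse-CDF sampling from the Beta truncated to (0, 0.5]
    z <- stats::pbeta(0.5, shape1, shape2)
    u <- stats::runif(n_sites, min = 1e-12, max = z)
    maf <- stats::qbeta(u, shape1, shape2)
    pmax(pmin(maf, 0.5), 1e-6)
  })
}

#' Simulate a full case-control cohort with truth tables
#'
#' Population genotypes are drawn per site under Hardy-Weinberg
#' equilibrium at the site's true MAF (sites independent; no linkage
#' disequilibrium). Disease status follows a logistic model on the
#' carrier indicator: carrying at least one rare (true MAF < 1%)
#' non-silent allele in a risk gene multiplies the disease odds by
#' `carrier_odds_ratio`. Individuals are simulated in batches and
#' case-control sampled until both group quotas are filled, so the
#' retrospective carrier odds ratio matches the prospective one.
#'
#' @param config a [sim_config()].
#' @param reads if `TRUE`, also generate per-site read evidence via
#'   [simulate_reads()] (can be slow for large cohorts).
#' @return a `simulated_cohort` list: `gm` ([genotype_matrix()] of true
#'   genotypes), `cohort` ([cohort()]), `truth` (per-site true MAF,
#'   per-gene causal flag, per-sample carrier indicator), and `reads`
#'   (a `site_read_data`, or `NULL`).
#' @export
simulate_cohort <- function(config, reads = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genes
  n_sites <- sum(g$n_sites)
  maf <- simulate_spectrum(n_sites, config$maf_shape1, config$maf_shape2,
                           config$maf_point,
                           seed = derive_seed(config$seed, "spectrum"))
  gene_of <- rep(g$gene, g$n_sites)
  class_of <- with_seed(derive_seed(config$seed, "classes"), {
    unlist(lapply(seq_len(nrow(g)), function(i) {
      sample(c("non-silent", "silent", "UTR"), g$n_sites[i], replace = TRUE,
             prob = c(g$p_nonsilent[i], g$p_silent[i], g$p_utr[i]))
    }))
  })
  variants <- data.frame(
    id = sprintf("var%05d", seq_len(n_sites)),
    chrom = "chr1",
    pos = seq_len(n_sites) * 100L,
    ref = "A", alt = "G",
    gene = gene_of, class = class_of, stringsAsFactors = FALSE)

  causal_site <- gene_of %in% config$risk_gene_set &
    class_of == "non-silent" & maf < 0.01
  logit0 <- stats::qlogis(config$baseline_prev)
  beta <- log(config$carrier_odds_ratio)

  n_cases <- config$n_cases; n_controls <- config$n_controls
  with_seed(derive_seed(config$seed, "cohort"), {
    draw_geno <- function(site_maf, n) {
      p1 <- (1 - site_maf)^2
      p12 <- p1 + 2 * site_maf * (1 - site_maf)
      u <- matrix(stats::runif(length(site_maf) * n),
                  length(site_maf), n)
      d <- (u > p1) + (u > p12)
      storage.mode(d) <- "integer"
      d
    }
    # phase 1: case-control sample carrier/disease status from the
    # causal sites only (cheap), keeping the causal genotypes of the
    # individuals taken into either group
    ci <- which(causal_site)
    dos_case <- vector("list", 0); dos_ctrl <- vector("list", 0)
    got_case <- 0L; got_ctrl <- 0L
    case_rate <- config$baseline_prev
    guard <- 0L
    while (got_case < n_cases || got_ctrl < n_controls) {
      guard <- guard + 1L
      if (guard > 10000L)
        stopf("case-control sampling failed to fill quotas")
      batch <- as.integer(min(5e5, max(
        256L, 1.5 * (n_cases - got_case) / max(case_rate, 1e-3),
        1.5 * (n_controls - got_ctrl))))
      dc <- draw_geno(maf[ci], batch)          # 0-row matrix if no ci
      carrier <- if (length(ci)) colSums(dc) > 0 else logical(batch)
      p_dis <- stats::plogis(logit0 + beta * carrier)
      is_dis <- stats::runif(batch) < p_dis
      case_rate <- max(mean(is_dis), 1e-3)
      take_case <- which(is_dis)[seq_len(min(sum(is_dis),
                                             n_cases - got_case))]
      take_ctrl <- which(!is_dis)[seq_len(min(sum(!is_dis),
                                              n_controls - got_ctrl))]
      if (length(take_case)) {
        dos_case[[length(dos_case) + 1L]] <- dc[, take_case, drop = FALSE]
        got_case <- got_case + length(take_case)
      }
      if (length(take_ctrl)) {
        dos_ctrl[[length(dos_ctrl) + 1L]] <- dc[, take_ctrl, drop = FALSE]
        got_ctrl <- got_ctrl + length(take_ctrl)
      }
    }
    causal_dos <- cbind(do.call(cbind, dos_case),
                        do.call(cbind, dos_ctrl))
    # phase 2: non-causal sites are independent of disease status, so
    # they are drawn once for the selected individuals
    n_total <- n_cases + n_controls
    dosage <- matrix(0L, n_sites, n_total)
    if (length(ci)) dosage[ci, ] <- causal_dos
    ni <- setdiff(seq_len(n_sites), ci)
    if (length(ni)) dosage[ni, ] <- draw_geno(maf[ni], n_total)
    ids <- sprintf("S%05d", seq_len(ncol(dosage)))
    colnames(dosage) <- ids
    status <- rep(c("case", "control"), c(n_cases, n_controls))
    ages <- sample(seq(config$age_range[1], config$age_range[2]),
                   ncol(dosage), replace = TRUE)
    ch <- cohort(ids, status, ages)
    carrier_true <- if (any(causal_site))
      colSums(dosage[causal_site, , drop = FALSE]) > 0
      else rep(FALSE, ncol(dosage))
    truth <- list(site_maf = maf,
                  causal_site = causal_site,
                  causal_gene = config$risk_gene_set,
                  carrier = stats::setNames(carrier_true, ids),
                  genotype = dosage)
    gm <- genotype_matrix(dosage, variants, ids)
    rd <- if (reads)
      simulate_reads(gm, config$mean_depth, config$base_error_rate,
                     seed = derive_seed(config$seed, "reads"))
      else NULL
    structure(list(gm = gm, cohort = ch, truth = truth, reads = rd,
                   config = config),
              class = "simulated_cohort")
  })
}

#' Simulate per-site read evidence from true genotypes
#'
#' For every sample x site, read depth is Poisson(`mean_depth`); each
#' read is assigned a true template allele (heterozygotes: either allele
#' with probability 1/2), miscalled with probability `base_error_rate`,
#' and placed on the forward or reverse strand with probability 1/2.
#' All base qualities equal the Phred encoding of `base_error_rate`
#' (capped at Q60), so likelihood models see a quality string consistent
#' with the true error process.
#'
#' @param gm a [genotype_matrix()] holding true genotypes (no missing).
#' @param mean_depth Poisson mean depth.
#' @param base_error_rate per-read miscall probability.
#' @param seed integer seed.
#' @param mean_mapq mean mapping quality attached to every site.
#' @return a `site_read_data`: data.table with one row per
#'   (variant, sample): counts `ref_fwd`, `ref_rev`, `alt_fwd`,
#'   `alt_rev`, scalar `qual` (Phred), `mapq`.
#' @export
simulate_reads <- function(gm, mean_depth, base_error_rate, seed = 1L,
                           mean_mapq = 45) {
  check_number(mean_depth, "mean_depth", min = 0, open_min = TRUE)
  check_number(base_error_rate, "base_error_rate", min = 0, max = 0.5,
               open_max = TRUE)
  qual <- if (base_error_rate <= 0) 60L
          else as.integer(min(60, round(-10 * log10(base_error_rate))))
  nv <- nrow(gm$dosage); ns <- ncol(gm$dosage)
  with_seed(seed, {
    d <- as.vector(gm$dosage)                 # true genotype per cell
    depth <- stats::rpois(nv * ns, mean_depth)
    # number of reads whose template is the alt allele
    p_alt_template <- c(0, 0.5, 1)[d + 1L]
    alt_t <- stats::rbinom(length(depth), depth, p_alt_template)
    ref_t <- depth - alt_t
    # sequencing error flips the observed allele (bi-allelic model)
    alt_err <- stats::rbinom(length(depth), alt_t, base_error_rate)
    ref_err <- stats::rbinom(length(depth), ref_t, base_error_rate)
    alt_obs <- alt_t - alt_err + ref_err
    ref_obs <- ref_t - ref_err + alt_err
    alt_fwd <- stats::rbinom(length(depth), alt_obs, 0.5)
    ref_fwd <- stats::rbinom(length(depth), ref_obs, 0.5)
    out <- data.table::data.table(
      variant = rep(gm$variants$id, times = ns),
      sample = rep(gm$samples, each = nv),
      ref_fwd = ref_fwd, ref_rev = ref_obs - ref_fwd,
      alt_fwd = alt_fwd, alt_rev = alt_obs - alt_fwd,
      qual = qual, mapq = mean_mapq)
    data.table::setattr(out, "class",
                        c("site_read_data", class(out)))
    out
  })
}

#' Write a simulated cohort to plain-text pipeline inputs
#'
#' Emits the interchange files the rest of the pipeline reads: a VCF
#' (GT + DP), a phenotype TSV, a variant annotation TSV, a gene-set
#' file naming the simulated risk set, a truth TSV of per-site true
#' MAFs, and (if reads were simulated) a read-summary TSV.
#'
#' @param sim a `simulated_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    pheno = file.path(dir, "phenotypes.tsv"),
    anno = file.path(dir, "annotation.tsv"),
    gene_set = file.path(dir, "risk_set.tsv"),
    truth = file.path(dir, "truth_sites.tsv"),
    reads = if (!is.null(sim$reads)) file.path(dir, "reads.tsv"))
  write_vcf(sim$gm, paths$vcf)
  write_phenotypes(sim$cohort, paths$pheno)
  data.table::fwrite(sim$gm$variants[, c("chrom", "pos", "ref", "alt",
                                         "gene", "class", "id")],
                     paths$anno, sep = "\t")
  writeLines(paste(c("risk_set", sim$truth$causal_gene), collapse = "\t"),
             paths$gene_set)
  data.table::fwrite(
    data.frame(id = sim$gm$variants$id, true_maf = sim$truth$site_maf,
               causal = sim$truth$causal_site),
    paths$truth, sep = "\t")
  if (!is.null(sim$reads))
    data.table::fwrite(sim$reads, paths$reads, sep = "\t")
  invisible(paths)
}

#' Read a read-summary TSV back into a `site_read_data`
#' @param path TSV written by [write_simulated_cohort()].
#' @return a `site_read_data` data.table.
#' @export
read_site_reads <- function(path) {
  out <- data.table::fread(path, sep = "\t",
                           colClasses = list(character =
                                               c("variant", "sample")))
  data.table::setattr(out, "class", c("site_read_data", class(out)))
  out
}
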