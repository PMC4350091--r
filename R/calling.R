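# Variant calling from per-site read evidence: genotype likelihoods,
# EM population allele frequency, likelihood-ratio site calling,
# Bayesian genotype calling, and the QC filter bank.

## Per-read error model (bi-allelic collapse): a read's template allele
## is miscalled as the other allele with probability e = 10^(-Q/10).
## Hence P(read | hom matching) = 1 - e, P(read | hom other) = e, and
## P(read | het) = 1/2 (1 - e) + 1/2 e = 1/2 exactly.

#' Genotype log-likelihood triple for one sample
#'
#' @param n_ref,n_alt read counts supporting the reference / alternate
#'   allele.
#' @param qual_ref,qual_alt Phred base qualities, either one value per
#'   read or a scalar shared by all reads of that allele.
#' @return numeric length-3 vector of log-likelihoods
#'   (hom-ref, het, hom-alt); `c(0, 0, 0)` when there are no reads.
#' @export
gl_triple <- function(n_ref, n_alt, qual_ref = 20, qual_alt = 20) {
  if (n_ref + n_alt == 0L) return(c(0, 0, 0))
  qr <- rep_len(qual_ref, n_ref)
  qa <- rep_len(qual_alt, n_alt)
  er <- 10^(-qr / 10)
  ea <- 10^(-qa / 10)
  c(sum(log1p(-er)) + sum(log(ea)),          # hom-ref
    (n_ref + n_alt) * log(0.5),              # het
    sum(log(er)) + sum(log1p(-ea)))          # hom-alt
}

#' Genotype likelihoods for every sample at one site
#'
#' @param site_reads rows of a `site_read_data` for a single variant.
#' @param samples character vector fixing the sample order; samples
#'   without read rows get depth 0 and a flat triple.
#' @return a `gl_set`: list with `gl` (samples x 3 matrix of
#'   log-likelihoods), `depth` (named integer vector).
#' @export
genotype_likelihoods <- function(site_reads, samples = NULL) {
  sr <- as.data.frame(site_reads)
  if (is.null(samples)) samples <- sr$sample
  idx <- match(samples, sr$sample)
  gl <- matrix(0, nrow = length(samples), ncol = 3,
               dimnames = list(samples, c("hom_ref", "het", "hom_alt")))
  depth <- stats::setNames(integer(length(samples)), samples)
  for (k in seq_along(samples)) {
    i <- idx[k]
    if (is.na(i)) next
    n_ref <- sr$ref_fwd[i] + sr$ref_rev[i]
    n_alt <- sr$alt_fwd[i] + sr$alt_rev[i]
    depth[k] <- n_ref + n_alt
    gl[k, ] <- gl_triple(n_ref, n_alt, sr$qual[i], sr$qual[i])
  }
  if (any(!is.finite(gl))) stopf("non-finite genotype likelihoods")
  structure(list(gl = gl, depth = depth), class = "gl_set")
}

## marginal log-likelihood of allele frequency p under HWE
af_loglik <- function(gl, p) {
  prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  m <- apply(gl, 1, max)
  sum(m + log(exp(gl - m) %*% prior))
}

#' EM estimate of the population allele frequency
#'
#' Maximizes the marginal likelihood of the alternate-allele frequency
#' under Hardy-Weinberg genotype priors by expectation-maximization
#' over the per-sample genotype likelihoods: the E-step computes
#' genotype posteriors at the current frequency, the M-step sets the
#' frequency to the posterior-mean dosage over samples with data,
#' divided by 2.
#'
#' @param gls a `gl_set` from [genotype_likelihoods()].
#' @param tol convergence tolerance on the frequency update.
#' @param max_iter iteration cap.
#' @param init starting frequency.
#' @return an `af_estimate` list: `p_hat`, `loglik` (at `p_hat`),
#'   `loglik0` (at p = 0), `iterations`, `converged`.
#' @export
estimate_af_em <- function(gls, tol = 1e-8, max_iter = 100L, init = 0.05) {
  gl <- gls$gl[gls$depth > 0, , drop = FALSE]
  if (nrow(gl) == 0L)
    return(structure(list(p_hat = 0, loglik = 0, loglik0 = 0,
                          iterations = 0L, converged = TRUE),
                     class = "af_estimate"))
  if (any(!is.finite(gl))) stopf("non-finite genotype likelihoods")
  lik <- exp(gl - apply(gl, 1, max))       # scaled likelihoods, rowwise
  p <- init
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    post <- sweep(lik, 2, prior, `*`)
    post <- post / rowSums(post)
    p_new <- mean(post %*% c(0, 1, 2)) / 2
    if (abs(p_new - p) < tol) { p <- p_new; converged <- TRUE; break }
    p <- p_new
  }
  structure(list(p_hat = p,
                 loglik = af_loglik(gl, p),
                 loglik0 = af_loglik(gl, 0),
                 iterations = it, converged = converged),
            class = "af_estimate")
}

#' Likelihood-ratio site call
#'
#' A site is called polymorphic when twice the log-likelihood ratio of
#' the fitted-frequency model against the monomorphic-reference null
#' (p = 0) exceeds the threshold (default 24, strict inequality).
#'
#' @param gls a `gl_set`.
#' @param af an `af_estimate` produced from `gls`.
#' @param threshold LRT threshold.
#' @return list `statistic` (2 x log-LR, floored at 0), `called`.
#' @export
lrt_call <- function(gls, af, threshold = 24) {
  stat <- max(0, 2 * (af$loglik - af$loglik0))
  list(statistic = stat, called = stat > threshold)
}

#' Bayesian per-sample genotype calls
#'
#' Genotype posteriors combine each sample's likelihood triple with the
#' Hardy-Weinberg prior at the EM allele-frequency estimate; the call
#' is the posterior mode. Samples with depth below `min_depth` are set
#' missing regardless of their likelihoods.
#'
#' @param gls a `gl_set`.
#' @param af an `af_estimate`.
#' @param min_depth per-sample depth cutoff (default 8: depth < 8 is
#'   masked).
#' @return list `genotype` (0/1/2/NA per sample), `posterior`
#'   (posterior probability of the called genotype), `gq` (Phred-scaled
#'   genotype quality, capped at 99).
#' @export
call_genotypes <- function(gls, af, min_depth = 8L) {
  prior <- c((1 - af$p_hat)^2, 2 * af$p_hat * (1 - af$p_hat), af$p_hat^2)
  lik <- exp(gls$gl - apply(gls$gl, 1, max))
  post <- sweep(lik, 2, prior, `*`)
  post <- post / rowSums(post)
  # ties broken toward the smaller dosage (argmax of the first maximum)
  g <- max.col(post, ties.method = "first") - 1L
  pp <- post[cbind(seq_len(nrow(post)), g + 1L)]
  miss <- gls$depth < min_depth
  g[miss] <- NA_integer_
  pp[miss] <- NA_real_
  gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1 - pp, 1e-10)))))
  gq[miss] <- NA_integer_
  list(genotype = stats::setNames(g, rownames(gls$gl)),
       posterior = pp, gq = gq)
}

## pooled major/minor read evidence for one site
pool_site <- function(site_reads) {
  sr <- as.data.frame(site_reads)
  ref <- sum(sr$ref_fwd + sr$ref_rev)
  alt <- sum(sr$alt_fwd + sr$alt_rev)
  minor_is_alt <- alt <= ref
  if (minor_is_alt) {
    list(minor_fwd = sum(sr$alt_fwd), minor_rev = sum(sr$alt_rev),
         major_fwd = sum(sr$ref_fwd), major_rev = sum(sr$ref_rev),
         minor_qual = rep(sr$qual, sr$alt_fwd + sr$alt_rev),
         major_qual = rep(sr$qual, sr$ref_fwd + sr$ref_rev))
  } else {
    list(minor_fwd = sum(sr$ref_fwd), minor_rev = sum(sr$ref_rev),
         major_fwd = sum(sr$alt_fwd), major_rev = sum(sr$alt_rev),
         minor_qual = rep(sr$qual, sr$ref_fwd + sr$ref_rev),
         major_qual = rep(sr$qual, sr$alt_fwd + sr$alt_rev))
  }
}

#' Base-quality rank-sum filter
#'
#' One-sided Wilcoxon rank-sum test comparing pooled minor-allele base
#' qualities against major-allele base qualities across all individuals
#' (alternative: minor smaller). Sites with significantly lower minor
#' qualities are flagged as likely systematic miscalls.
#'
#' @param site_reads rows of a `site_read_data` for one variant.
#' @param alpha removal threshold (remove when p < alpha).
#' @return list `p_value`, `keep`.
#' @export
filter_base_quality <- function(site_reads, alpha = 1e-5) {
  po <- pool_site(site_reads)
  if (length(po$minor_qual) == 0L) return(list(p_value = 1, keep = TRUE))
  p <- rank_sum_test(po$minor_qual, po$major_qual,
                     alternative = "less")$p_value
  list(p_value = p, keep = p >= alpha)
}

#' Strand-bias filter
#'
#' Two-sided Fisher's exact test on the pooled 2x2 table of allele
#' (major/minor) by strand (forward/reverse) across all individuals.
#'
#' @inheritParams filter_base_quality
#' @return list `p_value`, `keep`.
#' @export
filter_strand_bias <- function(site_reads, alpha = 1e-5) {
  po <- pool_site(site_reads)
  p <- fisher_2x2(po$major_fwd, po$major_rev,
                  po$minor_fwd, po$minor_rev)$p_value
  list(p_value = p, keep = p >= alpha)
}

#' Depth and mapping-quality filter
#'
#' A site is kept when its total (cohort-pooled) depth lies within
#' `n_sd` standard deviations of the cohort mean site depth, and its
#' mean mapping quality is at least `min_mapq`.
#'
#' @param site_depth total depth at the site.
#' @param depth_mean,depth_sd cohort site-depth statistics (computed
#'   over all candidate sites).
#' @param mapq mean mapping quality at the site.
#' @param n_sd width of the depth band in standard deviations.
#' @param min_mapq mapping-quality floor.
#' @return `TRUE` to keep, `FALSE` to remove.
#' @export
filter_depth_mapq <- function(site_depth, depth_mean, depth_sd, mapq,
                              n_sd = 3, min_mapq = 20) {
  lo <- max(0, depth_mean - n_sd * depth_sd)
  hi <- depth_mean + n_sd * depth_sd
  site_depth >= lo && site_depth <= hi && mapq >= min_mapq
}

#' Call variants across all sites of a read-summary table
#'
#' Runs the full calling stage: per-site genotype likelihoods, EM
#' allele-frequency estimation, likelihood-ratio site calling, the QC
#' filter bank (base-quality rank-sum, strand bias, depth/MAPQ), and
#' Bayesian genotype calling with the per-sample minimum-depth mask.
#'
#' @param reads a `site_read_data` covering one or more variants.
#' @param samples character vector fixing the sample order (defaults to
#'   the samples present in `reads`).
#' @param min_depth per-sample depth mask (genotypes at lower depth are
#'   missing).
#' @param lrt_threshold site-calling threshold on 2 x log-LR.
#' @param filter_alpha removal p-value threshold of the two test-based
#'   filters.
#' @param min_mapq,depth_n_sd depth/MAPQ filter parameters.
#' @return a `site_calls` object: `info` data frame (one row per site:
#'   `id`, `p_hat`, `em_iterations`, `lrt`, `called`, filter p-values
#'   and flags, `pass`), `dosage` and `depth` matrices
#'   (passing sites x samples), `samples`.
#' @export
call_variants <- function(reads, samples = NULL, min_depth = 8L,
                          lrt_threshold = 24, filter_alpha = 1e-5,
                          min_mapq = 20, depth_n_sd = 3) {
  rd <- data.table::as.data.table(reads)
  if (is.null(samples)) samples <- sort(unique(rd$sample))
  ids <- unique(rd$variant)
  by_site <- split(rd, factor(rd$variant, levels = ids))
  site_depth <- vapply(by_site, function(s)
    sum(s$ref_fwd + s$ref_rev + s$alt_fwd + s$alt_rev), numeric(1))
  if (length(site_depth) >= 2L) {
    dmean <- mean(site_depth); dsd <- stats::sd(site_depth)
  } else {
    warning("fewer than 2 sites: depth filter disabled")
    dmean <- mean(site_depth); dsd <- Inf
  }
  n <- length(ids)
  info <- data.frame(id = ids, p_hat = NA_real_,
                     em_iterations = NA_integer_, lrt = NA_real_,
                     called = FALSE, bq_p = NA_real_, sb_p = NA_real_,
                     bq_keep = TRUE, sb_keep = TRUE, dp_keep = TRUE,
                     pass = FALSE, stringsAsFactors = FALSE)
  dosage <- matrix(NA_integer_, n, length(samples),
                   dimnames = list(ids, samples))
  depth_m <- matrix(0L, n, length(samples), dimnames = list(ids, samples))
  for (i in seq_len(n)) {
    s <- by_site[[i]]
    gls <- genotype_likelihoods(s, samples)
    af <- estimate_af_em(gls)
    lrt <- lrt_call(gls, af, lrt_threshold)
    info$p_hat[i] <- af$p_hat
    info$em_iterations[i] <- af$iterations
    info$lrt[i] <- lrt$statistic
    info$called[i] <- lrt$called
    depth_m[i, ] <- gls$depth
    if (!lrt$called) next
    bq <- filter_base_quality(s, filter_alpha)
    sb <- filter_strand_bias(s, filter_alpha)
    dp <- filter_depth_mapq(site_depth[i], dmean, dsd, mean(s$mapq),
                            n_sd = depth_n_sd, min_mapq = min_mapq)
    info$bq_p[i] <- bq$p_value; info$bq_keep[i] <- bq$keep
    info$sb_p[i] <- sb$p_value; info$sb_keep[i] <- sb$keep
    info$dp_keep[i] <- dp
    info$pass[i] <- bq$keep && sb$keep && dp
    if (!info$pass[i]) next
    cg <- call_genotypes(gls, af, min_depth)
    dosage[i, ] <- cg$genotype
  }
  keep <- info$pass
  structure(list(info = info,
                 dosage = dosage[keep, , drop = FALSE],
                 depth = depth_m[keep, , drop = FALSE],
                 samples = samples),
            class = "site_calls")
}

#' Attach annotation to site calls, producing a genotype matrix
#'
#' @param calls a `site_calls` from [call_variants()].
#' @param anno annotation data frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `class`.
#' @return a [genotype_matrix()] over the passing sites.
#' @export
calls_to_genotype_matrix <- function(calls, anno) {
  ids <- rownames(calls$dosage)
  idx <- match(ids, anno$id)
  if (anyNA(idx))
    stopf("annotation missing for variant(s): %s",
          paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  genotype_matrix(calls$dosage, anno[idx, , drop = FALSE],
                  calls$samples, depth = calls$depth)
}
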