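# Single-marker association for common and low-frequency variants:
# differential-QC variant removal, logistic regression with age as a
# covariate, and permutation p-values.

#' Differential-QC screen between cases and controls
#'
#' Flags variants whose call rates (two-sided Fisher's exact test on
#' the missing/called x case/control table) or per-sample depths
#' (two-sided rank-sum test by group) differ between the groups at
#' `p < alpha`; such variants are removed from association testing to
#' avoid artefactual signals.
#'
#' @param gm a [genotype_matrix()] (its `depth` slot, if present, feeds
#'   the depth test).
#' @param ch a [cohort()] aligned with `gm$samples`.
#' @param alpha removal threshold.
#' @return data frame per variant: `id`, `callrate_p`, `depth_p`,
#'   `removed`.
#' @export
differential_qc <- function(gm, ch, alpha = 1e-5) {
  stopifnot(identical(gm$samples, ch$sample))
  case <- is_case(ch)
  ids <- gm$variants$id
  n <- length(ids)
  cr_p <- numeric(n); dp_p <- rep(1, n)
  for (i in seq_len(n)) {
    miss <- is.na(gm$dosage[i, ])
    cr_p[i] <- fisher_2x2(sum(!miss & case), sum(miss & case),
                          sum(!miss & !case), sum(miss & !case))$p_value
    if (!is.null(gm$depth)) {
      d <- gm$depth[i, ]
      dp_p[i] <- rank_sum_test(d[case], d[!case],
                               alternative = "two.sided",
                               exact_max_comb = 0)$p_value
    }
  }
  data.frame(id = ids, callrate_p = cr_p, depth_p = dp_p,
             removed = cr_p < alpha | dp_p < alpha,
             stringsAsFactors = FALSE)
}

#' Logistic regression score for one variant
#'
#' Fits `status ~ age + dosage` by IRLS and reports the Wald chi-square
#' on the dosage coefficient. Samples with missing dosage are dropped.
#' Monomorphic dosages and fits without a finite dosage standard error
#' (e.g. perfect separation) are returned flagged rather than raising.
#'
#' @param dosage per-sample dosage vector (0/1/2/NA).
#' @param ch a [cohort()] of matching length.
#' @return list `beta`, `statistic` (Wald z^2), `p_value` (asymptotic
#'   chi-square, 1 df), `ok` (FALSE when flagged), `n`.
#' @export
logistic_score <- function(dosage, ch) {
  keep <- !is.na(dosage)
  y <- as.integer(is_case(ch))[keep]
  x <- dosage[keep]
  age <- ch$age[keep]
  flagged <- list(beta = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, ok = FALSE, n = sum(keep))
  if (sum(keep) < 3L || stats::var(x) == 0 || length(unique(y)) < 2L)
    return(flagged)
  fit <- suppressWarnings(
    stats::glm(y ~ age + x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!"x" %in% rownames(co)) return(flagged)
  se <- co["x", "Std. Error"]
  if (!is.finite(se) || se > 50 || !fit$converged) return(flagged)
  z2 <- (co["x", "Estimate"] / se)^2
  list(beta = co["x", "Estimate"], statistic = z2,
       p_value = stats::pchisq(z2, df = 1, lower.tail = FALSE),
       ok = TRUE, n = sum(keep))
}

#' Permutation p-value for an arbitrary cohort statistic
#'
#' Phenotype labels are shuffled across samples while ages stay
#' attached to their samples, preserving the covariate structure;
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)`.
#'
#' @param statistic_fn function `(cohort) -> statistic`; larger values
#'   mean stronger case association.
#' @param ch a [cohort()].
#' @param B number of permutations.
#' @param seed integer seed.
#' @return list `p`, `observed`, `B`.
#' @export
permutation_p <- function(statistic_fn, ch, B = 10000L, seed = 1L) {
  B <- check_count(B, "B", min = 1L)
  obs <- statistic_fn(ch)
  eps <- 1e-9 * max(1, abs(obs))
  n <- nrow(ch)
  with_seed(seed, {
    r <- 0L
    for (k in seq_len(B)) {
      perm <- ch
      perm$status <- ch$status[sample.int(n)]
      s <- statistic_fn(perm)
      if (!is.na(s) && s >= obs - eps) r <- r + 1L
    }
    list(p = (r + 1) / (B + 1), observed = obs, B = B)
  })
}

#' Single-marker association scan
#'
#' Tests every variant with MAF >= 1% (low-frequency and common
#' strata; rare variants are left to the gene-based tests) by logistic
#' regression with age as a covariate, after the differential-QC
#' screen. Permutation p-values use the Wald chi-square as the
#' permuted statistic.
#'
#' @param gm a [genotype_matrix()].
#' @param ch a [cohort()] aligned with `gm$samples`.
#' @param B permutations per variant (0 skips permutation).
#' @param qc_alpha differential-QC removal threshold.
#' @param seed master seed.
#' @return data frame: `id`, `maf`, `beta`, `statistic`, `asymp_p`,
#'   `perm_p`, `n_permutations`, `qc_removed`, `flagged`.
#' @export
single_marker_scan <- function(gm, ch, B = 10000L, qc_alpha = 1e-5,
                               seed = 1L) {
  stopifnot(identical(gm$samples, ch$sample))
  qc <- differential_qc(gm, ch, qc_alpha)
  lab <- vapply(gm$variants$maf, classify_maf, character(1))
  testable <- which(lab != "rare" & !qc$removed)
  rows <- lapply(testable, function(i) {
    dosage <- gm$dosage[i, ]
    ls <- logistic_score(dosage, ch)
    perm <- if (B > 0L && ls$ok) {
      permutation_p(function(chp) logistic_score(dosage, chp)$statistic,
                    ch, B = B,
                    seed = derive_seed(seed, gm$variants$id[i]))
    } else list(p = NA_real_, B = 0L)
    data.frame(id = gm$variants$id[i], maf = gm$variants$maf[i],
               beta = ls$beta, statistic = ls$statistic,
               asymp_p = ls$p_value, perm_p = perm$p,
               n_permutations = perm$B, qc_removed = FALSE,
               flagged = !ls$ok, stringsAsFactors = FALSE)
  })
  removed <- data.frame()
  if (any(qc$removed))
    removed <- data.frame(id = qc$id[qc$removed],
                          maf = gm$variants$maf[qc$removed],
                          beta = NA_real_, statistic = NA_real_,
                          asymp_p = NA_real_, perm_p = NA_real_,
                          n_permutations = 0L, qc_removed = TRUE,
                          flagged = FALSE, stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), removed)
  if (is.null(out)) data.frame() else out
}
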