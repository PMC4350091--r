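# Gene-based rare-variant association: the BURDEN, FRQWGT, VT and UNIQ
# statistics, adaptive permutation p-values, and carrier-based Fisher
# summaries. All four tests are one-sided for excess burden in cases;
# missing genotypes count as zero minor alleles.

#' Classify a minor-allele frequency into the analysis strata
#'
#' Rare: MAF < 1%; low-frequency: 1% <= MAF < 5%; common: MAF >= 5%.
#' Both boundaries follow the inclusive-lower convention (MAF = 0.01 is
#' low-frequency, MAF = 0.05 is common).
#'
#' @param maf minor-allele frequency in [0, 0.5].
#' @return one of `"rare"`, `"low-frequency"`, `"common"`.
#' @export
classify_maf <- function(maf) {
  check_number(maf, "maf", min = 0, max = 0.5)
  if (maf < 0.01) "rare" else if (maf < 0.05) "low-frequency" else "common"
}

## dosage submatrix for a gene with missing -> 0 (variants x samples)
gene_dosage <- function(gm, gene, idx = seq_len(nrow(gm$dosage))) {
  rows <- idx[gm$variants$gene[idx] == gene]
  X <- gm$dosage[rows, , drop = FALSE]
  X[is.na(X)] <- 0L
  X
}

#' BURDEN statistic: total minor-allele count in cases
#'
#' @param X dosage matrix (qualifying variants x samples, missing
#'   encoded as 0).
#' @param case logical vector over samples.
#' @return the statistic (non-negative number).
#' @export
burden_stat <- function(X, case) {
  if (nrow(X) == 0L) stopf("no qualifying variants")
  sum(X[, case, drop = FALSE])
}

#' FRQWGT statistic: control-frequency weighted allele count in cases
#'
#' Each variant j is weighted by `1 / sqrt(n_ctrl * q_j * (1 - q_j))`
#' with the pseudocounted control frequency
#' `q_j = (minor alleles in controls + 1) / (2 n_ctrl + 2)`, so that
#' alleles absent from controls receive the largest weights. Weights
#' are recomputed from the (possibly permuted) control group, keeping
#' the statistic a fixed function of data and labels.
#'
#' @inheritParams burden_stat
#' @export
frqwgt_stat <- function(X, case) {
  if (nrow(X) == 0L) stopf("no qualifying variants")
  n_ctrl <- sum(!case)
  q <- (rowSums(X[, !case, drop = FALSE]) + 1) / (2 * n_ctrl + 2)
  w <- 1 / sqrt(n_ctrl * q * (1 - q))
  sum(w * rowSums(X[, case, drop = FALSE]))
}

#' VT statistic: maximum standardized burden over MAF thresholds
#'
#' For every observed variant MAF `t`, the per-sample burden over
#' variants with MAF <= `t` is summed in cases and standardized by its
#' exchangeable-label mean and standard deviation (sampling the case
#' set without replacement); the statistic is the maximum z over
#' thresholds, up-weighting the very rare end of the spectrum.
#'
#' @inheritParams burden_stat
#' @param maf per-variant minor-allele frequencies (fixed, label
#'   independent).
#' @export
vt_stat <- function(X, case, maf) {
  if (nrow(X) == 0L) stopf("no qualifying variants")
  n <- length(case); nc <- sum(case)
  thresholds <- sort(unique(maf))
  ord <- order(maf)
  Xo <- X[ord, , drop = FALSE]
  cum <- apply(Xo, 2, cumsum)
  if (nrow(Xo) == 1L) cum <- matrix(cum, nrow = 1L)
  # row of cum holding the burden at each threshold
  at <- findInterval(thresholds, maf[ord])
  z <- vapply(at, function(r) {
    b <- cum[r, ]
    s <- sum(b[case])
    mu <- nc * mean(b)
    v <- nc * (n - nc) / (n - 1) * mean((b - mean(b))^2)
    if (v <= 0) 0 else (s - mu) / sqrt(v)
  }, numeric(1))
  max(z)
}

#' UNIQ statistic: case minor alleles at control-free variants
#'
#' Counts the minor alleles carried by cases at variants where the
#' control group carries none.
#'
#' @inheritParams burden_stat
#' @export
uniq_stat <- function(X, case) {
  if (nrow(X) == 0L) stopf("no qualifying variants")
  ctrl_zero <- rowSums(X[, !case, drop = FALSE]) == 0
  sum(rowSums(X[, case, drop = FALSE])[ctrl_zero])
}

#' Adaptive permutation p-value
#'
#' Permutes the case/control labels in batches; after every batch, if
#' the number of permuted statistics at or above the observed one has
#' reached `r_stop`, stops early and reports `p = (r + 1) / (b + 1)`
#' over the `b` permutations performed; otherwise continues to `B_max`.
#' This resolves small p-values with many permutations while spending
#' only a handful on clearly null genes.
#'
#' @param stat_fn function `(X, case) -> statistic`.
#' @param X dosage matrix (variants x samples, missing as 0).
#' @param case logical case indicator over samples.
#' @param r_stop exceedance count triggering early stopping.
#' @param B_max permutation cap.
#' @param seed integer seed.
#' @param batch permutations per batch.
#' @return list `p` (empirical p-value), `b` (permutations used),
#'   `r` (exceedances), `observed`.
#' @export
adaptive_permutation <- function(stat_fn, X, case, r_stop = 10L,
                                 B_max = 1e5L, seed = 1L, batch = 100L) {
  r_stop <- check_count(r_stop, "r_stop", min = 1L)
  B_max <- check_count(B_max, "B_max", min = r_stop)
  obs <- stat_fn(X, case)
  eps <- 1e-9 * max(1, abs(obs))
  n <- length(case)
  with_seed(seed, {
    r <- 0L; b <- 0L
    while (b < B_max) {
      nb <- min(batch, B_max - b)
      for (k in seq_len(nb)) {
        perm <- case[sample.int(n)]
        if (stat_fn(X, perm) >= obs - eps) r <- r + 1L
      }
      b <- b + nb
      if (r >= r_stop) break
    }
    list(p = (r + 1) / (b + 1), b = b, r = r, observed = obs)
  })
}

#' Carrier-based Fisher summary from carrier counts
#'
#' @param k_case,n_case carriers and group size in cases.
#' @param k_ctrl,n_ctrl carriers and group size in controls.
#' @return list `carrier_freq_case`, `carrier_freq_ctrl` (percent),
#'   `odds_ratio` (cross-product; 0.5 continuity correction and
#'   `corrected = TRUE` when any cell is zero), `p_value` (two-sided
#'   Fisher's exact, probability-sum convention).
#' @export
carrier_fisher <- function(k_case, n_case, k_ctrl, n_ctrl) {
  f <- fisher_2x2(k_case, n_case - k_case, k_ctrl, n_ctrl - k_ctrl)
  list(carrier_freq_case = 100 * k_case / n_case,
       carrier_freq_ctrl = 100 * k_ctrl / n_ctrl,
       odds_ratio = f$odds_ratio, p_value = f$p_value,
       corrected = f$corrected)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Published tables often print carrier frequencies as rounded
#' percentages; given the group size, the underlying integer count is
#' usually unique. Errors when zero or several counts are compatible.
#'
#' @param pct printed percentage.
#' @param n group size.
#' @param digits decimal places of the printed percentage.
#' @return the unique integer count `k` with
#'   `round(100 k / n, digits) == pct`.
#' @export
reconstruct_count <- function(pct, n, digits = 1) {
  n <- check_count(n, "n", 1L)
  k <- which(round(100 * (0:n) / n, digits) == pct) - 1L
  if (length(k) != 1L)
    stopf("%d count(s) compatible with %.*f%% of %d", length(k),
          digits, pct, n)
  k
}

#' Published summary tables bundled with the package
#'
#' Plain-text copies of the summary tables of the motivating
#' azoospermia targeted-sequencing study (757 cases, 709 controls, 654
#' genes): `"geneset_counts"` (per-gene all/exclusive allele and
#' distinctive-locus counts of the epigenetic gene set, by MAF
#' stratum), `"carrier_freqs"` (printed carrier frequencies), and
#' `"pathway_table"` (pathway sizes, nominal-gene overlaps and
#' hypergeometric p-values).
#'
#' @param name table name.
#' @return data frame.
#' @export
published_table <- function(name = c("geneset_counts", "carrier_freqs",
                                     "pathway_table")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("published_", name, ".tsv"),
                      package = "rvburden", mustWork = TRUE)
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Carrier-based Fisher summary for one gene
#'
#' A carrier is a sample with at least one qualifying minor allele in
#' the gene.
#'
#' @param X qualifying dosage matrix for the gene (missing as 0).
#' @param case logical case indicator.
#' @return as [carrier_fisher()], plus carrier counts.
#' @export
gene_carrier_fisher <- function(X, case) {
  carrier <- colSums(X) > 0
  out <- carrier_fisher(sum(carrier & case), sum(case),
                        sum(carrier & !case), sum(!case))
  out$k_case <- sum(carrier & case)
  out$k_ctrl <- sum(carrier & !case)
  out
}

#' Gene-based association scan
#'
#' Runs the four burden tests with adaptive permutation, plus the
#' carrier Fisher summary, for every gene with at least one qualifying
#' variant in the requested class and MAF stratum.
#'
#' @param gm a [genotype_matrix()].
#' @param ch a [cohort()] aligned with `gm$samples`.
#' @param stratum `"rare"` (MAF < 1%) or `"rare_lowfreq"` (MAF < 5%).
#' @param class functional class of qualifying variants.
#' @param tests which statistics to run.
#' @param r_stop,B_max,batch adaptive-permutation controls.
#' @param seed master seed (per-gene streams are derived from it).
#' @return data frame with one row per tested gene: empirical p per
#'   test, permutations used, carrier frequencies (%), OR, Fisher p.
#' @export
gene_burden_scan <- function(gm, ch, stratum = "rare",
                             class = "non-silent",
                             tests = c("BURDEN", "FRQWGT", "VT", "UNIQ"),
                             r_stop = 10L, B_max = 1e4L, batch = 100L,
                             seed = 1L) {
  stopifnot(identical(gm$samples, ch$sample))
  case <- is_case(ch)
  idx <- qualifying_idx(gm, stratum, class)
  genes <- unique(gm$variants$gene[idx])
  rows <- lapply(genes, function(g) {
    rid <- idx[gm$variants$gene[idx] == g]
    X <- gm$dosage[rid, , drop = FALSE]
    X[is.na(X)] <- 0L
    if (sum(X) == 0) return(NULL)       # monomorphic after masking
    maf <- gm$variants$maf[rid]
    fns <- list(
      BURDEN = burden_stat,
      FRQWGT = frqwgt_stat,
      VT = function(X, case) vt_stat(X, case, maf),
      UNIQ = uniq_stat)[tests]
    ps <- lapply(names(fns), function(nm)
      adaptive_permutation(fns[[nm]], X, case, r_stop, B_max,
                           seed = derive_seed(seed, paste0(g, ":", nm)),
                           batch = batch))
    names(ps) <- names(fns)
    cf <- gene_carrier_fisher(X, case)
    out <- data.frame(gene = g, n_variants = nrow(X),
                      stratum = stratum, class = class,
                      stringsAsFactors = FALSE)
    for (nm in names(ps)) {
      out[[paste0("p_", nm)]] <- ps[[nm]]$p
      out[[paste0("b_", nm)]] <- ps[[nm]]$b
    }
    out$carrier_freq_case <- cf$carrier_freq_case
    out$carrier_freq_ctrl <- cf$carrier_freq_ctrl
    out$odds_ratio <- cf$odds_ratio
    out$fisher_p <- cf$p_value
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    message("no gene with qualifying variants")
    return(data.frame())
  }
  do.call(rbind, rows)
}
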