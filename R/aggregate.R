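# Gene-set burden aggregation: per-gene and total counts of all /
# group-exclusive variant alleles and distinctive loci, Fisher exact
# burden tests on allele and carrier counts, and the normalized
# distinctive-loci ratio R.

#' Build an aggregate burden table over a gene set
#'
#' For every gene of the set (restricted to qualifying variants in the
#' requested MAF stratum and functional class), tabulates per group:
#' the total minor-allele count over all qualifying variants; the
#' allele count restricted to group-exclusive variants (loci where the
#' other group carries zero minor alleles); and the number of
#' distinctive loci (variant sites at which the group carries at least
#' one minor allele). A totals row sums the gene rows.
#'
#' @param gm a [genotype_matrix()].
#' @param gene_set character vector of gene names (must all be present
#'   in `gm`).
#' @param ch a [cohort()] aligned with `gm$samples`.
#' @param stratum `"rare"` or `"rare_lowfreq"`.
#' @param class functional class of qualifying variants.
#' @return an `aggregate_table`: data frame of gene rows plus a
#'   `"Total"` row with columns `all_case`, `all_ctrl`, `excl_case`,
#'   `excl_ctrl`, `loci_case`, `loci_ctrl`; attributes `n_cases`,
#'   `n_controls`, `alleles_case` (2 x cases), `alleles_ctrl`.
#' @export
aggregate_counts <- function(gm, gene_set, ch, stratum = "rare",
                             class = "non-silent") {
  stopifnot(identical(gm$samples, ch$sample))
  if (!length(gene_set)) stopf("gene_set is empty")
  unknown <- setdiff(gene_set, unique(gm$variants$gene))
  if (length(unknown))
    stopf("unknown gene(s) in gene set: %s",
          paste(unknown, collapse = ", "))
  case <- is_case(ch)
  idx <- qualifying_idx(gm, stratum, class)
  per_gene <- lapply(gene_set, function(g) {
    rid <- idx[gm$variants$gene[idx] == g]
    X <- gm$dosage[rid, , drop = FALSE]
    X[is.na(X)] <- 0L
    ac_case <- rowSums(X[, case, drop = FALSE])
    ac_ctrl <- rowSums(X[, !case, drop = FALSE])
    data.frame(gene = g,
               all_case = sum(ac_case), all_ctrl = sum(ac_ctrl),
               excl_case = sum(ac_case[ac_ctrl == 0]),
               excl_ctrl = sum(ac_ctrl[ac_case == 0]),
               loci_case = sum(ac_case > 0), loci_ctrl = sum(ac_ctrl > 0),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_gene)
  tot <- data.frame(gene = "Total", t(colSums(tab[, -1])))
  tab <- rbind(tab, tot)
  structure(tab, class = c("aggregate_table", "data.frame"),
            n_cases = sum(case), n_controls = sum(!case),
            alleles_case = 2L * sum(case),
            alleles_ctrl = 2L * sum(!case))
}

#' Construct an aggregate table from printed counts
#'
#' For re-analysis of published per-gene tallies when genotype-level
#' data are unavailable: supply the per-gene counts directly.
#'
#' @param genes character vector of gene names.
#' @param all_case,all_ctrl,excl_case,excl_ctrl,loci_case,loci_ctrl
#'   integer vectors aligned with `genes`.
#' @param n_cases,n_controls group sizes.
#' @return an `aggregate_table` (totals recomputed from the rows).
#' @export
aggregate_table <- function(genes, all_case, all_ctrl, excl_case,
                            excl_ctrl, loci_case, loci_ctrl,
                            n_cases, n_controls) {
  tab <- data.frame(gene = genes, all_case = all_case,
                    all_ctrl = all_ctrl, excl_case = excl_case,
                    excl_ctrl = excl_ctrl, loci_case = loci_case,
                    loci_ctrl = loci_ctrl, stringsAsFactors = FALSE)
  if (any(tab$excl_case > tab$all_case) || any(tab$excl_ctrl > tab$all_ctrl))
    stopf("exclusive counts cannot exceed all-variant counts")
  tot <- data.frame(gene = "Total", t(colSums(tab[, -1])))
  structure(rbind(tab, tot),
            class = c("aggregate_table", "data.frame"),
            n_cases = check_count(n_cases, "n_cases", 1L),
            n_controls = check_count(n_controls, "n_controls", 1L),
            alleles_case = 2L * n_cases, alleles_ctrl = 2L * n_controls)
}

total_row <- function(tab) tab[tab$gene == "Total", , drop = FALSE]

#' Fisher exact test on aggregate allele burden
#'
#' Compares the total qualifying minor-allele count between groups
#' against the total chromosome counts (2N per group): the 2x2 table is
#' (count, 2N - count) per group. `which = "exclusive"` restricts to
#' group-exclusive variants.
#'
#' @param tab an `aggregate_table`.
#' @param which `"all"` or `"exclusive"`.
#' @return list `odds_ratio` (cross-product), `p_value` (two-sided
#'   Fisher), `table` (the 2x2), `corrected`.
#' @export
fisher_allele_burden <- function(tab, which = c("all", "exclusive")) {
  which <- match.arg(which)
  stopifnot(inherits(tab, "aggregate_table"))
  tot <- total_row(tab)
  a <- if (which == "all") tot$all_case else tot$excl_case
  c_ <- if (which == "all") tot$all_ctrl else tot$excl_ctrl
  na <- attr(tab, "alleles_case"); nc <- attr(tab, "alleles_ctrl")
  if (na <= 0 || nc <= 0) stopf("allele totals must be positive")
  f <- fisher_2x2(a, na - a, c_, nc - c_)
  list(odds_ratio = f$odds_ratio, p_value = f$p_value,
       table = matrix(c(a, na - a, c_, nc - c_), 2, byrow = TRUE),
       corrected = f$corrected)
}

#' Carrier burden of a gene set
#'
#' A carrier holds at least one qualifying minor allele in any gene of
#' the set; carrier counts are compared between groups by a two-sided
#' Fisher's exact test.
#'
#' @inheritParams aggregate_counts
#' @return as [carrier_fisher()], plus carrier counts.
#' @export
carrier_burden <- function(gm, gene_set, ch, stratum = "rare",
                           class = "non-silent") {
  stopifnot(identical(gm$samples, ch$sample))
  case <- is_case(ch)
  idx <- qualifying_idx(gm, stratum, class)
  rid <- idx[gm$variants$gene[idx] %in% gene_set]
  X <- gm$dosage[rid, , drop = FALSE]
  X[is.na(X)] <- 0L
  carrier <- colSums(X) > 0
  out <- carrier_fisher(sum(carrier & case), sum(case),
                        sum(carrier & !case), sum(!case))
  out$k_case <- sum(carrier & case); out$k_ctrl <- sum(carrier & !case)
  out
}

#' Normalized distinctive-loci ratio R
#'
#' `R = (case loci / n_cases) / (control loci / n_controls)`: the
#' per-capita number of distinct variant sites carried by cases
#' relative to controls.
#'
#' @param tab an `aggregate_table`.
#' @return the ratio (NA with a warning when the control count is 0).
#' @export
normalized_loci_ratio <- function(tab) {
  stopifnot(inherits(tab, "aggregate_table"))
  tot <- total_row(tab)
  if (tot$loci_ctrl == 0) {
    warning("control loci count is zero: R undefined")
    return(NA_real_)
  }
  (tot$loci_case / attr(tab, "n_cases")) /
    (tot$loci_ctrl / attr(tab, "n_controls"))
}

#' Full gene-set burden report
#'
#' Combines the aggregate table with the three Fisher tests (all
#' alleles, exclusive alleles, carriers) and the loci ratio R.
#'
#' @inheritParams aggregate_counts
#' @return list `table`, `all` and `exclusive` (Fisher results),
#'   `carrier`, `R`.
#' @export
geneset_burden_report <- function(gm, gene_set, ch, stratum = "rare",
                                  class = "non-silent") {
  tab <- aggregate_counts(gm, gene_set, ch, stratum, class)
  list(table = tab,
       all = fisher_allele_burden(tab, "all"),
       exclusive = fisher_allele_burden(tab, "exclusive"),
       carrier = carrier_burden(gm, gene_set, ch, stratum, class),
       R = normalized_loci_ratio(tab))
}
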