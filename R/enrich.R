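# Pathway enrichment of nominally associated genes: hypergeometric
# over-representation tests and Benjamini-Hochberg FDR.

#' Flag nominally associated genes
#'
#' A gene is nominal when the minimum of its empirical p-values across
#' the association tests is strictly below `alpha`.
#'
#' @param gene_results data frame with a `gene` column and one or more
#'   `p_*` columns of empirical p-values (as produced by
#'   [gene_burden_scan()]).
#' @param alpha nominal threshold (strict `<`).
#' @return character vector of flagged gene names.
#' @export
flag_nominal <- function(gene_results, alpha = 0.05) {
  if (!nrow(gene_results)) return(character(0))
  pcols <- grep("^p_", names(gene_results), value = TRUE)
  if (!length(pcols)) stopf("no p_* columns in gene_results")
  pm <- as.matrix(gene_results[, pcols, drop = FALSE])
  minp <- apply(pm, 1, min, na.rm = TRUE)
  unique(gene_results$gene[minp < alpha])
}

#' Hypergeometric enrichment p-value for one pathway
#'
#' Upper-tail probability `P(X >= k)` of the overlap between the
#' nominal gene set and the pathway, for X hypergeometric with
#' population `n_universe`, `n_nominal` successes and `n_pathway`
#' draws.
#'
#' @param n_universe number of genes tested (the universe).
#' @param n_nominal number of nominal genes in the universe.
#' @param n_pathway number of universe genes in the pathway.
#' @param k observed overlap (nominal genes in the pathway).
#' @return the enrichment p-value.
#' @export
hypergeom_enrichment <- function(n_universe, n_nominal, n_pathway, k) {
  n_universe <- check_count(n_universe, "n_universe", 1L)
  n_nominal <- check_count(n_nominal, "n_nominal")
  n_pathway <- check_count(n_pathway, "n_pathway")
  k <- check_count(k, "k")
  if (n_nominal > n_universe || n_pathway > n_universe || k > n_pathway)
    stopf("inconsistent hypergeometric margins")
  if (n_pathway == 0L) return(1)
  stats::phyper(k - 1, n_nominal, n_universe - n_nominal, n_pathway,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_(j) * m / j`, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

#' Pathway enrichment report
#'
#' Tests every pathway with strictly more than `min_genes` sequenced
#' member genes for over-representation of the nominal set, and adjusts
#' the analyzed rows by Benjamini-Hochberg.
#'
#' @param universe character vector of all genes tested.
#' @param nominal character vector of nominally associated genes
#'   (subset of `universe`).
#' @param pathways named list of character vectors (pathway -> member
#'   genes; members outside the universe are ignored).
#' @param min_genes pathways must have more than this many sequenced
#'   genes to be analyzed.
#' @return data frame sorted by p: `pathway`, `n_sequenced`,
#'   `n_nominal`, `p_value`, `fdr`.
#' @export
enrichment_report <- function(universe, nominal, pathways,
                              min_genes = 10L) {
  universe <- unique(as.character(universe))
  nominal <- intersect(unique(as.character(nominal)), universe)
  rows <- lapply(names(pathways), function(nm) {
    members <- intersect(unique(pathways[[nm]]), universe)
    if (length(members) <= min_genes) return(NULL)
    k <- length(intersect(members, nominal))
    data.frame(pathway = nm, n_sequenced = length(members),
               n_nominal = k,
               p_value = hypergeom_enrichment(length(universe),
                                              length(nominal),
                                              length(members), k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pathway = character(0), n_sequenced = integer(0),
                      n_nominal = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Read a pathway definition file
#'
#' One pathway per line: `name TAB gene TAB gene ...`.
#'
#' @param path file path.
#' @return named list of gene vectors.
#' @export
read_pathways <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1L) next
    out[[parts[1]]] <- parts[-1]
  }
  out
}
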