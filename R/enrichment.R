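#' Hypergeometric over-representation test for gene sets
#'
#' For each gene set (pathway or GO term), the p-value is the upper-tail
#' hypergeometric probability of drawing at least the observed overlap when
#' `length(query)` genes are sampled without replacement from the universe.
#' Term sizes are counted within the universe; terms smaller than
#' `min_term_size` are removed before testing. P-values are adjusted across
#' the surviving terms with Benjamini-Hochberg.
#'
#' @param query character vector of genes of interest. Genes outside the
#'   universe are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param universe background gene set; defaults to all genes appearing in
#'   the collection.
#' @param min_term_size smallest in-universe term size tested (default 10).
#' @param fdr_cutoff adjusted-p threshold for the `significant` flag
#'   (default 0.05).
#' @return data.frame sorted by adjusted p, then p, then term name: `term`,
#'   `overlap`, `term_size`, `query_size`, `universe_size`, `p`, `padj`,
#'   `significant`, and a `genes` list-column of overlap genes.
#' @export
enrich <- function(query, collection, universe = NULL, min_term_size = 10,
                   fdr_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(.norm_gene(query))
  if (!length(query)) stop("empty query", call. = FALSE)
  universe <- if (is.null(universe)) {
    unique(unlist(collection$sets, use.names = FALSE))
  } else {
    unique(.norm_gene(universe))
  }
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("no query genes left in the universe", call. = FALSE)

  sets_u <- lapply(collection$sets, intersect, universe)
  K <- lengths(sets_u)
  keep <- K >= min_term_size
  sets_u <- sets_u[keep]
  K <- K[keep]
  empty <- data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      padj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(sets_u)) {
    empty$genes <- I(list())
    return(empty)
  }

  N <- length(universe)
  n <- length(query)
  overlap_genes <- lapply(sets_u, intersect, query)
  k <- lengths(overlap_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")

  res <- data.frame(term = names(sets_u), overlap = as.integer(k),
                    term_size = as.integer(K), query_size = n,
                    universe_size = N, p = p, padj = padj,
                    significant = padj <= fdr_cutoff,
                    stringsAsFactors = FALSE)
  res$genes <- I(unname(overlap_genes))
  res <- res[order(res$padj, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top enriched terms, keeping ties at the cut
#'
#' Returns the first `n` terms under the enrichment sort order (adjusted p,
#' then p). Terms tied with the n-th term on both keys are retained as well,
#' so the list may exceed `n` (reported with a message).
#'
#' @param res an [enrich()] result table.
#' @param n number of terms requested.
#' @export
top_terms <- function(res, n) {
  if (nrow(res) <= n) return(res)
  tied <- res$padj == res$padj[n] & res$p == res$p[n]
  last <- max(which(tied))
  if (last > n) message("tie at position ", n, ": returning ", last, " terms")
  res[seq_len(max(n, last)), , drop = FALSE]
}

#' Simple two-group differential-expression summary
#'
#' Per-gene log2 fold change (mean case minus mean control on log2-scale
#' values) with a Welch t-test and Benjamini-Hochberg FDR. A gene with zero
#' variance in both groups gets p = 1 (counted in a message). The
#' significance flag follows the conventional |logFC| > 1 and FDR < 0.05
#' cutoffs. This is a transparent summary for synthetic or pre-normalized
#' data; precomputed moderated-statistics tables can be supplied instead via
#' [read_de_table()].
#'
#' @param expr genes-by-samples numeric matrix (log2 scale).
#' @param groups character vector (or named vector matching `colnames(expr)`)
#'   of group labels.
#' @param case,control the two group labels (defaults `"case"`, `"control"`).
#' @return data.frame `gene`, `logfc`, `p`, `fdr`, `significant`, with
#'   attribute `provenance = "computed"`.
#' @export
simple_de <- function(expr, groups, case = "case", control = "control") {
  if (!is.null(names(groups)) && !is.null(colnames(expr))) {
    groups <- groups[colnames(expr)]
  }
  i1 <- which(groups == case)
  i0 <- which(groups == control)
  if (length(i1) < 2 || length(i0) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  x1 <- expr[, i1, drop = FALSE]
  x0 <- expr[, i0, drop = FALSE]
  n1 <- length(i1)
  n0 <- length(i0)
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  lfc <- m1 - m0
  p <- rep(1, nrow(expr))
  ok <- se2 > 0
  if (any(!ok)) message(sum(!ok), " zero-variance gene(s): p set to 1")
  tt <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v0[ok] / n0)^2 / (n0 - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), logfc = unname(lfc),
                    p = p, fdr = fdr,
                    significant = abs(lfc) > 1 & fdr < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "provenance") <- "computed"
  out
}
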