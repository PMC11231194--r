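#' Interaction-intensity flow on pathogenic genes
#'
#' Propagates the optimization scores onto the pathogenic gene set. For a
#' pathogenic gene k:
#' * if k is itself a retained target (an ECP of the optimized network), its
#'   intensity is its own score S'_MOO(k);
#' * otherwise its intensity is the arithmetic mean of the scores of the
#'   retained target genes it shares a PPI edge with;
#' * a pathogenic gene with no retained-target interactions has intensity 0.
#'
#' @param opt an `optimized_ctp` (scores attached).
#' @return data.frame `gene`, `intensity`, `n_targets` (number of
#'   contributing target genes; 1 for retained-target pathogenic genes).
#' @export
gene_intensity <- function(opt) {
  stopifnot(inherits(opt, "optimized_ctp"))
  if (is.null(opt$scores) || anyNA(opt$scores$s_moo)) {
    stop("optimized network lacks s_moo scores", call. = FALSE)
  }
  s <- setNames(opt$scores$s_moo, opt$scores$gene)
  pathogenic <- opt$proteins$gene[opt$proteins$is_pathogenic]
  nb <- .neighbors(opt$pp_edges)
  res <- vapply(pathogenic, function(k) {
    if (!is.na(s[k])) return(c(s[[k]], 1))
    tk <- intersect(nb[[k]] %||% character(0), names(s))
    if (!length(tk)) c(0, 0) else c(mean(s[tk]), length(tk))
  }, numeric(2))
  data.frame(gene = pathogenic,
             intensity = unname(res[1, ]),
             n_targets = as.integer(res[2, ]),
             stringsAsFactors = FALSE)
}

#' Interaction intensity of compounds on pathogenic genes
#'
#' For compound i, its correlated pathogenic set C_i holds the pathogenic
#' genes that are direct (retained) targets of i, plus the pathogenic genes
#' sharing a PPI edge with at least one retained target of i. The compound's
#' intensity is the sum of the gene intensities over C_i.
#'
#' @param opt an `optimized_ctp`.
#' @param gi gene intensity table from [gene_intensity()].
#' @return data.frame of class `compound_intensity`: `compound`, `intensity`,
#'   `n_genes`, and a `genes` list-column (C_i). The per-gene intensities are
#'   carried in attribute `gene_intensity` for downstream union sums.
#' @export
compound_intensity <- function(opt, gi) {
  stopifnot(inherits(opt, "optimized_ctp"))
  iv <- setNames(gi$intensity, gi$gene)
  pathogenic <- gi$gene
  nb <- .neighbors(opt$pp_edges)
  targets_of <- split(opt$ct_edges$target, opt$ct_edges$compound)
  n_empty <- 0L
  cover <- lapply(opt$compounds, function(i) {
    ti <- unique(targets_of[[i]] %||% character(0))
    if (!length(ti)) {
      n_empty <<- n_empty + 1L
      return(character(0))
    }
    direct <- intersect(ti, pathogenic)
    hop <- intersect(unique(unlist(nb[ti], use.names = FALSE)), pathogenic)
    sort(union(direct, hop))
  })
  if (n_empty) message(n_empty, " compound(s) with no retained targets (intensity 0)")
  out <- data.frame(compound = opt$compounds,
                    intensity = vapply(cover, function(g) sum(iv[g]), 0),
                    n_genes = lengths(cover),
                    stringsAsFactors = FALSE)
  out$genes <- I(cover)
  attr(out, "gene_intensity") <- iv
  class(out) <- c("compound_intensity", "data.frame")
  out
}

# Union intensity of a compound subset: each covered gene counted once.
.union_value <- function(members, cover, iv) {
  sum(iv[unique(unlist(cover[members], use.names = FALSE))])
}

#' Select the minimal compound combination reaching a coverage threshold
#'
#' The intensity of a combination is the sum of gene intensities over the
#' union of its members' pathogenic sets (no double counting). For each size
#' m = 1, 2, ... the optimal combination is the one with the strongest union
#' intensity; the selection is the smallest m whose optimal combination
#' reaches `threshold` times the total intensity of all compounds together.
#'
#' The `exact` solver enumerates all combinations per size (guarded by
#' `exact_limit`); the default `greedy` solver adds, at each step, the
#' compound with maximal marginal union gain (ties broken by gain, then
#' compound intensity descending, then compound id ascending) -- the standard
#' maximum-coverage approximation, oracle-tested against the exact solver on
#' small instances.
#'
#' @param ci a [compound_intensity()] table.
#' @param threshold coverage fraction in (0, 1], default 0.9.
#' @param solver `"greedy"` or `"exact"`.
#' @param exact_limit largest compound count accepted by the exact solver.
#' @param gi optional gene intensity table (defaults to the intensities
#'   carried by `ci`).
#' @return object of class `combination_result`: `solver`, `threshold`,
#'   `total_intensity`, `per_size` (per-size optimum: `m`, `intensity`,
#'   `members`), and the selected `members`, `size`, `intensity`.
#' @export
select_combination <- function(ci, threshold = 0.9,
                               solver = c("greedy", "exact"),
                               exact_limit = 15, gi = NULL) {
  solver <- match.arg(solver)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  iv <- if (!is.null(gi)) setNames(gi$intensity, gi$gene) else {
    attr(ci, "gene_intensity")
  }
  if (is.null(iv)) stop("gene intensities unavailable; pass gi", call. = FALSE)
  ids <- sort(ci$compound)
  cover <- setNames(ci$genes, ci$compound)[ids]
  comp_int <- setNames(ci$intensity, ci$compound)[ids]
  total <- .union_value(ids, cover, iv)
  if (total <= 0) {
    stop("total interaction intensity is zero; nothing to select",
         call. = FALSE)
  }
  goal <- threshold * total
  eps <- 1e-12 * max(1, total)

  per_size <- list()
  if (solver == "exact") {
    if (length(ids) > exact_limit) {
      stop("exact solver limited to ", exact_limit,
           " compounds; use solver = 'greedy'", call. = FALSE)
    }
    for (m in seq_along(ids)) {
      combs <- utils::combn(ids, m, simplify = FALSE)
      vals <- vapply(combs, .union_value, 0, cover = cover, iv = iv)
      best <- which.max(vals)  # combn is lexicographic: first max = smallest ids
      per_size[[m]] <- list(members = combs[[best]], intensity = vals[[best]])
      if (vals[[best]] >= goal - eps) break
    }
  } else {
    remaining <- ids
    chosen <- character(0)
    covered <- character(0)
    cum <- 0
    while (cum < goal - eps && length(remaining)) {
      gains <- vapply(remaining, function(i) {
        sum(iv[setdiff(cover[[i]], covered)])
      }, 0)
      pick <- remaining[order(-gains, -comp_int[remaining], remaining)][1]
      chosen <- c(chosen, pick)
      covered <- union(covered, cover[[pick]])
      cum <- sum(iv[covered])
      remaining <- setdiff(remaining, pick)
      per_size[[length(chosen)]] <- list(members = chosen, intensity = cum)
    }
  }

  last <- per_size[[length(per_size)]]
  if (last$intensity < goal - eps) {
    stop("internal error: threshold not reachable", call. = FALSE)  # impossible: total is the full union
  }
  per_size_df <- data.frame(
    m = seq_along(per_size),
    intensity = vapply(per_size, `[[`, 0, "intensity"),
    members = vapply(per_size, function(x) paste(x$members, collapse = "+"), ""),
    stringsAsFactors = FALSE)
  structure(list(solver = solver, threshold = threshold,
                 total_intensity = total, per_size = per_size_df,
                 members = last$members, size = length(last$members),
                 intensity = last$intensity),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat("Minimal combination (", x$solver, " solver): ",
      paste(x$members, collapse = ", "), "\n",
      "  size ", x$size, ", intensity ", signif(x$intensity, 6),
      " of total ", signif(x$total_intensity, 6),
      " (threshold ", x$threshold * 100, "%)\n", sep = "")
  invisible(x)
}

#' Cumulative interaction-intensity flow on pathways
#'
#' Each pathway scores the sum, over its pathogenic member genes, of the gene
#' intensity divided by the gene's pathway multiplicity (the number of
#' pathways in the collection containing it), so a gene's total contribution
#' across pathways equals its own intensity. Pathways are ranked by
#' descending intensity; larger values mark the primary pathways affected.
#'
#' @param gi gene intensity table from [gene_intensity()].
#' @param genesets a [gene_set_collection()].
#' @param top_n optionally truncate the report to the strongest `top_n`
#'   pathways (the ranking is computed over all of them first).
#' @return data.frame `pathway`, `intensity`, `n_pathogenic`, `rank`, sorted
#'   by descending intensity (ties by name).
#' @export
pathway_intensity <- function(gi, genesets, top_n = NULL) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  counts <- gene_set_counts(genesets)
  iv <- setNames(gi$intensity, gi$gene)
  rows <- lapply(names(genesets$sets), function(p) {
    g <- intersect(genesets$sets[[p]], names(iv))
    data.frame(pathway = p,
               intensity = if (length(g)) sum(iv[g] / counts[g]) else 0,
               n_pathogenic = length(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$intensity, out$pathway), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  out
}
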