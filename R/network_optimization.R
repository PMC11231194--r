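# Min-max normalization to [0, 1]. A constant vector is degenerate (0/0) and
# maps to all zeros, with a message so the condition is visible in logs.
.minmax <- function(x, label = "objective") {
  rng <- range(x)
  if (!is.finite(rng[1]) || !is.finite(rng[2])) {
    stop("non-finite values in ", label, call. = FALSE)
  }
  if (rng[2] == rng[1]) {
    message("degenerate min-max for ", label, ": all values equal, set to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-target-gene optimization objectives
#'
#' Computes, for every target gene in the network, the three criteria the
#' multi-objective model scalarizes: association with compounds, association
#' with pathogenic genes, and dysregulation in disease.
#'
#' * `o_compound`: sum of incident compound-target prediction scores when all
#'   edges carry scores, otherwise the incident edge count; min-max
#'   normalized over the target set.
#' * `o_pathogenic`: number of pathogenic PPI neighbors, plus 1 when the gene
#'   is itself an ECP; min-max normalized.
#' * `o_dysreg`: |log2 fold change| from the DE table, min-max normalized
#'   over the targets present in the table; targets absent from the table
#'   (or when `de` is NULL) score 0.
#'
#' @param net a `ctp_network`.
#' @param de optional DE table (`gene`, `logfc`, `fdr`).
#' @return data.frame `gene`, `o_compound`, `o_pathogenic`, `o_dysreg`, each
#'   objective in \[0, 1\].
#' @export
compute_objectives <- function(net, de = NULL) {
  stopifnot(inherits(net, "ctp_network"))
  targets <- net$proteins$gene[net$proteins$is_target]
  if (!length(targets)) stop("network has no target genes", call. = FALSE)

  ct <- net$ct_edges
  use_scores <- nrow(ct) > 0 && all(!is.na(ct$score))
  raw_compound <- if (use_scores) {
    v <- tapply(ct$score, ct$target, sum)
    as.numeric(v[targets])
  } else {
    as.numeric(table(factor(ct$target, levels = targets)))
  }
  raw_compound[is.na(raw_compound)] <- 0

  pathogenic <- net$proteins$gene[net$proteins$is_pathogenic]
  nb <- .neighbors(net$pp_edges)
  raw_path <- vapply(targets, function(g) {
    length(intersect(nb[[g]] %||% character(0), pathogenic))
  }, 0L)
  raw_path <- raw_path + as.integer(targets %in% pathogenic)

  o_dysreg <- rep(0, length(targets))
  if (!is.null(de)) {
    lfc <- abs(de$logfc[match(targets, de$gene)])
    present <- !is.na(lfc)
    if (any(present)) o_dysreg[present] <- .minmax(lfc[present], "o_dysreg")
  }

  data.frame(gene = targets,
             o_compound = .minmax(raw_compound, "o_compound"),
             o_pathogenic = .minmax(raw_path, "o_pathogenic"),
             o_dysreg = o_dysreg,
             stringsAsFactors = FALSE)
}

# Shared retention rule: keep target genes scoring at or above the
# (1 - keep_quantile) quantile of s (ties retained), all compounds and all
# pathogenic genes; compound-target edges to retained targets; PPI edges with
# both endpoints still present and at least one retained-target or ECP
# endpoint.
.prune_network <- function(net, s, keep_quantile, model) {
  if (!(keep_quantile > 0 && keep_quantile <= 1)) {
    stop("keep_quantile must be in (0, 1]", call. = FALSE)
  }
  cut <- stats::quantile(s, 1 - keep_quantile, names = FALSE, type = 7)
  retained <- names(s)[s >= cut]
  if (!length(retained)) {
    stop("retention emptied the target set; increase keep_quantile",
         call. = FALSE)
  }
  ecp <- ecp_genes(net)
  prot <- net$proteins
  prot <- prot[prot$is_pathogenic | prot$gene %in% retained, , drop = FALSE]
  prot$is_target <- prot$gene %in% retained
  rownames(prot) <- NULL

  ct <- net$ct_edges[net$ct_edges$target %in% retained, , drop = FALSE]
  rownames(ct) <- NULL

  pp <- net$pp_edges
  if (nrow(pp)) {
    present <- pp$from %in% prot$gene & pp$to %in% prot$gene
    anchored <- pp$from %in% retained | pp$to %in% retained |
      pp$from %in% ecp | pp$to %in% ecp
    pp <- pp[present & anchored, , drop = FALSE]
    rownames(pp) <- NULL
  }

  scores <- data.frame(gene = retained, s_moo = unname(s[retained]),
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$gene), , drop = FALSE]
  rownames(scores) <- NULL

  structure(list(compounds = net$compounds, proteins = prot,
                 ct_edges = ct, pp_edges = pp, scores = scores,
                 model = model, keep_quantile = keep_quantile),
            class = c("optimized_ctp", "ctp_network"))
}

#' Optimize the network with the scalarized multi-objective model
#'
#' Scores every target gene as the weighted mean of the three min-max
#' normalized objectives from [compute_objectives()] (equal weights by
#' default) and retains the genes at or above the `(1 - keep_quantile)`
#' score quantile, ties included. All compounds and pathogenic genes stay;
#' compound-target edges are restricted to retained targets and PPI edges to
#' those with at least one retained-target or ECP endpoint.
#'
#' @param net a `ctp_network`.
#' @param de optional DE table feeding the dysregulation objective.
#' @param keep_quantile fraction of target genes to retain, in (0, 1].
#' @param weights length-3 positive weights for
#'   (o_compound, o_pathogenic, o_dysreg); normalized to sum to 1.
#' @param objectives precomputed objective table (overrides `net`/`de`
#'   recomputation).
#' @return an `optimized_ctp`: the pruned network plus `$scores`
#'   (`gene`, `s_moo` in \[0, 1\]) and `$model = "moo"`.
#' @export
optimize_moo <- function(net, de = NULL, keep_quantile = 0.5,
                         weights = c(1, 1, 1), objectives = NULL) {
  obj <- objectives %||% compute_objectives(net, de)
  if (length(weights) != 3 || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be 3 non-negative values with positive sum",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  s <- as.numeric(as.matrix(obj[, c("o_compound", "o_pathogenic",
                                    "o_dysreg")]) %*% w)
  names(s) <- obj$gene
  .prune_network(net, s, keep_quantile, model = "moo")
}

#' Optimize the network with a centrality baseline
#'
#' Ranks target genes by degree, closeness, or betweenness centrality and
#' applies the same retention rule as [optimize_moo()]. Path-based
#' centralities (closeness, betweenness) are computed on the protein-protein
#' subgraph so compound nodes do not distort shortest paths; degree
#' additionally counts incident compound-target edges. Isolated nodes score
#' 0 for closeness (component-wise convention). Scores are min-max
#' normalized to \[0, 1\].
#'
#' @param net a `ctp_network`.
#' @param model `"degree"`, `"closeness"`, or `"betweenness"`.
#' @param keep_quantile fraction of target genes to retain.
#' @return an `optimized_ctp` with `$model` set to the centrality name.
#' @export
optimize_centrality <- function(net,
                                model = c("degree", "closeness", "betweenness"),
                                keep_quantile = 0.5) {
  model <- match.arg(model)
  stopifnot(inherits(net, "ctp_network"))
  targets <- net$proteins$gene[net$proteins$is_target]
  if (!length(targets)) stop("network has no target genes", call. = FALSE)

  g <- igraph::graph_from_data_frame(net$pp_edges, directed = FALSE,
                                     vertices = net$proteins$gene)
  cen <- switch(model,
    degree = {
      ct_deg <- table(factor(net$ct_edges$target, levels = targets))
      igraph::degree(g)[targets] + as.numeric(ct_deg)
    },
    closeness = {
      cl <- suppressWarnings(igraph::closeness(g, mode = "all"))
      cl[!is.finite(cl)] <- 0
      cl[targets]
    },
    betweenness = igraph::betweenness(g, directed = FALSE)[targets])
  s <- .minmax(as.numeric(cen), paste0(model, " centrality"))
  names(s) <- targets
  .prune_network(net, s, keep_quantile, model = model)
}

# Mean Pearson correlation of expression profiles over retained PPI edges.
.mean_edge_correlation <- function(opt, expr) {
  if (is.null(expr) || ncol(expr) < 3) {
    message("average regulating intensity unavailable (<3 samples)")
    return(NA_real_)
  }
  pp <- opt$pp_edges
  if (!nrow(pp)) return(NA_real_)
  ok <- pp$from %in% rownames(expr) & pp$to %in% rownames(expr)
  if (sum(!ok)) message(sum(!ok), " edge pair(s) lacking expression skipped")
  pp <- pp[ok, , drop = FALSE]
  if (!nrow(pp)) return(NA_real_)
  r <- vapply(seq_len(nrow(pp)), function(i) {
    suppressWarnings(stats::cor(expr[pp$from[i], ], expr[pp$to[i], ]))
  }, 0)
  mean(r, na.rm = TRUE)
}

#' Compare optimization models on five aspects
#'
#' Benchmarks optimized networks (typically the multi-objective model against
#' degree, closeness, and betweenness baselines) on:
#' ECP coverage; overlap of the model's top `n_pathways` enriched pathways
#' with the reference list enriched from the ECP set; overlap of the model's
#' top `n_gobp` enriched GO biological processes with the ECP-derived
#' reference; average regulating intensity (mean Pearson correlation of
#' expression over retained PPI edges); and cumulative differential
#' expression (sum of |logFC| over retained ECPs). The compared gene set for
#' each model is its retained target-gene set -- the genes the model actually
#' ranked.
#'
#' @param nets list of `optimized_ctp` objects.
#' @param ecp character vector of ECP genes (from the unoptimized network).
#' @param de optional DE table.
#' @param expr optional expression matrix (genes x samples).
#' @param genesets optional pathway [gene_set_collection()].
#' @param gobp optional GO biological process [gene_set_collection()].
#' @param n_pathways size of the pathway reference list (default 100).
#' @param n_gobp size of the GOBP reference list (default 1000).
#' @param min_term_size enrichment term-size filter (default 10).
#' @return data.frame, one row per model: `model`, `ecp_coverage`,
#'   `pathway_overlap`, `gobp_overlap`, `avg_regulating_intensity`,
#'   `cumulative_de`. Metrics whose inputs are absent are NA.
#' @export
compare_models <- function(nets, ecp, de = NULL, expr = NULL,
                           genesets = NULL, gobp = NULL,
                           n_pathways = 100, n_gobp = 1000,
                           min_term_size = 10) {
  stopifnot(length(nets) >= 1,
            all(vapply(nets, inherits, TRUE, "optimized_ctp")))
  ecp <- unique(.norm_gene(ecp))

  ref_top <- function(collection, n) {
    if (is.null(collection)) return(NULL)
    res <- enrich(ecp, collection, min_term_size = min_term_size)
    top_terms(res, n)$term
  }
  ref_pw <- ref_top(genesets, n_pathways)
  ref_bp <- ref_top(gobp, n_gobp)

  model_overlap <- function(genes, collection, ref, n) {
    if (is.null(collection) || is.null(ref)) return(NA_integer_)
    res <- tryCatch(enrich(genes, collection, min_term_size = min_term_size),
                    error = function(e) NULL)
    if (is.null(res) || !nrow(res)) return(0L)
    length(intersect(top_terms(res, n)$term, ref))
  }

  rows <- lapply(nets, function(opt) {
    genes <- opt$scores$gene
    ret_ecp <- intersect(genes, ecp)
    cde <- if (is.null(de)) NA_real_ else {
      sum(abs(de$logfc[match(ret_ecp, de$gene)]), na.rm = TRUE)
    }
    data.frame(
      model = opt$model,
      ecp_coverage = length(ret_ecp),
      pathway_overlap = model_overlap(genes, genesets, ref_pw, n_pathways),
      gobp_overlap = model_overlap(genes, gobp, ref_bp, n_gobp),
      avg_regulating_intensity = .mean_edge_correlation(opt, expr),
      cumulative_de = cde,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
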