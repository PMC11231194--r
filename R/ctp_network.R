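#' Build the tripartite compound-target-pathogenic-gene network
#'
#' Merges compound-target predictions with a disease (pathogenic) gene list
#' and protein-protein interactions. The protein node set is the union of
#' predicted targets and pathogenic genes; PPI edges are kept only when both
#' endpoints are protein nodes; genes that are both target and pathogenic are
#' the essential common proteins (ECPs). Compound-target edges referring to
#' compounds outside the supplied pass set are dropped with a message.
#'
#' @param compounds character vector of (screened) compound ids, or a
#'   compound table with a `compound_id` column.
#' @param ct_edges data.frame `compound`, `target` (optional `score`), as from
#'   [read_edge_list()].
#' @param pathogenic character vector of pathogenic gene ids.
#' @param ppi optional data.frame `from`, `to` of undirected protein pairs.
#' @return object of class `ctp_network` with elements `compounds`,
#'   `proteins` (`gene`, `is_target`, `is_pathogenic`), `ct_edges`,
#'   `pp_edges`.
#' @export
build_ctp <- function(compounds, ct_edges, pathogenic, ppi = NULL) {
  ids <- if (is.data.frame(compounds)) compounds$compound_id else compounds
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("empty compound set", call. = FALSE)
  pathogenic <- unique(.norm_gene(pathogenic))
  if (!length(pathogenic)) stop("empty pathogenic gene list", call. = FALSE)

  ct <- ct_edges
  ct$compound <- as.character(ct$compound)
  ct$target <- .norm_gene(ct$target)
  if (!"score" %in% names(ct)) ct[["score"]] <- rep(NA_real_, nrow(ct))
  keep <- ct$compound %in% ids
  if (any(!keep)) {
    message(sum(!keep),
            " compound-target edge(s) dropped: compound not in pass set")
    ct <- ct[keep, , drop = FALSE]
  }
  ct <- ct[!duplicated(ct[, c("compound", "target")]), , drop = FALSE]
  rownames(ct) <- NULL
  targets <- unique(ct$target)

  genes <- union(targets, pathogenic)
  proteins <- data.frame(gene = genes,
                         is_target = genes %in% targets,
                         is_pathogenic = genes %in% pathogenic,
                         stringsAsFactors = FALSE)

  if (is.null(ppi) || !nrow(ppi)) {
    pp <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  } else {
    a <- .norm_gene(ppi[[1]])
    b <- .norm_gene(ppi[[2]])
    self <- a == b
    if (any(self)) {
      warning(sum(self), " PPI self-loop(s) dropped")
      a <- a[!self]
      b <- b[!self]
    }
    pp <- data.frame(from = pmin(a, b), to = pmax(a, b),
                     stringsAsFactors = FALSE)
    pp <- pp[!duplicated(pp), , drop = FALSE]
    pp <- pp[pp$from %in% genes & pp$to %in% genes, , drop = FALSE]
    rownames(pp) <- NULL
  }

  structure(list(compounds = ids, proteins = proteins,
                 ct_edges = ct, pp_edges = pp),
            class = "ctp_network")
}

#' Essential common proteins (targets that are also pathogenic genes)
#' @param net a `ctp_network`.
#' @return character vector of ECP gene ids.
#' @export
ecp_genes <- function(net) {
  stopifnot(inherits(net, "ctp_network"))
  net$proteins$gene[net$proteins$is_target & net$proteins$is_pathogenic]
}

#' Network size summary
#' @param net a `ctp_network`.
#' @return list of counts: compounds, targets, pathogenic genes, ECPs,
#'   compound-target edges, protein-protein edges.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "ctp_network"))
  list(n_compounds = length(net$compounds),
       n_targets = sum(net$proteins$is_target),
       n_pathogenic = sum(net$proteins$is_pathogenic),
       n_ecp = length(ecp_genes(net)),
       n_ct_edges = nrow(net$ct_edges),
       n_pp_edges = nrow(net$pp_edges))
}

#' @export
print.ctp_network <- function(x, ...) {
  s <- network_stats(x)
  cat(if (inherits(x, "optimized_ctp")) {
    paste0("Optimized C-T-P network (model: ", x$model, ")\n")
  } else "C-T-P network\n")
  cat("  compounds: ", s$n_compounds,
      "  targets: ", s$n_targets,
      "  pathogenic: ", s$n_pathogenic,
      "  ECPs: ", s$n_ecp, "\n",
      "  ct edges: ", s$n_ct_edges,
      "  pp edges: ", s$n_pp_edges, "\n", sep = "")
  invisible(x)
}

# Undirected adjacency as a named list of neighbor vectors.
.neighbors <- function(pp_edges) {
  if (!nrow(pp_edges)) return(list())
  nb <- split(c(pp_edges$to, pp_edges$from),
              c(pp_edges$from, pp_edges$to))
  lapply(nb, unique)
}
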