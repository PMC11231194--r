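#' @importFrom stats quantile p.adjust phyper pt setNames rnorm runif cor
#' @importFrom utils combn read.table write.table packageVersion
NULL

# The nine screenable compound properties. Counts are integers, `ob` is a
# percentage in [0, 100], `caco2` is the log-scale permeability as supplied,
# `tpsa` is in square Angstroms, `hepatotoxic` is logical.
.property_fields <- c("mw", "n_hd", "n_ha", "logp", "n_rot", "ob",
                      "caco2", "tpsa", "hepatotoxic")

`%||%` <- function(a, b) if (is.null(a)) b else a

# One gene namespace per run: identifiers are case-normalized exactly once,
# at load time.
.norm_gene <- function(x) toupper(trimws(as.character(x)))

.detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = .detect_sep(path), quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

.write_tab <- function(df, path) {
  utils::write.table(df, path, sep = .detect_sep(path), quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "y", "1")
}

#' Read a compound property table
#'
#' Reads a tabular (TSV or CSV, auto-detected from the extension) compound
#' table with one row per compound--herb pair (or a `herb` cell holding
#' several herbs separated by `|` or `;`). Rows sharing a `compound_id` are
#' merged into a single record whose herb set is the union of the rows' herbs;
#' the same compound listed under several herbs must carry identical
#' properties.
#'
#' Required columns: `compound_id`, `herb`, and the nine screening properties
#' `mw`, `n_hd`, `n_ha`, `logp`, `n_rot`, `ob`, `caco2`, `tpsa`,
#' `hepatotoxic`. Optional: `name`, `smiles`. Differently named columns can be
#' mapped with `col_map`.
#'
#' @param path path to the table.
#' @param col_map optional named list mapping standard column names to the
#'   names used in the file, e.g. `list(mw = "MolWt")`.
#' @param herb_sep regular expression splitting multi-herb cells.
#' @return a data.frame with one row per compound: `compound_id`, `name`,
#'   a `herbs` list-column of herb identifiers, the nine property columns and
#'   (if present) `smiles`. Attribute `n_herb_pairs` records the number of
#'   distinct (compound, herb) pairs seen, so merging can be audited.
#' @export
read_compound_table <- function(path, col_map = NULL, herb_sep = "[|;]") {
  raw <- .read_tab(path)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  required <- c("compound_id", "herb", .property_fields)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("compound table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(raw)) raw$name <- raw$compound_id
  keep_cols <- c("compound_id", "name", .property_fields,
                 intersect("smiles", names(raw)))
  if (nrow(raw) == 0) {
    out <- raw[, keep_cols, drop = FALSE]
    out$herbs <- I(list())
    attr(out, "n_herb_pairs") <- 0L
    return(out)
  }
  raw$compound_id <- as.character(raw$compound_id)
  raw$hepatotoxic <- .parse_logical(raw$hepatotoxic)

  herbs_split <- lapply(strsplit(as.character(raw$herb), herb_sep), trimws)
  rows <- raw[rep(seq_len(nrow(raw)), lengths(herbs_split)), , drop = FALSE]
  rows$herb <- unlist(herbs_split)
  if (any(rows$herb == "")) stop("empty herb identifier", call. = FALSE)
  pairs <- unique(rows[, c("compound_id", "herb")])

  ids <- unique(rows$compound_id)
  prop_cols <- c("name", .property_fields, intersect("smiles", names(raw)))
  dup_ids <- unique(rows$compound_id[duplicated(rows$compound_id)])
  for (id in dup_ids) {
    u <- unique(rows[rows$compound_id == id, prop_cols, drop = FALSE])
    if (nrow(u) > 1) {
      stop("duplicate compound_id '", id, "' with conflicting properties",
           call. = FALSE)
    }
  }
  out <- rows[match(ids, rows$compound_id), c("compound_id", prop_cols),
              drop = FALSE]
  herbs_by_id <- split(pairs$herb, pairs$compound_id)
  out$herbs <- I(unname(lapply(herbs_by_id[ids], function(h) sort(unique(h)))))
  rownames(out) <- NULL
  n_merged <- nrow(raw) - length(ids)
  if (n_merged > 0) {
    message(n_merged, " row(s) merged into multi-herb compound records")
  }
  attr(out, "n_herb_pairs") <- nrow(pairs)
  out
}

#' Read a compound-target or protein-protein edge list
#'
#' The first two columns are the edge endpoints; for `kind = "ct"` these are
#' compound and target gene (an optional `score` column is retained), for
#' `kind = "pp"` both are genes. Gene identifiers are case-normalized.
#' Duplicate edges are collapsed (protein pairs as unordered pairs) and
#' protein self-loops are dropped with a warning.
#'
#' @param path path to the edge table.
#' @param kind `"ct"` (compound-target) or `"pp"` (protein-protein).
#' @return for `"ct"` a data.frame `compound`, `target`, `score`; for `"pp"` a
#'   data.frame `from`, `to`.
#' @export
read_edge_list <- function(path, kind = c("ct", "pp")) {
  kind <- match.arg(kind)
  raw <- .read_tab(path)
  if (ncol(raw) < 2) stop("edge list needs at least two columns", call. = FALSE)
  a <- trimws(as.character(raw[[1]]))
  b <- trimws(as.character(raw[[2]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad)) {
    stop("malformed edge row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  if (kind == "ct") {
    score <- if ("score" %in% names(raw)) as.numeric(raw$score) else NA_real_
    out <- data.frame(compound = a, target = .norm_gene(b), score = score,
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(out[, c("compound", "target")]), , drop = FALSE]
  } else {
    a <- .norm_gene(a)
    b <- .norm_gene(b)
    self <- a == b
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped from protein-protein edges")
      a <- a[!self]
      b <- b[!self]
    }
    out <- data.frame(from = pmin(a, b), to = pmax(a, b),
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(out), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a plain gene list (one identifier per line)
#' @param path path to a text file.
#' @return character vector of unique, case-normalized gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- .norm_gene(readLines(path, encoding = "UTF-8"))
  unique(x[x != ""])
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene members).
#' @param category label for the collection, e.g. `"pathway"` or `"gobp"`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = "geneset") {
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets))) {
    stop("gene sets must have unique, non-empty names", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set rejected", call. = FALSE)
  sets <- lapply(sets, function(g) unique(.norm_gene(g)))
  structure(list(sets = sets, category = category),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Lines with fewer than three fields (including an empty member
#' list) are fatal.
#'
#' @param path path to the GMT file.
#' @param category collection label.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "geneset") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, category = category)
}

#' Write a gene-set collection as GMT
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$category, gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Per-gene pathway membership counts
#'
#' For every gene appearing in the collection, the number of sets it belongs
#' to (the gene's pathway multiplicity, used to down-weight shared genes in
#' pathway intensity flow). Genes in no set are simply absent (count 0).
#'
#' @param gsc a [gene_set_collection()].
#' @return named integer vector.
#' @export
gene_set_counts <- function(gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  tab <- table(unlist(gsc$sets, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Read a genes-by-samples expression matrix
#'
#' First column holds gene identifiers (case-normalized, duplicates fatal);
#' remaining columns are samples. Values are expected on the log2 scale.
#'
#' @param path path to the table.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  raw <- .read_tab(path)
  genes <- .norm_gene(raw[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene rows in expression matrix",
                                 call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read sample group labels
#'
#' Two columns, `sample` and `group`; returns a named character vector of
#' group labels keyed by sample name.
#'
#' @param path path to the table.
#' @export
read_sample_groups <- function(path) {
  raw <- .read_tab(path)
  if (!all(c("sample", "group") %in% names(raw))) {
    stop("sample group file needs columns 'sample' and 'group'", call. = FALSE)
  }
  setNames(as.character(raw$group), as.character(raw$sample))
}

#' Read a precomputed differential-expression table
#'
#' Columns `gene`, `logfc`, `fdr` (adjusted p in \[0, 1\]). The returned table
#' carries attribute `provenance = "loaded"` to distinguish it from tables
#' computed in-run by [simple_de()].
#'
#' @param path path to the table.
#' @export
read_de_table <- function(path) {
  raw <- .read_tab(path)
  need <- c("gene", "logfc", "fdr")
  if (!all(need %in% names(raw))) {
    stop("DE table needs columns gene, logfc, fdr", call. = FALSE)
  }
  out <- data.frame(gene = .norm_gene(raw$gene),
                    logfc = as.numeric(raw$logfc),
                    fdr = as.numeric(raw$fdr), stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) stop("duplicate genes in DE table", call. = FALSE)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE)) {
    stop("fdr values must lie in [0, 1]", call. = FALSE)
  }
  attr(out, "provenance") <- "loaded"
  out
}

#' Export a network as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` (id, type, role flags, and `s_moo` plus `model`
#' for optimized networks) and `<prefix>_edges.tsv` (from, to, kind, score).
#' The pair round-trips through [read_network()].
#'
#' @param net a `ctp_network` or `optimized_ctp`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "ctp_network"))
  optimized <- inherits(net, "optimized_ctp")
  prot <- net$proteins
  nodes <- data.frame(
    id = c(net$compounds, prot$gene),
    type = c(rep("compound", length(net$compounds)),
             rep("protein", nrow(prot))),
    is_target = c(rep(NA, length(net$compounds)), prot$is_target),
    is_pathogenic = c(rep(NA, length(net$compounds)), prot$is_pathogenic),
    stringsAsFactors = FALSE)
  if (optimized) {
    s <- setNames(net$scores$s_moo, net$scores$gene)
    nodes$s_moo <- s[nodes$id]
    nodes$model <- net$model
  }
  ct <- net$ct_edges
  pp <- net$pp_edges
  edges <- data.frame(
    from = c(ct$compound, pp$from),
    to = c(ct$target, pp$to),
    kind = c(rep("ct", nrow(ct)), rep("pp", nrow(pp))),
    score = c(if (nrow(ct)) ct$score else numeric(0), rep(NA_real_, nrow(pp))),
    stringsAsFactors = FALSE)
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
  .write_tab(nodes, paths[1])
  .write_tab(edges, paths[2])
  invisible(paths)
}

#' Read a network written by [write_network()]
#' @param prefix the path prefix used when writing.
#' @return a `ctp_network` (or `optimized_ctp` when scores were present).
#' @export
read_network <- function(prefix) {
  nodes <- .read_tab(paste0(prefix, "_nodes.tsv"))
  edges <- .read_tab(paste0(prefix, "_edges.tsv"))
  comp <- as.character(nodes$id[nodes$type == "compound"])
  prot_rows <- nodes$type == "protein"
  proteins <- data.frame(gene = as.character(nodes$id[prot_rows]),
                         is_target = as.logical(nodes$is_target[prot_rows]),
                         is_pathogenic = as.logical(nodes$is_pathogenic[prot_rows]),
                         stringsAsFactors = FALSE)
  ct_rows <- edges$kind == "ct"
  ct <- data.frame(compound = as.character(edges$from[ct_rows]),
                   target = as.character(edges$to[ct_rows]),
                   score = as.numeric(edges$score[ct_rows]),
                   stringsAsFactors = FALSE)
  pp <- data.frame(from = as.character(edges$from[edges$kind == "pp"]),
                   to = as.character(edges$to[edges$kind == "pp"]),
                   stringsAsFactors = FALSE)
  net <- structure(list(compounds = comp, proteins = proteins,
                        ct_edges = ct, pp_edges = pp), class = "ctp_network")
  if ("s_moo" %in% names(nodes) && any(!is.na(nodes$s_moo))) {
    sc <- nodes[prot_rows & !is.na(nodes$s_moo), , drop = FALSE]
    net$scores <- data.frame(gene = as.character(sc$id), s_moo = sc$s_moo,
                             stringsAsFactors = FALSE)
    net$model <- if ("model" %in% names(nodes)) {
      as.character(stats::na.omit(unique(nodes$model)))[1]
    } else "unknown"
    class(net) <- c("optimized_ctp", "ctp_network")
  }
  net
}
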