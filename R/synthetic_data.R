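#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale version of a multi-herb screening study:
#' eight herbs, an overall pass fraction of 0.22 of candidate compounds, and
#' an ECP fraction of 0.16 of the pathogenic gene list, with differential
#' expression planted on a subset of ECPs at |log2FC| = 2 and Gaussian noise
#' (sd 0.5) on log2-scale expression. Network sizes are scaled down so every
#' pipeline stage runs in seconds.
#'
#' @param seed mandatory RNG seed; the whole bundle is a pure function of
#'   the config.
#' @param n_herbs,compounds_per_herb herb count and primary compounds per
#'   herb (total compounds = product).
#' @param shared_compound_rate fraction of compounds also assigned to one or
#'   two extra herbs.
#' @param pass_fraction fraction of compounds planted to pass all nine
#'   screening rules (labels drawn first, properties sampled conditional on
#'   the label, so recovery is exact).
#' @param n_targets,n_pathogenic target and pathogenic gene counts.
#' @param ecp_fraction fraction of pathogenic genes that are also targets.
#' @param targets_per_compound inclusive range of targets per compound.
#' @param signal_fraction fraction of targets planted as high compound-degree
#'   "signal" targets.
#' @param signal_weight sampling weight multiplier for signal targets.
#' @param ppi_prob Erdos-Renyi edge probability for the PPI layer.
#' @param n_pathways,pathway_size,n_gobp pathway/GO-term counts and the
#'   inclusive size range of each set.
#' @param n_samples samples per expression group (case and control).
#' @param de_fraction fraction of ECPs planted as differentially expressed.
#' @param de_effect_size planted |log2 fold change|.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_herbs = 8, compounds_per_herb = 25,
                             shared_compound_rate = 0.15,
                             pass_fraction = 0.22,
                             n_targets = 150, n_pathogenic = 120,
                             ecp_fraction = 0.16,
                             targets_per_compound = c(2, 8),
                             signal_fraction = 0.2, signal_weight = 4,
                             ppi_prob = 0.02,
                             n_pathways = 40, pathway_size = c(10, 30),
                             n_gobp = 60,
                             n_samples = 10, de_fraction = 0.4,
                             de_effect_size = 2, noise_sd = 0.5) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  fracs <- c(shared_compound_rate, pass_fraction, ecp_fraction,
             signal_fraction, ppi_prob, de_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(c(n_herbs, compounds_per_herb, n_targets, n_pathogenic,
            n_samples) < 1)) {
    stop("sizes must be positive", call. = FALSE)
  }
  cfg$n_ecp <- round(ecp_fraction * n_pathogenic)
  if (cfg$n_ecp > n_targets) {
    stop("infeasible config: ecp_fraction * n_pathogenic exceeds n_targets",
         call. = FALSE)
  }
  if (pathway_size[1] < 1 || pathway_size[2] < pathway_size[1]) {
    stop("invalid pathway_size range", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Sample a value violating one screening rule (strictly beyond the
# threshold, so planted fail labels are unambiguous).
.violating_value <- function(field) {
  switch(field,
         mw = runif(1, 505, 900),
         n_hd = sample(6:12, 1),
         n_ha = sample(11:20, 1),
         logp = runif(1, 5.2, 9),
         n_rot = sample(11:25, 1),
         ob = runif(1, 0, 29.5),
         caco2 = runif(1, -1, 0.35),
         tpsa = runif(1, 61, 200),
         hepatotoxic = TRUE)
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Emits every input the pipeline consumes -- compound property table,
#' compound-target edges (with prediction scores), pathogenic gene list, PPI
#' edge list, pathway and GO-BP gene-set collections, and a case/control
#' expression matrix -- together with the planted truth (pass labels, ECP
#' set, DE genes with true log fold changes, signal targets). Generation is
#' label-first: pass/fail labels and DE memberships are drawn before the
#' observable values are sampled conditional on them, so recovery checks are
#' exact. The same config (including seed) reproduces the bundle exactly.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_bundle`: `compounds`, `ct_edges`,
#'   `pathogenic`, `ppi`, `pathways`, `gobp`, `expr`, `groups`, `truth`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  ## compounds and herb membership
  n_comp <- config$n_herbs * config$compounds_per_herb
  ids <- sprintf("CMP%04d", seq_len(n_comp))
  herbs <- sprintf("herb%02d", seq_len(config$n_herbs))
  herbs_list <- as.list(rep(herbs, each = config$compounds_per_herb))
  shared <- which(runif(n_comp) < config$shared_compound_rate)
  for (i in shared) {
    avail <- setdiff(herbs, herbs_list[[i]])
    k <- min(sample(1:2, 1), length(avail))
    if (k > 0) {
      extra <- avail[sample.int(length(avail), k)]
      herbs_list[[i]] <- sort(c(herbs_list[[i]], extra))
    }
  }

  ## label-first screening properties
  n_pass <- round(config$pass_fraction * n_comp)
  pass_idx <- sort(sample(n_comp, n_pass))
  props <- data.frame(
    mw = runif(n_comp, 150, 500),
    n_hd = sample(0:5, n_comp, replace = TRUE),
    n_ha = sample(0:10, n_comp, replace = TRUE),
    logp = runif(n_comp, -2, 5),
    n_rot = sample(0:10, n_comp, replace = TRUE),
    ob = runif(n_comp, 30, 100),
    caco2 = runif(n_comp, 0.4, 1.6),
    tpsa = runif(n_comp, 5, 60),
    hepatotoxic = FALSE)
  for (i in setdiff(seq_len(n_comp), pass_idx)) {
    for (f in sample(.property_fields, sample(1:3, 1))) {
      props[i, f] <- .violating_value(f)
    }
  }
  compounds <- data.frame(compound_id = ids,
                          name = paste0("compound_", seq_len(n_comp)),
                          stringsAsFactors = FALSE)
  compounds$herbs <- I(herbs_list)
  compounds <- cbind(compounds, props)

  ## gene layers
  targets <- sprintf("TGT%04d", seq_len(config$n_targets))
  ecp <- sort(sample(targets, config$n_ecp))
  extra_path <- sprintf("PGN%04d", seq_len(config$n_pathogenic - config$n_ecp))
  pathogenic <- c(ecp, extra_path)
  genes <- c(targets, extra_path)

  ## compound-target predictions, biased toward planted signal targets
  signal <- sort(sample(targets, round(config$signal_fraction *
                                         config$n_targets)))
  w <- ifelse(targets %in% signal, config$signal_weight, 1)
  rng <- config$targets_per_compound
  ct_rows <- lapply(seq_len(n_comp), function(i) {
    k <- sample(seq(rng[1], rng[2]), 1)
    data.frame(compound = ids[i],
               target = sample(targets, k, prob = w),
               stringsAsFactors = FALSE)
  })
  ct_edges <- do.call(rbind, ct_rows)
  ct_edges$score <- round(runif(nrow(ct_edges), 0.3, 1), 4)

  ## Erdos-Renyi PPI layer over all genes
  pairs <- utils::combn(genes, 2)
  hit <- runif(ncol(pairs)) < config$ppi_prob
  ppi <- data.frame(from = pmin(pairs[1, hit], pairs[2, hit]),
                    to = pmax(pairs[1, hit], pairs[2, hit]),
                    stringsAsFactors = FALSE)

  ## gene-set collections
  draw_sets <- function(n, prefix, category) {
    sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                    n, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(genes, min(s, length(genes))))
    names(sets) <- sprintf("%s%03d", prefix, seq_len(n))
    gene_set_collection(sets, category = category)
  }
  pathways <- draw_sets(config$n_pathways, "PW", "pathway")
  gobp <- draw_sets(config$n_gobp, "BP", "gobp")

  ## expression with DE planted on a subset of ECPs
  n_de <- round(config$de_fraction * config$n_ecp)
  de_genes <- if (n_de > 0) sort(sample(ecp, n_de)) else character(0)
  true_lfc <- if (n_de > 0) {
    sample(c(-1, 1), n_de, replace = TRUE) * config$de_effect_size
  } else numeric(0)
  ns <- config$n_samples
  mu <- rnorm(length(genes), mean = 7, sd = 1)
  expr <- matrix(rnorm(length(genes) * 2 * ns, sd = config$noise_sd),
                 nrow = length(genes)) + mu
  rownames(expr) <- genes
  colnames(expr) <- c(sprintf("case_%02d", seq_len(ns)),
                      sprintf("control_%02d", seq_len(ns)))
  if (n_de > 0) {
    expr[de_genes, seq_len(ns)] <- expr[de_genes, seq_len(ns)] + true_lfc
  }
  groups <- setNames(rep(c("case", "control"), each = ns), colnames(expr))

  truth <- list(pass_ids = ids[pass_idx],
                ecp = ecp,
                de = data.frame(gene = de_genes, true_logfc = true_lfc,
                                stringsAsFactors = FALSE),
                signal_targets = signal,
                config = unclass(config))

  structure(list(compounds = compounds, ct_edges = ct_edges,
                 pathogenic = pathogenic, ppi = ppi,
                 pathways = pathways, gobp = gobp,
                 expr = expr, groups = groups, truth = truth),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk in the readers' formats
#'
#' Files: `compounds.tsv` (long format, one row per compound-herb pair),
#' `ct_edges.tsv`, `pathogenic.txt`, `ppi.tsv`, `pathways.gmt`, `gobp.gmt`,
#' `expression.tsv`, `groups.tsv`, `truth.json`. Everything round-trips
#' through the package readers.
#'
#' @param bundle a [generate_synthetic()] (or [make_worked_toy()]) bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
write_synthetic <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    compounds = file.path(dir, "compounds.tsv"),
    ct_edges = file.path(dir, "ct_edges.tsv"),
    pathogenic = file.path(dir, "pathogenic.txt"),
    ppi = file.path(dir, "ppi.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    gobp = file.path(dir, "gobp.gmt"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json"))

  comp <- bundle$compounds
  long <- comp[rep(seq_len(nrow(comp)), lengths(comp$herbs)), , drop = FALSE]
  long$herb <- unlist(comp$herbs)
  long$herbs <- NULL
  .write_tab(long[, c("compound_id", "name", "herb", .property_fields)],
             paths$compounds)
  .write_tab(bundle$ct_edges, paths$ct_edges)
  writeLines(bundle$pathogenic, paths$pathogenic)
  .write_tab(bundle$ppi, paths$ppi)
  write_gmt(bundle$pathways, paths$pathways)
  write_gmt(bundle$gobp, paths$gobp)
  expr_df <- data.frame(gene = rownames(bundle$expr), bundle$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  .write_tab(expr_df, paths$expression)
  .write_tab(data.frame(sample = names(bundle$groups),
                        group = unname(bundle$groups),
                        stringsAsFactors = FALSE), paths$groups)
  jsonlite::write_json(bundle$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Fixed worked toy: three compounds covering three pathogenic genes
#'
#' A deterministic miniature used throughout the intensity-flow examples and
#' tests. Compounds A, B, C target pathogenic genes G1-G3 (all ECPs, no PPI
#' layer): A covers {G1, G2}, B covers {G2, G3}, C covers {G3}. The returned
#' `$opt` is a ready-made optimized network with planted scores
#' S'_MOO = (G1 = 0.5, G2 = 0.5, G3 = 0.4), so the total union intensity is
#' 1.4 and the minimal 90% combination is {A, B}. The returned `$bundle` holds
#' the same toy as pipeline input files (noise-free expression with log fold
#' changes 2, 1.5, 1), byte-stable across runs.
#'
#' @return list with elements `opt` (an `optimized_ctp`) and `bundle`
#'   (a `synthetic_bundle`).
#' @export
make_worked_toy <- function() {
  ct <- data.frame(compound = c("A", "A", "B", "B", "C"),
                   target = c("G1", "G2", "G2", "G3", "G3"),
                   score = NA_real_, stringsAsFactors = FALSE)
  proteins <- data.frame(gene = c("G1", "G2", "G3"),
                         is_target = TRUE, is_pathogenic = TRUE,
                         stringsAsFactors = FALSE)
  pp <- data.frame(from = character(0), to = character(0),
                   stringsAsFactors = FALSE)
  opt <- structure(list(compounds = c("A", "B", "C"), proteins = proteins,
                        ct_edges = ct, pp_edges = pp,
                        scores = data.frame(gene = c("G1", "G2", "G3"),
                                            s_moo = c(0.5, 0.5, 0.4),
                                            stringsAsFactors = FALSE),
                        model = "moo", keep_quantile = 1),
                   class = c("optimized_ctp", "ctp_network"))

  compounds <- data.frame(compound_id = c("A", "B", "C"),
                          name = c("A", "B", "C"), stringsAsFactors = FALSE)
  compounds$herbs <- I(list("herbA", "herbB", "herbC"))
  compounds <- cbind(compounds,
                     data.frame(mw = 300, n_hd = 2, n_ha = 4, logp = 2,
                                n_rot = 3, ob = 50, caco2 = 1, tpsa = 40,
                                hepatotoxic = FALSE))
  ns <- 5
  lfc <- c(G1 = 2, G2 = 1.5, G3 = 1)
  expr <- matrix(7, nrow = 3, ncol = 2 * ns,
                 dimnames = list(c("G1", "G2", "G3"),
                                 c(sprintf("case_%02d", seq_len(ns)),
                                   sprintf("control_%02d", seq_len(ns)))))
  expr[, seq_len(ns)] <- expr[, seq_len(ns)] + lfc
  groups <- setNames(rep(c("case", "control"), each = ns), colnames(expr))
  pathways <- gene_set_collection(list(PW001 = c("G1", "G2", "G3"),
                                       PW002 = c("G2", "G3")),
                                  category = "pathway")
  bundle <- structure(list(
    compounds = compounds, ct_edges = ct[, c("compound", "target")],
    pathogenic = c("G1", "G2", "G3"), ppi = pp,
    pathways = pathways, gobp = pathways,
    expr = expr, groups = groups,
    truth = list(pass_ids = c("A", "B", "C"), ecp = c("G1", "G2", "G3"),
                 de = data.frame(gene = names(lfc), true_logfc = unname(lfc),
                                 stringsAsFactors = FALSE),
                 signal_targets = character(0), config = list(preset = "toy"))),
    class = "synthetic_bundle")
  list(opt = opt, bundle = bundle)
}
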