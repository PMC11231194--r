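#' Default pipeline configuration
#'
#' @param preset `"default"` (seeded synthetic bundle), `"toy"` (the fixed
#'   worked toy), or `"files"` (read inputs from `paths`).
#' @param seed RNG seed; the single source of randomness for the run.
#' @param paths named list of input paths (used when `preset = "files"`):
#'   `compounds`, `ct_edges`, `pathogenic`, `ppi`, `pathways`, and optionally
#'   `gobp`, `expression`, `groups`, `de`.
#' @param model `"moo"`, `"degree"`, `"closeness"`, or `"betweenness"`.
#' @param keep_quantile fraction of target genes retained by optimization.
#' @param threshold combination coverage threshold (default 0.90).
#' @param solver combination solver, `"greedy"` or `"exact"`.
#' @param exact_limit exact-solver size guard.
#' @param min_term_size enrichment term-size filter.
#' @param top_pathways pathway intensities reported (default 20).
#' @param compare also run the three centrality baselines and a model
#'   comparison (default FALSE).
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(preset = "default", seed = 1, paths = list(),
                            model = "moo", keep_quantile = 0.5,
                            threshold = 0.9, solver = "greedy",
                            exact_limit = 15, min_term_size = 10,
                            top_pathways = 20, compare = FALSE) {
  stopifnot(preset %in% c("default", "toy", "files"),
            model %in% c("moo", "degree", "closeness", "betweenness"),
            threshold > 0, threshold <= 1,
            keep_quantile > 0, keep_quantile <= 1)
  if (preset == "files") {
    need <- c("compounds", "ct_edges", "pathogenic", "pathways")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop("preset 'files' requires paths: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

.load_inputs <- function(config) {
  if (config$preset == "toy") return(make_worked_toy()$bundle)
  if (config$preset == "default") {
    return(generate_synthetic(generator_config(seed = config$seed)))
  }
  p <- config$paths
  for (nm in c("compounds", "ct_edges", "pathogenic", "pathways")) {
    if (!file.exists(p[[nm]])) {
      stop("input file for '", nm, "' not found: ", p[[nm]], call. = FALSE)
    }
  }
  structure(list(
    compounds = read_compound_table(p$compounds),
    ct_edges = read_edge_list(p$ct_edges, kind = "ct"),
    pathogenic = read_gene_list(p$pathogenic),
    ppi = if (!is.null(p$ppi)) read_edge_list(p$ppi, kind = "pp") else NULL,
    pathways = read_gmt(p$pathways, category = "pathway"),
    gobp = if (!is.null(p$gobp)) read_gmt(p$gobp, category = "gobp") else NULL,
    expr = if (!is.null(p$expression)) read_expression(p$expression) else NULL,
    groups = if (!is.null(p$groups)) read_sample_groups(p$groups) else NULL,
    de = if (!is.null(p$de)) read_de_table(p$de) else NULL,
    truth = NULL), class = "synthetic_bundle")
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate/ingest, compound screening, C-T-P network
#' construction, differential expression, network optimization, gene /
#' compound / pathway intensity flow, minimal-combination selection, and ECP
#' enrichment under a single config. All stage artifacts are written to
#' `out_dir` as plain files; the machine-readable run report is
#' `report.json` and the config snapshot `config.yaml`. A failing stage
#' leaves a `FAILED` marker naming the stage next to any partial artifacts.
#' A fixed seed reproduces the report byte for byte.
#'
#' @param config a [pipeline_config()], a plain list of its fields, or the
#'   path of a YAML file holding them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  current_stage <- "setup"
  stage <- function(name) current_stage <<- name
  on_fail <- function(e) {
    writeLines(paste0("stage: ", current_stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  }

  report <- tryCatch({
    set.seed(config$seed)

    stage("ingest")
    inputs <- .load_inputs(config)
    if (config$preset != "files") {
      write_synthetic(inputs, file.path(out_dir, "inputs"))
    }

    stage("screen")
    scr <- screen(inputs$compounds)
    if (scr$n_pass == 0) stop("no compound passed screening")
    .write_tab(data.frame(compound_id = scr$compounds$compound_id,
                          pass = scr$compounds$pass,
                          violations = vapply(scr$compounds$violations,
                                              paste, "", collapse = ";")),
               file.path(out_dir, "screen.tsv"))

    stage("build-net")
    net <- build_ctp(pass_set(scr), inputs$ct_edges, inputs$pathogenic,
                     inputs$ppi)
    stats_before <- network_stats(net)

    stage("differential-expression")
    de <- inputs$de
    if (is.null(de) && !is.null(inputs$expr)) {
      de <- simple_de(inputs$expr, inputs$groups)
      .write_tab(de, file.path(out_dir, "de.tsv"))
    }

    stage("optimize")
    opt <- if (config$model == "moo") {
      optimize_moo(net, de = de, keep_quantile = config$keep_quantile)
    } else {
      optimize_centrality(net, model = config$model,
                          keep_quantile = config$keep_quantile)
    }
    write_network(opt, file.path(out_dir, "optimized"))
    stats_after <- network_stats(opt)

    stage("intensity")
    gi <- gene_intensity(opt)
    ci <- compound_intensity(opt, gi)
    .write_tab(gi, file.path(out_dir, "gene_intensity.tsv"))
    .write_tab(data.frame(compound = ci$compound, intensity = ci$intensity,
                          n_genes = ci$n_genes),
               file.path(out_dir, "compound_intensity.tsv"))

    stage("select")
    comb <- select_combination(ci, threshold = config$threshold,
                               solver = config$solver,
                               exact_limit = config$exact_limit)
    .write_tab(comb$per_size, file.path(out_dir, "combination_sizes.tsv"))

    stage("pathway-rank")
    pw <- pathway_intensity(gi, inputs$pathways)
    .write_tab(pw, file.path(out_dir, "pathway_intensity.tsv"))
    pw_top <- pw[seq_len(min(config$top_pathways, nrow(pw))), , drop = FALSE]

    stage("enrich")
    enr <- enrich(ecp_genes(net), inputs$pathways,
                  min_term_size = config$min_term_size)
    if (nrow(enr)) {
      .write_tab(enr[, setdiff(names(enr), "genes")],
                 file.path(out_dir, "ecp_enrichment.tsv"))
    }

    comparison <- NULL
    if (isTRUE(config$compare)) {
      stage("compare-models")
      baselines <- lapply(c("degree", "closeness", "betweenness"),
                          function(m) {
        optimize_centrality(net, model = m,
                            keep_quantile = config$keep_quantile)
      })
      comparison <- compare_models(c(list(opt), baselines),
                                   ecp = ecp_genes(net), de = de,
                                   expr = inputs$expr,
                                   genesets = inputs$pathways,
                                   gobp = inputs$gobp,
                                   min_term_size = config$min_term_size)
      .write_tab(comparison, file.path(out_dir, "model_comparison.tsv"))
    }

    stage("report")
    report <- list(
      software = paste0("ctpflow ",
                        as.character(utils::packageVersion("ctpflow"))),
      config = unclass(config)[setdiff(names(unclass(config)), "paths")],
      screen = list(n_input = scr$n_input, n_pass = scr$n_pass,
                    n_shared = scr$n_shared,
                    per_herb = scr$herb_counts),
      network = list(original = stats_before, optimized = stats_after),
      de = if (!is.null(de)) {
        list(n_genes = nrow(de), n_significant = sum(de$significant %||% NA))
      },
      combination = list(solver = comb$solver, threshold = comb$threshold,
                         size = comb$size, members = comb$members,
                         intensity = comb$intensity,
                         total_intensity = comb$total_intensity),
      top_pathways = pw_top[, c("pathway", "intensity", "rank")],
      enrichment = list(n_terms = nrow(enr),
                        n_significant = if (nrow(enr)) sum(enr$significant)
                                        else 0L),
      comparison = comparison)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    report
  }, error = on_fail)

  invisible(report)
}
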