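# Shared in-code fixtures: no data files, everything built at test time.

# A compound row with all nine properties satisfied.
passing_compound <- function(id = "C1", herbs = "herbA",
                             mw = 450, n_hd = 3, n_ha = 8, logp = 4.2,
                             n_rot = 6, ob = 45, caco2 = 0.6, tpsa = 55,
                             hepatotoxic = FALSE) {
  df <- data.frame(compound_id = id, name = id, mw = mw, n_hd = n_hd,
                   n_ha = n_ha, logp = logp, n_rot = n_rot, ob = ob,
                   caco2 = caco2, tpsa = tpsa, hepatotoxic = hepatotoxic,
                   stringsAsFactors = FALSE)
  df$herbs <- I(list(herbs))
  df
}

compound_table <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hand-built optimized network: ECPs E* (retained targets that are
# pathogenic), plain retained targets T*, pathogenic non-targets P*.
toy_optimized <- function(scores, pathogenic, ct_edges, pp_edges,
                          compounds = unique(ct_edges$compound)) {
  genes <- union(names(scores), pathogenic)
  proteins <- data.frame(gene = genes,
                         is_target = genes %in% names(scores),
                         is_pathogenic = genes %in% pathogenic,
                         stringsAsFactors = FALSE)
  if (!"score" %in% names(ct_edges)) ct_edges$score <- NA_real_
  structure(list(compounds = compounds, proteins = proteins,
                 ct_edges = ct_edges, pp_edges = pp_edges,
                 scores = data.frame(gene = names(scores),
                                     s_moo = unname(scores),
                                     stringsAsFactors = FALSE),
                 model = "moo", keep_quantile = 1),
            class = c("optimized_ctp", "ctp_network"))
}

empty_pp <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

# Random maximum-coverage instance for the exact-vs-greedy oracle.
random_coverage_instance <- function(n_compounds, n_genes = 8) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  iv <- stats::setNames(round(stats::runif(n_genes, 0.1, 1), 3), genes)
  cover <- lapply(seq_len(n_compounds), function(i) {
    sort(sample(genes, sample(seq_len(min(4, n_genes)), 1)))
  })
  ci <- data.frame(compound = sprintf("c%02d", seq_len(n_compounds)),
                   intensity = vapply(cover, function(g) sum(iv[g]), 0),
                   n_genes = lengths(cover), stringsAsFactors = FALSE)
  ci$genes <- I(cover)
  attr(ci, "gene_intensity") <- iv
  class(ci) <- c("compound_intensity", "data.frame")
  ci
}

# Exhaustive hypergeometric upper-tail probability by enumerating all
# C(N, n) draws is infeasible; instead enumerate the exact probability mass
# of every overlap value from binomial coefficients (independent of phyper).
hyper_upper_tail <- function(k, K, N, n) {
  kk <- max(0, n + K - N):min(K, n)
  mass <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(mass[kk >= k])
}
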