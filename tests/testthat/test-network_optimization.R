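# Small network: 4 targets with graded compound degree, pathogenic
# neighborhood, and dysregulation.
graded_net <- function() {
  ct <- data.frame(
    compound = c("c1", "c1", "c1", "c1", "c2", "c2", "c3", "c4", "c4", "c5"),
    target = c("T1", "T2", "T3", "T4", "T1", "T2", "T1", "T1", "T2", "T1"))
  ppi <- data.frame(from = c("T1", "T1", "T2"),
                    to = c("P1", "P2", "P1"))
  build_ctp(paste0("c", 1:5), ct, pathogenic = c("P1", "P2", "T4"), ppi)
}

test_that("objectives are min-max normalized with stated conventions", {
  net <- build_ctp(paste0("c", 1:6),
                   data.frame(compound = paste0("c", 1:6),
                              target = c("A", rep("B", 5))),
                   pathogenic = "Z")
  de <- data.frame(gene = "A", logfc = 2, fdr = 0.01)
  obj <- suppressMessages(compute_objectives(net, de))
  # ct-degrees {1, 5} map to the min-max endpoints
  expect_equal(obj$o_compound[match(c("A", "B"), obj$gene)], c(0, 1))
  # gene absent from the DE table scores 0 dysregulation
  expect_equal(obj$o_dysreg[obj$gene == "B"], 0)
  # constant objective degenerates to all zeros (with a message)
  expect_message(obj2 <- compute_objectives(net), "degenerate")
  expect_equal(obj2$o_pathogenic, c(0, 0))
  expect_true(all(obj$o_compound >= 0 & obj$o_compound <= 1))
})

test_that("ECP membership contributes to the pathogenic objective", {
  net <- graded_net()
  obj <- suppressMessages(compute_objectives(net))
  # raw pathogenic association: T1 has 2 pathogenic neighbors, T2 one,
  # T3 none, T4 none but is itself pathogenic (ECP bonus = one neighbor)
  o <- setNames(obj$o_pathogenic, obj$gene)
  expect_true(o[["T1"]] > o[["T2"]] && o[["T2"]] > o[["T3"]])
  expect_equal(o[["T4"]], o[["T2"]])
  expect_gt(o[["T4"]], 0)
})

test_that("quantile retention keeps the top scores with ties", {
  net <- graded_net()
  s <- c(T1 = 0.1, T2 = 0.2, T3 = 0.8, T4 = 0.9)
  obj <- data.frame(gene = names(s), o_compound = unname(s),
                    o_pathogenic = unname(s), o_dysreg = unname(s))
  opt <- optimize_moo(net, objectives = obj, keep_quantile = 0.5)
  expect_setequal(opt$scores$gene, c("T3", "T4"))
  # keep_quantile = 1 is the identity up to attached scores
  all_kept <- optimize_moo(net, objectives = obj, keep_quantile = 1)
  expect_setequal(all_kept$scores$gene, names(s))
  expect_equal(network_stats(all_kept)$n_pp_edges,
               network_stats(net)$n_pp_edges)
  expect_error(optimize_moo(net, objectives = obj, keep_quantile = 0),
               "keep_quantile")
})

test_that("pruning is monotone in keep_quantile and scores stay in [0,1]", {
  cfg <- generator_config(seed = 3, n_herbs = 2, compounds_per_herb = 30,
                          n_targets = 60, n_pathogenic = 50)
  b <- generate_synthetic(cfg)
  rep <- screen(b$compounds)
  net <- suppressMessages(build_ctp(pass_set(rep), b$ct_edges, b$pathogenic,
                                    b$ppi))
  de <- simple_de(b$expr, b$groups)
  prev <- character(0)
  for (q in c(0.2, 0.5, 0.8, 1)) {
    opt <- suppressMessages(optimize_moo(net, de = de, keep_quantile = q))
    expect_true(all(prev %in% opt$scores$gene), label = paste("q =", q))
    expect_true(all(opt$scores$s_moo >= 0 & opt$scores$s_moo <= 1))
    prev <- opt$scores$gene
  }
})

test_that("centrality baselines follow graph-theoretic ground truth", {
  # path graph A - B - C, every node a target of one compound
  ct <- data.frame(compound = c("c1", "c2", "c3"), target = c("A", "B", "C"))
  ppi <- data.frame(from = c("A", "B"), to = c("B", "C"))
  net <- build_ctp(c("c1", "c2", "c3"), ct, pathogenic = "A", ppi)

  deg <- optimize_centrality(net, "degree", keep_quantile = 1)
  sd_ <- setNames(deg$scores$s_moo, deg$scores$gene)
  expect_equal(unname(which.max(sd_[c("A", "B", "C")])), 2)

  btw <- optimize_centrality(net, "betweenness", keep_quantile = 1)
  sb <- setNames(btw$scores$s_moo, btw$scores$gene)
  # brute force: only the A..C geodesic has an interior vertex, B
  expect_equal(unname(sb[c("A", "B", "C")]), c(0, 1, 0))

  # isolated node scores zero closeness
  ct2 <- rbind(ct, data.frame(compound = "c4", target = "D"))
  net2 <- build_ctp(paste0("c", 1:4), ct2, pathogenic = "A", ppi)
  clo <- optimize_centrality(net2, "closeness", keep_quantile = 1)
  sc <- setNames(clo$scores$s_moo, clo$scores$gene)
  expect_equal(unname(sc[["D"]]), 0)
  expect_equal(unname(which.max(sc[c("A", "B", "C", "D")])), 2)
})

test_that("with dysregulation off and uniform ct-degree, the MOO ranking
           reduces to the pathogenic-neighbor ranking", {
  ct <- data.frame(compound = c("c1", "c2", "c3"),
                   target = c("T1", "T2", "T3"))
  ppi <- data.frame(from = c("T1", "T1", "T2"), to = c("P1", "P2", "P1"))
  net <- build_ctp(paste0("c", 1:3), ct, pathogenic = c("P1", "P2"), ppi)
  obj <- suppressMessages(compute_objectives(net))
  opt <- optimize_moo(net, objectives = obj, keep_quantile = 1,
                      weights = c(0, 1, 0))
  s <- setNames(opt$scores$s_moo, opt$scores$gene)
  expect_true(s[["T1"]] > s[["T2"]] && s[["T2"]] > s[["T3"]])
})

test_that("model comparison is permutation-invariant and bounded", {
  cfg <- generator_config(seed = 5, n_herbs = 2, compounds_per_herb = 30,
                          n_targets = 60, n_pathogenic = 50,
                          n_pathways = 15, n_gobp = 20)
  b <- generate_synthetic(cfg)
  net <- suppressMessages(build_ctp(pass_set(screen(b$compounds)),
                                    b$ct_edges, b$pathogenic, b$ppi))
  de <- simple_de(b$expr, b$groups)
  moo <- suppressMessages(optimize_moo(net, de = de))
  deg <- suppressMessages(optimize_centrality(net, "degree"))
  ecp <- ecp_genes(net)
  cmp1 <- suppressWarnings(suppressMessages(
    compare_models(list(moo, deg), ecp, de, b$expr, b$pathways, b$gobp,
                   n_pathways = 10, n_gobp = 10)))
  cmp2 <- suppressWarnings(suppressMessages(
    compare_models(list(deg, moo), ecp, de, b$expr, b$pathways, b$gobp,
                   n_pathways = 10, n_gobp = 10)))
  expect_equal(cmp1[order(cmp1$model), ], cmp2[order(cmp2$model), ],
               ignore_attr = TRUE)
  expect_true(all(cmp1$ecp_coverage <= length(ecp)))
  expect_true(all(cmp1$pathway_overlap <= 10, na.rm = TRUE))
  # two models retaining identical gene sets report identical metrics
  cmp3 <- suppressWarnings(suppressMessages(
    compare_models(list(moo, moo), ecp, de, b$expr, b$pathways, b$gobp,
                   n_pathways = 10, n_gobp = 10)))
  expect_equal(cmp3[1, -1], cmp3[2, -1], ignore_attr = TRUE)
})
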