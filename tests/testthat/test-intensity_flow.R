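test_that("gene intensity reproduces both equation branches exactly", {
  # E1 is a pathogenic retained target (ECP): intensity is its own score.
  # P1 interacts with retained targets T1, T2: intensity is their mean.
  # P2 has no retained-target interactions: intensity 0.
  opt <- toy_optimized(c(E1 = 0.7, T1 = 0.4, T2 = 0.8),
                       pathogenic = c("E1", "P1", "P2"),
                       ct_edges = data.frame(compound = "c1", target = "E1"),
                       pp_edges = data.frame(from = c("P1", "P1"),
                                             to = c("T1", "T2")))
  gi <- gene_intensity(opt)
  iv <- setNames(gi$intensity, gi$gene)
  expect_equal(iv[["E1"]], 0.7, tolerance = 1e-12)
  expect_equal(iv[["P1"]], 0.6, tolerance = 1e-12)
  expect_equal(iv[["P2"]], 0)
  expect_equal(gi$n_targets[match(c("E1", "P1", "P2"), gi$gene)],
               c(1L, 2L, 0L))
})

test_that("compound intensity sums direct and one-hop pathogenic coverage", {
  # c1 targets two ECPs: sum of their intensities
  opt <- toy_optimized(c(E1 = 0.6, E2 = 0.3),
                       pathogenic = c("E1", "E2"),
                       ct_edges = data.frame(compound = c("c1", "c1"),
                                             target = c("E1", "E2")),
                       pp_edges = empty_pp())
  ci <- compound_intensity(opt, gene_intensity(opt))
  expect_equal(ci$intensity[ci$compound == "c1"], 0.9)

  # 4-node hand trace: c1 -> T1, T1 -- K1 (pathogenic), K1 gets T1's score
  opt2 <- toy_optimized(c(T1 = 0.5), pathogenic = "K1",
                        ct_edges = data.frame(compound = "c1", target = "T1"),
                        pp_edges = data.frame(from = "K1", to = "T1"))
  gi2 <- gene_intensity(opt2)
  ci2 <- compound_intensity(opt2, gi2)
  expect_equal(ci2$intensity, 0.5)
  expect_equal(ci2$genes[[1]], "K1")

  # compound with empty pathogenic coverage has intensity 0
  opt3 <- toy_optimized(c(T1 = 0.5), pathogenic = "Q1",
                        ct_edges = data.frame(compound = "c1", target = "T1"),
                        pp_edges = empty_pp())
  ci3 <- compound_intensity(opt3, gene_intensity(opt3))
  expect_equal(ci3$intensity, 0)
})

test_that("the worked toy selects {A, B} at 90% and {A} at 30%", {
  toy <- make_worked_toy()
  gi <- gene_intensity(toy$opt)
  expect_equal(setNames(gi$intensity, gi$gene),
               c(G1 = 0.5, G2 = 0.5, G3 = 0.4))
  ci <- compound_intensity(toy$opt, gi)
  expect_equal(setNames(ci$intensity, ci$compound),
               c(A = 1.0, B = 0.9, C = 0.4))

  for (solver in c("exact", "greedy")) {
    res <- select_combination(ci, threshold = 0.9, solver = solver)
    expect_equal(res$total_intensity, 1.4)
    expect_equal(res$members, c("A", "B"))
    expect_equal(res$size, 2)
    low <- select_combination(ci, threshold = 0.3, solver = solver)
    expect_equal(low$members, "A")
  }
  # single compound covering everything qualifies at size 1
  solo <- ci[ci$compound == "A", ]
  attr(solo, "gene_intensity") <- attr(ci, "gene_intensity")
  expect_equal(select_combination(solo, threshold = 1)$size, 1)
})

test_that("greedy matches the exhaustive oracle on random instances", {
  set.seed(19)
  for (rep in 1:25) {
    ci <- random_coverage_instance(n_compounds = sample(3:10, 1))
    if (sum(attr(ci, "gene_intensity")[unique(unlist(ci$genes))]) == 0) next
    ex <- select_combination(ci, threshold = 0.9, solver = "exact")
    gr <- select_combination(ci, threshold = 0.9, solver = "greedy")
    expect_gte(gr$size, ex$size)
    expect_gte(ex$intensity, 0.9 * ex$total_intensity - 1e-9)
    expect_gte(gr$intensity, 0.9 * gr$total_intensity - 1e-9)
    # per-size optima are non-decreasing (monotone union value)
    expect_true(all(diff(ex$per_size$intensity) >= -1e-12))
  }
})

test_that("intensities scale linearly and rankings are scale-invariant", {
  toy <- make_worked_toy()
  opt <- toy$opt
  opt2 <- opt
  opt2$scores$s_moo <- opt$scores$s_moo * 3
  gi1 <- gene_intensity(opt)
  gi2 <- gene_intensity(opt2)
  expect_equal(gi2$intensity, 3 * gi1$intensity)
  ci1 <- compound_intensity(opt, gi1)
  ci2 <- compound_intensity(opt2, gi2)
  expect_equal(ci2$intensity, 3 * ci1$intensity)
  expect_equal(select_combination(ci1)$members,
               select_combination(ci2)$members)
})

test_that("pathway intensity down-weights shared genes and conserves mass", {
  gi <- data.frame(gene = c("G", "H", "Z"), intensity = c(0.6, 0.4, 0.3))
  gsc <- gene_set_collection(list(PA = c("G", "H"), PB = c("G", "X")))
  pw <- pathway_intensity(gi, gsc)
  expect_equal(pw$intensity[pw$pathway == "PA"], 0.3 + 0.4)
  expect_equal(pw$intensity[pw$pathway == "PB"], 0.3)
  # conservation: total pathway intensity = total intensity of annotated genes
  annotated <- intersect(gi$gene, names(gene_set_counts(gsc)))
  expect_equal(sum(pw$intensity),
               sum(gi$intensity[gi$gene %in% annotated]),
               tolerance = 1e-12)
  # pathway sharing no pathogenic genes scores zero
  gsc2 <- gene_set_collection(list(PZ = c("X", "Y")))
  expect_equal(pathway_intensity(gi, gsc2)$intensity, 0)
  expect_equal(pw$rank, seq_len(nrow(pw)))
})

test_that("missing scores and degenerate selections are fatal", {
  toy <- make_worked_toy()
  broken <- toy$opt
  broken$scores$s_moo[1] <- NA
  expect_error(gene_intensity(broken), "s_moo")
  gi <- gene_intensity(toy$opt)
  ci <- compound_intensity(toy$opt, gi)
  expect_error(select_combination(ci, threshold = 1.2), "threshold")
  expect_error(select_combination(ci, solver = "exact", exact_limit = 2),
               "greedy")
  zero <- ci
  attr(zero, "gene_intensity") <- setNames(rep(0, 3), c("G1", "G2", "G3"))
  zero$intensity <- 0
  expect_error(select_combination(zero), "zero")
})
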