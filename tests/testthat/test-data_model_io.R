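props_header <- "compound_id\tname\therb\tmw\tn_hd\tn_ha\tlogp\tn_rot\tob\tcaco2\ttpsa\thepatotoxic"

prop_row <- function(id, herb, name = id) {
  paste(id, name, herb, 300, 2, 4, 2, 3, 50, 1, 40, "FALSE", sep = "\t")
}

test_that("compound reader merges multi-herb rows into one record", {
  f <- withr::local_tempfile(fileext = ".tsv")
  herbs7 <- c("Bai Shao", "Dang Gui", "Fang Feng", "Gan Cao", "Huang Qi",
              "Qiang Huo", "Sheng Jiang")
  writeLines(c(props_header,
               vapply(herbs7, function(h) prop_row("JBD00018", h,
                                                   "Stearic acid"), "")), f)
  suppressMessages(tab <- read_compound_table(f))
  expect_equal(nrow(tab), 1)
  expect_length(tab$herbs[[1]], 7)
  expect_setequal(tab$herbs[[1]], herbs7)
  # herb-merge conservation: (compound, herb) pairs preserved
  expect_equal(attr(tab, "n_herb_pairs"), 7)
})

test_that("compound reader handles empty tables, unions, and conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(props_header, f)
  expect_equal(nrow(read_compound_table(f)), 0)

  writeLines(c(props_header, prop_row("X", "herbA"), prop_row("X", "herbB")),
             f)
  suppressMessages(tab <- read_compound_table(f))
  expect_equal(nrow(tab), 1)
  expect_setequal(tab$herbs[[1]], c("herbA", "herbB"))

  # conflicting properties for the same id are fatal
  bad <- sub("\t300\t", "\t400\t", prop_row("X", "herbB"))
  writeLines(c(props_header, prop_row("X", "herbA"), bad), f)
  expect_error(suppressMessages(read_compound_table(f)), "conflicting")

  # missing required column is fatal and names the column
  writeLines(c(sub("\tmw", "\tweight", props_header),
               prop_row("X", "herbA")), f)
  expect_error(read_compound_table(f), "mw")
})

test_that("edge reader deduplicates, drops pp self-loops, keeps ct scores", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "A\tB", "B\tA", "C\tD"), f)
  pp <- suppressWarnings(read_edge_list(f, kind = "pp"))
  expect_equal(nrow(pp), 2)

  writeLines(c("from\tto", "A\tA", "A\tB"), f)
  expect_warning(pp <- read_edge_list(f, kind = "pp"), "self-loop")
  expect_equal(nrow(pp), 1)

  writeLines(c("compound\ttarget\tscore", "c1\tG1\t0.9", "c1\tG2\t0.4"), f)
  ct <- read_edge_list(f, kind = "ct")
  expect_equal(ct$score, c(0.9, 0.4))
  expect_equal(ct$target, c("G1", "G2"))
})

test_that("GMT round-trips and membership counts are conserved", {
  gsc <- gene_set_collection(list(S1 = c("A", "B", "C", "D", "E"),
                                  S2 = c("D", "E", "F", "G", "H")),
                             category = "pathway")
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, f)
  back <- read_gmt(f, category = "pathway")
  expect_equal(back$sets, gsc$sets)

  counts <- gene_set_counts(gsc)
  expect_equal(unname(counts[c("D", "E")]), c(2L, 2L))
  expect_false("Z" %in% names(counts))  # gene in no set: count 0 (absent)
  # sum of set sizes equals sum of per-gene multiplicities
  expect_equal(sum(lengths(gsc$sets)), sum(counts))

  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc"), f)
  expect_error(read_gmt(f), "line 2")
  expect_error(gene_set_collection(list(S1 = character(0))), "empty")
})

test_that("network export round-trips node and edge sets", {
  net <- build_ctp(c("c1", "c2"),
                   data.frame(compound = c("c1", "c2"), target = c("A", "B")),
                   pathogenic = c("B", "C"),
                   ppi = data.frame(from = c("A", "C"), to = c("C", "D")))
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  back <- read_network(prefix)
  expect_setequal(back$compounds, net$compounds)
  expect_equal(back$proteins[order(back$proteins$gene), ],
               net$proteins[order(net$proteins$gene), ],
               ignore_attr = TRUE)
  expect_equal(back$ct_edges[order(back$ct_edges$compound), ],
               net$ct_edges[order(net$ct_edges$compound), ],
               ignore_attr = TRUE)
  expect_equal(back$pp_edges, net$pp_edges, ignore_attr = TRUE)
  expect_equal(network_stats(back), network_stats(net))

  # optimized networks keep scores and role flags through the round trip
  opt <- toy_optimized(c(A = 0.7), pathogenic = c("B", "C"),
                       ct_edges = data.frame(compound = "c1", target = "A"),
                       pp_edges = data.frame(from = "A", to = "C"))
  write_network(opt, prefix)
  back <- read_network(prefix)
  expect_s3_class(back, "optimized_ctp")
  expect_equal(back$scores$s_moo, 0.7)
  expect_equal(back$model, "moo")

  # empty network exports valid empty tables
  empty_net <- build_ctp("c1", data.frame(compound = "c9", target = "A")[0, ],
                         pathogenic = "P1")
  write_network(empty_net, prefix)
  expect_equal(network_stats(read_network(prefix)),
               network_stats(empty_net))
})

test_that("gene identifiers are case-normalized once at load", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tnf", "Il6", "TNF"), f)
  expect_equal(read_gene_list(f), c("TNF", "IL6"))
})
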