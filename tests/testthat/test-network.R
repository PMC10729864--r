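test_that("scale-free scan isolates the planted power-law subgraph", {
  pairs <- simulate_powerlaw_pairs(n_nodes = 2000, exponent = 2.5, seed = 1)
  sel <- select_scale_free_cutoff(pairs, c(1e-4, 1e-3, 1e-2, 0.5))
  expect_lte(sel$fdr_cutoff, 1e-3)
  got <- sel$fit_report[sel$fit_report$candidate == sel$fdr_cutoff, ]
  expect_gte(got$r_squared, 0.8)
  expect_lt(got$slope, 0)

  # pure random-graph degrees fit a power law worse at every threshold
  set.seed(2)
  g <- igraph::sample_gnm(2000, 6000)
  el <- igraph::as_edgelist(g, names = FALSE)
  er_pairs <- data.frame(gene_i = sprintf("N%05d", el[, 1]),
                         gene_j = sprintf("N%05d", el[, 2]),
                         fdr = 1e-4)
  er <- select_scale_free_cutoff(er_pairs, c(1e-4, 1e-3))
  expect_lt(max(er$fit_report$r_squared, na.rm = TRUE), got$r_squared)
})

test_that("single candidates and undersized networks behave as contracted", {
  pairs <- simulate_powerlaw_pairs(n_nodes = 200, n_noise_edges = 0,
                                   seed = 4)
  sel <- select_scale_free_cutoff(pairs, 0.01)
  expect_equal(sel$fdr_cutoff, 0.01)
  tiny <- pairs[1:3, ]
  expect_error(select_scale_free_cutoff(tiny, 0.01), "insufficient")
})

test_that("edge count is non-increasing as the cutoff tightens", {
  set.seed(5)
  pairs <- data.frame(gene_i = sprintf("x%03d", 1:200),
                      gene_j = sprintf("y%03d", 1:200),
                      fdr = runif(200))
  cuts <- c(0.5, 0.1, 0.01)
  ecounts <- vapply(cuts, function(f)
    igraph::ecount(build_coreg_network(pairs, f)), numeric(1))
  expect_true(all(diff(ecounts) <= 0))
})

test_that("Louvain modules recover disjoint and bridged cliques", {
  g <- make_clique_graph(10, 2, bridged = FALSE)
  part <- detect_modules(g, seed = 1)
  expect_equal(length(unique(part$module)), 2L)
  # module assignment constant within each clique
  for (q in 1:2) {
    mods <- part$module[startsWith(part$gene, paste0("q", q, "_"))]
    expect_equal(length(unique(mods)), 1L)
  }

  gb <- make_clique_graph(10, 2, bridged = TRUE)
  partb <- detect_modules(gb, seed = 1)
  expect_equal(length(unique(partb$module)), 2L)
  # the 2-clique split beats the one-module partition (exhaustive check
  # over the two candidate partitions via igraph's modularity)
  split2 <- as.integer(factor(substr(partb$gene, 1, 2)))
  expect_gt(igraph::modularity(gb, split2),
            igraph::modularity(gb, rep(1L, igraph::vcount(gb))))
  expect_gte(igraph::modularity(gb, partb$module),
             igraph::modularity(gb, rep(1L, igraph::vcount(gb))))
})

test_that("module detection is deterministic, recursive, and bounds-aware", {
  g <- make_clique_graph(8, 4, bridged = TRUE)
  a <- detect_modules(g, seed = 7)
  b <- detect_modules(g, seed = 7)
  expect_identical(a, b)

  # recursion splits any module above the size bound when a split exists
  part <- detect_modules(g, max_module_size = 10, seed = 7)
  expect_true(all(table(part$module[part$module != 0]) <= 10))

  # unassigned label for undersized modules
  g2 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "d"),
                                          c("c", "e"), c("d", "e")),
                                    directed = FALSE)
  p2 <- detect_modules(g2, min_module_size = 3, seed = 1)
  expect_equal(sort(p2$gene[p2$module == 0L]), c("a", "b"))

  empty <- detect_modules(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(nrow(empty), 0L)
})

test_that("annotation interaction density counts shared-term edges", {
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "f")),
    directed = FALSE)
  ann_all <- list(a = "T1", b = "T1", c = "T1", d = "T1", e = "T1", f = "T1")
  expect_equal(annotation_interaction_density(g, ann_all), 1)
  ann_none <- list(a = "T1", b = "T2", c = "T3", d = "T4", e = "T5", f = "T6")
  expect_equal(annotation_interaction_density(g, ann_none), 0)
  # 5 edges; f unannotated -> 4 annotated-both edges, 2 share a term
  ann_half <- list(a = "T1", b = "T1", c = "T2", d = "T2", e = "T3")
  expect_equal(annotation_interaction_density(g, ann_half), 0.5)
  expect_error(annotation_interaction_density(g, list()), "undefined")
})

test_that("density null test separates term-aligned modules from random graphs", {
  # modules aligned with annotation terms: high observed density
  g <- make_clique_graph(8, 3, bridged = FALSE)
  genes <- igraph::V(g)$name
  ann <- setNames(as.list(substr(genes, 1, 2)), genes)
  res <- density_null_test(g, ann, n_random = 50, seed = 3)
  expect_equal(res$observed, 1)
  expect_true(all(res$null_densities < 1))
  expect_equal(res$p_value, 1 / 51)

  # one common term everywhere: observed and null all 1, p = 1
  ann1 <- setNames(as.list(rep("T", length(genes))), genes)
  res1 <- density_null_test(g, ann1, n_random = 10, seed = 3)
  expect_equal(res1$observed, 1)
  expect_true(all(res1$null_densities == 1))
  expect_equal(res1$p_value, 1)

  # determinism
  res2 <- density_null_test(g, ann, n_random = 50, seed = 3)
  expect_identical(res$null_densities, res2$null_densities)

  # degree-preserving rewiring null is available
  res3 <- density_null_test(g, ann, n_random = 10, seed = 4,
                            null = "rewire")
  expect_true(res3$p_value > 0 && res3$p_value <= 1)
})

test_that("GMT files parse and invert into gene-to-term maps", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tg1\tg2\tg3",
               "SET2\tdesc\tg2\tg4"), f)
  gmt <- read_gmt(f)
  expect_equal(names(gmt), c("SET1", "SET2"))
  expect_equal(gmt$SET2, c("g2", "g4"))
  ann <- annotation_map(gmt)
  expect_equal(sort(ann$g2), c("SET1", "SET2"))
  expect_equal(ann$g4, "SET2")
  writeLines("BAD\tonly-two-fields", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("networks export to edge-list TSV and GraphML", {
  pairs <- data.frame(gene_i = c("a", "b"), gene_j = c("b", "c"),
                      fdr = c(1e-4, 1e-3), n = c(5L, 7L))
  g <- build_coreg_network(pairs, 0.01)
  f <- tempfile(fileext = ".tsv")
  export_network(g, f, format = "tsv")
  back <- read.delim(f)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("gene_i", "gene_j", "fdr", "n") %in% names(back)))
  fg <- tempfile(fileext = ".graphml")
  export_network(g, fg, format = "graphml")
  expect_true(file.size(fg) > 0)
  fp <- tempfile(fileext = ".tsv")
  write_partition(detect_modules(g, min_module_size = 1), fp)
  expect_equal(nrow(read.delim(fp)), 3L)
})
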