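test_that("gene_distance counts bases strictly between genes", {
  a <- list(contig_id = "c1", start = 1, end = 1000)
  expect_equal(gene_distance(a, list(contig_id = "c1", start = 251001,
                                     end = 252000)), 250000)
  expect_equal(gene_distance(a, list(contig_id = "c1", start = 251002,
                                     end = 252000)), 250001)
  expect_equal(gene_distance(a, list(contig_id = "c1", start = 500,
                                     end = 2000)), 0)    # overlap
  expect_true(is.na(gene_distance(a, list(contig_id = "c2", start = 5,
                                          end = 10))))
  # symmetry
  b <- list(contig_id = "c1", start = 5000, end = 6000)
  expect_equal(gene_distance(a, b), gene_distance(b, a))
})

test_that("pairwise_coloc classifies pairs at the inclusive threshold", {
  g <- toy_genome(c(1, 251002, 551004), c(1000, 252000, 552000),
                  labels = c("FANCM", "FANCT", "REV3"))
  p <- pairwise_coloc(g, window = 250000)
  expect_equal(nrow(p), 3)                     # complete graph on 3 genes
  # gaps: 250001 (long), 299003 (long), 550003 (long)
  expect_equal(sort(p$coloc_class), c("long_range", "long_range",
                                      "long_range"))
  g2 <- toy_genome(c(1, 251001), c(1000, 252000),
                   labels = c("FANCM", "FANCT"))
  expect_equal(pairwise_coloc(g2)$coloc_class, "colocalized")  # exactly W
})

test_that("pairwise_coloc never pairs across contigs", {
  g <- gene_records(c("a", "b"), "t", c("c1", "c2"), c(1, 1),
                    c(1000, 1000), label = c("FANCM", "FANCT"))
  expect_equal(nrow(pairwise_coloc(g)), 0)
})

test_that("chained pairs get per-gap classes", {
  # four genes with gaps 200 kb / 300 kb / 200 kb along one contig
  s <- c(1, 201002, 502003, 703004)
  e <- c(1000, 202000, 503000, 704000)
  g <- toy_genome(s, e, labels = c("REV3", "FANCT", "MUS81", "SLX1"))
  p <- pairwise_coloc(g, window = 250000)
  expect_equal(nrow(p), 6)
  key <- paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b))
  cls <- stats::setNames(p$coloc_class, key)
  expect_equal(unname(cls[paste("g01", "g02")]), "colocalized")   # 200 kb
  expect_equal(unname(cls[paste("g02", "g03")]), "long_range")    # 300 kb
  expect_equal(unname(cls[paste("g03", "g04")]), "colocalized")   # 200 kb
})

test_that("same-component copies are excluded unless requested", {
  g <- toy_genome(c(1, 5000), c(1000, 6000),
                  labels = c("FANCT", "FANCT"))
  expect_equal(nrow(pairwise_coloc(g)), 0)
  p <- pairwise_coloc(g, include_paralog_pairs = TRUE)
  expect_equal(nrow(p), 1)
  expect_equal(p$component_a, "FANCT")
})

test_that("coloc_fraction counts genes with a colocalized partner", {
  g2 <- toy_genome(c(1, 5000), c(1000, 6000), labels = c("FANCM", "FANCT"))
  expect_equal(coloc_fraction(g2, pairwise_coloc(g2)), 1.0)
  # 10 labeled genes, one colocalized pair -> 0.2
  s <- seq(0, 9) * 1e6 + 1
  labs <- fa_registry()$symbol[1:10]
  g10 <- toy_genome(c(s, 1200), c(s + 999, 2200),
                    labels = c(labs, "FANCT2"))
  g10$label[g10$label == "FANCT2"] <- "FANCT"
  p <- pairwise_coloc(g10, window = 250000)
  expect_equal(sum(p$coloc_class == "colocalized"), 1)
  expect_equal(coloc_fraction(g10[1:10, ], p), 0.2)
  expect_error(coloc_fraction(g2[0, ], p), "no labeled genes")
})

test_that("planted-cluster genomes give the expected coloc fraction", {
  g <- simulate_genome(4, 500, seed = 21)
  # 12 labels: a 3-gene cluster, the rest isolated beyond the window
  pl <- plant_labels(g, K = 12, mode = "clustered", cluster_size = 3,
                     max_span = 250000, seed = 21)
  p <- pairwise_coloc(pl$genes, window = 250000)
  frac <- coloc_fraction(pl$genes, p)
  expect_gte(frac, 0.25)  # at least the planted cluster is colocalized
  clustered <- unique(c(p$gene_a, p$gene_b)[rep(p$coloc_class ==
                                                  "colocalized", 2)])
  expect_true(all(pl$truth$cluster_gene_ids %in% clustered))
})

test_that("pair_network weights edges by contributing taxa", {
  mk <- function(tax) {
    g <- toy_genome(c(1, 5000), c(1000, 6000), taxon = tax,
                    labels = c("FANCT", "REV3"))
    pairwise_coloc(g)
  }
  pairs <- rbind(mk("t1"), mk("t2"), mk("t3"))
  net <- pair_network(pairs)
  expect_equal(nrow(net), 1)
  expect_equal(net$component_a, "FANCT")
  expect_equal(net$component_b, "REV3")
  expect_equal(net$n_taxa, 3L)
  expect_equal(nrow(pair_network(pairs[0, ])), 0)
  # graphml export is readable by igraph
  path <- file.path(withr::local_tempdir(), "net.graphml")
  write_pair_network(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), 1)
})

test_that("focal_neighbor_prob matches brute-force slot enumeration", {
  # spec of the slot model: K-1 labels over N-1 positions, d = 2m marked
  expect_equal(focal_neighbor_prob(11, 3, 2), 1 - choose(8, 4) / choose(10, 4))
  expect_equal(focal_neighbor_prob(11, 3, 2), oracle_slot_prob(11, 3, 4))
  for (cfg in list(c(8, 2, 1), c(9, 4, 2), c(12, 5, 3))) {
    N <- cfg[1]; K <- cfg[2]; m <- cfg[3]
    expect_equal(focal_neighbor_prob(N, K, m),
                 oracle_slot_prob(N, K, min(2 * m, N - 1)),
                 tolerance = 1e-12)
  }
  expect_equal(focal_neighbor_prob(100, 1, 10), 0)    # K = 1
  expect_equal(focal_neighbor_prob(10, 2, 0), 0)      # d = 0
  expect_equal(focal_neighbor_prob(10, 3, 5), 1)      # d = N - 1
  expect_error(focal_neighbor_prob(1, 1, 1), "bounds")
  # monotone in K and in m
  pk <- vapply(2:8, function(k) focal_neighbor_prob(50, k, 3), 1)
  pm <- vapply(0:10, function(m) focal_neighbor_prob(50, 4, m), 1)
  expect_false(is.unsorted(pk))
  expect_false(is.unsorted(pm))
})

test_that("analytic_pvalue is a binomial upper tail in x_obs", {
  expect_equal(analytic_pvalue(100, 5, 10, 0), 1)
  pf <- focal_neighbor_prob(100, 2, 10)
  expect_equal(analytic_pvalue(100, 2, 10, 2), pf^2)  # documented square
  px <- vapply(0:5, function(x) analytic_pvalue(100, 5, 10, x), 1)
  expect_false(is.unsorted(rev(px)))                  # non-increasing
  expect_error(analytic_pvalue(100, 5, 10, 6), "bounds")
})

test_that("permutation statistic agrees with the R oracle", {
  set.seed(99)
  for (rep in 1:5) {
    g <- simulate_genome(3, 60, seed = 400 + rep)
    pl <- plant_labels(g, K = 10, mode = "uniform", seed = 500 + rep)
    pv <- permutation_pvalue(pl$genes, window = 250000, B = 1, seed = 1)
    idx <- which(!is.na(pl$genes$label))
    expect_equal(pv$x_obs, oracle_stat(pl$genes, idx, 250000))
  }
})

test_that("permutation p-value honors degenerate configurations", {
  # K = N on one dense contig: every permutation identical
  g <- constant_genome(6, len = 500, gap = 100)
  g$label <- fa_registry()$symbol[1:6]
  pv <- permutation_pvalue(g, window = 1e4, B = 200, seed = 3)
  expect_equal(pv$p_perm, 1)
  expect_true(all(pv$x_null == pv$x_obs))
  # K = 1: no neighbor possible
  g1 <- constant_genome(10)
  g1$label[4] <- "FANCM"
  pv1 <- permutation_pvalue(g1, window = 1e5, B = 100, seed = 3)
  expect_equal(pv1$x_obs, 0)
  expect_equal(pv1$p_perm, 1)
  expect_gte(min(pv1$p_perm), 1 / 101)
})

test_that("permutation p-values are bit-reproducible under a seed", {
  g <- simulate_genome(2, 200, seed = 6)
  pl <- plant_labels(g, K = 8, mode = "uniform", seed = 6)
  a <- permutation_pvalue(pl$genes, B = 500, seed = 11)
  b <- permutation_pvalue(pl$genes, B = 500, seed = 11)
  expect_identical(a, b)
  c <- permutation_pvalue(pl$genes, B = 500, seed = 12)
  expect_false(identical(a$x_null, c$x_null))
})

test_that("run_coloc_test assembles the full per-genome result", {
  g <- constant_genome(10)
  g$label[4] <- "FANCM"
  res <- run_coloc_test(g, window = 1e5, B = 100, seed = 2)
  expect_s3_class(res, "coloc_test")
  expect_equal(res$n_fa, 1)
  expect_equal(res$p_analytic, 1)
  expect_equal(res$p_perm, 1)
  expect_false(res$significant)
  expect_equal(res$seed, 2L)
  expect_equal(res$n_permutations, 100L)
  tab <- coloc_test_table(list(res, res), bh = TRUE)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_perm_bh >= tab$p_perm))
})
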