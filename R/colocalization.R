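#' Genomic distance between two genes
#'
#' The number of bases strictly between two genes on the same contig:
#' `max(0, downstream_start - upstream_end - 1)` where upstream is the gene
#' with the smaller start. Overlapping genes are at distance 0; genes on
#' different contigs have no defined distance (`NA`). Symmetric; strand is
#' ignored.
#'
#' @param a,b Single gene records (one-row data.frames or lists with
#'   `contig_id`, `start`, `end`).
#' @return Distance in bp, or `NA_real_` across contigs.
#' @export
#' @examples
#' a <- list(contig_id = "c1", start = 1, end = 1000)
#' b <- list(contig_id = "c1", start = 251001, end = 252000)
#' gene_distance(a, b)  # 250000: at the inclusive 250 kb threshold
gene_distance <- function(a, b) {
  if (a$contig_id[1] != b$contig_id[1]) return(NA_real_)
  if (a$start[1] <= b$start[1]) {
    max(0, b$start[1] - a$end[1] - 1)
  } else {
    max(0, a$start[1] - b$end[1] - 1)
  }
}

#' Classify all same-contig pathway-gene pairs by distance
#'
#' Enumerates unordered pairs of labeled genes sharing a contig and
#' classifies each as `colocalized` (distance <= `window`, inclusive at
#' exactly the threshold) or `long_range`. Pairs between two copies of the
#' same component are excluded unless `include_paralog_pairs = TRUE`.
#'
#' @param genes A gene table; labeled genes are rows with non-missing
#'   `label`.
#' @param window Distance threshold in bp, default 250 kb.
#' @param include_paralog_pairs Keep pairs whose two genes carry the same
#'   component label.
#' @return A data.frame with one row per pair: `taxon_id`, `component_a`,
#'   `component_b` (sorted so `component_a <= component_b`), `gene_a`,
#'   `gene_b`, `contig_id`, `distance`, `coloc_class`; ordered by (taxon,
#'   contig, start).
#' @export
pairwise_coloc <- function(genes, window = 250000,
                           include_paralog_pairs = FALSE) {
  stopifnot(window > 0)
  genes <- validate_genes(genes)
  fa <- genes[!is.na(genes$label), , drop = FALSE]
  empty <- data.frame(taxon_id = character(0), component_a = character(0),
                      component_b = character(0), gene_a = character(0),
                      gene_b = character(0), contig_id = character(0),
                      distance = numeric(0), coloc_class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fa) < 2) return(empty)
  out <- list()
  grp <- paste(fa$taxon_id, fa$contig_id, sep = "\r")
  for (g in unique(grp)) {
    f <- fa[grp == g, , drop = FALSE]      # already sorted by start
    n <- nrow(f)
    if (n < 2) next
    ij <- combn(n, 2)
    i <- ij[1, ]
    j <- ij[2, ]
    dist <- pmax(0, f$start[j] - f$end[i] - 1)
    swap <- f$label[i] > f$label[j]
    comp_a <- ifelse(swap, f$label[j], f$label[i])
    comp_b <- ifelse(swap, f$label[i], f$label[j])
    gene_a <- ifelse(swap, f$gene_id[j], f$gene_id[i])
    gene_b <- ifelse(swap, f$gene_id[i], f$gene_id[j])
    keep <- if (include_paralog_pairs) rep(TRUE, length(i)) else
      comp_a != comp_b
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      taxon_id = f$taxon_id[1],
      component_a = comp_a[keep], component_b = comp_b[keep],
      gene_a = gene_a[keep], gene_b = gene_b[keep],
      contig_id = f$contig_id[1],
      distance = dist[keep],
      coloc_class = ifelse(dist[keep] <= window, "colocalized",
                           "long_range"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of pathway genes with a colocalized partner
#'
#' The number of labeled genes appearing in at least one `colocalized` pair
#' divided by the number of labeled genes (distinct loci, not copies).
#'
#' @param genes A gene table (labeled rows define the denominator).
#' @param pairs Output of [pairwise_coloc()] on the same genes.
#' @return A fraction in `[0, 1]`.
#' @export
coloc_fraction <- function(genes, pairs) {
  genes <- validate_genes(genes)
  fa <- genes[!is.na(genes$label), , drop = FALSE]
  if (nrow(fa) == 0) stop("no labeled genes")
  cp <- pairs[pairs$coloc_class == "colocalized", , drop = FALSE]
  hit <- unique(c(paste(cp$taxon_id, cp$gene_a, sep = "\r"),
                  paste(cp$taxon_id, cp$gene_b, sep = "\r")))
  mean(paste(fa$taxon_id, fa$gene_id, sep = "\r") %in% hit)
}

#' Cross-taxon component co-occurrence network
#'
#' Aggregates pair calls into one weighted edge per unordered component
#' pair, the weight counting the distinct taxa contributing at least one
#' pair of the requested class.
#'
#' @param pairs Output of [pairwise_coloc()], possibly pooled across taxa.
#' @param class_filter Which pair class to aggregate: `"colocalized"`
#'   (default) or `"long_range"`.
#' @return A data.frame with columns `component_a`, `component_b`,
#'   `n_taxa`, sorted by decreasing weight.
#' @export
pair_network <- function(pairs,
                         class_filter = c("colocalized", "long_range")) {
  class_filter <- match.arg(class_filter)
  empty <- data.frame(component_a = character(0), component_b = character(0),
                      n_taxa = integer(0), stringsAsFactors = FALSE)
  p <- pairs[pairs$coloc_class == class_filter, , drop = FALSE]
  if (nrow(p) == 0) return(empty)
  u <- unique(p[c("taxon_id", "component_a", "component_b")])
  agg <- stats::aggregate(taxon_id ~ component_a + component_b, data = u,
                          FUN = length)
  names(agg)[3] <- "n_taxa"
  agg <- agg[order(-agg$n_taxa, agg$component_a, agg$component_b), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a co-occurrence network as GraphML (or TSV)
#'
#' GraphML output (via igraph) loads directly in Cytoscape-style viewers;
#' edge weights are stored in the `n_taxa` attribute.
#'
#' @param edges Output of [pair_network()].
#' @param path Output path.
#' @param format `"graphml"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pair_network <- function(edges, path,
                               format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Probability a focal pathway gene has a pathway neighbor within a window
#'
#' Analytic approximation used by the closed-form co-localization test.
#' With `N` genes, `K` of them pathway-labeled, and `m` expected gene slots
#' per window side (see [genes_per_window()]), the two-sided neighborhood of
#' a focal labeled gene covers `d = min(2m, N - 1)` of the other `N - 1`
#' gene positions. Under uniform placement of the remaining `K - 1` labels,
#' the probability that at least one lands in the neighborhood is the
#' hypergeometric complement of the zero class:
#' `1 - choose(N - K, d) / choose(N - 1, d)` (computed in log space).
#' Returns 0 when `K = 1` or `d = 0`. Contig-end effects are ignored, as the
#' average-based construction implies; the permutation null handles them
#' exactly.
#'
#' @param N Total gene count (>= 2).
#' @param K Labeled gene count, `1 <= K <= N`.
#' @param m Expected gene slots per window side (>= 0).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' focal_neighbor_prob(11, 3, 2)  # 1 - choose(8, 4) / choose(10, 4)
focal_neighbor_prob <- function(N, K, m) {
  if (N < 2 || K < 1 || K > N || m < 0) stop("violated bounds: need N >= 2, 1 <= K <= N, m >= 0")
  if (K == 1) return(0)
  d <- min(2 * m, N - 1)
  if (d == 0) return(0)
  if (d > N - K) return(1)
  p <- 1 - exp(lchoose(N - K, d) - lchoose(N - 1, d))
  min(max(p, 0), 1)
}

#' Analytic co-localization p-value
#'
#' Upper-tail probability `P(X >= x_obs)` for the statistic `X` = number of
#' labeled genes with at least one labeled neighbor within the window, under
#' the independence approximation `X ~ Binomial(K, p_focal)` with `p_focal`
#' from [focal_neighbor_prob()].
#'
#' This closed form is an approximation: colocalization events flag two
#' genes at once, so `X` is over-dispersed relative to a binomial. In the
#' two-gene case the exact p-value equals `p_focal` while the binomial gives
#' `p_focal^2`. The approximation is accurate when expected colocalized
#' pairs are far below 1 (and in the saturated regime); the permutation
#' p-value ([permutation_pvalue()]) is authoritative in between.
#'
#' @param N,K,m As in [focal_neighbor_prob()].
#' @param x_obs Observed statistic, `0 <= x_obs <= K`.
#' @return p-value in `[0, 1]`; 1 when `x_obs = 0`.
#' @export
analytic_pvalue <- function(N, K, m, x_obs) {
  if (x_obs < 0 || x_obs > K) stop("violated bounds: need 0 <= x_obs <= K")
  if (x_obs == 0) return(1)
  p_focal <- focal_neighbor_prob(N, K, m)
  pbinom(x_obs - 1, K, p_focal, lower.tail = FALSE)
}

# Encode a single-taxon gene table for the C++ statistic: genes sorted by
# (contig, start), contigs as integer codes.
coloc_encode <- function(genes) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0) stop("no genes")
  if (length(unique(genes$taxon_id)) > 1) {
    stop("co-localization tests operate on a single taxon")
  }
  list(contig = as.integer(factor(genes$contig_id)),
       start = genes$start, end = genes$end,
       labeled = which(!is.na(genes$label)), genes = genes)
}

#' Permutation p-value for pathway-gene co-localization
#'
#' The authoritative null for the co-localization test: pathway labels are
#' reassigned uniformly without replacement over all gene positions
#' (coordinates and contig structure fixed), and the statistic `X` = number
#' of labeled genes with at least one labeled neighbor within `window` on
#' the same contig is recomputed for each of `B` draws. The p-value uses the
#' add-one estimator `p = (1 + #\{X_b >= x_obs\}) / (B + 1)`, so
#' `p >= 1/(B+1)`. Bit-reproducible for a given `seed`.
#'
#' @param genes A single-taxon gene table whose labeled rows (non-missing
#'   `label`) define the observed statistic.
#' @param window Window in bp, default 250 kb.
#' @param B Number of permutations (>= 1), default 10000.
#' @param seed Integer seed governing all draws.
#' @return A list with `x_obs`, `x_null` (integer vector of length `B`),
#'   `p_perm`, `B`, `seed`.
#' @export
permutation_pvalue <- function(genes, window = 250000, B = 10000, seed = 1) {
  stopifnot(B >= 1, window > 0)
  enc <- coloc_encode(genes)
  K <- length(enc$labeled)
  if (K < 1) stop("no labeled genes")
  x_obs <- coloc_stat_cpp(enc$labeled - 1L, enc$contig, enc$start, enc$end,
                          window)
  set.seed(seed)
  x_null <- coloc_perm_cpp(K, enc$contig, enc$start, enc$end, window,
                           as.integer(B))
  list(x_obs = x_obs, x_null = x_null,
       p_perm = (1 + sum(x_null >= x_obs)) / (B + 1),
       B = as.integer(B), seed = as.integer(seed))
}

#' Per-genome co-localization test
#'
#' Assembles the whole per-genome test: genome geometry ([genome_stats()]),
#' window slot count `m` ([genes_per_window()]), the observed statistic, the
#' analytic approximation ([analytic_pvalue()]) and the permutation p-value
#' ([permutation_pvalue()]). Significance is decided on the permutation
#' p-value at `alpha`. The number of colocalized distinct-component pairs is
#' reported as a secondary, descriptive statistic.
#'
#' @param genes A single-taxon gene table with pathway labels.
#' @param window Window in bp, default 250 kb.
#' @param B Permutations, default 10000.
#' @param seed Integer seed.
#' @param alpha Significance level on the permutation p-value, default 0.01.
#' @return An object of class `coloc_test`: a list echoing all inputs plus
#'   `n_genes`, `n_fa`, `m`, `x_obs`, `p_analytic`, `p_perm`,
#'   `n_permutations`, `significant`, `n_pairs_colocalized`, `x_null`.
#' @export
#' @examples
#' g <- simulate_genome(2, 100, seed = 5)
#' g <- plant_labels(g, K = 8, mode = "clustered", cluster_size = 5,
#'                   max_span = 1e5, seed = 5)$genes
#' run_coloc_test(g, B = 500, seed = 5)
run_coloc_test <- function(genes, window = 250000, B = 10000, seed = 1,
                           alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  st <- genome_stats(genes)
  m <- genes_per_window(st, window)
  perm <- permutation_pvalue(genes, window = window, B = B, seed = seed)
  K <- sum(!is.na(genes$label))
  p_analytic <- analytic_pvalue(st$n_genes, K, m, perm$x_obs)
  pairs <- pairwise_coloc(genes, window = window)
  structure(
    list(taxon_id = st$taxon_id, n_genes = st$n_genes, n_fa = K,
         window = window, m = m, x_obs = perm$x_obs,
         p_analytic = p_analytic, p_perm = perm$p_perm,
         n_permutations = perm$B, seed = perm$seed, alpha = alpha,
         significant = perm$p_perm < alpha,
         n_pairs_colocalized = sum(pairs$coloc_class == "colocalized"),
         x_null = perm$x_null),
    class = "coloc_test"
  )
}

#' @export
print.coloc_test <- function(x, ...) {
  cat("\n\tPathway-gene co-localization test (label permutation)\n\n")
  cat(sprintf("taxon: %s   genes: %d   labeled: %d   window: %g bp\n",
              x$taxon_id, x$n_genes, x$n_fa, x$window))
  cat(sprintf("m (slots per window side) = %d\n", x$m))
  cat(sprintf("X = %d labeled genes with a labeled neighbor within window\n",
              x$x_obs))
  cat(sprintf("colocalized distinct-component pairs: %d\n",
              x$n_pairs_colocalized))
  cat(sprintf("p (permutation, B = %d, seed = %d) = %.4g\n",
              x$n_permutations, x$seed, x$p_perm))
  cat(sprintf("p (analytic binomial approximation) = %.4g\n", x$p_analytic))
  cat(sprintf("significant at alpha = %g (permutation p): %s\n", x$alpha,
              x$significant))
  invisible(x)
}

#' @export
as.data.frame.coloc_test <- function(x, ...) {
  data.frame(taxon_id = x$taxon_id, n_genes = x$n_genes, n_fa = x$n_fa,
             window = x$window, m = x$m, x_obs = x$x_obs,
             p_analytic = x$p_analytic, p_perm = x$p_perm,
             n_permutations = x$n_permutations, seed = x$seed,
             alpha = x$alpha, significant = x$significant,
             n_pairs_colocalized = x$n_pairs_colocalized,
             stringsAsFactors = FALSE)
}

#' @export
plot.coloc_test <- function(x, ...) {
  graphics::hist(x$x_null, breaks = seq(-0.5, max(x$x_null, x$x_obs) + 0.5),
                 main = "Permutation null of X", xlab = "X", ...)
  graphics::abline(v = x$x_obs, col = "red", lwd = 2)
  invisible(x)
}

#' Tabulate co-localization tests across genomes
#'
#' Binds per-genome [run_coloc_test()] results into one table, optionally
#' adding Benjamini-Hochberg adjusted permutation p-values (the per-genome
#' test itself applies no multiplicity correction).
#'
#' @param tests A list of `coloc_test` objects.
#' @param bh Add a `p_perm_bh` column (and `significant_bh` at each test's
#'   alpha)?
#' @return A data.frame with one row per genome.
#' @export
coloc_test_table <- function(tests, bh = FALSE) {
  tab <- do.call(rbind, lapply(tests, as.data.frame))
  if (bh) {
    tab$p_perm_bh <- p.adjust(tab$p_perm, method = "BH")
    tab$significant_bh <- tab$p_perm_bh < tab$alpha
  }
  tab
}
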