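# Shared fixtures and independent oracles for the test suite.

# A small hand-positioned single-contig genome.
toy_genome <- function(starts, ends, contig = "c1", taxon = "toy",
                       labels = NA_character_) {
  gene_records(sprintf("g%02d", seq_along(starts)), taxon, contig,
               starts, ends, label = labels)
}

# Write a GFF3 fixture file and return its path.
write_gff_fixture <- function(lines) {
  path <- tempfile("fixture", fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Independent R-level oracle for the co-localization statistic: number of
# labeled genes with >= 1 labeled neighbor within `window`, computed by a
# plain double loop over gene_distance(). Deliberately does not share code
# with the compiled statistic.
oracle_stat <- function(genes, labeled_idx, window) {
  k <- length(labeled_idx)
  if (k < 2) return(0L)
  has <- logical(k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d <- gene_distance(genes[labeled_idx[i], ], genes[labeled_idx[j], ])
      if (!is.na(d) && d <= window) {
        has[i] <- TRUE
        has[j] <- TRUE
      }
    }
  }
  sum(has)
}

# Exact null distribution of the statistic by exhaustive enumeration of all
# choose(N, K) label placements (tiny N only).
oracle_null_distribution <- function(genes, K, window) {
  placements <- combn(nrow(genes), K)
  apply(placements, 2, function(idx) oracle_stat(genes, idx, window))
}

# Brute-force zero-class mass of the analytic slot model: K - 1 labels
# placed uniformly over N - 1 slots of which the first d are "within the
# window"; returns P(at least one label in the d slots) by enumeration.
oracle_slot_prob <- function(N, K, d) {
  if (K == 1 || d == 0) return(0)
  placements <- combn(N - 1, K - 1)
  mean(apply(placements, 2, function(idx) any(idx <= d)))
}

# A constant-geometry genome: gene length `len`, gap `gap`, so gene i sits
# at [(i-1)(len+gap) + gap + 1, (i-1)(len+gap) + gap + len].
constant_genome <- function(n, len = 1000, gap = 1000, contig = "c1") {
  s <- (seq_len(n) - 1) * (len + gap) + gap + 1
  toy_genome(s, s + len - 1, contig = contig)
}
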