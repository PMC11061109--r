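# Derive a bounded sub-seed from a global seed (fixed offsets per
# generator, so adding a generator does not perturb existing draws).
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

# Draw n positive integer lengths/gaps from a distribution spec: a single
# number (constant) or list(<name>, ...) with <name> in lognormal /
# exponential / uniform.
draw_dist <- function(n, spec, minimum = 1) {
  if (is.numeric(spec) && length(spec) == 1) {
    if (spec < minimum) stop("constant distribution value below ", minimum)
    return(rep(as.numeric(spec), n))
  }
  if (!is.list(spec) || length(spec) < 1) {
    stop("distribution spec must be a number or a list")
  }
  name <- spec[[1]]
  x <- switch(name,
    lognormal = rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    exponential = rexp(n, rate = 1 / spec$mean),
    uniform = runif(n, spec$min, spec$max),
    stop("unknown distribution: ", name)
  )
  if (any(!is.finite(x))) stop("invalid distribution parameters")
  pmax(minimum, round(x))
}

#' Simulate a multi-contig genome annotation
#'
#' Lays genes sequentially along each contig: a leading intergenic gap, then
#' alternating gene/gap draws, so `start_1 = 1 + gap_0`,
#' `end_i = start_i + length_i - 1`, `start_(i+1) = end_i + 1 + gap_i`.
#' Defaults emulate compact fungal genomes (log-normal gene lengths with
#' median 1.5 kb, exponential intergenic gaps with mean 1 kb), placing the
#' expected gene slots per 250 kb window in the order-100 regime typical of
#' fungal assemblies. Fully deterministic given the seed.
#'
#' @param n_contigs Number of contigs.
#' @param genes_per_contig Genes per contig: scalar or vector of length
#'   `n_contigs`.
#' @param gene_length Gene length distribution: a constant (bp) or
#'   `list("lognormal", meanlog=, sdlog=)` /
#'   `list("exponential", mean=)` / `list("uniform", min=, max=)`.
#' @param intergenic_gap Intergenic gap distribution, same forms; gaps may
#'   round to 0 (adjacent genes).
#' @param taxon_id Taxon identifier for the records.
#' @param seed Integer seed.
#' @return A gene table (see [gene_records()]), unlabeled.
#' @export
#' @examples
#' g <- simulate_genome(1, 3, gene_length = 1000, intergenic_gap = 1000,
#'                      seed = 1)
#' g[, c("start", "end")]  # 1001-2000, 3001-4000, 5001-6000
simulate_genome <- function(n_contigs = 5, genes_per_contig = 400,
                            gene_length = list("lognormal",
                                               meanlog = log(1500),
                                               sdlog = 0.6),
                            intergenic_gap = list("exponential",
                                                  mean = 1000),
                            taxon_id = "synthetic", seed = 1) {
  stopifnot(n_contigs >= 1)
  npc <- rep_len(as.integer(genes_per_contig), n_contigs)
  if (any(npc < 1)) stop("genes_per_contig must be >= 1")
  set.seed(seed)
  total <- sum(npc)
  lens <- draw_dist(total, gene_length, minimum = 1)
  gaps <- draw_dist(total, intergenic_gap, minimum = 0)
  strand <- sample(c("+", "-"), total, replace = TRUE)
  contig <- rep(sprintf("ctg%02d", seq_len(n_contigs)), npc)
  starts <- numeric(total)
  ends <- numeric(total)
  pos <- 1L
  for (c_i in seq_len(n_contigs)) {
    idx <- pos:(pos + npc[c_i] - 1L)
    l <- lens[idx]
    g <- gaps[idx]
    s <- cumsum(g) + c(0, cumsum(l)[-length(l)]) + 1
    starts[idx] <- s
    ends[idx] <- s + l - 1
    pos <- pos + npc[c_i]
  }
  gene_records(sprintf("%s_g%05d", taxon_id, seq_len(total)), taxon_id,
               contig, starts, ends, strand)
}

#' Plant pathway labels on a simulated genome
#'
#' Defines the null and alternative for the co-localization test. In
#' `uniform` mode, `K` labels are placed without replacement over all
#' genes. In `clustered` mode, `cluster_size` labels go on a run of
#' consecutive same-contig genes whose pairwise distances all fit within
#' `max_span`, and the remaining `K - cluster_size` labels are placed
#' uniformly over genes farther than `max_span` from every cluster gene (so
#' the planted signal is exactly the cluster). Labels are distinct registry
#' component symbols assigned in genome order.
#'
#' @param genes A gene table.
#' @param K Total labels, `K <= nrow(genes)`.
#' @param mode `"uniform"` or `"clustered"`.
#' @param cluster_size Labels in the planted cluster (clustered mode).
#' @param max_span Maximum pairwise distance within the cluster, bp.
#' @param seed Integer seed.
#' @param components Symbols to assign; defaults to the first `K` registry
#'   symbols. Must supply at least `K`.
#' @param registry Registry providing default symbols.
#' @return A list: `genes` (labels filled in), `truth` (list with
#'   `fa_gene_ids`, `cluster_gene_ids`, `label_map` named gene->component,
#'   `mode`, `max_span`).
#' @export
plant_labels <- function(genes, K, mode = c("uniform", "clustered"),
                         cluster_size = 5, max_span = 1e5, seed = 1,
                         components = NULL, registry = fa_registry()) {
  mode <- match.arg(mode)
  genes <- validate_genes(genes)
  N <- nrow(genes)
  if (K > N) stop("K exceeds the number of genes")
  if (is.null(components)) components <- registry$symbol
  if (K > length(components)) {
    stop("need at least K component symbols (pass `components` with ",
         "repeats to allow multi-copy labels)")
  }
  set.seed(seed)
  if (mode == "uniform") {
    idx <- sort(sample.int(N, K))
    cluster_idx <- integer(0)
  } else {
    if (cluster_size > K) stop("cluster_size must be <= K")
    if (cluster_size < 2) stop("cluster_size must be >= 2")
    # Vectorized prefilter on the outer pair of each run (exact for
    # non-overlapping layouts, where ends are monotone); the sampled run is
    # then verified pairwise, with a full exact pass as fallback.
    last <- seq_len(N - cluster_size + 1) + cluster_size - 1
    first <- seq_len(N - cluster_size + 1)
    cand <- which(genes$contig_id[first] == genes$contig_id[last] &
                  pmax(0, genes$start[last] - genes$end[first] - 1) <=
                    max_span)
    exact_ok <- function(i) {
      max_pair_distance(genes[i:(i + cluster_size - 1), ]) <= max_span
    }
    if (length(cand) == 0) {
      stop("no same-contig run of ", cluster_size, " genes fits max_span")
    }
    anchor <- cand[sample.int(length(cand), 1)]
    if (!exact_ok(anchor)) {
      cand <- cand[vapply(cand, exact_ok, logical(1))]
      if (length(cand) == 0) {
        stop("no same-contig run of ", cluster_size, " genes fits max_span")
      }
      anchor <- cand[sample.int(length(cand), 1)]
    }
    cluster_idx <- anchor:(anchor + cluster_size - 1)
    pool <- setdiff(which(!near_cluster(genes, cluster_idx, max_span)),
                    cluster_idx)
    need <- K - cluster_size
    if (length(pool) < need) {
      stop("not enough genes outside the cluster neighborhood")
    }
    extra <- if (need > 0) sort(sample(pool, need)) else integer(0)
    idx <- sort(c(cluster_idx, extra))
  }
  genes$label[idx] <- components[seq_len(K)]
  truth <- list(fa_gene_ids = genes$gene_id[idx],
                cluster_gene_ids = genes$gene_id[cluster_idx],
                label_map = stats::setNames(genes$label[idx],
                                            genes$gene_id[idx]),
                mode = mode, max_span = max_span)
  list(genes = genes, truth = truth)
}

# Largest pairwise intergenic distance within a (sorted) gene run.
max_pair_distance <- function(run) {
  n <- nrow(run)
  ij <- combn(n, 2)
  max(pmax(0, run$start[ij[2, ]] - run$end[ij[1, ]] - 1))
}

# Logical mask: genes within max_span of any gene in cluster_idx (same
# contig), cluster members included.
near_cluster <- function(genes, cluster_idx, max_span) {
  near <- logical(nrow(genes))
  near[cluster_idx] <- TRUE
  for (k in cluster_idx) {
    same <- genes$contig_id == genes$contig_id[k]
    d <- ifelse(genes$start >= genes$start[k],
                genes$start - genes$end[k] - 1,
                genes$start[k] - genes$end - 1)
    near <- near | (same & pmax(0, d) <= max_span)
  }
  near
}

#' Simulate a homology-hit table with planted truth
#'
#' True homologs receive e-values `10^-U(10, 100)` and dominant bitscores
#' for their true component plus one weaker cross-component hit; decoys
#' receive e-values `10^-U(0, 4.5)` only (all above the 1e-5 screening
#' cutoff), so the e-value filter retains exactly the true homologs and
#' best-bitscore assignment recovers the planted map. A matching domain
#' table is generated: each true protein carries the first diagnostic Pfam
#' accession of its component (components without accessions get no
#' domain); optionally, `n_wrong_domain` true proteins instead receive a
#' non-diagnostic accession so the domain gate has known victims.
#'
#' @param truth Named character vector: protein id -> component symbol.
#' @param n_decoys Number of decoy proteins.
#' @param seed Integer seed.
#' @param taxon_id Taxon for all hits.
#' @param registry Pathway registry.
#' @param fusions Optional data.frame (`protein_id`, `component_n`,
#'   `component_c`): each fusion protein gets strong hits to both components
#'   with disjoint target intervals and both diagnostic domains (N-terminal
#'   at 10-200 aa, C-terminal at 1500-1700 aa).
#' @param n_wrong_domain Number of true proteins given a wrong (non
#'   diagnostic) domain accession.
#' @return A list: `hits`, `domains`, `assignment` (expected post-filter
#'   best-hit map, named protein -> component), `wrong_domain_ids`.
#' @export
simulate_hit_table <- function(truth, n_decoys = 0, seed = 1,
                               taxon_id = "synthetic",
                               registry = fa_registry(), fusions = NULL,
                               n_wrong_domain = 0) {
  set.seed(seed)
  diag <- registry_pfam(registry)
  mk <- function(component, protein, evalue, bitscore, s, e) {
    data.frame(component = component, target_protein_id = protein,
               taxon_id = taxon_id, evalue = evalue, bitscore = bitscore,
               target_start = s, target_end = e, stringsAsFactors = FALSE)
  }
  hits <- list()
  domains <- list()
  n_true <- length(truth)
  if (n_true > 0) {
    prot <- names(truth)
    comp <- resolve_component(unname(truth), registry)
    s <- round(runif(n_true, 1, 50))
    e <- s + round(runif(n_true, 150, 400))
    hits[[1]] <- mk(comp, prot, 10^-runif(n_true, 10, 100),
                    runif(n_true, 250, 500), s, e)
    other <- vapply(comp, function(cc) {
      sample(setdiff(registry$symbol, cc), 1)
    }, character(1))
    hits[[2]] <- mk(other, prot, 10^-runif(n_true, 6, 9),
                    hits[[1]]$bitscore - runif(n_true, 75, 150), s, e)
    has_acc <- lengths(diag[comp]) > 0
    acc <- rep(NA_character_, n_true)
    acc[has_acc] <- vapply(diag[comp[has_acc]], `[`, character(1), 1)
    wrong_ids <- character(0)
    if (n_wrong_domain > 0) {
      eligible <- which(has_acc)
      if (n_wrong_domain > length(eligible)) {
        stop("n_wrong_domain exceeds proteins with diagnostic accessions")
      }
      w <- sample(eligible, n_wrong_domain)
      wrong_ids <- prot[w]
      all_acc <- unique(unlist(diag, use.names = FALSE))
      for (k in w) {
        acc[k] <- sample(setdiff(all_acc, diag[[comp[k]]]), 1)
      }
    }
    keep <- !is.na(acc)
    if (any(keep)) {
      domains[[1]] <- domain_annotations(prot[keep], acc[keep],
                                         rep(25, sum(keep)),
                                         rep(275, sum(keep)))
    }
  } else {
    wrong_ids <- character(0)
  }
  expected <- if (n_true > 0) stats::setNames(comp, prot) else
    stats::setNames(character(0), character(0))
  if (n_decoys > 0) {
    dprot <- sprintf("decoy_%03d", seq_len(n_decoys))
    dcomp <- sample(registry$symbol, n_decoys, replace = TRUE)
    ds <- round(runif(n_decoys, 1, 50))
    hits[[length(hits) + 1]] <- mk(dcomp, dprot,
                                   10^-runif(n_decoys, 0, 4.5),
                                   runif(n_decoys, 30, 60),
                                   ds, ds + round(runif(n_decoys, 50, 150)))
  }
  if (!is.null(fusions)) {
    for (i in seq_len(nrow(fusions))) {
      cn <- resolve_component(fusions$component_n[i], registry)
      cc <- resolve_component(fusions$component_c[i], registry)
      if (length(diag[[cn]]) == 0 || length(diag[[cc]]) == 0) {
        stop("fusion components must have diagnostic accessions")
      }
      pid <- fusions$protein_id[i]
      hits[[length(hits) + 1]] <- rbind(
        mk(cn, pid, 1e-50, 500, 10, 200),
        mk(cc, pid, 1e-45, 480, 1500, 1700))
      domains[[length(domains) + 1]] <- domain_annotations(
        c(pid, pid), c(diag[[cn]][1], diag[[cc]][1]),
        c(10, 1500), c(200, 1700))
      expected[pid] <- cn
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    homolog_hits(character(0), character(0), character(0), numeric(0),
                 numeric(0))
  domains <- if (length(domains)) do.call(rbind, domains) else
    domain_annotations(character(0), character(0), numeric(0), numeric(0))
  rownames(hits) <- NULL
  rownames(domains) <- NULL
  list(hits = hits, domains = domains, assignment = expected,
       wrong_domain_ids = wrong_ids)
}

#' Simulate a differential-expression results table with planted statuses
#'
#' Draws `log2fc` and `padj` with guaranteed margins so that
#' [classify_de()] recovers the planted status exactly: `up` gets
#' `log2fc ~ U(0.5, 3)` and `padj ~ U(0, alpha)`; `down` the negated fold
#' change; `not_significant` gets `padj ~ U(alpha, 1)`; `not_detected`
#' contributes no row.
#'
#' @param planted Named character vector: component symbol -> status (one of
#'   [de_status_levels()]).
#' @param alpha Significance threshold the margins respect.
#' @param seed Integer seed.
#' @param condition_id Condition identifier for the rows.
#' @return A data.frame with columns `gene_id`, `component`,
#'   `condition_id`, `log2fc`, `padj`.
#' @export
simulate_de_table <- function(planted, alpha = 0.05, seed = 1,
                              condition_id = "cond1") {
  bad <- setdiff(unique(planted), de_status_levels())
  if (length(bad) > 0) stop("unknown status: ", paste(bad, collapse = ", "))
  set.seed(seed)
  keep <- planted != "not_detected"
  comp <- as.character(names(planted))[keep]
  st <- unname(planted[keep])
  n <- length(comp)
  log2fc <- runif(n, 0.5, 3)
  log2fc[st == "down"] <- -log2fc[st == "down"]
  log2fc[st == "not_significant"] <- runif(sum(st == "not_significant"),
                                           -1, 1)
  padj <- runif(n, 0, alpha)
  padj[st == "not_significant"] <- runif(sum(st == "not_significant"),
                                         alpha, 1)
  gene_id <- if (n > 0) paste0(comp, "_g1") else character(0)
  data.frame(gene_id = gene_id, component = comp,
             condition_id = rep_len(condition_id, n), log2fc = log2fc,
             padj = padj, stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits A hit table (see [homolog_hits()]); the component symbol is
#'   written as qseqid and the taxon as a 13th column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  out <- data.frame(qseqid = hits$component,
                    sseqid = hits$target_protein_id,
                    pident = rep(50, n), length = rep(200, n),
                    mismatch = rep(0, n), gapopen = rep(0, n),
                    qstart = rep(1, n), qend = rep(200, n),
                    sstart = hits$target_start, send = hits$target_end,
                    evalue = hits$evalue, bitscore = hits$bitscore,
                    taxon = hits$taxon_id, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes a seeded, self-consistent dataset for exercising the whole
#' pipeline: `genome.gff3`, `genes.tsv` (the full labeled gene table),
#' `labels.tsv` (gene-to-component map), `hits.tsv` (BLAST outfmt-6 layout
#' plus taxon column), `domains.tsv`, `de.tsv` and `truth.json` (the planted
#' ground truth). The global seed fans out to fixed per-generator
#' sub-seeds.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"null"` (uniform labels) or `"clustered"` (planted
#'   5-gene cluster within 100 kb).
#' @param seed Integer seed.
#' @param K Number of labeled genes, default 12.
#' @return Invisibly, a list with the in-memory objects and `dir`.
#' @export
simulate_fa_dataset <- function(dir, preset = c("null", "clustered"),
                                seed = 1, K = 12) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(seed = sub_seed(seed, 101))
  planted <- plant_labels(genome, K = K, mode = if (preset == "null")
    "uniform" else "clustered", cluster_size = 5, max_span = 1e5,
    seed = sub_seed(seed, 211))
  genes <- planted$genes
  truth_map <- stats::setNames(planted$truth$label_map,
                               paste0(names(planted$truth$label_map), "_p"))
  sim <- simulate_hit_table(truth_map, n_decoys = 30,
                            seed = sub_seed(seed, 307))
  statuses <- rep_len(de_status_levels(),
                      length(unique(unname(truth_map))))
  planted_de <- stats::setNames(statuses, unique(unname(truth_map)))
  de <- simulate_de_table(planted_de, seed = sub_seed(seed, 401))
  write_gff3(genes, file.path(dir, "genome.gff3"))
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lab <- genes[!is.na(genes$label), ]
  write.table(data.frame(taxon_id = lab$taxon_id, gene_id = lab$gene_id,
                         component = lab$label, stringsAsFactors = FALSE),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_hits(sim$hits, file.path(dir, "hits.tsv"))
  write.table(sim$domains, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(de, file.path(dir, "de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(preset = preset, seed = seed,
                fa_gene_ids = planted$truth$fa_gene_ids,
                cluster_gene_ids = planted$truth$cluster_gene_ids,
                hit_truth = as.list(sim$assignment),
                de_truth = as.list(planted_de))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genes = genes, hits = sim$hits, domains = sim$domains,
                 de = de, truth = truth, dir = dir))
}
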