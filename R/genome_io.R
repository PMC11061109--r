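#' Construct a validated gene-record table
#'
#' The gene table is the package's central container: one row per annotated
#' gene with 1-based inclusive coordinates. Records are validated and sorted
#' by (taxon, contig, start).
#'
#' @param gene_id Character vector of gene identifiers, unique within a
#'   taxon.
#' @param taxon_id Taxon identifier(s), recycled if scalar.
#' @param contig_id Contig/scaffold identifier per gene.
#' @param start,end Integer coordinates, 1-based inclusive, `end >= start`.
#' @param strand Strand per gene: `"+"`, `"-"` or `"."` (unknown). Strand is
#'   ignored by all distance computations.
#' @param label Optional pathway component symbol per gene (`NA` =
#'   unlabeled).
#' @return A data.frame with columns `gene_id`, `taxon_id`, `contig_id`,
#'   `start`, `end`, `strand`, `label`, sorted by (taxon, contig, start).
#' @export
#' @examples
#' gene_records("g1", "tax1", "ctg1", 100, 400)
gene_records <- function(gene_id, taxon_id, contig_id, start, end,
                         strand = ".", label = NA_character_) {
  n <- length(gene_id)
  g <- data.frame(
    gene_id = as.character(gene_id),
    taxon_id = rep_len(as.character(taxon_id), n),
    contig_id = rep_len(as.character(contig_id), n),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_genes(g)
}

# Check gene-table invariants and return the table sorted.
validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  needed <- c("gene_id", "taxon_id", "contig_id", "start", "end")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0) {
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "."
  if (!"label" %in% names(genes)) genes$label <- NA_character_
  if (nrow(genes) > 0) {
    if (any(genes$start < 1)) stop("gene start coordinates must be >= 1")
    if (any(genes$end < genes$start)) stop("gene end must be >= start")
    key <- paste(genes$taxon_id, genes$gene_id, sep = "\r")
    if (anyDuplicated(key)) stop("(taxon_id, gene_id) must be unique")
    bad <- !genes$strand %in% c("+", "-", ".")
    if (any(bad)) stop("strand must be one of '+', '-', '.'")
  }
  o <- order(genes$taxon_id, genes$contig_id, genes$start, genes$end,
             genes$gene_id)
  g <- genes[o, c("gene_id", "taxon_id", "contig_id", "start", "end",
                  "strand", "label")]
  rownames(g) <- NULL
  g
}

#' Read gene records from a GFF3 annotation file
#'
#' Parses the tab-separated, 9-column GFF3 format (1-based inclusive
#' coordinates), keeping features of one type. Records with `end < start`
#' are rejected with a warning rather than failing the whole file. Attribute
#' handling is limited to `ID`/`Name` extraction; features without either
#' get a positional identifier.
#'
#' @param path Path to a GFF3 file. Lines starting with `#` are skipped; a
#'   `##FASTA` directive terminates parsing.
#' @param taxon_id Taxon identifier attached to every record.
#' @param feature_type GFF3 feature type to keep (column 3), default
#'   `"gene"`.
#' @param fallback_mrna If `TRUE` (default) and no features of
#'   `feature_type` exist, fall back to `"mRNA"` rows (some fungal GFFs lack
#'   gene rows).
#' @return A gene table as from [gene_records()], sorted by (contig, start);
#'   zero-row when the file contains no matching features.
#' @export
parse_gff <- function(path, taxon_id, feature_type = "gene",
                      fallback_mrna = TRUE) {
  lines <- readLines(path, warn = FALSE)
  fasta <- grep("^##FASTA", lines)
  if (length(fasta) > 0) lines <- lines[seq_len(fasta[1] - 1L)]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- gene_records(character(0), character(0), character(0),
                        numeric(0), numeric(0))
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok_cols <- lengths(fields) >= 8
  if (any(!ok_cols)) {
    warning(sum(!ok_cols), " GFF3 line(s) with fewer than 8 columns skipped")
    fields <- fields[ok_cols]
  }
  if (length(fields) == 0) return(empty)
  col <- function(i) vapply(fields, function(f) f[i], character(1))
  type <- col(3)
  keep <- type == feature_type
  if (!any(keep) && fallback_mrna && feature_type == "gene") {
    keep <- type == "mRNA"
  }
  if (!any(keep)) return(empty)
  fields <- fields[keep]
  seqid <- col(1)[keep]
  start <- suppressWarnings(as.numeric(col(4)[keep]))
  end <- suppressWarnings(as.numeric(col(5)[keep]))
  strand <- col(7)[keep]
  strand[!strand %in% c("+", "-")] <- "."
  attrs <- vapply(fields, function(f) if (length(f) >= 9) f[9] else "",
                  character(1))
  ids <- extract_gff_id(attrs)
  auto <- is.na(ids)
  ids[auto] <- sprintf("%s_%s_%d", taxon_id, feature_type,
                       which(auto))
  bad <- is.na(start) | is.na(end) | end < start | start < 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed coordinates rejected")
  }
  ok <- !bad
  gene_records(ids[ok], taxon_id, seqid[ok], start[ok], end[ok], strand[ok])
}

# Pull ID= (or, failing that, Name=) out of GFF3 column 9.
extract_gff_id <- function(attrs) {
  get <- function(key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"),
                                   attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  id <- get("ID")
  nm <- get("Name")
  id[is.na(id)] <- nm[is.na(id)]
  id
}

#' Write gene records to GFF3
#'
#' Inverse of [parse_gff()]: identifiers, contigs, coordinates and strand
#' round-trip losslessly. A non-missing `label` is written as a
#' `component=` attribute.
#'
#' @param genes A gene table (see [gene_records()]).
#' @param path Output path.
#' @param source Value for GFF3 column 2.
#' @param feature_type Value for GFF3 column 3.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "facoloc",
                       feature_type = "gene") {
  genes <- validate_genes(genes)
  attrs <- paste0("ID=", genes$gene_id)
  lab <- !is.na(genes$label)
  attrs[lab] <- paste0(attrs[lab], ";component=", genes$label[lab])
  lines <- c("##gff-version 3",
             paste(genes$contig_id, source, feature_type,
                   format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   ".", genes$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Per-genome gene geometry statistics
#'
#' Computes the quantities the analytic co-localization null consumes: gene
#' count, mean gene length, mean intergenic gap and their sum (mean
#' spacing). The intergenic gap between consecutive same-contig genes
#' (sorted by start) is the number of bases strictly between them,
#' `max(0, next_start - prev_end - 1)`; overlapping genes contribute 0.
#' Contigs holding a single gene contribute no gap terms.
#'
#' @param genes A gene table for one taxon with at least one gene.
#' @return An object of class `genome_stats`: a list with `taxon_id`,
#'   `n_genes`, `mean_gene_length`, `mean_intergenic_gap`, `mean_spacing`
#'   and `contig_gene_counts` (named integer vector).
#' @export
#' @examples
#' g <- gene_records(c("a", "b"), "t", "c1", c(1, 2001), c(1000, 3000))
#' genome_stats(g)  # mean length 1000, mean gap 1000, spacing 2000
genome_stats <- function(genes) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0) stop("no genes")
  if (length(unique(genes$taxon_id)) > 1) {
    stop("genome_stats expects genes from a single taxon")
  }
  n <- nrow(genes)
  mean_len <- mean(genes$end - genes$start + 1)
  same <- genes$contig_id[-1] == genes$contig_id[-n]
  if (n > 1 && any(same)) {
    gaps <- pmax(0, genes$start[-1] - genes$end[-n] - 1)[same]
    mean_gap <- mean(gaps)
  } else {
    warning("all contigs contain a single gene; mean intergenic gap set to 0")
    mean_gap <- 0
  }
  counts <- table(genes$contig_id)
  structure(
    list(taxon_id = genes$taxon_id[1],
         n_genes = n,
         mean_gene_length = mean_len,
         mean_intergenic_gap = mean_gap,
         mean_spacing = mean_len + mean_gap,
         contig_gene_counts = stats::setNames(as.integer(counts),
                                              names(counts))),
    class = "genome_stats"
  )
}

#' @export
print.genome_stats <- function(x, ...) {
  cat("Genome geometry for taxon", x$taxon_id, "\n")
  cat(sprintf("  genes: %d on %d contig(s)\n", x$n_genes,
              length(x$contig_gene_counts)))
  cat(sprintf("  mean gene length:    %.1f bp\n", x$mean_gene_length))
  cat(sprintf("  mean intergenic gap: %.1f bp\n", x$mean_intergenic_gap))
  cat(sprintf("  mean spacing:        %.1f bp\n", x$mean_spacing))
  invisible(x)
}

#' @export
as.data.frame.genome_stats <- function(x, ...) {
  data.frame(taxon_id = x$taxon_id, n_genes = x$n_genes,
             mean_gene_length = x$mean_gene_length,
             mean_intergenic_gap = x$mean_intergenic_gap,
             mean_spacing = x$mean_spacing, stringsAsFactors = FALSE)
}

#' Expected gene slots per window on one side of a focal gene
#'
#' Converts a window radius into an expected count of other gene positions
#' within it, `m = floor(window / mean_spacing)`, clamped to
#' `[0, n_genes - 1]`. The two-sided neighborhood used by the analytic null
#' is `2 * m` (see [focal_neighbor_prob()]).
#'
#' @param stats A [genome_stats()] object.
#' @param window Window radius in bp (> 0); default 250 kb.
#' @return Integer count `m`.
#' @export
#' @examples
#' s <- genome_stats(simulate_genome(1, 50, gene_length = 1500,
#'                                   intergenic_gap = 1000, seed = 1))
#' genes_per_window(s, 250000)
genes_per_window <- function(stats, window = 250000) {
  stopifnot(inherits(stats, "genome_stats"), window > 0)
  if (stats$mean_spacing <= 0) stop("degenerate spacing")
  m <- floor(window / stats$mean_spacing)
  as.integer(min(max(m, 0), stats$n_genes - 1))
}
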