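#' Construct a homology-hit table
#'
#' One row per (pathway component, target protein) hit, in the style of a
#' parsed BLAST tabular file. Target coordinates are amino-acid positions,
#' 1-based inclusive.
#'
#' @param component Component symbol per hit (registry symbols; aliases are
#'   accepted and resolved).
#' @param target_protein_id Subject protein identifier.
#' @param taxon_id Taxon of the subject proteome, recycled if scalar.
#' @param evalue,bitscore Hit statistics; `evalue >= 0`.
#' @param target_start,target_end Subject alignment interval (aa).
#' @param registry Registry used to resolve aliases.
#' @return A data.frame of hits.
#' @export
homolog_hits <- function(component, target_protein_id, taxon_id, evalue,
                         bitscore, target_start = 1L,
                         target_end = target_start,
                         registry = fa_registry()) {
  n <- max(length(component), length(target_protein_id), length(evalue),
           length(bitscore))
  h <- data.frame(
    component = resolve_component(rep_len(as.character(component), n),
                                  registry),
    target_protein_id = rep_len(as.character(target_protein_id), n),
    taxon_id = rep_len(as.character(taxon_id), n),
    evalue = as.numeric(evalue),
    bitscore = as.numeric(bitscore),
    target_start = rep_len(as.numeric(target_start), n),
    target_end = rep_len(as.numeric(target_end), n),
    stringsAsFactors = FALSE
  )
  if (any(h$evalue < 0)) stop("e-values must be >= 0")
  if (any(h$target_end < h$target_start)) {
    stop("target_end must be >= target_start")
  }
  h
}

#' Read a BLAST outfmt-6 style hit table
#'
#' Expects the standard 12 tab-separated columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), no
#' header. Query identifiers are mapped to registry component symbols
#' either through `map` (a reference-protein-to-component sidecar table) or
#' directly as symbols/aliases.
#'
#' @param path Path to the tabular file.
#' @param taxon_id Taxon of the subject proteome. Alternatively the file
#'   may carry a 13th column with per-row taxon identifiers.
#' @param map Optional data.frame with columns `reference_protein`,
#'   `component` mapping qseqid values to components.
#' @param registry Registry for alias resolution.
#' @return A hit table as from [homolog_hits()].
#' @export
read_hits <- function(path, taxon_id = NA_character_, map = NULL,
                      registry = fa_registry()) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12) stop("hit table must have at least 12 columns")
  names(raw)[1:12] <- cols
  taxon <- if (ncol(raw) >= 13) as.character(raw[[13]]) else taxon_id
  q <- raw$qseqid
  if (!is.null(map)) {
    idx <- match(q, map$reference_protein)
    q[!is.na(idx)] <- map$component[idx[!is.na(idx)]]
  }
  homolog_hits(q, raw$sseqid, taxon, raw$evalue, raw$bitscore,
               raw$sstart, raw$send, registry = registry)
}

#' Filter homology hits by e-value
#'
#' Keeps exactly the hits with `evalue <= evalue_max` (inclusive, matching
#' the standard BLASTp screening cutoff of 1e-5), preserving order. The
#' operation is idempotent.
#'
#' @param hits A hit table.
#' @param evalue_max Inclusive e-value cutoff (> 0); default `1e-5`.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5) {
  stopifnot(is.numeric(evalue_max), evalue_max > 0)
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Assign each target protein to one component by best bitscore
#'
#' Every target protein is assigned to the component of its maximum-bitscore
#' hit. Ties are broken by lower e-value, then by lexicographic component
#' symbol, so the assignment is deterministic and invariant to hit order.
#'
#' @param hits A (typically filtered) hit table.
#' @return A data.frame with one row per (taxon, protein): columns
#'   `taxon_id`, `protein_id`, `component`, `bitscore`, `evalue`.
#' @export
assign_best <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(taxon_id = character(0), protein_id = character(0),
                      component = character(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  o <- order(hits$taxon_id, hits$target_protein_id, -hits$bitscore,
             hits$evalue, hits$component)
  h <- hits[o, ]
  keep <- !duplicated(paste(h$taxon_id, h$target_protein_id, sep = "\r"))
  out <- data.frame(taxon_id = h$taxon_id[keep],
                    protein_id = h$target_protein_id[keep],
                    component = h$component[keep],
                    bitscore = h$bitscore[keep],
                    evalue = h$evalue[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct a protein domain-annotation table
#'
#' @param protein_id Protein identifier per domain hit.
#' @param domain_accession Pfam (or other) accession.
#' @param start,end Domain interval on the protein, aa, 1-based inclusive.
#' @return A data.frame of domain annotations.
#' @export
domain_annotations <- function(protein_id, domain_accession, start, end) {
  d <- data.frame(protein_id = as.character(protein_id),
                  domain_accession = as.character(domain_accession),
                  start = as.numeric(start), end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (any(d$end < d$start)) stop("domain end must be >= start")
  d
}

#' Read a pfam_scan-style domain table
#'
#' @param path TSV with columns `protein_id`, `accession`, `start`, `end`
#'   (header optional; detected from the first line).
#' @return A domain table as from [domain_annotations()].
#' @export
read_domains <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("protein", first, ignore.case = TRUE)
  d <- read.delim(path, header = header, stringsAsFactors = FALSE)
  names(d)[1:4] <- c("protein_id", "domain_accession", "start", "end")
  domain_annotations(d$protein_id, d$domain_accession, d$start, d$end)
}

#' Gate component assignments on diagnostic domain content
#'
#' When `require = TRUE`, assignments whose protein carries none of the
#' assigned component's diagnostic Pfam accessions are dropped (replacing
#' manual inspection of cluster members for domain conservation).
#' Components whose registry entry lists no Pfam accession are exempt. The
#' dropped assignments, with reasons, are attached as attribute
#' `"dropped"`.
#'
#' @param assignment Output of [assign_best()].
#' @param domains A domain table (see [domain_annotations()]).
#' @param registry Registry providing diagnostic accessions.
#' @param require If `FALSE`, return the assignment unchanged (gate off).
#' @return The retained assignment rows, with attribute `dropped`.
#' @export
confirm_architecture <- function(assignment, domains,
                                 registry = fa_registry(), require = TRUE) {
  unknown <- setdiff(assignment$component, registry$symbol)
  if (length(unknown) > 0) {
    stop("unknown component symbol(s) in assignment: ",
         paste(unknown, collapse = ", "))
  }
  dropped <- data.frame(taxon_id = character(0), protein_id = character(0),
                        component = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!require || nrow(assignment) == 0) {
    attr(assignment, "dropped") <- dropped
    return(assignment)
  }
  diag <- registry_pfam(registry)
  prot_acc <- split(domains$domain_accession, domains$protein_id)
  ok <- logical(nrow(assignment))
  reason <- character(nrow(assignment))
  for (i in seq_len(nrow(assignment))) {
    acc_needed <- diag[[assignment$component[i]]]
    if (length(acc_needed) == 0) {        # exempt: no diagnostic accession
      ok[i] <- TRUE
      next
    }
    acc_seen <- prot_acc[[assignment$protein_id[i]]]
    ok[i] <- length(intersect(acc_seen, acc_needed)) > 0
    if (!ok[i]) {
      reason[i] <- sprintf("no diagnostic domain for %s (expected %s)",
                           assignment$component[i],
                           paste(acc_needed, collapse = "/"))
    }
  }
  if (any(!ok)) {
    dropped <- data.frame(taxon_id = assignment$taxon_id[!ok],
                          protein_id = assignment$protein_id[!ok],
                          component = assignment$component[!ok],
                          reason = reason[!ok], stringsAsFactors = FALSE)
    message(sum(!ok), " assignment(s) dropped by domain confirmation")
  }
  out <- assignment[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Build a taxon-by-component presence/copy-number matrix
#'
#' `counts[t, c]` is the number of distinct proteins of taxon `t` assigned
#' to component `c`. Taxa and components without evidence appear as explicit
#' zero rows/columns.
#'
#' @param assignment Output of [assign_best()] (optionally gated by
#'   [confirm_architecture()]).
#' @param taxa Row order; defaults to the taxa present in `assignment`.
#' @param registry Registry defining the column order.
#' @param components Column order; defaults to all registry symbols.
#' @return An integer matrix with taxa as rows, components as columns.
#' @export
build_presence_matrix <- function(assignment, taxa = NULL,
                                  registry = fa_registry(),
                                  components = registry$symbol) {
  if (is.null(taxa)) taxa <- sort(unique(assignment$taxon_id))
  mat <- matrix(0L, nrow = length(taxa), ncol = length(components),
                dimnames = list(taxa, components))
  if (nrow(assignment) > 0) {
    unknown <- setdiff(assignment$component, components)
    if (length(unknown) > 0) {
      stop("assignment contains components outside the requested columns: ",
           paste(unknown, collapse = ", "))
    }
    u <- unique(assignment[c("taxon_id", "protein_id", "component")])
    tab <- table(factor(u$taxon_id, levels = taxa),
                 factor(u$component, levels = components))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Detect candidate gene fusions from domain architectures
#'
#' A protein is called a fusion when it carries diagnostic domains of at
#' least two distinct components whose intervals do not overlap and whose
#' midpoints are at least `min_separation` apart. One row is emitted per
#' qualifying component pair, with the components in N-to-C order of
#' interval midpoints and the interval evidence. Accessions shared between
#' components (e.g. the RAD51-family PF08423) cannot produce calls on their
#' own because a domain always overlaps itself.
#'
#' @param domains A domain table (see [domain_annotations()]).
#' @param registry Registry mapping accessions to components.
#' @param proteins Optional restriction: a character vector of protein ids,
#'   or an [assign_best()] data.frame (its `protein_id` column is used).
#'   Default: all proteins in `domains`.
#' @param min_separation Minimum midpoint separation (aa), default 100.
#' @return A data.frame with columns `protein_id`, `component_n`,
#'   `component_c`, `start_n`, `end_n`, `start_c`, `end_c`,
#'   `midpoint_gap`; zero rows when nothing qualifies.
#' @export
#' @examples
#' d <- domain_annotations("prot1", c("PF16783", "PF02732"),
#'                         c(10, 1500), c(200, 1700))
#' detect_fusions(d)  # FANCM (N) -> FANCQ/XPF (C)
detect_fusions <- function(domains, registry = fa_registry(),
                           proteins = NULL, min_separation = 100) {
  if (is.data.frame(proteins)) proteins <- proteins$protein_id
  if (!is.null(proteins)) {
    domains <- domains[domains$protein_id %in% proteins, , drop = FALSE]
  }
  acc2comp <- pfam_components(registry)
  empty <- data.frame(protein_id = character(0), component_n = character(0),
                      component_c = character(0), start_n = numeric(0),
                      end_n = numeric(0), start_c = numeric(0),
                      end_c = numeric(0), midpoint_gap = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(domains) == 0) return(empty)
  out <- list()
  for (pid in unique(domains$protein_id)) {
    d <- domains[domains$protein_id == pid, , drop = FALSE]
    comps <- acc2comp[d$domain_accession]
    hit <- data.frame(
      component = unlist(comps, use.names = FALSE),
      start = rep(d$start, lengths(comps)),
      end = rep(d$end, lengths(comps)),
      stringsAsFactors = FALSE
    )
    if (nrow(hit) == 0) next
    hit$mid <- (hit$start + hit$end) / 2
    comp_set <- sort(unique(hit$component))
    if (length(comp_set) < 2) next
    for (i in seq_len(length(comp_set) - 1)) {
      for (j in seq(i + 1, length(comp_set))) {
        a <- hit[hit$component == comp_set[i], , drop = FALSE]
        b <- hit[hit$component == comp_set[j], , drop = FALSE]
        best <- NULL
        for (ia in seq_len(nrow(a))) {
          for (ib in seq_len(nrow(b))) {
            overlap <- a$start[ia] <= b$end[ib] && b$start[ib] <= a$end[ia]
            sep <- abs(a$mid[ia] - b$mid[ib])
            if (!overlap && sep >= min_separation &&
                (is.null(best) || sep > best$sep)) {
              best <- list(ia = ia, ib = ib, sep = sep)
            }
          }
        }
        if (!is.null(best)) {
          aa <- a[best$ia, ]
          bb <- b[best$ib, ]
          nterm <- if (aa$mid <= bb$mid) aa else bb
          cterm <- if (aa$mid <= bb$mid) bb else aa
          comp_n <- if (aa$mid <= bb$mid) comp_set[i] else comp_set[j]
          comp_c <- if (aa$mid <= bb$mid) comp_set[j] else comp_set[i]
          out[[length(out) + 1]] <- data.frame(
            protein_id = pid, component_n = comp_n, component_c = comp_c,
            start_n = nterm$start, end_n = nterm$end,
            start_c = cterm$start, end_c = cterm$end,
            midpoint_gap = best$sep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$start_n, res$start_c), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare a protein's domain architecture against a reference
#'
#' Reports accessions of the reference architecture absent from the protein
#' (truncations, e.g. a FANCJ homolog missing its C-terminal RAD3 helicase),
#' accessions the protein carries beyond the reference (acquisitions, e.g.
#' an extra N-terminal S2P-M50 domain on SLX4), and the length ratio when
#' both lengths are supplied.
#'
#' @param protein_accessions Character vector of the protein's domain
#'   accessions (or a domain table for a single protein).
#' @param reference_accessions Non-empty ordered accession list of the
#'   reference architecture.
#' @param protein_length,reference_length Optional lengths (aa).
#' @return An object of class `architecture_report`: list with `missing`,
#'   `extra`, `length_ratio`.
#' @export
architecture_report <- function(protein_accessions, reference_accessions,
                                protein_length = NULL,
                                reference_length = NULL) {
  if (is.data.frame(protein_accessions)) {
    protein_accessions <- protein_accessions$domain_accession
  }
  if (length(reference_accessions) == 0) {
    stop("reference architecture must be non-empty")
  }
  ratio <- if (!is.null(protein_length) && !is.null(reference_length)) {
    protein_length / reference_length
  } else {
    NA_real_
  }
  structure(
    list(missing = setdiff(reference_accessions, protein_accessions),
         extra = setdiff(unique(protein_accessions), reference_accessions),
         length_ratio = ratio),
    class = "architecture_report"
  )
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("Domain architecture report\n")
  cat("  missing:", if (length(x$missing)) paste(x$missing, collapse = ", ")
      else "(none)", "\n")
  cat("  extra:  ", if (length(x$extra)) paste(x$extra, collapse = ", ")
      else "(none)", "\n")
  if (!is.na(x$length_ratio)) {
    cat(sprintf("  length ratio: %.2f\n", x$length_ratio))
  }
  invisible(x)
}
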