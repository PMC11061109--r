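#' Subcomplexes recognised in a pathway registry
#'
#' The closed set of Fanconi Anemia subcomplex names used by the bundled
#' registry, in pathway order: activation, core complex, monoubiquitination,
#' ID complex, endonucleases, homologous recombination / DNA repair,
#' deubiquitination.
#'
#' @return Character vector of subcomplex names.
#' @export
fa_subcomplexes <- function() {
  c("Activation", "Core complex", "Monoubiquitination", "ID complex",
    "Endonuclease", "HR and DNA repair", "Deubiquitination")
}

#' Bundled Fanconi Anemia pathway registry
#'
#' Returns the 40-component FA registry shipped with the package: gene
#' symbol, aliases, diagnostic Pfam accessions, InterPro accessions and
#' subcomplex. Pfam accession ranges are stored expanded (e.g. the FANCI
#' entry lists PF14674 through PF14680 individually). Three components
#' (FANCB, FANCG, REV3) have no Pfam accession and are exempt from domain
#' confirmation.
#'
#' The registry is user-replaceable: any table with the same columns can be
#' loaded with [read_registry()] so the pipeline generalizes to other
#' pathways.
#'
#' @return A data.frame with columns `symbol`, `aliases` (semicolon
#'   separated, may be empty), `pfam` (semicolon separated, may be empty),
#'   `interpro`, `subcomplex`.
#' @export
#' @examples
#' reg <- fa_registry()
#' nrow(reg)             # 40 components
#' table(reg$subcomplex)
fa_registry <- function() {
  path <- system.file("extdata", "fa_registry.tsv", package = "facoloc")
  read_registry(path)
}

#' Read a pathway registry from TSV or JSON
#'
#' @param path Path to a tab-separated file with columns `symbol`,
#'   `aliases`, `pfam`, `interpro`, `subcomplex` (aliases and pfam
#'   semicolon-separated), or a JSON array of objects with those fields.
#' @return A validated registry data.frame (see [fa_registry()]).
#' @export
read_registry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    reg <- jsonlite::fromJSON(path)
    reg <- as.data.frame(reg, stringsAsFactors = FALSE)
    list_cols <- c("aliases", "pfam")
    for (cl in intersect(list_cols, names(reg))) {
      if (is.list(reg[[cl]])) {
        reg[[cl]] <- vapply(reg[[cl]], function(x) paste(x, collapse = ";"),
                            character(1))
      }
    }
  } else {
    reg <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  }
  required <- c("symbol", "aliases", "pfam", "interpro", "subcomplex")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  }
  reg$aliases[is.na(reg$aliases)] <- ""
  reg$pfam[is.na(reg$pfam)] <- ""
  if (anyDuplicated(reg$symbol)) {
    stop("registry symbols must be unique")
  }
  bad <- setdiff(unique(reg$subcomplex), fa_subcomplexes())
  if (length(bad) > 0) {
    stop("unknown subcomplex value(s): ", paste(bad, collapse = ", "))
  }
  reg[required]
}

# Split a semicolon-separated registry field into a character vector.
split_field <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Resolve gene symbols or aliases to registry component symbols
#'
#' Maps a vector of names (component symbols or their aliases, e.g. "UBE2T"
#' or "XPF") onto canonical registry symbols.
#'
#' @param x Character vector of symbols or aliases.
#' @param registry A registry data.frame, default [fa_registry()].
#' @return Character vector of component symbols; an error lists any name
#'   that cannot be resolved.
#' @export
#' @examples
#' resolve_component(c("UBE2T", "XPF", "FANCM"))
resolve_component <- function(x, registry = fa_registry()) {
  alias_list <- split_field(registry$aliases)
  lookup <- registry$symbol
  names(lookup) <- registry$symbol
  for (i in seq_len(nrow(registry))) {
    for (a in alias_list[[i]]) {
      lookup[a] <- registry$symbol[i]
    }
  }
  out <- lookup[x]
  if (anyNA(out)) {
    stop("unknown component name(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# Named list: component symbol -> character vector of diagnostic Pfam
# accessions (possibly empty).
registry_pfam <- function(registry) {
  out <- split_field(registry$pfam)
  names(out) <- registry$symbol
  out
}

# Named list: pfam accession -> character vector of component symbols that
# list it as diagnostic (some accessions, e.g. PF08423, are shared).
pfam_components <- function(registry) {
  pf <- registry_pfam(registry)
  long <- data.frame(
    accession = unlist(pf, use.names = FALSE),
    symbol = rep(names(pf), lengths(pf)),
    stringsAsFactors = FALSE
  )
  split(long$symbol, long$accession)
}
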