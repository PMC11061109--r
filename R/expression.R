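#' Transcripts per million (TPM)
#'
#' Length-normalized expression: `rate_i = counts_i / lengths_i`,
#' `TPM_i = rate_i / sum(rate) * 1e6`. Each sample's TPM values sum to one
#' million (to floating tolerance), and scaling all counts by a constant
#' leaves TPM unchanged.
#'
#' @param counts Non-negative counts: a vector, or a genes-by-samples
#'   matrix (normalized column-wise).
#' @param lengths Gene lengths in bp, all positive, one per gene.
#' @return Numeric vector or matrix of TPM values matching `counts`.
#' @export
#' @examples
#' compute_tpm(c(10, 10), c(1000, 2000))  # 666666.67, 333333.33
compute_tpm <- function(counts, lengths) {
  if (is.matrix(counts)) {
    out <- apply(counts, 2, compute_tpm, lengths = lengths)
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  if (length(counts) != length(lengths)) {
    stop("counts and lengths must have equal length")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("no expressed genes")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Differential-expression status levels, in collapse-precedence order
#' @return `c("up", "down", "not_significant", "not_detected")`
#' @export
de_status_levels <- function() {
  c("up", "down", "not_significant", "not_detected")
}

#' Classify differential-expression results
#'
#' Applies the standard screening rule: a gene is `up` when
#' `padj <= alpha` and `log2fc > 0`, `down` when `padj <= alpha` and
#' `log2fc < 0`, `not_significant` when `padj > alpha` (or when
#' `log2fc == 0` exactly, which the "down < 0 > up" criterion assigns to
#' neither class), and `not_detected` when `padj` (or the gene) is missing.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Adjusted p-values in `[0, 1]`, `NA` = gene not detected.
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @return Character vector of statuses (see [de_status_levels()]).
#' @export
#' @examples
#' classify_de(c(1.4, -0.2, 3.0), c(0.01, 0.04, 0.2))
classify_de <- function(log2fc, padj, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- max(length(log2fc), length(padj))
  log2fc <- rep_len(log2fc, n)
  padj <- rep_len(padj, n)
  if (any(!is.na(padj) & (padj < 0 | padj > 1))) {
    stop("padj must lie in [0, 1]")
  }
  out <- rep("not_detected", n)
  det <- !is.na(padj) & !is.na(log2fc)
  out[det & padj > alpha] <- "not_significant"
  sig <- det & padj <= alpha
  out[sig & log2fc > 0] <- "up"
  out[sig & log2fc < 0] <- "down"
  out[sig & log2fc == 0] <- "not_significant"
  out
}

#' Component-by-condition expression profile matrix
#'
#' Builds the status grid summarising differential expression of pathway
#' components across conditions. Records are mapped to registry components
#' (aliases resolved); multiple gene copies of one component in one
#' condition collapse by the precedence up > down > not_significant >
#' not_detected, with the copy count retained in a `multiplicity` matrix.
#' Component/condition cells without any record are `not_detected` (the
#' "empty cell" of a profile heatmap).
#'
#' @param records Data.frame with columns `component`, `condition_id` and
#'   either `status` or both `log2fc` and `padj` (then classified with
#'   [classify_de()] at `alpha`).
#' @param registry Registry defining the component universe; unknown
#'   components are an error.
#' @param conditions Column order; defaults to order of appearance.
#' @param components Row order; defaults to all registry symbols.
#' @param alpha Threshold passed to [classify_de()] when statuses are
#'   derived.
#' @return Object of class `expression_profile`: list with `status`
#'   (character matrix components x conditions) and `multiplicity` (integer
#'   matrix of record counts).
#' @export
profile_matrix <- function(records, registry = fa_registry(),
                           conditions = NULL,
                           components = registry$symbol, alpha = 0.05) {
  records$component <- resolve_component(records$component, registry)
  unknown <- setdiff(records$component, components)
  if (length(unknown) > 0) {
    stop("record component(s) outside the requested rows: ",
         paste(unknown, collapse = ", "))
  }
  if (!"status" %in% names(records)) {
    records$status <- classify_de(records$log2fc, records$padj, alpha)
  }
  bad <- setdiff(unique(records$status), de_status_levels())
  if (length(bad) > 0) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(conditions)) conditions <- unique(records$condition_id)
  status <- matrix("not_detected", nrow = length(components),
                   ncol = length(conditions),
                   dimnames = list(components, conditions))
  mult <- matrix(0L, nrow = length(components), ncol = length(conditions),
                 dimnames = list(components, conditions))
  prec <- de_status_levels()
  for (i in seq_len(nrow(records))) {
    co <- records$component[i]
    cd <- as.character(records$condition_id[i])
    if (!cd %in% conditions) next
    mult[co, cd] <- mult[co, cd] + 1L
    if (match(records$status[i], prec) < match(status[co, cd], prec)) {
      status[co, cd] <- records$status[i]
    }
  }
  structure(list(status = status, multiplicity = mult),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  abbr <- c(up = "up", down = "down", not_significant = "ns",
            not_detected = ".")
  m <- matrix(abbr[x$status], nrow = nrow(x$status),
              dimnames = dimnames(x$status))
  keep <- rowSums(m != ".") > 0
  cat("Expression profile (", sum(keep), " of ", nrow(m),
      " components detected; '.' = not detected)\n", sep = "")
  print(m[keep, , drop = FALSE], quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.expression_profile <- function(x, ...) {
  abbr <- c(up = "up", down = "down", not_significant = "ns",
            not_detected = "nd")
  out <- as.data.frame(matrix(abbr[x$status], nrow = nrow(x$status),
                              dimnames = dimnames(x$status)),
                       stringsAsFactors = FALSE)
  cbind(component = rownames(x$status), out, row.names = NULL)
}
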