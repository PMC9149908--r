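## Quantitation-table and marker-list readers. Consumes Proteome
## Discoverer-style exports and EV-study supplementary tables re-saved as
## CSV/TSV. No gene-symbol fallback matching: everything is keyed by
## protein accession to avoid silent mis-mapping.

#' Normalize a protein accession
#'
#' Uppercases, strips surrounding whitespace and (by default) removes an
#' isoform suffix of the form \code{-<digits>} (\code{"Q96NT5-2"} becomes
#' \code{"Q96NT5"}), matching the primary-accession keying of the reference
#' map. Deterministic and idempotent.
#'
#' @param raw Character vector of raw accessions.
#' @param collapseIsoforms Strip trailing \code{-<digits>} isoform suffixes?
#' @return Character vector of normalized accessions.
#' @export
#' @examples
#' normalizeAccession(c(" q96nt5 ", "P11498-2"))
normalizeAccession <- function(raw, collapseIsoforms = TRUE) {
  if (length(raw) == 0L) return(character())
  out <- toupper(trimws(as.character(raw)))
  if (any(is.na(out) | out == ""))
    stop("empty accession at position ",
         which(is.na(out) | out == "")[1L])
  if (collapseIsoforms) out <- sub("-[0-9]+$", "", out)
  out
}

.collapse_duplicates <- function(m, policy) {
  acc <- rownames(m)
  if (!anyDuplicated(acc)) return(m)
  dup <- unique(acc[duplicated(acc)])
  if (policy == "error")
    stop("duplicate accession after normalization: ", dup[1L],
         " (use duplicatePolicy 'max' or 'sum' to aggregate)")
  fun <- switch(policy, max = function(v) if (all(is.na(v))) NA_real_ else
                  max(v, na.rm = TRUE),
                sum = function(v) if (all(is.na(v))) NA_real_ else
                  sum(v, na.rm = TRUE),
                stop("unknown duplicatePolicy: ", policy))
  out <- t(vapply(split(seq_len(nrow(m)), acc)[unique(acc)],
                  function(i) apply(m[i, , drop = FALSE], 2L, fun),
                  numeric(ncol(m))))
  colnames(out) <- colnames(m)
  message("aggregated ", length(dup), " duplicate accession(s) by '",
          policy, "'")
  out
}

#' Load a protein quantitation table
#'
#' Reads a CSV or TSV (sniffed by extension) of per-fraction MS intensities
#' into a \linkS4class{QuantTable}. Blank, \code{NA} and zero cells are all
#' treated as "not quantified in this fraction" (missing): label-free zeros
#' ordinarily mean not detected, and downstream ratio logic presumes
#' detection. Negative abundances are an error.
#'
#' @param path File path; \code{.csv} read as CSV, otherwise TSV.
#' @param columnSpec List with \code{accession} (column name) and optionally
#'   \code{fractions} (character vector of abundance columns; default: every
#'   other column).
#' @param duplicatePolicy \code{"error"} (default), \code{"max"} or
#'   \code{"sum"}: what to do with accessions that repeat after isoform
#'   collapse. Aggregation is applied per fraction and logged.
#' @param collapseIsoforms Strip isoform suffixes during normalization?
#' @return A \linkS4class{QuantTable}.
#' @export
loadQuantTable <- function(path,
                           columnSpec = list(accession = "accession",
                                             fractions = NULL),
                           duplicatePolicy = c("error", "max", "sum"),
                           collapseIsoforms = TRUE) {
  duplicatePolicy <- match.arg(duplicatePolicy)
  d <- .read_table_auto(path)
  accCol <- columnSpec$accession
  if (is.null(accCol)) accCol <- "accession"
  if (!accCol %in% colnames(d))
    stop("accession column '", accCol, "' not found in ", path)
  fractions <- columnSpec$fractions
  if (is.null(fractions)) fractions <- setdiff(colnames(d), accCol)
  miss <- setdiff(fractions, colnames(d))
  if (length(miss))
    stop("fraction column(s) not found: ", paste(miss, collapse = ", "))
  if (!length(fractions)) stop("at least one fraction column is required")
  m <- as.matrix(d[fractions])
  m <- suppressWarnings(apply(m, 2L, function(v) as.numeric(as.character(v))))
  m <- matrix(m, nrow = nrow(d), dimnames = list(NULL, fractions))
  if (any(m < 0, na.rm = TRUE))
    stop("negative abundance at row ",
         which(apply(m < 0, 1L, any, na.rm = TRUE))[1L])
  m[!is.na(m) & m == 0] <- NA_real_
  rownames(m) <- normalizeAccession(d[[accCol]],
                                    collapseIsoforms = collapseIsoforms)
  m <- .collapse_duplicates(m, duplicatePolicy)
  message("loaded quant table: ", nrow(m), " proteins x ", ncol(m),
          " fractions")
  QuantTable(m, normalize = FALSE)
}

#' Write a QuantTable to CSV
#'
#' Missing values are written as empty cells.
#'
#' @param quant A \linkS4class{QuantTable}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeQuantTable <- function(quant, path) {
  stopifnot(is(quant, "QuantTable"))
  m <- abundances(quant)
  d <- data.frame(accession = rownames(m), m, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a categorized marker list
#'
#' Reads a TSV with columns \code{accession}, \code{category} (1-5) and
#' optionally \code{role}; when \code{role} is absent it is derived from the
#' category (1, 2, 5 = ev-marker; 3 = contaminant; 4 = subtype). Categories
#' must be disjoint: an accession appearing twice is an error.
#'
#' @param path TSV path.
#' @param collapseIsoforms Strip isoform suffixes during normalization?
#' @return A \linkS4class{MarkerSet}.
#' @export
loadMarkerSet <- function(path, collapseIsoforms = TRUE) {
  d <- .read_table_auto(path)
  if (!all(c("accession", "category") %in% colnames(d)))
    stop("marker list needs columns accession, category")
  if (nrow(d) == 0L) return(MarkerSet())
  acc <- normalizeAccession(d$accession, collapseIsoforms = collapseIsoforms)
  role <- if ("role" %in% colnames(d)) as.character(d$role) else NULL
  ms <- MarkerSet(acc, as.integer(d$category), role = role,
                  normalize = FALSE)
  message("loaded marker set: ", nrow(ms@entries), " accessions, totals ",
          paste(categoryTotals(ms), collapse = "/"))
  ms
}

#' Write a MarkerSet to TSV
#'
#' @param markers A \linkS4class{MarkerSet}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerSet <- function(markers, path) {
  stopifnot(is(markers, "MarkerSet"))
  utils::write.table(as.data.frame(markers@entries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Accessions detected in a fraction
#'
#' A protein is "detected in fraction F" iff its abundance is present
#' (non-missing) in F.
#'
#' @param quant A \linkS4class{QuantTable}.
#' @param fraction Fraction id (must exist in the table).
#' @return Character vector of accessions.
#' @export
detectedIn <- function(quant, fraction) {
  stopifnot(is(quant, "QuantTable"))
  m <- abundances(quant)
  if (!fraction %in% colnames(m))
    stop("unknown fraction id: ", fraction, " (have: ",
         paste(colnames(m), collapse = ", "), ")")
  rownames(m)[!is.na(m[, fraction])]
}
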