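## Reference-map I/O and queries. The map (a fixed t-SNE embedding of a
## LOPIT experiment, e.g. the hyperLOPIT2017 u2os table exported to TSV) is
## treated as immutable input: coordinates are consumed as originally
## determined and never refined here.

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.resolve_compartment <- function(labels, aliases = compartmentAliases()) {
  low <- tolower(trimws(labels))
  canon <- .COMPARTMENTS[match(low, tolower(.COMPARTMENTS))]
  idx <- is.na(canon)
  canon[idx] <- unname(aliases[low[idx]])
  if (anyNA(canon)) {
    bad <- unique(labels[is.na(canon)])
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         "; allowed labels: ", paste(.COMPARTMENTS, collapse = ", "))
  }
  canon
}

#' Load an organellar reference map from tabular text
#'
#' Reads a TSV/CSV with one protein per row, validates it and returns a
#' \linkS4class{ReferenceMap}. Compartment spellings are resolved
#' case-insensitively against \code{\link{compartmentLabels}} and the
#' explicit alias table; anything unresolvable is an error (never coerced).
#' Accessions are normalized (see \code{\link{normalizeAccession}}); the
#' entry count is reported via \code{message()}.
#'
#' @param path Path to a TSV (default) or CSV (by extension) file with header.
#' @param columnSpec Named list giving the column names for \code{accession},
#'   \code{x}, \code{y}, \code{compartment}.
#' @param aliases Alias table, see \code{\link{compartmentAliases}}.
#' @param collapseIsoforms Strip isoform suffixes during normalization?
#' @return A validated \linkS4class{ReferenceMap}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tx\ty\tcompartment",
#'              "A1\t0.0\t1.0\tcytosol",
#'              "A2\t5.0\t-2.0\tnucleus"), f)
#' loadReferenceMap(f)
loadReferenceMap <- function(path,
                             columnSpec = list(accession = "accession",
                                               x = "x", y = "y",
                                               compartment = "compartment"),
                             aliases = compartmentAliases(),
                             collapseIsoforms = TRUE) {
  d <- .read_table_auto(path)
  miss <- setdiff(unlist(columnSpec), colnames(d))
  if (length(miss))
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  acc <- normalizeAccession(d[[columnSpec$accession]],
                            collapseIsoforms = collapseIsoforms)
  for (ax in c("x", "y")) {
    v <- d[[columnSpec[[ax]]]]
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.finite(num)))
      stop("non-numeric ", ax, " coordinate at row ",
           which(!is.finite(num))[1L], " ('", v[which(!is.finite(num))[1L]],
           "')")
    d[[columnSpec[[ax]]]] <- num
  }
  if (anyDuplicated(acc))
    stop("duplicate accession in reference map: ", acc[duplicated(acc)][1L])
  comp <- .resolve_compartment(d[[columnSpec$compartment]], aliases)
  map <- ReferenceMap(acc, d[[columnSpec$x]], d[[columnSpec$y]], comp)
  message("loaded reference map: ", nrow(map@entries), " proteins")
  map
}

#' Write a ReferenceMap to TSV
#'
#' Inverse of \code{\link{loadReferenceMap}} with default columns:
#' a load/write round trip reproduces accession, coordinate and compartment
#' content exactly.
#'
#' @param map A \linkS4class{ReferenceMap}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceMap <- function(map, path) {
  stopifnot(is(map, "ReferenceMap"))
  utils::write.table(as.data.frame(map@entries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compartment assignment of accessions
#'
#' Looks up accessions in the map after normalization. Proteins absent from
#' the map yield \code{NA} ("not in map"), which is deliberately distinct
#' from the \code{"unknown"} compartment assignment.
#'
#' @param map A \linkS4class{ReferenceMap}.
#' @param accession Character vector of accessions (raw; normalized here).
#' @param collapseIsoforms Passed to \code{\link{normalizeAccession}}.
#' @return Character vector of compartment labels, \code{NA} where the
#'   accession is not in the map.
#' @export
compartmentOf <- function(map, accession, collapseIsoforms = TRUE) {
  stopifnot(is(map, "ReferenceMap"))
  acc <- normalizeAccession(accession, collapseIsoforms = collapseIsoforms)
  unname(compartments(map)[acc])
}

#' Deterministic ellipse summarising compartment coordinates
#'
#' Builds a \linkS4class{RegionAnnotation} for a set of compartments:
#' centre = arithmetic mean of member-protein coordinates, covariance =
#' sample covariance scaled by \code{kSigma^2}. With all member points
#' identical the covariance degenerates to zero; this is returned with a
#' warning rather than an error so collapsed synthetic clusters remain
#' drawable.
#'
#' @param map A \linkS4class{ReferenceMap}.
#' @param compartments Compartment labels whose proteins define the region.
#' @param kSigma Positive standard-deviation multiple (default 2, covering
#'   the bulk of a Gaussian cluster).
#' @param regionId Short display label (default: initials of compartments).
#' @param role Region role: \code{"enriched-marker"},
#'   \code{"background-contaminant"} or \code{"neutral"}. Configuration,
#'   never computed.
#' @return A \linkS4class{RegionAnnotation}.
#' @export
regionEllipse <- function(map, compartments, kSigma = 2,
                          regionId = NULL, role = "neutral") {
  stopifnot(is(map, "ReferenceMap"), kSigma > 0)
  bad <- setdiff(compartments, .COMPARTMENTS)
  if (length(bad)) stop("unknown compartment label(s): ",
                        paste(bad, collapse = ", "))
  sel <- map@entries$compartment %in% compartments
  if (sum(sel) < 3L)
    stop("degenerate ellipse: need >= 3 member proteins, got ", sum(sel))
  xy <- cbind(map@entries$x[sel], map@entries$y[sel])
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  if (all(cv == 0))
    warning("all member coordinates identical; zero-covariance ellipse")
  if (is.null(regionId))
    regionId <- paste(toupper(substr(compartments, 1L, 1L)), collapse = "")
  new("RegionAnnotation", regionId = regionId,
      compartments = compartments, role = role,
      center = stats::setNames(ctr, c("x", "y")),
      covariance = cv * kSigma^2, kSigma = kSigma)
}
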