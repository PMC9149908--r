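#' Accessions stored in an object
#'
#' @param x A \linkS4class{ReferenceMap}, \linkS4class{QuantTable},
#'   \linkS4class{MarkerSet} or \linkS4class{MapOverlay}.
#' @return Character vector of (normalized) accessions.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessions
setMethod("accessions", "ReferenceMap", function(x) x@entries$accession)
#' @rdname accessions
setMethod("accessions", "QuantTable", function(x)
  rownames(SummarizedExperiment::assay(x, "abundance")))
#' @rdname accessions
setMethod("accessions", "MarkerSet", function(x) x@entries$accession)
#' @rdname accessions
setMethod("accessions", "MapOverlay", function(x)
  c(x@points$accession, x@unmapped))

#' Map coordinates of a ReferenceMap
#'
#' @param x A \linkS4class{ReferenceMap}.
#' @return Two-column numeric matrix (x, y) with accession rownames.
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname coordinates
setMethod("coordinates", "ReferenceMap", function(x) {
  m <- cbind(x = x@entries$x, y = x@entries$y)
  rownames(m) <- x@entries$accession
  m
})

#' Compartment labels per entry
#'
#' @param x A \linkS4class{ReferenceMap} or \linkS4class{MapOverlay}.
#' @return Named character vector (names = accessions).
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname compartments
setMethod("compartments", "ReferenceMap", function(x)
  stats::setNames(x@entries$compartment, x@entries$accession))
#' @rdname compartments
setMethod("compartments", "MapOverlay", function(x)
  stats::setNames(x@points$compartment, x@points$accession))

#' Abundance matrix of a QuantTable
#'
#' @param x A \linkS4class{QuantTable}.
#' @return Numeric matrix, NA = not quantified.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname abundances
setMethod("abundances", "QuantTable", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' Fraction identifiers of a QuantTable
#'
#' @param x A \linkS4class{QuantTable}.
#' @return Character vector of fraction/column ids.
#' @export
setGeneric("fractionIds", function(x) standardGeneric("fractionIds"))

#' @rdname fractionIds
setMethod("fractionIds", "QuantTable", function(x) colnames(abundances(x)))

#' Per-category totals of a MarkerSet
#'
#' @param x A \linkS4class{MarkerSet}.
#' @return Named integer vector over categories 1-5 (zeros kept).
#' @export
setGeneric("categoryTotals", function(x) standardGeneric("categoryTotals"))

#' @rdname categoryTotals
setMethod("categoryTotals", "MarkerSet", function(x) {
  tt <- table(factor(x@entries$category, levels = 1:5))
  stats::setNames(as.integer(tt), names(tt))
})
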