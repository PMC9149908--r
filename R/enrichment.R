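## Between-fraction fold change, the carboxylase positive-control benchmark
## and the enrichment cutoff used to separate candidate interactors from
## streptavidin-pulldown background. No between-fraction normalization is
## applied before ratioing.

#' Per-protein fold change between two fractions
#'
#' Ratio of numerator-fraction abundance over denominator-fraction abundance
#' (e.g. Elute over W-2). Each protein gets a presence status: \code{both}
#' (ratio defined), \code{numerator_only}, \code{denominator_only} or
#' \code{neither}.
#'
#' @param quant A \linkS4class{QuantTable}.
#' @param numeratorFraction,denominatorFraction Fraction ids in the table.
#' @return A \linkS4class{FoldChangeResult}.
#' @export
#' @examples
#' qt <- QuantTable(matrix(c(6, 2), 1, 2,
#'                  dimnames = list("A1", c("Elute", "W-2"))))
#' computeFoldChange(qt, "Elute", "W-2")
computeFoldChange <- function(quant, numeratorFraction, denominatorFraction) {
  stopifnot(is(quant, "QuantTable"))
  m <- abundances(quant)
  for (fr in c(numeratorFraction, denominatorFraction))
    if (!fr %in% colnames(m))
      stop("unknown fraction id: ", fr, " (have: ",
           paste(colnames(m), collapse = ", "), ")")
  num <- m[, numeratorFraction]
  den <- m[, denominatorFraction]
  hasN <- !is.na(num); hasD <- !is.na(den)
  status <- ifelse(hasN & hasD, "both",
            ifelse(hasN, "numerator_only",
            ifelse(hasD, "denominator_only", "neither")))
  ratio <- ifelse(hasN & hasD, num / den, NA_real_)
  res <- DataFrame(accession = rownames(m), numerator = unname(num),
                   denominator = unname(den), ratio = unname(ratio),
                   status = unname(status), passes = rep(NA, nrow(m)))
  new("FoldChangeResult", results = res,
      numeratorFraction = numeratorFraction,
      denominatorFraction = denominatorFraction,
      cutoff = NA_real_, includeNumeratorOnly = NA)
}

#' Carboxylase positive-control benchmark
#'
#' Endogenously biotinylated carboxylases are retained on streptavidin
#' through the washes and released in the elution, so their
#' numerator/denominator abundance ratios calibrate what "specifically
#' bound" looks like in a given experiment. Computes per-control ratios,
#' their min/max, and the total-abundance ratio (sum of numerator over sum
#' of denominator abundances across controls detected in both fractions).
#' Controls missing from either fraction are excluded (never imputed) and
#' reported with a warning.
#'
#' @param quant A \linkS4class{QuantTable}.
#' @param numeratorFraction,denominatorFraction Fraction ids.
#' @param controls Control accessions; default the four human carboxylases
#'   (\code{\link{carboxylaseControls}}).
#' @return A \linkS4class{CarboxylaseBenchmark}. Error if no control is
#'   detected in both fractions (benchmark undefined).
#' @export
carboxylaseBenchmark <- function(quant, numeratorFraction,
                                 denominatorFraction,
                                 controls = carboxylaseControls()) {
  stopifnot(is(quant, "QuantTable"))
  controls <- normalizeAccession(controls)
  m <- abundances(quant)
  for (fr in c(numeratorFraction, denominatorFraction))
    if (!fr %in% colnames(m)) stop("unknown fraction id: ", fr)
  present <- controls[controls %in% rownames(m)]
  num <- m[present, numeratorFraction]
  den <- m[present, denominatorFraction]
  ok <- !is.na(num) & !is.na(den)
  missing <- c(setdiff(controls, present), present[!ok])
  if (!any(ok))
    stop("benchmark undefined: no control detected in both fractions")
  if (length(missing))
    warning("control(s) not detected in both fractions, excluded: ",
            paste(missing, collapse = ", "))
  ratios <- stats::setNames((num / den)[ok], present[ok])
  new("CarboxylaseBenchmark", controls = controls, ratios = ratios,
      minRatio = min(ratios), maxRatio = max(ratios),
      totalRatio = sum(num[ok]) / sum(den[ok]), missing = missing)
}

#' Apply an enrichment cutoff to fold-change results
#'
#' A protein passes iff (status \code{both} and ratio >= cutoff) or (status
#' \code{numerator_only} and \code{includeNumeratorOnly}). The boundary is
#' inclusive ("at least" cutoff-fold). Numerator-only proteins — detected in
#' the eluate but absent from the wash — are included by default since
#' absence from the wash is the strongest enrichment signal; no pseudo-count
#' is imputed for them.
#'
#' @param fc A \linkS4class{FoldChangeResult}.
#' @param cutoff Finite ratio cutoff >= 0 (the benchmark-derived default in
#'   the workflow is 3).
#' @param includeNumeratorOnly Count numerator-only proteins as passing?
#' @return The \linkS4class{FoldChangeResult} with \code{passes} filled and
#'   the cutoff recorded; see \code{\link{passedProteins}} /
#'   \code{\link{nPassed}}.
#' @export
applyCutoff <- function(fc, cutoff, includeNumeratorOnly = TRUE) {
  stopifnot(is(fc, "FoldChangeResult"))
  if (!is.finite(cutoff) || cutoff < 0)
    stop("cutoff must be finite and >= 0")
  r <- fc@results
  passes <- (r$status == "both" & !is.na(r$ratio) & r$ratio >= cutoff) |
            (r$status == "numerator_only" & includeNumeratorOnly)
  fc@results$passes <- passes
  fc@cutoff <- cutoff
  fc@includeNumeratorOnly <- includeNumeratorOnly
  validObject(fc)
  fc
}

#' Proteins passing the applied cutoff
#'
#' @param fc A \linkS4class{FoldChangeResult} after \code{\link{applyCutoff}}.
#' @return Character vector of passing accessions.
#' @export
passedProteins <- function(fc) {
  stopifnot(is(fc, "FoldChangeResult"))
  if (is.na(fc@cutoff)) stop("applyCutoff first")
  fc@results$accession[fc@results$passes]
}

#' @rdname passedProteins
#' @return \code{nPassed}: the pass count.
#' @export
nPassed <- function(fc) length(passedProteins(fc))

#' Cutoff suggested by the carboxylase benchmark
#'
#' \code{"min_control"} returns the smallest per-control ratio (the minimum
#' enrichment a known biotinylated protein achieved); \code{"total"} the
#' total-abundance ratio; \code{"fixed"} the supplied value (the workflow's
#' conventional choice is a fixed 3).
#'
#' @param benchmark A \linkS4class{CarboxylaseBenchmark}.
#' @param policy \code{"fixed"}, \code{"min_control"} or \code{"total"}.
#' @param value Cutoff for \code{policy = "fixed"}.
#' @return Numeric cutoff.
#' @export
suggestCutoff <- function(benchmark,
                          policy = c("fixed", "min_control", "total"),
                          value = 3) {
  policy <- match.arg(policy)
  if (policy == "fixed") return(as.numeric(value))
  stopifnot(is(benchmark, "CarboxylaseBenchmark"))
  switch(policy, min_control = benchmark@minRatio,
         total = benchmark@totalRatio)
}

#' Overlay fold-change ratios on the reference map
#'
#' Builds a \linkS4class{MapOverlay} whose values are the both-status ratios
#' (optionally restricted to proteins passing the applied cutoff), with
#' point sizes binned on the ratio scale.
#'
#' @param fc A \linkS4class{FoldChangeResult}.
#' @param map A \linkS4class{ReferenceMap}.
#' @param passedOnly Only include proteins passing the applied cutoff?
#' @param nBins,scheme Passed to \code{\link{binValues}}.
#' @return A \linkS4class{MapOverlay} with \code{valueLabel = "ratio"}.
#' @export
foldChangeOverlay <- function(fc, map, passedOnly = FALSE, nBins = 5L,
                              scheme = c("quantile-log10",
                                         "equal-width-log10")) {
  scheme <- match.arg(scheme)
  stopifnot(is(fc, "FoldChangeResult"), is(map, "ReferenceMap"))
  r <- fc@results
  keep <- r$status == "both"
  if (passedOnly) {
    if (is.na(fc@cutoff)) stop("applyCutoff first")
    keep <- keep & r$passes
  }
  mapComp <- compartments(map)
  coords <- coordinates(map)
  acc <- r$accession[keep]; ratio <- r$ratio[keep]
  inMap <- acc %in% names(mapComp)
  pts <- if (any(inMap)) {
    a <- acc[inMap]
    DataFrame(accession = a, x = coords[a, "x"], y = coords[a, "y"],
              compartment = unname(mapComp[a]), value = ratio[inMap],
              bin = binValues(ratio[inMap], nBins = nBins, scheme = scheme))
  } else .empty_points()
  new("MapOverlay", points = pts, unmapped = acc[!inMap],
      valueLabel = "ratio")
}

#' Write fold-change results to TSV
#'
#' One row per protein with ratio, status, pass flag and (when a map is
#' supplied) the joined compartment; NA compartment means not in map.
#'
#' @param fc A \linkS4class{FoldChangeResult}.
#' @param path Output TSV path.
#' @param map Optional \linkS4class{ReferenceMap} for the compartment join.
#' @return \code{path}, invisibly.
#' @export
writeFoldChange <- function(fc, path, map = NULL) {
  stopifnot(is(fc, "FoldChangeResult"))
  d <- as.data.frame(fc@results)
  if (!is.null(map))
    d$compartment <- compartmentOf(map, d$accession)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
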