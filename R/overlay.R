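## Overlay of quantitation data on the reference map: abundance binning for
## size-coded display, per-fraction mapping statistics and per-compartment
## tallies of detected proteins.

#' Bin positive values for size-coded display
#'
#' MS intensities are roughly log-distributed, so values are log10
#' transformed before splitting into \code{nBins} bins. The default
#' \code{"quantile-log10"} scheme uses equal-frequency (quantile) breaks;
#' \code{"equal-width-log10"} splits the log10 range evenly. Ties at a bin
#' edge go to the lower bin; if every value is identical everything falls in
#' bin 1. Binning is monotone: a larger value never gets a smaller bin.
#'
#' @param values Positive numeric vector (missing/zero excluded upstream).
#' @param nBins Integer >= 1.
#' @param scheme \code{"quantile-log10"} or \code{"equal-width-log10"}.
#' @return Integer bin per value, in \code{1..nBins}; \code{integer(0)} for
#'   empty input. With heavy ties fewer than \code{nBins} bins may be
#'   occupied.
#' @export
#' @examples
#' binValues(c(1, 10, 100, 1000, 10000), nBins = 5)
binValues <- function(values, nBins = 5L,
                      scheme = c("quantile-log10", "equal-width-log10")) {
  scheme <- match.arg(scheme)
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 1L) stop("nBins must be >= 1")
  if (length(values) == 0L) return(integer())
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite; exclude missing values upstream")
  lv <- log10(values)
  breaks <- switch(scheme,
    "quantile-log10"    = stats::quantile(lv, probs = seq(0, 1,
                                          length.out = nBins + 1L),
                                          names = FALSE, type = 7),
    "equal-width-log10" = seq(min(lv), max(lv), length.out = nBins + 1L))
  breaks <- unique(breaks)
  if (length(breaks) < 2L) return(rep(1L, length(values)))
  ## right-closed intervals: a value sitting on an internal break falls in
  ## the lower bin
  as.integer(cut(lv, breaks = breaks, include.lowest = TRUE, right = TRUE,
                 labels = FALSE))
}

## overlay without mapping statistics, for internal subset tallies where an
## empty set is routine rather than noteworthy
.overlay_set <- function(acc, map, label = "presence") {
  acc <- unique(acc)
  mapComp <- compartments(map)
  coords <- coordinates(map)
  inMap <- acc[acc %in% names(mapComp)]
  pts <- if (length(inMap)) {
    DataFrame(accession = inMap, x = coords[inMap, "x"],
              y = coords[inMap, "y"], compartment = unname(mapComp[inMap]),
              value = rep(NA_real_, length(inMap)),
              bin = rep(NA_integer_, length(inMap)))
  } else .empty_points()
  new("MapOverlay", points = pts, unmapped = setdiff(acc, inMap),
      valueLabel = label)
}

.empty_points <- function() {
  DataFrame(accession = character(), x = numeric(), y = numeric(),
            compartment = character(), value = numeric(), bin = integer())
}

#' Overlay detected proteins on the reference map
#'
#' Joins a \linkS4class{QuantTable} (or a plain accession vector) onto a
#' \linkS4class{ReferenceMap}. Proteins present in the map receive
#' coordinates, a compartment and a size bin; the rest are listed as
#' \code{unmapped} (absence from the map is data, not an error). Mapping
#' statistics are computed per fraction, with detection defined as a
#' non-missing abundance in that fraction.
#'
#' @param x A \linkS4class{QuantTable} or character vector of accessions.
#' @param map A \linkS4class{ReferenceMap}.
#' @param valueColumn For a QuantTable: which fraction supplies the overlay
#'   values (default: first fraction). Ignored for accession vectors.
#' @param nBins,scheme Passed to \code{\link{binValues}} (applied to the
#'   values of mapped points).
#' @return A list with \code{overlay} (\linkS4class{MapOverlay}) and
#'   \code{stats} (DataFrame with \code{fraction}, \code{total_ids},
#'   \code{mapped}, \code{percent_mapped}). An empty detected set yields
#'   percent 0 with a warning.
#' @export
mapToReference <- function(x, map, valueColumn = NULL, nBins = 5L,
                           scheme = c("quantile-log10", "equal-width-log10")) {
  scheme <- match.arg(scheme)
  stopifnot(is(map, "ReferenceMap"))
  mapComp <- compartments(map)
  coords <- coordinates(map)

  if (is(x, "QuantTable")) {
    m <- abundances(x)
    if (is.null(valueColumn)) valueColumn <- colnames(m)[1L]
    if (!valueColumn %in% colnames(m))
      stop("unknown fraction id: ", valueColumn)
    stats <- do.call(rbind, lapply(colnames(m), function(fr) {
      det <- rownames(m)[!is.na(m[, fr])]
      .mapping_stats_row(fr, det, names(mapComp))
    }))
    det <- rownames(m)[!is.na(m[, valueColumn])]
    values <- stats::setNames(m[det, valueColumn], det)
    label <- valueColumn
  } else {
    det <- unique(normalizeAccession(as.character(x)))
    values <- stats::setNames(rep(NA_real_, length(det)), det)
    stats <- .mapping_stats_row("set", det, names(mapComp))
    label <- "presence"
  }

  inMap <- det[det %in% names(mapComp)]
  unmapped <- setdiff(det, inMap)
  if (length(inMap)) {
    v <- unname(values[inMap])
    bins <- if (all(is.na(v))) rep(NA_integer_, length(inMap))
            else binValues(v, nBins = nBins, scheme = scheme)
    pts <- DataFrame(accession = inMap,
                     x = coords[inMap, "x"], y = coords[inMap, "y"],
                     compartment = unname(mapComp[inMap]),
                     value = v, bin = bins)
  } else pts <- .empty_points()
  overlay <- new("MapOverlay", points = pts, unmapped = unmapped,
                 valueLabel = label)
  list(overlay = overlay, stats = stats)
}

.mapping_stats_row <- function(fraction, detected, mapAccessions) {
  total <- length(detected)
  mapped <- sum(detected %in% mapAccessions)
  if (total == 0L) {
    warning("no protein detected in '", fraction,
            "'; percent_mapped reported as 0")
    pct <- 0
  } else pct <- 100 * mapped / total
  DataFrame(fraction = fraction, total_ids = total, mapped = mapped,
            percent_mapped = pct)
}

#' Tally mapped proteins per compartment
#'
#' Counts the mapped points of an overlay in each of the 13 compartments
#' (zeros kept). Proteins absent from the map never appear in the tally;
#' they stay in the overlay's \code{unmapped} ledger. \code{"unknown"} is a
#' genuine row, as in the reference map itself.
#'
#' @param overlay A \linkS4class{MapOverlay}.
#' @return Named integer vector over \code{\link{compartmentLabels}}; the
#'   counts sum to the number of mapped points.
#' @export
tallyCompartments <- function(overlay) {
  stopifnot(is(overlay, "MapOverlay"))
  tt <- table(factor(overlay@points$compartment, levels = .COMPARTMENTS))
  stats::setNames(as.integer(tt), names(tt))
}

#' Share of a detected proteome that has map coordinates
#'
#' @param detectedTotal Number of detected proteins (> 0).
#' @param mapped Number of those with reference-map coordinates
#'   (0 <= mapped <= detectedTotal). A \code{\link{tallyCompartments}}
#'   result may be passed; it is summed.
#' @return List with \code{mapped}, \code{total}, \code{percent}
#'   (1 decimal) and \code{display} (integer-rounded percent).
#' @export
#' @examples
#' mappedFraction(1243, 908)$display  # 73
mappedFraction <- function(detectedTotal, mapped) {
  if (length(mapped) > 1L) mapped <- sum(mapped)
  detectedTotal <- as.numeric(detectedTotal); mapped <- as.numeric(mapped)
  if (is.na(detectedTotal) || detectedTotal <= 0)
    stop("detectedTotal must be > 0")
  if (is.na(mapped) || mapped < 0 || mapped > detectedTotal)
    stop("mapped must satisfy 0 <= mapped <= detectedTotal")
  pct <- 100 * mapped / detectedTotal
  list(mapped = mapped, total = detectedTotal,
       percent = round(pct, 1L), display = round(pct))
}

#' Compare two compartment tallies
#'
#' Signed per-compartment differences (a - b) plus human-readable summary
#' lines ("n fewer/more proteins in <compartment>").
#'
#' @param a,b Named integer vectors over the same compartment vocabulary
#'   (as returned by \code{\link{tallyCompartments}}).
#' @param nameA,nameB Labels used in the summary text.
#' @return List with \code{difference} (named integer, a - b) and
#'   \code{text} (character vector, one line per non-zero difference).
#' @export
compareTallies <- function(a, b, nameA = "A", nameB = "B") {
  if (!identical(sort(names(a)), sort(names(b))))
    stop("tallies must share the same compartment vocabulary")
  b <- b[names(a)]
  diff <- stats::setNames(as.integer(a) - as.integer(b), names(a))
  nz <- diff != 0L
  text <- if (any(nz)) {
    sprintf("%d %s protein%s in the %s compartment for %s compared to %s",
            abs(diff[nz]), ifelse(diff[nz] < 0L, "fewer", "more"),
            ifelse(abs(diff[nz]) == 1L, "", "s"), names(diff)[nz],
            nameA, nameB)
  } else character()
  list(difference = diff, text = unname(text))
}

#' Write a compartment tally to TSV
#'
#' Rows follow the canonical compartment order.
#'
#' @param tally Named integer vector from \code{\link{tallyCompartments}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTally <- function(tally, path) {
  d <- data.frame(assignment = .COMPARTMENTS,
                  mapped_proteins = as.integer(tally[.COMPARTMENTS]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mapping statistics to TSV
#'
#' @param stats DataFrame from \code{\link{mapToReference}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMappingStats <- function(stats, path) {
  d <- as.data.frame(stats)
  d$percent_mapped <- sprintf("%.2f%%", d$percent_mapped)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an overlay to TSV
#'
#' One row per detected protein: mapped points with coordinates, compartment,
#' value and bin, then unmapped accessions with empty fields.
#'
#' @param overlay A \linkS4class{MapOverlay}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeOverlay <- function(overlay, path) {
  stopifnot(is(overlay, "MapOverlay"))
  p <- as.data.frame(overlay@points)
  if (length(overlay@unmapped)) {
    u <- data.frame(accession = overlay@unmapped, x = NA_real_,
                    y = NA_real_, compartment = NA_character_,
                    value = NA_real_, bin = NA_integer_)
    p <- rbind(p, u)
  }
  p$in_map <- !is.na(p$compartment)
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
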