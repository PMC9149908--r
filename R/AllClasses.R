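#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Closed vocabulary of subcellular assignments carried by the reference map.
## "unknown" is a real assignment (diffuse / multi-fraction proteins) and is
## distinct from "not present in the map".
.COMPARTMENTS <- c(
  "cytosol", "endoplasmic reticulum", "golgi", "lysosome", "mitochondria",
  "nucleus", "nucleus-chromatin", "peroxisome", "plasma membrane",
  "proteasome", "ribosome 40S", "ribosome 60S", "unknown"
)

.ROLES <- c("ev-marker", "contaminant", "subtype")
.FC_STATUS <- c("both", "numerator_only", "denominator_only", "neither")

#' The 13 organellar assignment labels
#'
#' Returns the closed vocabulary of compartment labels used throughout the
#' package: twelve organellar assignments plus \code{"unknown"} for proteins
#' without a confident assignment. \code{"unknown"} is a legitimate map
#' assignment and is never used to stand in for "absent from the map".
#'
#' @return Character vector of 13 labels, in canonical (tally) order.
#' @export
#' @examples
#' compartmentLabels()
compartmentLabels <- function() .COMPARTMENTS

#' Default alias table for compartment spellings
#'
#' Input spellings are matched case-insensitively against the canonical
#' labels first, then against this explicit alias table. There is no fuzzy
#' matching: anything else is an error.
#'
#' @return Named character vector mapping lower-cased alias to canonical label.
#' @export
compartmentAliases <- function() {
  c("er"                   = "endoplasmic reticulum",
    "endoplasmic reticulum (er)" = "endoplasmic reticulum",
    "pm"                   = "plasma membrane",
    "mito"                 = "mitochondria",
    "mitochondrion"        = "mitochondria",
    "golgi apparatus"      = "golgi",
    "chromatin"            = "nucleus-chromatin",
    "nucleus - chromatin"  = "nucleus-chromatin",
    "40s ribosome"         = "ribosome 40S",
    "60s ribosome"         = "ribosome 60S")
}

#' Marker- and contaminant-region compartment sets
#'
#' Compartments whose proteins are expected (\code{markerRegion}) or not
#' expected (\code{contaminantRegion}) to contribute to extracellular-vesicle
#' preparations, following the MISEV2018 view of vesicle provenance: vesicle
#' markers map to the plasma membrane, lysosome, ER and cytosol, while
#' mitochondrial, ribosomal and nuclear proteins flag contamination.
#'
#' @return Character vector of compartment labels.
#' @export
markerRegion <- function() {
  c("plasma membrane", "lysosome", "endoplasmic reticulum", "cytosol")
}

#' @rdname markerRegion
#' @export
contaminantRegion <- function() {
  c("mitochondria", "nucleus", "nucleus-chromatin",
    "ribosome 40S", "ribosome 60S")
}

#' Endogenously biotinylated carboxylase control accessions
#'
#' The four human carboxylases used as positive controls for streptavidin
#' affinity selection: pyruvate carboxylase (P11498), propionyl-CoA
#' carboxylase alpha chain (P05165), methylcrotonoyl-CoA carboxylase subunit
#' alpha (Q96RQ3) and acetyl-CoA carboxylase 1 (Q13085). Overridable wherever
#' a control list is accepted (e.g. for other organisms).
#'
#' @return Character vector of four UniProt accessions.
#' @export
carboxylaseControls <- function() c("P11498", "P05165", "Q96RQ3", "Q13085")

## ---------------------------------------------------------------------------
## ReferenceMap

#' ReferenceMap: a fixed 2-D organellar reference map
#'
#' One row per protein: accession, t-SNE x/y coordinate and one of the 13
#' compartment labels. The map is immutable input; no re-embedding or
#' coordinate refinement is ever performed on it.
#'
#' @slot entries A \link[S4Vectors]{DataFrame} with columns \code{accession},
#'   \code{x}, \code{y}, \code{compartment}.
#' @export
setClass("ReferenceMap", representation(entries = "DataFrame"))

setValidity("ReferenceMap", function(object) {
  e <- object@entries
  need <- c("accession", "x", "y", "compartment")
  if (!all(need %in% colnames(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(e$accession))
    return(paste0("duplicate accession: ",
                  e$accession[duplicated(e$accession)][1L]))
  if (!is.numeric(e$x) || !is.numeric(e$y) ||
      any(!is.finite(e$x)) || any(!is.finite(e$y)))
    return("coordinates must be finite numbers")
  bad <- setdiff(unique(e$compartment), .COMPARTMENTS)
  if (length(bad))
    return(paste0("unknown compartment label(s): ",
                  paste(bad, collapse = ", "),
                  "; allowed: ", paste(.COMPARTMENTS, collapse = ", ")))
  TRUE
})

#' Construct a ReferenceMap
#'
#' @param accession Character vector of unique protein accessions.
#' @param x,y Numeric map coordinates (unitless t-SNE axes).
#' @param compartment Character vector of compartment labels drawn from
#'   \code{\link{compartmentLabels}}.
#' @return A \linkS4class{ReferenceMap}.
#' @export
ReferenceMap <- function(accession, x, y, compartment) {
  e <- DataFrame(accession = as.character(accession),
                 x = as.numeric(x), y = as.numeric(y),
                 compartment = as.character(compartment))
  rownames(e) <- e$accession
  new("ReferenceMap", entries = e)
}

## ---------------------------------------------------------------------------
## RegionAnnotation

#' RegionAnnotation: a labelled elliptical region of the map
#'
#' Regions summarise where a group of compartments sits on the map (e.g. the
#' plasma-membrane "P" or mitochondrial "M" ellipses drawn on overlay
#' figures). The ellipse is derived deterministically from member-protein
#' coordinates: centre = coordinate mean, covariance = sample covariance
#' scaled by \code{kSigma^2}. The role (enriched-marker / background /
#' neutral) is configuration, never computed.
#'
#' @slot regionId Short label, e.g. \code{"P"}, \code{"M"}.
#' @slot compartments Compartment labels the region covers.
#' @slot role One of \code{"enriched-marker"}, \code{"background-contaminant"},
#'   \code{"neutral"}.
#' @slot center Numeric length-2 centre (x, y).
#' @slot covariance 2x2 scaled covariance matrix.
#' @slot kSigma The standard-deviation multiple the ellipse was scaled to.
#' @export
setClass("RegionAnnotation", representation(
  regionId = "character", compartments = "character", role = "character",
  center = "numeric", covariance = "matrix", kSigma = "numeric"))

setValidity("RegionAnnotation", function(object) {
  if (length(object@center) != 2L) return("center must have length 2")
  if (!all(dim(object@covariance) == c(2L, 2L)))
    return("covariance must be 2x2")
  if (!object@role %in% c("enriched-marker", "background-contaminant",
                          "neutral"))
    return("invalid role")
  TRUE
})

## ---------------------------------------------------------------------------
## QuantTable

#' QuantTable: protein-by-fraction abundance matrix
#'
#' A thin \link[SummarizedExperiment]{SummarizedExperiment} with a single
#' \code{"abundance"} assay: rows are proteins (normalized accessions),
#' columns are fractions or preparation groups (e.g. \code{W-1}, \code{W-2},
#' \code{Elute}). Abundances are non-negative MS intensities; \code{NA} means
#' "not quantified in this fraction". Blank, \code{NA} and zero input cells
#' are all treated as missing.
#'
#' @export
setClass("QuantTable", contains = "SummarizedExperiment")

setValidity("QuantTable", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("QuantTable needs an 'abundance' assay")
  m <- SummarizedExperiment::assay(object, "abundance")
  if (ncol(m) < 1L) return("at least one fraction is required")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("accessions (rownames) must be present and unique")
  if (any(m < 0, na.rm = TRUE)) return("abundances must be non-negative")
  if (any(m == 0, na.rm = TRUE))
    return("zero abundances must be encoded as NA (missing)")
  TRUE
})

#' Construct a QuantTable from an abundance matrix
#'
#' @param abundance Numeric matrix, rows named by accession, columns by
#'   fraction id. Zeros and blanks are converted to \code{NA} (missing).
#' @param normalize Normalize accessions (uppercase, trim, isoform collapse)?
#' @return A \linkS4class{QuantTable}.
#' @export
QuantTable <- function(abundance, normalize = TRUE) {
  abundance <- as.matrix(abundance)
  if (normalize)
    rownames(abundance) <- normalizeAccession(rownames(abundance))
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate accession after normalization: ",
         rownames(abundance)[duplicated(rownames(abundance))][1L])
  abundance[!is.na(abundance) & abundance == 0] <- NA_real_
  new("QuantTable",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance)))
}

## ---------------------------------------------------------------------------
## MarkerSet

#' MarkerSet: categorized marker accessions
#'
#' MISEV2018-style marker list: each accession belongs to exactly one of five
#' categories; the role follows from the category (1, 2, 5 = ev-marker;
#' 3 = contaminant; 4 = subtype).
#'
#' @slot entries DataFrame with columns \code{accession}, \code{category}
#'   (integer 1-5) and \code{role}.
#' @export
setClass("MarkerSet", representation(entries = "DataFrame"))

setValidity("MarkerSet", function(object) {
  e <- object@entries
  if (!all(c("accession", "category", "role") %in% colnames(e)))
    return("entries must have columns accession, category, role")
  if (anyDuplicated(e$accession))
    return(paste0("accession assigned to more than one category: ",
                  e$accession[duplicated(e$accession)][1L]))
  if (length(e$category) && (!is.integer(e$category) ||
      any(!e$category %in% 1:5)))
    return("category must be an integer in 1..5")
  if (!all(e$role %in% .ROLES))
    return(paste("role must be one of", paste(.ROLES, collapse = ", ")))
  expect <- roleForCategory(e$category)
  if (length(e$role) && any(e$role != expect))
    return("role inconsistent with category (1,2,5 = ev-marker; 3 = contaminant; 4 = subtype)")
  TRUE
})

#' Role implied by a marker category
#'
#' @param category Integer vector of categories 1-5.
#' @return Character vector of roles.
#' @export
roleForCategory <- function(category) {
  unname(c(`1` = "ev-marker", `2` = "ev-marker", `3` = "contaminant",
           `4` = "subtype", `5` = "ev-marker")[as.character(category)])
}

#' Construct a MarkerSet
#'
#' @param accession Character accessions (normalized internally).
#' @param category Integer categories 1-5, one per accession.
#' @param role Optional roles; derived from category when omitted.
#' @param normalize Normalize accessions first?
#' @return A \linkS4class{MarkerSet}.
#' @export
MarkerSet <- function(accession = character(), category = integer(),
                      role = NULL, normalize = TRUE) {
  accession <- as.character(accession)
  if (normalize && length(accession))
    accession <- normalizeAccession(accession)
  category <- as.integer(category)
  if (is.null(role)) role <- roleForCategory(category)
  e <- DataFrame(accession = accession, category = category,
                 role = as.character(role))
  new("MarkerSet", entries = e)
}

## ---------------------------------------------------------------------------
## MapOverlay

#' MapOverlay: quantitation joined onto the reference map
#'
#' Result of overlaying a detected protein set (with optional values) on a
#' \linkS4class{ReferenceMap}. \code{points} holds the mapped proteins with
#' coordinates, compartment, value and size bin; \code{unmapped} lists
#' detected accessions absent from the map. Together they partition the
#' detected input set.
#'
#' @slot points DataFrame with columns \code{accession}, \code{x}, \code{y},
#'   \code{compartment}, \code{value}, \code{bin}.
#' @slot unmapped Character vector of detected accessions not in the map.
#' @slot valueLabel What \code{value} holds (fraction id, "ratio", ...).
#' @export
setClass("MapOverlay", representation(
  points = "DataFrame", unmapped = "character", valueLabel = "character"))

setValidity("MapOverlay", function(object) {
  p <- object@points
  need <- c("accession", "x", "y", "compartment", "value", "bin")
  if (!all(need %in% colnames(p)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(c(p$accession, object@unmapped)))
    return("accessions must be unique across points and unmapped")
  if (!all(p$compartment %in% .COMPARTMENTS))
    return("every mapped point must carry a valid compartment")
  b <- p$bin[!is.na(p$bin)]
  if (length(b) && any(b < 1L)) return("bins must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## FoldChangeResult

#' FoldChangeResult: per-protein between-fraction ratios
#'
#' Ratios of numerator-fraction over denominator-fraction abundance. Each
#' protein carries a presence status: \code{both} (ratio defined),
#' \code{numerator_only}, \code{denominator_only} or \code{neither}. After
#' \code{\link{applyCutoff}} the \code{passes} column and the \code{cutoff} /
#' \code{includeNumeratorOnly} slots are filled.
#'
#' @slot results DataFrame: \code{accession}, \code{numerator},
#'   \code{denominator}, \code{ratio}, \code{status}, \code{passes}.
#' @slot numeratorFraction,denominatorFraction The fraction ids ratioed.
#' @slot cutoff Applied cutoff (NA before \code{applyCutoff}).
#' @slot includeNumeratorOnly Whether numerator-only proteins count as passing.
#' @export
setClass("FoldChangeResult", representation(
  results = "DataFrame", numeratorFraction = "character",
  denominatorFraction = "character", cutoff = "numeric",
  includeNumeratorOnly = "logical"))

setValidity("FoldChangeResult", function(object) {
  r <- object@results
  need <- c("accession", "numerator", "denominator", "ratio", "status",
            "passes")
  if (!all(need %in% colnames(r)))
    return(paste("results must have columns", paste(need, collapse = ", ")))
  if (!all(r$status %in% .FC_STATUS)) return("invalid status value")
  ok <- r$status == "both"
  if (any(!is.na(r$ratio[!ok]))) return("ratio defined only for status=both")
  if (any(is.na(r$ratio[ok])) || any(r$ratio[ok] <= 0))
    return("both-status ratios must be finite and > 0")
  if (any(r$passes[r$status == "neither"], na.rm = TRUE))
    return("neither-status proteins can never pass")
  TRUE
})

## ---------------------------------------------------------------------------
## CarboxylaseBenchmark

#' CarboxylaseBenchmark: positive-control enrichment ratios
#'
#' Per-control numerator/denominator abundance ratios for the endogenously
#' biotinylated carboxylases, their min/max, and the total-abundance ratio
#' (sum of numerator abundances over sum of denominator abundances across
#' controls detected in both fractions). Controls missing from either
#' fraction are excluded and reported.
#'
#' @slot controls Control accessions requested.
#' @slot ratios Named numeric per-control ratios (both-detected controls).
#' @slot minRatio,maxRatio,totalRatio Summary ratios.
#' @slot missing Controls not detected in both fractions.
#' @export
setClass("CarboxylaseBenchmark", representation(
  controls = "character", ratios = "numeric", minRatio = "numeric",
  maxRatio = "numeric", totalRatio = "numeric", missing = "character"))

setValidity("CarboxylaseBenchmark", function(object) {
  if (length(object@ratios) == 0L) return("no control detected in both fractions")
  if (object@minRatio > object@maxRatio) return("minRatio > maxRatio")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "ReferenceMap", function(object) {
  e <- object@entries
  cat("ReferenceMap with", nrow(e), "proteins\n")
  tt <- table(factor(e$compartment, levels = .COMPARTMENTS))
  cat("  compartments:",
      paste0(names(tt)[tt > 0], " (", tt[tt > 0], ")", collapse = ", "), "\n")
})

setMethod("show", "QuantTable", function(object) {
  m <- SummarizedExperiment::assay(object, "abundance")
  cat("QuantTable:", nrow(m), "proteins x", ncol(m), "fractions (",
      paste(colnames(m), collapse = ", "), ")\n")
  cat("  missing cells:", sum(is.na(m)), "of", length(m), "\n")
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet with", nrow(object@entries), "accessions\n")
  tot <- categoryTotals(object)
  cat("  category totals:",
      paste(names(tot), tot, sep = ":", collapse = " "), "\n")
})

setMethod("show", "MapOverlay", function(object) {
  cat("MapOverlay (", object@valueLabel, "): ", nrow(object@points),
      " mapped, ", length(object@unmapped), " not in map\n", sep = "")
})

setMethod("show", "FoldChangeResult", function(object) {
  r <- object@results
  cat("FoldChangeResult ", object@numeratorFraction, "/",
      object@denominatorFraction, ": ", nrow(r), " proteins (",
      paste(names(table(r$status)), table(r$status), sep = "=",
            collapse = ", "), ")\n", sep = "")
  if (!is.na(object@cutoff))
    cat("  cutoff ", object@cutoff, ": ", nPassed(object), " pass\n", sep = "")
})

setMethod("show", "CarboxylaseBenchmark", function(object) {
  cat("CarboxylaseBenchmark over", length(object@ratios), "controls:",
      "min", signif(object@minRatio, 3), "max", signif(object@maxRatio, 3),
      "total", signif(object@totalRatio, 3), "\n")
  if (length(object@missing))
    cat("  missing from a fraction:", paste(object@missing, collapse = ", "),
        "\n")
})
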