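## Evaluation of a detected proteome against a categorized marker list:
## per-category recovery percentages, marker-vs-contaminant compartment
## summaries and a descriptive preparation report for extracellular-vesicle
## quality assessment.

#' Per-category marker recovery
#'
#' For each of the five marker categories: how many of its accessions appear
#' in the detected set, as a count and a percentage of the category total.
#' Exact set intersection on normalized accessions; adding non-marker
#' accessions to the detected set never changes the result.
#'
#' @param detected Character vector of detected accessions (normalized here).
#' @param markers A \linkS4class{MarkerSet}.
#' @return Data frame with columns \code{category}, \code{total},
#'   \code{detected}, \code{percent} (1 decimal; \code{NA} for an empty
#'   category, where the percentage is undefined).
#' @export
#' @examples
#' ms <- MarkerSet(c("A1", "A2", "B1"), c(1L, 1L, 3L))
#' categoryRecovery(c("A1", "X9"), ms)
categoryRecovery <- function(detected, markers) {
  stopifnot(is(markers, "MarkerSet"))
  detected <- unique(normalizeAccession(as.character(detected)))
  e <- markers@entries
  tot <- categoryTotals(markers)
  det <- vapply(1:5, function(k)
    sum(e$accession[e$category == k] %in% detected), integer(1L))
  pct <- ifelse(tot > 0L, round(100 * det / tot, 1L), NA_real_)
  data.frame(category = 1:5, total = as.integer(tot), detected = det,
             percent = pct)
}

#' Compartment tallies of detected markers, split by role
#'
#' Restricts the detected set to the marker list, overlays each role's
#' members (ev-marker, contaminant, subtype) on the reference map and
#' tallies compartments per role. Each detected marker is counted once,
#' under its role.
#'
#' @param detected Character vector of detected accessions.
#' @param markers A \linkS4class{MarkerSet}.
#' @param map A \linkS4class{ReferenceMap}.
#' @return Integer matrix, rows = roles, columns = the 13 compartments.
#'   Markers absent from the map are not counted (they have no compartment).
#' @export
roleSummary <- function(detected, markers, map) {
  stopifnot(is(markers, "MarkerSet"), is(map, "ReferenceMap"))
  detected <- unique(normalizeAccession(as.character(detected)))
  e <- markers@entries
  out <- matrix(0L, nrow = length(.ROLES), ncol = length(.COMPARTMENTS),
                dimnames = list(.ROLES, .COMPARTMENTS))
  for (role in .ROLES) {
    acc <- intersect(e$accession[e$role == role], detected)
    out[role, ] <- tallyCompartments(.overlay_set(acc, map))
  }
  out
}

#' Descriptive report on a vesicle preparation
#'
#' Bundles the quantities used to judge how vesicle-enriched a preparation
#' is: category recovery, per-role compartment tallies, the mapped fraction
#' of the detected proteome, the full compartment tally, and the shares of
#' mapped detected proteins falling in the marker region (plasma membrane,
#' lysosome, ER, cytosol) versus the contaminant region (mitochondria,
#' nucleus, nucleus-chromatin, ribosomes). A dense contaminant region
#' suggests a poorly enriched preparation. The report is purely descriptive:
#' no good/poor verdict is issued unless a threshold is configured.
#'
#' @param detected Character vector of detected accessions.
#' @param markers A \linkS4class{MarkerSet}.
#' @param map A \linkS4class{ReferenceMap}.
#' @param markerCompartments,contaminantCompartments Region definitions;
#'   defaults \code{\link{markerRegion}} / \code{\link{contaminantRegion}}.
#' @param contaminantShareThreshold Optional number in [0, 1]; when set, the
#'   report carries a \code{flagged} field that is \code{TRUE} if the
#'   contaminant-region share exceeds it. Default \code{NULL} (off).
#' @return A list with \code{recovery}, \code{roles}, \code{mapping}
#'   (\code{\link{mappedFraction}} result), \code{tally},
#'   \code{markerShare}, \code{contaminantShare} (shares of mapped detected
#'   proteins; \code{NA} when nothing maps) and optionally \code{flagged}.
#' @export
preparationReport <- function(detected, markers, map,
                              markerCompartments = markerRegion(),
                              contaminantCompartments = contaminantRegion(),
                              contaminantShareThreshold = NULL) {
  detected <- if (length(detected))
    unique(normalizeAccession(as.character(detected))) else character()
  tally <- tallyCompartments(.overlay_set(detected, map))
  nMapped <- sum(tally)
  mapping <- if (length(detected))
    mappedFraction(length(detected), nMapped)
  else list(mapped = 0, total = 0, percent = NA_real_, display = NA_real_)
  share <- function(set) if (nMapped > 0L) sum(tally[set]) / nMapped
                         else NA_real_
  rep <- list(recovery = categoryRecovery(detected, markers),
              roles = roleSummary(detected, markers, map),
              mapping = mapping, tally = tally,
              markerShare = share(markerCompartments),
              contaminantShare = share(contaminantCompartments))
  if (!is.null(contaminantShareThreshold))
    rep$flagged <- !is.na(rep$contaminantShare) &&
      rep$contaminantShare > contaminantShareThreshold
  rep
}

#' Write a preparation report to a directory
#'
#' Writes \code{category_recovery.tsv} (category order), \code{role_summary.tsv}
#' (compartment rows in tally order) and a plain-text
#' \code{preparation_report.txt} summary.
#'
#' @param report List from \code{\link{preparationReport}}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
writePreparationReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fRec <- file.path(dir, "category_recovery.tsv")
  utils::write.table(report$recovery, fRec, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  fRole <- file.path(dir, "role_summary.tsv")
  roles <- data.frame(assignment = colnames(report$roles),
                      t(report$roles), check.names = FALSE)
  utils::write.table(roles, fRole, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fTxt <- file.path(dir, "preparation_report.txt")
  lines <- c(
    "Vesicle preparation report",
    sprintf("Detected proteins: %d; with map coordinates: %d (%s%%)",
            as.integer(report$mapping$total),
            as.integer(report$mapping$mapped),
            format(report$mapping$display)),
    sprintf("Marker-region share of mapped proteins: %s",
            format(round(report$markerShare, 3L))),
    sprintf("Contaminant-region share of mapped proteins: %s",
            format(round(report$contaminantShare, 3L))),
    if (!is.null(report$flagged))
      sprintf("Contaminant-share flag: %s", report$flagged),
    "",
    "Category recovery:",
    sprintf("  category %d: %d / %d (%s%%)", report$recovery$category,
            report$recovery$detected, report$recovery$total,
            format(report$recovery$percent)))
  writeLines(lines, fTxt)
  invisible(c(fRec, fRole, fTxt))
}
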