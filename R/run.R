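## Pipeline entry points behind the command-line interface: each run*
## function validates its configuration up front, computes everything, then
## writes outputs plus a machine-readable provenance record. Inputs are
## validated before any file is written, so a failing run leaves no partial
## outputs.

.val_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("orgmap_validation_error",
                                             "error", "condition")))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .val_error("config file not found: ", path)
  yaml::read_yaml(path)
}

.as_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  if (!is.list(config)) .val_error("config must be a list or a YAML path")
  config
}

.need_paths <- function(config, keys) {
  for (k in keys) {
    p <- config$paths[[k]]
    if (is.null(p)) .val_error("config$paths$", k, " is required")
    if (k != "outdir" && !file.exists(p))
      .val_error("input file not found: ", p)
  }
}

.quant_colspec <- function(config) {
  cs <- config$columnSpec
  list(accession = if (is.null(cs$accession)) "accession" else cs$accession,
       fractions = cs$fractions)
}

.binning <- function(config) {
  b <- config$binning
  list(nBins = if (is.null(b$nBins)) 5L else as.integer(b$nBins),
       scheme = if (is.null(b$scheme)) "quantile-log10" else b$scheme)
}

.image_ext <- function(config) {
  fmt <- config$format
  if (is.null(fmt)) "png" else fmt
}

.write_provenance <- function(config, outdir, inputs) {
  rec <- list(package = "orgmap",
              version = as.character(utils::packageVersion("orgmap")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              config = config,
              input_checksums = as.list(tools::md5sum(inputs)))
  path <- file.path(outdir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the abundance-overlay pipeline
#'
#' Loads a reference map and a quantitation table, overlays the configured
#' fraction, and writes \code{overlay.tsv}, \code{mapping_stats.tsv},
#' \code{compartment_tally.tsv}, a map image and \code{provenance.json}
#' into \code{paths$outdir}. Reruns with an identical configuration produce
#' identical TSV outputs.
#'
#' @param config Configuration list or YAML path with \code{paths} (map,
#'   quant, outdir), optional \code{columnSpec} (accession, fractions),
#'   \code{valueColumn}, \code{binning} (nBins, scheme), \code{format}
#'   (png/svg/pdf) and \code{duplicatePolicy}.
#' @return Named character vector of output paths, invisibly.
#' @export
runOverlay <- function(config) {
  config <- .as_config(config)
  .need_paths(config, c("map", "quant", "outdir"))
  map <- loadReferenceMap(config$paths$map)
  quant <- loadQuantTable(config$paths$quant,
                          columnSpec = .quant_colspec(config),
                          duplicatePolicy = if (is.null(config$duplicatePolicy))
                            "error" else config$duplicatePolicy)
  b <- .binning(config)
  res <- mapToReference(quant, map, valueColumn = config$valueColumn,
                        nBins = b$nBins, scheme = b$scheme)
  tally <- tallyCompartments(res$overlay)

  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- c(overlay = writeOverlay(res$overlay,
                                  file.path(outdir, "overlay.tsv")),
           stats = writeMappingStats(res$stats,
                                     file.path(outdir, "mapping_stats.tsv")),
           tally = writeTally(tally,
                              file.path(outdir, "compartment_tally.tsv")),
           image = renderMap(res$overlay,
                             file.path(outdir,
                                       paste0("map.", .image_ext(config))),
                             map = map),
           provenance = .write_provenance(config, outdir,
                                          c(config$paths$map,
                                            config$paths$quant)))
  invisible(out)
}

.resolve_cutoff <- function(config, quant) {
  cut <- config$cutoff
  policy <- if (is.null(cut$policy)) "fixed" else cut$policy
  value <- if (is.null(cut$value)) 3 else as.numeric(cut$value)
  if (policy == "fixed") return(value)
  controls <- if (is.null(config$controls)) carboxylaseControls()
              else config$controls
  bench <- carboxylaseBenchmark(quant, config$numeratorFraction,
                                config$denominatorFraction,
                                controls = controls)
  suggestCutoff(bench, policy = policy, value = value)
}

#' Run the proximity-labeling enrichment pipeline
#'
#' Computes the Elute/wash fold change, the carboxylase benchmark and the
#' cutoff-filtered candidate set, writing \code{fold_change.tsv},
#' \code{benchmark.tsv}, \code{candidates.tsv}, optionally a fold-change
#' map image, and \code{provenance.json}.
#'
#' @param config Configuration list or YAML path with \code{paths} (quant,
#'   outdir and optionally map), \code{numeratorFraction} (default
#'   \code{"Elute"}), \code{denominatorFraction} (default \code{"W-2"}),
#'   \code{cutoff} (list: policy fixed/min_control/total, value),
#'   \code{controls}, \code{includeNumeratorOnly}, \code{columnSpec},
#'   \code{duplicatePolicy}, \code{format}.
#' @return Named character vector of output paths, invisibly.
#' @export
runBioid <- function(config) {
  config <- .as_config(config)
  .need_paths(config, c("quant", "outdir"))
  hasMap <- !is.null(config$paths$map)
  if (hasMap) .need_paths(config, "map")
  if (is.null(config$numeratorFraction)) config$numeratorFraction <- "Elute"
  if (is.null(config$denominatorFraction)) config$denominatorFraction <- "W-2"
  quant <- loadQuantTable(config$paths$quant,
                          columnSpec = .quant_colspec(config),
                          duplicatePolicy = if (is.null(config$duplicatePolicy))
                            "error" else config$duplicatePolicy)
  map <- if (hasMap) loadReferenceMap(config$paths$map) else NULL
  controls <- if (is.null(config$controls)) carboxylaseControls()
              else config$controls
  fc <- computeFoldChange(quant, config$numeratorFraction,
                          config$denominatorFraction)
  bench <- carboxylaseBenchmark(quant, config$numeratorFraction,
                                config$denominatorFraction,
                                controls = controls)
  cutoff <- .resolve_cutoff(config, quant)
  incNum <- if (is.null(config$includeNumeratorOnly)) TRUE
            else isTRUE(config$includeNumeratorOnly)
  fc <- applyCutoff(fc, cutoff, includeNumeratorOnly = incNum)

  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fBench <- file.path(outdir, "benchmark.tsv")
  utils::write.table(
    data.frame(control = names(bench@ratios),
               ratio = unname(bench@ratios)),
    fBench, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# min_ratio\t%g\n# max_ratio\t%g\n# total_ratio\t%g\n",
              bench@minRatio, bench@maxRatio, bench@totalRatio),
      file = fBench, append = TRUE)

  cand <- fc@results[fc@results$passes, ]
  candDf <- as.data.frame(cand)
  if (hasMap) candDf$compartment <- compartmentOf(map, candDf$accession)
  fCand <- file.path(outdir, "candidates.tsv")
  utils::write.table(candDf, fCand, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  out <- c(fold_change = writeFoldChange(fc,
                                         file.path(outdir,
                                                   "fold_change.tsv"),
                                         map = map),
           benchmark = fBench, candidates = fCand)
  if (hasMap)
    out <- c(out, image = renderComparison(
      fc, map, file.path(outdir, paste0("fold_change_map.",
                                        .image_ext(config))),
      passedOnly = TRUE))
  out <- c(out, provenance = .write_provenance(
    config, outdir, c(config$paths$quant,
                      if (hasMap) config$paths$map)))
  invisible(out)
}

#' Run the extracellular-vesicle evaluation pipeline
#'
#' Evaluates one preparation (one fraction of the quantitation table)
#' against a categorized marker list on the reference map, writing
#' \code{category_recovery.tsv}, \code{role_summary.tsv},
#' \code{preparation_report.txt}, a map image and \code{provenance.json}.
#'
#' @param config Configuration list or YAML path with \code{paths} (quant,
#'   markers, map, outdir), optional \code{valueColumn} (fraction holding
#'   the preparation; default first), \code{columnSpec}, \code{binning},
#'   \code{duplicatePolicy}, \code{format},
#'   \code{contaminantShareThreshold}.
#' @return Named character vector of output paths, invisibly.
#' @export
runEv <- function(config) {
  config <- .as_config(config)
  .need_paths(config, c("quant", "markers", "map", "outdir"))
  map <- loadReferenceMap(config$paths$map)
  quant <- loadQuantTable(config$paths$quant,
                          columnSpec = .quant_colspec(config),
                          duplicatePolicy = if (is.null(config$duplicatePolicy))
                            "error" else config$duplicatePolicy)
  markers <- loadMarkerSet(config$paths$markers)
  fraction <- if (is.null(config$valueColumn)) fractionIds(quant)[1L]
              else config$valueColumn
  detected <- detectedIn(quant, fraction)
  report <- preparationReport(
    detected, markers, map,
    contaminantShareThreshold = config$contaminantShareThreshold)
  b <- .binning(config)
  ov <- mapToReference(quant, map, valueColumn = fraction,
                       nBins = b$nBins, scheme = b$scheme)$overlay

  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- writePreparationReport(report, outdir)
  out <- c(recovery = files[1L], roles = files[2L], report = files[3L],
           image = renderMap(ov, file.path(outdir,
                                           paste0("ev_map.",
                                                  .image_ext(config))),
                             map = map),
           provenance = .write_provenance(
             config, outdir, c(config$paths$quant, config$paths$markers,
                               config$paths$map)))
  invisible(out)
}

#' Generate and write a full synthetic dataset
#'
#' Runs the three generators under the configured seed and writes
#' \code{reference_map.tsv}, \code{bioid_test.csv}, \code{bioid_control.csv},
#' \code{bioid_truth.tsv}, \code{markers.tsv}, \code{ev_quant.csv},
#' \code{ev_truth.tsv} and \code{provenance.json}.
#'
#' @param config Configuration list or YAML path with \code{paths$outdir},
#'   optional \code{seed} (default 1) and optional \code{bioid} / \code{ev}
#'   override lists (see \code{\link{synthConfig}}).
#' @return Named character vector of output paths, invisibly.
#' @export
runSynth <- function(config) {
  config <- .as_config(config)
  .need_paths(config, "outdir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- synthConfig(seed = seed,
                     bioid = if (is.null(config$bioid)) list() else
                       config$bioid,
                     ev = if (is.null(config$ev)) list() else config$ev)
  map <- generateReferenceMap(cfg)
  bio <- generateBioidExperiment(cfg, map)
  ev <- generateEvExperiment(cfg, map)

  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wTruth <- function(d, path) {
    utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  out <- c(map = writeReferenceMap(map,
                                   file.path(outdir, "reference_map.tsv")),
           bioid_test = writeQuantTable(bio$test,
                                        file.path(outdir, "bioid_test.csv")),
           bioid_control = writeQuantTable(bio$control,
                                           file.path(outdir,
                                                     "bioid_control.csv")),
           bioid_truth = wTruth(bio$truth,
                                file.path(outdir, "bioid_truth.tsv")),
           markers = writeMarkerSet(ev$markers,
                                    file.path(outdir, "markers.tsv")),
           ev_quant = writeQuantTable(ev$quant,
                                      file.path(outdir, "ev_quant.csv")),
           ev_truth = wTruth(ev$truth, file.path(outdir, "ev_truth.tsv")),
           provenance = .write_provenance(config, outdir, character()))
  invisible(out)
}
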