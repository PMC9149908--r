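## Map rendering: size-coded overlays on the organellar reference map with
## optional highlight colours and region ellipses. Point size is linear in
## bin index.

#' Default compartment colour palette
#'
#' One colour per compartment, following the conventional organellar-map
#' colouring (cytosol light blue, ER dark blue, golgi light green, lysosome
#' dark green, mitochondria pink, nucleus red, nucleus-chromatin light
#' orange, peroxisome dark orange, plasma membrane light purple, proteasome
#' dark purple, ribosome 40S yellow, ribosome 60S brown, unknown grey).
#' The exact hex values are package constants.
#'
#' @return Named character vector of 13 hex colours.
#' @export
compartmentPalette <- function() {
  c("cytosol"               = "#8FC9EF",
    "endoplasmic reticulum" = "#1F4E9C",
    "golgi"                 = "#9BDB8F",
    "lysosome"              = "#1F7A33",
    "mitochondria"          = "#F2A0C0",
    "nucleus"               = "#D62728",
    "nucleus-chromatin"     = "#FDBE6F",
    "peroxisome"            = "#E06A10",
    "plasma membrane"       = "#C5A3E0",
    "proteasome"            = "#5E2D91",
    "ribosome 40S"          = "#E8D21D",
    "ribosome 60S"          = "#8C5A2B",
    "unknown"               = "#BDBDBD")
}

.ellipse_path <- function(region, n = 120L) {
  ## boundary of the kSigma ellipse: center + L %*% unit circle, with
  ## L a Cholesky-like factor of the scaled covariance (eigen is robust to
  ## the zero-covariance degenerate case)
  eg <- eigen(region@covariance, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta))
  pts <- eg$vectors %*% diag(sqrt(lam), 2L) %*% circ
  data.frame(x = region@center["x"] + pts[1L, ],
             y = region@center["y"] + pts[2L, ],
             region = region@regionId, role = region@role)
}

.region_colour <- c("enriched-marker" = "#1F7A33",
                    "background-contaminant" = "#C0272D",
                    "neutral" = "#555555")

#' Build a size-coded map plot
#'
#' The full reference map is drawn as small grey background points (the
#' fixed organellar space), with the overlay's mapped points on top,
#' coloured by compartment and sized by bin. Highlighted accessions are
#' re-drawn in their highlight colour; region ellipses are drawn as open
#' outlines coloured by role (marker green, contaminant red).
#'
#' @param overlay A \linkS4class{MapOverlay}.
#' @param map Optional \linkS4class{ReferenceMap} for the background layer.
#' @param highlights Named character vector: accession -> colour. Accessions
#'   absent from the overlay are skipped with a warning.
#' @param regions List of \linkS4class{RegionAnnotation} objects.
#' @param palette Compartment colour map (all 13 labels).
#' @param background Draw the reference-map background layer?
#' @param sizeRange Point-size range (mm) mapped linearly over bins.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plotMap <- function(overlay, map = NULL, highlights = NULL, regions = NULL,
                    palette = compartmentPalette(), background = TRUE,
                    sizeRange = c(0.8, 3.2), title = NULL) {
  stopifnot(is(overlay, "MapOverlay"))
  if (nrow(overlay@points) == 0L) stop("empty overlay: nothing to plot")
  miss <- setdiff(.COMPARTMENTS, names(palette))
  if (length(miss)) stop("palette missing compartment(s): ",
                         paste(miss, collapse = ", "))
  p <- as.data.frame(overlay@points)
  p$bin[is.na(p$bin)] <- 1L
  g <- ggplot2::ggplot()
  if (background && !is.null(map)) {
    bg <- as.data.frame(map@entries)
    g <- g + ggplot2::geom_point(
      data = bg, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey85", size = 0.4)
  }
  g <- g + ggplot2::geom_point(
    data = p,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$compartment,
                 size = .data$bin)) +
    ggplot2::scale_colour_manual(values = palette, drop = FALSE) +
    ggplot2::scale_size_continuous(range = sizeRange,
                                   breaks = sort(unique(p$bin)))
  if (!is.null(highlights) && length(highlights)) {
    hit <- names(highlights) %in% p$accession
    if (any(!hit))
      warning("highlight accession(s) not in overlay, skipped: ",
              paste(names(highlights)[!hit], collapse = ", "))
    if (any(hit)) {
      hp <- p[match(names(highlights)[hit], p$accession), ]
      hp$colour <- unname(highlights[hit])
      g <- g + ggplot2::geom_point(
        data = hp, ggplot2::aes(x = .data$x, y = .data$y,
                                size = .data$bin),
        colour = hp$colour, stroke = 1.1, shape = 21)
    }
  }
  if (!is.null(regions)) {
    for (r in regions) {
      path <- .ellipse_path(r)
      g <- g + ggplot2::geom_path(
        data = path, ggplot2::aes(x = .data$x, y = .data$y),
        colour = .region_colour[[r@role]], linewidth = 0.6) +
        ggplot2::annotate("text", x = r@center["x"], y = r@center["y"],
                          label = r@regionId,
                          colour = .region_colour[[r@role]], fontface = 2)
    }
  }
  g + ggplot2::labs(title = title, x = "map x", y = "map y",
                    colour = "compartment", size = "bin") +
    ggplot2::theme_minimal()
}

.open_device <- function(path, width, height, dpi) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported image format: .", ext, " (use svg, png or pdf)"))
}

#' Render an overlay to an image file
#'
#' Writes SVG, PNG or PDF (chosen by extension). Given identical inputs the
#' output is deterministic.
#'
#' @param overlay A \linkS4class{MapOverlay}.
#' @param outPath Output file path ending in .svg, .png or .pdf.
#' @param ... Passed to \code{\link{plotMap}}.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG.
#' @return \code{outPath}, invisibly.
#' @export
renderMap <- function(overlay, outPath, ..., width = 7, height = 6,
                      dpi = 150) {
  g <- plotMap(overlay, ...)
  dir <- dirname(outPath)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  .open_device(outPath, width, height, dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(g)
  invisible(outPath)
}

#' Render a fold-change comparison map
#'
#' Convenience wrapper: overlays both-status fold-change ratios on the map
#' (point size encodes the binned ratio) and renders to file.
#'
#' @param fc A \linkS4class{FoldChangeResult}.
#' @param map A \linkS4class{ReferenceMap}.
#' @param outPath Output file path.
#' @param passedOnly Restrict to proteins passing the applied cutoff?
#' @param nBins Number of size bins.
#' @param ... Passed to \code{\link{renderMap}} / \code{\link{plotMap}}.
#' @return \code{outPath}, invisibly.
#' @export
renderComparison <- function(fc, map, outPath, passedOnly = FALSE,
                             nBins = 5L, ...) {
  ov <- foldChangeOverlay(fc, map, passedOnly = passedOnly, nBins = nBins)
  renderMap(ov, outPath, map = map, ...)
}
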