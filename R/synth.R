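## Synthetic-data generators: Gaussian compartment clusters for the
## reference map, BioID-style wash/elute tables with planted interactors and
## carboxylase controls, and EV-style preparations with category-structured
## marker sets. Fully deterministic under a fixed seed so every pipeline
## stage is testable without downloads.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Default synthetic compartment layout
#'
#' Twelve organellar clusters evenly spaced on a circle of radius 30 with
#' per-cluster spread sigma = 2.5, plus a broad central \code{"unknown"}
#' cloud (sigma 12), emulating the shape of a LOPIT t-SNE map. Cluster sizes
#' are roughly proportional to the compartment sizes of the u2os organellar
#' map, scaled to about a thousand proteins so simulations stay fast.
#'
#' @return Data frame with columns \code{label}, \code{x}, \code{y},
#'   \code{sigma}, \code{n}.
#' @export
defaultCompartmentLayout <- function() {
  lab <- setdiff(.COMPARTMENTS, "unknown")
  n <- c("cytosol" = 120L, "endoplasmic reticulum" = 90L, "golgi" = 40L,
         "lysosome" = 40L, "mitochondria" = 100L, "nucleus" = 120L,
         "nucleus-chromatin" = 50L, "peroxisome" = 25L,
         "plasma membrane" = 110L, "proteasome" = 35L,
         "ribosome 40S" = 40L, "ribosome 60S" = 45L)
  ang <- 2 * pi * (seq_along(lab) - 1L) / length(lab)
  rbind(
    data.frame(label = lab, x = 30 * cos(ang), y = 30 * sin(ang),
               sigma = 2.5, n = as.integer(n[lab])),
    data.frame(label = "unknown", x = 0, y = 0, sigma = 12, n = 250L))
}

#' Configuration for the synthetic-data generators
#'
#' Bundles and validates everything the generators need. BioID defaults
#' emulate a plasma-membrane bait with 60 planted interactors enriched
#' 10-fold in the eluate over 400 background proteins at 1-fold, log-normal
#' measurement noise of 0.2 on the log10 scale, and carboxylase-control
#' elute/wash ratios spanning 2.1 to 68.8. EV defaults use the five
#' MISEV2018-style category sizes 110/55/195/41/160 (561 markers) and a
#' contamination level of 0.5.
#'
#' @param seed Integer seed; identical configs give identical outputs.
#' @param compartments Layout data frame, see
#'   \code{\link{defaultCompartmentLayout}}.
#' @param bioid List overriding any of \code{nBackground}, \code{nInteractors},
#'   \code{baitCompartment}, \code{interactorEffect}, \code{backgroundEffect},
#'   \code{noiseSigmaLog10}, \code{carboxylaseRatios}, \code{detectionFloor}
#'   (abundance below which a measurement is dropped as missing;
#'   \code{NULL} = no dropout).
#' @param ev List overriding \code{markerCategorySizes} (length 5) or
#'   \code{contaminationLevel} (in [0, 1]).
#' @return A validated list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(seed = 1L, compartments = defaultCompartmentLayout(),
                        bioid = list(), ev = list()) {
  b <- utils::modifyList(list(
    nBackground = 400L, nInteractors = 60L,
    baitCompartment = "plasma membrane",
    interactorEffect = 10, backgroundEffect = 1,
    noiseSigmaLog10 = 0.2,
    carboxylaseRatios = c(2.1, 10, 30, 68.8),
    detectionFloor = NULL), bioid)
  e <- utils::modifyList(list(
    markerCategorySizes = c(110L, 55L, 195L, 41L, 160L),
    contaminationLevel = 0.5), ev)
  if (anyDuplicated(compartments$label))
    stop("duplicate compartment label in layout")
  bad <- setdiff(compartments$label, .COMPARTMENTS)
  if (length(bad)) stop("unknown compartment label(s) in layout: ",
                        paste(bad, collapse = ", "))
  stopifnot(all(compartments$n > 0L), all(compartments$sigma >= 0),
            b$nBackground > 0L, b$nInteractors > 0L,
            b$interactorEffect > 0, b$backgroundEffect > 0,
            b$noiseSigmaLog10 >= 0,
            all(b$carboxylaseRatios > 0),
            length(e$markerCategorySizes) == 5L,
            all(e$markerCategorySizes >= 0L),
            e$contaminationLevel >= 0, e$contaminationLevel <= 1)
  structure(list(seed = as.integer(seed), compartments = compartments,
                 bioid = b, ev = e), class = "SynthConfig")
}

#' Generate a synthetic organellar reference map
#'
#' Draws each compartment as a 2-D Gaussian cluster at its configured
#' centre; \code{"unknown"} comes from the broad central cloud. Synthetic
#' accessions are \code{SYNnnnnn}; when the layout contains a mitochondria
#' cluster of at least four proteins, the four carboxylase control
#' accessions are placed there so positive controls land where they belong.
#'
#' @param cfg A \code{\link{synthConfig}}.
#' @return A \linkS4class{ReferenceMap} whose compartment column is the
#'   ground-truth cluster label.
#' @export
generateReferenceMap <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  lay <- cfg$compartments
  .with_seed(cfg$seed, {
    acc <- sprintf("SYN%05d", seq_len(sum(lay$n)))
    comp <- rep(lay$label, lay$n)
    x <- stats::rnorm(length(acc), rep(lay$x, lay$n), rep(lay$sigma, lay$n))
    y <- stats::rnorm(length(acc), rep(lay$y, lay$n), rep(lay$sigma, lay$n))
    mito <- which(comp == "mitochondria")
    if (length(mito) >= 4L)
      acc[mito[1:4]] <- carboxylaseControls()
    ReferenceMap(acc, x, y, comp)
  })
}

.base_abundance <- function(n) 10^stats::rnorm(n, mean = 7, sd = 0.5)

.noisy <- function(base, sigma) base * 10^stats::rnorm(length(base), 0, sigma)

#' Generate a synthetic BioID wash/elute experiment
#'
#' Plants \code{nInteractors} true interactors among the bait-compartment
#' proteins of the map and \code{nBackground} background proteins drawn from
#' the whole map. For each protein, W-1, W-2 and Elute abundances share a
#' log-normal base intensity with multiplicative log-normal noise (sigma in
#' log10 units); the Elute is additionally multiplied by the protein's
#' effect — \code{interactorEffect} for interactors in the test group,
#' \code{backgroundEffect} otherwise. In the control group (unfused ligase)
#' interactors behave as background. The four carboxylase controls are
#' present in both groups with Elute/W-2 ratios set by
#' \code{carboxylaseRatios} (exact when the noise sigma is 0).
#'
#' @param cfg A \code{\link{synthConfig}}.
#' @param map A \linkS4class{ReferenceMap}, typically from
#'   \code{\link{generateReferenceMap}} on the same config.
#' @return List with \code{test} and \code{control}
#'   (\linkS4class{QuantTable}s with fractions \code{W-1}, \code{W-2},
#'   \code{Elute}) and \code{truth} (DataFrame: accession, role,
#'   compartment, effect in the test group).
#' @export
generateBioidExperiment <- function(cfg, map) {
  stopifnot(inherits(cfg, "SynthConfig"), is(map, "ReferenceMap"))
  b <- cfg$bioid
  comp <- compartments(map)
  ctrl <- intersect(carboxylaseControls(), names(comp))
  bait <- setdiff(names(comp)[comp == b$baitCompartment], ctrl)
  if (length(bait) < b$nInteractors)
    stop("nInteractors (", b$nInteractors, ") exceeds proteins in bait ",
         "compartment '", b$baitCompartment, "' (", length(bait), ")")
  .with_seed(cfg$seed + 1L, {
    interactors <- sample(bait, b$nInteractors)
    pool <- setdiff(names(comp), c(interactors, ctrl))
    if (length(pool) < b$nBackground)
      stop("nBackground exceeds available map proteins")
    background <- sample(pool, b$nBackground)
    acc <- c(interactors, background, ctrl)
    role <- c(rep("interactor", length(interactors)),
              rep("background", length(background)),
              rep("carboxylase", length(ctrl)))
    base <- .base_abundance(length(acc))
    base[role == "carboxylase"] <- 10^6.5
    effTest <- ifelse(role == "interactor", b$interactorEffect,
                      b$backgroundEffect)
    effCtrl <- rep(b$backgroundEffect, length(acc))
    cratio <- stats::setNames(rep(1, length(acc)), acc)
    cratio[ctrl] <- b$carboxylaseRatios[seq_along(ctrl)]
    s <- b$noiseSigmaLog10
    mk <- function(eff) {
      w2 <- .noisy(base, s)
      elute <- ifelse(role == "carboxylase",
                      w2 * cratio[acc] * 10^stats::rnorm(length(acc), 0, s),
                      .noisy(base * eff, s))
      m <- cbind(`W-1` = .noisy(base, s), `W-2` = w2, Elute = elute)
      rownames(m) <- acc
      if (!is.null(b$detectionFloor))
        m[m < b$detectionFloor] <- NA_real_
      QuantTable(m, normalize = FALSE)
    }
    test <- mk(effTest)
    control <- mk(effCtrl)
    truth <- DataFrame(accession = acc, role = role,
                       compartment = unname(comp[acc]),
                       effect = ifelse(role == "carboxylase",
                                       unname(cratio[acc]), effTest))
    list(test = test, control = control, truth = truth)
  })
}

#' Generate a synthetic extracellular-vesicle experiment
#'
#' Builds a disjoint five-category marker set of the configured sizes from
#' the map's proteins — categories 1, 2 and 5 (ev-marker) from the marker
#' region, category 3 (contaminant) from the contaminant region, category 4
#' (subtype) from the remainder — plus a two-preparation quantitation table.
#' Preparation A detects marker-region proteins with high probability (0.9)
#' and contaminant-region proteins rarely (0.1); preparation B detects
#' contaminant-region proteins with probability \code{0.9 *
#' contaminationLevel} (none at level 0) and marker-region proteins at 0.6.
#' Other compartments are detected at 0.5 in both. Detected abundances are
#' log-normal.
#'
#' @param cfg A \code{\link{synthConfig}}.
#' @param map A \linkS4class{ReferenceMap}.
#' @return List with \code{quant} (\linkS4class{QuantTable}, fractions
#'   \code{prepA}, \code{prepB}; rows detected in at least one preparation),
#'   \code{markers} (\linkS4class{MarkerSet}) and \code{truth} (DataFrame:
#'   accession, compartment, region).
#' @export
generateEvExperiment <- function(cfg, map) {
  stopifnot(inherits(cfg, "SynthConfig"), is(map, "ReferenceMap"))
  sizes <- as.integer(cfg$ev$markerCategorySizes)
  level <- cfg$ev$contaminationLevel
  comp <- compartments(map)
  region <- ifelse(comp %in% markerRegion(), "marker",
            ifelse(comp %in% contaminantRegion(), "contaminant", "other"))
  names(region) <- names(comp)
  .with_seed(cfg$seed + 2L, {
    markerPool <- names(region)[region == "marker"]
    contamPool <- names(region)[region == "contaminant"]
    needMark <- sum(sizes[c(1L, 2L, 5L)])
    if (length(markerPool) < needMark || length(contamPool) < sizes[3L])
      stop("marker category sizes exceed available map proteins")
    pick <- sample(markerPool, needMark)
    cat1 <- pick[seq_len(sizes[1L])]
    cat2 <- pick[sizes[1L] + seq_len(sizes[2L])]
    cat5 <- pick[sizes[1L] + sizes[2L] + seq_len(sizes[5L])]
    cat3 <- sample(contamPool, sizes[3L])
    rest <- setdiff(names(region), c(pick, cat3))
    if (length(rest) < sizes[4L])
      stop("marker category sizes exceed available map proteins")
    cat4 <- sample(rest, sizes[4L])
    markers <- MarkerSet(
      accession = c(cat1, cat2, cat3, cat4, cat5),
      category = rep(c(1L, 2L, 3L, 4L, 5L), times = sizes[c(1:4, 5L)]),
      normalize = FALSE)

    pDet <- function(prep) switch(prep,
      A = ifelse(region == "marker", 0.9,
          ifelse(region == "contaminant", 0.1, 0.5)),
      B = ifelse(region == "marker", 0.6,
          ifelse(region == "contaminant", 0.9 * level, 0.5)))
    draw <- function(prep) {
      hit <- stats::runif(length(region)) < pDet(prep)
      ifelse(hit, .base_abundance(length(region)), NA_real_)
    }
    m <- cbind(prepA = draw("A"), prepB = draw("B"))
    rownames(m) <- names(region)
    m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
    truth <- DataFrame(accession = names(region),
                       compartment = unname(comp),
                       region = unname(region))
    list(quant = QuantTable(m, normalize = FALSE), markers = markers,
         truth = truth)
  })
}
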