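test_that("generated maps honour the layout and are seed-deterministic", {
  lay <- data.frame(label = compartmentLabels(),
                    x = seq(0, 120, by = 10), y = 0, sigma = 1, n = 10L)
  cfg <- synthConfig(seed = 9L, compartments = lay)
  map <- generateReferenceMap(cfg)
  expect_equal(length(accessions(map)), 130L)
  expect_equal(unname(table(factor(compartments(map),
                                   levels = compartmentLabels()))),
               rep(10L, 13), ignore_attr = TRUE)
  map2 <- generateReferenceMap(cfg)
  expect_equal(coordinates(map), coordinates(map2))
  expect_error(synthConfig(compartments = rbind(lay, lay[1, ])),
               "duplicate")
})

test_that("generated cluster means land near configured centres", {
  cfg <- smallSynth(seed = 13L)
  map <- generateReferenceMap(cfg)
  lay <- cfg$compartments
  xy <- coordinates(map)
  comp <- compartments(map)
  for (i in seq_len(nrow(lay))) {
    sel <- comp == lay$label[i]
    tol <- 3 * lay$sigma[i] / sqrt(lay$n[i])
    expect_lt(abs(mean(xy[sel, "x"]) - lay$x[i]), tol)
    expect_lt(abs(mean(xy[sel, "y"]) - lay$y[i]), tol)
  }
})

test_that("noiseless pulldown data reproduce effects and control ratios", {
  cfg <- smallSynth(seed = 5L, bioid = list(noiseSigmaLog10 = 0))
  map <- generateReferenceMap(cfg)
  bio <- generateBioidExperiment(cfg, map)
  fc <- computeFoldChange(bio$test, "Elute", "W-2")
  r <- as.data.frame(fc@results)
  tr <- as.data.frame(bio$truth)
  ratio <- stats::setNames(r$ratio, r$accession)
  interactors <- tr$accession[tr$role == "interactor"]
  expect_equal(unname(ratio[interactors]),
               rep(cfg$bioid$interactorEffect, length(interactors)))
  b <- carboxylaseBenchmark(bio$test, "Elute", "W-2")
  expect_equal(b@minRatio, 2.1)
  expect_equal(b@maxRatio, 68.8)
  ## control group carries no interactor enrichment
  fcg <- computeFoldChange(bio$control, "Elute", "W-2")
  rg <- as.data.frame(fcg@results)
  rg <- stats::setNames(rg$ratio, rg$accession)
  expect_equal(unname(rg[interactors]),
               rep(cfg$bioid$backgroundEffect, length(interactors)))
})

test_that("impossible interactor counts are rejected", {
  cfg <- smallSynth(bioid = list(nInteractors = 10000L))
  map <- generateReferenceMap(cfg)
  expect_error(generateBioidExperiment(cfg, map), "exceeds")
})

test_that("generated quant tables pass loader validation unchanged", {
  cfg <- smallSynth(seed = 3L)
  map <- generateReferenceMap(cfg)
  bio <- generateBioidExperiment(cfg, map)
  f <- tempfile(fileext = ".csv")
  writeQuantTable(bio$test, f)
  back <- suppressMessages(loadQuantTable(f))
  expect_equal(abundances(back), abundances(bio$test))
})

test_that("EV generation produces the configured disjoint category sizes", {
  cfg <- smallSynth(seed = 101L)
  map <- generateReferenceMap(cfg)
  ev <- generateEvExperiment(cfg, map)
  expect_equal(unname(categoryTotals(ev$markers)),
               c(110L, 55L, 195L, 41L, 160L))
  expect_equal(sum(categoryTotals(ev$markers)), 561L)
  expect_false(anyDuplicated(accessions(ev$markers)) > 0)

  small <- synthConfig(seed = 1L, compartments = data.frame(
    label = c("cytosol", "mitochondria"), x = c(0, 10), y = 0,
    sigma = 1, n = 20L))
  expect_error(generateEvExperiment(small, generateReferenceMap(small)),
               "exceed")
})

test_that("contamination level controls contaminant-region carryover", {
  base <- list(seed = 103L)
  mk <- function(level) {
    cfg <- synthConfig(seed = 103L, ev = list(contaminationLevel = level))
    map <- generateReferenceMap(cfg)
    ev <- generateEvExperiment(cfg, map)
    det <- detectedIn(ev$quant, "prepB")
    tallyCompartments(mapToReference(det, map)$overlay)
  }
  t0 <- mk(0); t1 <- mk(1)
  expect_equal(sum(t0[contaminantRegion()]), 0L)
  expect_gt(sum(t1[contaminantRegion()]), sum(t0[contaminantRegion()]))
})

test_that("all generators are reproducible under a fixed seed", {
  cfg <- smallSynth(seed = 202L)
  m1 <- generateReferenceMap(cfg); m2 <- generateReferenceMap(cfg)
  b1 <- generateBioidExperiment(cfg, m1)
  b2 <- generateBioidExperiment(cfg, m2)
  e1 <- generateEvExperiment(cfg, m1); e2 <- generateEvExperiment(cfg, m2)
  expect_identical(abundances(b1$test), abundances(b2$test))
  expect_identical(abundances(e1$quant), abundances(e2$quant))
  expect_identical(as.data.frame(e1$markers@entries),
                   as.data.frame(e2$markers@entries))
})
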