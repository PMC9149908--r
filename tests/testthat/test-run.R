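synthRun <- function(dir, seed = 12L) {
  suppressMessages(runSynth(list(paths = list(outdir = dir), seed = seed)))
}

test_that("the synth pipeline writes a complete, reloadable dataset", {
  dir <- tempfile(); out <- synthRun(dir)
  expect_true(all(file.exists(out)))
  map <- suppressMessages(loadReferenceMap(out[["map"]]))
  expect_s4_class(map, "ReferenceMap")
  qt <- suppressMessages(loadQuantTable(out[["bioid_test"]]))
  expect_equal(fractionIds(qt), c("W-1", "W-2", "Elute"))
  ms <- suppressMessages(loadMarkerSet(out[["markers"]]))
  expect_equal(sum(categoryTotals(ms)), 561L)
})

test_that("overlay runs end to end and reruns byte-identically", {
  dir <- tempfile(); out <- synthRun(dir)
  cfg <- list(paths = list(map = out[["map"]], quant = out[["bioid_test"]],
                           outdir = file.path(dir, "run1")),
              valueColumn = "Elute")
  o1 <- suppressMessages(runOverlay(cfg))
  expect_true(all(file.exists(o1)))
  cfg$paths$outdir <- file.path(dir, "run2")
  o2 <- suppressMessages(runOverlay(cfg))
  for (k in c("overlay", "stats", "tally"))
    expect_identical(readLines(o1[[k]]), readLines(o2[[k]]))
})

test_that("a missing input path fails validation before any output", {
  dir <- tempfile(); out <- synthRun(dir)
  bad <- list(paths = list(map = file.path(dir, "no-such-map.tsv"),
                           quant = out[["bioid_test"]],
                           outdir = file.path(dir, "bad")))
  expect_error(suppressMessages(runOverlay(bad)),
               class = "orgmap_validation_error")
  expect_false(dir.exists(file.path(dir, "bad")))
})

test_that("the bioid run matches the brute-force candidate count", {
  dir <- tempfile(); out <- synthRun(dir)
  cfg <- list(paths = list(map = out[["map"]], quant = out[["bioid_test"]],
                           outdir = file.path(dir, "bioid")),
              cutoff = list(policy = "fixed", value = 3))
  files <- suppressMessages(runBioid(cfg))
  cand <- read.delim(files[["candidates"]])
  qt <- suppressMessages(loadQuantTable(out[["bioid_test"]]))
  fc <- computeFoldChange(qt, "Elute", "W-2")
  expect_setequal(cand$accession, bruteCutoff(fc, 3))

  bench <- read.delim(files[["benchmark"]], comment.char = "#")
  expect_equal(nrow(bench), 4L)   # all four controls present and ratioed

  cfg$cutoff$value <- 0
  cfg$paths$outdir <- file.path(dir, "bioid0")
  f0 <- suppressMessages(runBioid(cfg))
  cand0 <- read.delim(f0[["candidates"]])
  r <- as.data.frame(fc@results)
  expect_equal(nrow(cand0),
               sum(r$status %in% c("both", "numerator_only")))
})

test_that("the EV evaluation run writes the recovery and role tables", {
  dir <- tempfile(); out <- synthRun(dir)
  cfg <- list(paths = list(map = out[["map"]], quant = out[["ev_quant"]],
                           markers = out[["markers"]],
                           outdir = file.path(dir, "ev")),
              valueColumn = "prepA")
  files <- suppressMessages(runEv(cfg))
  expect_true(all(file.exists(files)))
  rec <- read.delim(files[["recovery"]])
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$total, c(110L, 55L, 195L, 41L, 160L))
  roles <- read.delim(files[["roles"]], check.names = FALSE)
  expect_equal(roles$assignment, compartmentLabels())
})

test_that("detecting every marker yields 100 percent recovery everywhere", {
  cfg <- smallSynth(seed = 77L)
  map <- generateReferenceMap(cfg)
  ev <- generateEvExperiment(cfg, map)
  rec <- categoryRecovery(accessions(ev$markers), ev$markers)
  expect_equal(rec$percent, rep(100, 5))
})

test_that("every run leaves a provenance record with checksums", {
  dir <- tempfile(); out <- synthRun(dir)
  cfg <- list(paths = list(map = out[["map"]], quant = out[["bioid_test"]],
                           outdir = file.path(dir, "prov")),
              valueColumn = "Elute")
  o <- suppressMessages(runOverlay(cfg))
  prov <- jsonlite::read_json(o[["provenance"]])
  expect_equal(prov$package, "orgmap")
  expect_equal(length(prov$input_checksums), 2L)
  expect_equal(prov$config$valueColumn, "Elute")
})
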