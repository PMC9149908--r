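test_that("loading a map preserves accessions, coordinates and compartments", {
  f <- writeTsv(c("accession\tx\ty\tcompartment",
                  "A1\t0\t1\tcytosol",
                  "A2\t5\t-2\tnucleus",
                  "A3\t1\t1\tunknown"))
  expect_message(map <- loadReferenceMap(f), "3 proteins")
  expect_s4_class(map, "ReferenceMap")
  expect_equal(accessions(map), c("A1", "A2", "A3"))
  expect_equal(unname(compartments(map)),
               c("cytosol", "nucleus", "unknown"))
  expect_equal(unname(coordinates(map)[, "x"]), c(0, 5, 1))
})

test_that("map validation rejects duplicates, bad coordinates and bad labels", {
  dup <- writeTsv(c("accession\tx\ty\tcompartment",
                    "A1\t0\t1\tcytosol", "A1\t2\t2\tnucleus"))
  expect_error(suppressMessages(loadReferenceMap(dup)), "A1")

  nonnum <- writeTsv(c("accession\tx\ty\tcompartment",
                       "A1\t0\t1\tcytosol", "A2\tfoo\t2\tnucleus"))
  expect_error(suppressMessages(loadReferenceMap(nonnum)), "row 2")

  bad <- writeTsv(c("accession\tx\ty\tcompartment",
                    "A1\t0\t1\tCytoplasm"))
  expect_error(suppressMessages(loadReferenceMap(bad)),
               "unknown compartment label.*allowed")
})

test_that("compartment aliasing is explicit, never fuzzy", {
  f <- writeTsv(c("accession\tx\ty\tcompartment",
                  "A1\t0\t1\tER", "A2\t1\t1\tPM",
                  "A3\t2\t2\tPlasma Membrane"))
  map <- suppressMessages(loadReferenceMap(f))
  expect_equal(unname(compartments(map)),
               c("endoplasmic reticulum", "plasma membrane",
                 "plasma membrane"))
})

test_that("write/load round trip reproduces the map exactly", {
  cfg <- smallSynth(seed = 11L)
  map <- generateReferenceMap(cfg)
  f <- tempfile(fileext = ".tsv")
  writeReferenceMap(map, f)
  back <- suppressMessages(loadReferenceMap(f))
  expect_equal(accessions(back), accessions(map))
  expect_equal(compartments(back), compartments(map))
  expect_equal(coordinates(back), coordinates(map), tolerance = 1e-12)
})

test_that("compartmentOf distinguishes unknown, not-in-map and normalizes", {
  map <- tinyMap()
  expect_equal(compartmentOf(map, "A2"), "nucleus")
  expect_true(is.na(compartmentOf(map, "ZZZ")))
  expect_equal(compartmentOf(map, "a1"), "cytosol")
  expect_equal(compartmentOf(map, "A3"), "unknown")
  ## every map accession resolves to the closed vocabulary, never NA
  got <- compartmentOf(map, accessions(map))
  expect_true(all(got %in% compartmentLabels()))
  expect_false(anyNA(got))
})

test_that("region ellipse centre is the member mean and scales with kSigma", {
  map <- ReferenceMap(paste0("P", 1:4), x = c(0, 2, 0, 2),
                      y = c(0, 0, 2, 2), compartment = rep("cytosol", 4))
  r1 <- regionEllipse(map, "cytosol", kSigma = 1)
  expect_equal(unname(r1@center), c(1, 1), tolerance = 1e-9)
  expect_equal(r1@covariance, stats::cov(cbind(c(0, 2, 0, 2),
                                               c(0, 0, 2, 2))))
  r2 <- regionEllipse(map, "cytosol", kSigma = 2)
  ## doubling kSigma quadruples the covariance, i.e. doubles axis lengths
  expect_equal(r2@covariance, 4 * r1@covariance)
})

test_that("region ellipse handles degenerate inputs per design", {
  map <- tinyMap()
  expect_error(regionEllipse(map, "cytosol"), ">= 3 member")
  same <- ReferenceMap(paste0("P", 1:3), x = rep(1, 3), y = rep(2, 3),
                       compartment = rep("golgi", 3))
  expect_warning(r <- regionEllipse(same, "golgi"), "zero-covariance")
  expect_equal(unname(r@center), c(1, 2))
  expect_true(all(r@covariance == 0))
})

test_that("ellipse centre matches coordinate mean on generated maps", {
  map <- generateReferenceMap(smallSynth(seed = 3L))
  for (comp in c("cytosol", "mitochondria", "unknown")) {
    r <- regionEllipse(map, comp)
    sel <- compartments(map) == comp
    expect_equal(unname(r@center),
                 unname(colMeans(coordinates(map)[sel, ])),
                 tolerance = 1e-9)
  }
})
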