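test_that("binning spans the requested range and respects ties", {
  b <- binValues(1:100, nBins = 5)
  expect_equal(b[1], 1L)
  expect_equal(b[100], 5L)
  expect_equal(b, bruteBin(1:100, 5))
  expect_equal(binValues(rep(7, 10), nBins = 5), rep(1L, 10))
  expect_equal(binValues(numeric()), integer())
  expect_error(binValues(1:10, nBins = 0), "nBins")
  expect_error(binValues(c(1, -1), nBins = 2), "positive")
})

test_that("binning is monotone and agrees with the sort-based oracle", {
  set.seed(31)
  for (scheme in c("quantile-log10", "equal-width-log10")) {
    v <- 10^runif(1000, -2, 8)
    b <- binValues(v, nBins = 5, scheme = scheme)
    o <- order(v)
    expect_true(all(diff(b[o]) >= 0))          # larger value, never smaller bin
    expect_equal(b, bruteBin(v, 5, scheme))
    expect_true(all(b >= 1 & b <= 5))
  }
})

test_that("overlay partitions detected proteins into mapped and unmapped", {
  map <- tinyMap()
  qt <- quantFromVectors(c("A1", "A2", "A3", "ZZ9"),
                         Elute = c(10, 20, 30, 40))
  res <- mapToReference(qt, map, valueColumn = "Elute")
  ov <- res$overlay
  expect_equal(nrow(ov@points), 3L)
  expect_equal(ov@unmapped, "ZZ9")
  expect_setequal(accessions(ov), accessions(qt))
  st <- as.data.frame(res$stats)
  expect_equal(st$total_ids, 4L)
  expect_equal(st$mapped, 3L)
  expect_equal(st$percent_mapped, 75)
})

test_that("overlay handles empty and fully mapped detected sets", {
  map <- tinyMap()
  expect_warning(res <- mapToReference(character(), map), "percent_mapped")
  expect_equal(as.data.frame(res$stats)$percent_mapped, 0)
  full <- mapToReference(accessions(map), map)
  expect_equal(as.data.frame(full$stats)$percent_mapped, 100)
  expect_length(full$overlay@unmapped, 0)
})

test_that("compartment tallies count mapped points and conserve totals", {
  map <- ReferenceMap(paste0("P", 1:5), x = 1:5, y = 1:5,
                      compartment = c(rep("cytosol", 3), rep("nucleus", 2)))
  ov <- mapToReference(paste0("P", 1:5), map)$overlay
  tally <- tallyCompartments(ov)
  expect_equal(tally[["cytosol"]], 3L)
  expect_equal(tally[["nucleus"]], 2L)
  expect_equal(sum(tally), 5L)
  expect_equal(sum(tally == 0L), 11L)

  empty <- mapToReference("P9", tinyMap())$overlay
  expect_equal(sum(tallyCompartments(empty)), 0L)
})

test_that("tally conservation holds on random synthetic overlays", {
  map <- generateReferenceMap(smallSynth(seed = 23L))
  set.seed(17)
  for (i in 1:20) {
    det <- sample(c(accessions(map), sprintf("XX%03d", 1:50)), 200)
    ov <- mapToReference(det, map)$overlay
    expect_equal(sum(tallyCompartments(ov)), nrow(ov@points))
    expect_equal(nrow(ov@points) + length(ov@unmapped), length(unique(det)))
  }
})

test_that("mapped fraction reproduces printed-table arithmetic", {
  expect_equal(mappedFraction(1243, 908)$display, 73)
  expect_equal(mappedFraction(6491, 2553)$display, 39)
  expect_equal(mappedFraction(561, 272)$display, 48)
  expect_equal(mappedFraction(100, 0)$percent, 0)
  expect_error(mappedFraction(0, 0), "detectedTotal")
  expect_error(mappedFraction(10, 11), "mapped")
  ## a tally can be passed directly; it is summed
  t <- stats::setNames(rep(1L, 13), compartmentLabels())
  expect_equal(mappedFraction(26, t)$percent, 50)
})

test_that("tally comparison is signed, antisymmetric and descriptive", {
  a <- stats::setNames(rep(0L, 13), compartmentLabels())
  b <- a
  a["plasma membrane"] <- 30L; b["plasma membrane"] <- 57L
  cmp <- compareTallies(a, b, "SEC", "293T")
  expect_equal(cmp$difference[["plasma membrane"]], -27L)
  expect_match(cmp$text, "27 fewer proteins in the plasma membrane")
  expect_equal(unname(compareTallies(a, a)$difference), rep(0L, 13))
  rev <- compareTallies(b, a)
  expect_equal(cmp$difference, -rev$difference)
})

test_that("mapping statistics recompute from their own counts", {
  map <- generateReferenceMap(smallSynth(seed = 29L))
  cfg <- smallSynth(seed = 29L)
  bio <- generateBioidExperiment(cfg, map)
  st <- as.data.frame(mapToReference(bio$test, map)$stats)
  expect_equal(st$percent_mapped, 100 * st$mapped / st$total_ids,
               tolerance = 1e-3)
})
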