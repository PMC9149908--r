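test_that("fold change ratios and statuses follow presence", {
  qt <- quantFromVectors(c("A1", "A2", "A3", "A4"),
                         Elute = c(6, 8, NA, NA),
                         `W-2` = c(2, NA, 3, NA))
  fc <- computeFoldChange(qt, "Elute", "W-2")
  r <- as.data.frame(fc@results)
  expect_equal(r$ratio[r$accession == "A1"], 3)
  expect_equal(r$status, c("both", "numerator_only", "denominator_only",
                           "neither"))
  expect_true(is.na(r$ratio[r$accession == "A2"]))
  expect_error(computeFoldChange(qt, "Elute", "W-9"), "unknown fraction")

  same <- computeFoldChange(qt, "Elute", "Elute")
  rs <- as.data.frame(same@results)
  expect_true(all(rs$ratio[rs$status == "both"] == 1))
})

test_that("swapping numerator and denominator inverts ratios and statuses", {
  set.seed(41)
  n <- 60
  m <- matrix(10^runif(2 * n, 2, 8), ncol = 2,
              dimnames = list(sprintf("P%03d", 1:n), c("Elute", "W-2")))
  m[sample(length(m), 25)] <- NA
  keep <- rowSums(!is.na(m)) > 0
  qt <- makeQuant(m[keep, ])
  ab <- computeFoldChange(qt, "Elute", "W-2")
  ba <- computeFoldChange(qt, "W-2", "Elute")
  ra <- as.data.frame(ab@results); rb <- as.data.frame(ba@results)
  both <- ra$status == "both"
  expect_equal(rb$ratio[both], 1 / ra$ratio[both])
  expect_equal(rb$status[ra$status == "numerator_only"],
               rep("denominator_only", sum(ra$status == "numerator_only")))
  expect_equal(rb$status[ra$status == "denominator_only"],
               rep("numerator_only", sum(ra$status == "denominator_only")))
})

test_that("carboxylase benchmark reproduces control ratio arithmetic", {
  qt <- quantFromVectors(carboxylaseControls(),
                         Elute = c(4.2, 20, 60, 137.6),
                         `W-2` = c(2, 2, 2, 2))
  b <- carboxylaseBenchmark(qt, "Elute", "W-2")
  expect_equal(unname(b@ratios), c(2.1, 10, 30, 68.8))
  expect_equal(b@minRatio, 2.1)
  expect_equal(b@maxRatio, 68.8)
  expect_equal(b@totalRatio, sum(c(4.2, 20, 60, 137.6)) / 8)
})

test_that("benchmark excludes controls missing from a fraction", {
  qt <- quantFromVectors(carboxylaseControls(),
                         Elute = c(4, 20, 60, 100),
                         `W-2` = c(2, NA, 2, 2))
  expect_warning(b <- carboxylaseBenchmark(qt, "Elute", "W-2"), "P05165")
  expect_length(b@ratios, 3)
  expect_false("P05165" %in% names(b@ratios))

  equal <- quantFromVectors(carboxylaseControls(),
                            Elute = rep(5, 4), `W-2` = rep(5, 4))
  be <- carboxylaseBenchmark(equal, "Elute", "W-2")
  expect_equal(c(be@minRatio, be@maxRatio, be@totalRatio), c(1, 1, 1))

  none <- quantFromVectors(c("X1", "X2"), Elute = c(1, 2), `W-2` = c(1, 2))
  expect_error(carboxylaseBenchmark(none, "Elute", "W-2"), "undefined")
})

test_that("the cutoff boundary is inclusive and counts are exact", {
  qt <- quantFromVectors(paste0("P", 1:4),
                         Elute = c(1, 2, 3, 4), `W-2` = rep(1, 4))
  fc <- computeFoldChange(qt, "Elute", "W-2")
  expect_equal(nPassed(applyCutoff(fc, 3)), 2L)   # 3 and 4 pass, >= boundary
  expect_equal(nPassed(applyCutoff(fc, 0)), 4L)
  expect_error(applyCutoff(fc, Inf), "finite")

  empty <- computeFoldChange(
    quantFromVectors("P1", Elute = NA_real_, `W-2` = 2), "Elute", "W-2")
  expect_equal(nPassed(applyCutoff(empty, 3)), 0L)
})

test_that("cutoff filtering matches the brute-force oracle and is monotone", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    m <- matrix(10^runif(2 * n, 0, 6), ncol = 2,
                dimnames = list(sprintf("Q%04d", 1:n), c("E", "W")))
    m[runif(2 * n) < 0.2] <- NA
    keep <- rowSums(!is.na(m)) > 0
    if (!any(keep)) next
    fc <- computeFoldChange(makeQuant(m[keep, , drop = FALSE]), "E", "W")
    inc <- i %% 2 == 0
    cuts <- sort(c(0, 10^runif(3, -1, 1.5)))
    prev <- Inf
    for (cut in cuts) {
      got <- applyCutoff(fc, cut, includeNumeratorOnly = inc)
      expect_setequal(passedProteins(got), bruteCutoff(fc, cut, inc))
      expect_lte(nPassed(got), prev)  # raising cutoff never adds passes
      prev <- nPassed(got)
    }
  }
})

test_that("cutoff suggestion follows the chosen policy", {
  qt <- quantFromVectors(carboxylaseControls(),
                         Elute = c(4.2, 20, 60, 137.6), `W-2` = rep(2, 4))
  b <- carboxylaseBenchmark(qt, "Elute", "W-2")
  expect_equal(suggestCutoff(b, "min_control"), 2.1)
  expect_equal(suggestCutoff(b, "total"), b@totalRatio)
  expect_equal(suggestCutoff(b, "fixed", value = 3), 3)

  one <- quantFromVectors("P11498", Elute = 13.4, `W-2` = 2)
  expect_warning(b1 <- carboxylaseBenchmark(one, "Elute", "W-2"))
  expect_equal(suggestCutoff(b1, "min_control"), 6.7)
})

test_that("planted interactors are recovered from synthetic pulldown data", {
  cfg <- smallSynth(seed = 42L)
  map <- generateReferenceMap(cfg)
  bio <- generateBioidExperiment(cfg, map)
  fc <- applyCutoff(computeFoldChange(bio$test, "Elute", "W-2"), 3)
  tr <- as.data.frame(bio$truth)
  pass <- passedProteins(fc)
  interactors <- tr$accession[tr$role == "interactor"]
  background <- tr$accession[tr$role == "background"]
  expect_gte(mean(interactors %in% pass), 0.9)
  expect_lte(mean(background %in% pass), 0.1)
})
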