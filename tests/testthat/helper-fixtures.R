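## Shared fixtures and independent oracles. Fixtures are built in code; the
## oracles are deliberately naive (loops, sort-and-split) so they stay
## independent of the vectorized implementation paths they check.

tinyMap <- function() {
  ReferenceMap(accession = c("A1", "A2", "A3"),
               x = c(0, 5, 1), y = c(1, -2, 1),
               compartment = c("cytosol", "nucleus", "unknown"))
}

writeTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

makeQuant <- function(m) QuantTable(m, normalize = FALSE)

quantFromVectors <- function(accession, ...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- accession
  makeQuant(m)
}

## brute-force oracle: scan every protein against the cutoff rule
bruteCutoff <- function(fc, cutoff, includeNumeratorOnly = TRUE) {
  r <- as.data.frame(fc@results)
  out <- character()
  for (i in seq_len(nrow(r))) {
    pass <- FALSE
    if (r$status[i] == "both" && r$ratio[i] >= cutoff) pass <- TRUE
    if (r$status[i] == "numerator_only" && includeNumeratorOnly) pass <- TRUE
    if (pass) out <- c(out, r$accession[i])
  }
  out
}

## brute-force binning oracle: compute breaks, then place each value by
## scanning intervals one by one (right-closed, lowest closed)
bruteBin <- function(values, nBins, scheme = "quantile-log10") {
  lv <- log10(values)
  breaks <- if (scheme == "quantile-log10")
    stats::quantile(lv, probs = seq(0, 1, length.out = nBins + 1),
                    names = FALSE, type = 7)
  else seq(min(lv), max(lv), length.out = nBins + 1)
  breaks <- unique(breaks)
  if (length(breaks) < 2) return(rep(1L, length(values)))
  vapply(lv, function(v) {
    if (v <= breaks[2]) return(1L)
    for (k in 2:(length(breaks) - 1))
      if (v > breaks[k] && v <= breaks[k + 1]) return(as.integer(k))
    as.integer(length(breaks) - 1)
  }, integer(1))
}

smallSynth <- function(seed = 7L, ...) {
  synthConfig(seed = seed, ...)
}
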