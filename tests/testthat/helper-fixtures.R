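# Shared fixtures, built in code.

# Wide synthetic ladder spanning the full simulated HA range. Ladder band
# masses are configuration inputs; this one is deliberately wider than
# commercial HA ladders so that simulated log-normal tails stay in range.
wideGelCalib <- function() {
  fitGelCalibration(data.frame(
    band_px = c(50, 200, 400, 600, 800, 1000, 1200),
    mw_kda = c(80000, 20000, 5000, 1200, 300, 80, 20)))
}

# Brute-force 1-D morphological opening: independent oracle for the
# rolling-ball background (double loop over window positions).
bruteOpening <- function(x, radius, shape = "ball") {
  n <- length(x)
  js <- seq.int(-radius, radius)
  s <- if (shape == "ball") sqrt(pmax(0, radius^2 - js^2)) else 0 * js
  ero <- vapply(seq_len(n), function(i) {
    idx <- i + js
    ok <- idx >= 1 & idx <= n
    min(x[idx[ok]] - s[ok])
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    idx <- i - js  # center positions whose window covers i
    ok <- idx >= 1 & idx <= n
    max(ero[idx[ok]] + s[ok])
  }, numeric(1))
}

# Overlap-based matching of detected events against a truth table.
eventPrecisionRecall <- function(events, truth) {
  hitDet <- vapply(seq_len(nrow(events)), function(i)
    any(events$start[i] <= truth$end & events$end[i] >= truth$start),
    logical(1))
  hitTruth <- vapply(seq_len(nrow(truth)), function(i)
    any(truth$start[i] <= events$end & truth$end[i] >= events$start),
    logical(1))
  list(precision = mean(hitDet), recall = mean(hitTruth))
}
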