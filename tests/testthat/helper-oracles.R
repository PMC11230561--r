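# Independent oracles used to cross-check the package's algorithms.
# These deliberately take different computational routes than the
# implementations they verify.

# Run-enumeration segmentation oracle. Enumerates maximal below/above
# threshold runs, then pairs "seed" below-runs (length >= min_run) with the
# next "separator" above-run (length >= min_run): a bar spans from the seed's
# first pixel to the pixel before the separator (or the profile end if no
# separator follows). Returns bars as a data.frame(start_px, end_px),
# 0-based half-open.
oracle_segment <- function(vals, min_run = 5L) {
  n <- length(vals)
  thr <- mean(vals)
  r <- rle(vals < thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- starts[r$values & r$lengths >= min_run]
  seps <- starts[!r$values & r$lengths >= min_run]
  bs <- integer(0); be <- integer(0)
  cursor <- 1L
  repeat {
    sd <- seeds[seeds >= cursor]
    if (length(sd) == 0L) break
    open <- sd[1L]
    sp <- seps[seps > open]
    if (length(sp) == 0L) {
      bs <- c(bs, open); be <- c(be, n)
      break
    }
    bs <- c(bs, open); be <- c(be, sp[1L] - 1L)
    cursor <- sp[1L]
  }
  data.frame(start_px = bs - 1L, end_px = be)
}

# Single-marker two-degree-of-freedom regression LOD via lm(), the oracle
# for the Haley-Knott scan at fully typed markers.
oracle_marker_lod <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  add <- (g == 3L) - (g == 1L)
  dom <- as.numeric(g == 2L)
  rss1 <- sum(stats::resid(stats::lm(y ~ add + dom))^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

oracle_marker_r2 <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  add <- (g == 3L) - (g == 1L)
  dom <- as.numeric(g == 2L)
  summary(stats::lm(y ~ add + dom))$r.squared
}

# random profiles for property tests
random_profile <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  intensity_profile(stats::runif(len, 0, 255))
}

toy_three_block <- function() {
  intensity_profile(c(rep(200, 10), rep(50, 10), rep(200, 10)),
                    scale_cm_per_px = 0.01)
}
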