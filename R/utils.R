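# Internal numerical helpers.

# t statistic -> z through the t CDF, numerically stable in the tails,
# capped at +/- zCap (degenerate fits would otherwise produce infinities).
.tToZ <- function(t, df, zCap = 40) {
  z <- ifelse(
    t >= 0,
    stats::qnorm(stats::pt(t, df, lower.tail = FALSE, log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE),
    stats::qnorm(stats::pt(t, df, lower.tail = TRUE, log.p = TRUE),
                 lower.tail = TRUE, log.p = TRUE)
  )
  z[!is.finite(z)] <- sign(t[!is.finite(z)]) * zCap
  pmin(pmax(z, -zCap), zCap)
}

# Evaluate a function under a temporary RNG state so callers' streams are
# untouched and results are reproducible for a given seed.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and an index, kept within 32-bit
# integer range.
.childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + as.double(index) * 7919L) %% 2147483629)
}

.flatten3D <- function(a) {
  dim(a) <- NULL
  a
}

# Gaussian blob spatial map on a voxel grid: weight = exp(-d^2 / (2 sigma^2))
# with d in voxel units, truncated to 0 below `floor` for compact support.
.gaussianBlob <- function(grid, center, sigma, floor = 0.2) {
  x <- seq_len(grid[1]); y <- seq_len(grid[2]); z <- seq_len(grid[3])
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  w <- exp(-d2 / (2 * sigma^2))
  w[w < floor] <- 0
  w / max(w)
}

# Dice coefficient of two logical supports.
.diceSupport <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
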