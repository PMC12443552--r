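# Shared fixtures: tiny phantom cohorts and independent metric oracles.
# Everything is generated in code at test time; nothing is read from disk.

tinyParams <- function(noiseSd = 0, aslFraction = 1, cbvFraction = 1,
                       seed = 7, nLesions = 0L, grid = c(16, 16, 16)) {
  phantomParams(grid = grid, spacingMm = c(2, 2, 2), nLesions = nLesions,
                lesionRadiusRangeMm = c(2, 4), noiseSd = noiseSd,
                aslFraction = aslFraction, cbvFraction = cbvFraction,
                seed = seed)
}

tinyCohort <- function(n, ...) makeCohort(tinyParams(...), n)

tinyIEDNConfig <- function(seed = 0, baseChannels = 4L, levels = 2L,
                           modalities = inputModalities()) {
  iednConfig(modalities = modalities, levels = levels,
             baseChannels = baseChannels, seed = seed)
}

# direct sliding-window SSIM: the definition evaluated window by window,
# independent of the separable-filter implementation
ssimOracle <- function(a, b, dataRange, window = 7L, sigma = 1.5) {
  k <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  k <- k / sum(k)
  W <- outer(outer(k, k), k)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  d <- dim(a)
  nOut <- d - window + 1L
  acc <- 0
  for (i in seq_len(nOut[1])) for (j in seq_len(nOut[2]))
    for (l in seq_len(nOut[3])) {
      xs <- a[i:(i + window - 1), j:(j + window - 1), l:(l + window - 1)]
      ys <- b[i:(i + window - 1), j:(j + window - 1), l:(l + window - 1)]
      mx <- sum(W * xs); my <- sum(W * ys)
      vx <- sum(W * xs * xs) - mx^2
      vy <- sum(W * ys * ys) - my^2
      cxy <- sum(W * xs * ys) - mx * my
      acc <- acc + ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  acc / prod(nOut)
}

# direct world-coordinate trilinear interpolation of one point
trilinearOracle <- function(vol, world) {
  cont <- (world - volOrigin(vol)) / volSpacing(vol)
  d <- dim(volData(vol))
  if (any(cont < 0) || any(cont > d - 1)) return(0)
  i0 <- pmin(floor(cont), d - 2); f <- cont - i0
  acc <- 0
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    wgt <- prod(ifelse(c(ox, oy, oz) == 1, f, 1 - f))
    acc <- acc + wgt * volData(vol)[i0[1] + ox + 1, i0[2] + oy + 1,
                                    i0[3] + oz + 1]
  }
  acc
}
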