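# Independent oracles used across the suite.  These deliberately use naive
# loop-based implementations, kept free of the package's own code paths.

# Per-pixel loop composites (mean and max across frames), unnormalized.
oracleComposite <- function(arr, frames) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  mn <- matrix(0, h, w); mx <- matrix(-Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- arr[i, j, frames]
    mn[i, j] <- sum(v) / length(v)
    mx[i, j] <- max(v)
  }
  list(mean = mn, max = mx)
}

# Exhaustive enumeration of the labelled-copy distribution for n recruited
# units: each unit is monomer/dimer, each copy labelled/unlabelled.
enumStepDist <- function(n, f, d, conditionVisible = TRUE) {
  maxSteps <- 2 * n
  prob <- numeric(maxSteps + 1)
  # enumerate dimer status of each unit
  for (mask in 0:(2^n - 1)) {
    dimers <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    pUnits <- d^dimers * (1 - d)^(n - dimers)
    copies <- n + dimers
    # labelled copies ~ Binomial(copies, f)
    for (k in 0:copies)
      prob[k + 1] <- prob[k + 1] + pUnits * choose(copies, k) *
        f^k * (1 - f)^(copies - k)
  }
  if (conditionVisible) {
    vis <- prob[-1]
    vis / sum(vis)
  } else prob
}

# Naive greedy one-to-one matcher: repeatedly pick the global minimum of
# the full distance matrix.
oracleGreedyMatch <- function(ref, oth, maxSep) {
  d <- sqrt(outer(ref$x, oth$x, "-")^2 + outer(ref$y, oth$y, "-")^2)
  d[d > maxSep] <- Inf
  pairs <- list()
  while (any(is.finite(d))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1L]] <- c(ij[1], ij[2])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  if (!length(pairs)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, pairs)
  m[order(m[, 1]), , drop = FALSE]
}

# Exhaustive best two-change-point segmentation by residual sum of squares.
oracleBestTwoCp <- function(y, minSeg = 3) {
  N <- length(y)
  best <- list(rss = Inf, cp = c(NA, NA))
  rssSeg <- function(a, b) { v <- y[a:b]; sum((v - mean(v))^2) }
  for (i in minSeg:(N - 2 * minSeg)) {
    for (j in (i + minSeg):(N - minSeg)) {
      r <- rssSeg(1, i) + rssSeg(i + 1, j) + rssSeg(j + 1, N)
      if (r < best$rss) best <- list(rss = r, cp = c(i, j))
    }
  }
  best
}

# RSS of a trace under a given set of change points.
rssOfSegmentation <- function(y, cps) {
  bounds <- c(0, cps, length(y))
  s <- 0
  for (k in seq_len(length(bounds) - 1)) {
    v <- y[(bounds[k] + 1):bounds[k + 1]]
    s <- s + sum((v - mean(v))^2)
  }
  s
}

# Match detections to ground truth within a radius; returns recall,
# precision and RMS localization error of the matched detections.
matchDetections <- function(spots, truth, radius = 2) {
  if (nrow(spots) == 0)
    return(list(recall = 0, precision = NA_real_, rmse = NA_real_))
  d <- sqrt(outer(spots$x, truth$xChan, "-")^2 +
              outer(spots$y, truth$yChan, "-")^2)
  detMin <- apply(d, 1, min)
  truthMin <- apply(d, 2, min)
  list(recall = mean(truthMin <= radius),
       precision = mean(detMin <= radius),
       rmse = sqrt(mean(detMin[detMin <= radius]^2)))
}
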