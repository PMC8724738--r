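# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 +
                as.numeric(stream) * 104729) %% 2147483629 + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Moving mean of a matrix over a k x k window (k odd), evaluated at every
# pixel where the window fits entirely inside the image; NA elsewhere.
movingMean <- function(m, k) {
  kern <- rep(1 / k, k)
  byrow <- t(apply(m, 1, function(v) stats::filter(v, kern, sides = 2)))
  out <- apply(byrow, 2, function(v) stats::filter(v, kern, sides = 2))
  matrix(out, nrow(m), ncol(m))
}

# Moving maximum over a k x k window (separable for square windows).
movingMax <- function(m, k) {
  pad <- (k - 1L) / 2L
  rmax <- t(apply(m, 1, function(v)
    c(rep(NA, pad), zoo::rollmax(v, k), rep(NA, pad))))
  out <- apply(rmax, 2, function(v)
    c(rep(NA, pad), zoo::rollmax(v, k, na.rm = FALSE), rep(NA, pad)))
  matrix(out, nrow(m), ncol(m))
}

# Strict local maxima over the 8-neighbourhood (interior pixels only).
localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(matrix(FALSE, nr, nc))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  ok <- matrix(TRUE, nr - 2, nc - 2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (core > m[2:(nr - 1) + di, 2:(nc - 1) + dj])
  }
  out <- matrix(FALSE, nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- ok
  out
}

# Scale to [0,1] by the image maximum (division only: the max/mean spot
# criterion stays scale-invariant and the fitted baseline B keeps its
# meaning as the background fraction of the peak).  A flat image maps to
# all zeros and is flagged degenerate.
normalize01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0)
    list(img = matrix(0, nrow(m), ncol(m)), range = rng, degenerate = TRUE)
  else
    list(img = m / rng[2], range = rng, degenerate = FALSE)
}

# 3 x 3 mean smoothing (edges keep their original values).
smooth3 <- function(m) {
  s <- movingMean(m, 3L)
  s[is.na(s)] <- m[is.na(s)]
  s
}
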