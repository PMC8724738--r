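#' @include AllClasses.R utils.R
NULL

#' Mean and maximum composite images for one channel
#'
#' Computes, per pixel, the mean and the maximum across all frames of the
#' requested channel, then min-max normalizes each composite to [0, 1].
#' The raw ranges are recorded so normalized quantities (fitted amplitudes,
#' baselines) can be mapped back to camera counts; a flat image is flagged
#' as degenerate and maps to all zeros.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param channel channel name.
#' @return a \code{\link{CompositePair}}.
#' @examples
#' st <- ImageStack(array(1:24, c(2, 3, 4)),
#'                  channelPlan("gfp", 488, 4L))
#' compositeImages(st, "gfp")
#' @export
compositeImages <- function(stack, channel) {
  stopifnot(is(stack, "ImageStack"))
  fr <- frameRange(stack, channel)
  sub <- stack@data[, , fr, drop = FALSE]
  meanI <- apply(sub, c(1, 2), mean)
  maxI <- apply(sub, c(1, 2), max)
  nm <- normalize01(meanI)
  nx <- normalize01(maxI)
  new("CompositePair", meanImage = nm$img, maxImage = nx$img,
      channel = channel,
      norm = list(meanRange = nm$range, maxRange = nx$range,
                  degenerate = nm$degenerate || nx$degenerate))
}

# Count intensity peaks inside a sub-box: strict 8-neighbour local maxima
# bright enough to satisfy the max/mean criterion themselves (noise wiggles
# at background level are not peaks of intensity).
.peaksInBox <- function(img, rows, cols, ratio) {
  sub <- img[rows, cols, drop = FALSE]
  lmx <- localMaxima(sub)
  if (!any(lmx)) return(0L)
  mu <- mean(sub)
  if (mu <= 0) return(sum(lmx))
  sum(sub[lmx] >= ratio * mu)
}

#' Find candidate spots by the max/mean box criterion
#'
#' Slides a square box across both composites; a region is a candidate when
#' the maximum pixel intensity inside the box is at least \code{ratio} times
#' the mean intensity inside it, on either composite.  Around each such
#' region the box is shrunk symmetrically (2 px per side per step, centred
#' on the brightest pixel) until exactly one local intensity peak remains
#' inside; candidates whose final box would be smaller than
#' \code{minBox} x \code{minBox} are rejected, and candidates whose centres
#' end up closer than \code{dedupDist} are merged keeping the brighter peak.
#'
#' @param pair a \code{\link{CompositePair}}.
#' @param ratio max/mean acceptance threshold (> 1).
#' @param box initial box size (odd).
#' @param minBox smallest acceptable final box (odd).
#' @param dedupDist merge distance for duplicate candidates (pixels).
#' @return data.frame with one row per candidate: \code{row}, \code{col}
#'   (peak pixel), \code{boxSize} (final), \code{peak} (normalized peak
#'   intensity on the composite that triggered detection).
#' @export
findCandidates <- function(pair, ratio = 1.119, box = 19L, minBox = 9L,
                           dedupDist = 4) {
  stopifnot(is(pair, "CompositePair"))
  if (box %% 2L != 1L || minBox %% 2L != 1L) stop("box sizes must be odd")
  if (ratio <= 1) stop("ratio must exceed 1")
  if (isTRUE(pair@norm$degenerate)) {
    return(data.frame(row = integer(), col = integer(),
                      boxSize = integer(), peak = numeric()))
  }
  half <- (box - 1L) %/% 2L
  out <- list()
  for (which in c("mean", "max")) {
    # the max composite is a per-pixel order statistic with a long-tailed
    # speckle; light smoothing before peak analysis controls it
    img <- if (which == "mean") pair@meanImage else smooth3(pair@maxImage)
    bmean <- movingMean(img, box)
    pass <- !is.na(bmean) & bmean > 0 & img >= ratio * bmean
    if (!any(pass)) next
    # candidates seed at strict local maxima that are themselves the peak
    # satisfying the max/mean criterion of their centred box
    lm <- localMaxima(img)
    seeds <- which(lm & pass, arr.ind = TRUE)
    if (nrow(seeds) == 0) next
    for (s in seq_len(nrow(seeds))) {
      r0 <- seeds[s, 1]; c0 <- seeds[s, 2]
      # shrink around the seeding peak until a single peak remains inside
      sz <- box
      r <- r0; c <- c0
      ok <- TRUE
      repeat {
        hh <- (sz - 1L) %/% 2L
        rows <- (r - hh):(r + hh); cols <- (c - hh):(c + hh)
        if (min(rows) < 1 || min(cols) < 1 ||
            max(rows) > nrow(img) || max(cols) > ncol(img)) {
          ok <- FALSE; break  # partially off-image: skip
        }
        if (.peaksInBox(img, rows, cols, ratio) <= 1L) break
        sz <- sz - 2L
        if (sz < minBox) { ok <- FALSE; break }
      }
      if (ok && sz >= minBox)
        out[[length(out) + 1L]] <- data.frame(row = r, col = c,
                                              boxSize = sz,
                                              peak = img[r, c])
    }
  }
  if (!length(out))
    return(data.frame(row = integer(), col = integer(),
                      boxSize = integer(), peak = numeric()))
  cand <- do.call(rbind, out)
  cand <- cand[order(-cand$peak), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d <- sqrt((cand$row[j] - cand$row[i])^2 +
                  (cand$col[j] - cand$col[i])^2)
      keep[j][d < dedupDist] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# Per-channel validity windows for the 1D Gaussian fit, on normalized images.
.defaultValidity <- list(
  cy5 = list(sigma = c(0.9, 3.5), B = c(0, 0.4)),
  gfp = list(sigma = c(0.3, 4.7), B = c(0, 0.53)),
  mcherry = list(sigma = c(0.3, 4.7), B = c(0, 0.53))
)

# Fit G(x) = B + A exp(-(x - mu)^2 / (2 sigma^2)) to one marginal profile
# by Levenberg-Marquardt least squares; x is measured from the box centre.
.fit1d <- function(y, pinAmplitude = FALSE) {
  n <- length(y)
  x <- seq_len(n) - (n + 1) / 2
  model <- function(p) {
    A <- if (pinAmplitude) 1 / (2 * pi) else p[["A"]]
    p[["B"]] + A * exp(-(x - p[["mu"]])^2 / (2 * p[["sigma"]]^2))
  }
  starts <- list(
    c(B = max(min(y), 0), A = max(y) - min(y),
      mu = x[which.max(y)], sigma = max(n / 8, 1)),
    c(B = max(min(y), 0), A = max(y) - min(y),
      mu = 0.1, sigma = max(n / 4, 2)),
    c(B = max(min(y), 0), A = max(y) - min(y),
      mu = x[which.max(y)], sigma = 0.6))
  best <- NULL
  for (start in starts) {
    if (pinAmplitude) start <- start[names(start) != "A"]
    out <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(p) y - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out) || !out$info %in% 1:4) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) return(NULL)
  cf <- as.list(best$par)
  if (pinAmplitude) cf$A <- 1 / (2 * pi)
  cf$sigma <- abs(cf$sigma)
  cf
}

#' Fit per-dimension 1D Gaussians to a candidate spot
#'
#' Extracts the marginal intensity profiles through the peak (the row and
#' the column of the candidate box on the mean composite) and fits each with
#' \eqn{G(x) = B + A\,\exp(-(x-\mu)^2/(2\sigma^2))}, x measured from the box
#' centre.  Validity requires, per channel, that both dimensions satisfy the
#' channel's sigma and baseline windows and that \eqn{|\mu| <}
#' \code{boxSize - muMargin}.
#'
#' @param pair a \code{\link{CompositePair}}.
#' @param candidate one row of \code{\link{findCandidates}} output.
#' @param validity named list of per-channel windows (each with elements
#'   \code{sigma} and \code{B}, ranges on the normalized scale).
#' @param muMargin the centre-offset bound is \code{boxSize - muMargin}.
#' @param pinAmplitude fit with the amplitude pinned to \code{1/(2*pi)}
#'   instead of free (historical fixed-amplitude parameterization).
#' @return one-row data.frame: peak position, per-dimension \code{mux, muy,
#'   sigmax, sigmay, Bx, By, Ax, Ay}, sub-pixel \code{x}, \code{y}
#'   (column/row + mu), \code{boxSize}, \code{valid} and \code{reason}.
#'   A non-convergent fit yields \code{valid = FALSE} with
#'   \code{reason = "no_convergence"}, never an error.
#' @export
fitSpot <- function(pair, candidate, validity = .defaultValidity,
                    muMargin = 2.5, pinAmplitude = FALSE) {
  stopifnot(is(pair, "CompositePair"))
  img <- pair@meanImage
  sz <- candidate$boxSize
  hh <- (sz - 1L) %/% 2L
  rows <- (candidate$row - hh):(candidate$row + hh)
  cols <- (candidate$col - hh):(candidate$col + hh)
  stopifnot(min(rows) >= 1, min(cols) >= 1,
            max(rows) <= nrow(img), max(cols) <= ncol(img))
  profX <- img[candidate$row, cols]   # along x (columns)
  profY <- img[rows, candidate$col]   # along y (rows)
  fx <- .fit1d(profX, pinAmplitude)
  fy <- .fit1d(profY, pinAmplitude)
  base <- data.frame(channel = pair@channel, row = candidate$row,
                     col = candidate$col, boxSize = sz,
                     peak = candidate$peak, stringsAsFactors = FALSE)
  if (is.null(fx) || is.null(fy)) {
    return(cbind(base, data.frame(mux = NA, muy = NA, sigmax = NA,
                                  sigmay = NA, Bx = NA, By = NA, Ax = NA,
                                  Ay = NA, x = NA, y = NA, valid = FALSE,
                                  reason = "no_convergence",
                                  stringsAsFactors = FALSE)))
  }
  win <- validity[[pair@channel]]
  if (is.null(win)) win <- validity[["gfp"]]
  muBound <- sz - muMargin
  reasons <- character()
  for (f in list(fx, fy)) {
    if (f$sigma < win$sigma[1] || f$sigma > win$sigma[2])
      reasons <- c(reasons, "sigma_window")
    if (f$B < win$B[1] || f$B > win$B[2])
      reasons <- c(reasons, "B_window")
    if (abs(f$mu) >= muBound)
      reasons <- c(reasons, "mu_bound")
  }
  reasons <- unique(reasons)
  cbind(base, data.frame(
    mux = fx$mu, muy = fy$mu, sigmax = fx$sigma, sigmay = fy$sigma,
    Bx = fx$B, By = fy$B, Ax = fx$A, Ay = fy$A,
    x = candidate$col + fx$mu, y = candidate$row + fy$mu,
    valid = length(reasons) == 0L,
    reason = if (length(reasons)) paste(reasons, collapse = ";") else "",
    stringsAsFactors = FALSE))
}

#' Detect and localize all spots of one channel
#'
#' Convenience wrapper: composites, candidate search and Gaussian fitting.
#'
#' @inheritParams findCandidates
#' @inheritParams fitSpot
#' @param stack an \code{\link{ImageStack}}.
#' @param channel channel name.
#' @param onlyValid drop fits failing the validity windows.
#' @return data.frame of spot fits (see \code{\link{fitSpot}}); zero rows
#'   when nothing is found.
#' @export
detectSpots <- function(stack, channel, ratio = 1.119, box = 19L,
                        minBox = 9L, validity = .defaultValidity,
                        muMargin = 2.5, onlyValid = TRUE) {
  pair <- compositeImages(stack, channel)
  cand <- findCandidates(pair, ratio = ratio, box = box, minBox = minBox)
  if (nrow(cand) == 0) return(cand)
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fitSpot(pair, cand[i, ], validity = validity, muMargin = muMargin)))
  if (onlyValid) fits <- fits[fits$valid, , drop = FALSE]
  rownames(fits) <- NULL
  fits
}
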