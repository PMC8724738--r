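#' @include AllClasses.R utils.R
NULL

#' StepResult: change points and plateau analysis of one bleaching trace
#'
#' @slot changePoints ordered change-point frames (last frame of the left
#'   segment, 1-based within the trace).
#' @slot plateaus mean level of each plateau (change points + 1 levels).
#' @slot steps number of counted downward bleaching steps (= fluorophores).
#' @slot reactivations data.frame of upward transitions (frame, magnitude)
#'   whose gain was discounted.
#' @slot photons summed corrected intensity from frame 1 to the final
#'   change point.
#' @slot stepClass "1".."5", ">5" or "X" (undetermined).
#' @slot minLogOdds smallest accepted change-point log posterior odds
#'   (Inf when no change point).
#' @exportClass StepResult
setClass("StepResult",
         representation(changePoints = "integer", plateaus = "numeric",
                        steps = "integer", reactivations = "data.frame",
                        photons = "numeric", stepClass = "character",
                        minLogOdds = "numeric"),
         validity = function(object) {
           if (length(object@plateaus) != length(object@changePoints) + 1L)
             "plateau count must equal change-point count + 1" else TRUE
         })

setMethod("show", "StepResult", function(object) {
  cat(sprintf("StepResult: %d step(s), class %s, %d change point(s), photons %.4g\n",
              object@steps, object@stepClass, length(object@changePoints),
              object@photons))
})

#' Extract a background-corrected intensity trace for one spot
#'
#' Per frame of the spot's channel, the trace value is the mean intensity of
#' the 3 x 3 pixel box centred on the spot's nearest pixel minus the mean
#' intensity of the ring of pixels at Chebyshev distance exactly 5 from that
#' pixel (the local background).  Values can be negative after background
#' subtraction.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param x,y raw spot position in this channel's pixel coordinates.
#' @param channel channel name.
#' @return list with \code{values} (length = channel frame count),
#'   \code{channel}, \code{frameRate} and \code{edgeClipped}; an
#'   edge-clipped trace has \code{values = NULL} and must be excluded
#'   downstream.
#' @export
extractTrace <- function(stack, x, y, channel) {
  stopifnot(is(stack, "ImageStack"))
  px <- round(x); py <- round(y)
  d <- dim(stack@data)
  if (py - 5 < 1 || px - 5 < 1 || py + 5 > d[1] || px + 5 > d[2]) {
    return(list(values = NULL, channel = channel,
                frameRate = stack@frameRate, edgeClipped = TRUE))
  }
  fr <- frameRange(stack, channel)
  sub <- stack@data[(py - 5):(py + 5), (px - 5):(px + 5), fr, drop = FALSE]
  ij <- expand.grid(i = -5:5, j = -5:5)
  cheb <- pmax(abs(ij$i), abs(ij$j))
  centre <- which(cheb <= 1)       # 3 x 3 central box
  ring <- which(cheb == 5)         # background ring
  flat <- matrix(sub, nrow = 121, ncol = length(fr))
  vals <- colMeans(flat[centre, , drop = FALSE]) -
    colMeans(flat[ring, , drop = FALSE])
  list(values = as.numeric(vals), channel = channel,
       frameRate = stack@frameRate, edgeClipped = FALSE)
}

# Log marginal evidence pieces for the single change-point model in
# piecewise-constant Gaussian noise, means given flat priors and the noise
# variance integrated out under a Jeffreys prior.  For a segment model with
# k means over N points and minimized residual sum RSS:
#   log p(D | model) = -((N-k)/2) log(2*pi) - 0.5*sum(log n_j)
#                      + lgamma((N-k)/2) - ((N-k)/2) log(RSS/2)
.segEvidence <- function(N, k, logNprod, rss) {
  nk <- N - k
  -nk / 2 * log(2 * pi) - 0.5 * logNprod + lgamma(nk / 2) -
    nk / 2 * log(rss / 2)
}

# One level of the detector: most probable change position and the log
# posterior odds of the one-change model against the no-change model.
.bestSplit <- function(y, minSegment) {
  N <- length(y)
  if (N < 2 * minSegment) return(NULL)
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  rss0 <- s2[N] - s1[N]^2 / N
  floorRss <- .Machine$double.eps * N * (1 + s2[N])
  if (rss0 <= floorRss) return(NULL)  # constant segment
  m <- minSegment:(N - minSegment)
  rssL <- s2[m] - s1[m]^2 / m
  rssR <- (s2[N] - s2[m]) - (s1[N] - s1[m])^2 / (N - m)
  rss <- pmax(rssL + rssR, floorRss)
  lm_ <- .segEvidence(N, 2L, log(m) + log(N - m), rss)
  best <- which.max(lm_)
  # posterior over positions (uniform prior): average the evidence
  logM1 <- max(lm_) + log(mean(exp(lm_ - max(lm_))))
  logM0 <- .segEvidence(N, 1L, log(N), rss0)
  list(pos = m[best], logOdds = logM1 - logM0)
}

#' Detect bleaching change points by recursive Bayesian segmentation
#'
#' Implements a recursive binary Bayesian step detector for
#' piecewise-constant signals in Gaussian noise of unknown variance.  At
#' each level the posterior over the position m of a single mean shift is
#' proportional to \eqn{[m(N-m)]^{-1/2} RSS(m)^{-(N-2)/2}} (the mean levels
#' carry flat priors and the variance is integrated out under a Jeffreys
#' prior); the most probable position is accepted when the log posterior
#' odds of the one-change model against the no-change model exceed
#' \code{logOddsThreshold}, and the detector then recurses on the sub-traces
#' to the left and right until no further change point qualifies.  The
#' trace is internally standardized, making the output exactly invariant to
#' affine intensity rescaling.
#'
#' @param values numeric trace (length >= 2 * minSegment for any detection).
#' @param logOddsThreshold recursion stop: accept a change point only while
#'   the log posterior odds exceed this (default 8).
#' @param minSegment smallest allowed segment length (frames).
#' @return sorted integer change points (last frame of each left segment),
#'   with attribute \code{logOdds} giving each accepted point's odds.
#'   Constant traces give an empty result; traces shorter than
#'   \code{2 * minSegment} give an empty result with a warning.
#' @examples
#' cp <- detectChangePoints(c(rep(2, 100), rep(0, 150)))
#' cp  # 100
#' @export
detectChangePoints <- function(values, logOddsThreshold = 8,
                               minSegment = 3L) {
  empty <- structure(integer(), logOdds = numeric())
  if (length(values) < 2 * minSegment) {
    warning("trace shorter than 2 * minSegment; no detection attempted")
    return(empty)
  }
  s <- stats::sd(values)
  z <- if (s > 0) (values - mean(values)) / s else values
  cps <- integer(); odds <- numeric()
  recurse <- function(lo, hi) {
    seg <- z[lo:hi]
    sp <- .bestSplit(seg, minSegment)
    if (is.null(sp) || sp$logOdds <= logOddsThreshold) return(invisible())
    cp <- lo + sp$pos - 1L
    cps <<- c(cps, cp)
    odds <<- c(odds, sp$logOdds)
    recurse(lo, cp)
    recurse(cp + 1L, hi)
  }
  recurse(1L, length(z))
  o <- order(cps)
  cps <- .refineCps(z, as.integer(cps[o]), minSegment)
  structure(cps, logOdds = odds[o])
}

# Coordinate-descent refinement: binary segmentation fixes each boundary
# before later splits exist, which can leave a change point a frame or two
# off; re-optimize each boundary by exact RSS with its neighbours fixed.
.refineCps <- function(z, cps, minSegment, maxPasses = 10L) {
  k <- length(cps)
  if (k == 0L) return(cps)
  N <- length(z)
  for (pass in seq_len(maxPasses)) {
    moved <- FALSE
    for (i in seq_len(k)) {
      a <- if (i == 1L) 0L else cps[i - 1L]
      b <- if (i == k) N else cps[i + 1L]
      lo <- a + minSegment; hi <- b - minSegment
      if (lo > hi) next
      seg <- z[(a + 1L):b]
      n <- length(seg)
      s1 <- cumsum(seg); s2 <- cumsum(seg^2)
      m <- (lo - a):(hi - a)
      rss <- (s2[m] - s1[m]^2 / m) +
        ((s2[n] - s2[m]) - (s1[n] - s1[m])^2 / (n - m))
      newCp <- a + m[which.min(rss)]
      if (newCp != cps[i]) { cps[i] <- newCp; moved <- TRUE }
    }
    if (!moved) break
  }
  cps
}

#' Count bleaching steps from change points with re-activation discounting
#'
#' Plateau levels are the segment means between consecutive change points.
#' An upward transition whose level increase exceeds the within-plateau
#' noise SD is recorded as a re-activation event and its gained intensity is
#' discounted: the matching later downward step is not counted.  The
#' fluorophore count is the number of counted downward transitions; classes
#' are "1".."5", ">5", or "X" when no consistent step count can be assigned
#' (no counted downward step, or a first plateau already at background
#' level, i.e. pre-bleached).  The photon count is the summed corrected
#' intensity from the first frame to the final change point.
#'
#' @param values numeric trace.
#' @param changePoints output of \code{\link{detectChangePoints}} (sorted).
#' @return a \code{\link{StepResult}}.
#' @examples
#' tr <- c(rep(2, 50), rep(1, 50), rep(0, 50))
#' countSteps(tr, detectChangePoints(tr))
#' @export
countSteps <- function(values, changePoints) {
  N <- length(values)
  stopifnot(all(changePoints >= 1), all(changePoints < N),
            !is.unsorted(changePoints))
  bounds <- c(0L, as.integer(changePoints), N)
  k <- length(bounds) - 1L
  plateaus <- numeric(k); rss <- 0
  for (i in seq_len(k)) {
    seg <- values[(bounds[i] + 1L):bounds[i + 1L]]
    plateaus[i] <- mean(seg)
    rss <- rss + sum((seg - plateaus[i])^2)
  }
  noiseSd <- if (N > k) sqrt(rss / (N - k)) else 0
  # transitions within the noise SD are plateau-estimation jitter, not
  # bleaching or re-activation events
  trans <- diff(plateaus)
  nUp <- sum(trans > noiseSd)
  nDown <- sum(trans < -noiseSd)
  steps <- max(0L, nDown - nUp)
  react <- data.frame(frame = as.integer(changePoints[trans > noiseSd]),
                      magnitude = trans[trans > noiseSd])
  odds <- attr(changePoints, "logOdds")
  minOdds <- if (length(odds)) min(odds) else Inf
  preBleached <- k >= 2 &&
    abs(plateaus[1] - plateaus[k]) <= max(noiseSd, 1e-12)
  cls <- if (steps == 0L || preBleached) "X"
  else if (steps > 5L) ">5" else as.character(steps)
  photons <- if (length(changePoints))
    sum(values[1:max(changePoints)]) else 0
  new("StepResult", changePoints = as.integer(changePoints),
      plateaus = plateaus, steps = as.integer(steps),
      reactivations = react, photons = photons, stepClass = cls,
      minLogOdds = minOdds)
}

#' Analyse one trace end to end
#'
#' @inheritParams detectChangePoints
#' @return a \code{\link{StepResult}}.
#' @export
analyseTrace <- function(values, logOddsThreshold = 8, minSegment = 3L) {
  countSteps(values, detectChangePoints(values, logOddsThreshold,
                                        minSegment))
}

#' Collate step results into a StepHistogram
#'
#' @param results list of \code{\link{StepResult}} objects (the analysed
#'   colocalized complexes).
#' @param totalRna total RNA spots detected in the same fields.
#' @param condition condition label.
#' @return a \code{\link{StepHistogram}}; class totals equal the number of
#'   analysed complexes.
#' @export
buildStepHistogram <- function(results, totalRna, condition = "condition") {
  cls <- vapply(results, function(r) r@stepClass, character(1))
  counts <- setNames(integer(7), .STEP_CLASSES)
  tab <- table(factor(cls, levels = .STEP_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  StepHistogram(counts, totalRna = totalRna, condition = condition)
}

#' Flag low-confidence step assignments for optional manual review
#'
#' The automated stand-in for by-eye checking of change points: flags
#' results whose smallest accepted log odds lies within \code{margin} of the
#' detection threshold, that contain re-activation events, or whose class is
#' "X".  The pipeline proceeds unaided by default; the flagged table can be
#' exported for manual override.
#'
#' @param results list of \code{\link{StepResult}}.
#' @param logOddsThreshold the threshold used during detection.
#' @param margin relative margin (default 0.1: within 10\% of threshold).
#' @return data.frame with index, class, minLogOdds and reason; zero rows
#'   when nothing needs review.
#' @export
reviewQueue <- function(results, logOddsThreshold = 8, margin = 0.1) {
  rows <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    reasons <- character()
    if (is.finite(r@minLogOdds) &&
        r@minLogOdds <= logOddsThreshold * (1 + margin))
      reasons <- c(reasons, "near_threshold")
    if (nrow(r@reactivations)) reasons <- c(reasons, "reactivation")
    if (r@stepClass == "X") reasons <- c(reasons, "undetermined")
    if (length(reasons))
      rows[[length(rows) + 1L]] <- data.frame(
        index = i, class = r@stepClass, minLogOdds = r@minLogOdds,
        reason = paste(reasons, collapse = ";"), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(index = integer(), class = character(),
                      minLogOdds = numeric(), reason = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Photon-count validation of one- vs two-molecule assignments
#'
#' Checks the internal consistency of step-count assignments through total
#' photon counts: complexes assigned two molecules should emit about twice
#' the photons of complexes assigned one.  Pseudo-double complexes are built
#' by adding the one-molecule photon counts to the same values rearranged in
#' a seeded random order (a fixed-point-free permutation, so no value is
#' added to itself); the two-molecule distribution is compared against the
#' singles and against the pseudo-doubles by two-tailed Mann-Whitney
#' (Wilcoxon rank-sum) tests.
#'
#' @param photons1,photons2 photon counts of complexes assigned 1 and 2
#'   molecules (>= 10 each).
#' @param seed integer seed for the permutation.
#' @return list with the three medians (single, double, pseudoDouble) and
#'   the two p-values (\code{p12}: 1 vs 2; \code{p2pseudo}: 2 vs
#'   pseudo-double).
#' @export
photonCountValidation <- function(photons1, photons2, seed = 1) {
  if (length(photons1) < 10 || length(photons2) < 10)
    stop("at least 10 traces per class are required")
  n <- length(photons1)
  perm <- withSeed(seed, {
    p <- sample(n)
    while (any(p == seq_len(n))) p <- sample(n)
    p
  })
  pseudo <- photons1 + photons1[perm]
  list(medianSingle = stats::median(photons1),
       medianDouble = stats::median(photons2),
       medianPseudoDouble = stats::median(pseudo),
       p12 = stats::wilcox.test(photons1, photons2, exact = FALSE)$p.value,
       p2pseudo = stats::wilcox.test(photons2, pseudo,
                                     exact = FALSE)$p.value)
}
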