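#' @include AllClasses.R
NULL

#' Apply a chromatic correction to spot positions
#'
#' Maps raw positions recorded in the transform's source channel into the
#' reference channel's frame: per dimension,
#' \eqn{x_t = x + (x - x_c)/SF_x}.  Pure arithmetic, exactly invertible
#' (see \code{\link{invertTransform}}); positions at the centre of zero
#' divergence are fixed points.
#'
#' @param position data.frame (or list) with numeric \code{x}, \code{y}.
#' @param transform a \code{\link{ChromaticTransform}}.
#' @return data.frame with corrected \code{x}, \code{y}.
#' @examples
#' t <- ChromaticTransform("gfp", "cy5", xc = 256, sfx = -800,
#'                         yc = 256, sfy = -800)
#' applyTransform(data.frame(x = 256, y = 256), t)  # fixed point
#' @export
applyTransform <- function(position, transform) {
  stopifnot(is(transform, "ChromaticTransform"))
  x <- position$x; y <- position$y
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  data.frame(x = x + (x - transform@xc) / transform@sfx,
             y = y + (y - transform@yc) / transform@sfy)
}

#' Invert a chromatic correction
#'
#' Returns the raw source-channel position whose correction equals the given
#' reference-frame position; \code{applyTransform} after
#' \code{invertTransform} is the identity to numerical precision.
#'
#' @inheritParams applyTransform
#' @return data.frame with raw \code{x}, \code{y}.
#' @export
invertTransform <- function(position, transform) {
  stopifnot(is(transform, "ChromaticTransform"))
  data.frame(x = .invert1d(position$x, transform@xc, transform@sfx),
             y = .invert1d(position$y, transform@yc, transform@sfy))
}

# One-dimensional calibration: least squares for (xc, sf) given source
# positions x (other channel) and reference positions xr.
# Model: xr = x + (x - xc)/sf  <=>  residual r = x + (x - xc)/sf - xr.
# For fixed sf the optimal xc is linear; profile over a = 1/sf:
# r = x - xr + a (x - xc) = (x - xr) + a x - b  with b = a xc.
# Linear least squares in (a, b).
.calibrate1d <- function(x, xr) {
  d <- xr - x
  X <- cbind(x, -1)
  fit <- stats::lm.fit(X, d)
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  if (!is.finite(a))
    stop("degenerate calibration geometry (no divergence gradient)")
  # no measurable divergence: represent "no correction" by a huge SF
  if (abs(a) < 1e-12) return(list(sf = 1e12, c = 0))
  list(sf = 1 / a, c = b / a)
}

#' Calibrate a chromatic transform from dual-labelled emitter pairs
#'
#' Fits, per dimension, the centre of zero divergence and the scaling factor
#' by least squares on matched localizations of emitters labelled with both
#' the reference and the source fluorophore (e.g. dual-labelled
#' oligonucleotides imaged at 633 and 488 nm), minimizing the squared
#' distance between corrected source positions and reference positions.
#'
#' @param pairs data.frame with columns \code{refX}, \code{refY} (reference
#'   channel) and \code{srcX}, \code{srcY} (source channel), >= 3 pairs
#'   spanning a nondegenerate geometry.
#' @param sourceChannel,refChannel channel names stored in the result.
#' @return a \code{\link{ChromaticTransform}} whose \code{residuals} slot
#'   holds the per-pair corrected separations (pixels).
#' @examples
#' t <- ChromaticTransform("gfp", "cy5", 256, -800, 256, -800)
#' beads <- simulateBeadPairs(50, t, noiseSd = 0, seed = 1)
#' calibrateTransform(beads)
#' @export
calibrateTransform <- function(pairs, sourceChannel = "gfp",
                               refChannel = "cy5") {
  need <- c("refX", "refY", "srcX", "srcY")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) < 3)
    stop("at least 3 calibration pairs are required")
  if (stats::sd(pairs$srcX) == 0 || stats::sd(pairs$srcY) == 0)
    stop("degenerate calibration geometry (pairs do not span the field)")
  cx <- .calibrate1d(pairs$srcX, pairs$refX)
  cy <- .calibrate1d(pairs$srcY, pairs$refY)
  tr <- ChromaticTransform(sourceChannel, refChannel,
                           xc = unname(cx$c), sfx = unname(cx$sf),
                           yc = unname(cy$c), sfy = unname(cy$sf))
  corr <- applyTransform(data.frame(x = pairs$srcX, y = pairs$srcY), tr)
  tr@residuals <- data.frame(
    dx = corr$x - pairs$refX, dy = corr$y - pairs$refY,
    separation = sqrt((corr$x - pairs$refX)^2 + (corr$y - pairs$refY)^2))
  tr
}

#' Read/write a chromatic transform as a key-value text file
#'
#' @param transform a \code{\link{ChromaticTransform}}.
#' @param path file path.
#' @return \code{readTransform} returns a \code{ChromaticTransform};
#'   \code{writeTransform} returns \code{path} invisibly.
#' @export
writeTransform <- function(transform, path) {
  lines <- c(
    paste0("source_channel\t", transform@sourceChannel),
    paste0("ref_channel\t", transform@refChannel),
    paste0("x_c\t", format(transform@xc, digits = 17)),
    paste0("SF_x\t", format(transform@sfx, digits = 17)),
    paste0("y_c\t", format(transform@yc, digits = 17)),
    paste0("SF_y\t", format(transform@sfy, digits = 17)))
  if (nrow(transform@residuals))
    lines <- c(lines, paste0("median_residual_px\t",
                             format(stats::median(transform@residuals$separation))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  g <- function(k) kv$value[match(k, kv$key)]
  ChromaticTransform(g("source_channel"), g("ref_channel"),
                     xc = as.numeric(g("x_c")), sfx = as.numeric(g("SF_x")),
                     yc = as.numeric(g("y_c")), sfy = as.numeric(g("SF_y")))
}
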