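#' @include AllClasses.R
NULL

.checkCoords <- function(spots, what) {
  if (!all(c("x", "y") %in% names(spots)))
    stop(what, " spots lack corrected coordinates (columns x, y)")
  bad <- which(!is.finite(spots$x) | !is.finite(spots$y))
  if (length(bad))
    stop(what, " spot record(s) without corrected coordinates: ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Pair spots across channels into colocalized complexes
#'
#' Two spots of different wavelengths are considered colocalized when their
#' corrected separation is at most \code{maxSep} pixels (default 2).
#' Matching is greedy one-to-one in increasing order of Euclidean
#' separation, so a single bright spot cannot be claimed by two partners;
#' ties are broken by peak intensity (brighter first, when a \code{peak}
#' column is present) and then by index.  The colocalization percentage is
#' matched reference spots / total reference spots x 100.
#'
#' @param reference data.frame of reference-channel spots (corrected
#'   \code{x}, \code{y}; rows are spot ids).
#' @param other data.frame of other-channel spots (corrected coordinates).
#' @param maxSep matching threshold (pixels).
#' @return list with \code{complexes} (data.frame: refId, otherId,
#'   separation, plus ref/other coordinates), \code{pct} (colocalization
#'   percentage) and \code{nRef}, \code{nOther}.
#' @examples
#' a <- data.frame(x = c(1, 10), y = c(1, 10))
#' colocalize(a, a)$pct  # 100
#' @export
colocalize <- function(reference, other, maxSep = 2.0) {
  .checkCoords(reference, "reference")
  .checkCoords(other, "other")
  nR <- nrow(reference); nO <- nrow(other)
  if (nR == 0 || nO == 0) {
    return(list(complexes = data.frame(refId = integer(),
                                       otherId = integer(),
                                       separation = numeric()),
                pct = 0, nRef = nR, nOther = nO))
  }
  dx <- outer(reference$x, other$x, `-`)
  dy <- outer(reference$y, other$y, `-`)
  d <- sqrt(dx^2 + dy^2)
  idx <- which(d <= maxSep, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(complexes = data.frame(refId = integer(),
                                       otherId = integer(),
                                       separation = numeric()),
                pct = 0, nRef = nR, nOther = nO))
  }
  sep <- d[idx]
  peak <- if ("peak" %in% names(other)) other$peak[idx[, 2]] else
    rep(0, nrow(idx))
  ord <- order(sep, -peak, idx[, 1], idx[, 2])
  usedR <- logical(nR); usedO <- logical(nO)
  rows <- list()
  for (k in ord) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (usedR[i] || usedO[j]) next
    usedR[i] <- TRUE; usedO[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      refId = i, otherId = j, separation = sep[k],
      refX = reference$x[i], refY = reference$y[i],
      otherX = other$x[j], otherY = other$y[j])
  }
  complexes <- do.call(rbind, rows)
  complexes <- complexes[order(complexes$refId), , drop = FALSE]
  rownames(complexes) <- NULL
  list(complexes = complexes, pct = 100 * nrow(complexes) / nR,
       nRef = nR, nOther = nO)
}

#' Intersect two pairwise colocalizations into three-way complexes
#'
#' Given complexes of the RNA channel with protein A and with protein B
#' (built over the same RNA spot set), returns the complexes whose RNA spot
#' carries both proteins.
#'
#' @param complexesA,complexesB outputs of \code{\link{colocalize}} sharing
#'   the same reference spot universe (checked via \code{nRef}).
#' @return data.frame keyed by \code{refId} with both protein spot ids and
#'   separations.
#' @export
threeWay <- function(complexesA, complexesB) {
  if (!identical(complexesA$nRef, complexesB$nRef))
    stop("the two colocalizations do not share the same RNA spot universe")
  a <- complexesA$complexes; b <- complexesB$complexes
  ids <- intersect(a$refId, b$refId)
  if (!length(ids)) {
    return(data.frame(refId = integer(), idA = integer(), idB = integer(),
                      sepA = numeric(), sepB = numeric()))
  }
  ia <- match(ids, a$refId); ib <- match(ids, b$refId)
  data.frame(refId = ids, idA = a$otherId[ia], idB = b$otherId[ib],
             sepA = a$separation[ia], sepB = b$separation[ib])
}

#' Random-background colocalization probability by translation controls
#'
#' Estimates the chance colocalization rate of one image by translating the
#' other-channel spot list by fixed large offsets (+/- \code{offset} px in x
#' and y, toroidal wrap at the field edges) and averaging the resulting
#' colocalization fractions.  Reported per image; with very few spots the
#' estimate is flagged low-confidence.
#'
#' @inheritParams colocalize
#' @param fieldDim \code{c(height, width)} pixels (positive).
#' @param offset translation magnitude (pixels).
#' @return list with \code{probability} (fraction in [0, 1]),
#'   \code{perOffset} rates and \code{lowConfidence}.
#' @export
backgroundProbability <- function(reference, other, maxSep = 2.0,
                                  fieldDim, offset = 10) {
  stopifnot(length(fieldDim) == 2, all(fieldDim > 0))
  nO <- nrow(other)
  if (nO == 0 || nrow(reference) == 0)
    return(list(probability = 0, perOffset = numeric(0),
                lowConfidence = TRUE))
  shifts <- list(c(offset, 0), c(-offset, 0), c(0, offset), c(0, -offset))
  rates <- vapply(shifts, function(s) {
    shifted <- data.frame(
      x = (other$x - 1 + s[1]) %% fieldDim[2] + 1,
      y = (other$y - 1 + s[2]) %% fieldDim[1] + 1)
    colocalize(reference, shifted, maxSep)$pct / 100
  }, numeric(1))
  list(probability = mean(rates), perOffset = rates,
       lowConfidence = nrow(reference) < 5 || nO < 5)
}
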