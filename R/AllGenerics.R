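#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package: channel names and frame
#' ranges of a movie, normalized composites, histogram counts and derived
#' colocalization percentage, label-model parameters.
#'
#' @param x an object.
#' @param channel a channel name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("frameRange", function(x, channel) standardGeneric("frameRange"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("stepCounts", function(x) standardGeneric("stepCounts"))

#' @rdname accessors
#' @export
setGeneric("colocPct", function(x) standardGeneric("colocPct"))

#' @rdname accessors
#' @export
setGeneric("labelledFraction", function(x) standardGeneric("labelledFraction"))

#' @rdname accessors
#' @export
setGeneric("dimerFraction", function(x) standardGeneric("dimerFraction"))

#' @rdname accessors
setMethod("channels", "ImageStack", function(x) x@plan$channel)

#' @rdname accessors
setMethod("nFrames", "ImageStack", function(x) dim(x@data)[3])

#' @rdname accessors
setMethod("frameRange", "ImageStack", function(x, channel) {
  i <- match(channel, x@plan$channel)
  if (is.na(i)) stop("unknown channel: ", channel)
  x@plan$first[i]:x@plan$last[i]
})

#' @rdname accessors
setMethod("stepCounts", "StepHistogram", function(x) x@counts)

#' @rdname accessors
setMethod("colocPct", "StepHistogram",
          function(x) 100 * sum(x@counts) / x@totalRna)

#' @rdname accessors
setMethod("labelledFraction", "LabelModel", function(x) x@f)

#' @rdname accessors
setMethod("dimerFraction", "LabelModel", function(x) x@d)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d px, %d frames @ %g fps\n",
              d[1], d[2], d[3], object@frameRate))
  p <- object@plan
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-8s %4g nm  frames %d-%d\n",
                p$channel[i], p$wavelength[i], p$first[i], p$last[i]))
})

setMethod("show", "CompositePair", function(object) {
  d <- dim(object@meanImage)
  cat(sprintf("CompositePair (%s): %d x %d px%s\n", object@channel,
              d[1], d[2],
              if (isTRUE(object@norm$degenerate)) " [flat image]" else ""))
})

setMethod("show", "ChromaticTransform", function(object) {
  cat(sprintf("ChromaticTransform %s -> %s\n", object@sourceChannel,
              object@refChannel))
  cat(sprintf("  x: centre %.3f, SF %.6g\n", object@xc, object@sfx))
  cat(sprintf("  y: centre %.3f, SF %.6g\n", object@yc, object@sfy))
  if (nrow(object@residuals))
    cat(sprintf("  calibration: %d pairs, median corrected separation %.4f px\n",
                nrow(object@residuals),
                stats::median(object@residuals$separation)))
})

setMethod("show", "LabelModel", function(object) {
  cat(sprintf("LabelModel: f = %.3f, d = %.3f%s\n", object@f, object@d,
              if (is.na(object@source)) "" else paste0(" (", object@source, ")")))
})

setMethod("show", "StepHistogram", function(object) {
  cat(sprintf("StepHistogram '%s': %d RNA spots, %d colocalized (%.1f%%)\n",
              object@condition, object@totalRna, sum(object@counts),
              colocPct(object)))
  print(object@counts)
})

setMethod("show", "OccupancyFit", function(object) {
  cat(sprintf("OccupancyFit: pi2 = %.3f, scale = %.1f, chisq = %.3g (df %d)%s\n",
              object@pi2, object@scale, object@chisq, object@df,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "PositionTable", function(object) {
  cat(sprintf("PositionTable '%s' (%s, %s): %d nt, %g pairs\n",
              object@experiment, object@role,
              ifelse(is.na(object@cellLine), "-", object@cellLine),
              length(object@coverage), sum(object@coverage)))
})
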