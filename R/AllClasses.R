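#' @import methods
NULL

#' Channel plan constructor
#'
#' A channel plan maps each excitation channel of a sequential multi-colour
#' acquisition to a contiguous, ordered block of frames.  The default plan
#' mirrors a typical three-colour acquisition: 50 frames at 633 nm (Cy5,
#' used to locate RNA spots), then 250 frames at 561 nm (mCherry) and 250
#' frames at 488 nm (mEGFP), collected at 20 frames/s.
#'
#' @param channels character vector of channel names, in acquisition order.
#' @param wavelengths numeric excitation wavelengths (nm).
#' @param frames integer number of frames per channel (all >= 1).
#' @return A data.frame with columns \code{channel}, \code{wavelength},
#'   \code{frames}, \code{first}, \code{last} (1-based frame indices).
#' @examples
#' channelPlan()
#' channelPlan(c("cy5", "gfp"), c(633, 488), c(10, 50))
#' @export
channelPlan <- function(channels = c("cy5", "mcherry", "gfp"),
                        wavelengths = c(633, 561, 488),
                        frames = c(50L, 250L, 250L)) {
  stopifnot(length(channels) == length(wavelengths),
            length(channels) == length(frames))
  frames <- as.integer(frames)
  if (any(frames < 1L)) stop("every channel needs at least one frame")
  if (anyDuplicated(channels)) stop("duplicate channel names")
  last <- cumsum(frames)
  data.frame(channel = as.character(channels),
             wavelength = as.numeric(wavelengths),
             frames = frames,
             first = c(1L, head(last, -1L) + 1L),
             last = last,
             stringsAsFactors = FALSE)
}

.validPlan <- function(plan) {
  ok <- is.data.frame(plan) &&
    all(c("channel", "wavelength", "frames", "first", "last") %in% names(plan))
  if (!ok) return("plan must be a channelPlan() data.frame")
  if (nrow(plan) == 0) return("plan has no channels")
  if (any(plan$frames < 1L)) return("frame counts must be >= 1")
  exp_first <- c(1L, head(cumsum(plan$frames), -1L) + 1L)
  if (!all(plan$first == exp_first) || !all(plan$last == cumsum(plan$frames)))
    return("channel frame ranges must be contiguous, ordered and disjoint")
  TRUE
}

#' ImageStack: a sequential multi-channel TIRF movie
#'
#' Holds the pixel data of a movie in which channels were recorded one after
#' another (not interleaved), together with the channel plan and frame rate.
#'
#' @slot data numeric array, \code{height x width x frames}, camera counts.
#' @slot plan channel plan data.frame (see \code{\link{channelPlan}}).
#' @slot frameRate frames per second.
#' @seealso \code{\link{simulateMovie}}, \code{\link{compositeImages}}
#' @exportClass ImageStack
setClass("ImageStack",
         representation(data = "array", plan = "data.frame",
                        frameRate = "numeric"),
         validity = function(object) {
           msg <- character()
           if (length(dim(object@data)) != 3L)
             msg <- c(msg, "data must be a height x width x frames array")
           p <- .validPlan(object@plan)
           if (!isTRUE(p)) msg <- c(msg, p)
           else if (dim(object@data)[3] != sum(object@plan$frames))
             msg <- c(msg, "number of frames does not match the channel plan")
           if (length(dim(object@data)) == 3L && any(object@data < 0))
             msg <- c(msg, "camera counts must be non-negative")
           if (length(object@frameRate) != 1L || object@frameRate <= 0)
             msg <- c(msg, "frameRate must be a single positive number")
           if (length(msg)) msg else TRUE
         })

#' @describeIn ImageStack constructor
#' @param data,plan,frameRate see slots.
#' @export
ImageStack <- function(data, plan = channelPlan(), frameRate = 20) {
  new("ImageStack", data = data, plan = plan, frameRate = frameRate)
}

#' CompositePair: mean and maximum projection of one channel
#'
#' Spot detection operates on two composite images per channel: the per-pixel
#' mean and the per-pixel maximum across all frames of that channel, each
#' min-max normalized to [0, 1].  The raw ranges used for normalization are
#' recorded so fitted (normalized) amplitudes can be converted back to counts.
#'
#' @slot meanImage,maxImage normalized matrices in [0, 1].
#' @slot channel channel name.
#' @slot norm list with elements \code{meanRange}, \code{maxRange} (raw
#'   min/max) and \code{degenerate} (TRUE when an image was flat).
#' @exportClass CompositePair
setClass("CompositePair",
         representation(meanImage = "matrix", maxImage = "matrix",
                        channel = "character", norm = "list"),
         validity = function(object) {
           msg <- character()
           if (!identical(dim(object@meanImage), dim(object@maxImage)))
             msg <- c(msg, "mean and max images must have the same shape")
           rng <- range(object@meanImage, object@maxImage)
           if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
             msg <- c(msg, "normalized composites must lie in [0, 1]")
           if (length(msg)) msg else TRUE
         })

#' ChromaticTransform: linear per-dimension chromatic correction
#'
#' Corrects the apparent position of a spot recorded in one channel into the
#' reference channel's coordinate frame.  The model assumes the divergence of
#' the source-channel signal from the reference grows linearly with distance
#' from a centre of zero divergence: per dimension,
#' \deqn{x_t = x + (x - x_c) / SF_x}
#' with centre \eqn{x_c} and dimensionless scaling factor \eqn{SF_x}
#' (likewise for y).  Large |SF| means little correction.
#'
#' @slot sourceChannel,refChannel channel names.
#' @slot xc,yc centre of zero divergence (pixels).
#' @slot sfx,sfy scaling factors (finite, nonzero; sign admissible).
#' @slot residuals data.frame of per-pair corrected separations from
#'   calibration (may be empty).
#' @seealso \code{\link{applyTransform}}, \code{\link{calibrateTransform}}
#' @exportClass ChromaticTransform
setClass("ChromaticTransform",
         representation(sourceChannel = "character", refChannel = "character",
                        xc = "numeric", yc = "numeric",
                        sfx = "numeric", sfy = "numeric",
                        residuals = "data.frame"),
         prototype(residuals = data.frame()),
         validity = function(object) {
           sf <- c(object@sfx, object@sfy)
           if (any(!is.finite(sf)) || any(sf == 0))
             "scaling factors must be finite and nonzero"
           else TRUE
         })

#' @describeIn ChromaticTransform constructor
#' @param sourceChannel,refChannel,xc,sfx,yc,sfy see slots.
#' @export
ChromaticTransform <- function(sourceChannel, refChannel, xc, sfx, yc, sfy) {
  new("ChromaticTransform", sourceChannel = sourceChannel,
      refChannel = refChannel, xc = xc, sfx = sfx, yc = yc, sfy = sfy)
}

#' LabelModel: labelled fraction and intrinsic dimerization
#'
#' The observable number of bleaching steps under-counts molecules because
#' only a fraction f of the protein pool carries the fluorescent tag
#' (measured by quantitative Western blotting, e.g. tagged:endogenous 90:10
#' gives f = 0.9), and over-counts because a recruited unit may be an
#' intrinsic homodimer with probability d (estimated from two-step bleaching
#' in the absence of added RNA).
#'
#' @slot f labelled fraction, 0 < f <= 1.
#' @slot d intrinsic dimer fraction, 0 <= d < 1.
#' @slot source free-text label for the extract the values came from.
#' @seealso \code{\link{unitStepDistribution}},
#'   \code{\link{estimateDimerFraction}}
#' @exportClass LabelModel
setClass("LabelModel",
         representation(f = "numeric", d = "numeric", source = "character"),
         prototype(source = NA_character_),
         validity = function(object) {
           msg <- character()
           if (!(object@f > 0 && object@f <= 1))
             msg <- c(msg, "labelled fraction f must satisfy 0 < f <= 1")
           if (!(object@d >= 0 && object@d < 1))
             msg <- c(msg, "dimer fraction d must satisfy 0 <= d < 1")
           if (length(msg)) msg else TRUE
         })

#' @describeIn LabelModel constructor
#' @param f,d,source see slots.
#' @export
LabelModel <- function(f, d, source = NA_character_) {
  new("LabelModel", f = f, d = d, source = source)
}

.STEP_CLASSES <- c("1", "2", "3", "4", "5", ">5", "X")

#' StepHistogram: step-count classes for one condition
#'
#' Counts of colocalized complexes whose protein fluorophores bleached in
#' 1, 2, ..., 5, more than 5 steps, or an undetermined number ("X"),
#' together with the total number of RNA spots examined.
#'
#' @slot condition condition label.
#' @slot counts named integer vector over classes 1..5, ">5", "X".
#' @slot totalRna total RNA spots detected.
#' @seealso \code{\link{simulateStepHistogram}},
#'   \code{\link{fitOccupancyMixture}}
#' @exportClass StepHistogram
setClass("StepHistogram",
         representation(condition = "character", counts = "integer",
                        totalRna = "integer"),
         validity = function(object) {
           msg <- character()
           if (!identical(names(object@counts), .STEP_CLASSES))
             msg <- c(msg, "counts must be named 1..5, '>5', 'X'")
           if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
           if (object@totalRna < sum(object@counts))
             msg <- c(msg, "colocalized spots cannot exceed total RNA spots")
           if (length(msg)) msg else TRUE
         })

#' @describeIn StepHistogram constructor
#' @param counts named (or length-7 ordered) counts; @param condition label;
#' @param totalRna total RNA spots.
#' @export
StepHistogram <- function(counts, totalRna, condition = "condition") {
  cc <- setNames(integer(7L), .STEP_CLASSES)
  if (is.null(names(counts))) {
    stopifnot(length(counts) <= 7L)
    cc[seq_along(counts)] <- as.integer(counts)
  } else {
    stopifnot(all(names(counts) %in% .STEP_CLASSES))
    cc[names(counts)] <- as.integer(counts)
  }
  new("StepHistogram", condition = condition, counts = cc,
      totalRna = as.integer(totalRna))
}

#' OccupancyFit: fitted 1- vs 2-molecule occupancy mixture
#'
#' Result of the chi-squared mixture fit that explains an observed
#' step-count histogram as a mixture of sites occupied by one or two
#' protein molecules, given the labelled fraction and dimerization of
#' the extract.
#'
#' @slot pi2 fitted fraction of occupied sites carrying two molecules.
#' @slot scale fitted effective accessible total (occupancy x accessible
#'   RNA), i.e. the expected number of visible complexes.
#' @slot chisq chi-squared over classes with expected count >= 5.
#' @slot df degrees of freedom used for chisq.
#' @slot table data.frame with class, observed, expected.
#' @slot converged logical.
#' @exportClass OccupancyFit
setClass("OccupancyFit",
         representation(pi2 = "numeric", scale = "numeric", chisq = "numeric",
                        df = "integer", table = "data.frame",
                        converged = "logical"),
         validity = function(object) {
           if (object@pi2 < 0 || object@pi2 > 1)
             "pi2 must lie in [0, 1]" else TRUE
         })

#' PositionTable: per-position eCLIP read-pair counts on one reference
#'
#' Per-position coverage and fragment 3'-terminus counts of deduplicated
#' read pairs aligned to a short reference RNA (positions 1-based), for one
#' experiment, with its role (signal or size-matched control).
#'
#' @slot ref reference name.
#' @slot coverage,termini non-negative count vectors of length = reference
#'   length.
#' @slot experiment experiment identifier.
#' @slot role "signal" or "control".
#' @slot cellLine cell line label (optional).
#' @exportClass PositionTable
setClass("PositionTable",
         representation(ref = "character", coverage = "numeric",
                        termini = "numeric", experiment = "character",
                        role = "character", cellLine = "character"),
         prototype(cellLine = NA_character_),
         validity = function(object) {
           msg <- character()
           if (length(object@coverage) != length(object@termini))
             msg <- c(msg, "coverage and termini must have equal length")
           if (any(object@coverage < 0) || any(object@termini < 0))
             msg <- c(msg, "counts must be non-negative")
           if (!object@role %in% c("signal", "control"))
             msg <- c(msg, "role must be 'signal' or 'control'")
           if (length(msg)) msg else TRUE
         })

#' @describeIn PositionTable constructor
#' @param ref,coverage,termini,experiment,role,cellLine see slots.
#' @export
PositionTable <- function(ref, coverage, termini, experiment = "exp1",
                          role = c("signal", "control"),
                          cellLine = NA_character_) {
  new("PositionTable", ref = ref, coverage = as.numeric(coverage),
      termini = as.numeric(termini), experiment = experiment,
      role = match.arg(role), cellLine = cellLine)
}
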