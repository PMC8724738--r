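#' @include AllClasses.R utils.R
NULL

#' Configuration for the synthetic movie generator
#'
#' Bundles every knob of the movie simulator.  Defaults emulate a typical
#' sequential three-colour TIRF acquisition (50 frames at 633 nm followed by
#' 250 at 561 nm and 250 at 488 nm, 20 frames/s) with diffraction-limited
#' isotropic Gaussian emitters, per-fluorophore exponential bleaching,
#' Poisson shot noise and Gaussian read noise.
#'
#' @slot dim field size, \code{c(height, width)} pixels.
#' @slot plan channel plan (see \code{\link{channelPlan}}).
#' @slot frameRate frames per second.
#' @slot psfSigma isotropic PSF width (pixels).
#' @slot bleachLifetime mean per-fluorophore bleach lifetime (frames).
#' @slot amplitude peak emitter amplitude per fluorophore (counts/frame).
#' @slot baseline constant background level (counts/frame).
#' @slot shotNoise apply Poisson noise to signal + baseline.
#' @slot readNoiseSd Gaussian read noise SD (counts).
#' @slot transforms named list of \code{ChromaticTransform} (one per
#'   non-reference channel); the first channel of the plan is the reference.
#' @slot exclusionRadius warn when two supplied emitters are closer than
#'   this (px).
#' @slot minSeparation hard-core minimum separation (px) enforced when
#'   emitter positions are drawn rather than supplied, emulating surface
#'   immobilization at proper dilution (resolvable complexes).
#' @slot seed mandatory random seed (no implicit entropy).
#' @exportClass SimConfig
setClass("SimConfig",
         representation(dim = "integer", plan = "data.frame",
                        frameRate = "numeric", psfSigma = "numeric",
                        bleachLifetime = "numeric", amplitude = "numeric",
                        baseline = "numeric", shotNoise = "logical",
                        readNoiseSd = "numeric", transforms = "list",
                        exclusionRadius = "numeric",
                        minSeparation = "numeric", seed = "integer"),
         validity = function(object) {
           msg <- character()
           p <- .validPlan(object@plan)
           if (!isTRUE(p)) msg <- c(msg, p)
           if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
           if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
           if (length(object@seed) != 1L || is.na(object@seed))
             msg <- c(msg, "an explicit integer seed is mandatory")
           if (length(msg)) msg else TRUE
         })

#' @describeIn SimConfig constructor
#' @param seed integer seed (required).
#' @param dim,plan,frameRate,psfSigma,bleachLifetime,amplitude,baseline,
#'   shotNoise,readNoiseSd,transforms,exclusionRadius,minSeparation see
#'   slots.
#' @export
simConfig <- function(seed, dim = c(64L, 64L), plan = channelPlan(),
                      frameRate = 20, psfSigma = 1.3, bleachLifetime = 50,
                      amplitude = 300, baseline = 120, shotNoise = TRUE,
                      readNoiseSd = 10, transforms = list(),
                      exclusionRadius = 4, minSeparation = 8) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  new("SimConfig", dim = as.integer(dim), plan = plan, frameRate = frameRate,
      psfSigma = psfSigma, bleachLifetime = bleachLifetime,
      amplitude = amplitude, baseline = baseline, shotNoise = shotNoise,
      readNoiseSd = readNoiseSd, transforms = transforms,
      exclusionRadius = exclusionRadius, minSeparation = minSeparation,
      seed = as.integer(seed))
}

# Inverse of applyTransform: the raw channel coordinate that corrects to xt.
.invert1d <- function(xt, xc, sf) {
  if (sf == -1) stop("SF = -1 makes the transform non-invertible")
  (sf * xt + xc) / (sf + 1)
}

#' Simulate a sequential multi-colour TIRF movie with known ground truth
#'
#' Renders per-frame images as the sum of the surviving fluorophores'
#' Gaussian PSF contributions plus a constant baseline, then applies Poisson
#' shot noise and Gaussian read noise.  Each fluorophore bleaches after an
#' exponentially distributed lifetime (in frames of its own channel).
#' Emitters in non-reference channels are rendered at the position whose
#' chromatic correction maps back onto the reference-frame truth, so the
#' registration stage can be exercised end to end.
#'
#' @param config a \code{\link{simConfig}}.
#' @param complexes data.frame with one row per molecular complex: optional
#'   \code{x}, \code{y} (reference-channel coordinates; drawn uniformly when
#'   absent) and one integer column per channel naming how many fluorophores
#'   that complex carries in that channel (0 allowed).
#' @return list with \code{stack} (an \code{\link{ImageStack}}) and
#'   \code{truth}, a data.frame of ground-truth emitters (one row per
#'   complex/channel with >= 1 fluorophore): linkage id, channel, reference
#'   and channel-frame coordinates, fluorophore count and comma-separated
#'   per-fluorophore bleach frames (frames are 1-based within the channel;
#'   \code{Inf} encodes "never bleached").
#' @examples
#' cfg <- simConfig(seed = 1, dim = c(32L, 32L),
#'                  plan = channelPlan("gfp", 488, 20L))
#' sim <- simulateMovie(cfg, data.frame(x = 16, y = 16, gfp = 1))
#' dim(sim$stack@data)
#' @export
simulateMovie <- function(config, complexes) {
  stopifnot(is(config, "SimConfig"))
  plan <- config@plan
  h <- config@dim[1]; w <- config@dim[2]
  refChan <- plan$channel[1]
  chanCols <- intersect(plan$channel, names(complexes))
  nC <- nrow(complexes)

  withSeed(config@seed, {
    if (nC > 0 && !all(c("x", "y") %in% names(complexes))) {
      xs <- numeric(0); ys <- numeric(0)
      tries <- 0L
      while (length(xs) < nC) {
        cx <- stats::runif(1, 11, w - 10)
        cy <- stats::runif(1, 11, h - 10)
        if (!length(xs) ||
            min((xs - cx)^2 + (ys - cy)^2) >= config@minSeparation^2) {
          xs <- c(xs, cx); ys <- c(ys, cy)
        }
        tries <- tries + 1L
        if (tries > 10000L * nC)
          stop("cannot place ", nC, " emitters at minSeparation ",
               config@minSeparation, " in this field")
      }
      complexes$x <- xs
      complexes$y <- ys
    } else if (nC > 1) {
      dmat <- as.matrix(stats::dist(complexes[, c("x", "y")]))
      diag(dmat) <- Inf
      if (min(dmat) < config@exclusionRadius)
        warning("emitters closer than the exclusion radius (",
                config@exclusionRadius, " px)")
    }

    truth <- list()
    stack <- array(config@baseline, dim = c(h, w, sum(plan$frames)))
    s2 <- 2 * config@psfSigma^2
    ext <- ceiling(4 * config@psfSigma)

    for (ci in seq_len(nrow(plan))) {
      chan <- plan$channel[ci]
      nf <- plan$frames[ci]
      frames <- plan$first[ci]:plan$last[ci]
      tr <- config@transforms[[chan]]
      if (!(chan %in% chanCols)) next
      for (k in seq_len(nC)) {
        nFluor <- complexes[[chan]][k]
        if (is.na(nFluor) || nFluor < 1) next
        xr <- complexes$x[k]; yr <- complexes$y[k]
        if (!is.null(tr)) {
          xs <- .invert1d(xr, tr@xc, tr@sfx)
          ys <- .invert1d(yr, tr@yc, tr@sfy)
        } else { xs <- xr; ys <- yr }
        # lifetime in frames; a fluorophore is visible in frames 1..bleach-1
        life <- stats::rexp(nFluor, rate = 1 / config@bleachLifetime)
        bleach <- ifelse(life >= nf, Inf, ceiling(life) + 1)
        rows <- max(1, round(ys) - ext):min(h, round(ys) + ext)
        cols <- max(1, round(xs) - ext):min(w, round(xs) + ext)
        patch <- config@amplitude *
          outer(exp(-(rows - ys)^2 / s2), exp(-(cols - xs)^2 / s2))
        for (f in seq_len(nf)) {
          alive <- sum(bleach > f)
          if (alive > 0)
            stack[rows, cols, frames[f]] <-
              stack[rows, cols, frames[f]] + alive * patch
        }
        truth[[length(truth) + 1L]] <- data.frame(
          linkage = k, channel = chan, x = xr, y = yr,
          xChan = xs, yChan = ys, n = nFluor,
          bleachFrames = paste(bleach, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }

    if (config@shotNoise)
      stack <- array(stats::rpois(length(stack), stack), dim = dim(stack))
    if (config@readNoiseSd > 0)
      stack <- stack + stats::rnorm(length(stack), 0, config@readNoiseSd)
    stack <- pmax(stack, 0)

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(linkage = integer(), channel = character(), x = numeric(),
                 y = numeric(), xChan = numeric(), yChan = numeric(),
                 n = integer(), bleachFrames = character(),
                 stringsAsFactors = FALSE)
    list(stack = ImageStack(stack, plan, config@frameRate), truth = truth)
  })
}

#' Sample a step-count histogram from the label/dimerization model
#'
#' Direct sampler for the generative model underlying the expected step
#' distributions: each RNA spot recruits a number of protein units drawn
#' from \code{occupancyMix}; each unit is independently an intrinsic dimer
#' (two protein copies) with probability d, else a monomer; each copy
#' carries a fluorescent label independently with probability f.  The
#' observed class of a spot is its total number of labelled copies; spots
#' with zero labelled copies are invisible and recorded as not colocalized.
#'
#' @param nSpots number of RNA spots.
#' @param occupancyMix named probability vector over the number of recruited
#'   units per spot (names "1", "2", ...); must sum to 1.
#' @param label a \code{\link{LabelModel}}.
#' @param seed integer seed.
#' @param condition condition label for the histogram.
#' @return list with \code{hist} (a \code{\link{StepHistogram}}) and
#'   \code{truth}, a per-spot data.frame (units, dimers, labelled copies,
#'   observed class) plus the exact mixture used.
#' @examples
#' simulateStepHistogram(100, c("1" = 1), LabelModel(1, 0), seed = 1)$hist
#' @export
simulateStepHistogram <- function(nSpots, occupancyMix, label, seed,
                                  condition = "simulated") {
  stopifnot(is(label, "LabelModel"))
  if (abs(sum(occupancyMix) - 1) > 1e-9)
    stop("occupancy probabilities must sum to 1")
  if (label@f <= 0) stop("f = 0: no labelled molecules are observable")
  nUnitsChoices <- as.integer(names(occupancyMix))
  withSeed(seed, {
    units <- nUnitsChoices[sample.int(length(nUnitsChoices), nSpots,
                                      replace = TRUE, prob = occupancyMix)]
    dimers <- stats::rbinom(nSpots, units, label@d)
    copies <- units + dimers
    labelled <- stats::rbinom(nSpots, copies, label@f)
    cls <- ifelse(labelled == 0, "0",
                  ifelse(labelled > 5, ">5", as.character(labelled)))
    counts <- setNames(integer(7), .STEP_CLASSES)
    tab <- table(cls[cls != "0"])
    counts[names(tab)] <- as.integer(tab)
    list(hist = StepHistogram(counts, totalRna = nSpots,
                              condition = condition),
         truth = list(perSpot = data.frame(units = units, dimers = dimers,
                                           copies = copies,
                                           labelled = labelled,
                                           class = cls,
                                           stringsAsFactors = FALSE),
                      occupancyMix = occupancyMix))
  })
}

#' Simulate background-corrected bleaching traces
#'
#' Generates idealized intensity traces directly (bypassing the imaging
#' stage): \code{nFluor} fluorophores each contribute a constant step
#' amplitude until an exponentially distributed bleach time (truncated so
#' that every fluorophore bleaches before the trace ends, emulating
#' acquisitions run until complete bleaching), plus Gaussian noise.  The
#' signal-to-noise ratio is stepAmplitude/noiseSd.
#'
#' @param n number of traces.
#' @param nFluor fluorophores per trace.
#' @param nFrames trace length (frames).
#' @param stepAmplitude per-fluorophore intensity (arbitrary units).
#' @param noiseSd Gaussian noise SD.
#' @param bleachLifetime mean bleach lifetime (frames).
#' @param minFrame earliest allowed bleach time (frames).
#' @param seed integer seed.
#' @return list with \code{traces} (matrix n x nFrames) and \code{bleach}
#'   (matrix n x nFluor of 1-based bleach frames: the first frame at
#'   background for that fluorophore).
#' @export
simulateTraces <- function(n, nFluor, nFrames = 250, stepAmplitude = 1,
                           noiseSd = 0.2, bleachLifetime = 50,
                           minFrame = 5, seed = 1) {
  withSeed(seed, {
    traces <- matrix(0, n, nFrames)
    bleach <- matrix(0L, n, nFluor)
    lo <- exp(-minFrame / bleachLifetime)
    hi <- exp(-(nFrames - 5) / bleachLifetime)
    for (i in seq_len(n)) {
      # doubly truncated exponential lifetimes (inverse CDF)
      u <- stats::runif(nFluor)
      life <- -bleachLifetime * log(lo - u * (lo - hi))
      b <- pmax(2L, ceiling(life) + 1L)
      bleach[i, ] <- b
      sig <- rowSums(outer(seq_len(nFrames), b, `<`)) * stepAmplitude
      traces[i, ] <- sig + stats::rnorm(nFrames, 0, noiseSd)
    }
    list(traces = traces, bleach = bleach)
  })
}

#' Simulate per-position eCLIP count tables with an optional spike
#'
#' Control counts are Poisson draws around a common smooth coverage profile;
#' at spiked positions the signal multiplies both the coverage and the
#' per-pair 3'-terminus rate by \code{spikeFold} (so terminus counts scale
#' by the fold squared, as expected of a cross-link site: more fragments
#' map there and a larger share of them end there).  Deterministic given
#' the seed.
#'
#' @param refLength reference length (nt).
#' @param nExperiments number of signal/control experiment pairs.
#' @param spikePositions integer positions (1-based) carrying the spike.
#' @param spikeFold fold change at spiked positions (values < 1 deplete).
#' @param depth expected read pairs per experiment (> 0).
#' @param seed integer seed.
#' @param ref reference name.
#' @return list of experiments; each element holds \code{signal} and
#'   \code{control} \code{\link{PositionTable}}s.
#' @export
simulateEclipCounts <- function(refLength, nExperiments, spikePositions,
                                spikeFold, depth = 1e4, seed = 1,
                                ref = "U1") {
  if (depth <= 0) stop("depth must be > 0")
  if (length(spikePositions) &&
      (min(spikePositions) < 1 || max(spikePositions) > refLength))
    stop("spike positions must lie within [1, refLength]")
  pos <- seq_len(refLength)
  # smooth unimodal coverage profile with a long-tailed baseline
  shape <- 0.25 + stats::dbeta(pos / (refLength + 1), 2.2, 1.8)
  wCov <- shape / sum(shape)
  # 3' termini concentrate mildly toward the downstream half
  tShape <- shape * (0.5 + pos / refLength)
  wTer <- 0.15 * tShape / sum(tShape)
  fold <- rep(1, refLength)
  fold[spikePositions] <- spikeFold
  withSeed(seed, {
    lapply(seq_len(nExperiments), function(e) {
      ctlCov <- stats::rpois(refLength, depth * wCov)
      ctlTer <- stats::rpois(refLength, depth * wTer)
      sigCov <- stats::rpois(refLength, depth * wCov * fold)
      sigTer <- stats::rpois(refLength, depth * wTer * fold^2)
      list(signal = PositionTable(ref, sigCov, sigTer,
                                  experiment = paste0("exp", e),
                                  role = "signal"),
           control = PositionTable(ref, ctlCov, ctlTer,
                                   experiment = paste0("exp", e),
                                   role = "control"))
    })
  })
}

#' Simulate dual-labelled calibration bead pairs
#'
#' Generates matched reference-/source-channel localizations of dual-labelled
#' emitters: true positions are uniform over the field, the source-channel
#' observation is displaced by the inverse of the chromatic transform, and
#' both observations carry Gaussian localization noise.
#'
#' @param n number of bead pairs.
#' @param transform the true \code{\link{ChromaticTransform}}.
#' @param noiseSd localization noise SD (pixels).
#' @param fieldDim \code{c(height, width)} pixels.
#' @param seed integer seed.
#' @return data.frame with refX, refY, srcX, srcY and the true positions.
#' @export
simulateBeadPairs <- function(n, transform, noiseSd = 0.1,
                              fieldDim = c(512, 512), seed = 1) {
  withSeed(seed, {
    tx <- stats::runif(n, 1, fieldDim[2])
    ty <- stats::runif(n, 1, fieldDim[1])
    data.frame(
      refX = tx + stats::rnorm(n, 0, noiseSd),
      refY = ty + stats::rnorm(n, 0, noiseSd),
      srcX = .invert1d(tx, transform@xc, transform@sfx) +
        stats::rnorm(n, 0, noiseSd),
      srcY = .invert1d(ty, transform@yc, transform@sfy) +
        stats::rnorm(n, 0, noiseSd),
      trueX = tx, trueY = ty)
  })
}
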