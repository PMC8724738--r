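#' @include AllClasses.R
NULL

#' Normalize per-position counts to percentages of aligned pairs
#'
#' Sequencing depth varies widely between eCLIP experiments; counts are made
#' comparable by expressing, at each position, the percentage of all read
#' pairs aligned to the reference that cover (or terminate at) that
#' position: \code{pct[i] = 100 * count[i] / totalAlignedPairs}.  Applied
#' separately to coverage and 3'-terminus counts, with the total aligned
#' pairs taken from the coverage-weighted pair count of the table.
#'
#' @param table a \code{\link{PositionTable}}.
#' @return list with \code{coverage} and \code{termini} percentage vectors.
#' @export
normalizePositions <- function(table) {
  stopifnot(is(table, "PositionTable"))
  tot <- sum(table@coverage)
  if (tot == 0) stop("all-zero count table cannot be normalized")
  totT <- sum(table@termini)
  list(coverage = 100 * table@coverage / tot,
       termini = if (totT > 0) 100 * table@termini / totT
       else rep(0, length(table@termini)))
}

#' Per-position enrichment of signal over size-matched control
#'
#' Divides the signal percentage at each position by the control percentage,
#' with a pseudocount equivalent to one read pair (on the percentage scale
#' of each library) so the ratio is always finite:
#' \code{enr[i] = (sig[i] + epsSig) / (ctl[i] + epsCtl)}.
#'
#' @param signal,control \code{\link{PositionTable}}s on the same reference.
#' @param pseudocount pseudocount in read pairs (default 1).
#' @return numeric enrichment vector (> 0).
#' @export
enrichment <- function(signal, control, pseudocount = 1) {
  stopifnot(is(signal, "PositionTable"), is(control, "PositionTable"))
  if (signal@ref != control@ref ||
      length(signal@coverage) != length(control@coverage))
    stop("signal and control must share reference and length")
  sp <- normalizePositions(signal)$coverage
  cp <- normalizePositions(control)$coverage
  epsS <- 100 * pseudocount / max(sum(signal@coverage), 1)
  epsC <- 100 * pseudocount / max(sum(control@coverage), 1)
  (sp + epsS) / (cp + epsC)
}

#' The 3'-terminus positional statistic
#'
#' Cross-link sites are marked by read-pair 3' termini; a genuine binding
#' position shows an excess of termini beyond what its (possibly already
#' enriched) coverage explains.  The statistic is
#' \deqn{v_i = \log(\mathrm{termini\ pct}_i + \epsilon) - \log(\mathrm{enr}_i)}
#' (natural logarithms), so doubling the enrichment at a position lowers v
#' by log 2 exactly.
#'
#' @param enr enrichment vector (see \code{\link{enrichment}}).
#' @param signal the signal \code{\link{PositionTable}} providing the
#'   terminus percentages.
#' @param pseudocount pseudocount in read pairs for the terminus
#'   percentages.
#' @return numeric vector v, one value per position.
#' @export
terminusStatistic <- function(enr, signal, pseudocount = 1) {
  stopifnot(is(signal, "PositionTable"),
            length(enr) == length(signal@termini))
  tp <- normalizePositions(signal)$termini
  eps <- 100 * pseudocount / max(sum(signal@termini), 1)
  log(tp + eps) - log(enr)
}

#' Position-wise/experiment-wise combined normal probabilities
#'
#' The terminus statistics are approximately normal both across experiments
#' at a fixed position and across positions within an experiment.  For each
#' cell the two normal cumulative probabilities are combined:
#' \deqn{p_{e,i} = \sqrt{\Phi_{pos}(v_{e,i}) \cdot \Phi_{exp}(v_{e,i})}}
#' where \eqn{\Phi_{pos}} uses the mean/SD over experiments at position i
#' and \eqn{\Phi_{exp}} the mean/SD over positions for experiment e.  A
#' zero SD in either direction makes that factor 0.5, with a warning.
#'
#' @param v matrix, experiments x positions.
#' @return matrix of probabilities in [0, 1], same shape as v.
#' @export
combinedProbability <- function(v) {
  stopifnot(is.matrix(v), nrow(v) >= 2, ncol(v) >= 2)
  posMean <- colMeans(v)
  posSd <- apply(v, 2, stats::sd)
  expMean <- rowMeans(v)
  expSd <- apply(v, 1, stats::sd)
  if (any(posSd == 0) || any(expSd == 0))
    warning("zero SD in a position-wise or experiment-wise distribution; ",
            "the corresponding factor is set to 0.5")
  phiPos <- matrix(0.5, nrow(v), ncol(v))
  okP <- posSd > 0
  if (any(okP))
    phiPos[, okP] <- stats::pnorm(sweep(sweep(v[, okP, drop = FALSE], 2,
                                              posMean[okP]), 2, posSd[okP],
                                        `/`))
  phiExp <- matrix(0.5, nrow(v), ncol(v))
  okE <- expSd > 0
  if (any(okE))
    phiExp[okE, ] <- stats::pnorm((v[okE, , drop = FALSE] - expMean[okE]) /
                                    expSd[okE])
  sqrt(phiPos * phiExp)
}

#' Collapse per-experiment probabilities into one per-protein score
#'
#' Cross-cell-type collapse: the per-position probabilities of all
#' experiments for one protein are multiplied and the product raised to the
#' power 1/n (0.5 for 2 experiments, 0.25 for 4) -- the geometric mean, so
#' the score is monotone in each experiment's probability and idempotent
#' when all experiments agree.
#'
#' @param p matrix of probabilities, experiments x positions (rows may come
#'   from different cell types).
#' @return numeric per-position score.
#' @export
collapseProtein <- function(p) {
  stopifnot(is.matrix(p))
  n <- nrow(p)
  apply(p, 2, function(col) prod(col))^(1 / n)
}

#' Run the positional enrichment statistic for one protein
#'
#' Convenience wrapper from signal/control tables to the collapsed
#' per-position score: normalization, enrichment, terminus statistic,
#' combined probabilities, geometric-mean collapse.
#'
#' @param experiments list of experiments, each a list with \code{signal}
#'   and \code{control} \code{\link{PositionTable}}s (>= 2 experiments).
#' @param pseudocount pseudocount in read pairs.
#' @return list with \code{v} (experiments x positions), \code{p} (combined
#'   probabilities) and \code{score} (collapsed per-position score).
#' @examples
#' sim <- simulateEclipCounts(60, 2, spikePositions = 30, spikeFold = 10,
#'                            depth = 5000, seed = 1)
#' res <- eclipScore(sim)
#' which.max(res$score)  # 30
#' @export
eclipScore <- function(experiments, pseudocount = 1) {
  stopifnot(length(experiments) >= 2)
  v <- t(vapply(experiments, function(e) {
    enr <- enrichment(e$signal, e$control, pseudocount)
    terminusStatistic(enr, e$signal, pseudocount)
  }, numeric(length(experiments[[1]]$signal@coverage))))
  p <- combinedProbability(v)
  list(v = v, p = p, score = collapseProtein(p))
}

#' Build a PositionTable from read-pair intervals
#'
#' Converts aligned read-pair spans (e.g. from a BED file of whole-pair
#' intervals) into per-position coverage and fragment 3'-terminus counts on
#' a short reference.  BED intervals are 0-based half-open; they are
#' converted to 1-based inclusive positions here.  The fragment 3' end is
#' taken on the reference strand (the interval end).
#'
#' @param start,end integer vectors: 0-based half-open spans, one per read
#'   pair.
#' @param refLength reference length (nt).
#' @param ref reference name.
#' @param experiment,role,cellLine metadata for the table.
#' @return a \code{\link{PositionTable}}.
#' @export
positionTableFromPairs <- function(start, end, refLength, ref = "U1",
                                   experiment = "exp1",
                                   role = c("signal", "control"),
                                   cellLine = NA_character_) {
  stopifnot(length(start) == length(end), all(end > start))
  s1 <- pmax(start + 1L, 1L)          # 1-based inclusive start
  e1 <- pmin(end, refLength)          # 1-based inclusive end
  keep <- s1 <= e1
  ir <- IRanges::IRanges(start = s1[keep], end = e1[keep])
  cov <- as.numeric(IRanges::coverage(ir, width = refLength))
  ter <- tabulate(e1[keep], nbins = refLength)
  PositionTable(ref, cov, ter, experiment = experiment,
                role = match.arg(role), cellLine = cellLine)
}

#' Read a BED6 file of read-pair spans into a PositionTable
#'
#' @param path BED file (chrom, start, end, name, score, strand; the first
#'   three columns suffice).
#' @param refLength reference length (nt).
#' @inheritParams positionTableFromPairs
#' @return a \code{\link{PositionTable}} for intervals on \code{ref}.
#' @export
readPairBed <- function(path, refLength, ref = "U1", experiment = "exp1",
                        role = c("signal", "control"),
                        cellLine = NA_character_) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed <- bed[bed$chrom == ref, , drop = FALSE]
  if (nrow(bed) == 0) stop("no intervals on reference ", ref)
  positionTableFromPairs(bed$start, bed$end, refLength, ref = ref,
                         experiment = experiment, role = role,
                         cellLine = cellLine)
}

#' Heat-map export of collapsed per-protein scores
#'
#' Assembles collapsed scores into a proteins x positions matrix and draws
#' it with \code{image()} (proteins as rows).
#'
#' @param scores named list of per-position score vectors (one per protein,
#'   equal lengths).
#' @param file optional PNG path; when given the plot is written there.
#' @return the score matrix, invisibly.
#' @export
scoreHeatmap <- function(scores, file = NULL) {
  lens <- vapply(scores, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("mismatched reference lengths across proteins")
  m <- do.call(rbind, scores)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 80 + 40 * nrow(m))
    on.exit(grDevices::dev.off())
  }
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position (nt)", ylab = "", axes = FALSE,
                  zlim = c(0, 1))
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2)
  graphics::box()
  invisible(m)
}
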