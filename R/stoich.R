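#' @include AllClasses.R
NULL

#' Binomial error bars for a step-count histogram
#'
#' For a class observed k times among n RNA spots the plotted frequency is
#' 100 k/n and its error bar is the square root of the variance of the
#' binomial probability: \eqn{100 \sqrt{\hat p (1-\hat p)/n}} with
#' \eqn{\hat p = k/n}.
#'
#' @param hist a \code{\link{StepHistogram}}.
#' @return data.frame with class, count, percent and sd (percent units).
#' @examples
#' h <- StepHistogram(c("1" = 129, "2" = 32), totalRna = 500)
#' binomialErrorBars(h)
#' @export
binomialErrorBars <- function(hist) {
  stopifnot(is(hist, "StepHistogram"))
  n <- hist@totalRna
  if (n <= 0) stop("total RNA spots must be > 0")
  k <- hist@counts
  p <- k / n
  data.frame(class = names(k), count = as.integer(k), percent = 100 * p,
             sd = 100 * sqrt(p * (1 - p) / n),
             stringsAsFactors = FALSE)
}

#' Distribution of observed bleaching steps for one recruited unit
#'
#' Under the label-fraction/dimerization model a recruited unit is an
#' intrinsic dimer (two protein copies) with probability d, else a monomer,
#' and each copy carries a label independently with probability f.  The
#' observed step count of one unit is its number of labelled copies:
#' \deqn{P(0) = (1-d)(1-f) + d(1-f)^2}
#' \deqn{P(1) = (1-d)f + 2df(1-f)}
#' \deqn{P(2) = df^2}
#'
#' @param label a \code{\link{LabelModel}}.
#' @return named numeric vector over steps "0", "1", "2" (sums to 1).
#' @examples
#' unitStepDistribution(LabelModel(1, 0.2))   # (0, 0.8, 0.2)
#' @export
unitStepDistribution <- function(label) {
  stopifnot(is(label, "LabelModel"))
  f <- label@f; d <- label@d
  c("0" = (1 - d) * (1 - f) + d * (1 - f)^2,
    "1" = (1 - d) * f + 2 * d * f * (1 - f),
    "2" = d * f^2)
}

# Unconditional distribution of total labelled copies for n recruited units
# (support 0..2n); polynomial convolution of the unit distribution.
.stepDistUncond <- function(nUnits, label) {
  u <- unitStepDistribution(label)
  p <- 1
  for (i in seq_len(nUnits)) {
    q <- numeric(length(p) + 2)
    for (k in 0:2) q[seq_along(p) + k] <- q[seq_along(p) + k] + p * u[k + 1]
    p <- q
  }
  setNames(p, as.character(seq_along(p) - 1L))
}

#' Expected step-class distribution for 1 or 2 recruited units
#'
#' Convolves \code{nUnits} independent unit distributions and renormalizes
#' over totals >= 1, because spots with zero labelled copies are invisible
#' (recorded as not colocalized).
#'
#' @param nUnits number of recruited protein units (1 or 2; larger values
#'   are supported).
#' @param label a \code{\link{LabelModel}}.
#' @return named probability vector over classes "1".."2*nUnits".
#' @examples
#' expectedStepDistribution(2, LabelModel(1, 0))  # all mass on class 2
#' @export
expectedStepDistribution <- function(nUnits, label) {
  p <- .stepDistUncond(nUnits, label)
  vis <- p[-1]
  vis / sum(vis)
}

#' Estimate the intrinsic dimer fraction from free-protein bleaching counts
#'
#' Protein molecules recorded in the absence of exogenous RNA bleach in one
#' or two steps; under the label model their expected ratio is
#' \deqn{R = n_2/n_1 = d f / ((1-d) + 2 d (1-f))}
#' which inverts to \eqn{\hat d = R / (f + R(2f - 1))}.  The confidence
#' interval is obtained by profiling the binomial likelihood of observing
#' \eqn{n_2} two-step molecules among \eqn{n_1 + n_2}.
#'
#' @param n1,n2 counts of molecules bleaching in one and two steps.
#' @param f labelled fraction.
#' @param level confidence level.
#' @return list with \code{d} and \code{ci} (length-2 vector).
#' @examples
#' estimateDimerFraction(129, 32, f = 0.9)$d  # about 0.226
#' @export
estimateDimerFraction <- function(n1, n2, f, level = 0.95) {
  stopifnot(n1 > 0, n2 >= 0, f > 0, f <= 1)
  R <- n2 / n1
  d <- R / (f + R * (2 * f - 1))
  if (d >= 1) stop("observed ratio implies d >= 1 (model violation)")
  # P(two-step | visible free molecule with 1 or 2 steps)
  pr2 <- function(dd) dd * f / ((1 - dd) + 2 * dd * (1 - f) + dd * f)
  ll <- function(dd) {
    p <- pr2(dd)
    stats::dbinom(n2, n1 + n2, p, log = TRUE)
  }
  if (n2 == 0) d <- 0
  llhat <- ll(d)
  crit <- stats::qchisq(level, 1) / 2
  g <- function(dd) llhat - ll(dd) - crit
  lower <- if (d <= 1e-12 || g(1e-12) < 0) 0 else
    stats::uniroot(g, c(1e-12, d))$root
  upper <- if (g(1 - 1e-9) < 0) 1 else
    stats::uniroot(g, c(max(d, 1e-12), 1 - 1e-9))$root
  list(d = d, ci = c(lower, upper))
}

#' Fit the 1- vs 2-molecule occupancy mixture to a step histogram
#'
#' Models the expected count in class k as
#' \deqn{E_k = S [(1-\pi_2) q_1(k) + \pi_2 q_2(k)]}
#' where \eqn{q_n(k)} is the unconditional probability that a site occupied
#' by n units shows k labelled copies (so S is the effective accessible
#' total: occupancy probability x accessible pre-mRNA molecules, including
#' the invisible zero-label sites), and minimizes chi-squared over the
#' observed classes 1..4 with both \eqn{\pi_2} and S free (bounded
#' multistart optimization from \eqn{\pi_2 \in \{0, 0.5, 1\}}).  Classes
#' ">5" and "X" are excluded, being attributed to the non-complex-A
#' background population.  The reported chi-squared follows the convention
#' of including only classes with expected values >= 5.
#'
#' @param hist a \code{\link{StepHistogram}} with >= 20 colocalized spots.
#' @param label a \code{\link{LabelModel}}.
#' @param classes step classes used in the fit.
#' @return an \code{\link{OccupancyFit}}.
#' @export
fitOccupancyMixture <- function(hist, label,
                                classes = c("1", "2", "3", "4")) {
  stopifnot(is(hist, "StepHistogram"), is(label, "LabelModel"))
  if (sum(hist@counts) < 20)
    stop("at least 20 colocalized spots are required")
  obs <- as.numeric(hist@counts[classes])
  if (sum(obs > 0) < 2) stop("under-determined: fewer than 2 usable classes")
  ks <- as.integer(classes)
  q1 <- .stepDistUncond(1L, label)[as.character(ks)]
  q2 <- .stepDistUncond(2L, label)[as.character(ks)]
  q1[is.na(q1)] <- 0; q2[is.na(q2)] <- 0
  chisqFun <- function(par) {
    pi2 <- par[1]; S <- par[2]
    E <- S * ((1 - pi2) * q1 + pi2 * q2)
    E <- pmax(E, 1e-9)
    sum((obs - E)^2 / E)
  }
  best <- NULL
  for (pi0 in c(0, 0.5, 1)) {
    fit <- stats::optim(c(pi0, max(sum(obs), 1)), chisqFun,
                        method = "L-BFGS-B",
                        lower = c(0, 1e-6), upper = c(1, Inf))
    if (is.null(best) || fit$value < best$value - 1e-10 ||
        (abs(fit$value - best$value) <= 1e-10 &&
           fit$par[1] < best$par[1]))
      best <- fit
  }
  pi2 <- best$par[1]; S <- best$par[2]
  E <- S * ((1 - pi2) * q1 + pi2 * q2)
  use <- E >= 5
  chisq <- sum((obs[use] - E[use])^2 / pmax(E[use], 1e-9))
  df <- max(0L, as.integer(sum(use)) - 2L)
  new("OccupancyFit", pi2 = pi2, scale = S, chisq = chisq, df = df,
      table = data.frame(class = classes, observed = obs, expected = E,
                         used = use, stringsAsFactors = FALSE),
      converged = best$convergence == 0)
}

#' Fit a zero-truncated Poisson or geometric background model
#'
#' The super-stoichiometric background population (molecules unable to form
#' complex A) is modelled by a zero-truncated Poisson or geometric
#' distribution over the number of bleaching steps, fitted by chi-squared
#' minimization over classes k = 1..5 and the aggregated tail (">5", i.e.
#' k >= 6).  Significance is computed over categories with expected counts
#' >= 4, with N - 2 (Poisson) or N - 3 (geometric) degrees of freedom.
#'
#' @param hist a \code{\link{StepHistogram}} (class "X" excluded).
#' @param family "poisson" (zero-truncated) or "geometric".
#' @param includeTail include the ">5" class as the aggregated k >= 6 tail.
#' @param dfOffset override the printed degrees-of-freedom convention
#'   (defaults: 2 for Poisson, 3 for geometric).
#' @return list with the fitted parameter (\code{lambda} or \code{p}),
#'   \code{chisq}, \code{df}, \code{pValue} and the observed/expected table.
#' @export
fitBackground <- function(hist, family = c("poisson", "geometric"),
                          includeTail = TRUE, dfOffset = NULL) {
  stopifnot(is(hist, "StepHistogram"))
  family <- match.arg(family)
  classes <- c("1", "2", "3", "4", "5")
  obs <- as.numeric(hist@counts[classes])
  labels <- classes
  if (includeTail) {
    obs <- c(obs, as.numeric(hist@counts[">5"]))
    labels <- c(labels, ">5")
  }
  if (sum(obs > 0) < 3)
    stop("need at least 3 non-empty classes to fit a background model")
  n <- sum(obs)
  probFun <- function(par) {
    if (family == "poisson") {
      pk <- stats::dpois(1:5, par) / (1 - exp(-par))
    } else {
      pk <- par * (1 - par)^(0:4)
    }
    if (includeTail) c(pk, max(1 - sum(pk), 0)) else pk / sum(pk)
  }
  chisqFun <- function(par) {
    E <- n * probFun(par)
    sum((obs - E)^2 / pmax(E, 1e-9))
  }
  opt <- if (family == "poisson")
    stats::optimize(chisqFun, c(1e-4, 30)) else
      stats::optimize(chisqFun, c(1e-6, 1 - 1e-6))
  par <- opt$minimum
  E <- n * probFun(par)
  use <- E >= 4
  stat <- sum((obs[use] - E[use])^2 / pmax(E[use], 1e-9))
  off <- if (is.null(dfOffset)) ifelse(family == "poisson", 2L, 3L) else
    as.integer(dfOffset)
  df <- max(1L, as.integer(sum(use)) - off)
  out <- list(family = family, chisq = stat, df = df,
              pValue = stats::pchisq(stat, df, lower.tail = FALSE),
              table = data.frame(class = labels, observed = obs,
                                 expected = E, used = use,
                                 stringsAsFactors = FALSE))
  if (family == "poisson") out$lambda <- par else out$p <- par
  out
}

#' Check robustness of a protein histogram to multi-RNA spots
#'
#' A fraction of RNA spots bleach in two or more steps (two pre-mRNA
#' molecules in one diffraction-limited spot).  This check recomputes the
#' protein step histogram after excluding complexes whose RNA spot bleached
#' in >= 2 steps and compares the retained and excluded complexes'
#' class distributions by a chi-squared contingency test.
#'
#' @param proteinClasses character vector of protein step classes per
#'   complex ("1".."5", ">5", "X").
#' @param rnaSteps integer vector of RNA bleaching steps per complex.
#' @return list with the full, retained and excluded class counts, the
#'   fraction of multi-RNA complexes, \code{chisq}, \code{pValue}, and
#'   \code{allExcluded} flag (TRUE when every complex had a multi-RNA
#'   spot).
#' @export
rnaDimerExclusion <- function(proteinClasses, rnaSteps) {
  stopifnot(length(proteinClasses) == length(rnaSteps))
  fac <- factor(proteinClasses, levels = .STEP_CLASSES)
  multi <- rnaSteps >= 2
  full <- table(fac)
  kept <- table(fac[!multi])
  excl <- table(fac[multi])
  if (!any(multi)) {
    return(list(full = full, kept = kept, excluded = excl,
                multiFraction = 0, chisq = 0, pValue = 1,
                allExcluded = FALSE))
  }
  if (all(multi)) {
    return(list(full = full, kept = kept, excluded = excl,
                multiFraction = 1, chisq = NA_real_, pValue = NA_real_,
                allExcluded = TRUE))
  }
  m <- rbind(kept = as.integer(kept), excluded = as.integer(excl))
  m <- m[, colSums(m) > 0, drop = FALSE]
  tst <- suppressWarnings(stats::chisq.test(m))
  list(full = full, kept = kept, excluded = excl,
       multiFraction = mean(multi),
       chisq = unname(tst$statistic), pValue = tst$p.value,
       allExcluded = FALSE)
}

#' Bar chart of a step histogram with binomial error bars
#'
#' @param hist a \code{\link{StepHistogram}}.
#' @param col bar colour.
#' @param ... passed to \code{barplot}.
#' @return the error-bar table, invisibly.
#' @export
plotStepHistogram <- function(hist, col = "darkgreen", ...) {
  eb <- binomialErrorBars(hist)
  mids <- graphics::barplot(eb$percent, names.arg = eb$class, col = col,
                            ylim = c(0, max(eb$percent + eb$sd) * 1.15 + 1),
                            xlab = "bleaching steps",
                            ylab = "% of RNA spots",
                            main = hist@condition, ...)
  graphics::arrows(mids, eb$percent - eb$sd, mids, eb$percent + eb$sd,
                   angle = 90, code = 3, length = 0.04)
  graphics::mtext(sprintf("RNA spots: %d   Coloc: %d (%.1f%%)",
                          hist@totalRna, sum(hist@counts), colocPct(hist)),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(eb)
}
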