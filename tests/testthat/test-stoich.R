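test_that("binomial error bars follow the closed form", {
  h <- StepHistogram(c("1" = 129, "2" = 32), totalRna = 500)
  eb <- binomialErrorBars(h)
  expect_equal(eb$sd[eb$class == "1"],
               100 * sqrt(0.258 * 0.742 / 500), tolerance = 1e-12)
  # empty classes have zero-width bars
  expect_equal(eb$sd[eb$class == "4"], 0)
  full <- StepHistogram(c("1" = 10), totalRna = 10)
  expect_equal(binomialErrorBars(full)$sd[1], 0)  # k = n edge
})

test_that("the unit step distribution matches its formulas and sums to 1", {
  expect_equal(unname(unitStepDistribution(LabelModel(1, 0))), c(0, 1, 0))
  expect_equal(unname(unitStepDistribution(LabelModel(1, 0.2))),
               c(0, 0.8, 0.2))
  for (f in c(0.3, 0.59, 0.9)) for (d in c(0, 0.226, 0.5)) {
    u <- unitStepDistribution(LabelModel(f, d))
    expect_equal(sum(u), 1, tolerance = 1e-12)
    expect_equal(unname(u),
                 enumStepDist(1, f, d, conditionVisible = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("expected distributions equal exhaustive enumeration", {
  expect_equal(unname(expectedStepDistribution(1, LabelModel(1, 0))),
               c(1, 0))
  expect_equal(unname(expectedStepDistribution(2, LabelModel(1, 0))),
               c(0, 1, 0, 0))
  grid <- seq(0.1, 0.9, by = 0.1)
  for (n in 1:3) for (f in grid) for (d in grid) {
    got <- expectedStepDistribution(n, LabelModel(f, d))
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(unname(got), enumStepDist(n, f, d), tolerance = 1e-12)
  }
})

test_that("the dimer-fraction estimator inverts the model ratio", {
  # zero two-step molecules mean zero estimated dimerization
  z <- estimateDimerFraction(100, 0, 0.8)
  expect_equal(z$d, 0)
  # printed free-protein counts with 90% tagging: independent numerical
  # oracle inverts R(d) by root finding instead of algebra
  f <- 0.9
  R <- 32 / 129
  oracle <- stats::uniroot(function(d)
    d * f / ((1 - d) + 2 * d * (1 - f)) - R, c(1e-9, 1 - 1e-9),
    tol = 1e-12)$root
  est <- estimateDimerFraction(129, 32, f)
  expect_equal(est$d, oracle, tolerance = 1e-9)
  expect_true(est$ci[1] < est$d && est$d < est$ci[2])
  # a ratio implying d >= 1 is a model violation
  expect_error(estimateDimerFraction(10, 200, 0.9), "model violation")
})

test_that("dimer estimation round-trips through the sampler unbiased", {
  f <- 0.9; dTrue <- 0.226
  lm <- LabelModel(f, dTrue)
  out <- simulateStepHistogram(1e4, c("1" = 1), lm, seed = 61)
  n1 <- out$hist@counts[["1"]]; n2 <- out$hist@counts[["2"]]
  est <- estimateDimerFraction(n1, n2, f)
  expect_lt(abs(est$d - dTrue), 0.02)  # single replicate, 3 SE margin
})

test_that("occupancy mixture fit is a fixed point on exact expectations", {
  lm <- LabelModel(0.9, 0.2)
  q1 <- expectedStepDistribution(1, lm)
  q2 <- expectedStepDistribution(2, lm)
  pi2 <- 0.4; S <- 400
  pVis1 <- 1 - enumStepDist(1, 0.9, 0.2, FALSE)[1]
  pVis2 <- 1 - enumStepDist(2, 0.9, 0.2, FALSE)[1]
  ek <- S * ((1 - pi2) * pVis1 * q1[c("1", "2")]
             + pi2 * pVis2 * q2[c("1", "2", "3", "4")][c("1", "2")])
  e34 <- S * pi2 * pVis2 * q2[c("3", "4")]
  counts <- round(c(ek, e34))
  h <- StepHistogram(setNames(as.integer(counts), c("1", "2", "3", "4")),
                     totalRna = 1000)
  fit <- fitOccupancyMixture(h, lm)
  expect_lt(fit@chisq, 0.05)            # rounding only
  expect_equal(fit@pi2, pi2, tolerance = 0.02)
})

test_that("the mixture fit recovers pure and mixed occupancies", {
  lm <- LabelModel(0.9, 0.226)
  h0 <- simulateStepHistogram(150, c("1" = 1), lm, seed = 71)$hist
  expect_lt(fitOccupancyMixture(h0, lm)@pi2, 0.05)
  h1 <- simulateStepHistogram(150, c("2" = 1), lm, seed = 72)$hist
  expect_gt(fitOccupancyMixture(h1, lm)@pi2, 0.85)
  hm <- simulateStepHistogram(150, c("1" = 0.55, "2" = 0.45), lm,
                              seed = 73)$hist
  expect_lt(abs(fitOccupancyMixture(hm, lm)@pi2 - 0.45), 0.15)
})

test_that("under-powered histograms are refused", {
  lm <- LabelModel(0.9, 0.2)
  expect_error(fitOccupancyMixture(
    StepHistogram(c("1" = 5), totalRna = 10), lm), "at least 20")
  expect_error(fitOccupancyMixture(
    StepHistogram(c("1" = 30), totalRna = 40), lm), "under-determined")
})

test_that("background fits are exact on exact expected counts", {
  n <- 1000
  p <- 0.45
  counts <- round(n * p * (1 - p)^(0:4))
  tail6 <- n - sum(counts)
  h <- StepHistogram(setNames(as.integer(c(counts, tail6)),
                              c("1", "2", "3", "4", "5", ">5")),
                     totalRna = 2000)
  fit <- fitBackground(h, "geometric")
  expect_equal(fit$p, p, tolerance = 0.01)
  expect_lt(fit$chisq, 1)
  expect_equal(fit$df, sum(fit$table$expected >= 4) - 3L)
})

test_that("geometric data are accepted and mixture data rejected", {
  # acceptance: p-values under the true model are not extreme
  pvals <- vapply(1:30, function(r) {
    counts <- withr::with_seed(800 + r, {
      k <- stats::rgeom(500, 0.5) + 1
      table(factor(pmin(k, 6), levels = 1:6))
    })
    h <- StepHistogram(setNames(as.integer(counts),
                                c("1", "2", "3", "4", "5", ">5")),
                       totalRna = 1000)
    fitBackground(h, "geometric")$pValue
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.8)
  expect_gt(mean(pvals > 0.5), 0.2)   # roughly uniform, not piled at 0
  # power: data from the occupancy mixture reject the geometric
  lm <- LabelModel(0.9, 0.226)
  rej <- vapply(1:30, function(r) {
    h <- simulateStepHistogram(500, c("1" = 0.55, "2" = 0.45), lm,
                               seed = 300 + r)$hist
    fitBackground(h, "geometric")$pValue < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("zero-truncated Poisson parameter is recovered", {
  lam <- 1.3
  pk <- stats::dpois(1:20, lam) / (1 - exp(-lam))
  counts <- round(2000 * c(pk[1:5], sum(pk[6:20])))
  h <- StepHistogram(setNames(as.integer(counts),
                              c("1", "2", "3", "4", "5", ">5")),
                     totalRna = 4000)
  fit <- fitBackground(h, "poisson")
  expect_equal(fit$lambda, lam, tolerance = 0.02)
  expect_equal(fit$df, sum(fit$table$expected >= 4) - 2L)
})

test_that("RNA-dimer exclusion reports identity and flags edge cases", {
  cls <- c(rep("1", 40), rep("2", 10))
  # no multi-RNA spots: identical histograms, p = 1
  r0 <- rnaDimerExclusion(cls, rep(1, 50))
  expect_equal(r0$pValue, 1)
  expect_equal(r0$multiFraction, 0)
  # all dimeric: flagged, empty retained set
  rAll <- rnaDimerExclusion(cls, rep(2, 50))
  expect_true(rAll$allExcluded)
  # 10% RNA dimers carrying the same protein mix: non-significant
  set.seed(77)
  n <- 400
  protein <- sample(c("1", "2"), n, replace = TRUE, prob = c(0.8, 0.2))
  rna <- sample(c(1, 2), n, replace = TRUE, prob = c(0.9, 0.1))
  r <- rnaDimerExclusion(protein, rna)
  expect_gt(r$pValue, 0.05)
  expect_equal(r$multiFraction, mean(rna >= 2))
})
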