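test_that("simulated movies are deterministic and conserve ground truth", {
  cfg <- simConfig(seed = 7, dim = c(48L, 48L),
                   plan = channelPlan(c("cy5", "gfp"), c(633, 488),
                                      c(5L, 15L)))
  cx <- data.frame(cy5 = c(1L, 1L, 0L), gfp = c(2L, 1L, 3L))
  a <- simulateMovie(cfg, cx)
  b <- simulateMovie(cfg, cx)
  expect_identical(a$stack@data, b$stack@data)
  expect_identical(a$truth, b$truth)
  # conservation: per channel, total fluorophores equal the spec'd sums
  agg <- tapply(a$truth$n, a$truth$channel, sum)
  expect_equal(unname(agg[["cy5"]]), 2)
  expect_equal(unname(agg[["gfp"]]), 6)
  # different seed changes the data
  cfg2 <- simConfig(seed = 8, dim = c(48L, 48L),
                    plan = channelPlan(c("cy5", "gfp"), c(633, 488),
                                       c(5L, 15L)))
  expect_false(identical(simulateMovie(cfg2, cx)$stack@data, a$stack@data))
})

test_that("a noiseless emitter gives a constant level then background", {
  cfg <- simConfig(seed = 3, dim = c(32L, 32L),
                   plan = channelPlan("gfp", 488, 40L),
                   shotNoise = FALSE, readNoiseSd = 0, baseline = 10,
                   amplitude = 100, bleachLifetime = 15)
  sim <- simulateMovie(cfg, data.frame(x = 16, y = 16, gfp = 1L))
  b <- as.numeric(strsplit(sim$truth$bleachFrames, ",")[[1]])
  px <- sim$stack@data[16, 16, ]
  expect_true(b >= 2 && b <= 40)
  expect_true(all(px[seq_len(b - 1)] > 10 + 50))      # bright pre-bleach
  expect_true(all(abs(px[b:40] - 10) < 1e-9))          # background after
  expect_equal(stats::sd(px[seq_len(b - 1)]), 0)       # constant level
})

test_that("zero complexes give a valid empty movie and empty truth", {
  cfg <- simConfig(seed = 1, dim = c(24L, 24L),
                   plan = channelPlan("gfp", 488, 4L), shotNoise = FALSE,
                   readNoiseSd = 0)
  sim <- simulateMovie(cfg, data.frame(gfp = integer()))
  expect_s4_class(sim$stack, "ImageStack")
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$stack@data == 120))
})

test_that("mean fitted amplitude across detections recovers the truth", {
  # Monte Carlo over three seeds; amplitudes on the normalized composite
  # are mapped back to counts through the recorded normalization
  rel <- vapply(1:3, function(s) {
    cfg <- simConfig(seed = s, dim = c(200L, 200L),
                     plan = channelPlan("gfp", 488, 50L),
                     bleachLifetime = 1e6)
    sim <- simulateMovie(cfg, data.frame(gfp = rep(1L, 40)))
    pair <- compositeImages(sim$stack, "gfp")
    spots <- detectSpots(sim$stack, "gfp")
    ampCounts <- 0.5 * (spots$Ax + spots$Ay) * pair@norm$meanRange[2]
    mean(ampCounts) / 300
  }, numeric(1))
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("step-histogram sampler records truth and matches the model", {
  lm <- LabelModel(0.9, 0.2)
  out <- simulateStepHistogram(2000, c("1" = 0.55, "2" = 0.45), lm,
                               seed = 11)
  expect_identical(out$truth$occupancyMix, c("1" = 0.55, "2" = 0.45))
  expect_equal(nrow(out$truth$perSpot), 2000)
  # bookkeeping: histogram equals the tabulated per-spot classes
  vis <- out$truth$perSpot$labelled
  expect_equal(sum(out$hist@counts), sum(vis > 0))
  expect_equal(unname(out$hist@counts[["2"]]), sum(vis == 2))
  # f = 1, d = 0, all single units: every colocalized spot in class 1
  all1 <- simulateStepHistogram(500, c("1" = 1), LabelModel(1, 0),
                                seed = 2)
  expect_equal(unname(all1$hist@counts[["1"]]), 500)
  expect_equal(sum(all1$hist@counts), 500)
})

test_that("sampler frequencies match the closed-form distribution", {
  # NE2-like label model, single units, many draws
  f <- 0.59
  d <- estimateDimerFraction(118, 9, f)$d
  lm <- LabelModel(f, d, "NE2")
  n <- 1e5
  out <- simulateStepHistogram(n, c("1" = 1), lm, seed = 5)
  expected <- expectedStepDistribution(1, lm)
  pVis <- 1 - ((1 - d) * (1 - f) + d * (1 - f)^2)
  for (cls in c("1", "2")) {
    phat <- out$hist@counts[[cls]] / sum(out$hist@counts)
    se <- sqrt(expected[[cls]] * (1 - expected[[cls]]) / (n * pVis))
    expect_lt(abs(phat - expected[[cls]]), 3 * se + 1e-12)
  }
})

test_that("sampler rejects invalid inputs", {
  expect_error(simulateStepHistogram(10, c("1" = 0.5), LabelModel(1, 0),
                                     seed = 1), "sum to 1")
  expect_error(LabelModel(0, 0.1))
})

test_that("eCLIP count tables are deterministic and null under fold 1", {
  a <- simulateEclipCounts(80, 2, integer(), 1, depth = 5000, seed = 9)
  b <- simulateEclipCounts(80, 2, integer(), 1, depth = 5000, seed = 9)
  expect_identical(a[[1]]$signal@coverage, b[[1]]$signal@coverage)
  expect_identical(a[[2]]$control@termini, b[[2]]$control@termini)
  # fold 1: signal and control draws share the same rates; compare totals
  # loosely (identically distributed, not identical draws)
  expect_lt(abs(sum(a[[1]]$signal@coverage) /
                  sum(a[[1]]$control@coverage) - 1), 0.1)
  expect_error(simulateEclipCounts(80, 2, integer(), 1, depth = 0,
                                   seed = 1), "depth")
  expect_error(simulateEclipCounts(80, 2, 200, 2, depth = 10, seed = 1),
               "within")
})

test_that("trace generator bleaches every fluorophore inside the trace", {
  sim <- simulateTraces(50, 3, nFrames = 120, bleachLifetime = 40,
                        seed = 13)
  expect_true(all(sim$bleach >= 2 & sim$bleach <= 120))
  expect_equal(dim(sim$traces), c(50, 120))
  # after the last bleach the trace is pure noise around 0
  i <- 1
  post <- sim$traces[i, max(sim$bleach[i, ]):120]
  expect_lt(abs(mean(post)), 0.15)
})
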