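test_that("trace extraction cancels flat background exactly", {
  arr <- array(7.5, c(32, 32, 12))
  st <- ImageStack(arr, channelPlan("gfp", 488, 12L))
  tr <- extractTrace(st, 16, 16, "gfp")
  expect_false(tr$edgeClipped)
  expect_equal(length(tr$values), 12)
  expect_equal(tr$values, rep(0, 12))
})

test_that("edge spots are marked clipped, not analysed", {
  arr <- array(1, c(32, 32, 4))
  st <- ImageStack(arr, channelPlan("gfp", 488, 4L))
  tr <- extractTrace(st, 3, 16, "gfp")
  expect_true(tr$edgeClipped)
  expect_null(tr$values)
})

test_that("noiseless emitter plateau equals the PSF integral minus leakage", {
  cfg <- simConfig(seed = 2, dim = c(32L, 32L),
                   plan = channelPlan("gfp", 488, 30L), shotNoise = FALSE,
                   readNoiseSd = 0, baseline = 50, amplitude = 200,
                   psfSigma = 1.3, bleachLifetime = 10)
  sim <- simulateMovie(cfg, data.frame(x = 16, y = 16, gfp = 1L))
  tr <- extractTrace(sim$stack, 16, 16, "gfp")
  # oracle: direct evaluation of the PSF on the centre box and ring
  psf <- function(i, j) 200 * exp(-((i - 16)^2 + (j - 16)^2) / (2 * 1.3^2))
  ij <- expand.grid(i = 11:21, j = 11:21)
  cheb <- pmax(abs(ij$i - 16), abs(ij$j - 16))
  expected <- mean(psf(ij$i, ij$j)[cheb <= 1]) -
    mean(psf(ij$i, ij$j)[cheb == 5])
  b <- as.numeric(strsplit(sim$truth$bleachFrames, ",")[[1]])
  expect_true(b > 2)
  expect_equal(unique(round(tr$values[seq_len(b - 1)], 9)),
               round(expected, 9))
  expect_equal(tr$values[b:30], rep(0, 30 - b + 1))
})

test_that("a noiseless two-level trace yields exactly one change point", {
  tr <- c(rep(2, 100), rep(0, 150))
  cp <- detectChangePoints(tr)
  expect_equal(as.integer(cp), 100L)
})

test_that("noiseless staircases are exactly recovered for K <= 5", {
  for (K in 1:5) {
    tr <- rep(seq(K, 0), each = 25)
    cp <- detectChangePoints(tr)
    expect_equal(as.integer(cp), seq_len(K) * 25L)
    res <- countSteps(tr, cp)
    expect_equal(res@steps, K)
    expect_equal(res@stepClass, as.character(K))
    expect_equal(res@plateaus, as.numeric(seq(K, 0)))
  }
})

test_that("detection is exactly invariant to affine intensity rescaling", {
  sim <- simulateTraces(20, 2, nFrames = 200, noiseSd = 0.2, seed = 17)
  for (i in c(1, 7, 13)) {
    y <- sim$traces[i, ]
    base <- detectChangePoints(y)
    scaled <- detectChangePoints(1234.5 * y - 99.7)
    expect_identical(as.integer(base), as.integer(scaled))
  }
})

test_that("constant and too-short traces give empty results", {
  expect_equal(length(detectChangePoints(rep(3, 50))), 0)
  expect_warning(cp <- detectChangePoints(c(1, 2, 3)), "shorter")
  expect_equal(length(cp), 0)
})

test_that("recursive detection is near the exhaustive two-change optimum", {
  # 60-frame traces with two well-defined change points at random positions
  set.seed(23)
  ok <- 0
  for (i in 1:100) {
    cp1 <- sample(5:30, 1)
    cp2 <- cp1 + sample(10:25, 1)
    y <- c(rep(2, cp1), rep(1, cp2 - cp1), rep(0, 60 - cp2)) +
      stats::rnorm(60, 0, 0.2)
    oracle <- oracleBestTwoCp(y)
    cp <- detectChangePoints(y)
    rss <- rssOfSegmentation(y, as.integer(cp))
    if (rss <= 1.05 * oracle$rss) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.95)
})

test_that("change points at SNR 5 land within 2 frames of the truth", {
  sim <- simulateTraces(500, 2, nFrames = 250, stepAmplitude = 1,
                        noiseSd = 0.2, seed = 29)
  hits <- 0
  for (i in 1:500) {
    cp <- as.integer(detectChangePoints(sim$traces[i, ]))
    truth <- sort(sim$bleach[i, ]) - 1L  # last bright frame
    if (length(cp) >= 2 &&
        all(vapply(truth, function(t) min(abs(cp - t)) <= 2, logical(1))))
      hits <- hits + 1
  }
  expect_gte(hits / 500, 0.90)
})

test_that("blinking is discounted as a re-activation", {
  tr <- rep(c(2, 1, 2, 1, 0), each = 30)
  res <- countSteps(tr, detectChangePoints(tr))
  expect_equal(res@steps, 2)
  expect_equal(nrow(res@reactivations), 1)
  expect_equal(res@stepClass, "2")
})

test_that("photon count of a noiseless trace is plateau level x length", {
  tr <- c(rep(3, 40), rep(0, 60))
  res <- countSteps(tr, detectChangePoints(tr))
  expect_equal(res@photons, 3 * 40)
})

test_that("exact-N recovery meets the simulation targets at SNR 5", {
  targets <- c(0.90, 0.90, 0.80)
  for (N in 1:3) {
    sim <- simulateTraces(500, N, nFrames = 250, stepAmplitude = 1,
                          noiseSd = 0.2, bleachLifetime = 50,
                          seed = 100 + N)
    rec <- vapply(seq_len(500),
                  function(i) analyseTrace(sim$traces[i, ])@steps,
                  integer(1))
    expect_gte(mean(rec == N), targets[N])
  }
})

test_that("the review queue flags what needs eyes and only that", {
  expect_equal(nrow(reviewQueue(list())), 0)
  tr <- rep(c(2, 1, 2, 1, 0), each = 30)
  withBlink <- analyseTrace(tr)
  clean <- analyseTrace(c(rep(5, 100), rep(0, 100)))
  q <- reviewQueue(list(clean, withBlink))
  expect_equal(q$index, 2)
  expect_match(q$reason, "reactivation")
  # a mostly clean simulation queues under 10%
  sim <- simulateTraces(200, 1, nFrames = 250, noiseSd = 0.2, seed = 33)
  results <- lapply(seq_len(200), function(i)
    analyseTrace(sim$traces[i, ]))
  expect_lt(nrow(reviewQueue(results)) / 200, 0.10)
})

test_that("photon-count validation separates classes with correct logic", {
  set.seed(41)
  singles <- stats::rlnorm(150, log(1500), 0.4)
  doubles <- singles * 2
  rep <- photonCountValidation(singles, doubles, seed = 1)
  # pseudo-doubles of a symmetric-ish distribution double the median
  expect_equal(rep$medianPseudoDouble / rep$medianSingle, 2,
               tolerance = 0.25)
  expect_lt(rep$p12, 0.001)
  expect_gt(rep$p2pseudo, 0.05)
  expect_error(photonCountValidation(singles[1:5], doubles), "at least 10")
})

test_that("doubled singles test significant, equal emission does not", {
  # compare complexes *assigned* to the one- and two-molecule classes, at
  # sample sizes typical of one experiment; note that class assignment
  # carries a small upward selection bias on two-step photon sums (merged
  # steps preferentially remove early-bleaching doubles), so the null
  # comparison is only approximately exact
  p12 <- numeric(40); p2p <- numeric(40)
  for (r in 1:40) {
    sim1 <- simulateTraces(140, 1, nFrames = 250, stepAmplitude = 1,
                           noiseSd = 0.2, seed = 500 + r)
    sim2 <- simulateTraces(40, 2, nFrames = 250, stepAmplitude = 1,
                           noiseSd = 0.2, seed = 900 + r)
    r1 <- lapply(1:140, function(i) analyseTrace(sim1$traces[i, ]))
    r2 <- lapply(1:40, function(i) analyseTrace(sim2$traces[i, ]))
    ph1 <- vapply(Filter(function(r) r@stepClass == "1", r1),
                  function(r) r@photons, numeric(1))
    ph2 <- vapply(Filter(function(r) r@stepClass == "2", r2),
                  function(r) r@photons, numeric(1))
    rep <- photonCountValidation(ph1, ph2, seed = r)
    p12[r] <- rep$p12
    p2p[r] <- rep$p2pseudo
  }
  expect_gte(mean(p12 < 0.001), 0.9)  # 1 vs 2 separates decisively
  expect_gte(mean(p2p > 0.05), 0.8)   # 2 vs pseudo-double mostly does not
})

test_that("class totals in a built histogram equal the analysed complexes", {
  sim <- simulateTraces(80, 2, nFrames = 200, noiseSd = 0.2, seed = 55)
  results <- lapply(seq_len(80), function(i) analyseTrace(sim$traces[i, ]))
  h <- buildStepHistogram(results, totalRna = 120)
  expect_equal(sum(h@counts), 80)
  expect_equal(colocPct(h), 100 * 80 / 120)
})
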