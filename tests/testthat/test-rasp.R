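test_that("Forster equation evaluates exactly", {
  expect_equal(efretForster(60, 60), 0.5)
  expect_equal(efretForster(0, 60), 1)
  expect_equal(efretForster(120, 60), 1 / 65)
  expect_equal(efretForster(c(30, 60), 60), c(64 / 65, 0.5))
  expect_error(efretForster(-1, 60), "R must")
  expect_error(efretForster(60, 0), "R0 must")
})

test_that("burst detection finds isolated clusters and applies thresholds", {
  mkStream <- function(times) data.frame(
    timestamp_us = times,
    channel = rep_len(c("donor", "acceptor"), length(times)),
    excitation = rep("donor", length(times)))
  quiet <- seq(0, 1e6, by = 2e4)            # 50 Hz background
  cluster25 <- seq(5e5, 5e5 + 1000, length.out = 25)
  bt <- detectBursts(mkStream(sort(c(quiet, cluster25))))
  expect_equal(nrow(bursts(bt)), 1L)
  expect_gte(bursts(bt)$nPhotons[1], 25)
  cluster15 <- seq(5e5, 5e5 + 600, length.out = 15)
  bt15 <- detectBursts(mkStream(sort(c(quiet, cluster15))))
  expect_equal(nrow(bursts(bt15)), 0L)
  expect_equal(nrow(bursts(detectBursts(mkStream(numeric(0))))), 0L)
})

test_that("simulated bursts are recovered at >= 95% by interval overlap", {
  spec <- photonStreamSpec(states = data.frame(E = 0.3, dwellMs = 10),
                           burstRate = 4, durationS = 50,
                           photonsPerBurstMean = 120,
                           backgroundRateD = 600, backgroundRateA = 600,
                           recurrenceProb = 0, seed = 91)
  sim <- simulateALEXPhotons(spec)
  expect_gte(nrow(sim$groundTruth), 150)
  bt <- detectBursts(sim$photons)
  b <- bursts(bt)
  hit <- vapply(seq_len(nrow(sim$groundTruth)), function(i) {
    any(b$start <= sim$groundTruth$end[i] + 100 &
          b$end >= sim$groundTruth$start[i] - 100)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("ALEX corrections follow the accurate-FRET algebra", {
  b <- new("BurstTable",
           bursts = data.frame(start = 0, end = 1000, nPhotons = 200,
                               FDD = 50, FDA = 50, FAA = 100,
                               Eraw = 0.5),
           params = list())
  c1 <- bursts(correctBursts(b, gamma = 1, leakage = 0,
                             directExcitation = 0))
  expect_equal(c1$Ecorr, 0.5)
  expect_equal(c1$S, 0.5)
  c2 <- bursts(correctBursts(b, gamma = 1, leakage = 0.1,
                             directExcitation = 0))
  expect_equal(c2$Ecorr, 45 / 95)
  donorOnly <- new("BurstTable",
                   bursts = data.frame(start = 0, end = 1, nPhotons = 60,
                                       FDD = 50, FDA = 10, FAA = 0,
                                       Eraw = 10 / 60),
                   params = list())
  expect_equal(bursts(correctBursts(donorOnly))$S, 1)
  expect_error(correctBursts(b, gamma = 0), "gamma")
  # with neutral parameters Ecorr reduces to the raw proximity ratio
  set.seed(92)
  counts <- data.frame(start = 1:20, end = 1:20 + 1,
                       nPhotons = 60,
                       FDD = rpois(20, 40) + 1, FDA = rpois(20, 30) + 1,
                       FAA = rpois(20, 50))
  counts$Eraw <- counts$FDA / (counts$FDA + counts$FDD)
  neutral <- bursts(correctBursts(new("BurstTable", bursts = counts,
                                      params = list())))
  expect_equal(neutral$Ecorr, counts$Eraw)
})

test_that("stoichiometry and acceptor-count filters drop the right bursts", {
  df <- data.frame(start = 1:4, end = 2:5, nPhotons = 100,
                   FDD = c(50, 50, 5, 50), FDA = c(10, 10, 90, 2),
                   FAA = c(60, 5, 60, 60))
  df$Eraw <- df$FDA / (df$FDA + df$FDD)
  bt <- correctBursts(new("BurstTable", bursts = df, params = list()))
  kept <- bursts(filterBursts(bt))
  # burst 1: S = 60/120 = 0.5, FDA = 10 -> kept
  # burst 2: S = 60/65 ~ 0.92 -> removed; burst 3: S = 95/155 but FDA = 90 kept
  # burst 4: FDA = 2 < 3 -> removed
  expect_equal(kept$start, c(1, 3))
  expect_lte(nrow(kept), nrow(df))
  expect_true(all(kept$S >= 0.25 & kept$S <= 0.75 & kept$FDA >= 3))
})

test_that("burst autocorrelation is ~1 for Poisson times and peaks for pairs", {
  set.seed(93)
  tPois <- sort(runif(5000, 0, 3e5))       # ms over 300 s
  acf <- burstACF(tPois, lagBins = seq(0, 100, by = 10))
  expect_true(all(abs(acf$g - 1) < 0.1))
  # doubling the observation window leaves g unchanged within noise
  tPois2 <- sort(runif(10000, 0, 6e5))
  acf2 <- burstACF(tPois2, lagBins = seq(0, 100, by = 10))
  expect_true(all(abs(acf2$g - 1) < 0.1))
  # every burst followed by a pair at +5 ms
  base <- sort(runif(2000, 0, 6e5))
  paired <- sort(c(base, base + 5))
  acfP <- burstACF(paired, lagBins = seq(0, 40, by = 2))
  g5 <- acfP$g[acfP$lagLo == 4]
  expect_gt(g5, 10)
  expect_error(burstACF(1), "at least 2")
})

test_that("same-molecule probability follows 1 - 1/g with clamping", {
  expect_equal(pSame(1), 0)
  expect_equal(pSame(2), 0.5)
  expect_equal(pSame(20), 0.95)
  expect_equal(pSame(0.5), 0)      # clamped
  expect_error(pSame(0), "g must")
})

test_that("recurrence pairs use end-to-start gaps below the window", {
  df <- data.frame(start = c(0, 10e3, 100e3), end = c(9e3, 20e3, 110e3),
                   nPhotons = 100, FDD = 50, FDA = 50, FAA = 50)
  df$Eraw <- 0.5
  bt <- correctBursts(new("BurstTable", bursts = df, params = list()))
  pr <- recurrencePairs(bt, dtMaxMs = 30)
  expect_equal(nrow(pr), 1L)            # 1 ms gap kept, 80 ms gap dropped
  expect_equal(pr$dt, 1)
  none <- recurrencePairs(bt, dtMaxMs = 0.5)
  expect_equal(nrow(none), 0L)
})

test_that("pair state changes match ground-truth transitions within CI", {
  spec <- photonStreamSpec(
    states = data.frame(E = c(0.2, 0.6), dwellMs = c(15, 15)),
    burstRate = 4, durationS = 120, photonsPerBurstMean = 600,
    backgroundRateD = 300, backgroundRateA = 300,
    recurrenceProb = 0.5, recurrenceGapRangeMs = c(1, 20), seed = 94)
  sim <- simulateALEXPhotons(spec)
  bt <- filterBursts(correctBursts(detectBursts(sim$photons)))
  b <- bursts(bt)
  pr <- recurrencePairs(bt, dtMaxMs = 30)
  expect_gt(nrow(pr), 30)
  # truth: match each detected burst to the overlapping true burst
  trueState <- function(i) {
    ov <- which(sim$groundTruth$start <= b$end[i] + 100 &
                  sim$groundTruth$end >= b$start[i] - 100)
    if (length(ov)) sim$groundTruth$state[ov[1]] else NA_integer_
  }
  s0 <- vapply(pr$i0, trueState, integer(1))
  s1 <- vapply(pr$i1, trueState, integer(1))
  ok <- !is.na(s0) & !is.na(s1)
  truthFrac <- mean(s0[ok] != s1[ok])
  measured <- abs(pr$E0 - pr$E1)[ok] > 0.2   # states 0.4 apart in E
  ci <- binom.test(sum(measured), length(measured))$conf.int
  expect_gte(truthFrac, ci[1])
  expect_lte(truthFrac, ci[2])
})

test_that("pair density equals the brute-force kernel sum", {
  set.seed(95)
  pairs <- data.frame(E0 = runif(300, 0.1, 0.9), E1 = runif(300, 0.1, 0.9))
  d <- pairDensity(pairs, bandwidth = 0.05, gridStep = 0.05)
  oracle <- bruteKDE(pairs, d$x, d$y, 0.05)
  expect_lt(max(abs(d$z - oracle)), 1e-9)
  # single pair: density argmax at the pair
  d1 <- pairDensity(data.frame(E0 = 0.2, E1 = 0.2), gridStep = 0.002)
  am <- which(d1$z == max(d1$z), arr.ind = TRUE)
  expect_equal(d1$x[am[1]], 0.2, tolerance = 1e-9)
  expect_equal(d1$y[am[2]], 0.2, tolerance = 1e-9)
  # symmetric pair sets give a density symmetric about the diagonal
  sym <- data.frame(E0 = c(0.2, 0.7, 0.4), E1 = c(0.7, 0.2, 0.4))
  ds <- pairDensity(sym, bandwidth = 0.03, gridStep = 0.02)
  expect_lt(max(abs(ds$z - t(ds$z))), 1e-9)
  expect_error(pairDensity(sym[0, ]), "at least one")
})

test_that("photon tables round-trip through the delimited format", {
  sim <- simulateALEXPhotons(photonStreamSpec(durationS = 1, burstRate = 5,
                                              seed = 96))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePhotons(sim$photons, path)
  back <- readPhotons(path)
  expect_equal(back$timestamp_us, sim$photons$timestamp_us)
  expect_equal(back$channel, sim$photons$channel)
  expect_equal(back$excitation, sim$photons$excitation)
})
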