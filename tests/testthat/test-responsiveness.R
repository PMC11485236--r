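test_that("a neuron with identical rates on all trials has F = 0 and is not modulated", {
  x <- matrix(1, nrow = 1, ncol = 32,
              dimnames = list("n1", NULL))
  res <- piriform:::rowAnovaF(x, rep(1:4, each = 8))
  expect_identical(res$F, 0)
  expect_identical(res$df1, 3L)
  expect_identical(res$df2, 28L)
  expect_false(res$p < 0.05)
})

test_that("the vectorised ANOVA F matches stats::aov on random matrices", {
  set.seed(99)
  for (rep_ in 1:5) {
    n <- sample(3:6, 1)
    g <- rep(1:4, each = 5)
    x <- matrix(rnorm(n * length(g)), nrow = n)
    res <- piriform:::rowAnovaF(x, g)
    for (i in seq_len(n)) {
      oracle <- aovF(x[i, ], g)
      expect_equal(res$F[i], unname(oracle["F"]), tolerance = 1e-10)
      expect_equal(res$p[i], unname(oracle["p"]), tolerance = 1e-10)
    }
  }
})

test_that("detection recovers strongly tuned synthetic neurons and respects df", {
  cfg <- smallConfig(regionCounts = c(PC = 12, AMY = 0, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 1, AMY = 0, EC = 0, HIP = 0,
                                       PHC = 0),
                     gainMean = 3, gainShape = 50)  # tight gain ~ 3
  s <- generateSession(cfg, seed = 31)
  rm <- suppressMessages(computeRateMatrix(s, normalization = "zscored"))
  det <- detectModulatedNeurons(rm)
  expect_identical(unique(det$df_between), 15L)
  expect_identical(unique(det$df_within), 112L)
  expect_gt(mean(det$modulated), 0.9)
  # control-excluded variant drops one group
  det15 <- detectModulatedNeurons(rm, excludeControl = TRUE)
  expect_identical(unique(det15$df_between), 14L)
})

test_that("type-I error of the selection is near alpha on null neurons", {
  cfg <- synthConfig(regionCounts = c(PC = 300, AMY = 0, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 0, AMY = 0, EC = 0, HIP = 0,
                                       PHC = 0),
                     imageBlock = FALSE)
  det <- do.call(rbind, lapply(1:4, function(sd_) {
    s <- generateSession(cfg, seed = 600 + sd_)
    detectModulatedNeurons(
      suppressMessages(computeRateMatrix(s, normalization = "zscored")))
  }))
  fpr <- mean(det$modulated)
  halfWidth <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / nrow(det))
  expect_gt(nrow(det), 1000)
  expect_lt(abs(fpr - 0.05), halfWidth)
})

test_that("PSTH of a stationary Poisson neuron is flat and bin arithmetic is exact", {
  cfg <- smallConfig(regionCounts = c(PC = 10, AMY = 0, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 0, AMY = 0, EC = 0, HIP = 0,
                                       PHC = 0))
  s <- generateSession(cfg, seed = 13)
  psth <- computePsth(s, window = c(-1, 2))
  expect_identical(nrow(psth$bins), 60L)   # 3 s / 50 ms
  m <- mean(psth$bins$mean_z)
  sem <- sd(psth$bins$mean_z) / sqrt(nrow(psth$bins))
  expect_lt(abs(m), 3 * sem + 0.05)
})

test_that("a tuned population shows a post-onset PSTH peak within latency + duration", {
  cfg <- smallConfig(regionCounts = c(PC = 14, AMY = 0, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 1, AMY = 0, EC = 0, HIP = 0,
                                       PHC = 0),
                     gainMean = 4, gainShape = 20)
  s <- generateSession(cfg, seed = 17)
  psth <- computePsth(s, window = c(-1, 3))
  peak <- psth$bins$bin_mid[which.max(psth$bins$mean_z)]
  expect_gt(peak, 0)
  expect_lt(peak, 0.2 + 1.5)  # configured latency + duration
})

test_that("PSTH z-scores are invariant under uniform rescaling of a neuron's rates", {
  s <- generateSession(smallConfig(), seed = 19)
  s2 <- s
  # doubling every spike is not a rate rescale; instead halve time axis:
  # scale all spike times by 1/2 and onsets likewise => rates double
  s2@spikes <- lapply(s@spikes, function(sp) sp / 2)
  s2@trials$onset_s <- s@trials$onset_s / 2
  p1 <- suppressMessages(computePsth(s, binWidth = 0.1, window = c(-1, 2)))
  p2 <- suppressMessages(computePsth(s2, binWidth = 0.05,
                                     window = c(-0.5, 1),
                                     baselineWindow = c(-2.5, 0)))
  expect_equal(p1$bins$mean_z, p2$bins$mean_z, tolerance = 1e-10)
})

test_that("odour vs control contrast behaves under strong and matched controls", {
  mk <- function(factor_, seed) {
    cfg <- smallConfig(regionCounts = c(PC = 60, AMY = 0, EC = 0, HIP = 0,
                                        PHC = 0),
                       tunedFraction = c(PC = 1, AMY = 0, EC = 0, HIP = 0,
                                         PHC = 0),
                       controlResponseFactor = factor_,
                       suppressionDecay = 1,
                       # breadth far above 15 so every neuron prefers
                       # all 15 odours (Poisson draw capped at 15)
                       tuningBreadth = c(PC = 60, AMY = 1, EC = 1,
                                         HIP = 1, PHC = 1),
                       pcFirstTrialBoost = 1)
    s <- generateSession(cfg, seed = seed)
    rm <- suppressMessages(computeRateMatrix(s, normalization = "zscored"))
    odourVsControlContrast(rm)
  }
  # control as strong as the odours (all odours preferred): diff ~ 0
  strong <- mk(0.999, 41)
  expect_lt(abs(median(strong$perNeuron$diff)), 0.25)
  # weak control: clearly positive differences
  weak <- mk(0.2, 41)
  expect_gt(median(weak$perNeuron$diff), median(strong$perNeuron$diff))
  expect_lt(weak$regional$p[1], 0.05)
})

test_that("the contrast is skipped without control trials and degenerates gracefully", {
  s <- generateSession(smallConfig(includeControl = FALSE), seed = 4)
  rm <- suppressMessages(computeRateMatrix(s, normalization = "zscored"))
  expect_warning(res <- odourVsControlContrast(rm), "control")
  expect_null(res)

  s2 <- generateSession(smallConfig(regionCounts = c(PC = 1, AMY = 0,
    EC = 0, HIP = 0, PHC = 0)), seed = 4)
  rm2 <- suppressMessages(computeRateMatrix(s2, normalization = "zscored"))
  res2 <- odourVsControlContrast(rm2)
  expect_identical(nrow(res2$perNeuron), 1L)
  expect_true(is.na(res2$regional$p))
})

test_that("event response test detects gain and is calibrated under the null", {
  set.seed(5)
  # null: event rates drawn from the same distribution as baseline
  pNull <- replicate(200, {
    ev <- rpois(8, 4) / 2
    base <- rpois(60, 4) / 2
    suppressWarnings(stats::wilcox.test(ev, base,
                                        alternative = "greater",
                                        exact = FALSE)$p.value)
  })
  expect_gt(mean(pNull), 0.35)
  expect_lt(mean(pNull), 0.65)

  # strong gain through the package path: 5x rate on 8 events
  onsets <- seq(0, 140, by = 20)
  breaks <- c(as.vector(rbind(onsets, onsets + 2)), 160)
  sp <- simulatePoissonSpikes(rep(c(10, 2), 8), breaks, seed = 6)
  baselineRates <- rpois(128, 2 * 2) / 2
  p <- eventResponseTest(sp, onsets, c(0, 2), baselineRates)
  expect_lt(p, 0.01)

  # all-zero spike train: heavy ties, p still well-defined
  p0 <- eventResponseTest(numeric(), onsets, c(0, 2), rep(0, 20))
  expect_true(is.finite(p0) && p0 > 0.4)
  expect_error(eventResponseTest(sp, numeric(), c(0, 2), baselineRates),
               "event")
})
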