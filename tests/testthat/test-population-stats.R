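test_that("sparseness index closed forms and scale invariance hold", {
  mkMatrix <- function(x) {
    # one "trial" per stimulus already holding the mean response
    m <- matrix(x, ncol = 1)
    rownames(m) <- paste0("n", seq_along(x))
    m
  }
  # uniform population: A = 1, SI = 0
  res <- populationSparseness(mkMatrix(rep(3, 6)), labels = 1)
  expect_equal(res$A, 1)
  expect_equal(res$SI, 0)
  # one-hot: SI = 1 for any N
  for (N in c(2, 5, 11)) {
    res <- populationSparseness(mkMatrix(c(7, rep(0, N - 1))), labels = 1)
    expect_equal(res$SI, 1)
  }
  # hand evaluation: x = (2, 2, 0, 0) -> A = 0.5, SI = 0.5 / 0.75 = 2/3
  res <- populationSparseness(mkMatrix(c(2, 2, 0, 0)), labels = 1)
  expect_equal(res$A, 0.5)
  expect_equal(res$SI, 2 / 3)
  # scale invariance: SI(c x) = SI(x)
  set.seed(12)
  for (i in 1:10) {
    x <- rexp(8)
    expect_equal(populationSparseness(mkMatrix(x), labels = 1)$SI,
                 populationSparseness(mkMatrix(17.3 * x), labels = 1)$SI)
  }
  # bounds on arbitrary non-negative input
  for (i in 1:20) {
    x <- rexp(6) * rbinom(6, 1, 0.7)
    if (all(x == 0)) next
    si <- populationSparseness(mkMatrix(x), labels = 1)$SI
    expect_true(si >= 0 && si <= 1)
  }
})

test_that("sparseness on session data excludes the control and flags all-zero stimuli", {
  s <- generateSession(smallConfig(regionCounts = c(PC = 8, AMY = 0,
    EC = 0, HIP = 0, PHC = 0)), seed = 3)
  rm <- computeRateMatrix(s, normalization = "raw")
  res <- populationSparseness(rm)
  expect_identical(res$stimulus_id, 1:15)
  expect_true(all(res$N == 8))
  expect_error(populationSparseness(
    computeRateMatrix(s, normalization = "raw")[1, ]), ">= 2 neurons")
  zm <- suppressMessages(computeRateMatrix(s, normalization = "zscored"))
  expect_error(populationSparseness(zm), "raw")
  # silent population for one stimulus
  m <- rbind(n1 = c(1, 0), n2 = c(2, 0))
  expect_warning(res0 <- populationSparseness(m, labels = c(1, 2)),
                 "all-zero")
  expect_equal(res0$stimulus_id, 1)
})

test_that("broad tuning yields a less sparse code when responses dominate baseline", {
  # SI contrasts tuning breadth only once stimulus-evoked activity
  # dominates the between-neuron baseline-rate heterogeneity; a strong,
  # tight gain puts the population in that regime (see the methods
  # vignette for the regime analysis)
  mk <- function(breadth, seed) {
    cfg <- smallConfig(regionCounts = c(PC = 25, AMY = 0, EC = 0,
                                        HIP = 0, PHC = 0),
                       tunedFraction = c(PC = 1, AMY = 0, EC = 0,
                                         HIP = 0, PHC = 0),
                       tuningBreadth = c(PC = breadth, AMY = 1, EC = 1,
                                         HIP = 1, PHC = 1),
                       gainMean = 10, gainShape = 20)
    s <- generateSession(cfg, seed = seed)
    mean(populationSparseness(
      computeRateMatrix(s, normalization = "raw"))$SI)
  }
  broad <- mean(vapply(1:4, function(i) mk(60, i), numeric(1)))
  narrow <- mean(vapply(1:4, function(i) mk(1, 50 + i), numeric(1)))
  expect_lt(broad, narrow)
})

test_that("repetition suppression recovers exact and generated slopes", {
  # z decreasing exactly 0.1 per cycle -> slope = -0.1 to machine precision
  nTrials <- 128
  cyc <- rep(1:8, each = 16)
  lab <- rep(0:15, times = 8)
  x <- matrix(rep(1 - 0.1 * cyc, each = 2), nrow = 2, byrow = FALSE,
              dimnames = list(c("n1", "n2"), NULL))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rate = x),
    rowData = S4Vectors::DataFrame(neuron_id = c("n1", "n2"),
                                   region = c("PC", "PC")),
    colData = S4Vectors::DataFrame(stimulus_id = lab,
                                   presentation_cycle = cyc))
  S4Vectors::metadata(se) <- list(window = c(0, 2),
                                  normalization = "zscored",
                                  excluded = character())
  rm <- as(se, "RateMatrix")
  res <- repetitionSuppression(rm)
  expect_equal(res$perNeuron$slope, c(-0.1, -0.1), tolerance = 1e-12)

  # constant responses -> slope 0, region p ~ 1
  x0 <- x; x0[] <- 0.7
  SummarizedExperiment::assay(rm, "rate") <- x0
  res0 <- repetitionSuppression(rm)
  expect_equal(res0$perNeuron$slope, c(0, 0))
  expect_equal(res0$regional$p, 1)

  # generator with decay 0.9: negative median slope, significant region p
  cfg <- smallConfig(regionCounts = c(PC = 30, AMY = 0, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 1, AMY = 0, EC = 0, HIP = 0,
                                       PHC = 0),
                     suppressionDecay = 0.9, gainMean = 3,
                     gainShape = 10, pcFirstTrialBoost = 1)
  s <- generateSession(cfg, seed = 71)
  zm <- suppressMessages(computeRateMatrix(s, normalization = "zscored"))
  resg <- repetitionSuppression(zm)
  expect_lt(median(resg$perNeuron$slope), 0)
  expect_lt(resg$regional$p[resg$regional$region == "PC"], 0.05)
})

test_that("missing cycles are an error", {
  s <- generateSession(smallConfig(), seed = 2)
  tt <- trials(s, "odour")
  tt <- tt[tt$presentation_cycle <= 4, ]
  rm <- suppressMessages(
    computeRateMatrix(s, trials = tt, normalization = "zscored"))
  expect_error(repetitionSuppression(rm), "cycles")
})

test_that("valence analysis recovers an amygdala-only effect in a pooled cohort", {
  # one session's odour-rating realization correlates all neurons that
  # share an odour, so -- as in the real analysis -- neurons are pooled
  # across sessions before the regional signed-rank test
  cfg <- synthConfig(regionCounts = c(PC = 20, AMY = 25, EC = 0, HIP = 0,
                                      PHC = 0),
                     tunedFraction = c(PC = 1, AMY = 1, EC = 0,
                                       HIP = 0, PHC = 0),
                     betaValence = 1, gainMean = 3, gainShape = 10,
                     tuningBreadth = c(PC = 4, AMY = 3, EC = 2,
                                       HIP = 1.5, PHC = 1.5),
                     imageBlock = FALSE)
  vas <- lapply(1:6, function(i) {
    s <- generateSession(cfg, seed = 100 + i)
    tt <- trials(s, "odour")
    tt <- tt[tt$phase == "rating" & tt$stimulus_id != 0, ]
    rm <- suppressMessages(
      computeRateMatrix(s, trials = tt, normalization = "zscored"))
    valenceAnalysis(rm, referenceValence = synthConfig()$valence,
                    nPerm = 200, seed = 14 + i)
  })
  pooled <- do.call(rbind, lapply(vas, `[[`, "perNeuron"))
  pReg <- vapply(split(pooled$diff, pooled$region), function(d)
    stats::wilcox.test(d, exact = FALSE)$p.value, numeric(1))
  expect_lt(pReg[["AMY"]], 0.05)
  expect_gt(pReg[["PC"]], 0.05)
  # pooled per-odour AMY activity correlates with the generating valence
  rs <- do.call(rbind, lapply(vas, function(v)
    v$correlation$r[v$correlation$region == "AMY"]))
  expect_gt(mean(rs), 0.3)
})

test_that("spearman permutation correlation handles exact and degenerate cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  res <- spearmanPermutation(x, x, nPerm = 200, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 201)
  resNeg <- spearmanPermutation(x, -x, nPerm = 200, seed = 1)
  expect_equal(resNeg$r, -1)
  expect_error(spearmanPermutation(rep(1, 5), x[1:5], seed = 1),
               "constant")
  expect_error(spearmanPermutation(x[1:2], x[1:2], seed = 1))
})

test_that("permutation p-values are uniform under the null", {
  set.seed(33)
  nPerm <- 99
  ps <- vapply(1:400, function(i)
    spearmanPermutation(rnorm(15), rnorm(15), nPerm = nPerm,
                        seed = 1000 + i)$p, numeric(1))
  # p takes values k/(nPerm+1); bin into deciles and chi-square for
  # uniformity
  bins <- cut(ps, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.001)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("exact binomial tail probabilities match brute-force pmf summation", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1)
    d <- dbinom(0:n, n, p0)
    expect_equal(exactBinomialTest(k, n, p0, "right"), sum(d[(k:n) + 1]),
                 tolerance = 1e-12)
    expect_equal(exactBinomialTest(k, n, p0, "left"), sum(d[0:k + 1]),
                 tolerance = 1e-12)
    expect_equal(exactBinomialTest(k, n, p0, "two"),
                 sum(d[d <= d[k + 1] * (1 + 1e-7)]), tolerance = 1e-12)
    # the small-p convention agrees with stats::binom.test
    expect_equal(exactBinomialTest(k, n, p0, "two"),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
  expect_equal(exactBinomialTest(5, 10, 0.5, "two"), 1)  # modal outcome
  expect_error(exactBinomialTest(11, 10, 0.5), "k <= n")
})

test_that("two-proportion Z-test is antisymmetric and errors on degenerate pools", {
  a <- twoProportionZTest(30, 100, 10, 80)
  b <- twoProportionZTest(10, 80, 30, 100)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p, b$p)
  expect_equal(twoProportionZTest(5, 50, 10, 100)$statistic, 0)
  expect_error(twoProportionZTest(0, 10, 0, 10), "pooled")
  expect_error(twoProportionZTest(10, 10, 10, 10), "pooled")
})

test_that("session significance counting uses the right-sided binomial", {
  res <- sessionSignificanceCount(c(rep(0.01, 0), rep(0.5, 20)))
  expect_identical(res$count, 0L)
  expect_equal(res$p, 1)  # P(X >= 0) = 1
  res5 <- sessionSignificanceCount(c(rep(0.01, 5), rep(0.5, 16)))
  expect_identical(res5$count, 5L)
  expect_equal(res5$p, exactBinomialTest(5, 21, 0.05, "right"))
})

test_that("behaviour-decoding correlation validates its inputs", {
  expect_error(behaviourDecodingCorrelation(1:2, 1:2, seed = 1), ">= 3")
  expect_error(behaviourDecodingCorrelation(rep(0.5, 8), runif(8),
                                            seed = 1), "constant")
  set.seed(2)
  x <- runif(10)
  res <- behaviourDecodingCorrelation(x, x + rnorm(10, sd = 0.01),
                                      nPerm = 200, seed = 3)
  expect_gt(res$r, 0.9)
  expect_lt(res$p, 0.05)
})
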