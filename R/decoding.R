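#' Decoding configuration
#'
#' Settings for pseudopopulation identity decoding. Defaults follow the
#' standard analysis: 16 classes (chance 1/16 = 6.25%), a \[0, 2) s
#' odour window, 8 cross-validation splits (leave-one-trial-per-class-out
#' with 8 trials per class), 10 resample runs, 1,000 random neuron
#' subsamples of 200 neurons, and a 1,000-permutation label-shuffle null.
#'
#' @param nClasses number of stimulus classes, default 16.
#' @param window decoding window `c(start, end)` s, default `c(0, 2)`.
#' @param nSplits cross-validation splits; must divide the trials per
#'   class, default 8.
#' @param nResampleRuns resample runs per decoding, default 10.
#' @param nSubsampleRuns random neuron subsamples, default 1000.
#' @param nNeurons neurons per subsample, default 200.
#' @param nPermutations label permutations for the null, default 1000.
#' @param nullResampleRuns resample runs per null decoding, default 10.
#' @param seed RNG seed for the whole analysis (mandatory for the
#'   stochastic entry points).
#' @param dropFirstCycle drop presentation cycle 1 before decoding (a
#'   control for first-trial effects), default `FALSE`.
#' @return A `DecodingConfig` list.
#' @export
decodingConfig <- function(nClasses = 16, window = c(0, 2), nSplits = 8,
                           nResampleRuns = 10, nSubsampleRuns = 1000,
                           nNeurons = 200, nPermutations = 1000,
                           nullResampleRuns = 10, seed = NULL,
                           dropFirstCycle = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "DecodingConfig"
  cfg
}

#' Maximum-correlation-coefficient template classifier
#'
#' Trains one template per class (the mean training population vector)
#' and assigns each test population vector to the class whose template
#' has the maximal Pearson correlation with it. A test vector with zero
#' variance has undefined correlations and is assigned a uniformly random
#' class from the tied set using the current RNG stream (logged).
#'
#' @param train neurons x trials training matrix (>= 2 neurons).
#' @param trainLabels class label per training trial (>= 1 per class).
#' @param test neurons x trials test matrix (same neuron order).
#' @return Character vector of predicted class labels, one per test
#'   trial.
#' @examples
#' tr <- cbind(a = c(1, 5, 2), b = c(4, 1, 1))
#' maxCorrelationClassify(tr, c("a", "b"), tr)
#' @export
maxCorrelationClassify <- function(train, trainLabels, test) {
  if (nrow(train) < 2L)
    stop("correlation templates need >= 2 neurons")
  stopifnot(ncol(train) == length(trainLabels),
            nrow(train) == nrow(test))
  g <- factor(trainLabels)
  templates <- vapply(levels(g), function(cl)
    rowMeans(train[, g == cl, drop = FALSE]), numeric(nrow(train)))
  cc <- suppressWarnings(stats::cor(test, templates))   # nTest x nClasses
  cc[is.na(cc)] <- -Inf
  unname(apply(cc, 1L, function(r) {
    best <- which(r >= max(r) - 1e-12)
    if (all(!is.finite(r))) best <- seq_along(r)
    if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
    levels(g)[best]
  }))
}

#' Pool region responses across sessions for pseudopopulation decoding
#'
#' Computes (by default z-scored) response rates for every neuron of a
#' region in each session and organises them by class label, the unit
#' from which pseudopopulations are assembled.
#'
#' @param sessions list of [OdourSession-class] objects (or a single one).
#' @param region region label (PC/AMY/EC/HIP/PHC), or `NULL` for all.
#' @param modality `"odour"` or `"image"`.
#' @param window decoding window; default the modality's response window.
#' @param normalization passed to [computeRateMatrix()].
#' @param phase restrict to a task phase (e.g. `"identification"`), or
#'   `NULL` for the whole block.
#' @param labelColumn trial-table column holding the class label,
#'   default `"stimulus_id"` (chemical identity); use
#'   `"chosen_stimulus_id"` for perceived identity.
#' @param dropFirstCycle drop presentation cycle 1.
#' @return A `ResponsePool` list of per-neuron records
#'   (`session`, `neuron_id`, `region`, `byClass`).
#' @export
poolRegionResponses <- function(sessions, region = NULL,
                                modality = c("odour", "image"),
                                window = NULL,
                                normalization = "zscored",
                                phase = NULL,
                                labelColumn = "stimulus_id",
                                dropFirstCycle = FALSE) {
  modality <- match.arg(modality)
  if (is(sessions, "OdourSession")) sessions <- list(sessions)
  if (is.null(window)) window <- defaultWindows(modality)$response
  pool <- list()
  for (s in sessions) {
    tt <- s@trials
    tt <- tt[tt$modality == modality, , drop = FALSE]
    if (!is.null(phase)) tt <- tt[tt$phase == phase, , drop = FALSE]
    if (dropFirstCycle)
      tt <- tt[tt$presentation_cycle > 1L, , drop = FALSE]
    if (nrow(tt) == 0L) next
    rm <- computeRateMatrix(s, trials = tt, window = window,
                            normalization = normalization,
                            modality = modality)
    lab <- SummarizedExperiment::colData(rm)[[labelColumn]]
    keep <- !is.na(lab)
    x <- rateValues(rm)[, keep, drop = FALSE]
    lab <- lab[keep]
    regs <- as.character(neuronRegions(rm))
    for (i in seq_len(nrow(x))) {
      if (!is.null(region) && regs[i] != region) next
      pool[[length(pool) + 1L]] <- list(
        session = s@sessionId, neuron_id = rownames(x)[i],
        region = regs[i],
        byClass = split(unname(x[i, ]), lab))
    }
  }
  structure(pool, class = "ResponsePool")
}

#' Assemble a pseudopopulation from pooled responses
#'
#' Samples `nNeurons` neurons without replacement from the pooled region
#' and builds pseudotrials: for each class, each neuron's trials are
#' independently shuffled and concatenated position-wise, so pseudotrial
#' j of class k combines one randomly chosen class-k trial from every
#' neuron (trial alignment by stimulus label). With a single session the
#' pseudotrials are a within-class permutation of the real trials.
#'
#' @param sessions list of sessions, a single session, or a
#'   `ResponsePool` from [poolRegionResponses()].
#' @param region,modality,window forwarded to [poolRegionResponses()]
#'   when `sessions` is not already a pool.
#' @param nNeurons neurons to sample; `NULL` uses the whole pool.
#' @param seed RNG seed (mandatory when called directly).
#' @param trialsPerClass pseudotrials per class, default 8.
#' @return list: `rates` (neurons x pseudotrials), `labels`, `neurons`
#'   (data.frame of sampled neuron provenance).
#' @export
buildPseudopopulation <- function(sessions, region = NULL, nNeurons = NULL,
                                  seed, modality = "odour", window = NULL,
                                  trialsPerClass = 8L) {
  pool <- if (inherits(sessions, "ResponsePool")) sessions
    else poolRegionResponses(sessions, region, modality, window)
  withSeed(seed, samplePseudopopulation(pool, nNeurons, trialsPerClass))
}

## uses the current RNG stream; callers seed
samplePseudopopulation <- function(pool, nNeurons = NULL,
                                   trialsPerClass = 8L) {
  if (length(pool) == 0L) stop("empty response pool")
  if (is.null(nNeurons)) nNeurons <- length(pool)
  if (nNeurons > length(pool))
    stop(sprintf("requested %d neurons but the pool holds only %d",
                 nNeurons, length(pool)))
  ## pool order is kept when the whole pool is used, so that paired
  ## analyses (cross-modal, chemical vs perceived) stay row-aligned
  idx <- if (nNeurons == length(pool)) seq_len(nNeurons)
    else sample.int(length(pool), nNeurons)
  classes <- sort(unique(unlist(lapply(pool[idx],
                                       function(p) names(p$byClass)))))
  nPseudo <- min(trialsPerClass,
                 min(vapply(pool[idx], function(p)
                   min(vapply(p$byClass[classes], length, integer(1L))),
                   integer(1L))))
  labels <- rep(classes, each = nPseudo)
  rates <- matrix(NA_real_, nrow = nNeurons, ncol = length(labels))
  for (j in seq_along(idx)) {
    p <- pool[[idx[j]]]
    rates[j, ] <- unlist(lapply(classes, function(cl) {
      v <- p$byClass[[cl]]
      v[sample.int(length(v))][seq_len(nPseudo)]
    }), use.names = FALSE)
  }
  rownames(rates) <- vapply(pool[idx], function(p)
    paste(p$session, p$neuron_id, sep = "/"), character(1L))
  list(rates = rates, labels = labels,
       neurons = data.frame(
         session = vapply(pool[idx], `[[`, character(1L), "session"),
         neuron_id = vapply(pool[idx], `[[`, character(1L), "neuron_id")))
}

#' Cross-validated decoding accuracy
#'
#' Stratified cross-validation of the maximum-correlation classifier:
#' on each resample run, every class's trials are randomly re-partitioned
#' into `nSplits` folds; each fold is held out in turn and accuracy is
#' averaged over folds and runs.
#'
#' @param rates neurons x trials matrix (e.g. from
#'   [buildPseudopopulation()]).
#' @param labels class label per trial; every class must have the same
#'   trial count, divisible by `config$nSplits`.
#' @param config a [decodingConfig()]; `config$seed` (if non-`NULL`)
#'   seeds the run, otherwise the current RNG stream is used.
#' @return Mean accuracy (fraction correct).
#' @export
crossValidatedAccuracy <- function(rates, labels, config = decodingConfig()) {
  if (!is.null(config$seed))
    withSeed(config$seed, cvAccuracyOnce(rates, labels, config$nSplits,
                                         config$nResampleRuns))
  else cvAccuracyOnce(rates, labels, config$nSplits, config$nResampleRuns)
}

cvAccuracyOnce <- function(rates, labels, nSplits, nResampleRuns) {
  g <- factor(labels)
  tab <- table(g)
  if (length(unique(tab)) != 1L)
    stop("all classes must have the same number of trials")
  tpc <- unique(as.vector(tab))
  if (tpc %% nSplits != 0L)
    stop(sprintf("trials per class (%d) not divisible by nSplits (%d)",
                 tpc, nSplits))
  perFold <- tpc %/% nSplits
  byClass <- split(seq_along(labels), g)
  acc <- numeric(nResampleRuns)
  for (r in seq_len(nResampleRuns)) {
    fold <- integer(length(labels))
    for (cl in byClass)
      fold[cl[sample.int(tpc)]] <- rep(seq_len(nSplits), each = perFold)
    hits <- 0L
    for (f in seq_len(nSplits)) {
      te <- fold == f
      pred <- maxCorrelationClassify(rates[, !te, drop = FALSE],
                                     labels[!te],
                                     rates[, te, drop = FALSE])
      hits <- hits + sum(pred == as.character(labels[te]))
    }
    acc[r] <- hits / length(labels)
  }
  mean(acc)
}

#' Pseudopopulation decoding with a label-permutation null
#'
#' The main regional decoding analysis: the observed accuracy is the
#' mean cross-validated accuracy over `nSubsampleRuns` random
#' `nNeurons`-neuron pseudopopulations; the surrogate distribution is
#' obtained by repeating the decoding `nPermutations` times with class
#' labels permuted within the assembled pseudopopulation (destroying
#' stimulus information while preserving each neuron's marginal rate
#' distribution). The permutation p-value uses the add-one percentile
#' rule, so its smallest attainable value is `1/(nPermutations + 1)`.
#'
#' @param sessions list of sessions (or a `ResponsePool`).
#' @param region region to decode.
#' @param config a [decodingConfig()] with a non-`NULL` `seed`.
#' @return A [DecodingResult-class].
#' @export
populationDecodingWithNull <- function(sessions, region,
                                       config = decodingConfig()) {
  withSeed(config$seed, {
    pool <- if (inherits(sessions, "ResponsePool")) sessions
      else poolRegionResponses(sessions, region,
                               window = config$window,
                               dropFirstCycle = config$dropFirstCycle)
    obs <- vapply(seq_len(config$nSubsampleRuns), function(r) {
      pp <- samplePseudopopulation(pool, config$nNeurons)
      cvAccuracyOnce(pp$rates, pp$labels, config$nSplits,
                     config$nResampleRuns)
    }, numeric(1L))
    null <- vapply(seq_len(config$nPermutations), function(r) {
      pp <- samplePseudopopulation(pool, config$nNeurons)
      cvAccuracyOnce(pp$rates, sample(pp$labels), config$nSplits,
                     config$nullResampleRuns)
    }, numeric(1L))
    observed <- mean(obs)
    p <- (1 + sum(null >= observed)) / (1 + length(null))
    new("DecodingResult", accuracy = observed, subsampleAccuracies = obs,
        nullAccuracies = null, p = p, config = unclass(config),
        region = region %||% "all", details = list())
  })
}

#' Decoding sweeps over window length or neuron count
#'
#' Repeats the pseudopopulation decoding along a grid of decoding-window
#' lengths (windows `[0, g)` s) or neuron counts, testing each grid
#' point against chance with a right-sided Wilcoxon signed-rank test
#' across subsample runs, Bonferroni-corrected for the grid size. The
#' decoding onset is the first grid point from which significance is
#' sustained through the end of the grid (`NA` if never).
#'
#' @param sessions list of sessions.
#' @param region region to decode.
#' @param axis `"window_length"` or `"n_neurons"`.
#' @param grid ascending numeric grid (seconds, or neuron counts).
#' @param config a [decodingConfig()] with a seed; `nSubsampleRuns`
#'   defaults to 100 for sweeps.
#' @return list: `table` (grid, accuracy, p, pBonferroni, significant),
#'   `onset` (grid value or `NA`), `axis`.
#' @export
sweepDecoding <- function(sessions, region,
                          axis = c("window_length", "n_neurons"),
                          grid, config = decodingConfig(nSubsampleRuns = 100)) {
  axis <- match.arg(axis)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and ascending")
  chance <- 1 / config$nClasses
  withSeed(config$seed, {
    poolFull <- if (axis == "n_neurons")
      poolRegionResponses(sessions, region, window = config$window)
      else NULL
    rows <- lapply(seq_along(grid), function(gi) {
      gv <- grid[gi]
      pool <- if (axis == "window_length")
        poolRegionResponses(sessions, region, window = c(0, gv))
        else poolFull
      nNeurons <- if (axis == "n_neurons") gv else config$nNeurons
      if (nNeurons > length(pool))
        stop(sprintf("grid point %g exceeds pool size %d", gv,
                     length(pool)))
      accs <- vapply(seq_len(config$nSubsampleRuns), function(r) {
        pp <- samplePseudopopulation(pool, nNeurons)
        cvAccuracyOnce(pp$rates, pp$labels, config$nSplits,
                       config$nResampleRuns)
      }, numeric(1L))
      p <- if (all(accs == chance)) 1 else
        suppressWarnings(stats::wilcox.test(accs, mu = chance,
                                            alternative = "greater",
                                            exact = FALSE)$p.value)
      data.frame(grid = gv, accuracy = mean(accs), p = p)
    })
    tab <- do.call(rbind, rows)
    tab$pBonferroni <- pmin(tab$p * length(grid), 1)
    tab$significant <- tab$pBonferroni < 0.05
    sustainedFrom <- NA_real_
    sig <- tab$significant
    runEnd <- rev(cumprod(rev(sig))) == 1   # significant through the end
    if (any(runEnd)) sustainedFrom <- grid[which(runEnd)[1L]]
    list(table = tab, onset = sustainedFrom, axis = axis)
  })
}

#' Session-level decoding
#'
#' Decodes stimulus identity from all neurons of a region recorded in a
#' single session (no subsampling across sessions). Regions with fewer
#' than 2 neurons are skipped with a reason code. The observed accuracy
#' uses `config$nResampleRuns` resample runs; the surrogate repeats the
#' decoding on label-permuted data with `config$nullResampleRuns` runs
#' each.
#'
#' @param session an [OdourSession-class].
#' @param region region label.
#' @param config a [decodingConfig()] with a seed; the session-level
#'   variant of the analysis uses `nResampleRuns = 1000`.
#' @return A [DecodingResult-class]; when skipped, `accuracy` is `NA`
#'   and `details$skipped` holds the reason code.
#' @export
sessionDecoding <- function(session, region,
                            config = decodingConfig(nResampleRuns = 1000)) {
  pool <- poolRegionResponses(session, region, window = config$window,
                              dropFirstCycle = config$dropFirstCycle)
  if (length(pool) < 2L)
    return(new("DecodingResult", accuracy = NA_real_, p = NA_real_,
               config = unclass(config), region = region,
               details = list(skipped = "TOO_FEW_NEURONS",
                              nNeurons = length(pool))))
  withSeed(config$seed, {
    pp <- samplePseudopopulation(pool, length(pool))
    observed <- cvAccuracyOnce(pp$rates, pp$labels, config$nSplits,
                               config$nResampleRuns)
    null <- vapply(seq_len(config$nPermutations), function(r) {
      ppn <- samplePseudopopulation(pool, length(pool))
      cvAccuracyOnce(ppn$rates, sample(ppn$labels), config$nSplits,
                     config$nullResampleRuns)
    }, numeric(1L))
    p <- (1 + sum(null >= observed)) / (1 + length(null))
    new("DecodingResult", accuracy = observed,
        subsampleAccuracies = observed, nullAccuracies = null, p = p,
        config = unclass(config), region = region,
        details = list(nNeurons = length(pool),
                       sessionId = session@sessionId))
  })
}

#' Cross-modal decoding (train on one modality, test on the other)
#'
#' Trains class templates on pseudopopulation responses from one
#' modality and tests them on the other, using the \[0, 2) s window for
#' both modalities. The null permutes the training labels. Results are
#' reported separately per direction, as cross-modal generalisation can
#' be asymmetric.
#'
#' @param sessions list of sessions containing both blocks (sessions
#'   without an image block are dropped with a log message).
#' @param region region to decode.
#' @param direction `"image_to_odour"` or `"odour_to_image"`.
#' @param config a [decodingConfig()] with a seed.
#' @return A [DecodingResult-class] with `details$direction`.
#' @export
crossModalDecoding <- function(sessions, region,
                               direction = c("image_to_odour",
                                             "odour_to_image"),
                               config = decodingConfig()) {
  direction <- match.arg(direction)
  if (is(sessions, "OdourSession")) sessions <- list(sessions)
  has <- vapply(sessions, hasImageBlock, logical(1L))
  if (!all(has))
    logMsg("dropping ", sum(!has), " session(s) without an image block")
  sessions <- sessions[has]
  if (length(sessions) == 0L)
    return(new("DecodingResult", accuracy = NA_real_, p = NA_real_,
               config = unclass(config), region = region,
               details = list(skipped = "NO_IMAGE_BLOCK",
                              direction = direction)))
  trainMod <- if (direction == "image_to_odour") "image" else "odour"
  testMod <- if (direction == "image_to_odour") "odour" else "image"
  win <- c(0, 2)   # both modalities use the odour-length window here
  poolTrain <- poolRegionResponses(sessions, region, trainMod, window = win)
  poolTest <- poolRegionResponses(sessions, region, testMod, window = win)
  keyT <- vapply(poolTrain, function(p)
    paste(p$session, p$neuron_id), character(1L))
  keyE <- vapply(poolTest, function(p)
    paste(p$session, p$neuron_id), character(1L))
  common <- intersect(keyT, keyE)
  poolTrain <- poolTrain[match(common, keyT)]
  poolTest <- poolTest[match(common, keyE)]
  class(poolTrain) <- class(poolTest) <- "ResponsePool"
  nNeurons <- min(config$nNeurons, length(common))

  decodeOnce <- function(permute) {
    idx <- sample.int(length(common), nNeurons)
    ppTr <- samplePseudopopulation(structure(poolTrain[idx],
                                             class = "ResponsePool"),
                                   nNeurons)
    ppTe <- samplePseudopopulation(structure(poolTest[idx],
                                             class = "ResponsePool"),
                                   nNeurons)
    labTr <- if (permute) sample(ppTr$labels) else ppTr$labels
    pred <- maxCorrelationClassify(ppTr$rates, labTr, ppTe$rates)
    mean(pred == as.character(ppTe$labels))
  }
  withSeed(config$seed, {
    obs <- vapply(seq_len(config$nSubsampleRuns),
                  function(r) decodeOnce(FALSE), numeric(1L))
    null <- vapply(seq_len(config$nPermutations),
                   function(r) decodeOnce(TRUE), numeric(1L))
    observed <- mean(obs)
    p <- (1 + sum(null >= observed)) / (1 + length(null))
    new("DecodingResult", accuracy = observed, subsampleAccuracies = obs,
        nullAccuracies = null, p = p, config = unclass(config),
        region = region,
        details = list(direction = direction, nNeurons = nNeurons))
  })
}

#' Chemical versus perceived odour-identity decoding
#'
#' During the identification task (4 trials per odour), decoders are
#' trained on the same neuronal populations with two label sets: the
#' chemical odour identity (the presented odour) and the perceived
#' identity (the odour label the participant selected). Only sessions in
#' which each odour label was chosen at least twice are eligible. Per
#' neuron subsample, the accuracy difference (chemical - perceived) is
#' recorded and the differences are compared with a two-sided Wilcoxon
#' signed-rank test across subsample runs. When behaviour is perfect the
#' two label sets coincide and every difference is exactly zero.
#'
#' @param sessions list of sessions.
#' @param region region to decode.
#' @param config a [decodingConfig()] with a seed; this analysis variant
#'   uses 2 cross-validation splits, 100-neuron subsamples and 10
#'   resample runs by default.
#' @return list: `chemical`, `perceived` (per-subsample accuracies),
#'   `diff`, `meanDiff`, `p`, `nEligibleSessions`.
#' @export
chemicalVsPerceivedDecoding <- function(sessions, region,
                                        config = decodingConfig(
                                          nSplits = 2, nNeurons = 100,
                                          nSubsampleRuns = 1000,
                                          nResampleRuns = 10)) {
  if (is(sessions, "OdourSession")) sessions <- list(sessions)
  eligible <- vapply(sessions, function(s) {
    tt <- s@trials
    tt <- tt[tt$modality == "odour" & tt$phase == "identification", ,
             drop = FALSE]
    if (nrow(tt) == 0L) return(FALSE)
    chosenTab <- table(factor(tt$chosen_stimulus_id,
                              levels = sort(unique(tt$stimulus_id))))
    all(chosenTab >= 2L)
  }, logical(1L))
  if (!any(eligible))
    stop("no eligible session: each odour label must be chosen >= 2 times")
  sessions <- sessions[eligible]

  poolChem <- poolRegionResponses(sessions, region,
                                  phase = "identification",
                                  labelColumn = "stimulus_id",
                                  window = config$window)
  poolPerc <- poolRegionResponses(sessions, region,
                                  phase = "identification",
                                  labelColumn = "chosen_stimulus_id",
                                  window = config$window)
  keyC <- vapply(poolChem, function(p)
    paste(p$session, p$neuron_id), character(1L))
  keyP <- vapply(poolPerc, function(p)
    paste(p$session, p$neuron_id), character(1L))
  common <- intersect(keyC, keyP)
  poolChem <- poolChem[match(common, keyC)]
  poolPerc <- poolPerc[match(common, keyP)]
  nNeurons <- min(config$nNeurons, length(common))

  evenPseudo <- function(pool, idx) {
    counts <- vapply(pool[idx], function(p)
      min(vapply(p$byClass, length, integer(1L))), integer(1L))
    n <- min(counts)
    n - (n %% config$nSplits)
  }
  withSeed(config$seed, {
    runSeeds <- sample.int(.Machine$integer.max %/% 2L,
                           config$nSubsampleRuns)
    accC <- accP <- numeric(config$nSubsampleRuns)
    for (r in seq_len(config$nSubsampleRuns)) {
      idx <- sample.int(length(common), nNeurons)
      for (which_ in c("chem", "perc")) {
        pool <- if (which_ == "chem") poolChem else poolPerc
        nPseudo <- evenPseudo(pool, idx)
        if (nPseudo < config$nSplits)
          stop("too few trials per class for ", config$nSplits, " splits")
        acc <- withSeed(runSeeds[r], {
          pp <- samplePseudopopulation(structure(pool[idx],
                                                 class = "ResponsePool"),
                                       nNeurons,
                                       trialsPerClass = nPseudo)
          cvAccuracyOnce(pp$rates, pp$labels, config$nSplits,
                         config$nResampleRuns)
        })
        if (which_ == "chem") accC[r] <- acc else accP[r] <- acc
      }
    }
    d <- accC - accP
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d, mu = 0,
                                          exact = FALSE)$p.value)
    list(chemical = accC, perceived = accP, diff = d,
         meanDiff = mean(d), p = p,
         nEligibleSessions = length(sessions))
  })
}
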