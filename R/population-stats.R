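#' Population sparseness (activity ratio and sparseness index)
#'
#' For each odour stimulus k, computes the activity ratio
#' \deqn{A_k = \left(\frac{1}{N}\sum_i x_i\right)^2 /
#'   \frac{1}{N}\sum_i x_i^2,}
#' where \eqn{x_i} is the mean (raw, non-negative) response rate of
#' neuron i to stimulus k and N is the number of neurons, and the
#' sparseness index
#' \deqn{SI_k = (1 - A_k) / (1 - 1/N) \in [0, 1],}
#' higher values corresponding to a sparser code (0 for uniform activity
#' across the population, 1 when a single neuron is active). The
#' odourless control is excluded, leaving the 15 odours; the
#' region-average sparseness is the mean over stimuli. SI is invariant
#' under rescaling of all rates.
#'
#' @param rates a raw [RateMatrix-class] (all recorded neurons of the
#'   region by default; pass a subset of rows for a modulated-only
#'   variant).
#' @param labels per-trial stimulus labels, default the matrix's
#'   `stimulus_id`.
#' @param controlId stimulus excluded from the odour set, default 0.
#' @return data.frame of class `SparsenessResult`: `stimulus_id`, `A`,
#'   `SI`, `N`; stimuli whose activity vector is all zero are skipped
#'   with a warning. The region-average SI is available as
#'   `mean(result$SI)`.
#' @examples
#' x <- c(2, 2, 0, 0)  # A = 0.5, SI = 2/3
#' @export
populationSparseness <- function(rates, labels = NULL, controlId = 0) {
  if (is(rates, "RateMatrix")) {
    if (rateNormalization(rates) != "raw")
      stop("sparseness requires raw (non-negative) rates")
    if (is.null(labels)) labels <- stimulusIds(rates)
    x <- rateValues(rates)
  } else x <- rates
  stopifnot(ncol(x) == length(labels))
  if (nrow(x) < 2L) stop("sparseness needs >= 2 neurons")
  stims <- sort(setdiff(unique(labels), controlId))
  rows <- lapply(stims, function(k) {
    xi <- rowMeans(x[, labels == k, drop = FALSE])
    if (all(xi == 0)) {
      warning("stimulus ", k, ": all-zero activity, skipped")
      return(NULL)
    }
    N <- length(xi)
    A <- mean(xi)^2 / mean(xi^2)
    data.frame(stimulus_id = k, A = A, SI = (1 - A) / (1 - 1 / N), N = N)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SparsenessResult", class(out))
  out
}

#' Compare population sparseness across regions
#'
#' One-way ANOVA on the per-odour sparseness indices (15 values per
#' region) with Tukey's honestly-significant-difference pairwise tests.
#'
#' @param resultsByRegion named list of [populationSparseness()] results.
#' @return list: `anova` (data.frame with F, df, p), `tukey` (pairwise
#'   comparisons), `means` (per-region mean SI).
#' @export
compareSparseness <- function(resultsByRegion) {
  df <- do.call(rbind, lapply(names(resultsByRegion), function(rg)
    data.frame(region = rg, SI = resultsByRegion[[rg]]$SI)))
  fit <- stats::aov(SI ~ region, data = df)
  an <- summary(fit)[[1L]]
  list(
    anova = data.frame(F = an[1L, "F value"], df1 = an[1L, "Df"],
                       df2 = an[2L, "Df"], p = an[1L, "Pr(>F)"]),
    tukey = as.data.frame(stats::TukeyHSD(fit)$region),
    means = vapply(split(df$SI, df$region), mean, numeric(1L))
  )
}

#' Repetition suppression of odour responses
#'
#' For each neuron, the mean z-scored response rate is computed for each
#' of the 8 presentation cycles (averaging over the 15 odours; control
#' trials excluded) and a least-squares line is fitted over the 8 cycle
#' means. The slope (change in z per presentation) measures repetition
#' suppression. Region-level significance is a two-sided Wilcoxon
#' signed-rank test of the slopes against zero; an additional paired
#' signed-rank test contrasts first- versus second-cycle responses (the
#' first-trial effect).
#'
#' @param rates z-scored [RateMatrix-class] whose `colData` carries
#'   `presentation_cycle`.
#' @param neuronIds subset (e.g. odour-modulated neurons); default all.
#' @param controlId control stimulus excluded from the cycle means.
#' @return list: `perNeuron` (neuron_id, region, slope), `cycleMeans`
#'   (neurons x 8 matrix), `regional` (region, n, statistic, p),
#'   `firstVsSecond` (region, statistic, p).
#' @export
repetitionSuppression <- function(rates, neuronIds = NULL, controlId = 0) {
  cd <- SummarizedExperiment::colData(rates)
  cycles <- cd$presentation_cycle
  labels <- cd$stimulus_id
  if (!all(1:8 %in% cycles)) stop("all 8 presentation cycles are required")
  x <- rateValues(rates)
  region <- as.character(neuronRegions(rates))
  if (!is.null(neuronIds)) {
    keep <- rownames(x) %in% neuronIds
    x <- x[keep, , drop = FALSE]
    region <- region[keep]
  }
  odour <- labels != controlId
  cycleMeans <- vapply(1:8, function(cy)
    rowMeans(x[, odour & cycles == cy, drop = FALSE]),
    numeric(nrow(x)))
  colnames(cycleMeans) <- paste0("cycle", 1:8)
  ## least-squares slope over the 8 cycle means
  cc <- 1:8 - mean(1:8)
  slope <- as.vector(cycleMeans %*% cc) / sum(cc^2)
  perNeuron <- data.frame(neuron_id = rownames(x), region = region,
                          slope = slope, row.names = NULL)
  byRegion <- split(seq_len(nrow(perNeuron)), perNeuron$region)
  regional <- do.call(rbind, lapply(names(byRegion), function(rg) {
    s <- perNeuron$slope[byRegion[[rg]]]
    if (length(s) < 2L || all(s == 0))
      return(data.frame(region = rg, n = length(s),
                        statistic = NA_real_,
                        p = if (all(s == 0)) 1 else NA_real_))
    wt <- stats::wilcox.test(s, mu = 0, exact = FALSE)
    data.frame(region = rg, n = length(s),
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
  firstVsSecond <- do.call(rbind, lapply(names(byRegion), function(rg) {
    i <- byRegion[[rg]]
    d <- cycleMeans[i, 1L] - cycleMeans[i, 2L]
    if (length(i) < 2L || all(d == 0))
      return(data.frame(region = rg, statistic = NA_real_,
                        p = if (all(d == 0)) 1 else NA_real_))
    wt <- stats::wilcox.test(cycleMeans[i, 1L], cycleMeans[i, 2L],
                             paired = TRUE, exact = FALSE)
    data.frame(region = rg, statistic = unname(wt$statistic),
               p = wt$p.value)
  }))
  list(perNeuron = perNeuron, cycleMeans = cycleMeans,
       regional = regional, firstVsSecond = firstVsSecond)
}

#' Valence analysis: liked versus disliked responses
#'
#' Contrasts each (odour-modulated) neuron's mean z-scored response to
#' odours rated liked versus disliked during the rating task, tests the
#' paired differences against zero per region (two-sided Wilcoxon
#' signed-rank), and correlates the per-odour population-mean z-scored
#' response with external reference valence scores (Spearman rank
#' correlation with a seeded two-sided permutation p, per region).
#' Neurons lacking liked or disliked trials are excluded from the
#' contrast with a log message. Reference valence ratings are an input,
#' never bundled data.
#'
#' @param rates z-scored [RateMatrix-class] restricted to rating-phase
#'   trials; `colData` must carry `rating` and `stimulus_id`.
#' @param neuronIds subset (e.g. odour-modulated neurons); default all.
#' @param referenceValence named or ordered numeric vector of valence
#'   scores for the 15 odours (stimulus ids 1-15), or `NULL` to skip the
#'   correlation.
#' @param nPerm permutations for the correlation p-value.
#' @param seed seed for the permutation test (required when
#'   `referenceValence` is given).
#' @return list: `perNeuron` (neuron_id, region, diff), `regional`
#'   (region, n, statistic, p), `correlation` (region, r, p) or `NULL`.
#' @export
valenceAnalysis <- function(rates, neuronIds = NULL,
                            referenceValence = NULL, nPerm = 1000,
                            seed = NULL) {
  cd <- SummarizedExperiment::colData(rates)
  if (!"rating" %in% names(cd)) stop("colData lacks a 'rating' column")
  rated <- !is.na(cd$rating) & cd$rating %in% c("liked", "disliked")
  x <- rateValues(rates)[, rated, drop = FALSE]
  rating <- cd$rating[rated]
  labels <- cd$stimulus_id[rated]
  region <- as.character(neuronRegions(rates))
  if (!is.null(neuronIds)) {
    keep <- rownames(x) %in% neuronIds
    x <- x[keep, , drop = FALSE]
    region <- region[keep]
  }
  if (!any(rating == "liked") || !any(rating == "disliked"))
    stop("both liked and disliked trials are required")
  d <- rowMeans(x[, rating == "liked", drop = FALSE]) -
    rowMeans(x[, rating == "disliked", drop = FALSE])
  perNeuron <- data.frame(neuron_id = rownames(x), region = region,
                          diff = d, row.names = NULL)
  regional <- do.call(rbind, lapply(split(perNeuron, perNeuron$region),
    function(df) {
      if (nrow(df) < 2L || all(df$diff == 0))
        return(data.frame(region = df$region[1L], n = nrow(df),
                          statistic = NA_real_, p = NA_real_))
      wt <- stats::wilcox.test(df$diff, mu = 0, exact = FALSE)
      data.frame(region = df$region[1L], n = nrow(df),
                 statistic = unname(wt$statistic), p = wt$p.value)
    }))
  rownames(regional) <- NULL

  correlation <- NULL
  if (!is.null(referenceValence)) {
    stopifnot(length(referenceValence) == 15L)
    odours <- 1:15
    correlation <- do.call(rbind, lapply(unique(region), function(rg) {
      xm <- x[region == rg, , drop = FALSE]
      popZ <- vapply(odours, function(k) {
        sel <- labels == k
        if (!any(sel)) return(NA_real_)
        mean(xm[, sel, drop = FALSE])
      }, numeric(1L))
      ok <- !is.na(popZ)
      if (sum(ok) < 3L)
        return(data.frame(region = rg, r = NA_real_, p = NA_real_))
      sp <- spearmanPermutation(popZ[ok],
                                as.numeric(referenceValence)[ok],
                                nPerm = nPerm, seed = seed)
      data.frame(region = rg, r = sp$r, p = sp$p)
    }))
  }
  list(perNeuron = perNeuron, regional = regional,
       correlation = correlation)
}

#' Spearman correlation with a seeded permutation p-value
#'
#' Rank correlation between `x` and `y` with a two-sided p-value from
#' `nPerm` seeded permutations of `y`, using the add-one rule
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r|\})/(1 + n_{perm})}.
#'
#' @param x,y numeric vectors of equal length >= 3; constant input is an
#'   error (the correlation is undefined).
#' @param nPerm number of permutations, default 1000.
#' @param seed RNG seed (mandatory).
#' @return list with `r` and `p`.
#' @export
spearmanPermutation <- function(x, y, nPerm = 1000, seed) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  r <- stats::cor(x, y, method = "spearman")
  withSeed(seed, {
    rperm <- vapply(seq_len(nPerm), function(i)
      stats::cor(x, sample(y), method = "spearman"), numeric(1L))
    list(r = r, p = (1 + sum(abs(rperm) >= abs(r) - 1e-12)) / (1 + nPerm))
  })
}

#' Exact binomial test (right, left, or small-p two-sided)
#'
#' Exact binomial tail probabilities: right-sided \eqn{P(X \ge k)},
#' left-sided \eqn{P(X \le k)}, and the two-sided "small-p" convention --
#' the sum of the probabilities of all outcomes no more probable than the
#' observed one, i.e. \eqn{\sum_{j: P(X=j) \le P(X=k)} P(X=j)} -- as used
#' by the classical exact-test implementations (tail doubling is not
#' used).
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p0 null success probability.
#' @param sided `"right"`, `"left"` or `"two"`.
#' @return p-value.
#' @examples
#' exactBinomialTest(13, 27, 0.05, "right")   # 1.3e-10
#' exactBinomialTest(35, 277, 0.05, "two")    # 5.7e-07
#' @export
exactBinomialTest <- function(k, n, p0, sided = c("two", "right", "left")) {
  sided <- match.arg(sided)
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= 1, k <= n,
            p0 >= 0, p0 <= 1)
  switch(sided,
    right = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    left = stats::pbinom(k, n, p0),
    two = {
      d <- stats::dbinom(0:n, n, p0)
      sum(d[d <= stats::dbinom(k, n, p0) * (1 + 1e-7)])
    })
}

#' Two-proportion Z-test (pooled)
#'
#' \deqn{Z = (\hat p_1 - \hat p_2) /
#'   \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)},}
#' with \eqn{\hat p} the pooled proportion, and a two-sided normal
#' p-value. A pooled proportion of exactly 0 or 1 leaves Z undefined and
#' is an error.
#'
#' @param k1,n1 successes and size of sample 1.
#' @param k2,n2 successes and size of sample 2.
#' @return list of class `StatTestResult`: `statistic` (Z), `p`,
#'   `method`, `inputs`.
#' @examples
#' twoProportionZTest(321, 1856, 185, 1856)$statistic  # 6.5
#' @export
twoProportionZTest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop("pooled proportion is 0 or 1: Z undefined")
  z <- (k1 / n1 - k2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(list(statistic = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 method = "two-proportion Z-test (pooled)",
                 inputs = c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)),
            class = "StatTestResult")
}

#' Count significant sessions against a chance rate
#'
#' Counts sessions with p < `alpha` and tests the count against the
#' per-session chance rate `p0` with a right-sided exact binomial test
#' (the session-counting analysis for regional decoding).
#'
#' @param pValues per-session p-values.
#' @param alpha per-session significance level, default 0.05.
#' @param p0 chance rate under the null, default 0.05.
#' @return list: `count`, `n`, `p`.
#' @examples
#' sessionSignificanceCount(c(rep(0.01, 5), rep(0.5, 16)))  # p = 0.0032
#' @export
sessionSignificanceCount <- function(pValues, alpha = 0.05, p0 = 0.05) {
  pValues <- pValues[!is.na(pValues)]
  if (length(pValues) == 0L) stop("at least one session p-value required")
  k <- sum(pValues < alpha)
  list(count = k, n = length(pValues),
       p = exactBinomialTest(k, length(pValues), p0, "right"))
}

#' Correlate per-session decoding accuracy with behaviour
#'
#' Spearman correlation (two-sided seeded permutation p) between
#' per-session neuronal decoding accuracies and behavioural
#' odour-identification accuracies.
#'
#' @param decodingAccuracies,behaviourAccuracies paired per-session
#'   values (>= 3 pairs; constant input is an error).
#' @param nPerm,seed forwarded to [spearmanPermutation()].
#' @return list with `r` and `p`.
#' @export
behaviourDecodingCorrelation <- function(decodingAccuracies,
                                         behaviourAccuracies,
                                         nPerm = 1000, seed) {
  ok <- !is.na(decodingAccuracies) & !is.na(behaviourAccuracies)
  if (sum(ok) < 3L) stop("need >= 3 paired sessions")
  spearmanPermutation(decodingAccuracies[ok], behaviourAccuracies[ok],
                      nPerm = nPerm, seed = seed)
}
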