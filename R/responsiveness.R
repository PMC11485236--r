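#' Detect stimulus-modulated neurons by one-way ANOVA
#'
#' For each neuron, tests whether its (baseline-z-scored) response firing
#' rate differs across stimulus identities with a one-way ANOVA over all
#' trials (128 for a full 16-stimulus x 8-presentation block; the
#' odourless control counts as a 16th group, giving the classical
#' F(15, 112) design). A neuron is flagged as modulated when p < `alpha`.
#' Selection is per neuron at fixed `alpha` with no multiple-testing
#' correction across neurons, so under the null ~`alpha` of untuned
#' neurons are flagged (the selection procedure's chance level).
#'
#' The F statistic is computed row-wise from between/within sums of
#' squares, which is algebraically identical to [stats::aov()] on each
#' neuron but vectorised over neurons.
#'
#' @param rates a z-scored [RateMatrix-class] (see [computeRateMatrix()];
#'   a config switch to raw rates is available by passing a raw matrix).
#' @param labels per-trial stimulus labels; default the matrix's
#'   `stimulus_id` column. Must have >= 2 groups with >= 2 trials each.
#' @param alpha significance level, default 0.05.
#' @param excludeControl drop control trials (stimulus 0) before the
#'   ANOVA, reproducing the control-excluded variant; default `FALSE`.
#' @return data.frame with one row per neuron: `neuron_id`, `region`,
#'   `F`, `p`, `df_between`, `df_within`, `modulated`, `modality`.
#'   Neurons excluded by the zero-baseline-variance rule are absent.
#' @examples
#' s <- generateSession(synthConfig(regionCounts = c(PC = 6, AMY = 0,
#'   EC = 0, HIP = 0, PHC = 0), imageBlock = FALSE), seed = 3)
#' rm <- computeRateMatrix(s, normalization = "zscored")
#' head(detectModulatedNeurons(rm))
#' @export
detectModulatedNeurons <- function(rates, labels = stimulusIds(rates),
                                   alpha = 0.05, excludeControl = FALSE) {
  x <- rateValues(rates)
  md <- S4Vectors::metadata(rates)
  if (excludeControl) {
    keep <- labels != 0
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  stopifnot(ncol(x) == length(labels))
  res <- rowAnovaF(x, labels)
  data.frame(
    neuron_id = rownames(x),
    region = as.character(neuronRegions(rates)),
    F = res$F, p = res$p,
    df_between = res$df1, df_within = res$df2,
    modulated = res$p < alpha,
    modality = md$modality %||%
      (if (isTRUE(all.equal(md$window, c(0, 1)))) "image" else "odour"),
    row.names = NULL
  )
}

## vectorised one-way ANOVA across matrix rows
rowAnovaF <- function(x, labels) {
  g <- factor(labels)
  k <- nlevels(g)
  N <- length(labels)
  if (k < 2L) stop("need >= 2 stimulus groups")
  nj <- as.vector(table(g))
  if (any(nj < 2L)) stop("need >= 2 trials per group")
  groupSums <- x %*% stats::model.matrix(~ 0 + g)
  groupMeans <- sweep(groupSums, 2L, nj, "/")
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((groupMeans - grand)^2, 2L, nj, "*"))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- N - k
  Fv <- unname(ifelse(ssb == 0, 0, (ssb / df1) / (ssw / df2)))
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2)
}

#' Baseline-z-scored peri-stimulus time histogram
#'
#' Bins each neuron's spiking around the supplied onsets (default 50 ms
#' bins), z-scores every bin by the mean and standard deviation of that
#' neuron's baseline-window bins (pooled over trials), averages the
#' z-scored bins across trials per neuron, and finally averages across
#' neurons (mean +/- s.e.m. per bin). Neurons with zero baseline-bin
#' variance are excluded with a logged message.
#'
#' @param session an [OdourSession-class].
#' @param neuronIds neurons to include; default all.
#' @param onsets trial onsets (s); default all odour-trial onsets.
#' @param binWidth bin width in seconds, default 0.05.
#' @param window PSTH extent `c(start, end)` relative to onset.
#' @param baselineWindow baseline used for z-scoring, default \[-5, 0).
#' @param label group label stored with the result.
#' @return list of class `Psth`: `bins` data.frame (`bin_start`,
#'   `bin_mid`, `mean_z`, `sem_z`), `binWidth`, `nNeurons`, `label`,
#'   `excluded`.
#' @export
computePsth <- function(session, neuronIds = NULL, onsets = NULL,
                        binWidth = 0.05, window = c(-1, 3),
                        baselineWindow = c(-5, 0), label = "all") {
  checkWindow(window); checkWindow(baselineWindow, "baselineWindow")
  if (is.null(neuronIds)) neuronIds <- session@neurons$neuron_id
  if (is.null(onsets)) {
    tt <- session@trials
    onsets <- tt$onset_s[tt$modality == "odour"]
  }
  nb <- round((window[2L] - window[1L]) / binWidth)
  edges <- window[1L] + binWidth * (0:nb)
  nbBase <- round((baselineWindow[2L] - baselineWindow[1L]) / binWidth)
  baseEdges <- baselineWindow[1L] + binWidth * (0:nbBase)
  if (nbBase < 2L) stop("baseline window must contain >= 2 bins")

  perNeuron <- matrix(NA_real_, nrow = length(neuronIds), ncol = nb)
  excluded <- character()
  for (i in seq_along(neuronIds)) {
    sp <- session@spikes[[neuronIds[i]]]
    counts <- binCountsPerTrial(sp, onsets, edges)          # trials x bins
    baseCounts <- binCountsPerTrial(sp, onsets, baseEdges)
    mu <- mean(baseCounts / binWidth)
    sdv <- stats::sd(as.vector(baseCounts / binWidth))
    if (!is.finite(sdv) || sdv == 0) {
      excluded <- c(excluded, neuronIds[i])
      next
    }
    z <- (counts / binWidth - mu) / sdv
    perNeuron[i, ] <- colMeans(z)
  }
  if (length(excluded))
    logMsg("PSTH: excluding ", length(excluded),
           " neuron(s) with zero baseline bin variance")
  keep <- !is.na(perNeuron[, 1L])
  pn <- perNeuron[keep, , drop = FALSE]
  if (nrow(pn) == 0L) stop("no neurons with usable baseline variance")
  sem <- apply(pn, 2L, stats::sd) / sqrt(nrow(pn))
  structure(list(
    bins = data.frame(bin_start = edges[-length(edges)],
                      bin_mid = edges[-length(edges)] + binWidth / 2,
                      mean_z = colMeans(pn), sem_z = sem),
    binWidth = binWidth, nNeurons = nrow(pn), label = label,
    excluded = excluded, perNeuron = pn
  ), class = "Psth")
}

binCountsPerTrial <- function(spikes, onsets, edges) {
  nb <- length(edges) - 1L
  out <- matrix(0L, nrow = length(onsets), ncol = nb)
  lo <- edges[1L]; hi <- edges[length(edges)]
  bw <- edges[2L] - edges[1L]
  for (t in seq_along(onsets)) {
    rel <- spikes - onsets[t]
    rel <- rel[rel >= lo & rel < hi]
    if (length(rel))
      out[t, ] <- tabulate(floor((rel - lo) / bw) + 1L, nbins = nb)
  }
  out
}

#' Odour versus odourless-control firing contrast
#'
#' For each (modulated) neuron, the mean z-scored response over odour
#' trials minus the mean over odourless-control trials, followed by a
#' population-level two-sided Wilcoxon signed-rank test of the paired
#' differences against zero, per region. With a single neuron the
#' per-neuron difference is returned and the population p is `NA`.
#'
#' @param rates z-scored [RateMatrix-class] including control trials.
#' @param neuronIds subset of neurons (e.g. the odour-modulated set);
#'   default all rows of `rates`.
#' @param controlId stimulus id of the odourless control, default 0.
#' @return list: `perNeuron` (neuron_id, region, diff), `regional`
#'   (region, n, statistic, p), or `NULL` with a warning when the session
#'   has no control trials.
#' @export
odourVsControlContrast <- function(rates, neuronIds = NULL, controlId = 0) {
  labels <- stimulusIds(rates)
  if (!any(labels == controlId)) {
    warning("no control trials in session; contrast skipped")
    return(NULL)
  }
  x <- rateValues(rates)
  region <- as.character(neuronRegions(rates))
  if (!is.null(neuronIds)) {
    keep <- rownames(x) %in% neuronIds
    x <- x[keep, , drop = FALSE]
    region <- region[keep]
  }
  d <- rowMeans(x[, labels != controlId, drop = FALSE]) -
    rowMeans(x[, labels == controlId, drop = FALSE])
  perNeuron <- data.frame(neuron_id = rownames(x), region = region,
                          diff = d, row.names = NULL)
  regional <- do.call(rbind, lapply(split(perNeuron, perNeuron$region),
    function(df) {
      if (nrow(df) < 2L || all(df$diff == 0))
        return(data.frame(region = df$region[1L], n = nrow(df),
                          statistic = NA_real_, p = NA_real_))
      wt <- stats::wilcox.test(df$diff, mu = 0, exact = FALSE,
                               correct = TRUE)
      data.frame(region = df$region[1L], n = nrow(df),
                 statistic = unname(wt$statistic), p = wt$p.value)
    }))
  rownames(regional) <- NULL
  list(perNeuron = perNeuron, regional = regional)
}

#' Single-neuron event response test
#'
#' Right-sided Wilcoxon rank-sum test comparing a neuron's firing rates
#' in a response window after each event onset with a supplied sample of
#' baseline rates (e.g. the 128 pre-odour baseline rates). Ties are
#' handled by mid-ranks with a normal approximation and continuity
#' correction for larger samples, exact enumeration otherwise (the
#' [stats::wilcox.test()] conventions).
#'
#' @param spikes the neuron's spike times (s).
#' @param eventOnsets one or more event onset times (s).
#' @param responseWindow `c(start, end)` relative to each onset.
#' @param baselineRates numeric vector of baseline firing rates (Hz).
#' @return one-sided (greater) p-value.
#' @export
eventResponseTest <- function(spikes, eventOnsets, responseWindow,
                              baselineRates) {
  if (length(eventOnsets) == 0L) stop("at least one event is required")
  checkWindow(responseWindow, "responseWindow")
  rates <- countSpikesInWindows(spikes, eventOnsets, responseWindow) /
    windowLength(responseWindow)
  n <- length(rates) + length(baselineRates)
  exact <- n <= 20L && !anyDuplicated(c(rates, baselineRates))
  wt <- suppressWarnings(
    stats::wilcox.test(rates, baselineRates, alternative = "greater",
                       exact = exact, correct = TRUE))
  wt$p.value
}
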