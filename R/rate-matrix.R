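#' Default analysis windows
#'
#' Response and baseline windows used throughout: odours are analysed in
#' \[0, 2) s after onset against a \[-5, 0) s baseline; images in
#' \[0, 1) s against \[-0.5, 0) s. All windows are half-open
#' `[start, end)` in seconds relative to trial onset; a spike exactly on
#' the end boundary is excluded.
#'
#' @param modality `"odour"` or `"image"`.
#' @return list with `response` and `baseline`, each `c(start, end)`.
#' @export
defaultWindows <- function(modality = c("odour", "image")) {
  modality <- match.arg(modality)
  if (modality == "odour")
    list(response = c(0, 2), baseline = c(-5, 0))
  else
    list(response = c(0, 1), baseline = c(-0.5, 0))
}

#' Build a neurons x trials firing-rate matrix
#'
#' Computes per-trial firing rates of every neuron in a time window
#' relative to trial onset. Raw rates are spike counts in
#' `[onset + start, onset + end)` divided by the window length (Hz).
#' Z-scored rates normalize each neuron's response rate by the mean and
#' sample standard deviation (n - 1) of its per-trial baseline-window
#' rates across the selected trials:
#' \deqn{z_t = (r_t - \mu_b) / \sigma_b.}
#' Neurons whose baseline rates have zero standard deviation cannot be
#' z-scored; they are excluded from the z-scored matrix and recorded in
#' `metadata()$excluded` with a logged message (never silently zeroed).
#'
#' @param session an [OdourSession-class].
#' @param trials trial subset: a data.frame of trial rows, a vector of
#'   `trial_idx` values, or `NULL` for all trials of `modality`.
#' @param window response window `c(start, end)` seconds, half-open.
#' @param normalization `"raw"` or `"zscored"`.
#' @param baselineWindow baseline window; required for `"zscored"`,
#'   default taken from [defaultWindows()] for the modality.
#' @param modality used when `trials` is `NULL` and for window defaults.
#' @return A [RateMatrix-class].
#' @examples
#' s <- generateSession(synthConfig(regionCounts = c(PC = 3, AMY = 0,
#'   EC = 0, HIP = 0, PHC = 0), imageBlock = FALSE), seed = 2)
#' rm <- computeRateMatrix(s, window = c(0, 2), normalization = "raw")
#' dim(rateValues(rm))
#' @export
computeRateMatrix <- function(session, trials = NULL, window = c(0, 2),
                              normalization = c("raw", "zscored"),
                              baselineWindow = NULL,
                              modality = c("odour", "image")) {
  normalization <- match.arg(normalization)
  modality <- match.arg(modality)
  checkWindow(window)
  tr <- resolveTrials(session, trials, modality)
  if (nrow(tr) == 0L) stop("no trials selected")
  if (normalization == "zscored" && is.null(baselineWindow))
    baselineWindow <- defaultWindows(modality)$baseline
  if (!is.null(baselineWindow)) checkWindow(baselineWindow, "baselineWindow")

  ids <- session@neurons$neuron_id
  rates <- t(vapply(ids, function(id)
    countSpikesInWindows(session@spikes[[id]], tr$onset_s, window) /
      windowLength(window),
    numeric(nrow(tr))))
  dimnames(rates) <- list(ids, NULL)
  excluded <- character()

  if (normalization == "zscored") {
    base <- t(vapply(ids, function(id)
      countSpikesInWindows(session@spikes[[id]], tr$onset_s,
                           baselineWindow) /
        windowLength(baselineWindow),
      numeric(nrow(tr))))
    mu <- rowMeans(base)
    sd_b <- apply(base, 1L, stats::sd)
    bad <- !is.finite(sd_b) | sd_b == 0
    if (any(bad)) {
      excluded <- ids[bad]
      logMsg("excluding ", sum(bad),
             " neuron(s) with zero baseline variability: ",
             paste(excluded, collapse = ", "))
    }
    rates <- (rates - mu) / sd_b
    rates <- rates[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }

  nr <- session@neurons[match(ids, session@neurons$neuron_id), ,
                        drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rate = rates),
    rowData = S4Vectors::DataFrame(nr, row.names = ids),
    colData = S4Vectors::DataFrame(tr)
  )
  S4Vectors::metadata(se) <- list(window = window,
                                  normalization = normalization,
                                  baselineWindow = baselineWindow,
                                  excluded = excluded,
                                  modality = modality,
                                  sessionId = session@sessionId)
  as(se, "RateMatrix")
}

resolveTrials <- function(session, trials, modality) {
  tt <- session@trials
  if (is.null(trials))
    return(tt[tt$modality == modality, , drop = FALSE])
  if (is.data.frame(trials)) return(trials)
  tt[tt$trial_idx %in% trials, , drop = FALSE]
}
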