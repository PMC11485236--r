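#' @import methods
NULL

REGIONS <- c("PC", "AMY", "EC", "HIP", "PHC")
MODALITIES <- c("odour", "image")
PHASES <- c("rating", "identification", "visual")
TRIAL_COLUMNS <- c("trial_idx", "modality", "stimulus_id", "onset_s",
                   "presentation_cycle", "phase", "rating",
                   "chosen_stimulus_id", "correct")

#' OdourSession: one recording session
#'
#' Container for a single session of an odour rating/identification
#' experiment: a neuron table (unit id and anatomical region), per-neuron
#' spike-time vectors (seconds from session start), and a trial table
#' covering the odour block (16 stimuli x 8 presentation cycles; the
#' odourless control, stimulus 0, may be absent) and an optional matched
#' image block. Synthetic sessions additionally carry the generating
#' ground truth.
#'
#' @slot sessionId character scalar.
#' @slot participantId character scalar.
#' @slot neurons data.frame with columns `neuron_id`, `region`
#'   (one of PC, AMY, EC, HIP, PHC).
#' @slot spikes named list of numeric vectors, one per neuron, sorted
#'   ascending, non-negative, seconds from session start.
#' @slot trials data.frame with columns `trial_idx` (0-based),
#'   `modality` ("odour"/"image"), `stimulus_id` (0-15; 0 = odourless
#'   control / grey screen), `onset_s`, `presentation_cycle` (1-8),
#'   `phase` ("rating"/"identification"/"visual"), `rating`
#'   ("liked"/"disliked"/NA), `chosen_stimulus_id` (int or NA),
#'   `correct` (logical or NA).
#' @slot groundTruth list; empty for real data, generator ground truth
#'   for synthetic sessions (see [generateSession()]).
#'
#' @seealso [readSession()], [writeSession()], [validateSession()],
#'   [generateSession()]
#' @export
setClass("OdourSession",
  representation(
    sessionId = "character",
    participantId = "character",
    neurons = "data.frame",
    spikes = "list",
    trials = "data.frame",
    groundTruth = "list"
  ),
  prototype(
    sessionId = NA_character_, participantId = NA_character_,
    neurons = data.frame(neuron_id = character(), region = character()),
    spikes = list(),
    trials = data.frame(),
    groundTruth = list()
  )
)

## Structural validity only (types, name agreement). Scientific
## invariants (block design, sorted spikes, behavioural consistency) are
## checked by validateSession(), which reports rather than throws, so
## that deliberately broken sessions can be constructed in order to test
## the validator itself.
setValidity("OdourSession", function(object) {
  msg <- character()
  if (length(object@sessionId) != 1L) msg <- c(msg, "sessionId must be length 1")
  if (!all(c("neuron_id", "region") %in% names(object@neurons)))
    msg <- c(msg, "neurons must have columns neuron_id, region")
  if (!setequal(names(object@spikes), object@neurons$neuron_id))
    msg <- c(msg, "names(spikes) must match neurons$neuron_id")
  if (nrow(object@trials) > 0L &&
      !all(TRIAL_COLUMNS %in% names(object@trials)))
    msg <- c(msg, paste("trials must have columns:",
                        paste(TRIAL_COLUMNS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OdourSession
#'
#' @param sessionId,participantId character scalars.
#' @param neurons data.frame (`neuron_id`, `region`).
#' @param spikes named list of sorted numeric spike-time vectors.
#' @param trials trial table (see [OdourSession-class]).
#' @param groundTruth optional generator ground truth list.
#' @param validate if `TRUE` (default) run [validateSession()] and stop
#'   on the first invariant violation.
#' @return An [OdourSession-class] object.
#' @export
OdourSession <- function(sessionId, participantId, neurons, spikes, trials,
                         groundTruth = list(), validate = TRUE) {
  neurons$neuron_id <- as.character(neurons$neuron_id)
  neurons$region <- as.character(neurons$region)
  spikes <- lapply(spikes, as.numeric)
  obj <- new("OdourSession", sessionId = as.character(sessionId),
             participantId = as.character(participantId),
             neurons = neurons, spikes = spikes[neurons$neuron_id],
             trials = trials, groundTruth = groundTruth)
  if (validate) {
    v <- validateSession(obj)
    if (nrow(v) > 0L)
      stop("invalid session: [", v$code[1L], "] ", v$message[1L],
           if (nrow(v) > 1L) sprintf(" (and %d further violations)",
                                     nrow(v) - 1L) else "")
  }
  obj
}

#' @describeIn OdourSession-class number of neurons
#' @param x,object an `OdourSession`
#' @export
setMethod("length", "OdourSession", function(x) nrow(x@neurons))

#' @rdname OdourSession-class
#' @export
setGeneric("neurons", function(object) standardGeneric("neurons"))
#' @describeIn OdourSession-class neuron table accessor
#' @export
setMethod("neurons", "OdourSession", function(object) object@neurons)

#' @rdname OdourSession-class
#' @export
setGeneric("spikeTimes", function(object, neuron) standardGeneric("spikeTimes"))
#' @describeIn OdourSession-class spike-time accessor (all neurons, or one)
#' @param neuron optional neuron id
#' @export
setMethod("spikeTimes", "OdourSession", function(object, neuron) {
  if (missing(neuron)) object@spikes else object@spikes[[neuron]]
})

#' @rdname OdourSession-class
#' @export
setGeneric("trials", function(object, ...) standardGeneric("trials"))
#' @describeIn OdourSession-class trial-table accessor, optionally
#'   filtered by modality
#' @param ... passed on; `modality` filters the trial table
#' @export
setMethod("trials", "OdourSession", function(object, modality = NULL) {
  tr <- object@trials
  if (!is.null(modality)) tr <- tr[tr$modality == modality, , drop = FALSE]
  tr
})

#' @rdname OdourSession-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @describeIn OdourSession-class generator ground truth (empty list for
#'   real sessions)
#' @export
setMethod("groundTruth", "OdourSession", function(object) object@groundTruth)

#' @rdname OdourSession-class
#' @export
setGeneric("hasImageBlock", function(object) standardGeneric("hasImageBlock"))
#' @describeIn OdourSession-class `TRUE` if the session contains a visual
#'   block
#' @export
setMethod("hasImageBlock", "OdourSession",
          function(object) any(object@trials$modality == "image"))

setMethod("show", "OdourSession", function(object) {
  tr <- object@trials
  cat("OdourSession '", object@sessionId, "' (participant ",
      object@participantId, ")\n", sep = "")
  tab <- table(factor(object@neurons$region, levels = REGIONS))
  cat("  ", nrow(object@neurons), " neurons: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  cat("  ", sum(tr$modality == "odour"), " odour trials",
      if (hasImageBlock(object))
        paste0(", ", sum(tr$modality == "image"), " image trials"),
      "\n", sep = "")
  if (length(object@groundTruth))
    cat("  synthetic session with ground truth\n")
})

#' RateMatrix: neurons x trials firing rates for a named time window
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"rate"` holding per-trial firing rates (Hz if raw, dimensionless if
#' baseline-z-scored), neuron metadata in `rowData` and the trial table in
#' `colData`. The response window, the normalization and (for z-scored
#' matrices) the baseline window and any excluded neurons are kept in
#' `metadata()`.
#'
#' Z-scoring: per neuron, \eqn{z_t = (r_t - \mu_b)/\sigma_b}, where
#' \eqn{r_t} is the response-window rate on trial \eqn{t} and
#' \eqn{\mu_b, \sigma_b} are the mean and sample standard deviation of the
#' per-trial baseline-window rates across the selected trials. Neurons
#' with zero baseline variability cannot be z-scored and are dropped from
#' the matrix (listed in `metadata()$excluded`).
#'
#' @seealso [computeRateMatrix()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("RateMatrix", contains = "SummarizedExperiment")

setValidity("RateMatrix", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (!"rate" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rate' is required")
  if (is.null(md$normalization) ||
      !md$normalization %in% c("raw", "zscored"))
    msg <- c(msg, "metadata normalization must be 'raw' or 'zscored'")
  else {
    v <- SummarizedExperiment::assay(object, "rate")
    if (md$normalization == "raw" && length(v) && min(v) < 0)
      msg <- c(msg, "raw rates must be non-negative")
    if (md$normalization == "zscored" && length(v) && !all(is.finite(v)))
      msg <- c(msg, "z-scored rates must be finite")
  }
  if (is.null(md$window)) msg <- c(msg, "metadata window is required")
  if (length(msg)) msg else TRUE
})

#' @rdname RateMatrix-class
#' @param object a `RateMatrix`
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))
#' @describeIn RateMatrix-class the neurons x trials rate matrix
#' @export
setMethod("rateValues", "RateMatrix",
          function(object) SummarizedExperiment::assay(object, "rate"))

#' @rdname RateMatrix-class
#' @export
setGeneric("rateNormalization",
           function(object) standardGeneric("rateNormalization"))
#' @describeIn RateMatrix-class `"raw"` or `"zscored"`
#' @export
setMethod("rateNormalization", "RateMatrix",
          function(object) S4Vectors::metadata(object)$normalization)

#' @rdname RateMatrix-class
#' @export
setGeneric("rateWindow", function(object) standardGeneric("rateWindow"))
#' @describeIn RateMatrix-class response window `c(start, end)` in
#'   seconds relative to trial onset (half-open)
#' @export
setMethod("rateWindow", "RateMatrix",
          function(object) S4Vectors::metadata(object)$window)

#' @rdname RateMatrix-class
#' @export
setGeneric("stimulusIds", function(object) standardGeneric("stimulusIds"))
#' @describeIn RateMatrix-class per-trial stimulus labels
#' @export
setMethod("stimulusIds", "RateMatrix",
          function(object) SummarizedExperiment::colData(object)$stimulus_id)

#' @rdname RateMatrix-class
#' @export
setGeneric("neuronRegions", function(object) standardGeneric("neuronRegions"))
#' @describeIn RateMatrix-class per-neuron anatomical region labels
#' @export
setMethod("neuronRegions", "RateMatrix",
          function(object) SummarizedExperiment::rowData(object)$region)

#' @rdname RateMatrix-class
#' @export
setGeneric("excludedNeurons",
           function(object) standardGeneric("excludedNeurons"))
#' @describeIn RateMatrix-class ids of neurons dropped by the
#'   zero-baseline-variance rule
#' @export
setMethod("excludedNeurons", "RateMatrix", function(object) {
  ex <- S4Vectors::metadata(object)$excluded
  if (is.null(ex)) character() else ex
})

setMethod("show", "RateMatrix", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("RateMatrix: %d neurons x %d trials, %s, window [%g, %g) s\n",
              nrow(object), ncol(object), md$normalization,
              md$window[1L], md$window[2L]))
  if (length(excludedNeurons(object)))
    cat("  excluded (zero baseline sd):",
        paste(excludedNeurons(object), collapse = ", "), "\n")
})

#' DecodingResult: outcome of a permutation-tested decoding analysis
#'
#' @slot accuracy observed mean decoding accuracy (fraction correct).
#' @slot subsampleAccuracies per-subsample-run accuracies.
#' @slot nullAccuracies surrogate distribution of mean accuracies from
#'   label-permuted decodings.
#' @slot p permutation p-value, add-one percentile rule:
#'   \eqn{p = (1 + \#\{null \ge observed\})/(1 + n_{perm})}.
#' @slot config the decoding configuration used (see [decodingConfig()]).
#' @slot region anatomical region decoded.
#' @slot details list of analysis-specific extras (e.g. direction for
#'   cross-modal decoding, skip reasons).
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", subsampleAccuracies = "numeric",
                 nullAccuracies = "numeric", p = "numeric",
                 config = "list", region = "character", details = "list"),
  prototype(accuracy = NA_real_, subsampleAccuracies = numeric(),
            nullAccuracies = numeric(), p = NA_real_, config = list(),
            region = NA_character_, details = list()))

setValidity("DecodingResult", function(object) {
  msg <- character()
  acc <- c(object@accuracy, object@subsampleAccuracies,
           object@nullAccuracies)
  acc <- acc[!is.na(acc)]
  if (length(acc) && (min(acc) < 0 || max(acc) > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    msg <- c(msg, "permutation p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname DecodingResult-class
#' @param object a `DecodingResult`
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @describeIn DecodingResult-class observed mean accuracy
#' @export
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)

#' @rdname DecodingResult-class
#' @export
setGeneric("nullAccuracies",
           function(object) standardGeneric("nullAccuracies"))
#' @describeIn DecodingResult-class surrogate accuracy distribution
#' @export
setMethod("nullAccuracies", "DecodingResult",
          function(object) object@nullAccuracies)

#' @rdname DecodingResult-class
#' @export
setGeneric("permutationP", function(object) standardGeneric("permutationP"))
#' @describeIn DecodingResult-class permutation p-value (add-one rule)
#' @export
setMethod("permutationP", "DecodingResult", function(object) object@p)

setMethod("show", "DecodingResult", function(object) {
  if (is.na(object@accuracy)) {
    cat("DecodingResult (skipped):",
        object@details$skipped %||% "no result", "\n")
    return(invisible(NULL))
  }
  chance <- 1 / (object@config$nClasses %||% 16)
  cat(sprintf("DecodingResult [%s]: accuracy %.1f%% (chance %.2f%%)\n",
              object@region, 100 * object@accuracy, 100 * chance))
  if (length(object@nullAccuracies))
    cat(sprintf("  null mean %.2f%% over %d permutations, p = %.4g\n",
                100 * mean(object@nullAccuracies),
                length(object@nullAccuracies), object@p))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
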