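#' Configuration for the synthetic session generator
#'
#' Defines the statistical structure of a simulated recording session:
#' an odour block of 16 stimuli (15 odours plus the odourless control,
#' stimulus 0) x 8 presentation cycles presented in pseudorandom order at
#' a ~19.4 s inter-trial interval (rating task on cycles 1-4,
#' 4-alternative identification on cycles 5-8), and an optional matched
#' 16-image x 8 visual block at 1 s exposures. Neurons fire as
#' inhomogeneous Poisson processes: a log-normal baseline rate, and, for
#' stimulus-tuned neurons, a multiplicative response plateau starting at
#' a region-specific latency.
#'
#' The response rate of a tuned neuron to a preferred stimulus on
#' presentation cycle \eqn{c} is
#' \deqn{baseline \times (1 + gain \times v_{mod}) \times d^{c-1}}
#' (times `pcFirstTrialBoost` on cycle 1 for piriform neurons), where
#' \eqn{v_{mod} = 1 + \beta_v v_k} for amygdala neurons (valence-gain
#' modulation) and 1 elsewhere, and \eqn{d} is the per-presentation
#' repetition-suppression decay. Control trials evoke
#' \eqn{baseline \times (1 + gain \times controlResponseFactor)} in
#' odour-tuned neurons. Ratings are drawn liked with probability
#' `plogis(2 * v_k)`; identification is correct with probability `pId`,
#' otherwise a uniformly random distractor is chosen.
#'
#' @param regionCounts named integer vector of neurons per region;
#'   defaults approximate per-session unit yields (PC 16, AMY 23, EC 21,
#'   HIP 23, PHC 16).
#' @param tunedFraction named numeric vector, fraction of stimulus-tuned
#'   neurons per region (defaults PC 0.40, AMY 0.20, EC 0.14, HIP 0.12,
#'   PHC 0.05).
#' @param baselineLogMedian,baselineLogSd log-normal baseline firing-rate
#'   distribution (median 2 Hz, log-sd 0.5).
#' @param tuningBreadth named numeric vector, mean number of preferred
#'   odours per tuned neuron (piriform broad, amygdala/hippocampus
#'   narrow).
#' @param gainMean,gainShape gamma response-gain distribution (mean 2,
#'   shape 2).
#' @param latency named numeric vector, response latency (s) per region
#'   (PC/AMY 0.2 s, EC/HIP 0.8 s).
#' @param responseDuration response plateau duration (s), default 1.5.
#' @param controlResponseFactor gain factor evoked by the odourless
#'   control in odour-tuned neurons, in \[0, 1); default 0.3.
#' @param suppressionDecay multiplicative decay d per presentation cycle,
#'   in (0, 1\]; default 0.95.
#' @param pcFirstTrialBoost extra multiplicative gain on the first
#'   presentation for piriform neurons, >= 1; default 1.5.
#' @param valence numeric length-15 vector of odour valence scores in
#'   \[-1, 1\].
#' @param betaValence amygdala valence gain \eqn{\beta_v}; default 0.5.
#' @param pId probability of correct odour identification; default 0.741.
#' @param imageBlock include the visual block; default `TRUE`.
#' @param crossModalOverlap fraction of odour-tuned neurons that are also
#'   tuned to the congruent images; default 0.2.
#' @param imageOnlyTunedFraction fraction of remaining neurons tuned to
#'   images only; default 0.05.
#' @param includeControl include the odourless control stimulus (off
#'   mirrors the one session recorded without it); default `TRUE`.
#' @param interTrialInterval,interTrialIntervalSd odour-block inter-trial
#'   interval mean/sd in seconds (19.4 +/- 0.4).
#' @param imageInterTrialInterval visual-block inter-trial interval (s).
#' @param imageLatency,imageResponseDuration visual response timing (s).
#' @return A `SynthConfig` list.
#' @seealso [generateSession()]
#' @export
synthConfig <- function(regionCounts = c(PC = 16, AMY = 23, EC = 21,
                                         HIP = 23, PHC = 16),
                        tunedFraction = c(PC = 0.40, AMY = 0.20, EC = 0.14,
                                          HIP = 0.12, PHC = 0.05),
                        baselineLogMedian = 2, baselineLogSd = 0.5,
                        tuningBreadth = c(PC = 4, AMY = 1.5, EC = 2,
                                          HIP = 1.5, PHC = 1.5),
                        gainMean = 2, gainShape = 2,
                        latency = c(PC = 0.2, AMY = 0.2, EC = 0.8,
                                    HIP = 0.8, PHC = 0.8),
                        responseDuration = 1.5,
                        controlResponseFactor = 0.3,
                        suppressionDecay = 0.95,
                        pcFirstTrialBoost = 1.5,
                        valence = seq(-0.6, 1, length.out = 15),
                        betaValence = 0.5,
                        pId = 0.741,
                        imageBlock = TRUE,
                        crossModalOverlap = 0.2,
                        imageOnlyTunedFraction = 0.05,
                        includeControl = TRUE,
                        interTrialInterval = 19.4,
                        interTrialIntervalSd = 0.4,
                        imageInterTrialInterval = 3,
                        imageLatency = 0.2,
                        imageResponseDuration = 0.8) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$tunedFraction >= 0 & cfg$tunedFraction <= 1),
            cfg$controlResponseFactor >= 0, cfg$controlResponseFactor < 1,
            cfg$suppressionDecay > 0, cfg$suppressionDecay <= 1,
            cfg$pcFirstTrialBoost >= 1,
            length(cfg$valence) == 15,
            all(abs(cfg$valence) <= 1),
            cfg$crossModalOverlap >= 0, cfg$crossModalOverlap <= 1,
            cfg$pId >= 0, cfg$pId <= 1,
            cfg$baselineLogMedian > 0, cfg$gainMean > 0)
  stopifnot(setequal(names(cfg$regionCounts), REGIONS))
  class(cfg) <- "SynthConfig"
  cfg
}

#' Simulate a piecewise-constant-rate (inhomogeneous) Poisson spike train
#'
#' Draws spike times from an inhomogeneous Poisson process whose rate is
#' constant on each segment `[breaks[i], breaks[i+1])`. Within each
#' segment the spike count is Poisson(rate x length) and spike times are
#' uniform; segments are independent.
#'
#' @param rates non-negative finite rates (Hz), one per segment.
#' @param breaks ascending segment boundaries (s),
#'   `length(breaks) == length(rates) + 1`.
#' @param seed optional seed; if omitted the current RNG stream is used
#'   (as when called from [generateSession()]).
#' @return Sorted numeric vector of spike times.
#' @examples
#' simulatePoissonSpikes(c(2, 8), c(0, 10, 20), seed = 1)
#' @export
simulatePoissonSpikes <- function(rates, breaks, seed = NULL) {
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  if (length(breaks) != length(rates) + 1L || is.unsorted(breaks))
    stop("breaks must be ascending with length(rates) + 1 elements")
  draw <- function() {
    lens <- diff(breaks)
    n <- stats::rpois(length(rates), rates * lens)
    if (sum(n) == 0L) return(numeric())
    sort(stats::runif(sum(n),
                      min = rep(breaks[-length(breaks)], n),
                      max = rep(breaks[-1L], n)))
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Generate a seeded synthetic session with ground truth
#'
#' Produces an [OdourSession-class] whose statistical structure matches
#' the experimental design assumed by the analysis pipeline (see
#' [synthConfig()]) together with the generating ground truth, enabling
#' parameter-recovery and calibration tests with no external data. The
#' same `(config, seed)` pair always yields a byte-identical session.
#'
#' @param config a [synthConfig()] list.
#' @param seed integer seed; mandatory.
#' @return An [OdourSession-class]; `groundTruth()` holds per-neuron
#'   tuning flags, preferred stimulus sets, gains, the odour valence
#'   scores and the key generator parameters.
#' @examples
#' s <- generateSession(synthConfig(regionCounts = c(PC = 4, AMY = 4,
#'   EC = 0, HIP = 0, PHC = 0), imageBlock = FALSE), seed = 7)
#' table(trials(s, "odour")$stimulus_id)
#' @export
generateSession <- function(config = synthConfig(), seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(config, "SynthConfig"))
  withSeed(seed, generateSessionImpl(config, seed))
}

generateSessionImpl <- function(cfg, seed) {
  odourIds <- 1:15
  stimIds <- if (cfg$includeControl) 0:15 else odourIds
  nStim <- length(stimIds)

  ## --- odour-block trial order: per-cycle permutations, no immediate
  ## repeats across the whole sequence (pseudorandom order)
  order_ <- pseudorandomOrder(stimIds, nCycles = 8L)
  nOdourTrials <- nrow(order_)
  iti <- pmax(stats::rnorm(nOdourTrials, cfg$interTrialInterval,
                           cfg$interTrialIntervalSd), 5)
  onsets <- 10 + cumsum(iti)   # >= 5 s pre-trial baseline before trial 1

  phase <- ifelse(order_$cycle <= 4L, "rating", "identification")
  vk <- c(0, cfg$valence)      # index by stimulus_id + 1; control v = 0
  rating <- rep(NA_character_, nOdourTrials)
  isRate <- phase == "rating"
  pLike <- stats::plogis(2 * vk[order_$stimulus + 1L])
  rating[isRate] <- ifelse(stats::runif(sum(isRate)) < pLike[isRate],
                           "liked", "disliked")
  chosen <- rep(NA_integer_, nOdourTrials)
  isId <- phase == "identification"
  for (i in which(isId)) {
    s <- order_$stimulus[i]
    chosen[i] <- if (stats::runif(1) < cfg$pId) s
      else sample(setdiff(stimIds, s), 1L)
  }
  odourTrials <- data.frame(
    trial_idx = seq_len(nOdourTrials) - 1L, modality = "odour",
    stimulus_id = order_$stimulus, onset_s = onsets,
    presentation_cycle = order_$cycle, phase = phase, rating = rating,
    chosen_stimulus_id = chosen,
    correct = ifelse(isId, chosen == order_$stimulus, NA)
  )

  ## --- optional image block after the odour block
  imageTrials <- NULL
  if (cfg$imageBlock) {
    iorder <- pseudorandomOrder(stimIds, nCycles = 8L)
    ionsets <- max(onsets) + 30 +
      cumsum(rep(cfg$imageInterTrialInterval, nrow(iorder)))
    imageTrials <- data.frame(
      trial_idx = nOdourTrials + seq_len(nrow(iorder)) - 1L,
      modality = "image", stimulus_id = iorder$stimulus,
      onset_s = ionsets, presentation_cycle = iorder$cycle,
      phase = "visual", rating = NA_character_,
      chosen_stimulus_id = NA_integer_, correct = NA
    )
  }
  trialTable <- rbind(odourTrials, imageTrials)
  sessionEnd <- max(trialTable$onset_s) + 10

  ## --- neurons
  counts <- cfg$regionCounts[REGIONS]
  counts <- counts[counts > 0]
  region <- rep(names(counts), counts)
  n <- length(region)
  ids <- sprintf("n%03d_%s", seq_len(n), region)
  baseline <- stats::rlnorm(n, meanlog = log(cfg$baselineLogMedian),
                            sdlog = cfg$baselineLogSd)
  tuned <- stats::runif(n) < cfg$tunedFraction[region]
  gain <- stats::rgamma(n, shape = cfg$gainShape,
                        scale = cfg$gainMean / cfg$gainShape)
  nPref <- pmin(1L + stats::rpois(n, pmax(cfg$tuningBreadth[region] - 1, 0)),
                15L)
  preferred <- lapply(seq_len(n), function(i)
    if (tuned[i]) sort(sample(odourIds, nPref[i])) else integer())
  imageTuned <- tuned & stats::runif(n) < cfg$crossModalOverlap
  imageOnly <- !tuned & stats::runif(n) < cfg$imageOnlyTunedFraction
  imagePreferred <- lapply(seq_len(n), function(i) {
    if (imageTuned[i]) preferred[[i]]
    else if (imageOnly[i]) sort(sample(odourIds, nPref[i]))
    else integer()
  })

  ## --- spike trains: piecewise-constant rate profile per neuron
  spikes <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    seg <- neuronResponseSegments(i, cfg, region[i], baseline[i], gain[i],
                                  tuned[i], preferred[[i]],
                                  imageTuned[i] || imageOnly[i],
                                  imagePreferred[[i]],
                                  odourTrials, imageTrials, vk)
    prof <- buildRateProfile(baseline[i], seg, sessionEnd)
    spikes[[ids[i]]] <- simulatePoissonSpikes(prof$rates, prof$breaks)
  }

  gt <- list(
    seed = seed,
    neurons = data.frame(
      neuron_id = ids, region = region, baseline_hz = baseline,
      tuned = tuned, gain = gain,
      preferred = vapply(preferred, paste, character(1L), collapse = ","),
      image_tuned = imageTuned | imageOnly,
      image_preferred = vapply(imagePreferred, paste, character(1L),
                               collapse = ",")
    ),
    valence = cfg$valence,
    params = list(suppression_decay = cfg$suppressionDecay,
                  pc_first_trial_boost = cfg$pcFirstTrialBoost,
                  beta_valence = cfg$betaValence,
                  control_response_factor = cfg$controlResponseFactor,
                  p_id = cfg$pId,
                  cross_modal_overlap = cfg$crossModalOverlap)
  )
  OdourSession(sessionId = sprintf("synth-seed%d", seed),
               participantId = sprintf("synthP%02d", seed %% 100),
               neurons = data.frame(neuron_id = ids, region = region),
               spikes = spikes, trials = trialTable, groundTruth = gt,
               validate = TRUE)
}

## per-cycle seeded permutations; resample a cycle until its first
## stimulus differs from the previous cycle's last (no immediate repeats)
pseudorandomOrder <- function(stimIds, nCycles) {
  out <- vector("list", nCycles)
  last <- NA_integer_
  for (cy in seq_len(nCycles)) {
    repeat {
      perm <- sample(stimIds)
      if (is.na(last) || perm[1L] != last) break
    }
    last <- perm[length(perm)]
    out[[cy]] <- data.frame(stimulus = perm, cycle = cy)
  }
  do.call(rbind, out)
}

## response segments (start, end, rate) for one neuron over both blocks
neuronResponseSegments <- function(i, cfg, region, baseline, gain, tuned,
                                   preferred, imgTuned, imgPreferred,
                                   odourTrials, imageTrials, vk) {
  seg <- list()
  if (tuned) {
    lat <- cfg$latency[region]
    for (j in seq_len(nrow(odourTrials))) {
      s <- odourTrials$stimulus_id[j]
      cyc <- odourTrials$presentation_cycle[j]
      rate <- NA_real_
      if (s %in% preferred) {
        vmod <- if (region == "AMY") 1 + cfg$betaValence * vk[s + 1L] else 1
        rate <- baseline * (1 + gain * vmod) *
          cfg$suppressionDecay^(cyc - 1L)
        if (region == "PC" && cyc == 1L) rate <- rate * cfg$pcFirstTrialBoost
      } else if (s == 0L) {
        rate <- baseline * (1 + gain * cfg$controlResponseFactor)
      }
      if (!is.na(rate))
        seg[[length(seg) + 1L]] <- c(odourTrials$onset_s[j] + lat,
                                     odourTrials$onset_s[j] + lat +
                                       cfg$responseDuration, rate)
    }
  }
  if (imgTuned && !is.null(imageTrials)) {
    for (j in seq_len(nrow(imageTrials))) {
      s <- imageTrials$stimulus_id[j]
      if (!s %in% imgPreferred) next
      cyc <- imageTrials$presentation_cycle[j]
      rate <- baseline * (1 + gain) * cfg$suppressionDecay^(cyc - 1L)
      seg[[length(seg) + 1L]] <-
        c(imageTrials$onset_s[j] + cfg$imageLatency,
          imageTrials$onset_s[j] + cfg$imageLatency +
            cfg$imageResponseDuration, rate)
    }
  }
  if (length(seg)) do.call(rbind, seg) else NULL
}

## interleave non-overlapping response segments into a full
## piecewise-constant profile over [0, sessionEnd)
buildRateProfile <- function(baseline, seg, sessionEnd) {
  if (is.null(seg))
    return(list(rates = baseline, breaks = c(0, sessionEnd)))
  seg <- seg[order(seg[, 1L]), , drop = FALSE]
  breaks <- 0
  rates <- numeric()
  for (j in seq_len(nrow(seg))) {
    if (seg[j, 1L] > breaks[length(breaks)]) {
      rates <- c(rates, baseline)
      breaks <- c(breaks, seg[j, 1L])
    }
    rates <- c(rates, seg[j, 3L])
    breaks <- c(breaks, seg[j, 2L])
  }
  if (sessionEnd > breaks[length(breaks)]) {
    rates <- c(rates, baseline)
    breaks <- c(breaks, sessionEnd)
  }
  list(rates = rates, breaks = breaks)
}
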