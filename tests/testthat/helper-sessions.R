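# Builders for small deterministic fixtures used across the suite.

# A minimal hand-built session: `rates` is a named list mapping
# neuron_id -> constant firing rate (Hz); spikes are laid on a regular
# grid so per-window counts are exact.
makeConstantRateSession <- function(rates = c(nA = 4, nB = 2),
                                    nTrials = 8, iti = 20,
                                    region = "PC") {
  onsets <- 10 + iti * (seq_len(nTrials) - 1)
  dur <- max(onsets) + 10
  spikes <- lapply(rates, function(r) {
    if (r == 0) return(numeric())
    seq(0, dur, by = 1 / r)
  })
  names(spikes) <- names(rates)
  trials <- data.frame(
    trial_idx = seq_len(nTrials) - 1L, modality = "odour",
    stimulus_id = rep(1:2, length.out = nTrials), onset_s = onsets,
    presentation_cycle = rep(1:(nTrials %/% 2), each = 2,
                             length.out = nTrials),
    phase = "rating", rating = "liked",
    chosen_stimulus_id = NA_integer_, correct = NA
  )
  OdourSession("const", "p1",
               neurons = data.frame(neuron_id = names(rates),
                                    region = region),
               spikes = spikes, trials = trials, validate = FALSE)
}

# Small generator configuration for fast tests.
smallConfig <- function(...) {
  defaults <- list(regionCounts = c(PC = 6, AMY = 6, EC = 0, HIP = 0,
                                    PHC = 0),
                   imageBlock = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthConfig, args)
}

emptyTrials <- function() {
  data.frame(trial_idx = integer(), modality = character(),
             stimulus_id = integer(), onset_s = numeric(),
             presentation_cycle = integer(), phase = character(),
             rating = character(), chosen_stimulus_id = integer(),
             correct = logical())
}

# Brute-force spike count in [onset+w1, onset+w2).
bruteCount <- function(sp, onset, w) sum(sp >= onset + w[1] & sp < onset + w[2])

# Brute-force one-way ANOVA F via stats::aov (the independent oracle).
aovF <- function(y, g) {
  fit <- summary(stats::aov(y ~ factor(g)))[[1]]
  c(F = fit[1, "F value"], p = fit[1, "Pr(>F)"])
}

# Brute-force max-correlation prediction for one test vector.
bruteMaxCor <- function(train, labels, v) {
  cls <- sort(unique(labels))
  cors <- vapply(cls, function(cl)
    stats::cor(v, rowMeans(train[, labels == cl, drop = FALSE])),
    numeric(1))
  cls[which.max(cors)]
}
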