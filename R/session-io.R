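#' Validate a session against the data-model invariants
#'
#' Checks every invariant of the session data model and returns the
#' violations found; it reports and never throws, so it can audit
#' deliberately malformed sessions. Each violation carries a
#' machine-readable `code`, a human-readable `message`, and, where a
#' specific row is at fault, its identifier.
#'
#' Checked invariants: spike times finite, non-negative and sorted
#' ascending per neuron; every spike vector belongs to a listed neuron;
#' regions drawn from PC/AMY/EC/HIP/PHC; trial indices unique; stimulus
#' ids in 0-15; a block design of 16 distinct stimuli x 8 presentation
#' cycles (the odourless control may be absent, giving 15 x 8); strictly
#' increasing onsets within each block; rating set on rating-phase
#' trials; chosen stimulus set on identification-phase trials with
#' `correct == (chosen_stimulus_id == stimulus_id)`.
#'
#' @param session an [OdourSession-class].
#' @return data.frame with columns `code`, `message`, `row` (NA when not
#'   row-specific); zero rows iff all invariants hold.
#' @examples
#' cfg <- synthConfig(regionCounts = c(PC = 2, AMY = 2, EC = 0, HIP = 0,
#'                                     PHC = 0), imageBlock = FALSE)
#' s <- generateSession(cfg, seed = 1)
#' nrow(validateSession(s))  # 0
#' @export
validateSession <- function(session) {
  bad <- list()
  flag <- function(code, message, row = NA_integer_)
    bad[[length(bad) + 1L]] <<- data.frame(code = code, message = message,
                                           row = row)
  nr <- session@neurons
  tr <- session@trials

  unknown <- setdiff(unique(nr$region), REGIONS)
  if (length(unknown))
    flag("UNKNOWN_REGION", paste("unknown region(s):",
                                 paste(unknown, collapse = ", ")))
  if (anyDuplicated(nr$neuron_id))
    flag("DUPLICATE_NEURON_ID", "neuron ids are not unique")
  orphan <- setdiff(names(session@spikes), nr$neuron_id)
  if (length(orphan))
    flag("SPIKE_NEURON_UNKNOWN",
         paste("spikes for unlisted neuron(s):",
               paste(orphan, collapse = ", ")))
  for (id in intersect(names(session@spikes), nr$neuron_id)) {
    sp <- session@spikes[[id]]
    if (length(sp) == 0L) next
    if (!all(is.finite(sp)))
      flag("NONFINITE_SPIKE_TIME", paste("non-finite spike time, neuron", id))
    else {
      if (min(sp) < 0)
        flag("NEGATIVE_SPIKE_TIME", paste("negative spike time, neuron", id))
      if (is.unsorted(sp))
        flag("UNSORTED_SPIKES", paste("spike times not ascending, neuron", id))
    }
  }

  if (nrow(tr) == 0L) return(collectViolations(bad))
  missing <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing)) {
    flag("MISSING_COLUMN", paste("trial table lacks:",
                                 paste(missing, collapse = ", ")))
    return(collectViolations(bad))
  }
  dup <- which(duplicated(tr$trial_idx))
  if (length(dup))
    flag("DUPLICATE_TRIAL_IDX", "duplicated trial_idx", dup[1L])
  badStim <- which(!tr$stimulus_id %in% 0:15)
  if (length(badStim))
    flag("BAD_STIMULUS_ID", "stimulus_id outside 0-15", badStim[1L])
  badMod <- which(!tr$modality %in% MODALITIES)
  if (length(badMod))
    flag("BAD_MODALITY", "modality must be 'odour' or 'image'", badMod[1L])

  for (mod in intersect(MODALITIES, unique(tr$modality))) {
    blk <- tr[tr$modality == mod, , drop = FALSE]
    tab <- table(blk$stimulus_id)
    nStim <- length(tab)
    controlAbsent <- !"0" %in% names(tab)
    okDesign <- (nStim == 16L || (nStim == 15L && controlAbsent)) &&
      all(tab == 8L)
    if (!okDesign)
      flag("BLOCK_DESIGN",
           sprintf("%s block is not 16 (or 15 w/o control) stimuli x 8 presentations", mod))
    if (any(!blk$presentation_cycle %in% 1:8))
      flag("BAD_CYCLE", paste(mod, "presentation_cycle outside 1-8"))
    ord <- blk[order(blk$trial_idx), , drop = FALSE]
    if (is.unsorted(ord$onset_s, strictly = TRUE))
      flag("NONINCREASING_ONSETS",
           paste(mod, "block onsets not strictly increasing"))
  }

  rat <- which(tr$phase == "rating" & tr$modality == "odour" &
                 (is.na(tr$rating) | !tr$rating %in% c("liked", "disliked")))
  if (length(rat))
    flag("RATING_MISSING", "rating-phase trial without liked/disliked rating",
         rat[1L])
  idn <- which(tr$phase == "identification" & is.na(tr$chosen_stimulus_id))
  if (length(idn))
    flag("CHOICE_MISSING",
         "identification-phase trial without chosen_stimulus_id", idn[1L])
  chk <- which(tr$phase == "identification" & !is.na(tr$chosen_stimulus_id) &
                 (is.na(tr$correct) |
                    tr$correct != (tr$chosen_stimulus_id == tr$stimulus_id)))
  if (length(chk))
    flag("CORRECT_MISMATCH",
         "correct != (chosen_stimulus_id == stimulus_id)", chk[1L])

  collectViolations(bad)
}

collectViolations <- function(bad) {
  if (length(bad) == 0L)
    return(data.frame(code = character(), message = character(),
                      row = integer()))
  do.call(rbind, bad)
}

#' Write a session to a directory of delimited text files
#'
#' Serializes an [OdourSession-class] as `neurons.tsv` (neuron_id, region,
#' n_spikes), `spikes.tsv` (neuron_id, spike_time_s), `trials.tsv` (the
#' trial table) and `session.json` (ids, format version, and for synthetic
#' sessions the generator ground truth). [readSession()] inverts the
#' format exactly; a write/read/write cycle is byte-identical.
#'
#' @param session a valid [OdourSession-class].
#' @param path directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", path)
  nr <- session@neurons
  nr$n_spikes <- vapply(session@spikes[nr$neuron_id], length, integer(1L))
  writeTsv(nr[, c("neuron_id", "region", "n_spikes")],
           file.path(path, "neurons.tsv"))
  allSpikes <- unlist(session@spikes[nr$neuron_id], use.names = FALSE)
  sp <- data.frame(
    neuron_id = rep(nr$neuron_id, nr$n_spikes),
    spike_time_s = if (is.null(allSpikes)) numeric() else allSpikes
  )
  writeTsv(sp, file.path(path, "spikes.tsv"))
  trdf <- if (all(TRIAL_COLUMNS %in% names(session@trials)))
    session@trials[, TRIAL_COLUMNS] else emptyTrialTable()
  writeTsv(trdf, file.path(path, "trials.tsv"))
  meta <- list(session_id = session@sessionId,
               participant_id = session@participantId,
               format_version = "1.0")
  if (length(session@groundTruth)) meta$ground_truth <- session@groundTruth
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

emptyTrialTable <- function() {
  data.frame(trial_idx = integer(), modality = character(),
             stimulus_id = integer(), onset_s = numeric(),
             presentation_cycle = integer(), phase = character(),
             rating = character(), chosen_stimulus_id = integer(),
             correct = logical())
}

writeTsv <- function(df, file) {
  ## doubles are written with 17 significant digits so that a
  ## write -> read -> write cycle is byte-identical
  for (j in seq_along(df))
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read a session from a directory written by [writeSession()]
#'
#' Loads and fully validates a session. Unknown columns in the TSV files
#' are ignored with a logged warning; any data-model invariant violation
#' is an error naming the offending row.
#'
#' @param path directory containing `neurons.tsv`, `spikes.tsv`,
#'   `trials.tsv` and `session.json`.
#' @return A validated [OdourSession-class].
#' @export
readSession <- function(path) {
  files <- c("neurons.tsv", "spikes.tsv", "trials.tsv", "session.json")
  for (f in files)
    if (!file.exists(file.path(path, f)))
      stop("missing file: ", file.path(path, f))
  nr <- readTsv(file.path(path, "neurons.tsv"),
                c(neuron_id = "character", region = "character",
                  n_spikes = "integer"))
  sp <- readTsv(file.path(path, "spikes.tsv"),
                c(neuron_id = "character", spike_time_s = "numeric"))
  tr <- readTsv(file.path(path, "trials.tsv"),
                c(trial_idx = "integer", modality = "character",
                  stimulus_id = "integer", onset_s = "numeric",
                  presentation_cycle = "integer", phase = "character",
                  rating = "character", chosen_stimulus_id = "integer",
                  correct = "logical"))
  meta <- jsonlite::fromJSON(file.path(path, "session.json"),
                             simplifyVector = TRUE)
  spikes <- split(sp$spike_time_s, factor(sp$neuron_id,
                                          levels = nr$neuron_id))
  spikes <- lapply(spikes, as.numeric)
  gt <- meta$ground_truth
  if (is.null(gt)) gt <- list()
  OdourSession(sessionId = meta$session_id,
               participantId = meta$participant_id,
               neurons = nr[, c("neuron_id", "region")],
               spikes = spikes, trials = tr, groundTruth = gt,
               validate = TRUE)
}

readTsv <- function(file, colClasses) {
  header <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1L]]
  extra <- setdiff(header, names(colClasses))
  if (length(extra))
    logMsg("ignoring unknown column(s) in ", basename(file), ": ",
           paste(extra, collapse = ", "))
  classes <- ifelse(header %in% names(colClasses),
                    colClasses[header], "NULL")
  df <- utils::read.delim(file, colClasses = classes,
                          na.strings = "NA", stringsAsFactors = FALSE)
  df[, intersect(names(colClasses), names(df)), drop = FALSE]
}
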