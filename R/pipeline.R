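#' Pipeline configuration
#'
#' Orchestration settings for the end-to-end analysis: which stages to
#' run, their parameters, and a master seed. Every stochastic stage
#' derives an explicit sub-seed from `seed`, so reruns with an identical
#' configuration are byte-identical. The configuration is echoed into
#' every output file.
#'
#' @param sessions list of [OdourSession-class] objects, or a character
#'   vector of session directories for [readSession()].
#' @param outDir output directory, or `NULL` to return results only.
#' @param stages character subset of
#'   `c("detect", "decode", "sparseness", "suppression", "valence",
#'   "stats")`.
#' @param alpha selection alpha for modulated neurons.
#' @param decoding a [decodingConfig()]; its seed is overridden by
#'   `seed`.
#' @param referenceValence optional length-15 valence scores for the
#'   valence correlation.
#' @param seed master seed (mandatory).
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(sessions, outDir = NULL,
                           stages = c("detect", "decode", "sparseness",
                                      "suppression", "valence", "stats"),
                           alpha = 0.05,
                           decoding = decodingConfig(nSubsampleRuns = 50,
                                                     nPermutations = 200),
                           referenceValence = NULL, seed) {
  if (missing(seed)) stop("a master seed is required")
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order -- modulated-neuron
#' detection, regional pseudopopulation decoding, population sparseness,
#' repetition suppression, valence analysis, and summary count
#' statistics -- over a cohort of sessions. Each stage's tabular output
#' is written to `outDir` (TSV/JSON with the configuration echoed) when
#' one is configured. A stage failure aborts with the stage name; rerun
#' with the same configuration and seed reproduces identical numbers.
#'
#' @param config a [pipelineConfig()].
#' @return A report bundle: named list with one element per completed
#'   stage plus `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  sessions <- config$sessions
  if (is.character(sessions)) sessions <- lapply(sessions, readSession)
  if (is(sessions, "OdourSession")) sessions <- list(sessions)
  bundle <- list(config = config)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## z-scored rate matrices per session, reused by several stages
  zrates <- lapply(sessions, computeRateMatrix,
                   normalization = "zscored", modality = "odour")

  bundle$detect <- stage("detect", {
    res <- do.call(rbind, lapply(seq_along(zrates), function(i) {
      df <- detectModulatedNeurons(zrates[[i]], alpha = config$alpha)
      df$session <- sessions[[i]]@sessionId
      df
    }))
    res
  })
  ## neuron ids are only unique within a session: filter per session
  modulatedIn <- function(sessionId) {
    if (is.null(bundle$detect)) return(NULL)
    d <- bundle$detect
    d$neuron_id[d$modulated & d$session == sessionId]
  }

  bundle$decode <- stage("decode", {
    regions <- intersect(REGIONS,
                         unique(unlist(lapply(sessions, function(s)
                           s@neurons$region))))
    out <- list()
    for (rg in regions) {
      dc <- config$decoding
      dc$seed <- config$seed + match(rg, REGIONS)
      pool <- poolRegionResponses(sessions, rg, window = dc$window)
      dc$nNeurons <- min(dc$nNeurons, length(pool))
      if (length(pool) < 2L) next
      out[[rg]] <- populationDecodingWithNull(pool, rg, dc)
    }
    out
  })

  bundle$sparseness <- stage("sparseness", {
    ## per session: neurons x 15 matrix of trial-averaged odour responses,
    ## then pool neurons across sessions per region
    raws <- lapply(sessions, computeRateMatrix, normalization = "raw",
                   modality = "odour")
    odours <- 1:15
    meansList <- lapply(raws, function(rm) {
      lab <- stimulusIds(rm)
      m <- vapply(odours, function(k)
        rowMeans(rateValues(rm)[, lab == k, drop = FALSE]),
        numeric(nrow(rm)))
      list(means = m, region = as.character(neuronRegions(rm)))
    })
    allRegions <- unique(unlist(lapply(meansList, `[[`, "region")))
    byRegion <- list()
    for (rg in intersect(REGIONS, allRegions)) {
      x <- do.call(rbind, lapply(meansList, function(ml)
        ml$means[ml$region == rg, , drop = FALSE]))
      if (nrow(x) >= 2L)
        byRegion[[rg]] <- populationSparseness(x, odours)
    }
    list(byRegion = byRegion,
         comparison = if (length(byRegion) >= 2L)
           compareSparseness(byRegion) else NULL)
  })

  bundle$suppression <- stage("suppression",
    do.call(rbind, lapply(seq_along(zrates), function(i) {
      sid <- sessions[[i]]@sessionId
      ids <- modulatedIn(sid)
      if (!is.null(ids) && length(ids) == 0L) return(NULL)
      rs <- repetitionSuppression(zrates[[i]], neuronIds = ids)
      rs$perNeuron$session <- sid
      rs$perNeuron
    })))

  bundle$valence <- stage("valence", {
    vres <- lapply(seq_along(sessions), function(i) {
      tt <- trials(sessions[[i]], "odour")
      tt <- tt[tt$phase == "rating", , drop = FALSE]
      zr <- computeRateMatrix(sessions[[i]], trials = tt,
                              normalization = "zscored")
      ids <- modulatedIn(sessions[[i]]@sessionId)
      if (!is.null(ids) && length(ids) == 0L) return(NULL)
      valenceAnalysis(zr, neuronIds = ids,
                      referenceValence = config$referenceValence,
                      seed = config$seed + 1000L + i)
    })
    vres <- vres[!vapply(vres, is.null, logical(1L))]
    do.call(rbind, lapply(vres, `[[`, "perNeuron"))
  })

  bundle$stats <- stage("stats", {
    if (is.null(bundle$detect)) return(NULL)
    byRegion <- split(bundle$detect, bundle$detect$region)
    data.frame(
      region = names(byRegion),
      nNeurons = vapply(byRegion, nrow, integer(1L)),
      nModulated = vapply(byRegion, function(d) sum(d$modulated),
                          integer(1L)),
      fractionModulated = vapply(byRegion, function(d)
        mean(d$modulated), numeric(1L)),
      row.names = NULL
    )
  })

  if (!is.null(config$outDir)) writeBundle(bundle, config$outDir)
  bundle
}

writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg$sessions <- NULL
  jsonlite::write_json(
    lapply(unclass(cfg), function(v)
      if (inherits(v, "DecodingConfig")) unclass(v) else v),
    file.path(outDir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    force = TRUE)
  if (!is.null(bundle$detect))
    writeTsv(bundle$detect, file.path(outDir, "detect.tsv"))
  if (!is.null(bundle$stats))
    writeTsv(bundle$stats, file.path(outDir, "stats.tsv"))
  if (!is.null(bundle$suppression))
    writeTsv(bundle$suppression, file.path(outDir, "suppression.tsv"))
  if (!is.null(bundle$valence))
    writeTsv(bundle$valence, file.path(outDir, "valence.tsv"))
  if (length(bundle$decode)) {
    dec <- do.call(rbind, lapply(names(bundle$decode), function(rg) {
      r <- bundle$decode[[rg]]
      data.frame(region = rg, accuracy = accuracy(r),
                 nullMean = mean(nullAccuracies(r)), p = permutationP(r))
    }))
    writeTsv(dec, file.path(outDir, "decoding.tsv"))
  }
  if (!is.null(bundle$sparseness) && length(bundle$sparseness$byRegion)) {
    sp <- do.call(rbind, lapply(names(bundle$sparseness$byRegion),
      function(rg) {
        d <- as.data.frame(bundle$sparseness$byRegion[[rg]])
        d$region <- rg
        d
      }))
    writeTsv(sp, file.path(outDir, "sparseness.tsv"))
  }
  invisible(outDir)
}

#' Render a human-readable report from a pipeline bundle
#'
#' Builds one figure per completed stage -- per-region modulated-neuron
#' fractions (chance line at the selection alpha), decoding accuracy
#' with its permutation-null band (chance line at `1/nClasses`, 6.25%
#' for the 16-class design), per-region sparseness, repetition
#' suppression curves, and the valence contrast. Panels for missing
#' stages are omitted with a notice; every number plotted comes from the
#' bundle (no report-side recomputation).
#'
#' @param bundle output of [runPipeline()].
#' @param outDir optional directory; figures are saved as PDFs there.
#' @return Named list of ggplot objects.
#' @export
renderReport <- function(bundle, outDir = NULL) {
  plots <- list()
  notice <- function(name) logMsg("stage '", name,
                                  "' missing; panel omitted")
  if (!is.null(bundle$stats)) {
    plots$modulated <- ggplot2::ggplot(bundle$stats,
        ggplot2::aes(x = region, y = 100 * fractionModulated)) +
      ggplot2::geom_col(fill = "firebrick") +
      ggplot2::geom_hline(yintercept = 100 * bundle$config$alpha,
                          linetype = "dashed") +
      ggplot2::labs(y = "stimulus-modulated neurons (%)", x = NULL,
                    title = "Modulated neurons per region") +
      ggplot2::theme_classic()
  } else notice("stats")
  if (length(bundle$decode)) {
    dd <- do.call(rbind, lapply(names(bundle$decode), function(rg) {
      r <- bundle$decode[[rg]]
      rbind(data.frame(region = rg, kind = "observed",
                       accuracy = r@subsampleAccuracies),
            data.frame(region = rg, kind = "null",
                       accuracy = nullAccuracies(r)))
    }))
    chance <- 100 / (bundle$config$decoding$nClasses %||% 16)
    plots$decoding <- ggplot2::ggplot(dd,
        ggplot2::aes(x = region, y = 100 * accuracy, colour = kind)) +
      ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
      ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
      ggplot2::scale_colour_manual(values = c(observed = "firebrick",
                                              null = "grey60")) +
      ggplot2::labs(y = "decoding accuracy (%)", x = NULL,
                    title = "Identity decoding vs label-permuted null") +
      ggplot2::theme_classic()
  } else notice("decode")
  if (!is.null(bundle$sparseness) && length(bundle$sparseness$byRegion)) {
    sp <- do.call(rbind, lapply(names(bundle$sparseness$byRegion),
      function(rg) data.frame(region = rg,
                              SI = bundle$sparseness$byRegion[[rg]]$SI)))
    plots$sparseness <- ggplot2::ggplot(sp,
        ggplot2::aes(x = region, y = SI)) +
      ggplot2::geom_jitter(width = 0.15, colour = "steelblue") +
      ggplot2::stat_summary(fun = mean, geom = "crossbar",
                            width = 0.4, linewidth = 0.3) +
      ggplot2::labs(y = "population sparseness index", x = NULL,
                    title = "Sparseness per odour and region") +
      ggplot2::theme_classic()
  } else notice("sparseness")
  if (!is.null(bundle$suppression)) {
    plots$suppression <- ggplot2::ggplot(bundle$suppression,
        ggplot2::aes(x = region, y = slope)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5,
                           colour = "darkorange") +
      ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                            width = 0.4, linewidth = 0.3) +
      ggplot2::labs(y = "response slope (z / presentation)", x = NULL,
                    title = "Repetition suppression") +
      ggplot2::theme_classic()
  } else notice("suppression")
  if (!is.null(bundle$valence)) {
    plots$valence <- ggplot2::ggplot(bundle$valence,
        ggplot2::aes(x = region, y = diff)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5,
                           colour = "purple") +
      ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                            width = 0.4, linewidth = 0.3) +
      ggplot2::labs(y = "liked - disliked (z)", x = NULL,
                    title = "Valence contrast") +
      ggplot2::theme_classic()
  } else notice("valence")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots))
      suppressMessages(ggplot2::ggsave(
        file.path(outDir, paste0("report_", nm, ".pdf")), plots[[nm]],
        width = 6, height = 4))
  }
  plots
}
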