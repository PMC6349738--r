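#' @include stats.R qc.R simulate.R
NULL

#' Run configuration for the analysis pipeline
#'
#' @param model an \code{\linkS4class{EpgModelConfig}}.
#' @param alpha significance level in (0, 1).
#' @param factor grouping column in the metadata (e.g. \code{"host"}).
#' @param proportionParams percentage parameters to arcsine-transform first.
#' @param censorPolicy \code{"exclude"} (default; insects lacking a waveform
#'   contribute missing values to the affected parameters) or
#'   \code{"max_time"} (time-to-event parameters of such insects are set to
#'   the recording length instead).
#' @param duration recording length in seconds used when annotation files
#'   carry no terminal end row.
#' @param nWired optional total number of wired insects for the QC report.
#' @param seed integer seed for any stochastic step.
#' @return list of class \code{epgRunConfig}.
#' @export
runConfig <- function(model = modelConfig(), alpha = 0.05, factor = "group",
                      proportionParams = "pct_E1_phloem",
                      censorPolicy = c("exclude", "max_time"),
                      duration = 43200, nWired = NA_integer_, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, nzchar(factor))
  structure(list(model = model, alpha = alpha, factor = factor,
                 proportionParams = proportionParams,
                 censorPolicy = match.arg(censorPolicy),
                 duration = duration, nWired = nWired, seed = as.integer(seed)),
            class = "epgRunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys (all optional): \code{model} (with
#' \code{early_g_threshold_s}, \code{sustained_threshold_s},
#' \code{short_c_threshold_s}, \code{merge_c_across_pd}), \code{alpha},
#' \code{factor}, \code{proportion_params}, \code{censor_policy},
#' \code{duration_s}, \code{n_wired}, \code{seed}.
#'
#' @param path YAML file path.
#' @return list of class \code{epgRunConfig}.
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  m <- x$model
  model <- modelConfig(
    earlyGThreshold = m$early_g_threshold_s %||% 600,
    sustainedThreshold = m$sustained_threshold_s %||% 600,
    shortCThreshold = m$short_c_threshold_s %||% 180,
    mergeCAcrossPd = m$merge_c_across_pd %||% TRUE
  )
  runConfig(model = model,
            alpha = x$alpha %||% 0.05,
            factor = x$factor %||% "group",
            proportionParams = x$proportion_params %||% "pct_E1_phloem",
            censorPolicy = x$censor_policy %||% "exclude",
            duration = x$duration_s %||% 43200,
            nWired = x$n_wired %||% NA_integer_,
            seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the censoring policy to a parameter table
#'
#' Under \code{"max_time"}, missing time-to-event values (parameters whose
#' triggering waveform never occurred) are replaced by the recording length,
#' the conservative alternative convention; under \code{"exclude"} the table
#' is returned unchanged.
#'
#' @param table parameter table in seconds units.
#' @param policy \code{"exclude"} or \code{"max_time"}.
#' @param duration recording length in seconds.
#' @return the adjusted table.
#' @export
applyCensorPolicy <- function(table, policy = c("exclude", "max_time"),
                              duration = 43200) {
  policy <- match.arg(policy)
  if (policy == "exclude") return(table)
  tcols <- grep("^t_", names(table), value = TRUE)
  for (col in tcols) table[[col]][is.na(table[[col]])] <- duration
  table
}

#' Simulate cohorts and write them as an annotation directory
#'
#' Writes, for each named profile, \code{n} annotation files in the canonical
#' dialect plus a combined \code{metadata.csv} (columns \code{insect_id},
#' \code{file}, \code{status}, \code{group}) — a self-contained synthetic
#' experiment that \code{\link{runPipeline}} can analyse.
#'
#' @param profiles named list of \code{\linkS4class{EpgSimProfile}} objects
#'   (a single profile is accepted).
#' @param n insects per profile.
#' @param seed integer; seeds are drawn consecutively per insect.
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata data.frame.
#' @export
simulateToDir <- function(profiles, n, seed, dir) {
  if (is(profiles, "EpgSimProfile"))
    profiles <- stats::setNames(list(profiles), profiles@name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- list()
  offset <- 0L
  for (g in names(profiles)) {
    recs <- simulateCohort(profiles[[g]], n, seed + offset, prefix = g)
    offset <- offset + n
    for (rec in recs) {
      fn <- paste0(insectId(rec), ".ana.tsv")
      writeAnnotation(rec, file.path(dir, fn))
      md[[length(md) + 1L]] <- data.frame(
        insect_id = insectId(rec), file = fn, status = "completed",
        group = g, stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, md)
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(md)
}

#' Run the full EPG analysis pipeline
#'
#' Orchestrates the complete analysis: read the metadata, parse and
#' grammar-validate every annotation file with status \code{completed},
#' apply the early-G reclassification, compute the per-insect parameter
#' battery, summarize cohorts, and run the transformation + Tukey-Kramer +
#' letter-display statistics for the configured grouping factor. Files that
#' fail to parse or contain error-severity grammar violations are collected
#' in the error log and excluded; the run continues for the others.
#'
#' When \code{outDir} is given, writes \code{parameters.csv} (display
#' units), \code{parameters_seconds.csv}, \code{cohorts.csv},
#' \code{stats.csv}, \code{stats_transformed.csv}, \code{qc.txt} (if
#' \code{nWired} is configured), \code{errors.csv} and a \code{manifest.yaml}
#' describing the run. The run is deterministic given the configuration.
#'
#' @param config an \code{epgRunConfig} (see \code{\link{runConfig}}).
#' @param annotationDir directory containing the annotation files referenced
#'   by the metadata.
#' @param metadataFile path to the metadata CSV (default
#'   \code{metadata.csv} inside \code{annotationDir}).
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @return invisibly, a result bundle: list with \code{parameters} (seconds
#'   table), \code{parametersDisplay}, \code{cohorts}, \code{stats},
#'   \code{statsSupplement}, \code{qc} (or NULL), \code{errors} (data.frame),
#'   \code{ok} (FALSE when every file failed).
#' @export
runPipeline <- function(config, annotationDir,
                        metadataFile = file.path(annotationDir, "metadata.csv"),
                        outDir = NULL) {
  stopifnot(inherits(config, "epgRunConfig"))
  md <- readMetadata(metadataFile)
  todo <- md[md$status == "completed", , drop = FALSE]
  if (nrow(todo) == 0L) stop("no completed recordings in metadata")

  records <- list()
  errors <- list()
  for (i in seq_len(nrow(todo))) {
    id <- todo$insect_id[i]
    path <- file.path(annotationDir, todo$file[i])
    res <- tryCatch({
      if (!file.exists(path)) stop("annotation file not found: ", path)
      rec <- readAnnotation(path, duration = config$duration, insectId = id)
      viol <- validateGrammar(rec)
      if (any(viol$severity == "error"))
        stop("grammar violation(s): ",
             paste(sprintf("%s@%d", viol$rule_id[viol$severity == "error"],
                           viol$position[viol$severity == "error"]),
                   collapse = ", "))
      rec <- reclassifyEarlyG(rec, config$model)
      computeInsectParameters(rec, config$model)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[[length(errors) + 1L]] <- data.frame(
        insect_id = id, file = todo$file[i], error = res,
        stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(insect_id = character(), file = character(), error = character())
  if (length(records) == 0L) {
    return(invisible(list(parameters = NULL, parametersDisplay = NULL,
                          cohorts = NULL, stats = NULL, statsSupplement = NULL,
                          qc = NULL, errors = errors, ok = FALSE)))
  }

  ptab <- applyCensorPolicy(parametersToTable(records, "seconds"),
                            config$censorPolicy, config$duration)
  ptabDisp <- parametersToTable(records, "display")

  fac <- config$factor
  cohorts <- NULL
  statsRes <- NULL
  if (fac %in% names(md)) {
    ids <- vapply(records, `[[`, "", "insect_id")
    groups <- md[[fac]][match(ids, md$insect_id)]
    cohorts <- do.call(rbind, lapply(split(seq_along(records), groups),
      function(idx) {
        cs <- computeCohort(records[idx],
                            group = as.character(groups[idx[1L]]))
        cbind(group = cs$group, n = cs$n, pct_with_E2 = cs$pct_with_E2,
              cs$table)
      }))
    rownames(cohorts) <- NULL
    if (length(unique(groups[!is.na(groups)])) >= 2L)
      statsRes <- groupCompare(ptab, md, fac, alpha = config$alpha,
                               proportionParams = config$proportionParams)
  }
  qc <- if (!is.na(config$nWired)) qcSummary(md, config$nWired) else NULL

  bundle <- list(parameters = ptab, parametersDisplay = ptabDisp,
                 cohorts = cohorts,
                 stats = if (!is.null(statsRes)) statsToTable(statsRes) else NULL,
                 statsSupplement = if (!is.null(statsRes))
                   statsToSupplement(statsRes) else NULL,
                 comparisons = statsRes, qc = qc, errors = errors, ok = TRUE)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ptabDisp, file.path(outDir, "parameters.csv"), row.names = FALSE)
    utils::write.csv(ptab, file.path(outDir, "parameters_seconds.csv"), row.names = FALSE)
    if (!is.null(cohorts))
      utils::write.csv(cohorts, file.path(outDir, "cohorts.csv"), row.names = FALSE)
    if (!is.null(bundle$stats)) {
      utils::write.csv(bundle$stats, file.path(outDir, "stats.csv"), row.names = FALSE)
      utils::write.csv(bundle$statsSupplement,
                       file.path(outDir, "stats_transformed.csv"), row.names = FALSE)
    }
    utils::write.csv(errors, file.path(outDir, "errors.csv"), row.names = FALSE)
    if (!is.null(qc)) {
      con <- file(file.path(outDir, "qc.txt"), "w")
      sink(con); print(qc); sink(); close(con)
    }
    manifest <- list(
      n_insects_analysed = length(records),
      n_errors = nrow(errors),
      factor = fac, alpha = config$alpha,
      censor_policy = config$censorPolicy,
      model = list(early_g_threshold_s = config$model@earlyGThreshold,
                   sustained_threshold_s = config$model@sustainedThreshold,
                   short_c_threshold_s = config$model@shortCThreshold,
                   merge_c_across_pd = config$model@mergeCAcrossPd),
      seed = config$seed)
    writeLines(yaml::as.yaml(manifest), file.path(outDir, "manifest.yaml"))
  }
  invisible(bundle)
}
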