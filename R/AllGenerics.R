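#' @include AllClasses.R
NULL

#' Accessors for EpgRecording objects
#'
#' \code{events} returns the event table (columns \code{code}, \code{start},
#' \code{end} in seconds); \code{insectId} the insect identifier;
#' \code{recordingDuration} the window length in seconds; \code{sampleRate}
#' the acquisition rate in Hz.
#'
#' @param x an \code{EpgRecording}.
#' @return See individual descriptions.
#' @name EpgRecording-accessors
#' @aliases events insectId recordingDuration sampleRate
NULL

#' @rdname EpgRecording-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname EpgRecording-accessors
#' @export
setGeneric("insectId", function(x) standardGeneric("insectId"))

#' @rdname EpgRecording-accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname EpgRecording-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname EpgRecording-accessors
setMethod("events", "EpgRecording", function(x) x@events)

#' @rdname EpgRecording-accessors
setMethod("insectId", "EpgRecording", function(x) x@insectId)

#' @rdname EpgRecording-accessors
setMethod("recordingDuration", "EpgRecording", function(x) x@duration)

#' @rdname EpgRecording-accessors
setMethod("sampleRate", "EpgRecording", function(x) x@sampleRate)

setMethod("show", "EpgRecording", function(object) {
  ev <- object@events
  dur <- tapply(ev$end - ev$start, factor(ev$code, levels = epgWaveformCodes()), sum)
  dur[is.na(dur)] <- 0
  cat(sprintf("EpgRecording '%s': %d events over %.1f h\n",
              object@insectId, nrow(ev), object@duration / 3600))
  cat("  time budget (min): ",
      paste(sprintf("%s=%.1f", names(dur), dur / 60), collapse = "  "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "EpgModelConfig", function(object) {
  cat("EpgModelConfig\n")
  cat(sprintf("  early-G reclassification window: %g s\n", object@earlyGThreshold))
  cat(sprintf("  sustained-event threshold:       %g s\n", object@sustainedThreshold))
  cat(sprintf("  short-C threshold:               %g s\n", object@shortCThreshold))
  cat(sprintf("  merge C across pd:               %s\n", object@mergeCAcrossPd))
  invisible(object)
})

setMethod("show", "EpgSimProfile", function(object) {
  cat(sprintf("EpgSimProfile '%s' (%.1f h recording)\n",
              object@name, object@duration / 3600))
  cat("  sojourn medians (s): ",
      paste(sprintf("%s=%g", names(object@median), object@median), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  pd bursts: %.2f per min of C, median %g s\n",
              object@pdRate, object@pdMedian))
  invisible(object)
})
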