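#' @include AllClasses.R
NULL

#' Segment a recording into probes
#'
#' A probe is a maximal interval of non-np events flanked by non-probing
#' periods or by a recording boundary (a probe truncated by the end of the
#' window is still a probe, flagged \code{censored}). Probes are disjoint and
#' ordered, and together with the np periods tile the recording exactly.
#'
#' @param rec an \code{\linkS4class{EpgRecording}}.
#' @return data.frame with one row per probe: \code{index}, \code{start},
#'   \code{end}, \code{duration} (s), \code{first_event}, \code{last_event}
#'   (row indices into \code{events(rec)}), \code{censored} (TRUE when the
#'   probe runs into the end of the recording).
#' @export
#' @examples
#' rec <- EpgRecording("w1", c("np", "C", "np"), c(0, 100, 400), 43200)
#' segmentProbes(rec)
segmentProbes <- function(rec) {
  ev <- events(rec)
  probing <- ev$code != "np"
  if (!any(probing)) {
    return(data.frame(index = integer(), start = numeric(), end = numeric(),
                      duration = numeric(), first_event = integer(),
                      last_event = integer(), censored = logical()))
  }
  r <- rle(probing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  first_event <- starts[keep]
  last_event <- ends[keep]
  data.frame(
    index = seq_along(first_event),
    start = ev$start[first_event],
    end = ev$end[last_event],
    duration = ev$end[last_event] - ev$start[first_event],
    first_event = first_event,
    last_event = last_event,
    censored = ev$end[last_event] == recordingDuration(rec)
  )
}

#' Relabel early xylem-like waveforms as derailed stylet mechanics
#'
#' Whiteflies are assumed unable to reach xylem within the first minutes of a
#' probe, so a G (xylem ingestion) event that starts strictly less than
#' \code{earlyGThreshold} seconds (default 10 min) after the start of its
#' containing probe is relabeled F (derailed stylet mechanics). Adjacent
#' events are re-merged afterwards; all other events are untouched and total
#' time is conserved. The operation is idempotent.
#'
#' @param rec an \code{\linkS4class{EpgRecording}}.
#' @param cfg an \code{\linkS4class{EpgModelConfig}}.
#' @return A relabeled \code{EpgRecording}.
#' @export
reclassifyEarlyG <- function(rec, cfg = modelConfig()) {
  ev <- events(rec)
  probes <- segmentProbes(rec)
  if (nrow(probes)) {
    for (p in seq_len(nrow(probes))) {
      idx <- probes$first_event[p]:probes$last_event[p]
      isEarlyG <- ev$code[idx] == "G" &
        (ev$start[idx] - probes$start[p]) < cfg@earlyGThreshold
      ev$code[idx[isEarlyG]] <- "F"
    }
  }
  ev <- .mergeAdjacent(ev)
  initialize(rec, events = ev)
}

# TRUE if the recording still contains G events the config would relabel
.hasEarlyG <- function(rec, cfg) {
  ev <- events(rec)
  probes <- segmentProbes(rec)
  for (p in seq_len(nrow(probes))) {
    idx <- probes$first_event[p]:probes$last_event[p]
    if (any(ev$code[idx] == "G" &
            (ev$start[idx] - probes$start[p]) < cfg@earlyGThreshold))
      return(TRUE)
  }
  FALSE
}

#' Effective event list for counting statistics
#'
#' Returns the event list on which event counts and mean durations are
#' computed. When \code{mergeCAcrossPd} is \code{TRUE} (default), each
#' maximal pathway run of the form C (pd C)* collapses to one C event whose
#' duration is the summed C time; the embedded potential drops remain as
#' their own events. When \code{FALSE}, the raw segments are returned. Total
#' C and total pd time are invariant to this choice; only counts and means
#' change.
#'
#' @param rec an \code{\linkS4class{EpgRecording}}.
#' @param cfg an \code{\linkS4class{EpgModelConfig}}.
#' @return data.frame with columns \code{code}, \code{start}, \code{end},
#'   \code{duration}; for a merged C event \code{start}/\code{end} span the
#'   run while \code{duration} is the summed C time only.
#' @export
effectiveEvents <- function(rec, cfg = modelConfig()) {
  ev <- events(rec)
  ev$duration <- ev$end - ev$start
  if (!cfg@mergeCAcrossPd || nrow(ev) < 3L) return(ev)

  n <- nrow(ev)
  keep <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    if (ev$code[i] == "C") {
      # extend over the maximal C (pd C)* run
      j <- i
      while (j + 2L <= n && ev$code[j + 1L] == "pd" && ev$code[j + 2L] == "C")
        j <- j + 2L
      if (j > i) {
        cidx <- seq(i, j, by = 2L)
        ev$duration[i] <- sum(ev$duration[cidx])
        ev$end[i] <- ev$end[j]
        keep[cidx[-1L]] <- FALSE
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
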