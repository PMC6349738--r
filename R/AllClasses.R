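#' @import methods
NULL

#' Canonical EPG waveform codes
#'
#' The seven waveform labels used throughout the package, in canonical
#' spelling: \code{np} (non-probing), \code{C} (stylet pathway), \code{pd}
#' (potential drop, intracellular puncture), \code{G} (xylem ingestion),
#' \code{E1} (phloem salivation), \code{E2} (phloem ingestion) and \code{F}
#' (derailed stylet mechanics).
#'
#' @return Character vector of the seven canonical codes.
#' @export
#' @examples
#' epgWaveformCodes()
epgWaveformCodes <- function() c("np", "C", "pd", "G", "E1", "E2", "F")

# dialect spellings accepted on input, mapped to canonical (lower-cased keys)
.code_aliases <- c(
  np = "np", n = "np", z = "np",
  c = "C",
  pd = "pd",
  g = "G",
  e1 = "E1", e = "E1",
  e2 = "E2",
  f = "F"
)

#' Normalize waveform labels to the canonical seven codes
#'
#' Matching is case-insensitive and tolerates common dialect spellings
#' (\code{NP}, \code{Pd}, \code{e1}, ...). Unknown labels yield \code{NA}.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical codes, \code{NA} where unknown.
#' @export
normalizeWaveformCode <- function(x) {
  out <- .code_aliases[tolower(trimws(as.character(x)))]
  names(out) <- NULL
  out
}

#' EpgRecording: one insect's annotated recording
#'
#' An \code{EpgRecording} holds the complete, contiguous sequence of waveform
#' events for a single insect over a fixed recording window (default 12 h =
#' 43200 s). Events are half-open intervals \code{[start, end)} in seconds
#' from recording start; they tile the window exactly and no two adjacent
#' events share a code.
#'
#' @slot insectId single string identifying the insect.
#' @slot duration recording length in seconds.
#' @slot events data.frame with columns \code{code}, \code{start}, \code{end}.
#' @slot sampleRate acquisition sampling rate in Hz (metadata only).
#'
#' @exportClass EpgRecording
setClass("EpgRecording",
  representation(
    insectId = "character",
    duration = "numeric",
    events = "data.frame",
    sampleRate = "numeric"
  )
)

.validEpgRecording <- function(object) {
  ev <- object@events
  msgs <- character()
  if (length(object@insectId) != 1L) msgs <- c(msgs, "insectId must be a single string")
  if (length(object@duration) != 1L || !is.finite(object@duration) || object@duration <= 0)
    msgs <- c(msgs, "duration must be a single positive number")
  if (!all(c("code", "start", "end") %in% names(ev)))
    return("events must have columns code, start, end")
  if (nrow(ev) == 0L) return("events must contain at least one event")
  if (!all(ev$code %in% epgWaveformCodes()))
    msgs <- c(msgs, sprintf("unknown waveform code(s): %s",
                            paste(setdiff(unique(ev$code), epgWaveformCodes()), collapse = ", ")))
  if (any(ev$end <= ev$start)) msgs <- c(msgs, "every event must have end > start")
  if (ev$start[1L] != 0) msgs <- c(msgs, "first event must start at 0")
  if (ev$end[nrow(ev)] != object@duration)
    msgs <- c(msgs, "last event must end at the recording duration")
  n <- nrow(ev)
  if (n > 1L) {
    if (any(ev$start[-1L] != ev$end[-n]))
      msgs <- c(msgs, "events must be contiguous (each start equals previous end)")
    if (any(ev$code[-1L] == ev$code[-n]))
      msgs <- c(msgs, "adjacent events must not share a waveform code (merge them)")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("EpgRecording", .validEpgRecording)

#' Construct an EpgRecording
#'
#' Builds a validated recording from parallel vectors of codes and onset
#' times. Each event extends from its onset to the next onset (the last to
#' \code{duration}). Adjacent events with the same code are merged.
#'
#' @param insectId single string.
#' @param codes character vector of waveform codes (canonical or dialect).
#' @param onsets numeric vector of onsets in seconds, strictly increasing,
#'   first element 0.
#' @param duration recording length in seconds (default 43200 = 12 h).
#' @param sampleRate sampling rate in Hz, metadata only (default 100).
#' @return An \code{EpgRecording}.
#' @export
#' @examples
#' rec <- EpgRecording("w1", c("np", "C", "E1", "E2", "np"),
#'                     c(0, 120, 900, 960, 4000))
#' rec
EpgRecording <- function(insectId, codes, onsets, duration = 43200,
                         sampleRate = 100) {
  codes <- normalizeWaveformCode(codes)
  if (anyNA(codes)) stop("unknown waveform code in input")
  stopifnot(length(codes) == length(onsets))
  ev <- data.frame(code = codes, start = as.numeric(onsets),
                   end = c(as.numeric(onsets[-1L]), as.numeric(duration)),
                   stringsAsFactors = FALSE)
  ev <- .mergeAdjacent(ev)
  new("EpgRecording", insectId = as.character(insectId), duration = as.numeric(duration),
      events = ev, sampleRate = as.numeric(sampleRate))
}

# merge runs of identical adjacent codes; keeps first start / last end
.mergeAdjacent <- function(ev) {
  if (nrow(ev) <= 1L) return(ev)
  grp <- cumsum(c(TRUE, ev$code[-1L] != ev$code[-nrow(ev)]))
  out <- data.frame(
    code = ev$code[!duplicated(grp)],
    start = tapply(ev$start, grp, min),
    end = tapply(ev$end, grp, max),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' EpgModelConfig: behavioral-model thresholds
#'
#' Thresholds governing probe-level interpretation: the early-xylem
#' reclassification window, the sustained-event threshold, the short-pathway
#' cutoff, and whether potential drops interrupt a pathway event for counting
#' purposes.
#'
#' @slot earlyGThreshold seconds; a G event starting strictly less than this
#'   long after the start of its probe is relabeled F (default 600 s = 10 min).
#' @slot sustainedThreshold seconds; an event strictly longer than this is
#'   "sustained" (default 600 s).
#' @slot shortCThreshold seconds; a pathway (C) event strictly shorter than
#'   this counts as a "short C event" (default 180 s).
#' @slot mergeCAcrossPd logical; if TRUE (default) a pathway run interrupted
#'   only by potential drops counts as one C event whose duration is the
#'   summed C time.
#'
#' @exportClass EpgModelConfig
setClass("EpgModelConfig",
  representation(
    earlyGThreshold = "numeric",
    sustainedThreshold = "numeric",
    shortCThreshold = "numeric",
    mergeCAcrossPd = "logical"
  )
)

setValidity("EpgModelConfig", function(object) {
  msgs <- character()
  for (s in c("earlyGThreshold", "sustainedThreshold", "shortCThreshold")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, paste(s, "must be a single positive number"))
  }
  if (length(object@mergeCAcrossPd) != 1L || is.na(object@mergeCAcrossPd))
    msgs <- c(msgs, "mergeCAcrossPd must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EpgModelConfig
#'
#' @param earlyGThreshold,sustainedThreshold,shortCThreshold thresholds in
#'   seconds; see \code{\linkS4class{EpgModelConfig}}.
#' @param mergeCAcrossPd logical.
#' @return An \code{EpgModelConfig}.
#' @export
#' @examples
#' modelConfig()
modelConfig <- function(earlyGThreshold = 600, sustainedThreshold = 600,
                        shortCThreshold = 180, mergeCAcrossPd = TRUE) {
  new("EpgModelConfig",
      earlyGThreshold = earlyGThreshold,
      sustainedThreshold = sustainedThreshold,
      shortCThreshold = shortCThreshold,
      mergeCAcrossPd = mergeCAcrossPd)
}

#' EpgSimProfile: semi-Markov feeding profile
#'
#' Specification of a synthetic feeding phenotype: an embedded Markov chain
#' over the six macroscopic states (np, C, G, E1, E2, F; potential drops are
#' modeled as a marked point process inside C), lognormal sojourn-time
#' distributions per state, and the pd burst process.
#'
#' @slot name profile name.
#' @slot transition 6 x 6 row-stochastic matrix over states
#'   np, C, G, E1, E2, F (diagonal zero).
#' @slot median named numeric, per-state sojourn median in seconds.
#' @slot sdlog named numeric, per-state lognormal log-scale sd.
#' @slot pdRate potential-drop insertions per minute of pathway time.
#' @slot pdMedian,pdSdlog lognormal parameters of pd durations (seconds).
#' @slot firstNpMedian median of the initial non-probing period, seconds
#'   (\code{NA} = same as np).
#' @slot duration recording length in seconds.
#'
#' @exportClass EpgSimProfile
setClass("EpgSimProfile",
  representation(
    name = "character",
    transition = "matrix",
    median = "numeric",
    sdlog = "numeric",
    pdRate = "numeric",
    pdMedian = "numeric",
    pdSdlog = "numeric",
    firstNpMedian = "numeric",
    duration = "numeric"
  )
)

.simStates <- c("np", "C", "G", "E1", "E2", "F")

# transitions that would violate the waveform grammar carry probability 0
.forbiddenTransitions <- rbind(
  c("np", "E2"), c("C", "E2"), c("G", "E2"), c("F", "E2"),
  c("E1", "G"), c("E1", "F")
)

setValidity("EpgSimProfile", function(object) {
  msgs <- character()
  tr <- object@transition
  st <- .simStates
  if (!identical(dim(tr), c(6L, 6L)) ||
      !identical(rownames(tr), st) || !identical(colnames(tr), st))
    return("transition must be a 6 x 6 matrix with dimnames np, C, G, E1, E2, F")
  if (any(tr < 0)) msgs <- c(msgs, "transition probabilities must be non-negative")
  if (any(abs(rowSums(tr) - 1) > 1e-8)) msgs <- c(msgs, "transition rows must sum to 1")
  for (k in seq_len(nrow(.forbiddenTransitions))) {
    i <- .forbiddenTransitions[k, 1L]; j <- .forbiddenTransitions[k, 2L]
    if (tr[i, j] != 0)
      msgs <- c(msgs, sprintf("transition %s -> %s is forbidden by the waveform grammar", i, j))
  }
  if (!identical(names(object@median), st) || any(object@median <= 0))
    msgs <- c(msgs, "median must be named by the six states and strictly positive")
  if (!identical(names(object@sdlog), st) || any(object@sdlog < 0))
    msgs <- c(msgs, "sdlog must be named by the six states and non-negative")
  if (object@pdRate < 0) msgs <- c(msgs, "pdRate must be non-negative")
  if (object@pdMedian <= 0) msgs <- c(msgs, "pdMedian must be positive")
  if (!is.na(object@firstNpMedian) && object@firstNpMedian <= 0)
    msgs <- c(msgs, "firstNpMedian must be positive (or NA)")
  if (object@duration <= 0) msgs <- c(msgs, "duration must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EpgSimProfile
#'
#' @param name profile name.
#' @param transition 6 x 6 row-stochastic matrix over np, C, G, E1, E2, F.
#' @param median named per-state sojourn medians (seconds).
#' @param sdlog named per-state lognormal log-sd values.
#' @param pdRate pd insertions per minute of pathway.
#' @param pdMedian,pdSdlog pd duration distribution (seconds).
#' @param firstNpMedian median of the initial non-probing bout (NA = as np).
#' @param duration recording length in seconds.
#' @return An \code{EpgSimProfile}.
#' @seealso \code{\link{builtinProfiles}} for ready-made profiles.
#' @export
simProfile <- function(name, transition, median, sdlog,
                       pdRate = 0, pdMedian = 5, pdSdlog = 0.2,
                       firstNpMedian = NA_real_, duration = 43200) {
  st <- .simStates
  new("EpgSimProfile", name = name,
      transition = transition[st, st, drop = FALSE],
      median = median[st], sdlog = sdlog[st],
      pdRate = pdRate, pdMedian = pdMedian, pdSdlog = pdSdlog,
      firstNpMedian = as.numeric(firstNpMedian), duration = duration)
}
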