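#' @include AllClasses.R
NULL

.splitAnnotationLine <- function(line) {
  fields <- strsplit(trimws(line), "[\t,;]+|[[:space:]]+")[[1]]
  fields[nzchar(fields)]
}

#' Read an EPG waveform annotation file
#'
#' Parses the package's annotation dialect: a two-column delimited text file
#' (tab, comma, semicolon or whitespace separated) with one row per waveform
#' onset — waveform label, then onset time in seconds from recording start —
#' sorted by onset. An optional terminal row with label \code{end} carries the
#' recording duration and overrides \code{duration}. A header row is detected
#' (non-numeric second field) and skipped. Adjacent events with identical
#' codes are merged on read, so event counts computed downstream are
#' well-defined regardless of annotator segmenting habits.
#'
#' @param source path to an annotation file, or a character vector of lines.
#' @param duration recording length in seconds, used when the file has no
#'   terminal \code{end} row (default 43200 s = 12 h).
#' @param insectId identifier stored in the result; defaults to the file
#'   base name (or \code{"recording"} for literal text input).
#' @param sampleRate acquisition rate in Hz, metadata only.
#' @return An \code{\linkS4class{EpgRecording}}.
#' @export
#' @examples
#' txt <- c("np\t0", "C\t120", "E1\t900", "E2\t960", "np\t4000", "end\t43200")
#' rec <- readAnnotation(txt)
#' events(rec)
readAnnotation <- function(source, duration = 43200, insectId = NULL,
                           sampleRate = 100) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(insectId))
      insectId <- sub("\\.ana(\\.tsv)?$", "", basename(source), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    if (is.null(insectId)) insectId <- "recording"
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("annotation parse error: empty input")

  fields <- lapply(lines, .splitAnnotationLine)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop(sprintf("annotation parse error: expected two fields at line %d", bad[1L]))

  labels <- vapply(fields, `[[`, "", 1L)
  times_raw <- vapply(fields, `[[`, "", 2L)

  offset <- 0L
  if (is.na(suppressWarnings(as.numeric(times_raw[1L]))) &&
      tolower(labels[1L]) != "end") {
    # header row
    labels <- labels[-1L]; times_raw <- times_raw[-1L]; offset <- 1L
    if (length(labels) == 0L) stop("annotation parse error: empty input")
  }

  times <- suppressWarnings(as.numeric(times_raw))
  if (anyNA(times)) {
    i <- which(is.na(times))[1L]
    stop(sprintf("annotation parse error: non-numeric onset '%s' at line %d",
                 times_raw[i], i + offset))
  }

  n <- length(labels)
  if (tolower(labels[n]) == "end") {
    duration <- times[n]
    labels <- labels[-n]; times <- times[-n]
    n <- n - 1L
  }
  if (n == 0L) stop("annotation parse error: no waveform rows")

  codes <- normalizeWaveformCode(labels)
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop(sprintf("annotation parse error: unknown label %s at line %d",
                 labels[i], i + offset))
  }
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("annotation parse error: non-monotone onset at line %d", i + offset))
  }
  if (times[1L] != 0)
    stop("annotation parse error: first onset must be 0")
  if (times[n] >= duration)
    stop("annotation parse error: last onset at or beyond recording duration")

  EpgRecording(insectId, codes, times, duration = duration,
               sampleRate = sampleRate)
}

#' Write an EPG annotation file in the canonical dialect
#'
#' Emits tab-separated rows of canonical code and onset, followed by a
#' terminal \code{end} row carrying the recording duration. Onsets that lie
#' on the 0.01-s grid are written with at most two decimal places; others are
#' written at full precision so that \code{readAnnotation(writeAnnotation(x))}
#' reproduces the event list exactly.
#'
#' @param rec a valid \code{\linkS4class{EpgRecording}}.
#' @param path output file path, or \code{NULL} to return the lines.
#' @return Invisibly, the character vector of lines written.
#' @export
writeAnnotation <- function(rec, path = NULL) {
  v <- validObject(rec, test = TRUE)
  if (!isTRUE(v))
    stop("refusing to write invalid recording: ", paste(v, collapse = "; "))
  ev <- events(rec)
  fmt <- function(x) {
    two <- sprintf("%.2f", x)
    full <- vapply(x, function(z) format(z, digits = 17, scientific = FALSE), "")
    out <- ifelse(as.numeric(two) == x, sub("\\.?0+$", "", two), full)
    out
  }
  lines <- c(paste(ev$code, fmt(ev$start), sep = "\t"),
             paste("end", fmt(recordingDuration(rec)), sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Validate the waveform grammar of a recording
#'
#' Checks the behavioral grammar of whitefly EPG annotations and returns the
#' violations found (an empty data frame means the recording is clean). The
#' closed rule list:
#' \describe{
#'   \item{R1 (error)}{every phloem ingestion (E2) event must be immediately
#'     preceded by phloem salivation (E1) or another E2 event.}
#'   \item{R2 (error)}{a potential drop (pd) must not be adjacent to
#'     non-probing (np): pds occur inside probes.}
#'   \item{R3 (warning)}{a probe should not begin directly with E1/E2 from
#'     np — phloem phase without preceding pathway in that probe.}
#'   \item{R4 (error)}{the recording must contain at least one non-probing
#'     or probing period (always satisfied by a non-empty event list).}
#' }
#'
#' @param rec an \code{\linkS4class{EpgRecording}}.
#' @return data.frame with columns \code{rule_id}, \code{position} (event
#'   index), \code{message}, \code{severity}.
#' @export
#' @examples
#' rec <- EpgRecording("w1", c("np", "C", "E2", "np"), c(0, 100, 200, 300), 400)
#' validateGrammar(rec)
validateGrammar <- function(rec) {
  ev <- events(rec)
  n <- nrow(ev)
  out <- data.frame(rule_id = character(), position = integer(),
                    message = character(), severity = character(),
                    stringsAsFactors = FALSE)
  add <- function(rule, pos, msg, sev) {
    rbind(out, data.frame(rule_id = rule, position = pos, message = msg,
                          severity = sev, stringsAsFactors = FALSE))
  }
  for (i in seq_len(n)) {
    code <- ev$code[i]
    prv <- if (i > 1L) ev$code[i - 1L] else NA_character_
    nxt <- if (i < n) ev$code[i + 1L] else NA_character_
    if (code == "E2" && (is.na(prv) || !prv %in% c("E1", "E2")))
      out <- add("R1", i, "E2 not immediately preceded by E1 (or E2)", "error")
    if (code == "pd" && ((!is.na(prv) && prv == "np") || (!is.na(nxt) && nxt == "np") ||
                         is.na(prv) || is.na(nxt)))
      out <- add("R2", i, "pd adjacent to np or recording boundary", "error")
    if (code %in% c("E1", "E2") && !is.na(prv) && prv == "np" && code == "E1")
      out <- add("R3", i, "probe begins with phloem phase without pathway", "warning")
  }
  if (n == 0L)
    out <- add("R4", 0L, "recording contains no events", "error")
  out
}

#' Read the experiment metadata table
#'
#' Reads a comma-separated metadata file with a header. Required columns:
#' \code{insect_id}, \code{file}, \code{status}; every remaining column (or
#' the subset named in \code{factors}) is treated as a group factor (host
#' plant, whitefly species, wire type, ...). Status must be one of
#' \code{completed} (high-quality retained recording), \code{escaped}
#' (detached/escaped before the 12-h window elapsed) or
#' \code{excluded_bad_recording} (recorded but discarded on quality).
#'
#' @param source path to a CSV file, or a data.frame.
#' @param factors character vector naming the group-factor columns;
#'   \code{NULL} (default) selects every non-required column.
#' @return data.frame with factor columns converted to \code{factor}; the
#'   factor column names are stored in \code{attr(, "factors")}.
#' @export
readMetadata <- function(source, factors = NULL) {
  md <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("insect_id", "file", "status")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$insect_id))
    stop("duplicate insect_id in metadata: ",
         paste(unique(md$insect_id[duplicated(md$insect_id)]), collapse = ", "))
  valid_status <- c("completed", "escaped", "excluded_bad_recording")
  bad <- setdiff(unique(md$status), valid_status)
  if (length(bad))
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(valid_status, collapse = ", "), ")")
  if (is.null(factors)) factors <- setdiff(names(md), required)
  absent <- setdiff(factors, names(md))
  if (length(absent))
    stop("factor column(s) not in metadata: ", paste(absent, collapse = ", "))
  for (f in factors) md[[f]] <- factor(md[[f]])
  attr(md, "factors") <- factors
  md
}
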