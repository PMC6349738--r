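#' @include annotation-io.R
NULL

#' Recording-quality accounting
#'
#' Computes the standard QC summary of an EPG experiment from the metadata
#' status column: how many wired insects were successfully recorded for the
#' full window (status \code{completed} or \code{excluded_bad_recording}),
#' and how many of those recordings were retained as high quality (status
#' \code{completed}). Percentages are reported rounded to the nearest
#' integer; exact values are retained.
#'
#' @param metadata metadata table (see \code{\link{readMetadata}}).
#' @param nWired total number of insects wired (the metadata only lists
#'   insects that produced a recording attempt, so escape losses before
#'   mounting are part of \code{nWired} but may be absent from the table).
#' @param nRecovered optional count of insects recovered after recording,
#'   for the report only.
#' @return An object of class \code{epgQcSummary}: list with counts
#'   \code{n_wired}, \code{n_recorded}, \code{n_high_quality},
#'   \code{n_recovered}, exact percentages \code{pct_recorded} (of wired)
#'   and \code{pct_high_quality} (of recorded), and their integer-rounded
#'   report versions \code{pct_recorded_report},
#'   \code{pct_high_quality_report}.
#' @export
#' @examples
#' md <- data.frame(insect_id = as.character(1:10), file = "x",
#'                  status = c(rep("completed", 7),
#'                             rep("excluded_bad_recording", 2), "escaped"),
#'                  host = "cassava")
#' qcSummary(readMetadata(md), nWired = 12)
qcSummary <- function(metadata, nWired, nRecovered = NA_integer_) {
  if (length(nWired) != 1L || is.na(nWired) || nWired <= 0)
    stop("nWired must be a positive count")
  nHigh <- sum(metadata$status == "completed")
  nRecorded <- nHigh + sum(metadata$status == "excluded_bad_recording")
  if (nWired < nRecorded)
    stop("nWired (", nWired, ") is smaller than the number of recorded insects (",
         nRecorded, ")")
  pctRecorded <- 100 * nRecorded / nWired
  if (nRecorded == 0) {
    warning("no completed recordings in metadata")
    pctHigh <- 0
  } else {
    pctHigh <- 100 * nHigh / nRecorded
  }
  structure(list(
    n_wired = as.integer(nWired),
    n_recorded = as.integer(nRecorded),
    n_high_quality = as.integer(nHigh),
    n_recovered = as.integer(nRecovered),
    pct_recorded = pctRecorded,
    pct_high_quality = pctHigh,
    pct_recorded_report = round(pctRecorded),
    pct_high_quality_report = round(pctHigh)
  ), class = "epgQcSummary")
}

#' @export
print.epgQcSummary <- function(x, ...) {
  cat(sprintf("EPG recording quality: %d/%d wired insects recorded (%d%%); ",
              x$n_recorded, x$n_wired, x$pct_recorded_report))
  cat(sprintf("%d/%d high quality (%d%%)\n",
              x$n_high_quality, x$n_recorded, x$pct_high_quality_report))
  if (!is.na(x$n_recovered))
    cat(sprintf("  insects recovered after recording: %d\n", x$n_recovered))
  invisible(x)
}
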