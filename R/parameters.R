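#' @include feeding-model.R
NULL

# registry of the parameter battery: storage is always seconds (durations,
# time-to-event), plain counts, or percentages in [0, 100]
.parameterRegistry <- function() {
  w <- epgWaveformCodes()
  reg <- rbind(
    data.frame(name = paste0("dur_total_", w), type = "duration", display = "min"),
    data.frame(name = paste0("dur_mean_", w), type = "duration",
               display = ifelse(w %in% c("pd", "E1"), "s", "min")),
    data.frame(name = paste0("n_", w), type = "count", display = "count"),
    data.frame(name = c("n_probes", "n_short_C", "n_sustained_E2", "n_sustained_G"),
               type = "count", display = "count"),
    data.frame(name = c("dur_mean_probe", "dur_first_probe", "dur_second_probe",
                        "dur_longest_E2", "dur_E1_before_first_sustained_E2"),
               type = "duration", display = "min"),
    data.frame(name = c("t_to_first_probe", "t_to_first_E1",
                        "t_probe_to_first_E1", "t_probe_to_first_E2"),
               type = "duration", display = "min"),
    data.frame(name = "t_first_probe_to_first_E1", type = "duration", display = "h"),
    data.frame(name = "pct_E1_phloem", type = "percent", display = "pct")
  )
  rownames(reg) <- reg$name
  reg
}

#' Names and units of the EPG parameter battery
#'
#' @return data.frame with columns \code{name}, \code{type}
#'   (\code{duration}/\code{count}/\code{percent}; durations stored in
#'   seconds) and \code{display} (the conventional reporting unit:
#'   \code{min}, \code{s}, \code{h}, \code{count}, \code{pct}).
#' @export
parameterRegistry <- function() .parameterRegistry()

#' Sustained events of a waveform
#'
#' Returns the effective events of the given code whose duration strictly
#' exceeds the threshold — the conventional criterion for committed phloem
#' (E2) or xylem (G) ingestion is 10 min.
#'
#' @param rec an \code{\linkS4class{EpgRecording}}.
#' @param code a canonical waveform code.
#' @param threshold threshold in seconds (default from \code{cfg}).
#' @param cfg an \code{\linkS4class{EpgModelConfig}}.
#' @return data.frame of qualifying effective events, in temporal order.
#' @export
sustainedEvents <- function(rec, code, threshold = cfg@sustainedThreshold,
                            cfg = modelConfig()) {
  code <- normalizeWaveformCode(code)
  ev <- effectiveEvents(rec, cfg)
  out <- ev[ev$code == code & ev$duration > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the per-insect EPG parameter battery
#'
#' Computes, from one annotated recording, the full set of EPG parameters
#' reported in whitefly feeding studies: per-waveform total duration, event
#' count and mean event duration (on effective events, i.e. with pathway runs
#' merged across embedded potential drops); probe counts and durations;
#' time-to-event measures (to first probe, to first phloem salivation "1st E",
#' within-probe latencies to the first E1 and first E2); sustained-event
#' counts (strictly longer than the sustained threshold); the longest E2
#' event; the duration of the E1 bout immediately preceding the first
#' sustained E2; and the percent contribution of E1 to the phloem phase,
#' \eqn{100 \cdot E1 / (E1 + E2)} on total durations.
#'
#' A parameter whose triggering waveform never occurs is \code{NA} with its
#' censoring flag set, and is excluded from group statistics downstream.
#'
#' @param rec an \code{\linkS4class{EpgRecording}} with the early-G rule
#'   already applied (see \code{\link{reclassifyEarlyG}}).
#' @param cfg an \code{\linkS4class{EpgModelConfig}}.
#' @return An object of class \code{epgParameterRecord}: a list with
#'   \code{insect_id}, \code{values} (named numeric, durations in seconds),
#'   and \code{censored} (named logical).
#' @export
#' @examples
#' rec <- EpgRecording("w1", c("np", "C", "E1", "E2", "np"),
#'                     c(0, 600, 1200, 1260, 2460))
#' p <- computeInsectParameters(rec)
#' p$values[["t_to_first_probe"]]
computeInsectParameters <- function(rec, cfg = modelConfig()) {
  if (.hasEarlyG(rec, cfg))
    stop("recording contains early-probe G events; apply reclassifyEarlyG() ",
         "before computing parameters")
  reg <- .parameterRegistry()
  vals <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  cens <- stats::setNames(rep(FALSE, nrow(reg)), reg$name)

  raw <- events(rec)
  raw$duration <- raw$end - raw$start
  eff <- effectiveEvents(rec, cfg)
  probes <- segmentProbes(rec)

  for (w in epgWaveformCodes()) {
    vals[paste0("dur_total_", w)] <- sum(raw$duration[raw$code == w])
    nw <- sum(eff$code == w)
    vals[paste0("n_", w)] <- nw
    if (nw > 0) {
      vals[paste0("dur_mean_", w)] <- sum(eff$duration[eff$code == w]) / nw
    } else {
      cens[paste0("dur_mean_", w)] <- TRUE
    }
  }

  np <- nrow(probes)
  vals["n_probes"] <- np
  if (np > 0) {
    vals["dur_mean_probe"] <- mean(probes$duration)
    vals["dur_first_probe"] <- probes$duration[1L]
    vals["t_to_first_probe"] <- probes$start[1L]
  } else {
    cens[c("dur_mean_probe", "dur_first_probe", "t_to_first_probe")] <- TRUE
  }
  if (np > 1) vals["dur_second_probe"] <- probes$duration[2L] else
    cens["dur_second_probe"] <- TRUE

  vals["n_short_C"] <- sum(eff$code == "C" & eff$duration < cfg@shortCThreshold)

  # time-to-event battery; "1st E" = first phloem salivation (E1) onset
  firstE1 <- which(raw$code == "E1")[1L]
  if (!is.na(firstE1)) {
    tE1 <- raw$start[firstE1]
    vals["t_to_first_E1"] <- tE1
    if (np > 0) vals["t_first_probe_to_first_E1"] <- tE1 - probes$start[1L]
    probeOfE1 <- which(probes$first_event <= firstE1 & probes$last_event >= firstE1)
    vals["t_probe_to_first_E1"] <- tE1 - probes$start[probeOfE1]
  } else {
    cens[c("t_to_first_E1", "t_first_probe_to_first_E1", "t_probe_to_first_E1")] <- TRUE
  }

  firstE2 <- which(raw$code == "E2")[1L]
  if (!is.na(firstE2)) {
    probeOfE2 <- which(probes$first_event <= firstE2 & probes$last_event >= firstE2)
    vals["t_probe_to_first_E2"] <- raw$start[firstE2] - probes$start[probeOfE2]
  } else {
    cens["t_probe_to_first_E2"] <- TRUE
  }

  e2 <- eff[eff$code == "E2", , drop = FALSE]
  vals["n_sustained_E2"] <- sum(e2$duration > cfg@sustainedThreshold)
  vals["n_sustained_G"] <- sum(eff$duration[eff$code == "G"] > cfg@sustainedThreshold)
  if (nrow(e2) > 0) vals["dur_longest_E2"] <- max(e2$duration) else
    cens["dur_longest_E2"] <- TRUE

  sustIdx <- which(eff$code == "E2" & eff$duration > cfg@sustainedThreshold)[1L]
  if (!is.na(sustIdx) && sustIdx > 1L && eff$code[sustIdx - 1L] == "E1") {
    vals["dur_E1_before_first_sustained_E2"] <- eff$duration[sustIdx - 1L]
  } else {
    cens["dur_E1_before_first_sustained_E2"] <- TRUE
  }

  phloem <- vals[["dur_total_E1"]] + vals[["dur_total_E2"]]
  if (phloem > 0) {
    vals["pct_E1_phloem"] <- 100 * vals[["dur_total_E1"]] / phloem
  } else {
    cens["pct_E1_phloem"] <- TRUE
  }

  vals[cens] <- NA_real_
  structure(list(insect_id = insectId(rec), values = vals, censored = cens),
            class = "epgParameterRecord")
}

#' @export
print.epgParameterRecord <- function(x, ...) {
  cat(sprintf("EPG parameter record for insect '%s' (%d parameters, %d censored)\n",
              x$insect_id, length(x$values), sum(x$censored)))
  print(utils::head(round(x$values, 2), 12))
  invisible(x)
}

# display-unit conversion of a stored (seconds / count / percent) value
.displayValue <- function(values, reg) {
  div <- c(min = 60, s = 1, h = 3600, count = 1, pct = 1)
  values / div[reg[names(values), "display"]]
}

#' Collect parameter records into a table
#'
#' One row per insect, one column per parameter. With
#' \code{units = "seconds"} (default) durations are left in seconds; with
#' \code{units = "display"} each column is converted to its conventional
#' reporting unit (minutes generally; mean pd and mean E1 durations in
#' seconds; the first-probe-to-first-E1 latency in hours) and the header is
#' annotated with the unit.
#'
#' @param records list of \code{epgParameterRecord} objects.
#' @param units \code{"seconds"} or \code{"display"}.
#' @return data.frame with column \code{insect_id} then one numeric column
#'   per parameter.
#' @export
parametersToTable <- function(records, units = c("seconds", "display")) {
  units <- match.arg(units)
  reg <- .parameterRegistry()
  if (length(records) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(numeric()), nrow(reg))),
      c("insect_id", reg$name)))
    return(out)
  }
  rows <- lapply(records, function(r) {
    v <- r$values[reg$name]
    if (units == "display") v <- .displayValue(v, reg)
    v
  })
  out <- data.frame(insect_id = vapply(records, `[[`, "", "insect_id"),
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("insect_id", if (units == "display")
    paste0(reg$name, "_", reg$display) else reg$name)
  rownames(out) <- NULL
  out
}

#' Summarize a cohort of parameter records
#'
#' Per-parameter arithmetic mean and variance over non-missing values on the
#' original (seconds) scale, plus the percentage of insects in the cohort
#' showing at least one phloem ingestion (E2) event.
#'
#' @param records non-empty list of \code{epgParameterRecord} objects.
#' @param group cohort label.
#' @return An object of class \code{epgCohortSummary}: list with
#'   \code{group}, \code{n}, \code{pct_with_E2} and \code{table}
#'   (data.frame: parameter, n_nonmissing, mean, variance).
#' @export
computeCohort <- function(records, group = "cohort") {
  if (length(records) == 0L) stop("computeCohort requires at least one record")
  tab <- parametersToTable(records)
  params <- setdiff(names(tab), "insect_id")
  summ <- data.frame(
    parameter = params,
    n_nonmissing = vapply(params, function(p) sum(!is.na(tab[[p]])), 0L),
    mean = vapply(params, function(p) {
      v <- tab[[p]][!is.na(tab[[p]])]
      if (length(v)) mean(v) else NA_real_
    }, 0),
    variance = vapply(params, function(p) {
      v <- tab[[p]][!is.na(tab[[p]])]
      if (length(v) > 1) stats::var(v) else NA_real_
    }, 0),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  structure(list(group = group, n = length(records),
                 pct_with_E2 = 100 * mean(tab$n_E2 >= 1),
                 table = summ),
            class = "epgCohortSummary")
}

#' @export
print.epgCohortSummary <- function(x, ...) {
  cat(sprintf("EPG cohort '%s': n = %d insects, %.1f%% with phloem ingestion (E2)\n",
              x$group, x$n, x$pct_with_E2))
  print(utils::head(x$table, 10))
  invisible(x)
}
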