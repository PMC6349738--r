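# Brute-force reference for the parameter engine: expand a recording into
# 100 Hz ticks and compute every parameter by scanning the tick sequence.
# Written independently of the interval-arithmetic engine; durations come
# from tick counts, times from tick indices.

oracle_parameters <- function(rec, cfg = modelConfig()) {
  ev <- events(rec)
  nticks <- as.integer(round((ev$end - ev$start) * 100))
  ticks <- rep(ev$code, nticks)
  N <- length(ticks)
  stopifnot(N == round(recordingDuration(rec) * 100))

  r <- rle(ticks)
  run_code <- r$values
  run_len <- r$lengths
  run_dur <- run_len / 100
  run_start <- (cumsum(run_len) - run_len) / 100
  nr <- length(run_code)

  # effective event list: collapse C (pd C)* to one C, pd events kept
  eff_code <- character(0)
  eff_dur <- numeric(0)
  i <- 1L
  while (i <= nr) {
    if (cfg@mergeCAcrossPd && run_code[i] == "C") {
      j <- i
      ctotal <- run_dur[i]
      while (j + 2L <= nr && run_code[j + 1L] == "pd" && run_code[j + 2L] == "C") {
        ctotal <- ctotal + run_dur[j + 2L]
        j <- j + 2L
      }
      eff_code <- c(eff_code, "C")
      eff_dur <- c(eff_dur, ctotal)
      if (j > i) {
        for (k in seq(i + 1L, j - 1L, by = 2L)) {
          eff_code <- c(eff_code, "pd")
          eff_dur <- c(eff_dur, run_dur[k])
        }
      }
      i <- j + 1L
    } else {
      eff_code <- c(eff_code, run_code[i])
      eff_dur <- c(eff_dur, run_dur[i])
      i <- i + 1L
    }
  }

  vals <- list()
  for (w in epgWaveformCodes()) {
    vals[[paste0("dur_total_", w)]] <- sum(run_len[run_code == w]) / 100
    nw <- sum(eff_code == w)
    vals[[paste0("n_", w)]] <- nw
    vals[[paste0("dur_mean_", w)]] <-
      if (nw > 0) sum(eff_dur[eff_code == w]) / nw else NA_real_
  }

  # probes from the probing/non-probing tick mask
  pr <- rle(ticks != "np")
  pr_len <- pr$lengths
  pr_start <- (cumsum(pr_len) - pr_len) / 100
  probe_dur <- pr_len[pr$values] / 100
  probe_start <- pr_start[pr$values]
  np_probes <- length(probe_dur)
  vals$n_probes <- np_probes
  vals$dur_mean_probe <- if (np_probes > 0) mean(probe_dur) else NA_real_
  vals$dur_first_probe <- if (np_probes > 0) probe_dur[1L] else NA_real_
  vals$dur_second_probe <- if (np_probes > 1) probe_dur[2L] else NA_real_
  vals$t_to_first_probe <- if (np_probes > 0) probe_start[1L] else NA_real_

  vals$n_short_C <- sum(eff_code == "C" & eff_dur < cfg@shortCThreshold)

  firstE1_tick <- match("E1", ticks)
  if (!is.na(firstE1_tick)) {
    tE1 <- (firstE1_tick - 1) / 100
    vals$t_to_first_E1 <- tE1
    vals$t_first_probe_to_first_E1 <- tE1 - probe_start[1L]
    pidx <- max(which(probe_start <= tE1))
    vals$t_probe_to_first_E1 <- tE1 - probe_start[pidx]
  } else {
    vals$t_to_first_E1 <- NA_real_
    vals$t_first_probe_to_first_E1 <- NA_real_
    vals$t_probe_to_first_E1 <- NA_real_
  }

  firstE2_tick <- match("E2", ticks)
  if (!is.na(firstE2_tick)) {
    tE2 <- (firstE2_tick - 1) / 100
    pidx <- max(which(probe_start <= tE2))
    vals$t_probe_to_first_E2 <- tE2 - probe_start[pidx]
  } else {
    vals$t_probe_to_first_E2 <- NA_real_
  }

  e2dur <- eff_dur[eff_code == "E2"]
  vals$n_sustained_E2 <- sum(e2dur > cfg@sustainedThreshold)
  vals$n_sustained_G <- sum(eff_dur[eff_code == "G"] > cfg@sustainedThreshold)
  vals$dur_longest_E2 <- if (length(e2dur)) max(e2dur) else NA_real_

  sidx <- which(eff_code == "E2" & eff_dur > cfg@sustainedThreshold)[1L]
  vals$dur_E1_before_first_sustained_E2 <-
    if (!is.na(sidx) && sidx > 1L && eff_code[sidx - 1L] == "E1")
      eff_dur[sidx - 1L] else NA_real_

  totE1 <- vals$dur_total_E1
  totE2 <- vals$dur_total_E2
  vals$pct_E1_phloem <- if (totE1 + totE2 > 0) 100 * totE1 / (totE1 + totE2) else NA_real_

  unlist(vals)[parameterRegistry()$name]
}

# compare an engine record against the oracle: counts exact, durations and
# derived values within tol seconds; NA patterns must agree
expect_matches_oracle <- function(rec, cfg = modelConfig(), tol = 1e-9) {
  engine <- computeInsectParameters(rec, cfg)$values
  oracle <- oracle_parameters(rec, cfg)
  expect_identical(names(engine), names(oracle))
  expect_identical(is.na(engine), is.na(oracle),
                   info = paste("NA pattern mismatch for", insectId(rec)))
  reg <- parameterRegistry()
  for (p in reg$name) {
    e <- engine[[p]]; o <- oracle[[p]]
    if (is.na(e)) next
    if (reg[p, "type"] == "count") {
      expect_identical(as.integer(e), as.integer(o),
                       info = paste(insectId(rec), p))
    } else {
      expect_lt(abs(e - o), tol, label = paste(insectId(rec), p, "|diff|"))
    }
  }
  invisible(TRUE)
}
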