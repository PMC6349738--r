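test_that("worked example: time-to-event and phloem-share arithmetic", {
  rec <- make_rec(c("np", "C", "E1", "E2", "np"), c(0, 600, 1200, 1260, 2460))
  v <- computeInsectParameters(rec)$values
  expect_equal(v[["t_to_first_probe"]], 600)
  expect_equal(v[["t_to_first_E1"]], 1200)
  expect_equal(v[["t_probe_to_first_E1"]], 600)
  expect_equal(v[["t_first_probe_to_first_E1"]], 600)
  expect_equal(v[["t_probe_to_first_E2"]], 660)
  expect_equal(v[["n_sustained_E2"]], 1)  # 1200 s > 600 s
  expect_equal(v[["pct_E1_phloem"]], 100 * 60 / 1260)
  expect_equal(v[["dur_longest_E2"]], 1200)
  expect_equal(v[["dur_E1_before_first_sustained_E2"]], 60)
  expect_equal(v[["n_probes"]], 1)
  expect_equal(v[["dur_first_probe"]], 1860)
})

test_that("all-np recording yields zero counts and censored time-to-event values", {
  p <- computeInsectParameters(make_rec("np", 0))
  v <- p$values
  expect_equal(v[["dur_total_np"]], 43200)
  expect_equal(unname(v[paste0("n_", epgWaveformCodes())]),
               c(1, 0, 0, 0, 0, 0, 0))
  censored <- c("t_to_first_probe", "t_to_first_E1", "t_first_probe_to_first_E1",
                "t_probe_to_first_E1", "t_probe_to_first_E2", "dur_longest_E2",
                "dur_mean_probe", "dur_first_probe", "dur_second_probe",
                "dur_E1_before_first_sustained_E2", "pct_E1_phloem")
  expect_true(all(is.na(v[censored])))
  expect_true(all(p$censored[censored]))
  expect_equal(v[["n_sustained_E2"]], 0)
})

test_that("sustained events use a strict threshold", {
  rec <- make_rec(c("np", "C", "E1", "E2", "C", "E1", "E2", "np"),
                  c(0, 10, 20, 30, 650, 700, 710, 1310))
  # E2 events: 620 s and 600 s
  s <- sustainedEvents(rec, "E2", threshold = 600)
  expect_equal(nrow(s), 1)
  expect_equal(s$duration, 620)
  expect_equal(nrow(sustainedEvents(rec, "G", threshold = 600)), 0)
})

test_that("unreclassified recordings are rejected with guidance", {
  rec <- make_rec(c("np", "C", "G", "np"), c(0, 100, 200, 400))
  expect_error(computeInsectParameters(rec), "reclassifyEarlyG")
  expect_silent(computeInsectParameters(reclassifyEarlyG(rec)))
})

test_that("engine equals the tick-expansion oracle on simulated recordings", {
  for (rec in sim_pool(n_per_profile = 3, seed = 41)) {
    expect_matches_oracle(rec)
  }
  # and with merging disabled
  cfgOff <- modelConfig(mergeCAcrossPd = FALSE)
  for (rec in sim_pool(n_per_profile = 1, seed = 51)) {
    expect_matches_oracle(rec, cfgOff)
  }
})

test_that("conservation and mean-times-count identities hold", {
  for (rec in sim_pool(n_per_profile = 2, seed = 61)) {
    v <- computeInsectParameters(rec)$values
    expect_equal(sum(v[paste0("dur_total_", epgWaveformCodes())]), 43200)
    for (w in epgWaveformCodes()) {
      n <- v[[paste0("n_", w)]]
      if (n > 0)
        expect_equal(v[[paste0("dur_mean_", w)]] * n,
                     sum(effectiveEvents(rec)$duration[
                       effectiveEvents(rec)$code == w]))
    }
  }
})

test_that("raising the sustained threshold never increases the sustained count", {
  for (rec in sim_pool(n_per_profile = 2, seed = 71)) {
    counts <- vapply(c(60, 300, 600, 1200, 3600), function(th)
      computeInsectParameters(rec, modelConfig(sustainedThreshold = th))$
        values[["n_sustained_E2"]], 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("removing the phloem phase flips exactly the documented parameters", {
  rec <- make_rec(c("np", "C", "E1", "E2", "C", "G", "np"),
                  c(0, 100, 700, 800, 2000, 2800, 3500))
  rec <- reclassifyEarlyG(rec)
  full <- computeInsectParameters(rec)$values
  # same structure with the phloem phase replaced by pathway
  noPhloem <- reclassifyEarlyG(
    make_rec(c("np", "C", "G", "np"), c(0, 100, 2800, 3500)))
  dropped <- computeInsectParameters(noPhloem)$values
  nowMissing <- names(full)[!is.na(full) & is.na(dropped)]
  expect_setequal(nowMissing,
    c("dur_mean_E1", "dur_mean_E2", "t_to_first_E1",
      "t_first_probe_to_first_E1", "t_probe_to_first_E1",
      "t_probe_to_first_E2", "dur_longest_E2",
      "dur_E1_before_first_sustained_E2", "pct_E1_phloem"))
})

test_that("cohort summaries average non-missing values and count E2 presence", {
  recs <- list(
    make_rec(c("np", "C", "E1", "E2", "np"), c(0, 10, 20, 30, 700), id = "a"),
    make_rec(c("np", "C", "np"), c(0, 10, 700), id = "b"),
    make_rec(c("np", "C", "E1", "E2", "np"), c(0, 10, 20, 50, 700), id = "c"))
  params <- lapply(recs, computeInsectParameters)
  cs <- computeCohort(params, group = "g1")
  expect_equal(cs$n, 3)
  expect_equal(cs$pct_with_E2, 100 * 2 / 3)
  # mean over {670, MISSING, 650} -> 660, n_nonmissing = 2
  row <- cs$table[cs$table$parameter == "dur_longest_E2", ]
  expect_equal(row$n_nonmissing, 2)
  expect_equal(row$mean, 660)
  expect_error(computeCohort(list()), "at least one record")
})

test_that("display units follow the reporting conventions", {
  rec <- make_rec(c("np", "C", "E1", "E2", "np"), c(0, 600, 1200, 1266, 2466))
  p <- computeInsectParameters(rec)
  sec <- parametersToTable(list(p), units = "seconds")
  disp <- parametersToTable(list(p), units = "display")
  expect_equal(sec$dur_mean_E1, 66)
  expect_equal(disp$dur_mean_E1_s, 66)        # mean E1 reported in seconds
  expect_equal(disp$dur_total_E1_min, 1.1)    # totals reported in minutes
  expect_equal(disp$t_first_probe_to_first_E1_h, 600 / 3600)
  expect_equal(disp$n_probes_count, 1)

  empty <- parametersToTable(list())
  expect_equal(nrow(empty), 0)
  expect_true("insect_id" %in% names(empty))

  tmp <- tempfile(fileext = ".csv")
  write.csv(sec, tmp, row.names = FALSE)
  back <- read.csv(tmp)
  num <- setdiff(names(sec), "insect_id")
  expect_equal(as.matrix(back[num]), as.matrix(sec[num]), tolerance = 1e-6)
})
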