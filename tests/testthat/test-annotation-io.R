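test_that("annotation parsing builds contiguous recordings with correct durations", {
  rec <- readAnnotation(c("np\t0", "C\t120", "E1\t900", "E2\t960",
                          "np\t4000", "end\t43200"))
  ev <- events(rec)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$end - ev$start, c(120, 780, 60, 3040, 39200))
  expect_equal(recordingDuration(rec), 43200)
  expect_equal(sum(ev$end - ev$start), 43200)
})

test_that("parser accepts comma/semicolon delimiters, headers, and dialect codes", {
  rec <- readAnnotation(c("waveform,onset", "NP,0", "c,10", "Pd,20",
                          "C,26", "e1,50", "E2,60", "np,100", "end,200"))
  expect_equal(events(rec)$code, c("np", "C", "pd", "C", "E1", "E2", "np"))
  rec2 <- readAnnotation(c("np;0", "C;50", "end;100"))
  expect_equal(events(rec2)$code, c("np", "C"))
})

test_that("adjacent same-code segments are merged on read", {
  rec <- readAnnotation(c("np\t0", "np\t50", "C\t120", "end\t300"))
  ev <- events(rec)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start, c(0, 120))
  expect_equal(ev$end, c(120, 300))
})

test_that("parse errors name the offending label, line, or condition", {
  expect_error(readAnnotation(character(0)), "empty input")
  expect_error(readAnnotation("   \n  "), "empty input")
  expect_error(readAnnotation(c("C\t0", "np\t10", "X9\t20", "end\t100")),
               "unknown label X9 at line 3")
  expect_error(readAnnotation(c("np\t0", "C\t50", "E1\t40", "end\t100")),
               "non-monotone")
  expect_error(readAnnotation(c("np\t5", "C\t50", "end\t100")),
               "first onset must be 0")
  expect_error(readAnnotation(c("np\t0", "C\t150", "end\t100")),
               "beyond recording duration")
})

test_that("terminal end row overrides the duration argument", {
  rec <- readAnnotation(c("np\t0", "C\t60", "end\t600"), duration = 43200)
  expect_equal(recordingDuration(rec), 600)
})

test_that("canonical writer round-trips recordings exactly", {
  rec <- make_rec(c("np", "C", "E1", "E2", "np"), c(0, 120.25, 900, 960.5, 4000))
  lines <- writeAnnotation(rec)
  back <- readAnnotation(lines, insectId = insectId(rec))
  expect_identical(events(back), events(rec))
  expect_identical(recordingDuration(back), recordingDuration(rec))

  one <- make_rec("np", 0)
  expect_identical(writeAnnotation(one), c("np\t0", "end\t43200"))
})

test_that("round-trip and merge idempotence hold over simulated recordings", {
  for (rec in sim_pool(n_per_profile = 2, seed = 77)) {
    lines <- writeAnnotation(rec)
    back <- readAnnotation(lines, insectId = insectId(rec))
    expect_identical(events(back), events(rec))
    # tiling: event durations sum exactly to the window
    ev <- events(back)
    expect_equal(sum(ev$end - ev$start), recordingDuration(back))
    # re-reading a written file never changes the event count
    expect_equal(nrow(events(readAnnotation(writeAnnotation(back)))), nrow(ev))
  }
})

test_that("writer refuses invalid recordings", {
  rec <- make_rec(c("np", "C", "np"), c(0, 100, 200))
  rec@events$start[2] <- 90  # break contiguity behind the constructor's back
  expect_error(writeAnnotation(rec), "refusing to write")
})

test_that("grammar validation flags the documented rules", {
  expect_equal(nrow(validateGrammar(
    make_rec(c("np", "C", "E1", "E2", "np"), c(0, 1, 2, 3, 4), 10))), 0)

  v1 <- validateGrammar(make_rec(c("np", "C", "E2", "np"), c(0, 1, 2, 3), 10))
  expect_equal(v1$rule_id, "R1")
  expect_equal(v1$position, 3L)
  expect_equal(v1$severity, "error")

  v2 <- validateGrammar(make_rec(c("np", "pd", "C", "np"), c(0, 1, 2, 3), 10))
  expect_true("R2" %in% v2$rule_id)
  expect_equal(v2$position[v2$rule_id == "R2"], 2L)

  v3 <- validateGrammar(make_rec(c("np", "E1", "C", "np"), c(0, 1, 2, 3), 10))
  expect_equal(v3$rule_id, "R3")
  expect_equal(v3$severity, "warning")
})

test_that("metadata reader types factors and enforces its contract", {
  md <- readMetadata(data.frame(
    insect_id = c("a", "b", "c"), file = c("a.tsv", "b.tsv", "c.tsv"),
    status = "completed", host = c("cassava", "cassava", "tomato"),
    stringsAsFactors = FALSE))
  expect_s3_class(md$host, "factor")
  expect_equal(nlevels(md$host), 2)
  expect_equal(attr(md, "factors"), "host")

  expect_error(readMetadata(data.frame(insect_id = "a", status = "completed")),
               "missing required column")
  expect_error(readMetadata(data.frame(
    insect_id = c("a", "a"), file = "f", status = "completed", g = 1)),
    "duplicate insect_id")
  expect_error(readMetadata(data.frame(
    insect_id = "a", file = "f", status = "lost", g = 1)),
    "invalid status value\\(s\\): lost")
})
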