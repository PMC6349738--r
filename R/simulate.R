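#' @include AllClasses.R
NULL

# run body with a private, seed-initialized RNG stream; restores global state
.withSeed <- function(seed, body) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  body()
}

.roundGrid <- function(x) pmax(round(x, 2), 0.01)

#' Simulate one annotated EPG recording
#'
#' Draws a semi-Markov trajectory from the profile's embedded chain with
#' lognormal sojourn times, inserts potential-drop bursts inside pathway (C)
#' events as a marked point process, truncates at the recording length, and
#' returns a grammar-valid \code{\linkS4class{EpgRecording}}. All onsets lie
#' on the 0.01-s (100 Hz) grid. The same seed always yields a bit-identical
#' recording; the global RNG state is left untouched.
#'
#' The vector of sojourn durations as drawn (before truncation by the
#' recording window) is attached as \code{attr(rec, "sojournDraws")}, a
#' data.frame with columns \code{state}, \code{duration}, \code{initial};
#' it is the quantity the profile's closed-form lognormal means describe,
#' free of the length-biased censoring that the fixed window imposes on
#' realized event durations.
#'
#' @param profile an \code{\linkS4class{EpgSimProfile}}.
#' @param seed integer seed.
#' @param insectId identifier for the simulated insect.
#' @return An \code{EpgRecording}.
#' @export
#' @examples
#' prof <- builtinProfiles()[["host_adapted"]]
#' rec <- simulateRecording(prof, seed = 42)
#' rec
simulateRecording <- function(profile, seed, insectId = sprintf("sim%04d", seed)) {
  v <- validObject(profile, test = TRUE)
  if (!isTRUE(v)) stop("invalid simulation profile: ", paste(v, collapse = "; "))
  .withSeed(seed, function() .simulateOne(profile, insectId))
}

.simulateOne <- function(profile, insectId) {
  st <- .simStates
  dur_total <- profile@duration
  tr <- profile@transition

  states <- character(0)
  sojourns <- numeric(0)
  state <- "np"
  total <- 0
  first <- TRUE
  while (total < dur_total) {
    med <- if (first && state == "np" && !is.na(profile@firstNpMedian))
      profile@firstNpMedian else profile@median[[state]]
    d <- .roundGrid(stats::rlnorm(1, meanlog = log(med),
                                  sdlog = profile@sdlog[[state]]))
    states <- c(states, state)
    sojourns <- c(sojourns, d)
    total <- total + d
    state <- sample(st, 1L, prob = tr[state, ])
    first <- FALSE
  }
  draws <- data.frame(state = states, duration = sojourns,
                      initial = seq_along(states) == 1L,
                      stringsAsFactors = FALSE)

  # expand to events, inserting pd bursts inside C sojourns
  codes <- character(0)
  durs <- numeric(0)
  for (i in seq_along(states)) {
    if (states[i] == "C" && profile@pdRate > 0) {
      seg <- .pdBurst(states[i], sojourns[i], profile)
      codes <- c(codes, seg$code)
      durs <- c(durs, seg$duration)
    } else {
      codes <- c(codes, states[i])
      durs <- c(durs, sojourns[i])
    }
  }
  onsets <- cumsum(c(0, durs[-length(durs)]))
  onsets <- round(onsets, 2)

  # truncate at the recording window
  keep <- onsets < dur_total
  codes <- codes[keep]; onsets <- onsets[keep]
  # a potential drop must not abut the recording end; absorb it into pathway
  while (length(codes) > 1L && codes[length(codes)] == "pd") {
    codes <- codes[-length(codes)]
    onsets <- onsets[-length(onsets)]
  }
  rec <- EpgRecording(insectId, codes, onsets, duration = dur_total)
  attr(rec, "sojournDraws") <- draws
  rec
}

# split one C sojourn of length d into C (pd C)* segments
.pdBurst <- function(state, d, profile) {
  code <- character(0); dur <- numeric(0)
  pos <- 0
  repeat {
    gap <- .roundGrid(stats::rexp(1, rate = profile@pdRate / 60))
    pd <- .roundGrid(stats::rlnorm(1, meanlog = log(profile@pdMedian),
                                   sdlog = profile@pdSdlog))
    if (pos + gap + pd + 0.01 > d) break
    code <- c(code, "C", "pd")
    dur <- c(dur, gap, pd)
    pos <- pos + gap + pd
  }
  code <- c(code, "C")
  dur <- c(dur, round(d - pos, 2))
  list(code = code, duration = dur)
}

#' Simulate a cohort of recordings
#'
#' @param profile an \code{\linkS4class{EpgSimProfile}}.
#' @param n number of insects.
#' @param seed integer; insect k uses seed \code{seed + k - 1}.
#' @param prefix insect-id prefix.
#' @return list of \code{EpgRecording} objects.
#' @export
simulateCohort <- function(profile, n, seed, prefix = profile@name) {
  lapply(seq_len(n), function(k)
    simulateRecording(profile, seed = seed + k - 1L,
                      insectId = sprintf("%s_%03d", prefix, k)))
}

# build a transition matrix from a named list of named probability vectors
.trMatrix <- function(rows) {
  st <- .simStates
  m <- matrix(0, 6, 6, dimnames = list(st, st))
  for (s in names(rows)) m[s, names(rows[[s]])] <- rows[[s]]
  m
}

# profile parameterized by target mean sojourns; lognormal median =
# mean * exp(-sdlog^2 / 2)
.profileFromMeans <- function(name, transition, means, sdlog, pdRate,
                              pdMeanDur, firstNpMean = NA_real_) {
  med <- means * exp(-sdlog^2 / 2)
  pdSdlog <- 0.2
  simProfile(name, transition, median = med, sdlog = sdlog,
             pdRate = pdRate, pdMedian = pdMeanDur * exp(-pdSdlog^2 / 2),
             pdSdlog = pdSdlog,
             firstNpMedian = if (is.na(firstNpMean)) NA_real_ else
               firstNpMean * exp(-0.8^2 / 2))
}

#' Built-in simulation profiles
#'
#' Four feeding phenotypes whose expected event durations are patterned on
#' the magnitudes reported for whitefly EPG studies on true and rejected
#' hosts; they are emulation targets for testing the pipeline, not claims
#' about any real cohort.
#' \describe{
#'   \item{host_adapted}{a well-adapted insect on its preferred host: long
#'     committed phloem ingestion bouts (mean E2 event about 260 min), short
#'     non-probing periods, frequent potential drops.}
#'   \item{phloem_rejection}{probing proceeds but phloem acceptance fails:
#'     short, rare E2 events (mean about 41 min), repeated salivation, a high
#'     E1 share of the phloem phase, elevated xylem ingestion.}
#'   \item{delayed_acceptance}{strongly delayed first probe (mean about
#'     99 min) with long non-probing bouts, then successful but shorter
#'     phloem ingestion.}
#'   \item{thick_wire}{a tethering artifact phenotype: many short probes,
#'     elevated derailed stylet mechanics (F), reduced phloem ingestion.}
#' }
#'
#' @return named list of \code{\linkS4class{EpgSimProfile}} objects.
#' @export
#' @examples
#' names(builtinProfiles())
builtinProfiles <- function() {
  sd_default <- c(np = 0.9, C = 0.8, G = 0.7, E1 = 0.5, E2 = 0.7, F = 0.7)

  host_adapted <- .profileFromMeans(
    "host_adapted",
    .trMatrix(list(
      np = c(C = 1),
      C = c(np = .45, E1 = .35, G = .08, F = .12),
      E1 = c(E2 = .60, C = .25, np = .15),
      E2 = c(np = .55, C = .45),
      G = c(C = .45, np = .55),
      F = c(C = .50, np = .50))),
    means = c(np = 300, C = 618, G = 2220, E1 = 65.6, E2 = 15600, F = 1158),
    sdlog = sd_default, pdRate = 0.22, pdMeanDur = 6.0)

  phloem_rejection <- .profileFromMeans(
    "phloem_rejection",
    .trMatrix(list(
      np = c(C = 1),
      C = c(np = .50, E1 = .20, G = .15, F = .15),
      E1 = c(E2 = .25, C = .45, np = .30),
      E2 = c(np = .60, C = .40),
      G = c(C = .50, np = .50),
      F = c(C = .55, np = .45))),
    means = c(np = 312, C = 534, G = 912, E1 = 96.9, E2 = 2460, F = 654),
    sdlog = sd_default, pdRate = 0.25, pdMeanDur = 5.0)

  delayed_acceptance <- .profileFromMeans(
    "delayed_acceptance",
    .trMatrix(list(
      np = c(C = 1),
      C = c(np = .40, E1 = .42, G = .04, F = .14),
      E1 = c(E2 = .55, C = .30, np = .15),
      E2 = c(np = .50, C = .50),
      G = c(C = .50, np = .50),
      F = c(C = .50, np = .50))),
    means = c(np = 1212, C = 336, G = 3456, E1 = 91.1, E2 = 2148, F = 1398),
    sdlog = sd_default, pdRate = 0.17, pdMeanDur = 4.4,
    firstNpMean = 5946)

  thick_wire <- .profileFromMeans(
    "thick_wire",
    .trMatrix(list(
      np = c(C = 1),
      C = c(np = .62, E1 = .10, G = .03, F = .25),
      E1 = c(E2 = .40, C = .35, np = .25),
      E2 = c(np = .70, C = .30),
      G = c(C = .40, np = .60),
      F = c(C = .45, np = .55))),
    means = c(np = 246, C = 270, G = 3366, E1 = 42, E2 = 3852, F = 1092),
    sdlog = sd_default, pdRate = 0.09, pdMeanDur = 6.0)

  list(host_adapted = host_adapted,
       phloem_rejection = phloem_rejection,
       delayed_acceptance = delayed_acceptance,
       thick_wire = thick_wire)
}

#' Analytic mean sojourn durations of a profile
#'
#' The closed-form lognormal mean \eqn{\exp(\mu + \sigma^2/2)} per state,
#' in seconds.
#'
#' @param profile an \code{\linkS4class{EpgSimProfile}}.
#' @return named numeric vector over np, C, G, E1, E2, F.
#' @export
profileMeanSojourns <- function(profile) {
  profile@median * exp(profile@sdlog^2 / 2)
}

#' Serialize / deserialize simulation profiles as YAML
#'
#' @param profile an \code{\linkS4class{EpgSimProfile}}.
#' @param path file path; for \code{writeProfileYaml}, \code{NULL} returns
#'   the YAML text.
#' @return \code{readProfileYaml} returns an \code{EpgSimProfile}.
#' @export
writeProfileYaml <- function(profile, path = NULL) {
  x <- list(
    name = profile@name,
    transition = stats::setNames(
      lapply(.simStates, function(s) as.list(profile@transition[s, ])),
      .simStates),
    median = as.list(profile@median),
    sdlog = as.list(profile@sdlog),
    pd = list(rate_per_min_C = profile@pdRate,
              median_s = profile@pdMedian, sdlog = profile@pdSdlog),
    first_np_median_s = if (is.na(profile@firstNpMedian)) NULL else
      profile@firstNpMedian,
    duration_s = profile@duration
  )
  txt <- yaml::as.yaml(x)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeProfileYaml
#' @export
readProfileYaml <- function(path) {
  x <- yaml::read_yaml(path)
  st <- .simStates
  tr <- matrix(0, 6, 6, dimnames = list(st, st))
  for (s in st) {
    row <- unlist(x$transition[[s]])
    tr[s, names(row)] <- row
  }
  simProfile(x$name, tr,
             median = unlist(x$median)[st], sdlog = unlist(x$sdlog)[st],
             pdRate = x$pd$rate_per_min_C, pdMedian = x$pd$median_s,
             pdSdlog = x$pd$sdlog,
             firstNpMedian = if (is.null(x$first_np_median_s)) NA_real_ else
               x$first_np_median_s,
             duration = x$duration_s)
}
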