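# shorthand constructors for hand-built fixtures

make_rec <- function(codes, onsets, duration = 43200, id = "test") {
  EpgRecording(id, codes, onsets, duration = duration)
}

# small mixed pool of simulated recordings, reclassified, for property tests
sim_pool <- function(n_per_profile = 5, seed = 2024) {
  profs <- builtinProfiles()
  out <- list()
  k <- 0L
  for (nm in names(profs)) {
    for (i in seq_len(n_per_profile)) {
      k <- k + 1L
      out[[k]] <- reclassifyEarlyG(
        simulateRecording(profs[[nm]], seed = seed + k,
                          insectId = sprintf("%s_%02d", nm, i)))
    }
  }
  out
}
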