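# small-but-realistic synthetic configurations for the test suite; only the
# problem size (number of sweeps) is reduced relative to the generator
# defaults
quick_cfg <- function(..., n_sweeps = 20) {
  synthetic_config(..., n_sweeps = n_sweeps)
}

quick_recording <- function(..., n_sweeps = 20) {
  generate_recording(quick_cfg(..., n_sweeps = n_sweeps))
}

# wrap a plain 60-sample vector as an aligned-waveform object (feature
# functions only need samples + derivatives, not the alignment invariant)
wave_from_samples <- function(s, track = "TrackX") {
  d <- differentiate_waveform(s)
  structure(list(samples = as.numeric(s), fd = d$fd, sd = d$sd,
                 align_index = 31L, source_time = NA_real_, track = track),
            class = "mng_waveform")
}

# a batch of realistic aligned waveforms extracted from a synthetic recording
generator_waveforms <- function(seed = 42, noise_sd = 0.25, n_sweeps = 15) {
  rec <- quick_recording(noise_sd = noise_sd, seed = seed,
                         n_sweeps = n_sweeps)
  extract_waveforms(rec)$waveforms
}
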