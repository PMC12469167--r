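test_that("window extraction honors the half-open sample convention", {
  sig <- as.numeric(seq_len(10000))
  rec <- recording(sig, fs = 10000)
  w <- extract_window(rec, 0.5)       # sample 5000 (0-based)
  expect_length(w, 30L)
  expect_identical(attr(w, "start0"), 4985)
  # 0-based slice [4985, 5015) -> R indices 4986:5015
  expect_equal(as.numeric(w), sig[4986:5015])
  # all-zero signal gives an all-zero window
  rec0 <- recording(numeric(10000), fs = 10000)
  expect_equal(as.numeric(extract_window(rec0, 0.5)), rep(0, 30))
  # windows crossing the boundary raise a classed boundary error
  expect_error(extract_window(rec, (10000 - 10) / 10000),
               class = "mng_boundary_error")
  expect_error(extract_window(rec, 0.0005), class = "mng_boundary_error")
  # 30 kHz windows span 60 samples
  rec30 <- recording(numeric(30000), fs = 30000)
  expect_length(extract_window(rec30, 0.5), 60L)
})

test_that("Fourier resampling is exact for constants, sinusoids, identity", {
  expect_equal(resample_to_60(rep(2.5, 30)), rep(2.5, 60))
  # a sinusoid with a 10-sample period is band-limited: resampling doubles the
  # grid without changing frequency or amplitude
  x <- sin(2 * pi * (0:29) / 10)
  expect_equal(resample_to_60(x), sin(2 * pi * (0:59) / 20), tolerance = 1e-6)
  y <- stats::rnorm(60)
  expect_identical(resample_to_60(y), y)
  expect_error(resample_to_60(numeric(45)), "parameter error")
})

test_that("difference quotients match the finite-difference oracle", {
  m <- 0.7
  ramp <- m * seq_len(60)
  d <- differentiate_waveform(ramp)
  expect_equal(d$fd, rep(m, 60))
  expect_equal(d$sd, rep(0, 60))
  d0 <- differentiate_waveform(rep(1.3, 60))
  expect_equal(d0$fd, rep(0, 60))
  # quadratic: second difference quotient is constant 2 in the interior
  q <- as.numeric(seq_len(60))^2
  dq <- differentiate_waveform(q)
  expect_equal(dq$sd[3:58], rep(2, 56))
})

test_that("alignment puts the first-derivative minimum at the center and is idempotent", {
  waves <- generator_waveforms(seed = 5)
  for (w in waves[1:10]) {
    expect_identical(which.min(w$fd), 31L)
    # idempotence: re-aligning an aligned waveform changes nothing
    again <- align_waveform(w$samples, mode = "pad")
    expect_equal(again$samples, w$samples)
  }
})

test_that("circular alignment undoes a known shift and preserves the sample multiset", {
  w <- generator_waveforms(seed = 6)[[1]]
  shifted <- mngsort:::shift_window(w$samples, 5L, "circular")
  # the fd minimum of the shifted window sits 5 samples early (0-based 25)
  dsh <- differentiate_waveform(shifted)
  expect_identical(which.min(dsh$fd), 26L)
  realigned <- align_waveform(shifted, mode = "circular")
  expect_identical(which.min(realigned$fd), 31L)
  expect_equal(sort(realigned$samples), sort(shifted))
  expect_equal(realigned$samples, w$samples)
})

test_that("constant windows cannot be aligned", {
  expect_error(align_waveform(rep(1, 60)), class = "mng_alignment_error")
})

test_that("templates are pointwise means and commute with scaling", {
  waves <- generator_waveforms(seed = 8)
  one <- waves[[1]]
  expect_equal(compute_template(list(one))$values, one$samples)
  # v and -v average to zero
  neg <- one; neg$samples <- -one$samples
  expect_equal(compute_template(list(one, neg))$values, rep(0, 60))
  # template(c * W) = c * template(W)
  all_tracks <- vapply(waves, function(w) w$track, character(1))
  sub <- waves[all_tracks == "Track1"][1:6]
  scaled <- lapply(sub, function(w) { w$samples <- 2.5 * w$samples; w })
  expect_equal(compute_template(scaled)$values,
               2.5 * compute_template(sub)$values)
  expect_error(compute_template(list()), "parameter error")
  # refuses to average across tracks
  tracks <- vapply(waves, function(w) w$track, character(1))
  mixed <- list(waves[[which(tracks == "Track1")[1]]],
                waves[[which(tracks == "Track2")[1]]])
  expect_error(compute_template(mixed), "multiple tracks")
})

test_that("extraction conserves spikes: aligned + excluded = labeled", {
  rec <- quick_recording(noise_sd = 0, seed = 3, n_sweeps = 8)
  n <- length(rec$signal)
  # inject a spike too close to the end (boundary) and one in a flat,
  # noise-free region (no derivative peak -> alignment failure)
  extra <- data.frame(time = c((n - 5) / rec$fs, 3.0),
                      track = c("Track1", "Track2"))
  rec$spikes <- rbind(rec$spikes, extra)
  out <- extract_waveforms(rec)
  n_labeled <- sum(!is.na(rec$spikes$track))
  expect_identical(length(out$waveforms) + nrow(out$excluded), n_labeled)
  expect_identical(sort(out$excluded$reason), c("alignment", "boundary"))
})

test_that("waterfall latencies are constant for zero-jitter fibres and shift after extra stimuli", {
  rec <- quick_recording(latency_jitter_sd_ms = 0, seed = 4, n_sweeps = 10)
  wf <- build_waterfall(rec)
  expect_length(wf$sweeps, 10L)
  lat <- wf$latencies
  for (tr in unique(lat$track)) {
    expect_lt(diff(range(lat$latency_ms[lat$track == tr])), 1e-9)
  }
  # an extra-stimulus burst raises the next sweep's latency for every fibre
  cfg <- quick_cfg(latency_jitter_sd_ms = 0, seed = 4, n_sweeps = 12,
                   extra_stimulus_schedule = data.frame(sweep = 6,
                                                        n_pulses = 2))
  rec2 <- generate_recording(cfg)
  gt <- attr(rec2, "ground_truth")$latency_table
  bg <- gt[gt$evoked_by == "background", ]
  for (tr in unique(bg$track)) {
    g <- bg[bg$track == tr, ]
    expect_gt(g$latency_ms[g$sweep == 7], g$latency_ms[g$sweep == 6])
  }
  # the waterfall sees the same jump
  wf2 <- build_waterfall(rec2)
  l2 <- wf2$latencies
  first_lat <- function(sw, tr) {
    min(l2$latency_ms[l2$sweep == sw & l2$track == tr])
  }
  expect_gt(first_lat(7, "Track1"), first_lat(6, "Track1"))
})

test_that("waterfall edge cases: no spikes, spike before first onset", {
  rec <- recording(numeric(20000), fs = 10000, stimulus_onsets = c(0.5, 1.5))
  wf <- build_waterfall(rec)
  expect_identical(nrow(wf$latencies), 0L)
  expect_length(wf$sweeps, 2L)
  rec2 <- recording(numeric(20000), fs = 10000, stimulus_onsets = c(0.5, 1.5),
                    spikes = data.frame(time = 0.2, track = "Track1"))
  expect_warning(wf2 <- build_waterfall(rec2), "before the first")
  expect_equal(wf2$latencies$latency_ms, 200)
  expect_error(build_waterfall(recording(numeric(10), fs = 10000)),
               "at least one stimulus")
})
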