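test_that("write/read round trip is the identity on all recording fields", {
  rec <- quick_recording(seed = 7, n_sweeps = 5)
  path <- file.path(tempdir(), "roundtrip_rec")
  on.exit(unlink(path, recursive = TRUE))
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-9)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$t0, rec$t0)
  expect_equal(back$stimulus_onsets, rec$stimulus_onsets, tolerance = 1e-9)
  expect_equal(back$spikes$time, rec$spikes$time, tolerance = 1e-9)
  expect_equal(back$spikes$track, rec$spikes$track)
  expect_equal(back$meta$dataset, rec$meta$dataset)
})

test_that("containers with no spikes and unlabeled spikes survive I/O", {
  rec <- recording(signal = numeric(10000), fs = 10000,
                   stimulus_onsets = c(0.1, 0.5))
  path <- file.path(tempdir(), "empty_rec")
  on.exit(unlink(path, recursive = TRUE))
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(nrow(back$spikes), 0L)
  expect_length(back$signal, 10000L)
  expect_length(back$stimulus_onsets, 2L)

  rec2 <- recording(signal = numeric(10000), fs = 10000,
                    spikes = data.frame(time = c(0.2, 0.4),
                                        track = c("Track1", NA)))
  path2 <- file.path(tempdir(), "unlabeled_rec")
  on.exit(unlink(path2, recursive = TRUE), add = TRUE)
  write_recording(rec2, path2)
  back2 <- read_recording(path2)
  expect_identical(back2$spikes$track, c("Track1", NA_character_))
})

test_that("malformed containers and invalid recordings are rejected", {
  rec <- quick_recording(seed = 1, n_sweeps = 3)
  path <- file.path(tempdir(), "broken_rec")
  on.exit(unlink(path, recursive = TRUE))
  write_recording(rec, path)
  file.remove(file.path(path, "spikes.csv"))
  expect_error(read_recording(path), "spikes.csv")
  expect_error(read_recording(file.path(tempdir(), "does_not_exist_xyz")),
               "format error")
  # NaN in the signal is rejected before writing
  rec$signal[5] <- NaN
  expect_error(write_recording(rec, path), "non-finite")
  # non-monotonic onsets never make a valid recording
  expect_error(recording(numeric(100), fs = 10000,
                         stimulus_onsets = c(0.5, 0.2)),
               "strictly increasing")
  # spike outside the recorded interval
  expect_error(recording(numeric(100), fs = 10000,
                         spikes = data.frame(time = 2, track = "Track1")),
               "within")
})

test_that("dialect corrections follow their conventions", {
  rec3 <- recording(signal = c(1, -2, 3), fs = 10000)
  # generic is the identity
  expect_identical(apply_dialect(rec3, dialect_spec("generic"))$signal,
                   rec3$signal)
  # B with window 1: pure negation
  b1 <- dialect_spec("B", smoothing_window = 1)
  expect_equal(apply_dialect(rec3, b1)$signal, c(-1, 2, -3))
  # B with window 3: hand-rolled centered mean of the negated signal,
  # shrinking windows at the edges
  b3 <- dialect_spec("B", smoothing_window = 3)
  neg <- c(-1, 2, -3)
  expect_equal(apply_dialect(rec3, b3)$signal,
               c(mean(neg[1:2]), mean(neg), mean(neg[2:3])))
  expect_error(apply_dialect(rec3, dialect_spec("B", smoothing_window = 10)),
               "smoothing_window")
  # dialect invariants
  expect_error(dialect_spec("B", polarity_invert = FALSE), "polarity_invert")
  expect_error(dialect_spec("A", pad_gaps = FALSE), "pad_gaps")
  # signal length and fs preserved by B
  rec <- quick_recording(seed = 2, n_sweeps = 3)
  out <- apply_dialect(rec, b3)
  expect_length(out$signal, length(rec$signal))
  expect_equal(out$fs, rec$fs)
})

test_that("dialect A fills declared gaps with zeros on a uniform time base", {
  sig <- sin(seq_len(1000) / 50)
  rec <- recording(sig, fs = 10000,
                   meta = list(gaps = data.frame(start = 0.05, end = 0.07)))
  out <- apply_dialect(rec, dialect_spec("A"))
  n_pad <- round(0.02 * 10000)
  expect_length(out$signal, 1000 + n_pad)
  expect_equal(out$signal[1:500], sig[1:500])
  expect_equal(out$signal[501:(500 + n_pad)], rep(0, n_pad))
  expect_equal(out$signal[(501 + n_pad):(1000 + n_pad)], sig[501:1000])
  expect_null(out$meta$gaps)
})

test_that("read-time gap padding restores a uniform time base", {
  # container written with a hole in signal.csv (Dapsys-style acquisition gap)
  path <- file.path(tempdir(), "gap_rec")
  on.exit(unlink(path, recursive = TRUE))
  dir.create(path, showWarnings = FALSE)
  fs <- 10000
  t_keep <- c(0:499, 700:999) / fs
  v_keep <- c(rep(1, 500), rep(2, 300))
  data.table::fwrite(data.frame(t = t_keep, v = v_keep),
                     file.path(path, "signal.csv"))
  data.table::fwrite(data.frame(t = 0.01), file.path(path, "stimuli.csv"))
  data.table::fwrite(data.frame(t = numeric(0), track = character(0)),
                     file.path(path, "spikes.csv"))
  jsonlite::write_json(list(fs = fs, t0 = 0, meta = list()),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  expect_error(read_recording(path, dialect_spec("generic")), "gaps")
  rec <- read_recording(path, dialect_spec("A"))
  expect_length(rec$signal, 1000L)
  expect_equal(rec$signal[501:700], rep(0, 200))
  expect_equal(rec$signal[701:1000], rep(2, 300))
})
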