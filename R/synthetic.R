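#' Parametric C-fibre spike template
#'
#' A spike shape modelled as a sum of Gaussian lobes in continuous time — by
#' default a tri-lobe negative-positive-negative pulse resembling
#' extracellular C-fibre spikes. Because the family is linear in the lobe
#' amplitudes, the pointwise morph `(1-lambda)*A + lambda*B` of two shapes is
#' again a member, which gives exact control over pairwise template distances.
#'
#' @param amps Lobe amplitudes (volts).
#' @param centers_ms Lobe centers relative to the spike time (ms).
#' @param widths_ms Lobe Gaussian SDs (ms).
#' @return Object of class `mng_parametric_template`.
#' @export
parametric_template <- function(amps, centers_ms, widths_ms) {
  stopifnot(length(amps) == length(centers_ms),
            length(amps) == length(widths_ms), all(widths_ms > 0))
  structure(list(amps = as.numeric(amps), centers_ms = as.numeric(centers_ms),
                 widths_ms = as.numeric(widths_ms)),
            class = "mng_parametric_template")
}

#' Evaluate a parametric template in continuous time
#'
#' @param tpl A [parametric_template()].
#' @param t_ms Times relative to the spike reference point (ms).
#' @return Voltages at `t_ms`.
#' @export
template_eval <- function(tpl, t_ms) {
  out <- numeric(length(t_ms))
  for (l in seq_along(tpl$amps)) {
    out <- out + tpl$amps[l] *
      exp(-((t_ms - tpl$centers_ms[l]) / tpl$widths_ms[l])^2 / 2)
  }
  out
}

#' Pointwise linear morph of two parametric templates
#'
#' Returns the template whose waveform is exactly
#' `(1-lambda) * A + lambda * B` at every time point (implemented by scaling
#' and concatenating the lobe sets of both shapes).
#'
#' @param a,b [parametric_template()] objects.
#' @param lambda Morph parameter in `[0, 1]`.
#' @return A [parametric_template()].
#' @export
template_morph <- function(a, b, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  parametric_template(c((1 - lambda) * a$amps, lambda * b$amps),
                      c(a$centers_ms, b$centers_ms),
                      c(a$widths_ms, b$widths_ms))
}

#' Realize a parametric template on the 60-sample analysis grid
#'
#' Samples the shape at the native window of the given rate (30 samples at
#' 10 kHz, 60 at 30 kHz, spike reference at the window center) and resamples
#' to the common 60-sample grid. This is the representation on which template
#' distances are defined.
#'
#' @param tpl A [parametric_template()].
#' @param fs Sampling rate (10000 or 30000 Hz).
#' @return Numeric vector of length 60.
#' @export
template_values <- function(tpl, fs = 10000) {
  half <- window_half(fs)
  t_ms <- ((seq_len(2L * half) - 1L) - half) / fs * 1000
  resample_to_60(template_eval(tpl, t_ms))
}

# default base shapes: same lobe geometry, different amplitudes, so that the
# steepest downstroke (the alignment anchor) stays at the same grid position
# along the whole morph path
default_shape_a <- function() {
  parametric_template(amps = c(-1.6, 4.8, -2.0),
                      centers_ms = c(-0.65, 0.0, 0.75),
                      widths_ms = c(0.28, 0.30, 0.45))
}
default_shape_b <- function() {
  parametric_template(amps = c(-0.5, 1.6, -0.7),
                      centers_ms = c(-0.65, 0.0, 0.75),
                      widths_ms = c(0.28, 0.30, 0.45))
}

#' Construct a template pair with an exact target distance
#'
#' Morphs base shape B toward base shape A so that the RMSE between the
#' returned pair, measured on the 60-sample analysis grid, equals
#' `target_rmse` exactly: by linearity,
#' `RMSE(A, (1-lambda)A + lambda B) = lambda * RMSE(A, B)`.
#'
#' @param target_rmse Desired RMSE (volts); must not exceed the base-pair
#'   RMSE.
#' @param base_a,base_b Base shapes (defaults span the package's realistic
#'   amplitude range).
#' @param fs Sampling rate defining the analysis grid.
#' @return List: `a`, `b` (parametric templates), `lambda`, `base_rmse`.
#' @export
make_template_pair <- function(target_rmse, base_a = default_shape_a(),
                               base_b = default_shape_b(), fs = 10000) {
  base_rmse <- template_distance(template_values(base_a, fs),
                                 template_values(base_b, fs), "rmse")
  if (target_rmse > base_rmse) {
    stop("parameter error: target_rmse exceeds the base-pair RMSE (",
         signif(base_rmse, 4), ")")
  }
  lambda <- target_rmse / base_rmse
  list(a = base_a, b = template_morph(base_a, base_b, lambda),
       lambda = lambda, base_rmse = base_rmse)
}

# templates for k fibres spread evenly along the morph path between the two
# base shapes (adjacent fibres get more similar as k grows)
default_templates <- function(n_fibers) {
  a <- default_shape_a(); b <- default_shape_b()
  lam <- if (n_fibers == 1) 0 else (seq_len(n_fibers) - 1) / (n_fibers - 1)
  lapply(lam, function(l) template_morph(a, b, l))
}

#' Configuration of a synthetic marking-method recording
#'
#' The generator emulates the study conditions of marking-method
#' microneurography: low-frequency background stimulation (default 0.25 Hz),
#' per-fibre near-constant response latency with small jitter, and
#' activity-dependent slowing (ADS) after extra stimuli: the slowing state of
#' fibre f evolves as `s_f <- (s_f + ads_increment * n_extra_spikes) *
#' exp(-dt/tau)` between sweeps, so an extra-stimulus burst raises the next
#' sweep's latency, which then decays geometrically back to baseline under
#' continued background stimulation.
#'
#' @param fs Sampling rate, 10000 (default) or 30000 Hz.
#' @param n_fibers Number of fibres (tracks).
#' @param stim_freq Background stimulation frequency in Hz (default 0.25).
#' @param n_sweeps Number of background stimuli (default 80, i.e. about
#'   320 s of stimulation).
#' @param base_latency_ms Distinct per-fibre response latencies (default
#'   150, 175, 200, ... ms).
#' @param latency_jitter_sd_ms SD of the per-spike latency jitter (default
#'   0.1 ms — tracks are near-constant).
#' @param templates List of `n_fibers` [parametric_template()]s (default:
#'   evenly spread morphs of the two base shapes).
#' @param noise_sd Additive white Gaussian noise SD in volts (default 0.25).
#' @param ads_increment_ms Latency increment per extra evoked spike (default
#'   2 ms).
#' @param ads_recovery_tau_s Recovery time constant of the slowing state
#'   (default 30 s).
#' @param extra_stimulus_schedule `NULL`, or data frame with columns `sweep`
#'   and `n_pulses`: extra electrical pulses delivered after the given
#'   sweep's background response; every pulse evokes one labelled spike per
#'   fibre.
#' @param overlap_guard_ms Minimum separation between any two spikes
#'   (default 3 ms, one analysis window); violating configurations raise a
#'   generation error, mirroring the exclusion of overlapping-spike
#'   recordings from the study data.
#' @param seed Integer seed; the recording is a deterministic function of the
#'   configuration and seed.
#' @param dataset Dataset identifier written into the recording metadata.
#' @return A validated `mng_synthetic_config` list.
#' @export
synthetic_config <- function(fs = 10000, n_fibers = 2, stim_freq = 0.25,
                             n_sweeps = 80,
                             base_latency_ms = 150 + 25 * (seq_len(n_fibers) - 1),
                             latency_jitter_sd_ms = 0.1,
                             templates = default_templates(n_fibers),
                             noise_sd = 0.25,
                             ads_increment_ms = 2,
                             ads_recovery_tau_s = 30,
                             extra_stimulus_schedule = NULL,
                             overlap_guard_ms = 3,
                             seed = 1L,
                             dataset = "synthetic") {
  window_half(fs)  # validates the rate
  stopifnot(n_fibers >= 1, stim_freq > 0, n_sweeps >= 1,
            length(base_latency_ms) == n_fibers,
            !any(duplicated(base_latency_ms)),
            latency_jitter_sd_ms >= 0, noise_sd >= 0,
            ads_increment_ms >= 0, ads_recovery_tau_s > 0,
            length(templates) == n_fibers)
  if (!is.null(extra_stimulus_schedule)) {
    extra_stimulus_schedule <- as.data.frame(extra_stimulus_schedule)
    stopifnot(all(c("sweep", "n_pulses") %in% names(extra_stimulus_schedule)),
              all(extra_stimulus_schedule$sweep >= 1),
              all(extra_stimulus_schedule$sweep <= n_sweeps),
              all(extra_stimulus_schedule$n_pulses >= 1))
  }
  structure(list(fs = fs, n_fibers = as.integer(n_fibers),
                 stim_freq = stim_freq, n_sweeps = as.integer(n_sweeps),
                 base_latency_ms = as.numeric(base_latency_ms),
                 latency_jitter_sd_ms = latency_jitter_sd_ms,
                 templates = templates, noise_sd = noise_sd,
                 ads_increment_ms = ads_increment_ms,
                 ads_recovery_tau_s = ads_recovery_tau_s,
                 extra_stimulus_schedule = extra_stimulus_schedule,
                 overlap_guard_ms = overlap_guard_ms,
                 seed = as.integer(seed), dataset = dataset),
            class = "mng_synthetic_config")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(unclass(cfg)), tf)
  substr(unname(tools::md5sum(tf)), 1, 8)
}

# the ground-truth aligned template of one fibre: the clean (noise-free)
# waveform as the pipeline sees it after extraction, resampling and alignment
reference_template <- function(tpl, fs, latency_ms, track) {
  margin <- 0.5
  n <- round(2 * margin * fs)
  t_spike <- margin + latency_ms / 1000
  sig <- numeric(n)
  half <- window_half(fs)
  c0 <- floor(t_spike * fs)
  idx <- (c0 - half + 1L):(c0 + half)
  t_ms <- (((idx - 1L) / fs) - t_spike) * 1000
  sig[idx] <- template_eval(tpl, t_ms)
  rec <- recording(sig, fs, stimulus_onsets = numeric(0), t0 = 0)
  w <- align_waveform(extract_window(rec, t_spike), rec = rec, t = t_spike,
                      track = track)
  structure(list(track = track, values = w$samples, n_spikes = NA_integer_),
            class = "mng_template")
}

#' Generate a synthetic marking-method recording
#'
#' Builds the continuous trace (white Gaussian noise plus each fibre's
#' template inserted at its current latency after every background stimulus
#' and after every extra pulse), the stimulus onsets, and the fully labelled
#' spike table. The result is a deterministic function of the configuration
#' and its seed.
#'
#' Ground truth beyond the labels is attached as
#' `attr(rec, "ground_truth")`: the per-fibre aligned reference templates
#' (clean-signal realization at the base latency), the per-sweep latency
#' table, and the configuration.
#'
#' @param cfg A [synthetic_config()].
#' @return An `mng_recording` with one track per fibre.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "mng_synthetic_config"))
  period <- 1 / cfg$stim_freq
  lead_in <- 0.5
  onsets <- lead_in + (seq_len(cfg$n_sweeps) - 1) * period
  duration <- lead_in + cfg$n_sweeps * period
  n <- round(duration * cfg$fs)
  k <- cfg$n_fibers
  half <- window_half(cfg$fs)
  sched <- cfg$extra_stimulus_schedule
  with_seed(cfg$seed, {
    sig <- stats::rnorm(n, 0, cfg$noise_sd)
    s_f <- numeric(k)
    times <- numeric(0); tracks <- character(0)
    lat_rows <- vector("list", cfg$n_sweeps)
    for (sw in seq_len(cfg$n_sweeps)) {
      np <- 0L
      if (!is.null(sched)) {
        hit <- sched$n_pulses[sched$sweep == sw]
        if (length(hit)) np <- as.integer(hit[1])
      }
      lat <- cfg$base_latency_ms + s_f +
        stats::rnorm(k, 0, cfg$latency_jitter_sd_ms)
      sweep_times <- onsets[sw] + lat / 1000
      sweep_tracks <- sprintf("Track%d", seq_len(k))
      evoked <- rep("background", k)
      if (np > 0L) {
        pulse_t <- onsets[sw] + 1.0 + (seq_len(np) - 1) * 0.2
        for (pt in pulse_t) {
          lat_x <- cfg$base_latency_ms + s_f +
            stats::rnorm(k, 0, cfg$latency_jitter_sd_ms)
          sweep_times <- c(sweep_times, pt + lat_x / 1000)
          sweep_tracks <- c(sweep_tracks, sprintf("Track%d", seq_len(k)))
          evoked <- c(evoked, rep("extra", k))
        }
      }
      guard <- cfg$overlap_guard_ms / 1000
      if (length(sweep_times) > 1 &&
          min(diff(sort(sweep_times))) < guard) {
        stop("generation error: spike separation below the overlap guard (",
             cfg$overlap_guard_ms, " ms) in sweep ", sw)
      }
      times <- c(times, sweep_times)
      tracks <- c(tracks, sweep_tracks)
      lat_rows[[sw]] <- data.frame(sweep = sw, track = sweep_tracks,
                                   latency_ms = (sweep_times - onsets[sw]) * 1000,
                                   evoked_by = evoked,
                                   stringsAsFactors = FALSE)
      s_f <- (s_f + cfg$ads_increment_ms * np) * exp(-period / cfg$ads_recovery_tau_s)
    }
    fiber_of <- as.integer(sub("Track", "", tracks))
    for (i in seq_along(times)) {
      c0 <- floor(times[i] * cfg$fs)
      idx <- (c0 - half + 1L):(c0 + half)
      if (idx[1] < 1L || idx[length(idx)] > n) {
        stop("generation error: spike window outside the signal")
      }
      t_ms <- (((idx - 1L) / cfg$fs) - times[i]) * 1000
      sig[idx] <- sig[idx] + template_eval(cfg$templates[[fiber_of[i]]], t_ms)
    }
    ord <- order(times)
    rec <- recording(
      signal = sig, fs = cfg$fs, t0 = 0, stimulus_onsets = onsets,
      spikes = data.frame(time = times[ord], track = tracks[ord],
                          stringsAsFactors = FALSE),
      meta = list(dataset = cfg$dataset, dialect = "generic",
                  seed = as.character(cfg$seed),
                  config_hash = config_hash(cfg)))
    ref <- lapply(seq_len(k), function(f) {
      reference_template(cfg$templates[[f]], cfg$fs, cfg$base_latency_ms[f],
                         sprintf("Track%d", f))
    })
    names(ref) <- sprintf("Track%d", seq_len(k))
    attr(rec, "ground_truth") <- list(templates = ref,
                                      latency_table = do.call(rbind, lat_rows),
                                      config = cfg)
    rec
  })
}

#' Generate a reproducible benchmark suite of synthetic recordings
#'
#' Expands the grid `n_fibers x target_rmse x noise_sd x seeds` into one
#' recording per cell. `target_rmse` (template-pair distance control) applies
#' to two-fibre cells; multi-fibre cells use the evenly spread default
#' templates. A manifest records the cell parameters and a configuration hash
#' per recording.
#'
#' @param n_fibers Integer vector of fibre counts.
#' @param target_rmse Numeric vector of two-fibre template RMSE targets, or
#'   `NA` for the default templates.
#' @param noise_sd Numeric vector of noise levels (volts).
#' @param seeds Integer vector of seeds.
#' @param ... Further arguments passed to [synthetic_config()] (e.g.
#'   `n_sweeps`).
#' @return List with `recordings` (named list of `mng_recording`) and
#'   `manifest` (data frame `id`, `n_fibers`, `target_rmse`, `noise_sd`,
#'   `seed`, `config_hash`).
#' @export
generate_benchmark_suite <- function(n_fibers = 2, target_rmse = NA,
                                     noise_sd = 0.25, seeds = 1L, ...) {
  grid <- expand.grid(n_fibers = n_fibers, target_rmse = target_rmse,
                      noise_sd = noise_sd, seed = seeds)
  recs <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  hashes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tpl <- if (!is.na(g$target_rmse) && g$n_fibers == 2) {
      pair <- make_template_pair(g$target_rmse)
      list(pair$a, pair$b)
    } else {
      default_templates(g$n_fibers)
    }
    id <- sprintf("syn_k%d_r%s_n%s_s%d", g$n_fibers,
                  ifelse(is.na(g$target_rmse), "def",
                         format(g$target_rmse, nsmall = 2)),
                  format(g$noise_sd, nsmall = 2), g$seed)
    cfg <- synthetic_config(n_fibers = g$n_fibers, templates = tpl,
                            noise_sd = g$noise_sd, seed = g$seed,
                            dataset = id, ...)
    recs[[i]] <- generate_recording(cfg)
    ids[i] <- id
    hashes[i] <- config_hash(cfg)
  }
  names(recs) <- ids
  list(recordings = recs,
       manifest = data.frame(id = ids, n_fibers = grid$n_fibers,
                             target_rmse = grid$target_rmse,
                             noise_sd = grid$noise_sd, seed = grid$seed,
                             config_hash = hashes, stringsAsFactors = FALSE))
}
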