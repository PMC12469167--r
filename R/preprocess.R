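# condition helpers: boundary/alignment exclusions are signalled as classed
# errors so the extraction loop can count them per reason (the per-feature-set
# spike accounting depends on these counts)
mng_stop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

window_half <- function(fs) {
  # an extracellular C-fibre spike spans ~3 ms; 30 samples at 10 kHz,
  # 60 samples at 30 kHz (the two acquisition rates in use)
  if (fs == 10000) 15L
  else if (fs == 30000) 30L
  else stop("parameter error: window extraction supports fs of 10000 or 30000 Hz")
}

#' Extract the raw data slice around a spike
#'
#' Returns the window `[t - 15, t + 15)` samples at 10 kHz (30 samples) or
#' `[t - 30, t + 30)` at 30 kHz (60 samples), centered on the sample that
#' contains `t` (half-open sample convention). Spikes whose window would cross
#' the recording boundary raise a boundary error and are excluded from
#' downstream feature sets.
#'
#' @param rec A [recording()].
#' @param t Spike time in seconds.
#' @return Numeric window with attributes `start0` (0-based index of the first
#'   sample) and `center0` (0-based index of the sample containing `t`).
#' @export
extract_window <- function(rec, t) {
  half <- window_half(rec$fs)
  c0 <- floor((t - rec$t0) * rec$fs)  # 0-based sample containing t
  n <- length(rec$signal)
  if (c0 - half < 0 || c0 + half > n) {
    mng_stop("mng_boundary_error",
             sprintf("boundary error: window for t=%.6f s exceeds signal bounds", t))
  }
  w <- rec$signal[(c0 - half + 1L):(c0 + half)]
  attr(w, "start0") <- c0 - half
  attr(w, "center0") <- c0
  w
}

#' Band-limited resampling of a spike window to 60 samples
#'
#' Fourier (FFT zero-padding) resampling, the band-limited scheme used to bring
#' 30-sample windows (10 kHz) onto the common 60-sample analysis grid.
#' Length-60 input is returned unchanged. The Nyquist bin of the 30-sample
#' spectrum is split symmetrically, so a pure sinusoid below Nyquist is
#' reproduced exactly.
#'
#' @param window Numeric vector of length 30 or 60.
#' @return Numeric vector of length 60.
#' @export
resample_to_60 <- function(window) {
  n <- length(window)
  if (n == 60L) return(as.numeric(window))
  if (n != 30L) stop("parameter error: window must have 30 or 60 samples")
  x <- stats::fft(as.numeric(window))
  m <- 60L
  y <- complex(m)
  half <- n %/% 2L                      # 15: Nyquist bin of the even-length input
  y[1:half] <- x[1:half]                # DC .. k=14
  y[half + 1L] <- x[half + 1L] / 2      # split Nyquist
  y[m - half + 1L] <- Conj(x[half + 1L]) / 2
  if (half > 1L) y[(m - half + 2L):m] <- x[(half + 2L):n]
  Re(stats::fft(y, inverse = TRUE)) / n # scaling: (1/m) * m/n
}

#' First and second derivatives of an aligned window
#'
#' Central difference quotients in the interior and one-sided differences at
#' the two ends, in volts per sample. The second derivative is the same
#' operator applied to the first derivative.
#'
#' @param samples Numeric vector of length 60.
#' @return List with numeric vectors `fd` and `sd`, both length 60.
#' @export
differentiate_waveform <- function(samples) {
  stopifnot(length(samples) == 60L)
  d1 <- function(x) {
    n <- length(x)
    fd <- numeric(n)
    fd[1] <- x[2] - x[1]
    fd[n] <- x[n] - x[n - 1]
    fd[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    fd
  }
  fd <- d1(as.numeric(samples))
  list(fd = fd, sd = d1(fd))
}

# shift window content: positive shift moves content left (out[i] = x[i+shift]).
# "pad" replicates the edge value (a zero step would inject a spurious
# derivative peak); "circular" wraps.
shift_window <- function(x, shift, mode = c("pad", "circular")) {
  mode <- match.arg(mode)
  n <- length(x)
  idx <- seq_len(n) + shift
  if (mode == "circular") idx <- ((idx - 1L) %% n) + 1L else idx <- pmin(pmax(idx, 1L), n)
  x[idx]
}

#' Align a spike window at the negative peak of its first derivative
#'
#' Spikes are aligned so that the maximum negative peak of the first derivative
#' sits at the canonical grid position 30 (0-based; index 31 of the 60-sample
#' window), i.e. at the window center. Ties are broken by the earliest index.
#' By default the aligned window is re-extracted from the raw signal at the
#' shifted center whenever the shift maps to whole raw samples and stays in
#' bounds, which avoids padding artifacts; otherwise the window is shifted on
#' the 60-sample grid with edge padding (or circularly, if requested).
#'
#' @param samples Window of 30 or 60 samples (e.g. from [extract_window()]).
#' @param rec,t Optional source recording and spike time enabling
#'   re-extraction; required for `mode = "reextract"` to have any effect.
#' @param mode `"reextract"` (default), `"pad"`, or `"circular"`.
#' @param track Track label carried on the result.
#' @return An object of class `mng_waveform` with fields `samples`, `fd`, `sd`
#'   (length 60), `align_index` (31, 1-based), `source_time`, `track`.
#' @export
align_waveform <- function(samples, rec = NULL, t = NULL,
                           mode = c("reextract", "pad", "circular"),
                           track = NA_character_) {
  mode <- match.arg(mode)
  canon <- 31L  # 0-based 30
  if (inherits(samples, "mng_waveform")) samples <- samples$samples
  s <- resample_to_60(as.numeric(samples))
  d <- differentiate_waveform(s)
  if (max(d$fd) - min(d$fd) <= 0) {
    mng_stop("mng_alignment_error",
             "alignment error: first derivative has no negative peak")
  }
  can_reextract <- mode == "reextract" && !is.null(rec) && !is.null(t)
  grid_mode <- if (mode == "circular") "circular" else "pad"
  half <- if (can_reextract) window_half(rec$fs) else NA_integer_
  step_raw <- if (can_reextract) (2 * half) / 60 else NA_real_  # raw samples per grid step
  c0 <- if (can_reextract) floor((t - rec$t0) * rec$fs) else NA_integer_
  for (iter in 1:6) {
    j <- which.min(d$fd)
    shift <- j - canon
    if (shift == 0L) break
    if (can_reextract) {
      rs <- trunc(shift * step_raw)
      if (rs != 0 && c0 + rs - half >= 0 && c0 + rs + half <= length(rec$signal)) {
        c0 <- c0 + rs
        w <- rec$signal[(c0 - half + 1L):(c0 + half)]
        s <- resample_to_60(w)
        d <- differentiate_waveform(s)
        can_reextract <- FALSE  # at most one re-extraction, then grid shifts
        next
      }
      can_reextract <- FALSE
    }
    s <- shift_window(s, shift, grid_mode)
    d <- differentiate_waveform(s)
  }
  j <- which.min(d$fd)
  if (j != canon) {
    mng_stop("mng_alignment_error",
             "alignment error: first-derivative minimum did not converge to the window center")
  }
  structure(list(samples = s, fd = d$fd, sd = d$sd, align_index = canon,
                 source_time = if (is.null(t)) NA_real_ else t, track = track),
            class = "mng_waveform")
}

#' Extract and align every labeled spike of a recording
#'
#' Runs [extract_window()] + [align_waveform()] over all labeled spikes.
#' Spikes whose window crosses the recording boundary or whose first
#' derivative has no negative peak are excluded and counted by reason, so that
#' included + excluded always equals the number of labeled spikes.
#'
#' @param rec A [recording()].
#' @param mode Alignment shift mode, see [align_waveform()].
#' @return List with `waveforms` (list of `mng_waveform`) and `excluded`
#'   (data frame `time`, `track`, `reason`).
#' @export
extract_waveforms <- function(rec, mode = "reextract") {
  sp <- rec$spikes[!is.na(rec$spikes$track), , drop = FALSE]
  waves <- vector("list", nrow(sp))
  exc_time <- numeric(0); exc_track <- character(0); exc_reason <- character(0)
  kept <- logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    res <- tryCatch({
      w <- extract_window(rec, sp$time[i])
      align_waveform(w, rec = rec, t = sp$time[i], mode = mode,
                     track = sp$track[i])
    },
    mng_boundary_error = function(e) "boundary",
    mng_alignment_error = function(e) "alignment")
    if (is.character(res)) {
      exc_time <- c(exc_time, sp$time[i])
      exc_track <- c(exc_track, sp$track[i])
      exc_reason <- c(exc_reason, res)
    } else {
      waves[[i]] <- res
      kept[i] <- TRUE
    }
  }
  list(waveforms = waves[kept],
       excluded = data.frame(time = exc_time, track = exc_track,
                             reason = exc_reason, stringsAsFactors = FALSE))
}

#' Per-track template by averaging aligned spikes
#'
#' The template of a track is the pointwise mean of all its aligned spike
#' waveforms; it is the representative waveform used for morphology comparison
#' and the between-template distance metrics.
#'
#' @param waveforms Non-empty list of `mng_waveform` sharing one track label.
#' @return An object of class `mng_template` with `track`, `values` (60
#'   samples) and `n_spikes`.
#' @export
compute_template <- function(waveforms) {
  if (!length(waveforms)) stop("parameter error: no waveforms to average")
  tracks <- unique(vapply(waveforms, function(w) w$track, character(1)))
  if (length(tracks) > 1) stop("parameter error: waveforms span multiple tracks")
  m <- do.call(rbind, lapply(waveforms, function(w) w$samples))
  structure(list(track = tracks, values = colMeans(m),
                 n_spikes = length(waveforms)),
            class = "mng_template")
}

#' Templates for every track of a waveform set
#'
#' @param waveforms List of `mng_waveform` (mixed tracks allowed).
#' @return Named list of `mng_template`, one per track, sorted by track name.
#' @export
compute_templates <- function(waveforms) {
  tracks <- vapply(waveforms, function(w) w$track, character(1))
  out <- lapply(split(waveforms, tracks), compute_template)
  out[order(names(out))]
}

#' Waterfall representation of a recording
#'
#' Cuts the signal into one sweep per background stimulus (each sweep spans to
#' the next onset, the last one to the end of the signal) and expresses every
#' labeled spike as a latency (ms) from its sweep onset. Stacking the sweeps
#' makes the tracks appear as vertical spike alignments, the standard
#' marking-method display.
#'
#' @param rec A [recording()] with at least one stimulus onset.
#' @return Object of class `mng_waterfall`: list with `sweeps` (list of
#'   `onset`, `segment`) and `latencies` (data frame `sweep`, `onset`,
#'   `latency_ms`, `track`).
#' @export
build_waterfall <- function(rec) {
  on <- rec$stimulus_onsets
  if (!length(on)) stop("parameter error: waterfall needs at least one stimulus onset")
  n <- length(rec$signal)
  bounds0 <- c(round((on - rec$t0) * rec$fs), n)  # 0-based segment starts + end
  sweeps <- lapply(seq_along(on), function(i) {
    list(onset = on[i],
         segment = rec$signal[(bounds0[i] + 1L):bounds0[i + 1L]])
  })
  sp <- rec$spikes[!is.na(rec$spikes$track), , drop = FALSE]
  if (nrow(sp)) {
    sweep <- findInterval(sp$time, on)
    onset <- ifelse(sweep >= 1L, on[pmax(sweep, 1L)], rec$t0)
    if (any(sweep < 1L)) {
      warning("spike(s) before the first stimulus onset: latency taken relative to t0")
    }
    lat <- data.frame(sweep = sweep, onset = onset,
                      latency_ms = (sp$time - onset) * 1000,
                      track = sp$track, stringsAsFactors = FALSE)
  } else {
    lat <- data.frame(sweep = integer(0), onset = numeric(0),
                      latency_ms = numeric(0), track = character(0))
  }
  structure(list(sweeps = sweeps, latencies = lat), class = "mng_waterfall")
}

#' Export aligned waveforms as a flat matrix
#'
#' @param waveforms List of `mng_waveform`.
#' @return Matrix (one row per spike, 60 columns) with rownames dropped and
#'   attribute `tracks` (character vector of labels).
#' @export
waveform_matrix <- function(waveforms) {
  m <- do.call(rbind, lapply(waveforms, function(w) w$samples))
  attr(m, "tracks") <- vapply(waveforms, function(w) w$track, character(1))
  m
}
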