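#' Harmonized microneurography recording
#'
#' A `recording` bundles everything the sorting pipeline needs about one
#' microneurography session: the continuous voltage trace, its sampling rate,
#' the onset times of the low-frequency background stimulation, and the spike
#' events together with their track labels (a *track* is the sequence of
#' time-locked responses of one C-fibre, the equivalent of a unit in
#' conventional spike sorting). Times are seconds, 0-based relative to `t0`;
#' sample `i` (0-based) covers the half-open interval
#' `[t0 + i/fs, t0 + (i+1)/fs)`.
#'
#' @param signal Numeric vector of voltages (volts).
#' @param fs Sampling rate in Hz; 10000 and 30000 are the rates the window
#'   extraction supports.
#' @param stimulus_onsets Strictly increasing numeric vector of background
#'   stimulus times (seconds).
#' @param spikes `data.frame` with columns `time` (seconds) and `track`
#'   (character label; `NA` marks an unlabeled spike, which is carried through
#'   I/O but excluded from every evaluation).
#' @param t0 Start time of the first sample (seconds).
#' @param meta Named list of string metadata (lab dialect, dataset id, ...).
#' @return An object of class `mng_recording`.
#' @seealso [read_recording()], [write_recording()], [apply_dialect()]
#' @export
recording <- function(signal, fs, stimulus_onsets = numeric(0),
                      spikes = data.frame(time = numeric(0),
                                          track = character(0)),
                      t0 = 0, meta = list()) {
  spikes <- as.data.frame(spikes)
  if (!all(c("time", "track") %in% names(spikes))) {
    stop("spikes must have columns 'time' and 'track'")
  }
  spikes$track <- as.character(spikes$track)
  rec <- structure(
    list(signal = as.numeric(signal), fs = as.numeric(fs),
         t0 = as.numeric(t0),
         stimulus_onsets = as.numeric(stimulus_onsets),
         spikes = spikes[, c("time", "track")], meta = meta),
    class = "mng_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks that `fs > 0`, the signal is finite, stimulus onsets are strictly
#' increasing, and every spike time lies inside the recorded interval.
#'
#' @param rec A [recording()].
#' @return `rec`, invisibly; errors otherwise.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "mng_recording"))
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("fs must be > 0")
  if (anyNA(rec$signal) || !all(is.finite(rec$signal))) {
    stop("signal contains non-finite values")
  }
  on <- rec$stimulus_onsets
  if (length(on) > 1 && any(diff(on) <= 0)) {
    stop("validation error: stimulus_onsets must be strictly increasing")
  }
  t_end <- rec$t0 + length(rec$signal) / rec$fs
  tt <- rec$spikes$time
  if (length(tt) && (any(!is.finite(tt)) || any(tt < rec$t0) || any(tt > t_end))) {
    stop("validation error: spike times must be finite and within [t0, t0 + len/fs]")
  }
  lab <- rec$spikes$track
  if (length(lab) && any(!is.na(lab) & !nzchar(lab))) {
    stop("validation error: labeled tracks must be non-empty strings")
  }
  invisible(rec)
}

#' Lab-dialect correction specification
#'
#' The two contributing laboratories export signals with different conventions.
#' Dialect `"B"` (Bristol-style, 30 kHz) records with inverted polarity, so the
#' signal is negated and then smoothed with a centered rolling mean. Dialect
#' `"A"` (Aachen-style, 10 kHz) occasionally contains acquisition gaps which
#' must be zero-padded so the time base stays uniform. `"generic"` applies no
#' correction.
#'
#' @param name One of `"generic"`, `"A"`, `"B"`.
#' @param polarity_invert Negate the signal before smoothing. Forced `TRUE` for
#'   dialect `"B"`.
#' @param smoothing_window Centered rolling-mean window length in samples
#'   (default 3; the source labs do not publish a value, so it is a parameter).
#'   `1` disables smoothing.
#' @param pad_gaps Fill declared acquisition gaps with zeros. Forced `TRUE` for
#'   dialect `"A"`.
#' @return A `mng_dialect` list.
#' @export
dialect_spec <- function(name = c("generic", "A", "B"),
                         polarity_invert = NULL,
                         smoothing_window = 3L,
                         pad_gaps = NULL) {
  name <- match.arg(name)
  if (is.null(polarity_invert)) polarity_invert <- identical(name, "B")
  if (is.null(pad_gaps)) pad_gaps <- identical(name, "A")
  if (identical(name, "B") && !polarity_invert) {
    stop("dialect B requires polarity_invert = TRUE")
  }
  if (identical(name, "A") && !pad_gaps) {
    stop("dialect A requires pad_gaps = TRUE")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L) stop("smoothing_window must be >= 1")
  structure(list(name = name, polarity_invert = polarity_invert,
                 smoothing_window = smoothing_window, pad_gaps = pad_gaps),
            class = "mng_dialect")
}

# centered rolling mean; edge windows shrink to the available samples so the
# output keeps the input length without NA padding
rolling_mean <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Apply lab-dialect corrections to a recording
#'
#' Dialect `"B"`: the signal is replaced by a centered rolling mean of the
#' negated trace. Dialect `"A"`: acquisition gaps declared in
#' `rec$meta$gaps` (a data frame of `start`,`end` seconds) are filled with
#' zeros so that sample index and time stay consistent. `"generic"` is the
#' identity.
#'
#' @param rec A [recording()].
#' @param dialect A [dialect_spec()].
#' @return A corrected `mng_recording` (same `fs`).
#' @export
apply_dialect <- function(rec, dialect = dialect_spec("generic")) {
  validate_recording(rec)
  stopifnot(inherits(dialect, "mng_dialect"))
  if (identical(dialect$name, "generic")) return(rec)
  if (identical(dialect$name, "B")) {
    if (dialect$smoothing_window > length(rec$signal)) {
      stop("parameter error: smoothing_window exceeds signal length")
    }
    x <- if (dialect$polarity_invert) -rec$signal else rec$signal
    rec$signal <- rolling_mean(x, dialect$smoothing_window)
    return(validate_recording(rec))
  }
  # dialect A: insert zeros for every declared gap
  gaps <- rec$meta$gaps
  if (dialect$pad_gaps && !is.null(gaps) && nrow(gaps)) {
    gaps <- gaps[order(gaps$start), , drop = FALSE]
    sig <- rec$signal
    # process from the last gap so earlier insert positions stay valid
    for (g in rev(seq_len(nrow(gaps)))) {
      n_pad <- round((gaps$end[g] - gaps$start[g]) * rec$fs)
      if (n_pad <= 0) next
      at <- round((gaps$start[g] - rec$t0) * rec$fs)  # 0-based insert position
      sig <- append(sig, rep(0, n_pad), after = at)
    }
    rec$signal <- sig
    rec$meta$gaps <- NULL
  }
  validate_recording(rec)
  rec
}

#' Write a recording to a plain-text container
#'
#' The container is a directory holding `signal.csv` (`t,v`), `stimuli.csv`
#' (`t`), `spikes.csv` (`t,track`) and a `meta.json` sidecar carrying `fs`,
#' `t0` and the metadata map. The layout is a direct translation of the
#' HDF5/NIX grouping `/signal{data,fs,t0}`, `/stimuli{onsets}`,
#' `/spikes{times,tracks}`, `/meta`.
#'
#' @param rec A valid [recording()]; a signal containing NaN/Inf is rejected.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create ", path)
  t <- rec$t0 + (seq_along(rec$signal) - 1L) / rec$fs
  data.table::fwrite(data.table::data.table(t = t, v = rec$signal),
                     file.path(path, "signal.csv"))
  data.table::fwrite(data.table::data.table(t = rec$stimulus_onsets),
                     file.path(path, "stimuli.csv"))
  data.table::fwrite(data.table::data.table(t = rec$spikes$time,
                                            track = rec$spikes$track),
                     file.path(path, "spikes.csv"))
  meta <- rec$meta
  meta$gaps <- NULL
  sidecar <- list(fs = rec$fs, t0 = rec$t0, meta = meta)
  if (!is.null(rec$meta$gaps)) sidecar$gaps <- rec$meta$gaps
  jsonlite::write_json(sidecar, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from a plain-text container
#'
#' Reads the directory layout written by [write_recording()] and applies the
#' dialect corrections. For dialect `"A"`, gaps in the `signal.csv` time base
#' (consecutive samples more than 1.5 sample intervals apart) are zero-filled
#' at read time so the returned signal is uniformly sampled.
#'
#' @param path Container directory.
#' @param dialect A [dialect_spec()].
#' @return A validated `mng_recording`.
#' @export
read_recording <- function(path, dialect = dialect_spec("generic")) {
  if (!dir.exists(path)) stop("format error: no such container: ", path)
  need <- c("signal.csv", "stimuli.csv", "spikes.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("format error: container is missing '", f, "'")
    }
  }
  sidecar <- jsonlite::read_json(file.path(path, "meta.json"),
                                 simplifyVector = TRUE)
  for (field in c("fs", "t0")) {
    if (is.null(sidecar[[field]])) {
      stop("format error: meta.json is missing field '", field, "'")
    }
  }
  fs <- as.numeric(sidecar$fs)
  t0 <- as.numeric(sidecar$t0)
  sig_df <- data.table::fread(file.path(path, "signal.csv"))
  if (!all(c("t", "v") %in% names(sig_df))) {
    stop("format error: signal.csv must have columns t,v")
  }
  sig <- as.numeric(sig_df$v)
  tt <- as.numeric(sig_df$t)
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(dt > 1.5 / fs)) {
      if (!dialect$pad_gaps) {
        stop("validation error: signal time base has gaps; use a pad_gaps dialect")
      }
      pieces <- list()
      brk <- which(dt > 1.5 / fs)
      start <- 1L
      for (b in brk) {
        pieces[[length(pieces) + 1L]] <- sig[start:b]
        n_pad <- round(dt[b] * fs) - 1L
        pieces[[length(pieces) + 1L]] <- rep(0, n_pad)
        start <- b + 1L
      }
      pieces[[length(pieces) + 1L]] <- sig[start:length(sig)]
      sig <- unlist(pieces)
    }
  }
  sp <- data.table::fread(file.path(path, "spikes.csv"),
                          colClasses = list(character = "track"))
  if (!all(c("t", "track") %in% names(sp))) {
    stop("format error: spikes.csv must have columns t,track")
  }
  st <- data.table::fread(file.path(path, "stimuli.csv"))
  if (!"t" %in% names(st)) stop("format error: stimuli.csv must have column t")
  meta <- as.list(sidecar$meta)
  if (!is.null(sidecar$gaps)) meta$gaps <- as.data.frame(sidecar$gaps)
  track <- sp$track
  track[!is.na(track) & track == ""] <- NA_character_
  rec <- recording(signal = sig, fs = fs, t0 = t0,
                   stimulus_onsets = as.numeric(st$t),
                   spikes = data.frame(time = as.numeric(sp$t),
                                       track = track,
                                       stringsAsFactors = FALSE),
                   meta = meta)
  if (!identical(dialect$name, "generic")) rec <- apply_dialect(rec, dialect)
  rec
}

#' @export
print.mng_recording <- function(x, ...) {
  n_lab <- sum(!is.na(x$spikes$track))
  cat(sprintf(paste0("<mng_recording> %.1f s @ %g Hz | %d stimuli | ",
                     "%d spikes (%d labeled, %d tracks)\n"),
              length(x$signal) / x$fs, x$fs, length(x$stimulus_onsets),
              nrow(x$spikes), n_lab,
              length(unique(stats::na.omit(x$spikes$track)))))
  invisible(x)
}
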