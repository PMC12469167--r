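#' Amplitude and full-width-half-maximum ("simple") features
#'
#' Amplitude `a` is the positive peak voltage of the aligned spike; width `w`
#' is the full width at half maximum: the distance (in grid samples) between
#' the two nearest points on either side of the peak where the signal falls
#' below `a/2`, located by linear interpolation. A spike is excluded when its
#' peak is not positive or when a half-amplitude crossing is missing on either
#' side of the peak within the window.
#'
#' @param w An `mng_waveform` (see [align_waveform()]) or a length-60 numeric.
#' @return Named numeric `c(a, w)`, or `NULL` when the spike is excluded.
#' @export
feat_simple <- function(w) {
  s <- if (inherits(w, "mng_waveform")) w$samples else as.numeric(w)
  a <- max(s)
  if (a <= 0) return(NULL)
  p <- which.max(s)
  half <- a / 2
  n <- length(s)
  # left crossing: first sample below a/2 when scanning left from the peak
  xl <- NA_real_
  if (p > 1L) {
    for (i in (p - 1L):1L) {
      if (s[i] < half) {
        xl <- i + (half - s[i]) / (s[i + 1L] - s[i])
        break
      }
    }
  }
  xr <- NA_real_
  if (p < n) {
    for (i in (p + 1L):n) {
      if (s[i] < half) {
        xr <- (i - 1L) + (s[i - 1L] - half) / (s[i - 1L] - s[i])
        break
      }
    }
  }
  if (is.na(xl) || is.na(xr)) return(NULL)
  c(a = a, w = xr - xl)
}

# first index i >= 2 whose sign differs from the previous sample's sign
# (exact zeros count as a sign change); NA when the sign never changes
first_sign_change <- function(x, from = 2L, to = length(x)) {
  s <- sign(x)
  for (i in from:to) if (s[i] != s[i - 1L]) return(i)
  NA_integer_
}

#' Fundamental points of a spike
#'
#' Six landmark indices of the aligned window anchor the shape/phase/
#' distribution feature computations. The first (P1) is the first
#' zero-crossing of the first derivative, scanning from the window start; a
#' spike with no such crossing has undefined fundamental points and is
#' excluded from the derivative-based feature sets. The remaining landmarks
#' follow this package's documented interpretation of the SS-SPDF construction:
#' P2/P3 are the positive/negative peaks of the first derivative, P4 the
#' first-derivative zero-crossing between them (the spike peak; falls back to
#' the sample maximum between P2 and P3 when no crossing exists), and P5/P6
#' the positive/negative peaks of the second derivative.
#'
#' @param w An `mng_waveform`.
#' @return List `P1..P6` (1-based indices) and logical `defined`.
#' @export
fundamental_points <- function(w) {
  stopifnot(inherits(w, "mng_waveform"))
  fd <- w$fd; sd_ <- w$sd
  P1 <- first_sign_change(fd)
  if (is.na(P1)) {
    return(list(P1 = NA_integer_, P2 = NA_integer_, P3 = NA_integer_,
                P4 = NA_integer_, P5 = NA_integer_, P6 = NA_integer_,
                defined = FALSE))
  }
  P2 <- which.max(fd)
  P3 <- which.min(fd)
  lo <- min(P2, P3); hi <- max(P2, P3)
  P4 <- if (hi > lo) first_sign_change(fd, from = lo + 1L, to = hi) else NA_integer_
  if (is.na(P4)) P4 <- lo + which.max(w$samples[lo:hi]) - 1L
  list(P1 = P1, P2 = P2, P3 = P3, P4 = P4,
       P5 = which.max(sd_), P6 = which.min(sd_), defined = TRUE)
}

safe_moment <- function(x, fun) {
  if (stats::sd(x) == 0) return(0)
  fun(x)
}

# run length of consecutive samples satisfying pred that contains index i
run_containing <- function(keep, i) {
  if (!keep[i]) return(0L)
  lo <- i; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- i; while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' The shape/phase/distribution feature registry
#'
#' Twenty-three per-spike features computed from the first derivative (fd),
#' the second derivative (sd) and the fundamental points of the aligned
#' window. Feature 4 of the original 24-feature catalogue is omitted (its
#' reference waveform is not reproducible) and feature 8 is the mean of the
#' squared fd amplitudes between the window start and P1. Features 14, 18 and
#' 19 are the positive peak of fd, the positive peak of sd and the negative
#' peak of sd. The remaining formulas are this package's documented
#' interpretation of the construction, grouped as *shape* (fd time-domain
#' geometry, f1-f8), *phase* (fd/sd phase-plane relations at fundamental
#' points, f9-f16) and *distribution* (moments and extrema of the fd and sd
#' amplitude distributions, f17-f24).
#'
#' @return Data frame `name`, `group`, `description`, one row per feature in
#'   matrix column order.
#' @export
spdf_feature_registry <- function() {
  data.frame(
    name = c("f1", "f2", "f3", "f5", "f6", "f7", "f8",
             "f9", "f10", "f11", "f12", "f13", "f14", "f15", "f16",
             "f17", "f18", "f19", "f20", "f21", "f22", "f23", "f24"),
    group = c(rep("shape", 7), rep("phase", 8), rep("distribution", 8)),
    description = c(
      "samples between the fd extrema (P3 - P2)",
      "rise-region width (P4 - P1)",
      "signed area of fd over the window",
      "area of |fd| over the window",
      "width of the positive fd lobe containing P2",
      "width of the negative fd lobe containing P3",
      "mean squared fd amplitude before P1 (window start to P1-1)",
      "sd at the positive fd peak (sd[P2])",
      "sd at the negative fd peak (sd[P3])",
      "fd at the positive sd peak (fd[P5])",
      "fd at the negative sd peak (fd[P6])",
      "phase-plane radius at P3: sqrt(fd[P3]^2 + sd[P3]^2)",
      "positive peak of fd (max fd)",
      "phase-plane angle at P2: atan2(sd[P2], fd[P2])",
      "phase-plane radius at P2: sqrt(fd[P2]^2 + sd[P2]^2)",
      "standard deviation of the fd amplitudes",
      "positive peak of sd (max sd)",
      "negative peak of sd (min sd)",
      "skewness of the fd amplitude distribution",
      "excess kurtosis of the fd amplitude distribution",
      "standard deviation of the sd amplitudes",
      "skewness of the sd amplitude distribution",
      "excess kurtosis of the sd amplitude distribution"),
    stringsAsFactors = FALSE)
}

#' Full 23-component shape/phase/distribution feature vector
#'
#' See [spdf_feature_registry()] for the catalogue. Spikes whose fundamental
#' points are undefined (no first-derivative zero-crossing) are excluded; the
#' reduced three-feature subset ([feat_fv3()]) shares exactly this exclusion
#' rule, so both feature sets keep the same spikes.
#'
#' @param w An `mng_waveform`.
#' @param points Optional precomputed [fundamental_points()].
#' @return Named numeric of length 23, or `NULL` when excluded.
#' @export
feat_spdf <- function(w, points = fundamental_points(w)) {
  if (!points$defined) return(NULL)
  fd <- w$fd; sd_ <- w$sd
  P1 <- points$P1; P2 <- points$P2; P3 <- points$P3
  P5 <- points$P5; P6 <- points$P6
  vals <- c(
    f1  = as.numeric(P3 - P2),
    f2  = as.numeric(points$P4 - P1),
    f3  = sum(fd),
    f5  = sum(abs(fd)),
    f6  = as.numeric(run_containing(fd > 0, P2)),
    f7  = as.numeric(run_containing(fd < 0, P3)),
    f8  = sum(fd[seq_len(P1 - 1L)]^2) / (P1 - 1L),
    f9  = sd_[P2],
    f10 = sd_[P3],
    f11 = fd[P5],
    f12 = fd[P6],
    f13 = sqrt(fd[P3]^2 + sd_[P3]^2),
    f14 = max(fd),
    f15 = atan2(sd_[P2], fd[P2]),
    f16 = sqrt(fd[P2]^2 + sd_[P2]^2),
    f17 = stats::sd(fd),
    f18 = max(sd_),
    f19 = min(sd_),
    f20 = safe_moment(fd, e1071::skewness),
    f21 = safe_moment(fd, e1071::kurtosis),
    f22 = stats::sd(sd_),
    f23 = safe_moment(sd_, e1071::skewness),
    f24 = safe_moment(sd_, e1071::kurtosis))
  vals
}

#' Reduced three-feature subset (FV3)
#'
#' The positive peak of the first derivative (f14), the positive peak of the
#' second derivative (f18) and the negative peak of the second derivative
#' (f19). Shares the exclusion mask of [feat_spdf()].
#'
#' @inheritParams feat_spdf
#' @return Named numeric `c(f14, f18, f19)`, or `NULL` when excluded.
#' @export
feat_fv3 <- function(w, points = fundamental_points(w)) {
  if (!points$defined) return(NULL)
  c(f14 = max(w$fd), f18 = max(w$sd), f19 = min(w$sd))
}

#' Raw waveform feature vector
#'
#' The aligned voltage samples themselves; never excluded beyond the
#' preprocessing exclusions.
#'
#' @param w An `mng_waveform`.
#' @return Numeric vector of the 60 aligned samples.
#' @export
feat_raw <- function(w) {
  if (inherits(w, "mng_waveform")) w$samples else as.numeric(w)
}

#' Fit a per-recording PCA on raw waveform features
#'
#' Mean-centered (unscaled) principal component analysis of the raw waveform
#' matrix of one recording, retaining `n_comp` components.
#'
#' @param X Numeric matrix (spikes x samples).
#' @param n_comp Number of components, must be `< nrow(X)`.
#' @return List with `model` (fields `mean`, `components`,
#'   `explained_variance_ratio` over all available components) and `scores`
#'   (`nrow(X)` x `n_comp`).
#' @export
fit_pca <- function(X, n_comp) {
  X <- as.matrix(X)
  if (n_comp >= nrow(X)) stop("parameter error: n_comp must be < number of spikes")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  list(model = list(mean = p$center,
                    components = p$rotation[, seq_len(n_comp), drop = FALSE],
                    explained_variance_ratio = ratio),
       scores = p$x[, seq_len(n_comp), drop = FALSE])
}

#' The six feature sets
#' @return Character vector of the recognized feature-set names.
#' @export
feature_sets <- function() {
  c("simple", "SPDF_FV3", "SPDF_raw", "W_2PCA", "W_3PCA", "W_raw")
}

#' Build the feature matrix of one feature set
#'
#' Applies the chosen per-spike feature function to every aligned waveform and
#' assembles the rows of the included spikes. The inclusion mask and exclusion
#' reasons are kept so that included + excluded always equals the number of
#' input waveforms. The PCA feature sets are fitted per recording on the raw
#' waveform matrix.
#'
#' @param waveforms List of `mng_waveform` (see [extract_waveforms()]).
#' @param feature_set One of [feature_sets()].
#' @return Object of class `mng_feature_matrix`: list with `feature_set`, `X`
#'   (included spikes x features, named columns), `labels`, `included`
#'   (logical over input waveforms), `reasons` (per excluded spike), and for
#'   PCA sets the fitted `pca` model.
#' @export
feature_matrix <- function(waveforms, feature_set = feature_sets()) {
  feature_set <- match.arg(feature_set)
  n <- length(waveforms)
  tracks <- vapply(waveforms, function(w) w$track, character(1))
  pca <- NULL
  if (feature_set %in% c("W_raw", "W_2PCA", "W_3PCA")) {
    X <- do.call(rbind, lapply(waveforms, feat_raw))
    included <- rep(TRUE, n)
    reasons <- character(0)
    if (feature_set != "W_raw") {
      n_comp <- if (feature_set == "W_2PCA") 2L else 3L
      fit <- fit_pca(X, n_comp)
      pca <- fit$model
      X <- fit$scores
      colnames(X) <- paste0("PC", seq_len(n_comp))
    } else {
      colnames(X) <- paste0("w", seq_len(ncol(X)))
    }
  } else {
    fun <- switch(feature_set,
                  simple = feat_simple,
                  SPDF_FV3 = feat_fv3,
                  SPDF_raw = feat_spdf)
    rows <- lapply(waveforms, fun)
    included <- !vapply(rows, is.null, logical(1))
    reason <- if (feature_set == "simple") "no positive peak or missing half-crossing"
              else "undefined fundamental points"
    reasons <- rep(reason, sum(!included))
    X <- do.call(rbind, rows[included])
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = 0)
  structure(list(feature_set = feature_set, X = X,
                 labels = tracks[included], included = included,
                 reasons = reasons, n_input = n, pca = pca),
            class = "mng_feature_matrix")
}

#' Write a feature matrix to CSV
#'
#' One row per included spike: feature columns, then `track`.
#'
#' @param fm An `mng_feature_matrix`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$X)
  df$track <- fm$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_feature_matrix()]; all rows are marked included.
#'
#' @param path CSV file with feature columns and a `track` column.
#' @param feature_set Name recorded on the result.
#' @return An `mng_feature_matrix`.
#' @export
read_feature_matrix <- function(path, feature_set = "W_raw") {
  df <- as.data.frame(data.table::fread(path))
  if (!"track" %in% names(df)) stop("format error: feature CSV is missing 'track'")
  X <- as.matrix(df[, setdiff(names(df), "track"), drop = FALSE])
  structure(list(feature_set = feature_set, X = X,
                 labels = as.character(df$track),
                 included = rep(TRUE, nrow(X)), reasons = character(0),
                 n_input = nrow(X), pca = NULL),
            class = "mng_feature_matrix")
}
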