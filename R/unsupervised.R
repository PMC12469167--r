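#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same spikes;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones, can be negative.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  rs <- rowSums(tab); cs <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (rs[i] * cs[j]))
  }
  unname(mi)
}

#' Normalized mutual information
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; 1 for identical partitions, 0 for independent ones. With this
#' normalization NMI coincides with the V-measure at `beta = 1`.
#'
#' @inheritParams adjusted_rand_index
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b))
  ha <- entropy_counts(table(a))
  hb <- entropy_counts(table(b))
  if (ha == 0 && hb == 0) return(1)
  mi <- mutual_information(a, b)
  denom <- (ha + hb) / 2
  if (denom == 0) return(1)
  min(1, max(0, mi / denom))
}

#' V-measure
#'
#' Harmonic mean of homogeneity (each cluster contains members of one track)
#' and completeness (all members of a track fall into one cluster).
#'
#' @inheritParams adjusted_rand_index
#' @param beta Weight of completeness relative to homogeneity (default 1).
#' @return V-measure in `[0, 1]`.
#' @export
v_measure <- function(a, b, beta = 1) {
  stopifnot(length(a) == length(b))
  ha <- entropy_counts(table(a))   # truth entropy H(C)
  hb <- entropy_counts(table(b))   # cluster entropy H(K)
  mi <- mutual_information(a, b)
  h <- if (ha == 0) 1 else mi / ha
  c_ <- if (hb == 0) 1 else mi / hb
  if (h + c_ == 0) return(0)
  (1 + beta) * h * c_ / (beta * h + c_)
}

# k-means with k-means++ seeding and multiple restarts; the restart with the
# smallest total within-cluster sum of squares wins
kmeans_pp <- function(X, k, seed, nstart = 10L, iter_max = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- matrix(NA_real_, k, ncol(X))
      centers[1, ] <- X[sample.int(n, 1L), ]
      d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
      for (j in seq_len(k - 1L) + 1L) {
        probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
        d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                           byrow = TRUE))^2))
      }
      fit <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' k-means clustering scored against the track labels
#'
#' Runs k-means (k-means++ initialization, 10 restarts) with `k` fixed to the
#' known number of tracks and scores the partition against the ground-truth
#' labels with ARI, NMI and V-measure. Fixing `k` to the truth inflates the
#' indices relative to a fully blind analysis; the reports exist to quantify
#' the *limitation* of unsupervised sorting on this data, not to endorse it.
#'
#' @param fm An `mng_feature_matrix`.
#' @param k Number of clusters; must equal the number of distinct labels.
#' @param truth Ground-truth labels (defaults to the matrix labels).
#' @param seed Integer seed.
#' @param nstart Restarts (default 10).
#' @return Object of class `mng_cluster_report`: `dataset`, `feature_space`,
#'   `k`, `ari`, `nmi`, `v_measure`, `seed`, `cluster` (the assignment).
#' @export
run_kmeans_eval <- function(fm, k, truth = fm$labels, seed = 0L,
                            nstart = 10L, dataset = "dataset") {
  if (k != length(unique(truth))) {
    stop("parameter error: k must equal the number of distinct truth labels")
  }
  if (nrow(fm$X) <= k) stop("parameter error: need more spikes than clusters")
  fit <- kmeans_pp(fm$X, k, seed = seed, nstart = nstart)
  cl <- fit$cluster
  structure(list(dataset = dataset, feature_space = fm$feature_set, k = k,
                 ari = adjusted_rand_index(truth, cl),
                 nmi = normalized_mutual_info(truth, cl),
                 v_measure = v_measure(truth, cl),
                 seed = seed, cluster = cl),
            class = "mng_cluster_report")
}

#' Clustering performance across PCA component counts
#'
#' Fits PCA on the raw waveform matrix for each component count, clusters the
#' scores with k-means (`k` = number of tracks) and scores against the truth,
#' reporting the cumulative explained variance alongside the external indices.
#'
#' @param fm_raw An `mng_feature_matrix` of the raw waveform set.
#' @param truth Ground-truth labels (defaults to the matrix labels).
#' @param comps Component counts to sweep (default `2:8`).
#' @param seed Integer seed.
#' @param dataset Dataset identifier.
#' @return Data frame: `n_comp`, `cum_explained_variance`, `ari`, `nmi`,
#'   `v_measure`.
#' @export
pca_component_sweep <- function(fm_raw, truth = fm_raw$labels, comps = 2:8,
                                seed = 0L, dataset = "dataset") {
  k <- length(unique(truth))
  out <- lapply(comps, function(m) {
    fit <- fit_pca(fm_raw$X, m)
    sub <- structure(list(feature_set = sprintf("W_%dPCA", m), X = fit$scores,
                          labels = truth, included = rep(TRUE, nrow(fit$scores)),
                          reasons = character(0), n_input = nrow(fit$scores),
                          pca = fit$model),
                     class = "mng_feature_matrix")
    rep_ <- run_kmeans_eval(sub, k, truth, seed = seed, dataset = dataset)
    data.frame(n_comp = m,
               cum_explained_variance =
                 sum(fit$model$explained_variance_ratio[seq_len(m)]),
               ari = rep_$ari, nmi = rep_$nmi, v_measure = rep_$v_measure)
  })
  do.call(rbind, out)
}
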