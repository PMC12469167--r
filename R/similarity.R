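#' Distance between two spike templates
#'
#' Templates are compared sample-by-sample on the aligned 60-sample grid
#' without renormalization, so RMSE stays in the units of the recorded
#' voltage. For templates `T = (t_1..t_n)` and `T-hat`:
#' `MSE = mean((t_i - that_i)^2)`, `MAE = mean(|t_i - that_i|)`,
#' `RMSE = sqrt(MSE)`.
#'
#' @param a,b `mng_template` objects or numeric vectors of equal length.
#' @param metric `"rmse"` (default), `"mse"` or `"mae"`.
#' @return The distance (non-negative scalar).
#' @export
template_distance <- function(a, b, metric = c("rmse", "mse", "mae")) {
  metric <- match.arg(metric)
  va <- if (inherits(a, "mng_template")) a$values else as.numeric(a)
  vb <- if (inherits(b, "mng_template")) b$values else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("parameter error: templates must have equal length")
  }
  d <- va - vb
  switch(metric,
         mse = mean(d^2),
         mae = mean(abs(d)),
         rmse = sqrt(mean(d^2)))
}

#' Pairwise template distance matrix
#'
#' @param templates Named list of `mng_template` (>= 2).
#' @param metric See [template_distance()].
#' @return Symmetric matrix with zero diagonal; dimnames are the track labels.
#' @export
pairwise_template_distances <- function(templates, metric = "rmse") {
  if (length(templates) < 2) stop("parameter error: need at least 2 templates")
  labs <- vapply(templates, function(t) t$track, character(1))
  k <- length(templates)
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- template_distance(templates[[i]], templates[[j]],
                                            metric)
  }
  m
}

#' Most similar template pair
#'
#' For recordings with more than two fibres the headline distance is taken
#' from the most similar pair (the off-diagonal minimum); ties are broken by
#' the lexicographically first track pair. This reduction can misrepresent
#' multi-fibre recordings and is flagged as a workaround in the sortability
#' table.
#'
#' @param m Symmetric distance matrix with dimnames.
#' @return List with `pair` (character 2-vector, sorted) and `distance`.
#' @export
most_similar_pair <- function(m) {
  if (nrow(m) < 2) stop("parameter error: need at least 2 templates")
  labs <- rownames(m)
  best <- NULL
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):ncol(m)) {
    pair <- sort(c(labs[i], labs[j]))
    cand <- list(pair = pair, distance = m[i, j])
    if (is.null(best) || cand$distance < best$distance ||
        (cand$distance == best$distance &&
         paste(cand$pair, collapse = "\r") < paste(best$pair, collapse = "\r"))) {
      best <- cand
    }
  }
  best
}

#' Sortability table: template distances versus achieved accuracy
#'
#' Joins, per dataset, the minimum pairwise template distance under each
#' metric with the best mean cross-validated accuracy over feature sets and
#' the chance level `1/k`. Small distances flag recordings whose fibres are
#' morphologically too similar to sort reliably.
#'
#' @param templates_by_dataset Named list: dataset id -> list of
#'   `mng_template`.
#' @param reports List of `mng_eval_report` covering the same datasets.
#' @return Data frame: `dataset`, `n_fibers`, `mse`, `mae`, `rmse` (most
#'   similar pair), `pair_reduced` (TRUE when >2 fibres, i.e. the most-similar
#'   pair workaround was applied), `best_accuracy`, `best_feature_set`,
#'   `chance`.
#' @export
sortability_table <- function(templates_by_dataset, reports) {
  acc <- do.call(rbind, lapply(reports, function(r) {
    data.frame(dataset = r$dataset, feature_set = r$feature_set,
               accuracy = unname(r$mean["accuracy"]),
               stringsAsFactors = FALSE)
  }))
  rows <- lapply(names(templates_by_dataset), function(id) {
    tpl <- templates_by_dataset[[id]]
    k <- length(tpl)
    dists <- vapply(c("mse", "mae", "rmse"), function(met) {
      most_similar_pair(pairwise_template_distances(tpl, met))$distance
    }, numeric(1))
    g <- acc[acc$dataset == id, , drop = FALSE]
    if (!nrow(g)) stop("parameter error: no evaluation reports for dataset ", id)
    g <- g[order(-g$accuracy, g$feature_set), , drop = FALSE]
    data.frame(dataset = id, n_fibers = k,
               mse = dists[["mse"]], mae = dists[["mae"]], rmse = dists[["rmse"]],
               pair_reduced = k > 2,
               best_accuracy = g$accuracy[1], best_feature_set = g$feature_set[1],
               chance = 1 / k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
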