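# deterministic RNG scoping: run `expr` under a seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Classifier specification
#'
#' `svm_rbf`: support vector machine with radial basis function kernel,
#' regularization constant `C = 1`, kernel width `gamma = 1 / (d * Var(X))`
#' (the variance of the pooled training matrix entries), one-vs-one
#' multiclass, no feature scaling. `random_forest`: a random forest with the
#' `randomForest` package defaults (500 trees, `sqrt(d)` candidate splits).
#'
#' @param kind `"svm_rbf"` or `"random_forest"`.
#' @param params Named list overriding the defaults (`cost`, `gamma` for SVM;
#'   `ntree` for the forest).
#' @param seed Integer seed controlling fold assignment and classifier RNG.
#' @return A `mng_classifier` list.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "random_forest"),
                            params = list(), seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "mng_classifier")
}

fit_predict <- function(spec, x_train, y_train, x_test) {
  if (spec$kind == "svm_rbf") {
    d <- ncol(x_train)
    v <- mean((x_train - mean(x_train))^2)  # population variance of all entries
    gamma <- spec$params$gamma
    if (is.null(gamma)) gamma <- if (v > 0) 1 / (d * v) else 1
    cost <- spec$params$cost %||% 1
    fit <- e1071::svm(x = x_train, y = factor(y_train), scale = FALSE,
                      kernel = "radial", cost = cost, gamma = gamma)
    as.character(stats::predict(fit, x_test))
  } else {
    ntree <- spec$params$ntree %||% 500L
    fit <- randomForest::randomForest(x = x_train, y = factor(y_train),
                                      ntree = ntree)
    as.character(stats::predict(fit, x_test))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# macro-averaged precision / recall / F1 plus accuracy
classification_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  c(accuracy = mean(pred == truth), precision = mean(prec),
    recall = mean(rec), macro_f1 = mean(f1))
}

# stratified fold assignment, invariant to row permutation: rows are first
# brought into a canonical order (label, then feature values), then folds are
# dealt per class from a seeded shuffle
stratified_folds <- function(X, labels, folds, seed) {
  canon <- do.call(order, c(list(labels), as.data.frame(X)))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (k in sort(unique(labels))) {
      idx <- canon[labels[canon] == k]
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated supervised sorting evaluation
#'
#' Stratified k-fold cross-validation (default 5 folds, i.e. 80% training /
#' 20% testing per fold) of a classifier on one feature matrix. Accuracy is
#' the fraction of correctly predicted spikes; precision, recall and F1 are
#' macro-averaged over tracks. Metrics are computed per fold and averaged.
#' Fold assignment is deterministic given the classifier seed and invariant to
#' the row order of the feature matrix.
#'
#' @param fm An `mng_feature_matrix`.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 5).
#' @param dataset Dataset identifier carried on the report.
#' @return Object of class `mng_eval_report`: `dataset`, `feature_set`,
#'   `folds` (per-fold metric data frame), `mean` (named metric vector),
#'   `n_classes`, `chance`, `seed`.
#' @export
run_cv <- function(fm, spec = classifier_spec(), folds = 5L,
                   dataset = "dataset") {
  X <- as.matrix(fm$X)
  labels <- fm$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("evaluation error: need at least 2 classes")
  cnt <- table(labels)
  small <- names(cnt)[cnt < folds]
  if (length(small)) {
    stop("evaluation error: class '", small[1], "' has fewer than ", folds,
         " spikes")
  }
  fold <- stratified_folds(X, labels, folds, spec$seed)
  per_fold <- matrix(NA_real_, nrow = folds, ncol = 4,
                     dimnames = list(NULL, c("accuracy", "precision",
                                             "recall", "macro_f1")))
  for (f in seq_len(folds)) {
    tr <- fold != f
    pred <- with_seed(spec$seed + f,
                      fit_predict(spec, X[tr, , drop = FALSE], labels[tr],
                                  X[!tr, , drop = FALSE]))
    per_fold[f, ] <- classification_metrics(labels[!tr], pred)
  }
  structure(list(dataset = dataset, feature_set = fm$feature_set,
                 folds = data.frame(fold = seq_len(folds), per_fold),
                 mean = colMeans(per_fold), n_classes = length(classes),
                 chance = 1 / length(classes), seed = spec$seed),
            class = "mng_eval_report")
}

#' Random-chance accuracy baseline
#'
#' For the near-balanced designs produced by the marking method the chance
#' level of a k-track recording is `1/k`.
#'
#' @param labels Character vector of track labels (NA ignored).
#' @param majority If `TRUE`, return the majority-class rate instead.
#' @return Chance accuracy in (0, 1].
#' @export
chance_level <- function(labels, majority = FALSE) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("parameter error: no labels")
  if (majority) return(max(table(labels)) / length(labels))
  1 / length(unique(labels))
}

#' Rank feature sets across datasets
#'
#' Summarizes a collection of evaluation reports into per-feature-set
#' mean/median/quartiles of the mean cross-validated metric and identifies the
#' best feature set per dataset. Ties in the ranking are broken by feature-set
#' name so the order is stable.
#'
#' @param reports List of `mng_eval_report`.
#' @param metric Metric to rank by (default `"accuracy"`).
#' @return Data frame (one row per feature set, ordered best first) with
#'   attribute `best_per_dataset` (data frame `dataset`, `feature_set`,
#'   `value`).
#' @export
rank_feature_sets <- function(reports, metric = "accuracy") {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(dataset = r$dataset, feature_set = r$feature_set,
               value = unname(r$mean[metric]), stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(df, df$feature_set), function(g) {
    q <- stats::quantile(g$value, c(.25, .5, .75), names = FALSE)
    data.frame(feature_set = g$feature_set[1], n = nrow(g),
               mean = mean(g$value), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$mean, agg$feature_set), , drop = FALSE]
  rownames(agg) <- NULL
  best <- do.call(rbind, lapply(split(df, df$dataset), function(g) {
    g <- g[order(-g$value, g$feature_set), , drop = FALSE]
    g[1, , drop = FALSE]
  }))
  rownames(best) <- NULL
  attr(agg, "best_per_dataset") <- best
  agg
}
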