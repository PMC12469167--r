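#' Run the end-to-end sortability pipeline
#'
#' Orchestrates the full workflow over a set of recordings: preprocessing
#' (window extraction, resampling, alignment), all requested feature sets,
#' cross-validated supervised evaluation, k-means clustering against the
#' track labels, between-template distances, and — when at least six datasets
#' are available — the pairwise feature-set statistics. Exclusion counts
#' (boundary, alignment, per-feature-set) are accounted per dataset.
#'
#' @param config Named list (or path to a YAML file with the same fields):
#'   `recordings` — named list of `mng_recording` objects and/or container
#'   paths readable by [read_recording()]; or `synthetic` — a list of
#'   argument lists for [synthetic_config()] used to simulate recordings;
#'   `feature_sets` (default all six), `classifier` (`"svm"` or `"rf"`),
#'   `seed` (default 0), `alpha` (default 0.01), `stages` (subset of
#'   `c("cluster", "stats")` to add to the always-run core).
#' @param outdir Optional directory; when given, CSV/JSON report artifacts are
#'   written there.
#' @return Object of class `mng_bundle`: list with `evaluation` (data frame),
#'   `cluster` (data frame or NULL), `sortability`, `statistics` (or NULL),
#'   `exclusions`, `reports` (raw report objects), `config`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 0L)
  feature_sets_req <- config$feature_sets %||% feature_sets()
  stopifnot(all(feature_sets_req %in% feature_sets()))
  classifier <- switch(config$classifier %||% "svm",
                       svm = classifier_spec("svm_rbf", seed = seed),
                       rf = classifier_spec("random_forest", seed = seed),
                       stop("configuration error: unknown classifier"))
  stages <- config$stages %||% c("cluster", "stats")

  recs <- list()
  if (!is.null(config$recordings)) {
    for (nm in names(config$recordings)) {
      r <- config$recordings[[nm]]
      if (is.character(r)) r <- read_recording(r)
      recs[[nm]] <- r
    }
  }
  if (!is.null(config$synthetic)) {
    for (i in seq_along(config$synthetic)) {
      args <- config$synthetic[[i]]
      if (is.null(args$seed)) args$seed <- seed + i
      cfg <- do.call(synthetic_config, args)
      recs[[cfg$dataset]] <- generate_recording(cfg)
    }
  }
  if (!length(recs)) stop("configuration error: no recordings configured")

  reports <- list()
  cluster_rows <- list()
  excl_rows <- list()
  templates_by_dataset <- list()
  for (id in names(recs)) {
    rec <- recs[[id]]
    prep <- extract_waveforms(rec)
    templates_by_dataset[[id]] <- compute_templates(prep$waveforms)
    excl_rows[[id]] <- data.frame(
      dataset = id, labeled_spikes = sum(!is.na(rec$spikes$track)),
      aligned = length(prep$waveforms),
      boundary_excluded = sum(prep$excluded$reason == "boundary"),
      alignment_excluded = sum(prep$excluded$reason == "alignment"),
      stringsAsFactors = FALSE)
    for (fs_name in feature_sets_req) {
      fm <- feature_matrix(prep$waveforms, fs_name)
      reports[[paste(id, fs_name, sep = "/")]] <-
        run_cv(fm, classifier, dataset = id)
      if ("cluster" %in% stages) {
        k <- length(unique(fm$labels))
        cr <- run_kmeans_eval(fm, k, seed = seed, dataset = id)
        cluster_rows[[paste(id, fs_name, sep = "/")]] <-
          data.frame(dataset = id, feature_space = fs_name, k = k,
                     ari = cr$ari, nmi = cr$nmi, v_measure = cr$v_measure,
                     seed = seed, stringsAsFactors = FALSE)
      }
    }
  }

  evaluation <- do.call(rbind, lapply(reports, function(r) {
    data.frame(dataset = r$dataset, feature_set = r$feature_set,
               t(r$mean), n_classes = r$n_classes, chance = r$chance,
               seed = r$seed, stringsAsFactors = FALSE)
  }))
  rownames(evaluation) <- NULL
  sortability <- sortability_table(templates_by_dataset, reports)

  statistics <- NULL
  if ("stats" %in% stages && length(recs) >= 6 &&
      length(feature_sets_req) >= 2) {
    acc <- stats::xtabs(accuracy ~ dataset + feature_set, data = evaluation)
    acc <- matrix(acc, nrow = nrow(acc), dimnames = dimnames(acc))
    p <- wilcoxon_pairwise(acc)
    n_comp <- length(feature_sets_req) * (length(feature_sets_req) - 1) / 2
    alpha_adj <- bonferroni_alpha(config$alpha %||% 0.01, n_comp)
    statistics <- list(p_values = p, alpha_adj = alpha_adj,
                       significant = significance_table(p, alpha_adj))
  }

  bundle <- structure(
    list(evaluation = evaluation,
         cluster = if (length(cluster_rows)) {
           out <- do.call(rbind, cluster_rows); rownames(out) <- NULL; out
         },
         sortability = sortability, statistics = statistics,
         exclusions = { out <- do.call(rbind, excl_rows)
                        rownames(out) <- NULL; out },
         reports = reports,
         config = list(seed = seed, feature_sets = feature_sets_req,
                       classifier = classifier$kind, stages = stages)),
    class = "mng_bundle")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(bundle$evaluation, file.path(outdir, "evaluation.csv"))
    if (!is.null(bundle$cluster)) {
      data.table::fwrite(bundle$cluster, file.path(outdir, "clustering.csv"))
    }
    data.table::fwrite(bundle$sortability, file.path(outdir, "sortability.csv"))
    data.table::fwrite(bundle$exclusions, file.path(outdir, "exclusions.csv"))
    if (!is.null(bundle$statistics)) {
      utils::write.csv(bundle$statistics$p_values,
                       file.path(outdir, "wilcoxon_p.csv"))
      utils::write.csv(bundle$statistics$significant,
                       file.path(outdir, "significance.csv"))
    }
    jsonlite::write_json(bundle$config, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Human-readable summary of a pipeline bundle
#'
#' One row per dataset: the best feature set and its mean accuracy, the
#' chance level, and the most-similar-pair template RMSE; notes absent stages.
#'
#' @param bundle An `mng_bundle` from [run_pipeline()].
#' @return Data frame summary (printed nicely via its own class).
#' @export
summarize_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "mng_bundle"))
  best <- attr(rank_feature_sets(bundle$reports), "best_per_dataset")
  out <- merge(best,
               bundle$sortability[, c("dataset", "n_fibers", "rmse",
                                      "pair_reduced", "chance")],
               by = "dataset")
  names(out)[names(out) == "value"] <- "best_accuracy"
  names(out)[names(out) == "feature_set"] <- "best_feature_set"
  notes <- character(0)
  if (is.null(bundle$cluster)) notes <- c(notes, "clustering stage absent")
  if (is.null(bundle$statistics)) {
    notes <- c(notes, "statistics stage absent (needs >= 6 datasets)")
  }
  attr(out, "notes") <- notes
  out
}
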