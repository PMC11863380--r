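#' Evaluate one pipeline configuration on a sequence-level split
#'
#' Trains a classifier on the training partition and reports threshold
#' metrics plus AUC on the test partition. This is the unit of work the
#' ablation grid repeats.
#'
#' @param records A tibble of annotated protein records.
#' @param store An [embedding_store()] covering the records.
#' @param split A `dataset_split` from [split_by_sequence()].
#' @param config An [mcnn_config()] (ignored for baseline classifiers
#'   except for `half_width`).
#' @param resample A [resample_config()] applied to the training windows.
#' @param classifier `"mcnn"` or one of the [fit_baseline()] methods.
#' @param pca_k Optional PCA target dimension; the reduction is fitted on
#'   training-partition residues only and applied to both partitions.
#' @param threshold Decision threshold for the confusion metrics.
#' @return A one-row tibble of metrics (see [evaluate_scores()]).
#' @export
evaluate_configuration <- function(records, store, split, config,
                                   resample = resample_config("none"),
                                   classifier = "mcnn", pca_k = NULL,
                                   threshold = 0.5) {
  stopifnot(inherits(split, "dataset_split"))
  train_recs <- dplyr::filter(records, .data$id %in% split$train_ids)
  test_recs <- dplyr::filter(records, .data$id %in% split$test_ids)
  if (!is.null(pca_k)) {
    pca <- pca_fit(embedding_store(store$matrices[train_recs$id]), pca_k)
    store <- pca_transform(pca, store)
  }
  ds_train <- make_dataset(train_recs, store, config$half_width)
  ds_test <- make_dataset(test_recs, store, config$half_width)
  if (identical(classifier, "mcnn")) {
    model <- mcnn_build(config, store$dim)
    model <- mcnn_train(model, ds_train, resample = resample)
    scores <- mcnn_forward(model, ds_test)
  } else {
    model <- fit_baseline(ds_train, method = classifier, seed = config$seed)
    scores <- predict(model, ds_test)
  }
  evaluate_scores(scores, ds_test$y, threshold)
}

#' Run an ablation grid
#'
#' Re-runs the train/evaluate cycle while varying one configuration axis,
#' producing one metrics row per grid point — the shape of the published
#' single-window, window-combination, filter-count, context-length,
#' imbalance-handling, PCA-dimension and classifier comparison tables.
#'
#' For `axis = "combination"` the grid is built greedily: each candidate
#' window size is first evaluated alone, candidates are ranked by
#' descending single-window AUC, and combinations grow one window at a
#' time in that order (see [greedy_combinations()]).
#'
#' @inheritParams evaluate_configuration
#' @param axis One of `"window"`, `"combination"`, `"filters"`,
#'   `"half_width"`, `"imbalance"`, `"pca_k"`, `"classifier"`.
#' @param values The grid values for that axis: window sizes, candidate
#'   windows, filter counts, half-widths, resampling method names, PCA
#'   dimensions, or classifier names.
#' @param base_config The [mcnn_config()] every grid point starts from.
#' @return A tibble with columns `axis`, `setting` and the metric
#'   columns of [evaluate_scores()]. Re-running with identical seeds
#'   reproduces the table exactly.
#' @export
run_ablation <- function(records, store, split, axis, values,
                         base_config = mcnn_config(),
                         resample = resample_config("none"),
                         threshold = 0.5) {
  allowed <- c("window", "combination", "filters", "half_width",
               "imbalance", "pca_k", "classifier")
  if (!axis %in% allowed) {
    abort(paste0("unknown ablation axis '", axis, "'; expected one of: ",
                 paste(allowed, collapse = ", ")))
  }
  run_one <- function(setting, cfg, rs = resample, classifier = "mcnn",
                      pca_k = NULL) {
    m <- evaluate_configuration(records, store, split, cfg, resample = rs,
                                classifier = classifier, pca_k = pca_k,
                                threshold = threshold)
    dplyr::bind_cols(tibble::tibble(axis = axis, setting = setting), m)
  }
  cfg_with <- function(...) {
    args <- modifyList(unclass(base_config), list(...))
    do.call(mcnn_config, args)
  }
  rows <- switch(axis,
    window = lapply(values, function(w) {
      run_one(as.character(w), cfg_with(window_sizes = w))
    }),
    combination = {
      singles <- vapply(values, function(w) {
        evaluate_configuration(records, store, split,
                               cfg_with(window_sizes = w),
                               resample = resample,
                               threshold = threshold)$auc
      }, numeric(1))
      combos <- greedy_combinations(as.integer(values), singles)
      lapply(combos, function(ws) {
        run_one(paste0("[", paste(ws, collapse = ", "), "]"),
                cfg_with(window_sizes = ws))
      })
    },
    filters = lapply(values, function(f) {
      run_one(as.character(f), cfg_with(filters = f))
    }),
    half_width = lapply(values, function(L) {
      run_one(as.character(L), cfg_with(half_width = L))
    }),
    imbalance = lapply(values, function(m) {
      run_one(m, base_config,
              rs = resample_config(m, seed = base_config$seed))
    }),
    pca_k = lapply(values, function(k) {
      run_one(as.character(k), base_config, pca_k = k)
    }),
    classifier = lapply(values, function(cl) {
      run_one(cl, base_config, classifier = cl)
    })
  )
  dplyr::bind_rows(rows)
}

#' Plot an ablation table
#'
#' AUC (or another metric) against the grid settings of a [run_ablation()]
#' result.
#'
#' @param table A tibble returned by [run_ablation()].
#' @param metric Metric column to plot (default `"auc"`).
#' @return A ggplot object.
#' @export
plot_ablation <- function(table, metric = "auc") {
  stopifnot(metric %in% names(table))
  table$setting <- factor(table$setting, levels = unique(table$setting))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$setting,
                                      y = .data[[metric]], group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(table$axis), y = metric,
                  title = sprintf("Ablation over %s", unique(table$axis))) +
    ggplot2::theme_minimal()
}
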