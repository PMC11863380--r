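#' Baseline classifiers on flattened context windows
#'
#' Thin contract around standard classifiers (k-nearest neighbours,
#' support vector machine, random forest, gradient boosting) so they plug
#' into the same train/predict surface as the mCNN for classifier
#' comparisons. All operate on the flattened `(2L+1)*d` window vectors.
#'
#' @param dataset A `window_dataset` from [make_dataset()].
#' @param method One of `"knn"`, `"svm"`, `"rf"`, `"xgboost"`.
#' @param seed Integer seed.
#' @param k Neighbourhood size for `"knn"` (default 5).
#' @param nrounds Boosting rounds for `"xgboost"` (default 50).
#' @param ... Passed through to the underlying fitting function.
#' @return An object of class `baseline_model` with a `predict()` method
#'   returning scores in `[0, 1]`.
#' @export
fit_baseline <- function(dataset, method = c("knn", "svm", "rf", "xgboost"),
                         seed = 1L, k = 5L, nrounds = 50L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "window_dataset"))
  x <- flatten_windows(dataset)
  y <- dataset$y
  if (length(unique(y)) < 2L) abort("baseline training needs both classes")
  need <- c(knn = "class", svm = "e1071", rf = "randomForest",
            xgboost = "xgboost")[[method]]
  if (!requireNamespace(need, quietly = TRUE)) {
    abort(paste0("package '", need, "' is required for method '", method, "'"))
  }
  fit <- with_seed(seed, switch(method,
    knn = list(x = x, y = y, k = as.integer(k)),   # lazy learner
    svm = e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE, ...),
    rf = randomForest::randomForest(x, factor(y, levels = c(0, 1)), ...),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1L, ...),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = as.integer(nrounds), verbose = 0
    )
  ))
  structure(
    list(method = method, fit = fit, L = dataset$L, d = dataset$d,
         seed = as.integer(seed)),
    class = "baseline_model"
  )
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s on %d x %d windows\n",
              x$method, 2L * x$L + 1L, x$d))
  invisible(x)
}

#' @rdname fit_baseline
#' @param object A fitted `baseline_model`.
#' @param newdata A `window_dataset` or a flattened numeric matrix of
#'   window vectors.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "window_dataset")) {
    flatten_windows(newdata)
  } else {
    as.matrix(newdata)
  }
  scores <- switch(object$method,
    knn = {
      pr <- class::knn(object$fit$x, x,
                       factor(object$fit$y, levels = c(0, 1)),
                       k = object$fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    svm = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = predict(object$fit, x, type = "prob")[, "1"],
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1L))
  )
  as.numeric(scores)
}

# per-residue scores for a full sequence, mirroring predict_sequence()
predict_sequence_baseline <- function(model, M) {
  L <- model$L
  R <- 2L * L + 1L
  Mp <- pad_matrix(M, L)
  Xflat <- matrix(0, nrow = nrow(M), ncol = R * ncol(M))
  for (c0 in seq_len(nrow(M))) {
    Xflat[c0, ] <- as.vector(t(Mp[c0:(c0 + R - 1L), , drop = FALSE]))
  }
  predict(model, Xflat)
}
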