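#' Configuration for minority-class oversampling
#'
#' @param method One of `"none"`, `"random"` (duplicate minority samples),
#'   `"smote"` (interpolate between minority neighbours) or `"adasyn"`
#'   (like SMOTE, but the number of synthetic points per minority sample
#'   grows with the local majority density).
#' @param k_neighbors Neighbourhood size for SMOTE/ADASYN (default 5).
#' @param seed Integer seed; resampling is reproducible bit-for-bit.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(method = c("none", "random", "smote", "adasyn"),
                            k_neighbors = 5L, seed = 1L) {
  method <- match.arg(method)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) abort("`k_neighbors` must be >= 1")
  structure(
    list(method = method, k_neighbors = k_neighbors, seed = as.integer(seed)),
    class = "resample_config"
  )
}

# row indices of the k nearest rows of `pool` to vector x (euclidean),
# excluding `exclude`; ties broken by ascending row index (stable sort)
knn_indices <- function(pool, x, k, exclude = integer(0)) {
  d2 <- colSums((t(pool) - x)^2)
  d2[exclude] <- Inf
  head(order(d2, seq_along(d2)), k)
}

#' Oversample the minority class of a training set
#'
#' Operates on flattened sample vectors (rows of `x`). The original
#' samples are always preserved, unmodified, as a prefix of the output;
#' synthetic/duplicated minority rows are appended after them. `"random"`
#' and `"smote"` balance the minority count exactly to the majority
#' count; `"adasyn"` approximately, following its density rule: each
#' minority sample receives a share of the synthetic budget proportional
#' to the fraction of majority samples among its `k` nearest neighbours
#' in the full training set.
#'
#' @param x Numeric matrix, one sample per row.
#' @param y Binary 0/1 labels, one per row of `x`.
#' @param config A [resample_config()].
#' @return A list with `x`, `y` (resampled) and `n_original`.
#' @export
resample <- function(x, y, config = resample_config("none")) {
  stopifnot(inherits(config, "resample_config"))
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) abort("`y` must have one label per row of `x`")
  if (!all(y %in% c(0L, 1L))) abort("labels must be 0/1")
  if (config$method == "none") {
    return(list(x = x, y = y, n_original = nrow(x)))
  }
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) {
    abort("resampling needs both classes present in the training set")
  }
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  G <- length(maj_idx) - length(min_idx)
  if (G == 0L) return(list(x = x, y = y, n_original = nrow(x)))
  k <- config$k_neighbors

  if (config$method %in% c("smote", "adasyn") && length(min_idx) <= k) {
    abort(sprintf(
      "%s needs more than k_neighbors = %d minority samples (have %d); use a smaller k",
      toupper(config$method), k, length(min_idx)
    ))
  }

  new_rows <- with_seed(config$seed, {
    switch(config$method,
      random = {
        picks <- min_idx[sample.int(length(min_idx), G, replace = TRUE)]
        x[picks, , drop = FALSE]
      },
      smote = {
        base <- min_idx[sample.int(length(min_idx), G, replace = TRUE)]
        smote_points(x, min_idx, base, k)
      },
      adasyn = {
        # r_i = majority fraction among the k nearest neighbours of each
        # minority point in the whole set; synthetic budget ~ normalized r
        r <- vapply(min_idx, function(i) {
          nn <- knn_indices(x, x[i, ], k, exclude = i)
          mean(y[nn] != minority)
        }, numeric(1))
        if (sum(r) == 0) {
          abort("ADASYN found no majority samples near any minority sample; nothing to adapt to")
        }
        g <- round(r / sum(r) * G)
        base <- rep(min_idx, times = g)
        smote_points(x, min_idx, base, k)
      }
    )
  })
  list(
    x = rbind(x, new_rows),
    y = c(y, rep(minority, nrow(new_rows))),
    n_original = nrow(x)
  )
}

# SMOTE interpolation: for each base minority row, pick one of its k
# nearest minority neighbours and a uniform point on the joining segment
smote_points <- function(x, min_idx, base, k) {
  if (length(base) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(x)))
  }
  pool <- x[min_idx, , drop = FALSE]
  nn_cache <- lapply(seq_along(min_idx), function(j) {
    knn_indices(pool, pool[j, ], k, exclude = j)
  })
  pos_in_pool <- match(base, min_idx)
  out <- matrix(0, nrow = length(base), ncol = ncol(x))
  for (s in seq_along(base)) {
    j <- pos_in_pool[s]
    nb <- nn_cache[[j]][sample.int(k, 1L)]
    u <- runif(1)
    out[s, ] <- pool[j, ] + u * (pool[nb, ] - pool[j, ])
  }
  out
}
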