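#' Produce per-residue embeddings for protein records
#'
#' One contract, several backends. The first-class, fully tested backends
#' are `precomputed` (look matrices up in an existing [embedding_store()])
#' and `synthetic` (seeded standard-normal matrices, useful for plumbing
#' tests). The live protein-language-model backends (`prott5`,
#' `esm2-650m`, `esm2-3b`, `tape`) require external multi-gigabyte model
#' weights and are deliberately not bundled: selecting one raises an error
#' that points at the precomputed-matrix path, which is the supported way
#' to bring real PLM embeddings into the pipeline.
#'
#' @param records A tibble of protein records ([read_fasta()]).
#' @param backend One of `"precomputed"`, `"synthetic"`, `"prott5"`,
#'   `"esm2-650m"`, `"esm2-3b"`, `"tape"`.
#' @param store For `backend = "precomputed"`: an [embedding_store()]
#'   holding a matrix for every record id.
#' @param d For `backend = "synthetic"`: embedding dimension (default 32).
#' @param seed For `backend = "synthetic"`: integer seed; output is a pure
#'   function of `(records, d, seed)`.
#' @return An [embedding_store()] with one `L x d` matrix per record.
#' @export
embed_records <- function(records,
                          backend = c("precomputed", "synthetic", "prott5",
                                      "esm2-650m", "esm2-3b", "tape"),
                          store = NULL, d = 32L, seed = 1L) {
  backend <- match.arg(backend)
  check_records(records)
  plm_dims <- c("prott5" = 1024L, "esm2-650m" = 1280L,
                "esm2-3b" = 2560L, "tape" = 768L)
  if (backend %in% names(plm_dims)) {
    abort(paste0(
      "the '", backend, "' adapter (d = ", plm_dims[[backend]], ") is not ",
      "installed: live PLM inference needs external model weights. ",
      "Generate the matrices with the upstream model, save them with ",
      "write_embedding_store(), and use backend = 'precomputed'."
    ))
  }
  if (backend == "precomputed") {
    if (is.null(store)) {
      abort("backend = 'precomputed' requires a `store`")
    }
    pair_records_store(records, store)
    return(embedding_store(store$matrices[records$id]))
  }
  # synthetic: per-sequence seeds derived from (seed, id) so matrices do
  # not depend on record order
  mats <- lapply(seq_len(nrow(records)), function(i) {
    len <- nchar(records$sequence[[i]])
    with_seed(derive_seed(seed, records$id[[i]]), {
      matrix(rnorm(len * d), nrow = len, ncol = as.integer(d))
    })
  })
  embedding_store(setNames(mats, records$id))
}

#' Concatenate two embedding matrices feature-wise
#'
#' Row-wise feature fusion of two per-residue embedding matrices for the
#' same sequence: the result has the same number of rows and
#' `ncol(A) + ncol(B)` columns, with `A`'s columns first.
#'
#' @param A,B Numeric matrices with equal row counts.
#' @return A matrix of dimension `nrow(A) x (ncol(A) + ncol(B))`.
#' @export
#' @examples
#' merge_features(matrix(0, 5, 3), matrix(1, 5, 2)) |> dim()
merge_features <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B)) {
    abort("`A` and `B` must be matrices")
  }
  if (nrow(A) != nrow(B)) {
    abort(sprintf("row mismatch: A has %d rows, B has %d", nrow(A), nrow(B)))
  }
  cbind(A, B)
}

#' @rdname merge_features
#' @param A_store,B_store Two [embedding_store()]s over the same ids.
#' @export
merge_stores <- function(A_store, B_store) {
  stopifnot(inherits(A_store, "embedding_store"),
            inherits(B_store, "embedding_store"))
  ids <- store_ids(A_store)
  if (!setequal(ids, store_ids(B_store))) {
    abort("the two stores hold different sequence ids")
  }
  embedding_store(setNames(
    lapply(ids, function(i) merge_features(store_matrix(A_store, i),
                                           store_matrix(B_store, i))),
    ids
  ))
}

#' Fit a PCA reduction on training-partition residue embeddings
#'
#' Principal-component reduction of per-residue embedding vectors, as used
#' to shrink 1024-dimensional PLM embeddings to 64-512 dimensions. The
#' model must be fitted only on training-partition matrices and then
#' applied unchanged to validation/test matrices, so no information leaks
#' across the sequence-level split.
#'
#' @param train_matrices A list of numeric matrices (or an
#'   [embedding_store()]) from the training partition.
#' @param k Target dimension, `1 <= k <= d` and at most the number of
#'   training residue vectors.
#' @return An object of class `pca_model` with fields `mean` (length-d
#'   centre), `rotation` (`d x k`, orthonormal columns ordered by
#'   decreasing explained variance), `sdev`, `k` and `d`.
#' @export
pca_fit <- function(train_matrices, k) {
  if (inherits(train_matrices, "embedding_store")) {
    train_matrices <- train_matrices$matrices
  }
  stopifnot(is.list(train_matrices), length(train_matrices) > 0L)
  X <- do.call(rbind, train_matrices)
  k <- as.integer(k)
  if (k < 1L || k > ncol(X)) {
    abort(sprintf("`k` must lie in 1..d (d = %d), got %d", ncol(X), k))
  }
  if (k > nrow(X)) {
    abort(sprintf("`k` = %d exceeds the %d training residue vectors", k, nrow(X)))
  }
  fit <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(
    list(
      mean = fit$center,
      rotation = fit$rotation[, seq_len(k), drop = FALSE],
      sdev = fit$sdev,
      k = k, d = ncol(X), n_train = nrow(X)
    ),
    class = "pca_model"
  )
}

#' @rdname pca_fit
#' @param model A fitted `pca_model`.
#' @param M A numeric matrix with `d` columns (or an [embedding_store()],
#'   transformed matrix-wise).
#' @export
pca_transform <- function(model, M) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(M, "embedding_store")) {
    return(embedding_store(lapply(M$matrices, function(m) pca_transform(model, m))))
  }
  if (!is.matrix(M) || ncol(M) != model$d) {
    abort(sprintf("matrix must have %d columns to match the PCA model", model$d))
  }
  sweep(M, 2L, model$mean) %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- x$sdev^2
  cat(sprintf(
    "<pca_model> d = %d -> k = %d (%.1f%% variance retained, n = %d residues)\n",
    x$d, x$k, 100 * sum(ev[seq_len(x$k)]) / sum(ev), x$n_train
  ))
  invisible(x)
}

#' @describeIn pca_fit One row per retained component: its standard
#'   deviation and the proportion of variance explained.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  ev <- x$sdev^2
  tibble::tibble(
    component = seq_len(x$k),
    sdev = x$sdev[seq_len(x$k)],
    prop_variance = ev[seq_len(x$k)] / sum(ev),
    cum_variance = cumsum(ev)[seq_len(x$k)] / sum(ev)
  )
}
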