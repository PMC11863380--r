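#' Extract the residue context window around one position
#'
#' Returns the `(2L+1) x d` sub-matrix of per-residue embeddings centred
#' on a residue, zero-padding rows that fall beyond either terminus. `L`
#' is the context half-width ("splitting window length"): the window spans
#' residues `center - L .. center + L`.
#'
#' @param M An `L x d` per-residue embedding matrix.
#' @param center 0-based residue index, `0 <= center < nrow(M)`.
#' @param L Context half-width, `L >= 1`.
#' @return A `(2L+1) x d` numeric matrix.
#' @export
extract_window <- function(M, center, L) {
  stopifnot(is.matrix(M))
  center <- as.integer(center)
  L <- as.integer(L)
  if (L < 1L) abort("`L` must be >= 1")
  if (center < 0L || center >= nrow(M)) {
    abort(sprintf("center %d out of range 0..%d", center, nrow(M) - 1L))
  }
  out <- matrix(0, nrow = 2L * L + 1L, ncol = ncol(M))
  idx <- (center - L):(center + L)
  keep <- idx >= 0L & idx < nrow(M)
  out[which(keep), ] <- M[idx[keep] + 1L, , drop = FALSE]
  out
}

# pad M with L zero rows at each end; window at 0-based center c is then
# rows (c+1)..(c+2L+1) of the padded matrix
pad_matrix <- function(M, L) {
  z <- matrix(0, nrow = L, ncol = ncol(M))
  rbind(z, M, z)
}

#' Build a labelled window dataset from records and embeddings
#'
#' Produces one training sample per residue of every record: the
#' `(2L+1) x d` context window and a binary label that is 1 iff the
#' centre residue is an annotated binding residue.
#'
#' @param records A tibble of protein records with `binding_positions`.
#' @param store An [embedding_store()] covering all record ids.
#' @param L Context half-width.
#' @return An object of class `window_dataset`: a list with `x` (array
#'   `n x (2L+1) x d`), `y` (integer 0/1), `id`, `center` (0-based),
#'   `L` and `d`.
#' @export
make_dataset <- function(records, store, L) {
  pair_records_store(records, store)
  L <- as.integer(L)
  if (L < 1L) abort("`L` must be >= 1")
  d <- store$dim
  lens <- nchar(records$sequence)
  n <- sum(lens)
  x <- array(0, dim = c(n, 2L * L + 1L, d))
  y <- integer(n)
  ids <- character(n)
  centers <- integer(n)
  at <- 0L
  for (i in seq_len(nrow(records))) {
    M <- store_matrix(store, records$id[[i]])
    Mp <- pad_matrix(M, L)
    len <- lens[i]
    for (c0 in 0:(len - 1L)) {
      x[at + c0 + 1L, , ] <- Mp[(c0 + 1L):(c0 + 2L * L + 1L), , drop = FALSE]
    }
    rows <- at + seq_len(len)
    ids[rows] <- records$id[[i]]
    centers[rows] <- 0:(len - 1L)
    pos <- records$binding_positions[[i]]
    y[at + pos] <- 1L
    at <- at + len
  }
  structure(
    list(x = x, y = y, id = ids, center = centers, L = L, d = d),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d samples (%d positive), window %d x %d (L = %d)\n",
    length(x$y), sum(x$y), 2L * x$L + 1L, x$d, x$L
  ))
  invisible(x)
}

#' @method as_tibble window_dataset
#' @export
as_tibble.window_dataset <- function(x, ...) {
  tibble::tibble(id = x$id, center = x$center, position = x$center + 1L,
                 label = x$y)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# subset a window_dataset by sample index, preserving structure
dataset_subset <- function(ds, idx) {
  structure(
    list(x = ds$x[idx, , , drop = FALSE], y = ds$y[idx], id = ds$id[idx],
         center = ds$center[idx], L = ds$L, d = ds$d),
    class = "window_dataset"
  )
}

# flatten the window tensor to n x ((2L+1) d); row-major over window rows,
# i.e. column (r-1)*d + j holds window row r, embedding dim j
flatten_windows <- function(ds) {
  n <- dim(ds$x)[1]
  R <- dim(ds$x)[2]
  d <- dim(ds$x)[3]
  out <- matrix(ds$x, nrow = n)
  # base R unravels [n, R, d] so flat column (j-1)*R + r holds (row r, dim j);
  # reorder to (r-1)*d + j so each window row occupies a contiguous block
  src <- as.vector(t(matrix(seq_len(R * d), nrow = R)))
  out[, src, drop = FALSE]
}

#' Split records into train and test sets by whole sequence
#'
#' Sequence-level splitting: every residue of a sequence lands in the same
#' partition, so residue-level leakage between train and test is
#' impossible. The train partition receives `floor(ratio * n)` sequences
#' of a seeded permutation.
#'
#' @param records A tibble of protein records.
#' @param ratio Train fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed for the permutation.
#' @return An object of class `dataset_split`: list with `train_ids`,
#'   `test_ids`, `ratio`, `seed`.
#' @export
#' @examples
#' recs <- tibble::tibble(id = paste0("P", 1:27), sequence = "ACDEF",
#'                        binding_positions = list(integer(0)))
#' s <- split_by_sequence(recs, 0.8, seed = 1)
#' lengths(s[c("train_ids", "test_ids")])
split_by_sequence <- function(records, ratio = 0.8, seed = 1L) {
  check_records(records)
  n <- nrow(records)
  if (n < 2L) abort("need at least 2 records to split")
  if (!(ratio > 0 && ratio < 1)) abort("`ratio` must lie strictly in (0, 1)")
  n_train <- floor(ratio * n)
  if (n_train < 1L || n_train >= n) {
    abort(sprintf("split of %d records at ratio %.3f leaves a partition empty",
                  n, ratio))
  }
  perm <- with_seed(seed, sample(records$id))
  structure(
    list(
      train_ids = sort(perm[seq_len(n_train)]),
      test_ids = sort(perm[(n_train + 1L):n]),
      ratio = ratio, seed = as.integer(seed)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}
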