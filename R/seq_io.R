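#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a tibble of protein records, one
#' row per sequence. Sequences are upper-cased and validated against the 20
#' standard amino-acid letters plus `X`; record order is preserved.
#'
#' @param path Path to an existing FASTA file.
#' @return A tibble with columns `id` (character, the first whitespace-
#'   delimited token of each header), `sequence` (character) and
#'   `binding_positions` (list of integer vectors, empty until annotations
#'   are attached with [read_annotations()]).
#' @seealso [write_fasta()], [read_annotations()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "ACDEFGHIKL", ">P2", "MNPQRSTVWY"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  seqs <- suppressWarnings(Biostrings::readAAStringSet(path))
  if (length(seqs) == 0L) {
    abort(paste0("no sequences in FASTA file: ", path))
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("FASTA contains a record with an empty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sequence id(s) in FASTA: ",
                 paste(unique(dup), collapse = ", ")))
  }
  # validate characters against the raw text: the parser silently drops
  # invalid one-letter codes, which would hide annotation off-by-ones
  raw <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(raw, ">")
  rec_of_line <- cumsum(is_hdr)
  body <- gsub("[ \t\r]", "", raw[!is_hdr & rec_of_line > 0L])
  sequences <- toupper(vapply(
    split(body, rec_of_line[!is_hdr & rec_of_line > 0L]),
    paste, character(1), collapse = ""
  ))
  if (length(sequences) != length(ids)) {
    sequences <- c(sequences, rep("", length(ids) - length(sequences)))
  }
  for (i in seq_along(sequences)) {
    check_sequence_alphabet(sequences[[i]], ids[[i]])
  }
  tibble::tibble(
    id = unname(ids),
    sequence = unname(sequences),
    binding_positions = rep(list(integer(0)), length(ids))
  )
}

check_sequence_alphabet <- function(sequence, id) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "illegal character '%s' at position %d of sequence '%s'",
      chars[bad[1]], bad[1], id
    ))
  }
  invisible(TRUE)
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble of protein records as returned by [read_fasta()]
#'   or [generate_synthetic()].
#' @param path Output path.
#' @param width Line width for wrapped sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_records(records)
  seqs <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

check_records <- function(records) {
  need <- c("id", "sequence")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort("`records` must be a data frame with columns `id` and `sequence`")
  }
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(records$id[duplicated(records$id)]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Attach binding-site annotations to protein records
#'
#' Reads a two-column TSV of `(id, position)` pairs giving 1-based residue
#' indices of annotated calcium-binding residues and attaches them to the
#' matching records. Duplicate `(id, position)` rows collapse to one
#' position (set semantics).
#'
#' @param path Path to a TSV file with header columns `id` and `position`.
#' @param records A tibble of protein records ([read_fasta()]).
#' @return `records` with `binding_positions` filled (sorted unique
#'   integer vectors).
#' @export
read_annotations <- function(path, records) {
  check_records(records)
  ann <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    position = readr::col_integer()
  ), progress = FALSE)
  if (!all(c("id", "position") %in% names(ann))) {
    abort("annotation TSV must have columns `id` and `position`")
  }
  unknown <- setdiff(unique(ann$id), records$id)
  if (length(unknown) > 0L) {
    abort(paste0("annotation refers to unknown sequence id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  lens <- setNames(nchar(records$sequence), records$id)
  bad <- which(ann$position < 1L | ann$position > lens[ann$id])
  if (length(bad) > 0L) {
    abort(sprintf(
      "annotation position %d out of range 1..%d for sequence '%s'",
      ann$position[bad[1]], lens[[ann$id[bad[1]]]], ann$id[bad[1]]
    ))
  }
  by_id <- split(ann$position, ann$id)
  records$binding_positions <- lapply(records$id, function(i) {
    sort(unique(as.integer(by_id[[i]] %||% integer(0))))
  })
  records
}

#' Write binding-site annotations to TSV
#'
#' Inverse of [read_annotations()]: writes one `(id, position)` row per
#' annotated binding residue, 1-based.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  check_records(records)
  ann <- tidyr::unnest(
    tibble::tibble(id = records$id, position = records$binding_positions),
    "position"
  )
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}

#' Keyed per-residue embedding store
#'
#' An embedding store maps sequence ids to L x d real matrices (one row per
#' residue). All matrices in one store share the same embedding dimension
#' d; mixing dimensions is an error.
#'
#' @param matrices A named list of numeric matrices.
#' @return An object of class `embedding_store`.
#' @export
embedding_store <- function(matrices) {
  if (!is.list(matrices) || is.null(names(matrices)) ||
      any(!nzchar(names(matrices)))) {
    abort("`matrices` must be a named list of matrices")
  }
  if (anyDuplicated(names(matrices))) {
    abort("duplicate ids in embedding store")
  }
  ok <- vapply(matrices, function(m) is.matrix(m) && is.numeric(m), logical(1))
  if (!all(ok)) {
    abort("every element of an embedding store must be a numeric matrix")
  }
  dims <- vapply(matrices, ncol, integer(1))
  if (length(unique(dims)) > 1L) {
    abort(sprintf(
      "inconsistent dimension in embedding store: found d = {%s}",
      paste(sort(unique(dims)), collapse = ", ")
    ))
  }
  structure(
    list(matrices = matrices, dim = unname(dims[1])),
    class = "embedding_store"
  )
}

#' @export
print.embedding_store <- function(x, ...) {
  lens <- vapply(x$matrices, nrow, integer(1))
  cat(sprintf(
    "<embedding_store> %d sequence(s), d = %d, %d residue rows total\n",
    length(x$matrices), x$dim, sum(lens)
  ))
  invisible(x)
}

#' @export
length.embedding_store <- function(x) length(x$matrices)

#' @rdname embedding_store
#' @param store An `embedding_store`.
#' @param id A sequence id present in the store.
#' @export
store_matrix <- function(store, id) {
  stopifnot(inherits(store, "embedding_store"))
  m <- store$matrices[[id]]
  if (is.null(m)) {
    abort(paste0("sequence id not present in embedding store: ", id))
  }
  m
}

#' @rdname embedding_store
#' @export
store_ids <- function(store) {
  stopifnot(inherits(store, "embedding_store"))
  names(store$matrices)
}

#' Read / write an embedding store
#'
#' The on-disk container is a single versioned RDS file holding the named
#' list of matrices plus its shared embedding dimension; round-trips are
#' bit-identical. The file is validated on read (format marker, version,
#' dimension consistency).
#'
#' @param path File path.
#' @return `read_embedding_store()` returns an `embedding_store`;
#'   `write_embedding_store()` returns `path` invisibly.
#' @export
read_embedding_store <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("embedding store not found: ", path))
  }
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "cabindr_embedding_store")) {
    abort(paste0("not an embedding store file: ", path))
  }
  if (!identical(obj$version, 1L)) {
    abort(sprintf("unsupported embedding store version: %s", obj$version))
  }
  embedding_store(obj$matrices)
}

#' @rdname read_embedding_store
#' @param store An `embedding_store`.
#' @export
write_embedding_store <- function(store, path) {
  stopifnot(inherits(store, "embedding_store"))
  obj <- list(
    format = "cabindr_embedding_store",
    version = 1L,
    dim = store$dim,
    matrices = store$matrices
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Check that records and an embedding store agree
#'
#' Fails fast if any record id is missing from the store or its matrix row
#' count differs from the sequence length.
#'
#' @inheritParams write_fasta
#' @param store An `embedding_store`.
#' @return `TRUE`, invisibly.
#' @export
pair_records_store <- function(records, store) {
  check_records(records)
  stopifnot(inherits(store, "embedding_store"))
  missing <- setdiff(records$id, store_ids(store))
  if (length(missing) > 0L) {
    abort(paste0("embedding store is missing id(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(records))) {
    len <- nchar(records$sequence[[i]])
    rows <- nrow(store_matrix(store, records$id[[i]]))
    if (rows != len) {
      abort(sprintf(
        "sequence '%s' has length %d but its embedding matrix has %d rows",
        records$id[[i]], len, rows
      ))
    }
  }
  invisible(TRUE)
}

#' Read / write per-residue predictions
#'
#' Predictions are TSVs with one row per residue of each predicted
#' sequence: columns `id`, `position` (1-based), `residue`, `score`
#' (in `[0, 1]`) and `label` (0/1 at the active threshold).
#'
#' @param path File path.
#' @return A tibble of predictions.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    score = readr::col_double(),
    label = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname read_predictions
#' @param predictions A tibble as produced by [predict_records()].
#' @export
write_predictions <- function(predictions, path) {
  need <- c("id", "position", "residue", "score", "label")
  if (!all(need %in% names(predictions))) {
    abort(paste0("predictions must have columns: ", paste(need, collapse = ", ")))
  }
  readr::write_tsv(predictions[, need], path, progress = FALSE)
  invisible(path)
}
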