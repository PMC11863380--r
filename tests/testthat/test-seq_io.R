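test_that("read_fasta preserves count, length, order and upper-cases", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 first", "ACDEFGHIKL", ">P2", tolower("ACDEFGHIKLMNPQRSTVWYACDEF")), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("P1", "P2"))
  expect_equal(nchar(recs$sequence), c(10L, 25L))
  expect_equal(recs$sequence[2], "ACDEFGHIKLMNPQRSTVWYACDEF")
  expect_true(all(lengths(recs$binding_positions) == 0L))
})

test_that("FASTA round-trip is lossless over random records", {
  recs <- random_records(50, c(5L, 80L), seed = 42)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("read_fasta rejects bad input with informative errors", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no sequences")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACD", ">A", "EFG"), dup)
  expect_error(read_fasta(dup), "duplicate.*A")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "AC1DE"), bad)
  expect_error(read_fasta(bad), "position 3")

  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("annotations attach with set semantics and bounds checks", {
  recs <- tibble::tibble(
    id = c("P1", "P2"),
    sequence = c("ACDEFGHIKL", "ACDEF"),
    binding_positions = list(integer(0), integer(0))
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tposition", "P1\t3", "P1\t5", "P1\t3"), tsv)
  out <- read_annotations(tsv, recs)
  expect_equal(out$binding_positions[[1]], c(3L, 5L))
  expect_equal(out$binding_positions[[2]], integer(0))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tposition", "P1\t11"), bad)
  expect_error(read_annotations(bad, recs), "11.*P1|P1.*11")

  unk <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tposition", "PX\t1"), unk)
  expect_error(read_annotations(unk, recs), "unknown.*PX")
})

test_that("annotation write/read round-trips", {
  recs <- random_records(10, c(10L, 30L), seed = 3, with_positions = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(recs, tsv)
  stripped <- recs
  stripped$binding_positions <- rep(list(integer(0)), nrow(recs))
  back <- read_annotations(tsv, stripped)
  expect_equal(back$binding_positions, recs$binding_positions)
})

test_that("embedding store round-trips bit-identically and checks dims", {
  mats <- list(P1 = matrix(rnorm(10 * 6), 10, 6),
               P2 = matrix(rnorm(25 * 6), 25, 6))
  store <- embedding_store(mats)
  expect_equal(store$dim, 6L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_embedding_store(store, path)
  back <- read_embedding_store(path)
  expect_identical(back$matrices, store$matrices)

  expect_error(
    embedding_store(list(P1 = matrix(0, 10, 6), P2 = matrix(0, 5, 4))),
    "inconsistent dimension"
  )
  expect_error(read_embedding_store(withr::local_tempfile()), "not found")
})

test_that("pairing records with a store fails fast on mismatch", {
  recs <- random_records(3, c(10L, 12L), seed = 5)
  store <- store_for(recs, d = 4)
  expect_true(pair_records_store(recs, store))

  # wrong row count for one id
  broken <- store$matrices
  broken[[2]] <- broken[[2]][-1, , drop = FALSE]
  expect_error(pair_records_store(recs, embedding_store(broken)),
               "length.*rows|rows.*length")

  expect_error(pair_records_store(recs, embedding_store(store$matrices[-1])),
               "missing")
})

test_that("prediction TSV round-trips", {
  preds <- tibble::tibble(
    id = "P1", position = 1:5,
    residue = c("A", "C", "D", "E", "F"),
    score = c(0.1, 0.9, 0.5, 0.2, 0.7),
    label = as.integer(c(0, 1, 1, 0, 1))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  expect_identical_tibbles(read_predictions(path), preds)
})
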