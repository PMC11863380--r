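# in-code fixtures: every test input is generated here, nothing is shipped

random_records <- function(n = 5, len_range = c(8L, 30L), seed = 1L,
                           with_positions = FALSE) {
  withr::with_seed(seed, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    lens <- len_range[1] +
      sample.int(len_range[2] - len_range[1] + 1L, n, replace = TRUE) - 1L
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      sequence = vapply(lens, function(l) {
        paste(sample(aa, l, replace = TRUE), collapse = "")
      }, character(1)),
      binding_positions = lapply(lens, function(l) {
        if (with_positions) sort(sample.int(l, min(2L, l))) else integer(0)
      })
    )
  })
}

store_for <- function(records, d = 8L, seed = 1L) {
  embed_records(records, "synthetic", d = d, seed = seed)
}

# a small corpus with a planted signal, shared across model tests
tiny_sim <- function(seed = 1L, n = 8L, d = 16L, rate = 0.05,
                     effect = 3, lens = c(30L, 60L)) {
  generate_synthetic(synthetic_spec(
    n_sequences = n, length_range = lens, d = d, binding_rate = rate,
    effect_size = effect, signal_halfwidth = 2L, seed = seed
  ))
}

expect_identical_tibbles <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
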