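test_that("configuration enforces the kernel-fit constraint", {
  expect_error(mcnn_config(window_sizes = c(6, 14), half_width = 6),
               "2 \\* half_width \\+ 1")
  cfg <- mcnn_config(window_sizes = c(6, 8, 10, 12), half_width = 6)
  expect_equal(cfg$window_sizes, c(6L, 8L, 10L, 12L))
})

test_that("parameter count follows the closed form", {
  # single conv block: kernel k x d x F plus F biases
  cfg <- mcnn_config(window_sizes = 3, filters = 1, half_width = 2,
                     dense_units = 4)
  m <- mcnn_build(cfg, d = 2)
  conv_params <- 3 * 2 * 1 + 1
  expect_equal(length(m$params$conv[[1]]$W) + length(m$params$conv[[1]]$b),
               conv_params)
  expect_equal(mcnn_param_count(m),
               conv_params + (1 * 1) * 4 + 4 + 4 + 1)

  # pooled feature length is |W| * F regardless of L and d
  cfg2 <- mcnn_config(window_sizes = c(6, 8, 10, 12), filters = 64,
                      half_width = 6)
  m2 <- mcnn_build(cfg2, d = 4)
  expect_equal(nrow(m2$params$W1), 4 * 64)
})

test_that("building and forward passes are deterministic", {
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 4, half_width = 3,
                     dense_units = 8, seed = 42)
  m1 <- mcnn_build(cfg, d = 6)
  m2 <- mcnn_build(cfg, d = 6)
  expect_identical(m1$params, m2$params)

  zero <- matrix(0, 7, 6)
  s1 <- mcnn_forward(m1, zero)
  expect_identical(s1, mcnn_forward(m1, zero))
  expect_true(s1 > 0 && s1 < 1)
})

test_that("batched forward equals elementwise singleton forward", {
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 4, half_width = 3,
                     dense_units = 8, seed = 1)
  m <- mcnn_build(cfg, d = 5)
  withr::with_seed(8, {
    xb <- array(rnorm(10 * 7 * 5), dim = c(10, 7, 5))
  })
  batch <- mcnn_forward(m, xb)
  singles <- vapply(seq_len(10), function(i) mcnn_forward(m, xb[i, , ]),
                    numeric(1))
  expect_equal(batch, singles)
  expect_error(mcnn_forward(m, matrix(0, 6, 5)), "must be 7 x 5")
})

test_that("conv + global max-pool is translation invariant for interior patterns", {
  cfg <- mcnn_config(window_sizes = 3, filters = 1, half_width = 4,
                     dense_units = 2, seed = 2)
  m <- mcnn_build(cfg, d = 2)
  # non-negative filter weights and pattern: the aligned position dominates
  m$params$conv[[1]]$W <- abs(m$params$conv[[1]]$W)
  withr::with_seed(3, pattern <- matrix(abs(rnorm(3 * 2)), 3, 2))
  # offsets deep enough that every partial kernel alignment stays inside
  # the window (margin k - 1), so the pooled maximum is offset-free
  scores <- vapply(2:4, function(off) {
    x <- matrix(0, 9, 2)
    x[(off + 1):(off + 3), ] <- pattern
    mcnn_forward(m, x)
  }, numeric(1))
  expect_true(all(abs(scores - scores[1]) < 1e-12))
})

test_that("training reduces loss on separable data and records history", {
  sim <- tiny_sim(seed = 31, n = 6, d = 8, rate = 0.08, effect = 4)
  ds <- make_dataset(sim$records, sim$store, L = 3)
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 4, half_width = 3,
                     dense_units = 16, epochs = 8, batch_size = 64,
                     validation_fraction = 0, seed = 7)
  m <- mcnn_train(mcnn_build(cfg, 8), ds)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 8L)
  expect_gt(m$history$loss[1], m$history$loss[8])
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$epochs_trained, 8L)
})

test_that("training errors on degenerate inputs", {
  sim <- tiny_sim(seed = 32, n = 4, d = 6, rate = 0.05)
  ds <- make_dataset(sim$records, sim$store, L = 3)
  cfg <- mcnn_config(window_sizes = 3, filters = 2, half_width = 3,
                     epochs = 2, validation_fraction = 0, seed = 1)
  # single-class training set
  ds0 <- ds
  ds0$y <- rep(0L, length(ds0$y))
  expect_error(mcnn_train(mcnn_build(cfg, 6), ds0), "both classes")
  # non-finite inputs surface as a divergence error naming the epoch
  dsn <- ds
  dsn$x[1, , ] <- NA_real_
  expect_error(mcnn_train(mcnn_build(cfg, 6), dsn), "epoch 1")
})

test_that("predict_sequence equals forward over extracted windows", {
  sim <- tiny_sim(seed = 33, n = 1, d = 6, lens = c(10L, 10L))
  M <- store_matrix(sim$store, sim$records$id[1])
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 3, half_width = 3,
                     dense_units = 8, seed = 5)
  m <- mcnn_build(cfg, 6)
  s <- predict_sequence(m, M)
  expect_length(s, 10L)
  oracle <- vapply(0:9, function(c0) {
    mcnn_forward(m, extract_window(M, c0, 3))
  }, numeric(1))
  expect_equal(s, oracle)
  expect_identical(s, predict_sequence(m, M))
  expect_error(predict_sequence(m, M[, 1:4]), "d = 4")
})

test_that("predict_records returns the tidy per-residue table", {
  sim <- tiny_sim(seed = 34, n = 3, d = 6, lens = c(8L, 12L))
  cfg <- mcnn_config(window_sizes = 3, filters = 2, half_width = 3, seed = 1)
  m <- mcnn_build(cfg, 6)
  preds <- predict_records(m, sim$records, sim$store, threshold = 0.5)
  expect_equal(nrow(preds), sum(nchar(sim$records$sequence)))
  expect_equal(names(preds), c("id", "position", "residue", "score", "label"))
  expect_equal(preds$label, as.integer(preds$score >= 0.5))
  expect_equal(
    preds$residue[preds$id == sim$records$id[1]],
    strsplit(sim$records$sequence[1], "")[[1]]
  )
})

test_that("checkpoints round-trip through save/load", {
  sim <- tiny_sim(seed = 35, n = 2, d = 6, lens = c(10L, 14L))
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 2, half_width = 3,
                     epochs = 2, validation_fraction = 0, seed = 3)
  ds <- make_dataset(sim$records, sim$store, L = 3)
  m <- mcnn_train(mcnn_build(cfg, 6), ds)
  path <- withr::local_tempfile(fileext = ".rds")
  mcnn_save(m, path)
  back <- mcnn_load(path)
  M <- store_matrix(sim$store, sim$records$id[1])
  expect_identical(predict_sequence(back, M), predict_sequence(m, M))

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(mcnn_load(junk), "not an mCNN checkpoint")
})

test_that("removing the planted direction degrades skill toward chance", {
  sim <- tiny_sim(seed = 36, n = 10, d = 12, rate = 0.06, effect = 4,
                  lens = c(40L, 60L))
  split <- split_by_sequence(sim$records, 0.8, seed = 1)
  tr <- dplyr::filter(sim$records, id %in% split$train_ids)
  te <- dplyr::filter(sim$records, id %in% split$test_ids)
  cfg <- mcnn_config(window_sizes = c(3, 5), filters = 8, half_width = 3,
                     epochs = 12, dropout = 0.3, validation_fraction = 0,
                     seed = 2)
  run_auc <- function(store) {
    dtr <- make_dataset(tr, store, 3)
    dte <- make_dataset(te, store, 3)
    m <- mcnn_train(mcnn_build(cfg, 12), dtr,
                    resample = resample_config("random", seed = 2))
    roc_auc(mcnn_forward(m, dte), dte$y)$auc
  }
  auc_full <- run_auc(sim$store)
  auc_proj <- run_auc(project_out_direction(sim$store, sim$signal_direction))
  expect_gt(auc_full, 0.85)
  expect_lt(auc_proj, 0.75)
  expect_gt(auc_full - auc_proj, 0.15)
})
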