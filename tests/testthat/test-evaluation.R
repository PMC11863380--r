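# confusion-count rows from the published feature/imbalance/PCA/merged/
# classifier comparison tables whose printed metrics are internally
# consistent with their own counts, frozen here with the printed values
published_rows <- list(
  list(c(26, 80, 3647, 5),   c(0.8387, 0.9785, 0.9774, 0.4465)),  # ProtT5 / mCNN
  list(c(26, 178, 3549, 5),  c(0.8387, 0.9522, 0.9513, 0.3157)),  # SMOTE
  list(c(27, 330, 3397, 4),  c(0.8710, 0.9115, 0.9111, 0.2414)),  # ADASYN
  list(c(26, 182, 3545, 5),  c(0.8387, 0.9512, 0.9502, 0.3124)),  # random os.
  list(c(26, 264, 3463, 5),  c(0.8387, 0.9292, 0.9284, 0.2603)),  # PCA 64
  list(c(25, 149, 3578, 6),  c(0.8065, 0.9600, 0.9588, 0.3299)),  # PCA 128
  list(c(26, 314, 3413, 5),  c(0.8387, 0.9157, 0.9151, 0.2379)),  # PCA 256
  list(c(25, 196, 3531, 6),  c(0.8065, 0.9474, 0.9462, 0.2898)),  # PCA 512
  list(c(27, 211, 3516, 4),  c(0.8710, 0.9434, 0.9428, 0.3024)),  # +ESM-650M
  list(c(27, 322, 3405, 4),  c(0.8710, 0.9136, 0.9133, 0.2445)),  # +TAPE
  list(c(26, 263, 3464, 5),  c(0.8387, 0.9294, 0.9287, 0.2608)),  # ESM+TAPE
  list(c(27, 308, 3419, 4),  c(0.8710, 0.9174, 0.9170, 0.2502)),  # three-way
  list(c(14, 5, 3722, 17),   c(0.4516, 0.9987, 0.9941, 0.5742)),  # KNN
  list(c(11, 6, 3721, 20),   c(0.3548, 0.9984, 0.9931, 0.4761)),  # SVM
  list(c(4, 2, 3725, 27),    c(0.1290, 0.9995, 0.9923, 0.2911)),  # RF
  list(c(6, 2, 3725, 25),    c(0.1935, 0.9995, 0.9928, 0.3788)),  # XGBoost
  list(c(25, 403, 3324, 6),  c(0.8065, 0.8919, 0.8912, 0.1988)),  # plain CNN
  list(c(25, 360, 3367, 6),  c(0.8065, 0.9034, 0.9026, 0.2117))   # LSTM
)

test_that("published confusion counts reproduce their printed metrics to 4 dp", {
  for (row in published_rows) {
    cc <- confusion_counts(TP = row[[1]][1], FP = row[[1]][2],
                           TN = row[[1]][3], FN = row[[1]][4])
    m <- compute_metrics(cc)
    got <- round(c(m$sensitivity, m$specificity, m$accuracy, m$mcc), 4)
    expect_equal(got, row[[2]])
  }
})

test_that("confusion matches exhaustive counting on random inputs", {
  withr::with_seed(19, {
    for (i in seq_len(100)) {
      n <- sample(5:80, 1)
      scores <- round(runif(n), 2)
      labels <- sample(0:1, n, replace = TRUE)
      t <- runif(1)
      cc <- confusion(scores, labels, t)
      TP <- FP <- TN <- FN <- 0L
      for (j in seq_len(n)) {
        pred <- scores[j] >= t
        if (pred && labels[j] == 1L) TP <- TP + 1L
        if (pred && labels[j] == 0L) FP <- FP + 1L
        if (!pred && labels[j] == 0L) TN <- TN + 1L
        if (!pred && labels[j] == 1L) FN <- FN + 1L
      }
      expect_equal(unlist(unclass(cc)), c(TP = TP, FP = FP, TN = TN, FN = FN))
    }
  })
})

test_that("confusion degenerate cases behave as documented", {
  cc <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0), 0.5)
  expect_equal(cc$FP + cc$FN, 0L)
  cc0 <- confusion(rep(0, 6), c(1, 1, 0, 0, 0, 0), 0.5)
  expect_equal(cc0$TP, 0L)
  expect_equal(cc0$FP, 0L)
  expect_error(confusion(numeric(0), integer(0)), "empty")
  # ties at the threshold count as positive
  expect_equal(confusion(c(0.5, 0.5), c(1L, 0L), 0.5)$TP, 1L)
  expect_equal(confusion(c(0.5, 0.5), c(1L, 0L), 0.5)$FP, 1L)
})

test_that("perfect counts give all metrics 1; empty denominators warn", {
  m <- compute_metrics(confusion_counts(TP = 7, FP = 0, TN = 13, FN = 0))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1,
                            accuracy = 1, mcc = 1))
  expect_warning(
    z <- compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 0)),
    "MCC"
  )
  expect_equal(z$mcc, 0)
})

test_that("roc_auc handles the degenerate extremes", {
  expect_equal(roc_auc(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0L, 1L), 5))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1L, 1L)), "both classes")
})

test_that("rank AUC equals pair counting and the trapezoidal curve area", {
  brute <- function(s, y) {
    pos <- s[y == 1L]; neg <- s[y == 0L]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(23, {
    for (i in seq_len(500)) {
      n <- sample(4:60, 1)
      s <- round(runif(n), sample(1:3, 1))    # coarse grid forces ties
      y <- sample(0:1, n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      r <- roc_auc(s, y)
      expect_equal(r$auc, brute(s, y), tolerance = 1e-12)
      trap <- sum(diff(r$curve$fpr) *
                    (utils::head(r$curve$tpr, -1) + utils::tail(r$curve$tpr, -1)) / 2)
      expect_equal(trap, r$auc, tolerance = 1e-12)
    }
  })
})

test_that("AUC of negated scores complements and pROC agrees", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    s <- runif(200)
    y <- rbinom(200, 1, 0.3)
    r <- roc_auc(s, y)
    expect_equal(r$auc + roc_auc(-s, y)$auc, 1, tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, direction = "<", quiet = TRUE)))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("threshold metrics are invariant under monotone score transforms", {
  withr::with_seed(31, {
    s <- runif(100)
    y <- rbinom(100, 1, 0.4)
    t <- 0.37
    a <- compute_metrics(confusion(s, y, t))
    b <- compute_metrics(confusion(plogis(5 * s), y, plogis(5 * t)))
    expect_equal(a, b)
  })
})

test_that("youden threshold separates separable scores", {
  s <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.3)
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  t <- youden_threshold(s, y)
  cc <- confusion(s, y, t)
  expect_equal(cc$FP + cc$FN, 0L)
})

test_that("greedy combination ordering follows descending single AUC", {
  combos <- greedy_combinations(c(2, 4, 6), c(0.97, 0.98, 0.96))
  expect_equal(combos, list(4L, c(4L, 2L), c(4L, 2L, 6L)))
})
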