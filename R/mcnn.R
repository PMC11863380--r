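#' Multi-window CNN configuration
#'
#' Architecture and training hyperparameters for the multi-window
#' convolutional scanner. The model runs one 1-D convolution block per
#' window size in `window_sizes` over the residue axis of the
#' `(2L+1) x d` context window (kernels span the full embedding depth,
#' valid mode), applies ReLU and global max-pooling per block,
#' concatenates the pooled features (length `length(window_sizes) *
#' filters`), and classifies through one dense ReLU layer with dropout
#' and a sigmoid output.
#'
#' Every kernel must fit the context: `max(window_sizes) <= 2 *
#' half_width + 1`. The optimizer (adaptive-moment, cross-entropy loss),
#' dense width, dropout and early stopping are package defaults, exposed
#' here because the original study design leaves them open.
#'
#' @param window_sizes Integer vector of convolution kernel sizes
#'   (default `c(6, 8, 10, 12)`).
#' @param filters Filters per convolution block (default 64).
#' @param half_width Context half-width L; windows are `2L+1` residues
#'   (default 6).
#' @param dense_units Width of the dense hidden layer (default 128).
#' @param dropout Dropout rate on the dense layer during training, in
#'   `[0, 1)` (default 0.2).
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay Decoupled L2 weight decay applied to the kernel
#'   and dense weight matrices (not biases) at each step (default 1e-4).
#' @param input_noise Standard deviation of Gaussian jitter added to each
#'   training batch (augmentation; 0 disables, default 0).
#' @param lr_schedule `"constant"` or `"cosine"` (cosine anneal of the
#'   learning rate over `epochs`).
#' @param patience Early-stopping patience on validation AUC (default 5).
#' @param validation_fraction Fraction of training windows held out,
#'   stratified by label, to monitor validation AUC (default 0.1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `mcnn_config`.
#' @export
mcnn_config <- function(window_sizes = c(6L, 8L, 10L, 12L), filters = 64L,
                        half_width = 6L, dense_units = 128L, dropout = 0.2,
                        epochs = 50L, batch_size = 256L,
                        learning_rate = 1e-3, weight_decay = 1e-4,
                        input_noise = 0, lr_schedule = c("constant", "cosine"),
                        patience = 5L,
                        validation_fraction = 0.1, seed = 1L) {
  window_sizes <- sort(unique(as.integer(window_sizes)))
  filters <- as.integer(filters)
  half_width <- as.integer(half_width)
  if (length(window_sizes) < 1L || any(window_sizes < 1L)) {
    abort("`window_sizes` must be positive integers")
  }
  if (filters < 1L) abort("`filters` must be >= 1")
  if (half_width < 1L) abort("`half_width` must be >= 1")
  if (max(window_sizes) > 2L * half_width + 1L) {
    abort(sprintf(
      paste0("kernel size %d cannot scan a %d-row context: ",
             "max(window_sizes) must be <= 2 * half_width + 1 = %d"),
      max(window_sizes), 2L * half_width + 1L, 2L * half_width + 1L
    ))
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1)")
  lr_schedule <- match.arg(lr_schedule)
  if (input_noise < 0) abort("`input_noise` must be >= 0")
  structure(
    list(
      window_sizes = window_sizes, filters = filters, half_width = half_width,
      dense_units = as.integer(dense_units), dropout = dropout,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, weight_decay = weight_decay,
      input_noise = input_noise, lr_schedule = lr_schedule,
      patience = as.integer(patience),
      validation_fraction = validation_fraction, seed = as.integer(seed)
    ),
    class = "mcnn_config"
  )
}

#' Build an (untrained) multi-window CNN
#'
#' Initializes one convolution block per window size plus the dense
#' classifier head, deterministically from `config$seed`.
#'
#' @param config An [mcnn_config()].
#' @param d Embedding dimension of the input windows.
#' @return An object of class `mcnn_model`.
#' @export
mcnn_build <- function(config, d) {
  stopifnot(inherits(config, "mcnn_config"))
  d <- as.integer(d)
  if (d < 1L) abort("`d` must be >= 1")
  params <- with_seed(config$seed, {
    conv <- lapply(config$window_sizes, function(k) {
      list(
        W = matrix(rnorm(k * d * config$filters, sd = sqrt(2 / (k * d))),
                   nrow = k * d, ncol = config$filters),
        b = numeric(config$filters)
      )
    })
    names(conv) <- paste0("w", config$window_sizes)
    p0 <- length(config$window_sizes) * config$filters
    list(
      conv = conv,
      W1 = matrix(rnorm(p0 * config$dense_units, sd = sqrt(2 / p0)),
                  nrow = p0, ncol = config$dense_units),
      b1 = numeric(config$dense_units),
      W2 = matrix(rnorm(config$dense_units, sd = sqrt(2 / config$dense_units)),
                  nrow = config$dense_units, ncol = 1L),
      b2 = 0
    )
  })
  structure(
    list(config = config, d = d, params = params, trained = FALSE,
         history = tibble::tibble(epoch = integer(), loss = numeric(),
                                  val_auc = numeric()),
         version = 1L),
    class = "mcnn_model"
  )
}

#' @export
print.mcnn_model <- function(x, ...) {
  cat(sprintf(
    "<mcnn_model> windows {%s} x %d filters, context %d x %d, %s (%d parameters)\n",
    paste(x$config$window_sizes, collapse = ","), x$config$filters,
    2L * x$config$half_width + 1L, x$d,
    if (x$trained) "trained" else "untrained", mcnn_param_count(x)
  ))
  invisible(x)
}

#' Total number of trainable parameters of an mCNN
#'
#' @param model An `mcnn_model`.
#' @return Integer parameter count.
#' @export
mcnn_param_count <- function(model) {
  cfg <- model$config
  conv <- sum(vapply(cfg$window_sizes,
                     function(k) k * model$d * cfg$filters + cfg$filters,
                     numeric(1)))
  p0 <- length(cfg$window_sizes) * cfg$filters
  as.integer(conv + p0 * cfg$dense_units + cfg$dense_units +
               cfg$dense_units + 1L)
}

# ---- forward / backward ----------------------------------------------------

# forward pass on flattened windows (n x (2L+1)*d, window rows contiguous);
# returns scores plus the cache needed for backprop when requested
mcnn_forward_flat <- function(params, Xflat, config, d,
                              dropout_mask = NULL, cache = FALSE) {
  R <- 2L * config$half_width + 1L
  nF <- config$filters
  n <- nrow(Xflat)
  nk <- length(config$window_sizes)
  H0 <- matrix(0, nrow = n, ncol = nk * nF)
  pool_arg <- if (cache) vector("list", nk)
  for (ki in seq_len(nk)) {
    k <- config$window_sizes[ki]
    blk <- params$conv[[ki]]
    P <- R - k + 1L
    Amax <- matrix(-Inf, n, nF)
    Aarg <- matrix(1L, n, nF)
    for (p in seq_len(P)) {
      cols <- ((p - 1L) * d + 1L):((p + k - 1L) * d)
      A <- Xflat[, cols, drop = FALSE] %*% blk$W
      A <- sweep(A, 2L, blk$b, "+")
      upd <- is.na(A) | A > Amax   # NAs propagate to the loss check
      Aarg[upd] <- p
      Amax[upd] <- A[upd]
    }
    H0[, ((ki - 1L) * nF + 1L):(ki * nF)] <- pmax(Amax, 0)
    if (cache) pool_arg[[ki]] <- Aarg
  }
  Z1 <- sweep(H0 %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(Z1, 0)
  H1d <- if (is.null(dropout_mask)) H1 else H1 * dropout_mask
  logits <- as.vector(H1d %*% params$W2) + params$b2
  out <- list(scores = plogis(logits), logits = logits)
  if (cache) {
    out$H0 <- H0; out$Z1 <- Z1; out$H1d <- H1d; out$pool_arg <- pool_arg
  }
  out
}

mcnn_backward_flat <- function(params, Xflat, y, fwd, config, d,
                               dropout_mask = NULL) {
  R <- 2L * config$half_width + 1L
  nF <- config$filters
  n <- nrow(Xflat)
  dlogits <- (fwd$scores - y) / n
  grads <- list(conv = vector("list", length(config$window_sizes)))
  names(grads$conv) <- names(params$conv)
  grads$W2 <- crossprod(fwd$H1d, dlogits)
  grads$b2 <- sum(dlogits)
  dH1d <- outer(dlogits, as.vector(params$W2))  # n x dense_units
  dH1 <- if (is.null(dropout_mask)) dH1d else dH1d * dropout_mask
  dZ1 <- dH1 * (fwd$Z1 > 0)
  grads$W1 <- crossprod(fwd$H0, dZ1)
  grads$b1 <- colSums(dZ1)
  dH0 <- tcrossprod(dZ1, params$W1)             # n x nk*F
  for (ki in seq_along(config$window_sizes)) {
    k <- config$window_sizes[ki]
    P <- R - k + 1L
    block <- ((ki - 1L) * nF + 1L):(ki * nF)
    # ReLU on the pooled value: gradient flows only where the max was > 0
    G <- dH0[, block, drop = FALSE] * (fwd$H0[, block, drop = FALSE] > 0)
    Aarg <- fwd$pool_arg[[ki]]
    dW <- matrix(0, nrow = k * d, ncol = nF)
    db <- numeric(nF)
    for (p in seq_len(P)) {
      mask <- Aarg == p
      if (!any(mask)) next
      Gp <- G * mask
      cols <- ((p - 1L) * d + 1L):((p + k - 1L) * d)
      dW <- dW + crossprod(Xflat[, cols, drop = FALSE], Gp)
      db <- db + colSums(Gp)
    }
    grads$conv[[ki]] <- list(W = dW, b = db)
  }
  grads
}

bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - y * logits + log1p(exp(-abs(logits))))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, decay) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)
      out <- list(p = p, m = m, v = v)
      for (nm in keys) {
        # decay weight matrices only, never biases
        dk <- if (is.character(nm) && nm %in% c("b", "b1", "b2")) 0 else decay
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]], dk)
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * (mhat / (sqrt(vhat) + eps) + decay * p), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v, weight_decay)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- training --------------------------------------------------------------

#' Train a multi-window CNN on a window dataset
#'
#' Minibatch training with cross-entropy loss and an adaptive-moment
#' optimizer. A stratified fraction of the training windows is held out
#' to monitor validation AUC; training stops early when it has not
#' improved for `patience` epochs, and the best-validation parameters are
#' kept. Optional minority oversampling (see [resample_config()]) is
#' applied to the fitting portion only, never to the validation windows.
#'
#' @param model An untrained (or previously trained) `mcnn_model` from
#'   [mcnn_build()].
#' @param dataset A `window_dataset` from [make_dataset()].
#' @param resample A [resample_config()]; default no resampling.
#' @param seed Integer seed for shuffling/dropout (defaults to the
#'   config seed).
#' @param verbose Print per-epoch progress.
#' @return The trained `mcnn_model`, with `history` filled (one row per
#'   epoch: loss and validation AUC).
#' @export
mcnn_train <- function(model, dataset, resample = resample_config("none"),
                       seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mcnn_model"), inherits(dataset, "window_dataset"))
  cfg <- model$config
  if (dataset$d != model$d) {
    abort(sprintf("dataset has d = %d but model expects d = %d",
                  dataset$d, model$d))
  }
  if (dataset$L != cfg$half_width) {
    abort(sprintf("dataset was built with L = %d but the model expects L = %d",
                  dataset$L, cfg$half_width))
  }
  seed <- seed %||% cfg$seed
  Xall <- flatten_windows(dataset)
  yall <- dataset$y

  with_seed(seed, {
    # stratified validation split for early stopping
    n <- length(yall)
    n_val <- floor(cfg$validation_fraction * n)
    val_idx <- integer(0)
    if (n_val >= 2L) {
      pos <- which(yall == 1L); neg <- which(yall == 0L)
      n_val_pos <- min(length(pos) - 1L, max(1L, round(cfg$validation_fraction * length(pos))))
      if (n_val_pos >= 1L && length(pos) > n_val_pos) {
        val_idx <- c(pos[sample.int(length(pos), n_val_pos)],
                     neg[sample.int(length(neg), max(1L, n_val - n_val_pos))])
      }
    }
    monitor <- length(val_idx) > 0L
    fit_idx <- setdiff(seq_len(n), val_idx)
    Xfit <- Xall[fit_idx, , drop = FALSE]
    yfit <- yall[fit_idx]
    rs <- resample(Xfit, yfit, resample)
    Xfit <- rs$x; yfit <- rs$y
    if (length(unique(yfit)) < 2L) {
      abort("training requires both classes present after resampling")
    }

    params <- model$params
    state <- adam_init(params)
    best <- list(auc = -Inf, params = params, epoch = 0L)
    history <- vector("list", cfg$epochs)
    stale <- 0L
    nf <- nrow(Xfit)
    last_epoch <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      lr <- if (identical(cfg$lr_schedule, "cosine")) {
        cfg$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1L) / cfg$epochs))
      } else {
        cfg$learning_rate
      }
      ord <- sample.int(nf)
      losses <- numeric(0)
      for (start in seq(1L, nf, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, nf)]
        Xb <- Xfit[idx, , drop = FALSE]
        if (cfg$input_noise > 0) {
          Xb <- Xb + matrix(rnorm(length(Xb), sd = cfg$input_noise),
                            nrow = nrow(Xb))
        }
        yb <- yfit[idx]
        mask <- if (cfg$dropout > 0) {
          matrix(
            (runif(length(idx) * cfg$dense_units) >= cfg$dropout) /
              (1 - cfg$dropout),
            nrow = length(idx)
          )
        }
        fwd <- mcnn_forward_flat(params, Xb, cfg, model$d,
                                 dropout_mask = mask, cache = TRUE)
        loss <- bce_loss(fwd$logits, yb)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        losses <- c(losses, loss)
        grads <- mcnn_backward_flat(params, Xb, yb, fwd, cfg, model$d,
                                    dropout_mask = mask)
        st <- adam_step(params, grads, state, lr,
                        weight_decay = cfg$weight_decay %||% 0)
        params <- st$params
        state <- st$state
      }
      val_auc <- NA_real_
      if (monitor) {
        vs <- mcnn_forward_flat(params, Xall[val_idx, , drop = FALSE],
                                cfg, model$d)$scores
        val_auc <- roc_auc(vs, yall[val_idx])$auc
        if (val_auc > best$auc + 1e-6) {
          best <- list(auc = val_auc, params = params, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(losses), val_auc = val_auc
      )
      last_epoch <- epoch
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val AUC %s", epoch, mean(losses),
                        ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
      }
      if (monitor && stale >= cfg$patience) break
    }
    model$params <- if (monitor && best$epoch > 0L) best$params else params
    model$history <- dplyr::bind_rows(history[seq_len(last_epoch)])
    model$best_val_auc <- if (monitor) best$auc else NA_real_
    model$trained <- TRUE
    model
  })
}

#' Score context windows with an mCNN
#'
#' @param model An `mcnn_model`.
#' @param x A single `(2L+1) x d` window matrix, or an array
#'   `n x (2L+1) x d` of windows, or a `window_dataset`.
#' @return Numeric scores in `(0, 1)`, one per window.
#' @export
mcnn_forward <- function(model, x) {
  stopifnot(inherits(model, "mcnn_model"))
  R <- 2L * model$config$half_width + 1L
  if (inherits(x, "window_dataset")) {
    Xflat <- flatten_windows(x)
    if (x$L != model$config$half_width || x$d != model$d) {
      abort("window_dataset shape does not match the model")
    }
  } else if (is.matrix(x)) {
    if (!identical(dim(x), c(R, model$d))) {
      abort(sprintf("window must be %d x %d, got %d x %d",
                    R, model$d, nrow(x), ncol(x)))
    }
    Xflat <- matrix(as.vector(t(x)), nrow = 1L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != R || dim(x)[3] != model$d) {
      abort(sprintf("window array must be n x %d x %d", R, model$d))
    }
    ds <- structure(list(x = x, L = model$config$half_width, d = model$d),
                    class = "window_dataset")
    Xflat <- flatten_windows(ds)
  } else {
    abort("`x` must be a window matrix, window array, or window_dataset")
  }
  mcnn_forward_flat(model$params, Xflat, model$config, model$d)$scores
}

#' Per-residue scores for one sequence
#'
#' Applies the model at every residue of an embedding matrix: the context
#' window (zero-padded at the termini) is extracted at each centre and
#' scored, yielding one score per residue. Equivalent to looping
#' [extract_window()] + [mcnn_forward()].
#'
#' @param model A trained `mcnn_model`.
#' @param M An `L x d` per-residue embedding matrix.
#' @return Numeric vector of `nrow(M)` scores in `(0, 1)`.
#' @export
predict_sequence <- function(model, M) {
  stopifnot(inherits(model, "mcnn_model"), is.matrix(M))
  if (ncol(M) != model$d) {
    abort(sprintf("embedding matrix has d = %d but the model expects d = %d",
                  ncol(M), model$d))
  }
  L <- model$config$half_width
  R <- 2L * L + 1L
  Mp <- pad_matrix(M, L)
  len <- nrow(M)
  Xflat <- matrix(0, nrow = len, ncol = R * ncol(M))
  for (c0 in seq_len(len)) {
    Xflat[c0, ] <- as.vector(t(Mp[c0:(c0 + R - 1L), , drop = FALSE]))
  }
  mcnn_forward_flat(model$params, Xflat, model$config, model$d)$scores
}

#' Predict binding residues for a set of records
#'
#' Runs [predict_sequence()] over every record and assembles the tidy
#' per-residue prediction table.
#'
#' @param model A trained `mcnn_model` (or a `baseline_model`).
#' @param records A tibble of protein records.
#' @param store An [embedding_store()] covering the records.
#' @param threshold Decision threshold; a residue is called binding when
#'   `score >= threshold` (default 0.5).
#' @return A tibble with columns `id`, `position`, `residue`, `score`,
#'   `label`.
#' @export
predict_records <- function(model, records, store, threshold = 0.5) {
  pair_records_store(records, store)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    M <- store_matrix(store, records$id[[i]])
    s <- if (inherits(model, "baseline_model")) {
      predict_sequence_baseline(model, M)
    } else {
      predict_sequence(model, M)
    }
    tibble::tibble(
      id = records$id[[i]],
      position = seq_len(nrow(M)),
      residue = strsplit(records$sequence[[i]], "")[[1]],
      score = as.numeric(s),
      label = as.integer(s >= threshold)
    )
  })
  dplyr::bind_rows(rows)
}

# ---- serialization ---------------------------------------------------------

#' Save / load an mCNN checkpoint
#'
#' Single-file checkpoint holding the configuration, embedding dimension,
#' weights and training history, with a format marker and version so
#' incompatible files fail loudly.
#'
#' @param model An `mcnn_model`.
#' @param path Checkpoint file path.
#' @return `mcnn_save()` returns `path` invisibly; `mcnn_load()` the
#'   restored `mcnn_model`.
#' @export
mcnn_save <- function(model, path) {
  stopifnot(inherits(model, "mcnn_model"))
  saveRDS(list(format = "cabindr_mcnn_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname mcnn_save
#' @export
mcnn_load <- function(path) {
  if (!file.exists(path)) abort(paste0("model checkpoint not found: ", path))
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "cabindr_mcnn_model")) {
    abort(paste0("not an mCNN checkpoint: ", path))
  }
  if (!identical(obj$version, 1L)) {
    abort(sprintf("unsupported checkpoint version: %s", obj$version))
  }
  obj$model
}

# ---- broom-style methods ---------------------------------------------------

#' @describeIn mcnn_train Per-epoch training history (epoch, loss,
#'   validation AUC) as a tibble.
#' @param x An `mcnn_model`.
#' @param ... Unused.
#' @method tidy mcnn_model
#' @export
tidy.mcnn_model <- function(x, ...) x$history

#' @describeIn mcnn_train One-row model summary: parameter count, epochs
#'   trained, best validation AUC.
#' @method glance mcnn_model
#' @export
glance.mcnn_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = mcnn_param_count(x),
    n_windows = length(x$config$window_sizes),
    filters = x$config$filters,
    half_width = x$config$half_width,
    trained = x$trained,
    epochs_trained = nrow(x$history),
    best_val_auc = x$best_val_auc %||% NA_real_
  )
}

#' Plot the training history of an mCNN
#'
#' Loss and validation AUC per epoch.
#'
#' @param object A trained `mcnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcnn_model
#' @export
autoplot.mcnn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "mCNN training history") +
    ggplot2::theme_minimal()
}
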