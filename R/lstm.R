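# Prediction unit: a per-base structural labeller.  A multi-layer
# bidirectional LSTM encoder (peephole cells) turns each one-hot base into a
# context vector; a fully connected decoder maps it to scores over the 7
# structural symbols.  Implemented directly in vectorised R with
# hand-derived backpropagation through time and Adam updates: the networks
# used in tests are small, and keeping the implementation self-contained
# makes every gradient checkable by finite differences.

#' Labeller architecture configuration
#'
#' Defaults follow the full-scale architecture: a 3-layer bidirectional
#' LSTM with 300 hidden units per direction (concatenated state 600) and a
#' fully connected decoder with layer widths 600, 1024, 512 and 7, ReLU
#' activations, over 8-bit one-hot base inputs and 300-base windows.  The
#' decoder input width must equal twice the per-direction hidden width.
#'
#' @param encoder_layers Number of stacked bidirectional LSTM layers.
#' @param hidden Hidden units per direction.
#' @param decoder_widths Fully connected layer widths; the first must be
#'   `2 * hidden`, the last 7.
#' @param input_width One-hot base width (8).
#' @param window Window length the model operates on.
#' @return A list of class `model_config`.
#' @export
model_config <- function(encoder_layers = 3L, hidden = 300L,
                         decoder_widths = c(600L, 1024L, 512L, 7L),
                         input_width = 8L, window = 300L) {
  if (decoder_widths[1L] != 2L * hidden) {
    stop("model_config: decoder input width ", decoder_widths[1L],
         " must be twice the per-direction hidden width (", 2L * hidden, ")")
  }
  if (decoder_widths[length(decoder_widths)] != 7L) {
    stop("model_config: decoder must end in 7 output nodes")
  }
  stopifnot(encoder_layers >= 1L, hidden >= 1L, input_width >= 1L,
            window >= 1L)
  structure(
    list(encoder_layers = as.integer(encoder_layers),
         hidden = as.integer(hidden),
         decoder_widths = as.integer(decoder_widths),
         input_width = as.integer(input_width),
         window = as.integer(window)),
    class = "model_config"
  )
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay, so the
#'   rate is non-increasing across epochs.
#' @param keep_prob Dropout keep probability in encoder and decoder
#'   (`0.9` means 10% of activations dropped during training).
#' @param batch_size Mini-batch size.
#' @param init_std Standard deviation of the normal weight initialisation.
#' @param folds Folds for cross-validation.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, lr = 0.002, lr_decay = 0.96,
                         keep_prob = 0.9, batch_size = 32L,
                         init_std = 0.1, folds = 10L, seed = 1L) {
  stopifnot(keep_prob > 0, keep_prob <= 1, folds >= 2L, epochs >= 1L,
            lr >= 0, lr_decay > 0, lr_decay <= 1, batch_size >= 1L,
            init_std > 0)
  structure(
    list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
         keep_prob = keep_prob, batch_size = as.integer(batch_size),
         init_std = init_std, folds = as.integer(folds),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Gate block order within the 4h-wide stacked matrices: input, forget,
# cell candidate, output.
gate_idx <- function(h) {
  list(i = 1:h, f = (h + 1L):(2L * h), g = (2L * h + 1L):(3L * h),
       o = (3L * h + 1L):(4L * h))
}

rnorm_mat <- function(nr, nc, sd) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Build an untrained labeller
#'
#' All weights, biases and peephole vectors are initialised from a normal
#' distribution with the given standard deviation.
#'
#' @param config A [model_config()].
#' @param init_std Initialisation standard deviation.
#' @param seed Optional integer seed for reproducible initialisation.
#' @return An object of class `lstm_predictor`.
#' @export
build_model <- function(config = model_config(), init_std = 0.1,
                        seed = NULL) {
  with_seed(seed, {
    h <- config$hidden
    enc <- lapply(seq_len(config$encoder_layers), function(l) {
      d_in <- if (l == 1L) config$input_width else 2L * h
      lapply(c(fwd = 1, bwd = 2), function(dir) {
        list(W = rnorm_mat(d_in, 4L * h, init_std),
             U = rnorm_mat(h, 4L * h, init_std),
             b = stats::rnorm(4L * h, sd = init_std),
             p_i = stats::rnorm(h, sd = init_std),
             p_f = stats::rnorm(h, sd = init_std),
             p_o = stats::rnorm(h, sd = init_std))
      })
    })
    w <- config$decoder_widths
    dec <- lapply(seq_len(length(w) - 1L), function(j) {
      list(W = rnorm_mat(w[j], w[j + 1L], init_std),
           b = stats::rnorm(w[j + 1L], sd = init_std))
    })
    structure(list(config = config, enc = enc, dec = dec, opt = NULL),
              class = c("lstm_predictor", "knotfold_predictor"))
  })
}

#' @export
print.lstm_predictor <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lstm_predictor> %d-layer bidirectional LSTM (%d/dir) -> decoder %s\n",
    cfg$encoder_layers, cfg$hidden,
    paste(cfg$decoder_widths, collapse = "-")
  ))
  invisible(x)
}

# ---- forward pass -----------------------------------------------------------

# One directional LSTM layer over a batch.  x: array (B, T, d_in).
# Returns list(h = array (B, T, h), cache) where cache holds what backprop
# needs.
lstm_layer_forward <- function(x, par, reverse = FALSE) {
  B <- dim(x)[1L]; T_ <- dim(x)[2L]
  h <- ncol(par$U)/4L
  gi <- gate_idx(h)
  order_t <- if (reverse) T_:1 else 1:T_
  H <- array(0, c(B, T_, h))
  cache <- vector("list", T_)
  h_prev <- matrix(0, B, h)
  c_prev <- matrix(0, B, h)
  for (t in order_t) {
    xt <- matrix(x[, t, ], B)
    z <- xt %*% par$W + h_prev %*% par$U
    z <- sweep(z, 2L, par$b, `+`)
    zi <- z[, gi$i, drop = FALSE] + c_prev * matrix(par$p_i, B, h, byrow = TRUE)
    zf <- z[, gi$f, drop = FALSE] + c_prev * matrix(par$p_f, B, h, byrow = TRUE)
    ig <- 1 / (1 + exp(-zi))
    fg <- 1 / (1 + exp(-zf))
    gg <- tanh(z[, gi$g, drop = FALSE])
    ct <- fg * c_prev + ig * gg
    zo <- z[, gi$o, drop = FALSE] + ct * matrix(par$p_o, B, h, byrow = TRUE)
    og <- 1 / (1 + exp(-zo))
    tc <- tanh(ct)
    ht <- og * tc
    H[, t, ] <- ht
    cache[[t]] <- list(x = xt, h_prev = h_prev, c_prev = c_prev,
                       i = ig, f = fg, g = gg, o = og, c = ct, tc = tc)
    h_prev <- ht
    c_prev <- ct
  }
  list(h = H, cache = cache, order_t = order_t)
}

# Backward through one directional layer.  dH: (B, T, h) gradient w.r.t.
# the layer's hidden outputs.  Returns list(dx, grads).
lstm_layer_backward <- function(dH, par, fwd) {
  B <- dim(dH)[1L]; T_ <- dim(dH)[2L]
  h <- ncol(par$U)/4L
  gi <- gate_idx(h)
  g <- list(W = par$W * 0, U = par$U * 0, b = par$b * 0,
            p_i = par$p_i * 0, p_f = par$p_f * 0, p_o = par$p_o * 0)
  dx <- array(0, c(B, T_, nrow(par$W)))
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  P_i <- matrix(par$p_i, B, h, byrow = TRUE)
  P_f <- matrix(par$p_f, B, h, byrow = TRUE)
  P_o <- matrix(par$p_o, B, h, byrow = TRUE)
  for (t in rev(fwd$order_t)) {
    cc <- fwd$cache[[t]]
    dh <- matrix(dH[, t, ], B) + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    do_pre <- do_ * cc$o * (1 - cc$o)
    dc <- dc + do_pre * P_o
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    di_pre <- di * cc$i * (1 - cc$i)
    df_pre <- df * cc$f * (1 - cc$f)
    dg_pre <- dg * (1 - cc$g^2)
    dz <- cbind(di_pre, df_pre, dg_pre, do_pre)
    g$W <- g$W + crossprod(cc$x, dz)
    g$U <- g$U + crossprod(cc$h_prev, dz)
    g$b <- g$b + colSums(dz)
    g$p_i <- g$p_i + colSums(di_pre * cc$c_prev)
    g$p_f <- g$p_f + colSums(df_pre * cc$c_prev)
    g$p_o <- g$p_o + colSums(do_pre * cc$c)
    dh_next <- dz %*% t(par$U)
    dc_next <- dc * cc$f + di_pre * P_i + df_pre * P_f
    dx[, t, ] <- dz %*% t(par$W)
  }
  list(dx = dx, grads = g)
}

# Full forward pass.  x: (B, T, 8).  keep_prob < 1 applies inverted
# dropout to encoder layer outputs and decoder hidden activations (training
# mode).  Returns logits (B*T, 7) plus caches for backprop.
model_forward <- function(predictor, x, keep_prob = 1) {
  B <- dim(x)[1L]; T_ <- dim(x)[2L]
  enc_caches <- list()
  drop_masks <- list()
  inp <- x
  for (l in seq_along(predictor$enc)) {
    fwd <- lstm_layer_forward(inp, predictor$enc[[l]]$fwd, reverse = FALSE)
    bwd <- lstm_layer_forward(inp, predictor$enc[[l]]$bwd, reverse = TRUE)
    h2 <- array(0, c(B, T_, 2L * dim(fwd$h)[3L]))
    h2[, , seq_len(dim(fwd$h)[3L])] <- fwd$h
    h2[, , dim(fwd$h)[3L] + seq_len(dim(fwd$h)[3L])] <- bwd$h
    if (keep_prob < 1) {
      mask <- array(stats::rbinom(length(h2), 1L, keep_prob) / keep_prob,
                    dim(h2))
      h2 <- h2 * mask
      drop_masks[[l]] <- mask
    }
    enc_caches[[l]] <- list(fwd = fwd, bwd = bwd, input = inp)
    inp <- h2
  }
  # decoder operates position-wise on the flattened (B*T, 2h) matrix
  H <- matrix(aperm(inp, c(1, 2, 3)), B * T_, dim(inp)[3L])
  dec_cache <- list()
  a <- H
  n_dec <- length(predictor$dec)
  for (j in seq_len(n_dec)) {
    z <- sweep(a %*% predictor$dec[[j]]$W, 2L, predictor$dec[[j]]$b, `+`)
    if (j < n_dec) {
      act <- pmax(z, 0)
      if (keep_prob < 1) {
        dmask <- matrix(stats::rbinom(length(act), 1L, keep_prob) / keep_prob,
                        nrow(act))
        act <- act * dmask
      } else dmask <- NULL
      dec_cache[[j]] <- list(input = a, z = z, mask = dmask)
      a <- act
    } else {
      dec_cache[[j]] <- list(input = a, z = z, mask = NULL)
      a <- z
    }
  }
  list(logits = a, enc_caches = enc_caches, dec_cache = dec_cache,
       drop_masks = drop_masks, B = B, T_ = T_)
}

# Masked softmax cross-entropy.  y: (B*T, 7) one-hot rows, all-zero rows
# are padding and excluded from loss and gradient.
masked_ce <- function(logits, y) {
  mask <- rowSums(y) > 0
  m <- sum(mask)
  if (m == 0L) stop("masked_ce: no non-padding labels in batch")
  lx <- logits - apply(logits, 1L, max)
  ex <- exp(lx)
  probs <- ex / rowSums(ex)
  eps <- 1e-12
  loss <- -sum(y[mask, , drop = FALSE] *
                 log(pmax(probs[mask, , drop = FALSE], eps))) / m
  dlogits <- (probs - y) / m
  dlogits[!mask, ] <- 0
  acc <- mean(apply(probs[mask, , drop = FALSE], 1L, which.max) ==
                apply(y[mask, , drop = FALSE], 1L, which.max))
  list(loss = loss, dlogits = dlogits, acc = acc)
}

# Full backward pass; returns gradients in the same nested shape as the
# parameters.
model_backward <- function(predictor, fw, dlogits) {
  n_dec <- length(predictor$dec)
  dec_grads <- vector("list", n_dec)
  da <- dlogits
  for (j in n_dec:1) {
    cc <- fw$dec_cache[[j]]
    if (j < n_dec) {
      if (!is.null(cc$mask)) da <- da * cc$mask
      da <- da * (cc$z > 0)
    }
    dec_grads[[j]] <- list(W = crossprod(cc$input, da), b = colSums(da))
    da <- da %*% t(predictor$dec[[j]]$W)
  }
  B <- fw$B; T_ <- fw$T_
  dH <- array(da, c(B, T_, ncol(da)))
  enc_grads <- vector("list", length(predictor$enc))
  for (l in length(predictor$enc):1) {
    if (length(fw$drop_masks) >= l && !is.null(fw$drop_masks[[l]])) {
      dH <- dH * fw$drop_masks[[l]]
    }
    h <- dim(dH)[3L] / 2L
    bk_f <- lstm_layer_backward(dH[, , seq_len(h), drop = FALSE],
                                predictor$enc[[l]]$fwd,
                                fw$enc_caches[[l]]$fwd)
    bk_b <- lstm_layer_backward(dH[, , h + seq_len(h), drop = FALSE],
                                predictor$enc[[l]]$bwd,
                                fw$enc_caches[[l]]$bwd)
    enc_grads[[l]] <- list(fwd = bk_f$grads, bwd = bk_b$grads)
    dH <- bk_f$dx + bk_b$dx
  }
  list(enc = enc_grads, dec = dec_grads)
}

# ---- Adam -------------------------------------------------------------------

# Flatten/apply over the nested parameter structure.
map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- map_params(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map_params(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

# Stack a list of samples (list(x = T x 8, y = T x 7)) into batch arrays.
stack_batch <- function(samples) {
  B <- length(samples)
  T_ <- nrow(samples[[1L]]$x)
  x <- array(0, c(B, T_, ncol(samples[[1L]]$x)))
  y <- array(0, c(B, T_, ncol(samples[[1L]]$y)))
  for (k in seq_len(B)) {
    x[k, , ] <- samples[[k]]$x
    y[k, , ] <- samples[[k]]$y
  }
  list(x = x, y = y)
}

eval_batchwise <- function(predictor, dataset, batch_size) {
  tot_loss <- 0; tot_acc <- 0; nb <- 0
  idx <- seq_along(dataset)
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    bt <- stack_batch(dataset[sel])
    fw <- model_forward(predictor, bt$x, keep_prob = 1)
    y_flat <- matrix(bt$y, dim(bt$y)[1L] * dim(bt$y)[2L], dim(bt$y)[3L])
    ce <- masked_ce(fw$logits, y_flat)
    tot_loss <- tot_loss + ce$loss; tot_acc <- tot_acc + ce$acc
    nb <- nb + 1L
  }
  list(loss = tot_loss / nb, acc = tot_acc / nb)
}

#' Train a labeller
#'
#' Mini-batch training with softmax cross-entropy (padding positions, whose
#' label is the all-zero vector, are masked out of both the loss and the
#' accuracy), Adam updates, per-epoch multiplicative learning-rate decay
#' and inverted dropout.
#'
#' @param predictor An [build_model()] predictor.
#' @param dataset Non-empty list of samples, each `list(x, y)` with `x` a
#'   `T x 8` encoded window and `y` a `T x 7` one-hot label window.
#' @param config A [train_config()].
#' @param val_dataset Optional validation samples evaluated after each
#'   epoch.
#' @return List with `predictor` (trained) and `history` (a tibble with
#'   one row per epoch: `epoch`, `lr`, `train_loss`, `train_acc`,
#'   `val_loss`, `val_acc`).
#' @export
train_predictor <- function(predictor, dataset, config = train_config(),
                            val_dataset = NULL) {
  if (length(dataset) == 0L) stop("train_predictor: empty dataset")
  with_seed(config$seed, {
    params <- list(enc = predictor$enc, dec = predictor$dec)
    state <- list(t = 0L, m = zeros_like(params), v = zeros_like(params))
    history <- vector("list", config$epochs)
    lr <- config$lr
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(length(dataset))
      ep_loss <- 0; ep_acc <- 0; nb <- 0
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        sel <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        bt <- stack_batch(dataset[sel])
        predictor$enc <- params$enc; predictor$dec <- params$dec
        fw <- model_forward(predictor, bt$x, keep_prob = config$keep_prob)
        y_flat <- matrix(bt$y, dim(bt$y)[1L] * dim(bt$y)[2L], dim(bt$y)[3L])
        ce <- masked_ce(fw$logits, y_flat)
        grads <- model_backward(predictor, fw, ce$dlogits)
        if (lr > 0) {
          stepped <- adam_step(params, grads, state, lr)
          params <- stepped$params
          state <- stepped$state
        }
        ep_loss <- ep_loss + ce$loss; ep_acc <- ep_acc + ce$acc
        nb <- nb + 1L
      }
      predictor$enc <- params$enc; predictor$dec <- params$dec
      if (!is.null(val_dataset)) {
        vl <- eval_batchwise(predictor, val_dataset, config$batch_size)
        val_loss <- vl$loss; val_acc <- vl$acc
      } else {
        val_loss <- NA_real_; val_acc <- NA_real_
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / nb, train_acc = ep_acc / nb,
        val_loss = val_loss, val_acc = val_acc
      )
      lr <- lr * config$lr_decay
    }
    predictor$enc <- params$enc
    predictor$dec <- params$dec
    history <- do.call(rbind, history)
    class(history) <- c("knotfold_history", class(history))
    list(predictor = predictor, history = history)
  })
}

# ---- the predictor contract -------------------------------------------------

#' Score a window of encoded bases
#'
#' The contract every predictor satisfies: given a `T x 8` one-hot window
#' (and the window's coordinates, which oracle predictors use), return a
#' `T x 7` matrix of symbol scores.
#'
#' @param predictor A predictor object.
#' @param x `T x 8` one-hot matrix.
#' @param window Optional list with `id`, `start`, `end` giving the
#'   window's position in its record.
#' @return `T x 7` numeric score matrix.
#' @export
predict_scores <- function(predictor, x, window = NULL) {
  UseMethod("predict_scores")
}

#' @export
predict_scores.lstm_predictor <- function(predictor, x, window = NULL) {
  xx <- array(0, c(1L, nrow(x), ncol(x)))
  xx[1L, , ] <- x
  fw <- model_forward(predictor, xx, keep_prob = 1)
  fw$logits
}

#' Oracle predictor: emits a stored labelling, optionally corrupted
#'
#' Stands in for a trained network so the correction unit can be exercised
#' at a controlled error rate.  The true dot-bracket of each record is
#' corrupted once, at construction, so overlapping windows see consistent
#' symbols.
#'
#' @param truths Named list (by record id) of true dot-bracket strings.
#' @param noise Optional [noise_config()]; `NULL` gives the identity
#'   oracle.
#' @return An object of class `oracle_predictor`.
#' @export
oracle_predictor <- function(truths, noise = NULL) {
  stopifnot(is.list(truths), !is.null(names(truths)))
  emitted <- if (is.null(noise)) {
    truths
  } else {
    out <- truths
    seeds <- if (is.null(noise$seed)) {
      rep(list(NULL), length(truths))
    } else {
      as.list((noise$seed + seq_along(truths) * 97L) %% 2147483587L)
    }
    for (k in seq_along(out)) {
      cfg <- noise
      cfg$seed <- seeds[[k]]
      out[[k]] <- corrupt_symbols(truths[[k]], cfg)
    }
    out
  }
  structure(list(symbols = emitted),
            class = c("oracle_predictor", "knotfold_predictor"))
}

#' @export
predict_scores.oracle_predictor <- function(predictor, x, window = NULL) {
  if (is.null(window) || is.null(predictor$symbols[[window$id]])) {
    stop("oracle predictor needs a window with a known record id")
  }
  db <- predictor$symbols[[window$id]]
  T_ <- nrow(x)
  sym <- strsplit(substr(db, window$start, window$end), "")[[1]]
  pad <- T_ - length(sym)
  encode_symbol(c(sym, rep("N", pad)))
}

#' Predict the full-length symbol string of a record
#'
#' Windows the sequence, scores each window through the predictor, hardens
#' scores to symbols by argmax, and splices the windows back together
#' (padding dropped, overlaps resolved by the window-midpoint rule).
#'
#' @param predictor Any predictor satisfying [predict_scores()].
#' @param record An [rna_record()].
#' @param width,overlap Windowing parameters.
#' @return Symbol string with `nchar` equal to the sequence length.
#' @export
predict_sequence <- function(predictor, record, width = 300L,
                             overlap = 200L) {
  wins <- window_sequence(record$sequence, width, overlap)
  preds <- vapply(wins, function(w) {
    x <- encode_base(w$padded)
    sc <- predict_scores(predictor, x,
                         list(id = record$id, start = w$start, end = w$end))
    paste(decode_symbol(sc), collapse = "")
  }, "")
  merge_window_predictions(wins, preds, nchar(record$sequence), width)
}

# ---- cross-validation -------------------------------------------------------

#' Cross-validate a labeller architecture
#'
#' Holds out a pure test split (10% by default) untouched by training,
#' partitions the remainder into `config$folds` folds, trains one model
#' per fold (training on the other folds, validating on the fold), and
#' averages the per-epoch curves.
#'
#' @param dataset List of samples as in [train_predictor()].
#' @param mcfg A [model_config()].
#' @param config A [train_config()].
#' @param pure_test_frac Fraction held out before folding.
#' @return List with `histories` (per fold), `mean_curve` (per-epoch means
#'   across folds), `fold_of` (fold assignment of each non-test sample)
#'   and `pure_test` (indices of the held-out split).
#' @export
cross_validate <- function(dataset, mcfg = model_config(),
                           config = train_config(),
                           pure_test_frac = 0.1) {
  n <- length(dataset)
  if (n < config$folds) {
    stop("cross_validate: dataset smaller than the number of folds")
  }
  with_seed(config$seed, {
    perm <- sample(n)
    n_test <- floor(n * pure_test_frac)
    pure_test <- sort(perm[seq_len(n_test)])
    rest <- perm[(n_test + 1L):n]
    fold_of <- rep_len(seq_len(config$folds), length(rest))
    histories <- vector("list", config$folds)
    for (f in seq_len(config$folds)) {
      tr <- dataset[rest[fold_of != f]]
      va <- dataset[rest[fold_of == f]]
      model <- build_model(mcfg, init_std = config$init_std,
                           seed = config$seed + f)
      cfg_f <- config
      cfg_f$seed <- config$seed + 1000L + f
      histories[[f]] <- train_predictor(model, tr, cfg_f, va)$history
    }
    mean_curve <- histories[[1L]]
    for (col in c("train_loss", "train_acc", "val_loss", "val_acc", "lr")) {
      mean_curve[[col]] <- rowMeans(
        vapply(histories, function(hh) hh[[col]], numeric(nrow(mean_curve)))
      )
    }
    list(histories = histories, mean_curve = mean_curve,
         fold_of = fold_of, pure_test = pure_test)
  })
}

# ---- tidiers and plots ------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted labeller, one row per epoch
#'
#' @param x A `knotfold_history` (from [train_predictor()]).
#' @param ... Unused.
#' @return The history tibble.
#' @method tidy knotfold_history
#' @export
tidy.knotfold_history <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a labeller
#'
#' @param x An `lstm_predictor`.
#' @param ... Unused.
#' @return Tibble with architecture and parameter count.
#' @method glance lstm_predictor
#' @export
glance.lstm_predictor <- function(x, ...) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 0)) else length(p)
  tibble::tibble(
    encoder_layers = x$config$encoder_layers,
    hidden_per_direction = x$config$hidden,
    decoder = paste(x$config$decoder_widths, collapse = "-"),
    n_parameters = count(list(x$enc, x$dec))
  )
}

#' Plot training curves
#'
#' Loss and accuracy per epoch for training and (when present) validation.
#'
#' @param object A `knotfold_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.knotfold_history <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2")
  }
  h <- tibble::as_tibble(unclass(object))
  long <- do.call(rbind, lapply(
    c("train_loss", "train_acc", "val_loss", "val_acc"),
    function(col) {
      tibble::tibble(
        epoch = h$epoch, value = h[[col]],
        split = sub("_.*", "", col),
        measure = sub(".*_", "", col)
      )
    }
  ))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}
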