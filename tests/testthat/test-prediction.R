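# Tiny architectures keep these tests fast; the contract (shapes,
# gradients, masking, windowing) is identical at full scale.

tiny_mcfg <- function(hidden = 3, layers = 2, window = 6) {
  model_config(encoder_layers = layers, hidden = hidden,
               decoder_widths = c(2L * hidden, 5L, 7L), window = window)
}

random_sample <- function(T_, pad = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::runif(T_ * 8), T_, 8)
  y <- matrix(0, T_, 7)
  for (t in seq_len(T_ - pad)) y[t, sample(7, 1)] <- 1
  list(x = x, y = y)
}

test_that("model configuration enforces the decoder width rule", {
  cfg <- model_config()
  expect_equal(cfg$decoder_widths, c(600L, 1024L, 512L, 7L))
  expect_equal(cfg$hidden * 2L, cfg$decoder_widths[1])
  # test-size: hidden 4 implies decoder input 8
  cfg <- model_config(hidden = 4, decoder_widths = c(8, 5, 7))
  expect_equal(cfg$decoder_widths[1], 8L)
  expect_error(model_config(hidden = 4, decoder_widths = c(10, 5, 7)),
               "twice")
  expect_error(model_config(hidden = 4, decoder_widths = c(8, 5, 6)),
               "7 output nodes")
})

test_that("built models have the configured parameter shapes", {
  m <- build_model(tiny_mcfg(hidden = 3, layers = 2), seed = 1)
  expect_length(m$enc, 2)
  expect_equal(dim(m$enc[[1]]$fwd$W), c(8L, 12L))   # 8 -> 4h
  expect_equal(dim(m$enc[[1]]$bwd$U), c(3L, 12L))
  expect_equal(dim(m$enc[[2]]$fwd$W), c(6L, 12L))   # 2h -> 4h
  expect_equal(dim(m$dec[[1]]$W), c(6L, 5L))
  expect_equal(dim(m$dec[[2]]$W), c(5L, 7L))
  # seeded initialisation is reproducible
  m2 <- build_model(tiny_mcfg(hidden = 3, layers = 2), seed = 1)
  expect_identical(m$enc, m2$enc)
  g <- glance(m)
  expect_gt(g$n_parameters, 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  m <- build_model(tiny_mcfg(), init_std = 0.3, seed = 11)
  B <- 2; T_ <- 6
  x <- array(stats::runif(B * T_ * 8), c(B, T_, 8))
  y <- array(0, c(B, T_, 7))
  for (b in 1:B) for (t in 1:T_) if (stats::runif(1) > 0.2) {
    y[b, t, sample(7, 1)] <- 1
  }
  yf <- matrix(y, B * T_, 7)
  loss_fn <- function(model) {
    fw <- knotfold:::model_forward(model, x, keep_prob = 1)
    knotfold:::masked_ce(fw$logits, yf)$loss
  }
  fw <- knotfold:::model_forward(m, x, keep_prob = 1)
  ce <- knotfold:::masked_ce(fw$logits, yf)
  gr <- knotfold:::model_backward(m, fw, ce$dlogits)
  eps <- 1e-5
  worst <- 0
  for (l in 1:2) for (d in c("fwd", "bwd")) {
    for (nm in c("W", "U", "b", "p_i", "p_f", "p_o")) {
      idx <- sample(length(m$enc[[l]][[d]][[nm]]), 2)
      for (i in idx) {
        mp <- m; mp$enc[[l]][[d]][[nm]][i] <- mp$enc[[l]][[d]][[nm]][i] + eps
        mm <- m; mm$enc[[l]][[d]][[nm]][i] <- mm$enc[[l]][[d]][[nm]][i] - eps
        num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
        ana <- gr$enc[[l]][[d]][[nm]][i]
        denom <- max(1e-6, abs(num) + abs(ana))
        worst <- max(worst, abs(num - ana) / denom)
      }
    }
  }
  for (j in 1:2) for (nm in c("W", "b")) {
    idx <- sample(length(m$dec[[j]][[nm]]), 2)
    for (i in idx) {
      mp <- m; mp$dec[[j]][[nm]][i] <- mp$dec[[j]][[nm]][i] + eps
      mm <- m; mm$dec[[j]][[nm]][i] <- mm$dec[[j]][[nm]][i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      ana <- gr$dec[[j]][[nm]][i]
      denom <- max(1e-6, abs(num) + abs(ana))
      worst <- max(worst, abs(num - ana) / denom)
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  m <- build_model(tiny_mcfg(window = 8), seed = 2)
  samples <- lapply(1:4, function(k) random_sample(8, seed = 20 + k))
  fit <- train_predictor(m, samples,
                         train_config(epochs = 3, lr = 0, keep_prob = 1,
                                      batch_size = 4, seed = 5))
  expect_identical(fit$predictor$enc, m$enc)
  expect_identical(fit$predictor$dec, m$dec)
  expect_equal(stats::var(fit$history$train_loss), 0)
  # with lr 0 the train and validation curves coincide
  fit2 <- train_predictor(m, samples,
                          train_config(epochs = 3, lr = 0, keep_prob = 1,
                                       batch_size = 4, seed = 5),
                          val_dataset = samples)
  expect_equal(fit2$history$train_loss, fit2$history$val_loss)
  expect_equal(fit2$history$train_acc, fit2$history$val_acc)
})

test_that("training is deterministic and the learning rate decays", {
  m <- build_model(tiny_mcfg(window = 8), seed = 3)
  samples <- lapply(1:6, function(k) random_sample(8, seed = 30 + k))
  cfg <- train_config(epochs = 4, lr = 0.01, lr_decay = 0.9,
                      batch_size = 3, seed = 77)
  f1 <- train_predictor(m, samples, cfg)
  f2 <- train_predictor(m, samples, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$predictor$dec, f2$predictor$dec)
  expect_true(all(diff(f1$history$lr) < 0))
  expect_error(train_predictor(m, list(), cfg), "empty")
  h <- tidy(f1$history)
  expect_s3_class(h, "tbl_df")
  expect_equal(nrow(h), 4)
})

test_that("padding labels are excluded from loss and accuracy", {
  # two identical samples except one is half padding; a model that is
  # right on real positions but arbitrary on padding scores identically
  s_full <- random_sample(8, pad = 0, seed = 50)
  s_pad <- list(x = s_full$x, y = s_full$y)
  s_pad$y[5:8, ] <- 0
  m <- build_model(tiny_mcfg(window = 8), seed = 4)
  fw <- knotfold:::model_forward(m, knotfold:::stack_batch(list(s_pad))$x)
  ce <- knotfold:::masked_ce(fw$logits, s_pad$y)
  # gradient w.r.t. padded rows is exactly zero
  expect_true(all(ce$dlogits[5:8, ] == 0))
})

test_that("a small labelling task is learnable by the reduced model", {
  ds <- generate_dataset(6, gen_config(length_range = c(40, 55),
                                       n_stems_range = c(1, 1), pk_prob = 0,
                                       seed = 61))
  samples <- knotfold:::windows_to_samples(
    lapply(ds$instances, `[[`, "record"),
    lapply(ds$instances, `[[`, "db"),
    width = 60L, overlap = 40L
  )
  m <- build_model(model_config(encoder_layers = 2, hidden = 12,
                                decoder_widths = c(24, 32, 7), window = 60),
                   seed = 6)
  fit <- train_predictor(m, samples,
                         train_config(epochs = 130, lr = 0.02,
                                      lr_decay = 0.995, keep_prob = 1,
                                      batch_size = 2, seed = 62))
  final <- knotfold:::eval_batchwise(fit$predictor, samples, 6)
  expect_gt(final$acc, 0.9)
  expect_lt(fit$history$train_loss[130], fit$history$train_loss[1])
})

test_that("the identity oracle reproduces the labelling through windowing", {
  for (n in c(80, 350, 400)) {
    inst <- generate_instance(gen_config(length_range = c(n, n),
                                         n_stems_range = c(2, 4),
                                         pk_prob = 0.5, seed = 7000 + n))
    truths <- stats::setNames(list(inst$db), inst$record$id)
    oracle <- oracle_predictor(truths)
    expect_identical(predict_sequence(oracle, inst$record), inst$db)
  }
})

test_that("a noisy oracle is consistent across overlapping windows", {
  inst <- generate_instance(gen_config(length_range = c(400, 400),
                                       n_stems_range = c(3, 4),
                                       pk_prob = 0.3, seed = 404))
  truths <- stats::setNames(list(inst$db), inst$record$id)
  noisy <- oracle_predictor(truths, noise_config(0.1, seed = 405))
  out1 <- predict_sequence(noisy, inst$record)
  out2 <- predict_sequence(noisy, inst$record)
  expect_identical(out1, out2)  # corruption fixed at construction
  expect_equal(nchar(out1), 400)
  # roughly the configured corruption rate
  mismatch <- mean(strsplit(out1, "")[[1]] != strsplit(inst$db, "")[[1]])
  expect_lt(abs(mismatch - 0.1), 0.06)
})

test_that("neural predictors satisfy the scoring contract end to end", {
  m <- build_model(model_config(encoder_layers = 1, hidden = 4,
                                decoder_widths = c(8, 7), window = 300),
                   seed = 8)
  inst <- generate_instance(gen_config(length_range = c(80, 80), seed = 88))
  sc <- predict_scores(m, encode_base(window_sequence(inst$record$sequence)[[1]]$padded))
  expect_equal(dim(sc), c(300L, 7L))
  out <- predict_sequence(m, inst$record)
  expect_equal(nchar(out), 80)
  expect_true(all(strsplit(out, "")[[1]] %in%
                    c("(", ")", "[", "]", "{", "}", ".")))
})

test_that("cross-validation partitions data and averages fold curves", {
  samples <- lapply(1:12, function(k) random_sample(8, seed = 300 + k))
  cv <- cross_validate(samples,
                       tiny_mcfg(window = 8),
                       train_config(epochs = 2, lr = 0.005, folds = 3,
                                    batch_size = 4, seed = 9),
                       pure_test_frac = 0.25)
  expect_length(cv$histories, 3)
  expect_length(cv$pure_test, 3)      # 25% of 12
  expect_length(cv$fold_of, 9)
  expect_setequal(unique(cv$fold_of), 1:3)
  # the mean curve is the arithmetic mean of the fold curves
  expect_equal(cv$mean_curve$val_loss,
               rowMeans(vapply(cv$histories, function(h) h$val_loss,
                               numeric(2))))
  expect_error(cross_validate(samples[1:2], tiny_mcfg(window = 8),
                              train_config(folds = 3)),
               "smaller than")
})
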