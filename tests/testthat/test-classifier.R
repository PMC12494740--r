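test_that("model shapes and parameter count follow the layer arithmetic", {
  spec <- cnn_spec(27, 11, c(64, 64), c(16, 32))
  expect_equal(spec$pooled_spatial, c(16L, 16L))
  expect_equal(spec$flatten, 16 * 16 * 32)
  model <- build_model(spec, seed = 1)
  # closed-form sum over layers: conv (9C+1)F, fc (D+1)H, out (H+1)K
  expected <- (9 * 27 + 1) * 16 + (9 * 16 + 1) * 32 +
    (16 * 16 * 32 + 1) * 512 + (512 + 1) * 11
  expect_equal(count_params(model), expected)

  x <- array(runif(64 * 64 * 27), c(64, 64, 27))
  logits <- hsiband:::cnn_forward(model$params, x, spec)$logits
  expect_length(logits, 11)

  one_band <- cnn_spec(1, 2, c(8, 8), c(4, 4))
  m1 <- build_model(one_band, seed = 1)
  expect_length(hsiband:::cnn_forward(
    m1$params, array(runif(64), c(8, 8, 1)), one_band)$logits, 2)

  expect_error(cnn_spec(27, 11, c(3, 8)), ">= 4")
  expect_error(cnn_spec(27, 1, c(8, 8)), ">= 2")
})

test_that("odd spatial extents pool with floor semantics", {
  spec <- cnn_spec(3, 2, c(9, 11), c(2, 3))
  expect_equal(spec$pooled_spatial, c(2L, 2L))
  m <- build_model(spec, seed = 2)
  x <- array(runif(9 * 11 * 3), c(9, 11, 3))
  expect_length(hsiband:::cnn_forward(m$params, x, spec)$logits, 2)
})

test_that("backprop matches finite differences on a tiny model", {
  spec <- cnn_spec(3, 4, c(8, 8), c(2, 3), fc_hidden = 5)
  m <- build_model(spec, seed = 1)
  set.seed(1)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3)); y <- 2L
  fwd <- hsiband:::cnn_forward(m$params, x, spec, keep_cache = TRUE)
  ce <- hsiband:::softmax_ce(fwd$logits, y)
  g <- hsiband:::cnn_backward(m$params, fwd, ce$dlogits, spec)
  loss_at <- function(p) hsiband:::softmax_ce(
    hsiband:::cnn_forward(p, x, spec)$logits, y)$loss
  eps <- 1e-6
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in idx) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("stratified split partitions the dataset deterministically", {
  ds <- simulate_dataset(tiny_sim(n_classes = 3, cubes_per_class = 10))
  tc <- train_config(seed = 5)
  sp <- split_dataset(ds, tc)
  idx <- sp$indices
  all_idx <- sort(c(idx$train, idx$val, idx$test))
  expect_identical(all_idx, seq_len(30L))           # complete + disjoint
  expect_equal(n_cubes(sp$test), 6)                 # 2 per class
  expect_equal(as.vector(table(ds$labels[idx$test])), rep(2, 3))

  sp2 <- split_dataset(ds, tc)
  expect_identical(sp$indices, sp2$indices)         # seed-deterministic
  tc2 <- train_config(seed = 6)
  expect_false(identical(split_dataset(ds, tc2)$indices, sp$indices))

  tiny <- labeled_dataset(ds$cubes[c(1, 11, 21)], c(1, 2, 3),
                          ds$class_names)
  expect_error(split_dataset(tiny, tc), "at least 2")
})

test_that("early stopping halts after `patience` non-improving epochs", {
  # validation loss strictly increasing from epoch 1, patience 15 -> 16
  expect_equal(hsiband:::stopping_epoch(seq(1, 2, length.out = 40), 15, 40),
               16)
  expect_equal(hsiband:::stopping_epoch(c(5, 4, 3, 2, 1), 3, 5), 5)
  expect_equal(hsiband:::stopping_epoch(c(3, 2, 2.5, 2.4, 2.3, 2.2), 4, 6),
               6)
  # real training run: flat/rising validation loss stops before max_epochs
  ds <- simulate_dataset(tiny_sim(n_classes = 2, cubes_per_class = 6,
                                  spatial = c(8, 8), peak_amplitude = 1))
  tc <- train_config(lr_init = 1e-2, max_epochs = 40, patience = 3,
                     seed = 3, val_fraction_of_train = 0.25)
  sp <- split_dataset(ds, tc)
  norm <- fit_normalizer(sp$train)
  fit <- train_model(build_model(cnn_spec(200, 2, c(8, 8), c(2, 2)),
                                 seed = 3),
                     prepare_cnn_data(sp$train, normalizer = norm),
                     prepare_cnn_data(sp$val, normalizer = norm), tc)
  expect_lte(fit$stopped_epoch, tc$max_epochs)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("training separates an easy two-class problem quickly", {
  ds <- simulate_dataset(tiny_sim(n_classes = 2, cubes_per_class = 8,
                                  spatial = c(8, 8), peak_amplitude = 2,
                                  noise = noise_model(0.001, 1, 0)))
  tc <- train_config(lr_init = 1e-3, max_epochs = 10, patience = 10,
                     seed = 4, val_fraction_of_train = 0.2)
  sp <- split_dataset(ds, tc)
  win <- select_for_dataset(sp$train, selection_config("std", 20))
  norm <- fit_normalizer(sp$train, win)
  fit <- train_model(
    build_model(cnn_spec(window_width(win), 2, c(8, 8), c(4, 8)), seed = 4),
    prepare_cnn_data(sp$train, win, norm),
    prepare_cnn_data(sp$val, win, norm), tc)
  expect_equal(max(fit$history$val_acc), 1)
  expect_lte(which.max(fit$history$val_acc == 1), 10)
  ev <- evaluate_model(fit, prepare_cnn_data(sp$test, win, norm))
  expect_equal(ev$accuracy, 1)
})

test_that("training is deterministic given the seed", {
  ds <- simulate_dataset(tiny_sim(n_classes = 2, cubes_per_class = 4,
                                  spatial = c(8, 8)))
  tc <- train_config(lr_init = 1e-3, max_epochs = 3, patience = 3,
                     seed = 8, val_fraction_of_train = 0.34)
  sp <- split_dataset(ds, tc)
  norm <- fit_normalizer(sp$train)
  dtr <- prepare_cnn_data(sp$train, normalizer = norm)
  dva <- prepare_cnn_data(sp$val, normalizer = norm)
  run <- function() train_model(build_model(
    cnn_spec(200, 2, c(8, 8), c(2, 2)), seed = 8), dtr, dva, tc)
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("evaluation reports accuracy and a conserved confusion matrix", {
  spec <- cnn_spec(4, 3, c(8, 8), c(2, 2), fc_hidden = 4)
  model <- build_model(spec, seed = 9)
  # force a constant prediction: zero everything but the last-layer bias
  model$params <- lapply(model$params, function(p) p * 0)
  model$params$bf2 <- c(1, 0, 0)
  set.seed(9)
  data <- list(x = replicate(9, array(runif(8 * 8 * 4), c(8, 8, 4)),
                             simplify = FALSE),
               y = rep(1:3, each = 3))
  ev <- evaluate_model(model, data)
  expect_equal(ev$accuracy, 1 / 3)            # chance on a balanced set
  expect_equal(rowSums(ev$confusion), rep(3, 3), ignore_attr = TRUE)
  expect_equal(sum(ev$confusion), 9)
  expect_true(all(ev$confusion[, 2:3] == 0))  # constant class-1 predictor
  expect_error(evaluate_model(model, list(x = list(), y = integer(0))),
               "empty")
})

test_that("spectral width only changes first-layer arithmetic", {
  sfull <- cnn_spec(1004, 11, c(64, 64))
  scut <- cnn_spec(27, 11, c(64, 64))
  expect_equal(sfull$pooled_spatial, scut$pooled_spatial)
  expect_equal(sfull$flatten, scut$flatten)
  mfull <- build_model(sfull, seed = 1)
  mcut <- build_model(scut, seed = 1)
  expect_equal(dim(mfull$params$W2), dim(mcut$params$W2))
  expect_equal(dim(mfull$params$Wf1), dim(mcut$params$Wf1))
  expect_equal(count_params(mfull) - count_params(mcut),
               9 * (1004 - 27) * 16)
})
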