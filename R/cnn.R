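#' Compact CNN specification
#'
#' The whole-cube classifier: two 3x3 same-padded convolutions (spectral
#' channels are the input feature channels), each followed by ReLU and
#' 2x2/stride-2 max pooling, then a 512-unit fully connected layer with
#' ReLU and a final linear layer with one output per class. After the two
#' pool stages the spatial extent is `floor(floor(y/2)/2)` x
#' `floor(floor(x/2)/2)`, so the flattened feature length is that area
#' times the second conv's filter count.
#'
#' @param in_channels Spectral channel count of the (possibly sliced)
#'   input cubes.
#' @param n_classes Number of output classes (>= 2).
#' @param input_spatial Length-2 integer `(y, x)`; both >= 4 so two pool
#'   stages are possible.
#' @param conv_filters Filter counts of the two conv layers.
#' @param fc_hidden Width of the hidden fully connected layer.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(in_channels, n_classes, input_spatial = c(64L, 64L),
                     conv_filters = c(16L, 32L), fc_hidden = 512L) {
  if (!is_count(in_channels) || in_channels < 1L)
    stop_domain("`in_channels` must be a positive integer")
  if (!is_count(n_classes) || n_classes < 2L)
    stop_domain("`n_classes` must be >= 2")
  input_spatial <- as.integer(input_spatial)
  if (length(input_spatial) != 2L || any(input_spatial < 4L))
    stop_domain("`input_spatial` must be (y, x) with both >= 4 ",
                "(two pool stages)")
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) != 2L || any(conv_filters < 1L))
    stop_domain("`conv_filters` must be two positive integers")
  p1 <- input_spatial %/% 2L
  p2 <- p1 %/% 2L
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 input_spatial = input_spatial,
                 conv_filters = conv_filters,
                 fc_hidden = as.integer(fc_hidden),
                 pooled_spatial = p2,
                 flatten = p2[1] * p2[2] * conv_filters[2]),
            class = "cnn_spec")
}

#' Build an initialized model from a spec
#'
#' Weights use He (fan-in) Gaussian initialization; biases start at zero.
#' Convolution weights are stored as `(9 * in_channels) x filters`
#' matrices matching the im2col patch layout.
#'
#' @param spec A [cnn_spec()].
#' @param seed Optional seed making the initialization deterministic.
#' @return An object of class `cnn_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  params <- with_seed(seed, list(
    W1 = he(9L * spec$in_channels, spec$conv_filters[1]),
    b1 = numeric(spec$conv_filters[1]),
    W2 = he(9L * spec$conv_filters[1], spec$conv_filters[2]),
    b2 = numeric(spec$conv_filters[2]),
    Wf1 = he(spec$flatten, spec$fc_hidden),
    bf1 = numeric(spec$fc_hidden),
    Wf2 = he(spec$fc_hidden, spec$n_classes),
    bf2 = numeric(spec$n_classes)
  ))
  structure(list(spec = spec, params = params), class = "cnn_model")
}

#' Trainable parameter count of a model
#' @param model A [cnn_model][build_model()].
#' @return Integer total over all weight and bias tensors.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- layer primitives ------------------------------------------------------

# 3x3 same-padding patch matrix: (H*W) x (9*C); offset-major, channel-minor
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    block <- xp[(1L + dy):(H + dy), (1L + dx):(W + dx), , drop = FALSE]
    cols[, k * C + seq_len(C)] <- matrix(block, H * W, C)
    k <- k + 1L
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    dxp[(1L + dy):(H + dy), (1L + dx):(W + dx), ] <-
      dxp[(1L + dy):(H + dy), (1L + dx):(W + dx), , drop = FALSE] +
      array(dcols[, k * C + seq_len(C)], c(H, W, C))
    k <- k + 1L
  }
  dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

maxpool_fwd <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  or_ <- seq.int(1L, 2L * H2, 2L); er <- or_ + 1L
  oc <- seq.int(1L, 2L * W2, 2L); ec <- oc + 1L
  s11 <- x[or_, oc, , drop = FALSE]; s12 <- x[or_, ec, , drop = FALSE]
  s21 <- x[er, oc, , drop = FALSE]; s22 <- x[er, ec, , drop = FALSE]
  out <- pmax(s11, s12, s21, s22)
  m11 <- s11 == out
  m12 <- (s12 == out) & !m11
  m21 <- (s21 == out) & !(m11 | m12)
  m22 <- !(m11 | m12 | m21)
  list(out = out, in_dim = d,
       idx = list(or_ = or_, er = er, oc = oc, ec = ec),
       masks = list(m11, m12, m21, m22))
}

maxpool_bwd <- function(dout, pool) {
  dX <- array(0, pool$in_dim)
  i <- pool$idx; m <- pool$masks
  dX[i$or_, i$oc, ] <- dout * m[[1]]
  dX[i$or_, i$ec, ] <- dout * m[[2]]
  dX[i$er, i$oc, ] <- dout * m[[3]]
  dX[i$er, i$ec, ] <- dout * m[[4]]
  dX
}

cnn_forward <- function(params, x, spec, keep_cache = FALSE) {
  d <- dim(x)
  M1 <- im2col3(x)
  Z1 <- M1 %*% params$W1 + rep(params$b1, each = nrow(M1))
  A1 <- array(pmax(Z1, 0), c(d[1], d[2], spec$conv_filters[1]))
  P1 <- maxpool_fwd(A1)
  pd <- dim(P1$out)
  M2 <- im2col3(P1$out)
  Z2 <- M2 %*% params$W2 + rep(params$b2, each = nrow(M2))
  A2 <- array(pmax(Z2, 0), c(pd[1], pd[2], spec$conv_filters[2]))
  P2 <- maxpool_fwd(A2)
  f <- as.vector(P2$out)
  h_pre <- drop(crossprod(params$Wf1, f)) + params$bf1
  h <- pmax(h_pre, 0)
  logits <- drop(crossprod(params$Wf2, h)) + params$bf2
  out <- list(logits = logits)
  if (keep_cache)
    out <- c(out, list(M1 = M1, Z1 = Z1, P1 = P1, pd = pd, M2 = M2,
                       Z2 = Z2, P2 = P2, f = f, h_pre = h_pre, h = h,
                       in_dim = d))
  out
}

cnn_backward <- function(params, cache, dlogits, spec) {
  dWf2 <- cache$h %o% dlogits
  dbf2 <- dlogits
  dh <- drop(params$Wf2 %*% dlogits) * (cache$h_pre > 0)
  dWf1 <- cache$f %o% dh
  dbf1 <- dh
  df <- drop(params$Wf1 %*% dh)
  dP2 <- array(df, dim(cache$P2$out))
  dA2 <- maxpool_bwd(dP2, cache$P2)
  dZ2 <- matrix(dA2, prod(cache$pd[1:2]), spec$conv_filters[2]) *
    (cache$Z2 > 0)
  dW2 <- crossprod(cache$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- tcrossprod(dZ2, params$W2)
  dP1out <- col2im3(dM2, cache$pd[1], cache$pd[2], spec$conv_filters[1])
  dA1 <- maxpool_bwd(dP1out, cache$P1)
  dZ1 <- matrix(dA1, prod(cache$in_dim[1:2]), spec$conv_filters[1]) *
    (cache$Z1 > 0)
  dW1 <- crossprod(cache$M1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

# numerically stable softmax cross-entropy for one sample
softmax_ce <- function(logits, y) {
  z <- logits - max(logits)
  lse <- log(sum(exp(z)))
  p <- exp(z - lse)
  d <- p
  d[y] <- d[y] - 1
  list(loss = lse - z[y], dlogits = d, probs = p)
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the study protocol at full scale: Adam from a 1e-4
#' learning rate with multiplicative per-epoch decay, cross-entropy loss,
#' batch size 2, and early stopping once the validation loss has failed
#' to improve for 15 consecutive epochs. The validation set is carved
#' from the training portion (never the test set) at
#' `val_fraction_of_train`.
#'
#' @param lr_init Initial Adam learning rate.
#' @param lr_decay Multiplicative learning-rate factor applied each epoch.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param max_epochs Hard epoch cap.
#' @param train_fraction Fraction of each class assigned to
#'   training(+validation); the rest is the test set.
#' @param val_fraction_of_train Fraction of the training portion held out
#'   for validation.
#' @param seed Seed controlling the split, weight init and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_init = 1e-4, lr_decay = 0.95, batch_size = 2L,
                         patience = 15L, max_epochs = 100L,
                         train_fraction = 0.8,
                         val_fraction_of_train = 0.1, seed = 1L) {
  if (!is.numeric(lr_init) || lr_init <= 0)
    stop_domain("`lr_init` must be positive")
  if (!is.numeric(lr_decay) || lr_decay <= 0 || lr_decay > 1)
    stop_domain("`lr_decay` must be in (0, 1]")
  if (!is_count(patience) || patience < 1L)
    stop_domain("`patience` must be >= 1")
  if (!is_count(max_epochs) || max_epochs < 1L)
    stop_domain("`max_epochs` must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_domain("`train_fraction` must be in (0, 1)")
  if (val_fraction_of_train < 0 || val_fraction_of_train >= 1)
    stop_domain("`val_fraction_of_train` must be in [0, 1)")
  structure(list(lr_init = lr_init, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train / validation / test split
#'
#' Splits each class independently: `train_fraction` of its cubes go to
#' the training portion (rounded to the nearest cube, at least one cube
#' on each side), then `val_fraction_of_train` of that portion is held
#' out for validation. With 11 classes of 100 cubes and the default 0.8
#' fraction this yields 880 training(+validation) and 220 test cubes.
#' Deterministic given `config$seed`.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [train_config()].
#' @return List with `train`, `val`, `test` ([labeled_dataset()] each;
#'   `val` is `NULL` when the fraction rounds to zero cubes) and
#'   `indices` (the integer indices of each portion).
#' @export
split_dataset <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "train_config"))
  idx_tr <- integer(0); idx_val <- integer(0); idx_te <- integer(0)
  with_seed(config$seed, {
    for (k in sort(unique(dataset$labels))) {
      idx <- which(dataset$labels == k)
      n <- length(idx)
      if (n < 2L)
        stop_domain("class '", dataset$class_names[k],
                    "' has ", n, " cube(s); stratified splitting needs ",
                    "at least 2")
      perm <- idx[sample.int(n)]
      n_tr <- min(n - 1L, max(1L, as.integer(floor(
        config$train_fraction * n + 0.5))))
      tr_all <- perm[seq_len(n_tr)]
      idx_te <- c(idx_te, perm[(n_tr + 1L):n])
      n_val <- min(n_tr - 1L, as.integer(floor(
        config$val_fraction_of_train * n_tr + 0.5)))
      n_val <- max(0L, n_val)
      if (n_val > 0L) {
        idx_val <- c(idx_val, tr_all[seq_len(n_val)])
        idx_tr <- c(idx_tr, tr_all[(n_val + 1L):n_tr])
      } else {
        idx_tr <- c(idx_tr, tr_all)
      }
    }
  })
  list(train = dataset_subset(dataset, idx_tr),
       val = if (length(idx_val)) dataset_subset(dataset, idx_val) else NULL,
       test = dataset_subset(dataset, idx_te),
       indices = list(train = idx_tr, val = idx_val, test = idx_te))
}

#' Turn a dataset into normalized CNN inputs
#'
#' Optionally slices every cube to a spectral window, then applies global
#' min-max normalization to `[0, 1]`. The normalizer must be fitted on
#' the training portion only (see [fit_normalizer()]) so the test set
#' never leaks into preprocessing.
#'
#' @param dataset A [labeled_dataset()].
#' @param window Optional [spectral_window()] applied to every cube.
#' @param normalizer Optional list `(min, max)` from [fit_normalizer()];
#'   omitted means raw intensities.
#' @return List with `x` (list of `y x x x channels` arrays) and `y`
#'   (integer labels).
#' @export
prepare_cnn_data <- function(dataset, window = NULL, normalizer = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  cubes <- dataset$cubes
  if (!is.null(window))
    cubes <- lapply(cubes, slice_bands, window = window)
  xs <- lapply(cubes, function(cb) {
    v <- cb$values
    if (!is.null(normalizer)) {
      rng <- normalizer$max - normalizer$min
      v <- if (rng > 0) (v - normalizer$min) / rng else v * 0
    }
    v
  })
  list(x = xs, y = dataset$labels)
}

#' Fit a global min-max normalizer on (sliced) training cubes
#'
#' @inheritParams prepare_cnn_data
#' @return List with `min` and `max` over all training voxels.
#' @export
fit_normalizer <- function(dataset, window = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  cubes <- dataset$cubes
  if (!is.null(window))
    cubes <- lapply(cubes, slice_bands, window = window)
  rngs <- vapply(cubes, function(cb) range(cb$values), numeric(2))
  list(min = min(rngs[1, ]), max = max(rngs[2, ]))
}

# mean loss (and accuracy) over a prepared set, forward only
eval_loss <- function(params, data, spec) {
  n <- length(data$x)
  losses <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    logits <- cnn_forward(params, data$x[[i]], spec)$logits
    losses[i] <- softmax_ce(logits, data$y[i])$loss
    pred[i] <- which.max(logits)
  }
  list(loss = mean(losses), acc = mean(pred == data$y), pred = pred)
}

# early-stopping bookkeeping: epoch training halts at, given the
# validation-loss sequence and patience (pure, for testability)
stopping_epoch <- function(val_losses, patience, max_epochs) {
  best <- Inf; streak <- 0L
  for (ep in seq_along(val_losses)) {
    if (val_losses[ep] < best) { best <- val_losses[ep]; streak <- 0L }
    else streak <- streak + 1L
    if (streak >= patience) return(ep)
  }
  min(length(val_losses), max_epochs)
}

#' Train a model with Adam, learning-rate decay and early stopping
#'
#' Minimizes cross-entropy with Adam starting at `lr_init` and decaying
#' multiplicatively each epoch. Training halts once the validation loss
#' has failed to improve for `patience` consecutive epochs, or at
#' `max_epochs`; the returned fit carries the parameters of the
#' best-validation epoch as well as the final ones. Fully deterministic
#' given `config$seed` (batch order is drawn from a locally seeded
#' stream).
#'
#' @param model A [cnn_model][build_model()].
#' @param train,val Prepared data from [prepare_cnn_data()]; `val` drives
#'   early stopping and must be non-empty.
#' @param config A [train_config()].
#' @param monitor Optional prepared set (typically the test set) whose
#'   accuracy is recorded each epoch for learning curves; it never
#'   influences training.
#' @return An object of class `cnn_fit`: the model (best-epoch
#'   parameters), `final_params`, a per-epoch `history` data frame
#'   (losses, accuracies, learning rate, epoch wall-time), `best_epoch`
#'   and `stopped_epoch`.
#' @export
train_model <- function(model, train, val, config, monitor = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (length(train$x) == 0L || length(val$x) == 0L)
    stop_domain("training and validation sets must be non-empty")
  spec <- model$spec
  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n_tr <- length(train$x)
  best <- list(val = Inf, epoch = 0L, params = params)
  streak <- 0L
  hist <- vector("list", config$max_epochs)
  stopped <- config$max_epochs
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- config$lr_init * config$lr_decay^(epoch - 1L)
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      batch_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        grads <- NULL
        loss_b <- 0
        for (i in b) {
          fwd <- cnn_forward(params, train$x[[i]], spec, keep_cache = TRUE)
          ce <- softmax_ce(fwd$logits, train$y[i])
          if (!is.finite(ce$loss))
            stop_domain("training diverged (non-finite loss) at epoch ",
                        epoch)
          loss_b <- loss_b + ce$loss / length(b)
          g <- cnn_backward(params, fwd, ce$dlogits / length(b), spec)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g)
        }
        batch_losses[bi] <- loss_b
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (nm in names(params)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] +
            (1 - beta2) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] - lr * (adam_m[[nm]] / corr1) /
            (sqrt(adam_v[[nm]] / corr2) + eps)
        }
      }
      vl <- eval_loss(params, val, spec)
      mon <- if (!is.null(monitor)) eval_loss(params, monitor, spec)
             else list(acc = NA_real_)
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(batch_losses),
        val_loss = vl$loss, val_acc = vl$acc, test_acc = mon$acc,
        epoch_s = proc.time()[["elapsed"]] - t0)
      if (vl$loss < best$val) {
        best <- list(val = vl$loss, epoch = epoch, params = params)
        streak <- 0L
      } else {
        streak <- streak + 1L
      }
      if (streak >= config$patience) { stopped <- epoch; break }
      stopped <- epoch
    }
  })
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(list(model = structure(list(spec = spec, params = best$params),
                                   class = "cnn_model"),
                 final_params = params,
                 history = history,
                 best_epoch = best$epoch,
                 stopped_epoch = stopped),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf(paste0("<cnn_fit> %d epochs (best %d), final val loss ",
                     "%.4f\n"),
              x$stopped_epoch, x$best_epoch,
              x$history$val_loss[nrow(x$history)]))
  invisible(x)
}

#' Predict class labels for prepared inputs
#'
#' @param object A [cnn_model][build_model()] or [cnn_fit][train_model()]
#'   (best-epoch parameters are used).
#' @param x List of input arrays (as in [prepare_cnn_data()]'s `x`).
#' @param ... Unused.
#' @return Integer vector of predicted class indices.
#' @export
predict.cnn_model <- function(object, x, ...) {
  vapply(x, function(xi)
    which.max(cnn_forward(object$params, xi, object$spec)$logits),
    integer(1))
}

#' @export
predict.cnn_fit <- function(object, x, ...) predict(object$model, x, ...)

#' Evaluate a model on a prepared set
#'
#' @param model A [cnn_model][build_model()] or [cnn_fit][train_model()].
#' @param data Prepared data from [prepare_cnn_data()].
#' @return List with `accuracy` (correct / total), `confusion` (rows:
#'   true class, columns: predicted) and `predictions`.
#' @export
evaluate_model <- function(model, data) {
  if (inherits(model, "cnn_fit")) model <- model$model
  stopifnot(inherits(model, "cnn_model"))
  if (length(data$x) == 0L) stop_domain("test set is empty")
  pred <- predict(model, data$x)
  K <- model$spec$n_classes
  confusion <- matrix(0L, K, K,
                      dimnames = list(true = NULL, predicted = NULL))
  for (i in seq_along(pred))
    confusion[data$y[i], pred[i]] <- confusion[data$y[i], pred[i]] + 1L
  list(accuracy = mean(pred == data$y), confusion = confusion,
       predictions = pred)
}
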