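#' Compare band-selection methods over repeated seeded runs
#'
#' For every method and every run: split the dataset (stratified, seeded),
#' select the spectral window *on the non-test portion only*, slice all
#' cubes to it, fit the min-max normalizer on the non-test portion, train
#' the CNN, and evaluate on the held-out test set. Run `r` uses seed
#' `config$seed + r - 1` for the split, the weight initialization and the
#' batch order, so all methods see identical splits and initial weights
#' within a run. Reported accuracy is the test accuracy at the
#' best-validation epoch (`accuracy`); the final-epoch test accuracy is
#' kept alongside (`accuracy_final`). Epoch wall-times are informational
#' only — they depend on the host.
#'
#' @param dataset A [labeled_dataset()].
#' @param methods List of [selection_config()] objects (or a character
#'   vector of method names, expanded with defaults).
#' @param n_runs Number of independent seeded runs per method (>= 2).
#' @param config A [train_config()].
#' @param conv_filters Filter counts passed to [cnn_spec()].
#' @param verbose Print one line per completed run.
#' @return An object of class `comparison_result`: `table` (per-method
#'   mean/sd accuracy and epoch time over exactly `n_runs` runs), `runs`
#'   (one row per method x run) and `curves` (per-epoch history rows).
#' @export
run_comparison <- function(dataset, methods, n_runs = 10L,
                           config = train_config(),
                           conv_filters = c(16L, 32L), verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "train_config"))
  if (!is_count(n_runs) || n_runs < 2L)
    stop_domain("`n_runs` must be >= 2")
  if (is.character(methods))
    methods <- lapply(methods, function(m) selection_config(m))
  stopifnot(all(vapply(methods, inherits, logical(1), "selection_config")))
  method_names <- vapply(methods, `[[`, character(1), "method")
  axis <- dataset$cubes[[1]]$axis
  sp <- dim(dataset$cubes[[1]]$values)[1:2]
  K <- length(dataset$class_names)

  run_rows <- list()
  curve_rows <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- config$seed + r - 1L
    cfg_r <- config
    cfg_r$seed <- seed_r
    sp_split <- split_dataset(dataset, cfg_r)
    trainval_idx <- c(sp_split$indices$train, sp_split$indices$val)
    trainval <- dataset_subset(dataset, trainval_idx)
    for (mi in seq_along(methods)) {
      sel <- methods[[mi]]
      if (sel$method == "random") sel$seed <- seed_r
      window <- select_for_dataset(trainval, sel)
      norm <- fit_normalizer(trainval, window)
      d_tr <- prepare_cnn_data(sp_split$train, window, norm)
      d_val <- prepare_cnn_data(sp_split$val, window, norm)
      d_te <- prepare_cnn_data(sp_split$test, window, norm)
      spec <- cnn_spec(window_width(window), K, sp, conv_filters)
      model <- build_model(spec, seed = seed_r)
      fit <- train_model(model, d_tr, d_val, cfg_r, monitor = d_te)
      acc_best <- evaluate_model(fit, d_te)$accuracy
      acc_final <- evaluate_model(
        structure(list(spec = spec, params = fit$final_params),
                  class = "cnn_model"), d_te)$accuracy
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        method = method_names[mi], run = r, seed = seed_r,
        s = window$s, e = window$e,
        accuracy = acc_best, accuracy_final = acc_final,
        best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch,
        mean_epoch_s = mean(fit$history$epoch_s))
      h <- fit$history
      h$method <- method_names[mi]
      h$run <- r
      curve_rows[[length(curve_rows) + 1L]] <- h
      if (verbose)
        message(sprintf("run %d/%d %-8s window [%d,%d) acc %.3f",
                        r, n_runs, method_names[mi], window$s, window$e,
                        acc_best))
    }
  }
  runs <- do.call(rbind, run_rows)
  tab <- do.call(rbind, lapply(unique(method_names), function(m) {
    sub <- runs[runs$method == m, ]
    data.frame(method = m,
               mean_acc = mean(sub$accuracy),
               sd_acc = stats::sd(sub$accuracy),
               mean_epoch_s = mean(sub$mean_epoch_s),
               sd_epoch_s = stats::sd(sub$mean_epoch_s),
               n_runs = nrow(sub))
  }))
  structure(list(table = tab, runs = runs,
                 curves = do.call(rbind, curve_rows)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
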