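#' Contiguous spectral window
#'
#' A half-open 0-based channel interval `[s, e)` of width `e - s`,
#' carrying the cumulative criterion score of its member channels and the
#' tag of the criterion that selected it.
#'
#' @param s Start channel (inclusive, 0-based).
#' @param e End channel (exclusive).
#' @param score Cumulative window score.
#' @param method Criterion tag (`"std"`, `"mi"`, `"entropy"`, `"random"`,
#'   or a free-form tag).
#' @return An object of class `spectral_window`.
#' @export
spectral_window <- function(s, e, score = NA_real_, method = "std") {
  if (!is_count(s) || !is_count(e) || s < 0 || e <= s)
    stop_domain("need 0 <= s < e; got [", s, ", ", e, ")")
  structure(list(s = as.integer(s), e = as.integer(e),
                 score = as.numeric(score), method = as.character(method)),
            class = "spectral_window")
}

#' @export
print.spectral_window <- function(x, ...) {
  cat(sprintf("<spectral_window> [%d, %d) width %d, method=%s, score=%.6g\n",
              x$s, x$e, x$e - x$s, x$method, x$score))
  invisible(x)
}

#' Width of a window in channels
#' @param window A [spectral_window()].
#' @export
window_width <- function(window) window$e - window$s

#' Do two windows share at least one channel?
#' @param a,b [spectral_window()] objects.
#' @return Logical.
#' @export
windows_overlap <- function(a, b) a$s < b$e && b$s < a$e

#' Cumulative score of every sliding-window position
#'
#' Slides a width-`w` window along the channel axis with stride 1; the
#' k-th value (k = 1 .. n - w + 1) is the sum of the per-channel scores
#' over channels `[k-1, k-1+w)`.
#'
#' @param scores A [band_scores()] or plain numeric vector.
#' @param w Window width in channels, `1 <= w <= n`.
#' @return Numeric vector of length `n - w + 1`.
#' @examples
#' cumulative_window_scores(c(1, 2, 3, 4, 5), 2)  # 3 5 7 9
#' @export
cumulative_window_scores <- function(scores, w) {
  v <- score_vector(scores)
  n <- length(v)
  if (!is_count(w) || w < 1L || w > n)
    stop_domain("window width ", w, " out of range [1, ", n, "]")
  cs <- cumsum(c(0, v))
  cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
}

#' Select the maximal-score window
#'
#' Returns the width-`w` window maximizing the cumulative score; ties
#' resolve to the smallest start channel.
#'
#' @inheritParams cumulative_window_scores
#' @return A [spectral_window()] whose `score` is the winning cumulative
#'   sum.
#' @examples
#' select_window(c(1, 2, 3, 4, 5), 2)  # window [3, 5), score 9
#' @export
select_window <- function(scores, w) {
  ws <- cumulative_window_scores(scores, w)
  k <- which.max(ws)
  method <- if (inherits(scores, "band_scores")) scores$method else "std"
  spectral_window(k - 1L, k - 1L + as.integer(w), score = ws[k],
                  method = method)
}

#' Draw a window start uniformly at random
#'
#' The chance baseline: the start channel is uniform over the
#' `n_channels - w + 1` admissible positions. When a score vector is
#' supplied the drawn window's cumulative score is filled in (for
#' reporting); otherwise it is 0.
#'
#' @param n_channels Total channel count.
#' @param w Window width in channels.
#' @param seed Optional integer; the draw is deterministic given the seed
#'   and leaves the caller's RNG stream untouched.
#' @param scores Optional [band_scores()] / numeric vector used only to
#'   fill the window's `score` field.
#' @return A [spectral_window()] with `method = "random"`.
#' @export
random_window <- function(n_channels, w, seed = NULL, scores = NULL) {
  if (!is_count(n_channels) || n_channels < 1L)
    stop_domain("`n_channels` must be a positive integer")
  if (!is_count(w) || w < 1L || w > n_channels)
    stop_domain("window width ", w, " out of range [1, ", n_channels, "]")
  s <- with_seed(seed, sample.int(n_channels - w + 1L, 1L)) - 1L
  sc <- if (is.null(scores)) 0 else sum(score_vector(scores)[(s + 1L):(s + w)])
  spectral_window(s, s + as.integer(w), score = sc, method = "random")
}

#' Band-selection configuration
#'
#' @param method One of `"std"`, `"mi"`, `"entropy"`, `"random"`.
#' @param window_nm Window width in nanometres. Widths below 20 nm are
#'   accepted but risk locking onto instrument noise near the spectral
#'   edges rather than sample features; [run_experiment()] and the CLI
#'   warn about them.
#' @param n_bins Histogram bins for the MI and entropy criteria (>= 2).
#' @param aggregation How per-cube score vectors are combined across a
#'   dataset; only `"per_cube_mean"` (unweighted mean) is defined.
#' @param seed Seed for the random method.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(method = c("std", "mi", "entropy", "random"),
                             window_nm = 20, n_bins = 64L,
                             aggregation = "per_cube_mean", seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(window_nm) || length(window_nm) != 1L || window_nm <= 0)
    stop_domain("`window_nm` must be a single positive number")
  if (!is_count(n_bins) || n_bins < 2L)
    stop_domain("`n_bins` must be an integer >= 2")
  aggregation <- match.arg(aggregation, "per_cube_mean")
  structure(list(method = method, window_nm = as.numeric(window_nm),
                 n_bins = as.integer(n_bins), aggregation = aggregation,
                 seed = seed),
            class = "selection_config")
}

# per-cube score vector for one criterion
cube_scores <- function(cube, method, n_bins) {
  switch(method,
         std = band_std_scores(cube),
         mi = mi_scores(cube, n_bins),
         entropy = entropy_scores(cube, n_bins),
         stop_domain("no scorer for method '", method, "'"))
}

#' Select one global window for a whole dataset
#'
#' Scores every cube with the configured criterion, averages the score
#' vectors across cubes (unweighted mean), and picks the maximal
#' cumulative window — one shared window that is then applied to every
#' cube downstream. The `random` method skips scoring and draws the start
#' uniformly (deterministic under `config$seed`).
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [selection_config()].
#' @return A [spectral_window()].
#' @export
select_for_dataset <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "selection_config"))
  axis <- dataset$cubes[[1]]$axis
  w <- nm_width_to_channels(config$window_nm, axis$step_nm)
  if (w > axis$n_channels)
    stop_domain("window of ", config$window_nm, " nm (", w,
                " channels) exceeds the ", axis$n_channels,
                "-channel axis")
  if (config$method == "random")
    return(random_window(axis$n_channels, w, seed = config$seed))
  mat <- vapply(dataset$cubes,
                function(cb) cube_scores(cb, config$method,
                                         config$n_bins)$scores,
                numeric(axis$n_channels))
  mean_scores <- band_scores(rowMeans(as.matrix(mat)), config$method)
  select_window(mean_scores, w)
}

#' One-row selection report
#'
#' Tabulates a selected window the way the comparison tables print it:
#' channel interval, wavelength interval, cumulative score, and the
#' spectral data-size reduction it achieves.
#'
#' @param window A [spectral_window()].
#' @param axis The [wavelength_axis()] the window indexes.
#' @param window_nm The requested width in nanometres (for the record).
#' @return A one-row `data.frame`.
#' @export
selection_report <- function(window, axis, window_nm = NA_real_) {
  stopifnot(inherits(window, "spectral_window"),
            inherits(axis, "wavelength_axis"))
  w <- window_width(window)
  data.frame(
    method = window$method,
    window_nm = window_nm,
    w_channels = w,
    s = window$s,
    e = window$e,
    start_nm = axis$start_nm + window$s * axis$step_nm,
    end_nm = axis$start_nm + window$e * axis$step_nm,
    score = window$score,
    reduction_percent = 100 * reduction_fraction(w, axis$n_channels),
    stringsAsFactors = FALSE
  )
}
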