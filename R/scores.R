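#' Per-channel score vector
#'
#' The common container for the three ranking criteria: one non-negative,
#' finite score per spectral channel, tagged with the method that produced
#' it (`"std"`, `"mi"` or `"entropy"`).
#'
#' @param scores Numeric vector, one value per channel.
#' @param method Criterion tag.
#' @return An object of class `band_scores`.
#' @export
band_scores <- function(scores, method = c("std", "mi", "entropy")) {
  method <- match.arg(method)
  scores <- as.numeric(scores)
  if (length(scores) < 1L)
    stop_domain("`scores` must be non-empty")
  if (anyNA(scores) || any(!is.finite(scores)))
    stop_domain("band scores must be finite")
  if (any(scores < -1e-12))
    stop_domain("band scores must be non-negative")
  structure(list(scores = pmax(scores, 0), method = method,
                 n_channels = length(scores)),
            class = "band_scores")
}

#' @export
print.band_scores <- function(x, ...) {
  cat(sprintf("<band_scores> method=%s, %d channels, max=%.4g at channel %d\n",
              x$method, x$n_channels, max(x$scores),
              which.max(x$scores) - 1L))
  invisible(x)
}

score_vector <- function(scores) {
  if (inherits(scores, "band_scores")) scores$scores else as.numeric(scores)
}

#' Spatial standard deviation of every spectral band
#'
#' For each channel the population standard deviation of the band's pixel
#' intensities is computed:
#' \deqn{\sigma_\lambda = \sqrt{\frac{1}{yx}\sum_{i,j}
#'   (X_{ij\lambda}-\mu_\lambda)^2}}
#' with \eqn{\mu_\lambda} the spatial mean of the band. The divisor is the
#' pixel count `y*x`, not `y*x - 1`: the statistic describes the observed
#' spatial dispersion of the band, not an estimate from a sample.
#'
#' @param cube A [hypercube()].
#' @return [band_scores()] with `method = "std"`.
#' @export
band_std_scores <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  M <- as_pixel_matrix(cube)
  mu <- colMeans(M)
  dev <- M - rep(mu, each = nrow(M))
  band_scores(sqrt(colMeans(dev * dev)), "std")
}

# equal-width bin indices over x's own [min, max]; a constant variable
# occupies one bin
bin_indices <- function(x, n_bins) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

# MI in bits from a joint count matrix (rows: variable 1, cols: variable 2)
mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p)
  pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

#' Mutual information of every band with the mean spectrum image
#'
#' The cube is viewed as a pixels-by-channels matrix; the reference
#' variable is the per-pixel mean intensity across all channels. Each band
#' and the reference are independently discretized into `n_bins`
#' equal-width bins over their own ranges, and the mutual information
#' \deqn{I(\lambda;\mu) = \sum_{v,u} p(v,u)\log_2\frac{p(v,u)}{p(v)p(u)}}
#' is estimated from the joint pixel counts, in bits. A spatially constant
#' band (or a constant reference) carries no information and scores 0.
#'
#' @param cube A [hypercube()] with at least 2 pixels.
#' @param n_bins Number of histogram bins per variable (>= 2).
#' @return [band_scores()] with `method = "mi"`.
#' @export
mi_scores <- function(cube, n_bins = 64L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!is_count(n_bins) || n_bins < 2L)
    stop_domain("`n_bins` must be an integer >= 2")
  M <- as_pixel_matrix(cube)
  if (nrow(M) < 2L)
    stop_domain("mutual information needs at least 2 pixels")
  mu <- rowMeans(M)
  u <- bin_indices(mu, n_bins)
  scores <- vapply(seq_len(ncol(M)), function(l) {
    v <- bin_indices(M[, l], n_bins)
    counts <- matrix(tabulate((u - 1L) * n_bins + v, n_bins * n_bins),
                     n_bins, n_bins)
    mi_from_counts(counts)
  }, numeric(1))
  band_scores(pmax(scores, 0), "mi")
}

#' Shannon entropy of every band's intensity histogram
#'
#' Per channel, the pixel intensities are binned into `n_bins` equal-width
#' bins over the band's own range and the entropy
#' \deqn{H(\lambda) = -\sum_b p_b \log_2 p_b} of the occupancy
#' distribution is returned in bits. Empty bins contribute nothing; a
#' constant band has a single occupied bin and entropy 0.
#'
#' @inheritParams mi_scores
#' @return [band_scores()] with `method = "entropy"`.
#' @export
entropy_scores <- function(cube, n_bins = 64L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!is_count(n_bins) || n_bins < 2L)
    stop_domain("`n_bins` must be an integer >= 2")
  M <- as_pixel_matrix(cube)
  n <- nrow(M)
  scores <- vapply(seq_len(ncol(M)), function(l) {
    p <- tabulate(bin_indices(M[, l], n_bins), n_bins) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  band_scores(scores, "entropy")
}
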