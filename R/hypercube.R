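#' Hyperspectral hypercube
#'
#' A hypercube is a 3-D array of non-negative intensities indexed
#' `(y row, x column, spectral channel)` together with a
#' [wavelength_axis()] describing the spectral grid, an optional class
#' label, and free-form metadata. Values must be finite; cubes containing
#' NaN or Inf are rejected rather than repaired, because the intended data
#' regime is raw (un-denoised) microscope output.
#'
#' @param values 3-D numeric array, non-negative and finite. The third
#'   extent must equal `axis$n_channels`.
#' @param axis A [wavelength_axis()].
#' @param label Optional class label (single character or integer).
#' @param meta Named list of free-form annotations.
#' @return An object of class `hypercube`.
#' @examples
#' ax <- wavelength_axis(325, 0.728, 10)
#' cube <- hypercube(array(runif(4 * 4 * 10), c(4, 4, 10)), ax)
#' dim(cube$values)
#' @export
hypercube <- function(values, axis, label = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_domain("`values` must be a 3-D array (y, x, channel)")
  if (!inherits(axis, "wavelength_axis"))
    stop_domain("`axis` must be a wavelength_axis")
  d <- dim(values)
  if (d[1] < 1L || d[2] < 1L)
    stop_domain("spatial extents must be at least 1x1, got ",
                d[1], "x", d[2])
  if (d[3] != axis$n_channels)
    stop_domain("cube has ", d[3], " spectral channels but the axis ",
                "declares ", axis$n_channels)
  if (anyNA(values) || any(!is.finite(values)))
    stop_domain("cube values must be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop_domain("cube values must be non-negative")
  if (!is.null(label) && length(label) != 1L)
    stop_domain("`label` must be a single value or NULL")
  storage.mode(values) <- "double"
  structure(list(values = values, axis = axis, label = label,
                 meta = as.list(meta)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %dx%d spatial, %d channels (%.6g-%.6g nm)%s\n",
              d[1], d[2], d[3], x$axis$start_nm,
              x$axis$start_nm + (d[3] - 1L) * x$axis$step_nm,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

n_channels <- function(cube) cube$axis$n_channels

# pixels-by-channels view used by all per-band statistics
as_pixel_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, d[1] * d[2], d[3])
}

#' Spatial mean of one spectral band
#'
#' @param cube A [hypercube()].
#' @param l 0-based spectral channel index.
#' @return The arithmetic mean of the band's pixel intensities.
#' @export
spatial_mean <- function(cube, l) {
  stopifnot(inherits(cube, "hypercube"))
  if (!is_count(l) || l < 0 || l >= n_channels(cube))
    stop_domain("channel index ", l, " out of range [0, ",
                n_channels(cube), ")")
  mean(cube$values[, , l + 1L])
}

#' Extract a contiguous spectral window from a cube
#'
#' Windows are half-open 0-based channel intervals `[s, e)`: the result
#' keeps channels `s .. e-1` and its axis starts at the wavelength of
#' channel `s`.
#'
#' @param cube A [hypercube()].
#' @param window A [spectral_window()], or anything coercible via
#'   `list(s =, e =)`.
#' @return A new `hypercube` with `e - s` channels.
#' @examples
#' ax <- wavelength_axis(325, 0.728, 10)
#' cube <- hypercube(array(1, c(2, 2, 10)), ax)
#' slice_bands(cube, spectral_window(3, 5))$axis$n_channels  # 2
#' @export
slice_bands <- function(cube, window) {
  stopifnot(inherits(cube, "hypercube"))
  s <- window$s; e <- window$e
  nc <- n_channels(cube)
  if (!is_count(s) || !is_count(e) || s < 0 || e <= s || e > nc)
    stop_domain("window [", s, ", ", e, ") out of range for a ",
                nc, "-channel cube")
  vals <- cube$values[, , (s + 1L):e, drop = FALSE]
  ax <- wavelength_axis(cube$axis$start_nm + s * cube$axis$step_nm,
                        cube$axis$step_nm, e - s)
  hypercube(vals, ax, label = cube$label, meta = cube$meta)
}

#' Render a pseudo-RGB image from three wavelengths
#'
#' Picks the channel nearest each requested wavelength and min-max
#' normalizes each plane to `[0, 1]`. A spatially constant plane (zero
#' dynamic range) renders as mid-gray 0.5.
#'
#' @param cube A [hypercube()].
#' @param r_nm,g_nm,b_nm Wavelengths (nm) for the red, green and blue
#'   planes; each must lie inside the axis range.
#' @return A `y x x x 3` array with values in `[0, 1]`.
#' @export
pseudo_rgb <- function(cube, r_nm, g_nm, b_nm) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- wavelengths(cube$axis)
  pick <- function(nm) {
    if (!is.numeric(nm) || length(nm) != 1L || !is.finite(nm) ||
        nm < wl[1] || nm > wl[length(wl)])
      stop_domain("wavelength ", nm, " nm outside axis range [",
                  wl[1], ", ", wl[length(wl)], "] nm")
    which.min(abs(wl - nm))
  }
  idx <- c(pick(r_nm), pick(g_nm), pick(b_nm))
  d <- dim(cube$values)
  out <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) {
    plane <- cube$values[, , idx[k]]
    rng <- range(plane)
    out[, , k] <- if (rng[2] > rng[1]) (plane - rng[1]) / (rng[2] - rng[1])
                  else 0.5
  }
  out
}

#' Labeled hypercube dataset
#'
#' Bundles cubes with integer class labels (1-based, indexing
#' `class_names`). All cubes must share one wavelength axis and one
#' spatial extent; this is the unit of training and evaluation.
#'
#' @param cubes List of [hypercube()] objects.
#' @param labels Integer vector, one label per cube, each in
#'   `1 .. length(class_names)`.
#' @param class_names Character vector of class identifiers.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(cubes, labels, class_names) {
  if (!is.list(cubes) || length(cubes) == 0L)
    stop_domain("`cubes` must be a non-empty list of hypercubes")
  if (!all(vapply(cubes, inherits, logical(1), "hypercube")))
    stop_domain("every element of `cubes` must be a hypercube")
  labels <- as.integer(labels)
  if (length(labels) != length(cubes))
    stop_domain("need one label per cube: ", length(cubes), " cubes vs ",
                length(labels), " labels")
  if (anyNA(labels) || any(labels < 1L) || any(labels > length(class_names)))
    stop_domain("labels must index `class_names` (1..",
                length(class_names), ")")
  ax <- cubes[[1]]$axis
  sp <- dim(cubes[[1]]$values)[1:2]
  for (cb in cubes) {
    if (!(cb$axis == ax))
      stop_domain("all cubes must share one wavelength axis")
    if (!identical(dim(cb$values)[1:2], sp))
      stop_domain("all cubes must share one spatial extent")
  }
  structure(list(cubes = cubes, labels = labels,
                 class_names = as.character(class_names)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d cubes, %d classes (%s)\n",
              length(x$cubes), length(x$class_names),
              paste(utils::head(x$class_names, 4), collapse = ", ")))
  invisible(x)
}

#' Number of cubes in a dataset
#' @param dataset A [labeled_dataset()].
#' @export
n_cubes <- function(dataset) length(dataset$cubes)

# subset keeping class bookkeeping
dataset_subset <- function(dataset, idx) {
  labeled_dataset(dataset$cubes[idx], dataset$labels[idx],
                  dataset$class_names)
}
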