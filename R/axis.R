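#' Uniform wavelength axis
#'
#' A `wavelength_axis` describes the spectral grid of a hypercube: the
#' wavelength of channel 0 (`start_nm`), the per-channel spectral resolution
#' (`step_nm`), and the number of channels. Channel indices are 0-based
#' throughout the package, so channel `i` sits at
#' `start_nm + i * step_nm` and the total span is
#' `n_channels * step_nm` nanometres. The microscope configuration this
#' package targets records 1004 channels at 0.728 nm from 325 nm, a span
#' that rounds to 731 nm.
#'
#' @param start_nm Wavelength of channel 0, in nanometres.
#' @param step_nm Per-channel resolution in nanometres; must be positive.
#' @param n_channels Number of spectral channels; at least 1.
#' @return An object of class `wavelength_axis`.
#' @examples
#' ax <- wavelength_axis(325, 0.728, 1004)
#' round(axis_span_nm(ax))   # 731
#' @export
wavelength_axis <- function(start_nm, step_nm, n_channels) {
  if (!is.numeric(start_nm) || length(start_nm) != 1L || !is.finite(start_nm))
    stop_domain("`start_nm` must be a single finite number")
  if (!is.numeric(step_nm) || length(step_nm) != 1L || !is.finite(step_nm) ||
      step_nm <= 0)
    stop_domain("`step_nm` must be a single positive number")
  if (!is_count(n_channels) || n_channels < 1)
    stop_domain("`n_channels` must be a positive integer")
  structure(
    list(start_nm = as.numeric(start_nm), step_nm = as.numeric(step_nm),
         n_channels = as.integer(n_channels)),
    class = "wavelength_axis"
  )
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf("<wavelength_axis> %d channels, %.4g nm step, %.6g-%.6g nm\n",
              x$n_channels, x$step_nm, x$start_nm,
              x$start_nm + (x$n_channels - 1L) * x$step_nm))
  invisible(x)
}

#' @export
`==.wavelength_axis` <- function(e1, e2) {
  isTRUE(all.equal(e1$start_nm, e2$start_nm)) &&
    isTRUE(all.equal(e1$step_nm, e2$step_nm)) &&
    e1$n_channels == e2$n_channels
}

#' Wavelengths of every channel
#'
#' @param axis A [wavelength_axis()].
#' @return Numeric vector of length `n_channels`: the wavelength (nm) of
#'   channels `0 .. n_channels - 1`.
#' @export
wavelengths <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  axis$start_nm + (seq_len(axis$n_channels) - 1) * axis$step_nm
}

#' Total spectral span of an axis
#'
#' The span is `n_channels * step_nm`, i.e. the width covered when every
#' channel is treated as one resolution element.
#'
#' @inheritParams wavelengths
#' @return Span in nanometres.
#' @export
axis_span_nm <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  axis$n_channels * axis$step_nm
}

#' Convert a window width in nanometres to a channel count
#'
#' Band selection works on windows of a fixed physical width (e.g. 20 nm).
#' The width is converted to channels by rounding `width_nm / step_nm` to
#' the nearest integer (half away from zero), never below one channel.
#' On a 0.728 nm grid a 20 nm window is 27 channels.
#'
#' @param width_nm Window width in nanometres; positive.
#' @param step_nm Spectral resolution in nanometres; positive.
#' @return Positive integer channel count.
#' @examples
#' nm_width_to_channels(20, 0.728)   # 27
#' nm_width_to_channels(100, 0.728)  # 137
#' @export
nm_width_to_channels <- function(width_nm, step_nm) {
  if (!is.numeric(width_nm) || length(width_nm) != 1L ||
      !is.finite(width_nm) || width_nm <= 0)
    stop_domain("`width_nm` must be a single positive number")
  if (!is.numeric(step_nm) || length(step_nm) != 1L ||
      !is.finite(step_nm) || step_nm <= 0)
    stop_domain("`step_nm` must be a single positive number")
  max(1L, as.integer(floor(width_nm / step_nm + 0.5)))
}

#' Fraction of spectral channels discarded by a window
#'
#' Data-size reduction is accounted spectrally: keeping `w_channels` of
#' `total_channels` discards `1 - w_channels / total_channels` of the cube
#' (spatial extents are unchanged). A 27-channel window on a 1004-channel
#' axis discards 97.3% of the data.
#'
#' @param w_channels Channels kept; positive integer.
#' @param total_channels Channels available; positive integer,
#'   `>= w_channels`.
#' @return Fraction in `[0, 1)`.
#' @examples
#' round(100 * reduction_fraction(27, 1004), 1)  # 97.3
#' @export
reduction_fraction <- function(w_channels, total_channels) {
  if (!is_count(w_channels) || w_channels < 1)
    stop_domain("`w_channels` must be a positive integer")
  if (!is_count(total_channels) || total_channels < 1)
    stop_domain("`total_channels` must be a positive integer")
  if (w_channels > total_channels)
    stop_domain("`w_channels` (", w_channels,
                ") exceeds `total_channels` (", total_channels, ")")
  1 - w_channels / total_channels
}

# nm -> 0-based channel index. `floor` / `ceiling` bracket a wavelength
# interval so that [floor(lo), ceiling(hi)) covers it.
nm_to_channel <- function(axis, nm, how = c("floor", "ceiling", "nearest")) {
  how <- match.arg(how)
  pos <- (nm - axis$start_nm) / axis$step_nm
  i <- switch(how,
              floor = floor(pos),
              ceiling = ceiling(pos),
              nearest = floor(pos + 0.5))
  as.integer(i)
}
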