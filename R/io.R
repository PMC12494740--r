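#' Read a hypercube from disk
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`envi`}{An ENVI header/raw pair: `path` names the `.hdr` text
#'     header (or the raw file; the sibling is inferred). The header must
#'     declare `samples`, `lines`, `bands`, BSQ interleave, little-endian
#'     byte order, data type 4 (float32) or 5 (float64), and a
#'     `wavelength = { ... }` list on a uniform grid.}
#'   \item{`container`}{A single self-describing file holding one dataset
#'     named `cube` plus `start_nm` / `step_nm` / `label` / `meta`
#'     attributes (written via R serialization). Round-trips bit-exactly.}
#' }
#' Cubes containing non-finite values are rejected at load time.
#'
#' @param path File to read.
#' @param format `"envi"` or `"container"`.
#' @return A [hypercube()].
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = c("container", "envi")) {
  format <- match.arg(format)
  if (format == "container") read_cube_container(path) else read_cube_envi(path)
}

#' Write a hypercube to disk
#'
#' @param cube A [hypercube()].
#' @param path Destination file. For ENVI this is the header path
#'   (`.hdr` appended if absent); the raw file takes the same stem.
#' @param format `"envi"` or `"container"`.
#' @param envi_data_type 4 (float32, ENVI's common default) or 5
#'   (float64, lossless).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("container", "envi"),
                       envi_data_type = 4L) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "hypercube"))
  if (format == "container") write_cube_container(cube, path)
  else write_cube_envi(cube, path, envi_data_type)
  invisible(path)
}

# ---- container dialect -----------------------------------------------------

write_cube_container <- function(cube, path) {
  obj <- list(cube = cube$values,
              start_nm = cube$axis$start_nm,
              step_nm = cube$axis$step_nm,
              label = cube$label,
              meta = cube$meta)
  ok <- tryCatch({ saveRDS(obj, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_domain("cannot write container file: ", path)
  path
}

read_cube_container <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    stop_domain("not a readable container file: ", path))
  if (!is.list(obj) || is.null(obj$cube))
    stop_domain("container is missing the `cube` dataset: ", path)
  for (key in c("start_nm", "step_nm")) {
    if (is.null(obj[[key]]))
      stop_domain("container is missing wavelength metadata `", key,
                  "`: ", path)
  }
  vals <- obj$cube
  if (!is.array(vals) || length(dim(vals)) != 3L)
    stop_domain("container `cube` dataset is not a 3-D array: ", path)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop_domain("container holds non-finite values: ", path)
  ax <- wavelength_axis(obj$start_nm, obj$step_nm, dim(vals)[3])
  hypercube(vals, ax, label = obj$label, meta = obj$meta %||% list())
}

# ---- ENVI dialect ----------------------------------------------------------

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path)) {
    list(hdr = path, raw = sub("\\.hdr$", ".raw", path))
  } else if (grepl("\\.raw$", path)) {
    list(hdr = sub("\\.raw$", ".hdr", path), raw = path)
  } else {
    list(hdr = paste0(path, ".hdr"), raw = paste0(path, ".raw"))
  }
}

write_cube_envi <- function(cube, path, data_type = 4L) {
  if (!data_type %in% c(4L, 5L))
    stop_domain("`envi_data_type` must be 4 (float32) or 5 (float64)")
  p <- envi_paths(path)
  d <- dim(cube$values)
  wl <- wavelengths(cube$axis)
  hdr <- c(
    "ENVI",
    "description = {hsiband export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(sprintf("%.10g", wl), collapse = ", "),
           "}")
  )
  ok <- tryCatch({ writeLines(hdr, p$hdr); TRUE }, error = function(e) FALSE)
  if (!ok) stop_domain("cannot write ENVI header: ", p$hdr)
  # BSQ: band-sequential, within each band samples (x) vary fastest
  band_major <- aperm(cube$values, c(2L, 1L, 3L))
  con <- tryCatch(file(p$raw, "wb"),
                  error = function(e)
                    stop_domain("cannot write ENVI raw file: ", p$raw))
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(band_major), con,
           size = if (data_type == 4L) 4L else 8L, endian = "little")
  path
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key,
                                        "\\s*=\\s*([^\n{]+)"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2L) return(NULL)
    trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key,
                                        "\\s*=\\s*\\{([^}]*)\\}"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2L) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]")[[1]])
  }
  needed <- c("samples", "lines", "bands", "data type")
  vals <- lapply(needed, get_scalar)
  missing <- needed[vapply(vals, is.null, logical(1))]
  if (length(missing))
    stop_domain("ENVI header is missing key(s): ",
                paste(missing, collapse = ", "))
  wl <- get_list("wavelength")
  if (is.null(wl))
    stop_domain("ENVI header is missing wavelength metadata ",
                "(`wavelength` list)")
  list(samples = as.integer(vals[[1]]), lines = as.integer(vals[[2]]),
       bands = as.integer(vals[[3]]), data_type = as.integer(vals[[4]]),
       interleave = tolower(get_scalar("interleave") %||% "bsq"),
       byte_order = as.integer(get_scalar("byte order") %||% "0"),
       wavelength = wl)
}

read_cube_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop_domain("ENVI header not found: ", p$hdr)
  if (!file.exists(p$raw)) stop_domain("ENVI raw file not found: ", p$raw)
  h <- parse_envi_header(p$hdr)
  if (!h$data_type %in% c(4L, 5L))
    stop_domain("unsupported ENVI data type ", h$data_type,
                " (only 4/float32 and 5/float64)")
  if (h$interleave != "bsq")
    stop_domain("unsupported ENVI interleave '", h$interleave,
                "' (only bsq)")
  if (h$byte_order != 0L)
    stop_domain("unsupported ENVI byte order ", h$byte_order,
                " (only little-endian)")
  if (length(h$wavelength) != h$bands)
    stop_domain("ENVI header declares ", h$bands, " bands but lists ",
                length(h$wavelength), " wavelengths")
  size <- if (h$data_type == 4L) 4L else 8L
  n_expect <- h$samples * h$lines * h$bands
  actual <- file.info(p$raw)$size
  if (actual != n_expect * size)
    stop_domain("ENVI raw size mismatch: header implies ",
                n_expect * size, " bytes, file holds ", actual)
  con <- file(p$raw, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = n_expect, size = size,
                  endian = "little")
  if (anyNA(vals) || any(!is.finite(vals)))
    stop_domain("ENVI raw file holds non-finite values: ", p$raw)
  cube_vals <- aperm(array(vals, c(h$samples, h$lines, h$bands)),
                     c(2L, 1L, 3L))
  steps <- diff(h$wavelength)
  if (h$bands > 1L &&
      (any(steps <= 0) || diff(range(steps)) > 1e-6 * mean(steps)))
    stop_domain("ENVI wavelength list is not a uniform increasing grid")
  step <- if (h$bands > 1L) mean(steps) else 1
  ax <- wavelength_axis(h$wavelength[1], step, h$bands)
  hypercube(cube_vals, ax)
}

# ---- dataset directory + PNG helpers ---------------------------------------

#' Write a labeled dataset to a directory of container files
#'
#' Writes one container file per cube (`cube_0001.rds`, ...), a
#' `labels.csv` (file, label index, class name) and, when `manifest` is
#' supplied, a `manifest.json` echoing it (e.g. the simulation
#' configuration and planted window).
#'
#' @param dataset A [labeled_dataset()].
#' @param dir Output directory (created if absent).
#' @param manifest Optional list serialized as JSON alongside the cubes.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, manifest = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_cubes(dataset)
  files <- sprintf("cube_%04d.rds", seq_len(n))
  for (i in seq_len(n))
    write_cube(dataset$cubes[[i]], file.path(dir, files[i]), "container")
  utils::write.csv(
    data.frame(file = files, label = dataset$labels,
               class_name = dataset$class_names[dataset$labels]),
    file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param dir Directory holding `labels.csv` and container files.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path))
    stop_domain("no labels.csv under ", dir)
  tab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  cubes <- lapply(file.path(dir, tab$file), read_cube, format = "container")
  class_names <- character(max(tab$label))
  class_names[tab$label] <- tab$class_name
  labeled_dataset(cubes, tab$label, class_names)
}

#' Export a pseudo-RGB rendering as PNG
#'
#' @inheritParams pseudo_rgb
#' @param path Destination `.png` file.
#' @return `path`, invisibly.
#' @export
write_pseudo_rgb <- function(cube, path, r_nm, g_nm, b_nm) {
  img <- pseudo_rgb(cube, r_nm, g_nm, b_nm)
  png::writePNG(img, path)
  invisible(path)
}
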