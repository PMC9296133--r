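#' Construct a calibrated image stack
#'
#' Container for multi-dimensional fluorescence data. Pixels are held as a
#' 5-D array indexed (time, z, y, x, channel); missing axes of the input are
#' padded to length 1.
#'
#' @param pixels numeric array with 2 to 5 dimensions interpreted, from the
#'   fastest-varying end, as (y, x), (z, y, x), (time, z, y, x) or
#'   (time, z, y, x, channel).
#' @param channels character vector of channel labels, one per channel.
#' @param pixel_size_um physical size of one pixel in x and y (micrometres,
#'   isotropic).
#' @param z_step_um spacing between z slices (micrometres).
#' @param time_step_s interval between frames (seconds).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channels = NULL, pixel_size_um,
                        z_step_um = 1, time_step_s = 1) {
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || nd < 2 || nd > 5)
    .stop_class("pixels must be an array with 2 to 5 dimensions", "nedyn_input_error")
  d <- dim(pixels)
  dim(pixels) <- switch(as.character(nd),
    "2" = c(1L, 1L, d, 1L),
    "3" = c(1L, d, 1L),
    "4" = c(d, 1L),
    "5" = d)
  if (any(dim(pixels) < 1L))
    .stop_class("all axis lengths must be >= 1", "nedyn_input_error")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    .stop_class("intensities must be finite and non-negative", "nedyn_input_error")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    .stop_class("pixel_size_um must be > 0", "nedyn_config_error")
  if (time_step_s <= 0)
    .stop_class("time_step_s must be > 0", "nedyn_config_error")
  nc <- dim(pixels)[5]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    .stop_class("one channel label per channel required", "nedyn_config_error")
  structure(list(pixels = pixels, channels = channels,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 time_step_s = time_step_s, origin = "0-based, x right, y down"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d t x %d z x %d y x %d x px, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], d[5], paste(x$channels, collapse = ", ")))
  cat(sprintf("  pixel %g um, z step %g um, frame interval %g s\n",
              x$pixel_size_um, x$z_step_um, x$time_step_s))
  invisible(x)
}

#' Extract one 2-D frame from a stack
#'
#' @param stack an `image_stack`.
#' @param t,z,channel 1-based indices.
#' @return numeric matrix indexed (y, x).
#' @export
stack_frame <- function(stack, t = 1, z = 1, channel = 1) {
  stopifnot(inherits(stack, "image_stack"))
  stack$pixels[t, z, , , channel]
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written t-major, then z, then channel. Intensities must be
#' integer-valued in \[0, 65535\] (16-bit camera counts) so that
#' `read_stack(write_stack(s))` reproduces them exactly. Calibration, axis
#' shape and channel labels are stored in a JSON sidecar (`<path>.json`).
#'
#' @param stack an `image_stack`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixels
  if (any(px != round(px)) || any(px > 65535))
    .stop_class("intensities must be integer-valued in [0, 65535]", "nedyn_input_error")
  d <- dim(px)
  pages <- vector("list", d[1] * d[2] * d[5])
  i <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
    pages[[i]] <- px[t, z, , , ch] / 65535
    i <- i + 1L
  }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .stop_class(sprintf("cannot write TIFF '%s'", path), "nedyn_io_error")
  meta <- list(dim = d, channels = stack$channels,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um, time_step_s = stack$time_step_s)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Axes are normalized to (time, z, y, x, channel); a plain 2-D image
#' becomes shape (1, 1, Y, X) with one channel. Calibration precedence is
#' explicit override, then the JSON sidecar written by [write_stack()];
#' if neither supplies a pixel size, a configuration error is raised.
#'
#' @param path TIFF file path.
#' @param calibration optional named list overriding any of `pixel_size_um`,
#'   `z_step_um`, `time_step_s`, `channels`.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, calibration = NULL) {
  if (!file.exists(path))
    .stop_class(sprintf("file '%s' does not exist", path), "nedyn_input_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) NULL)
  if (is.null(pages))
    .stop_class(sprintf("cannot read '%s' as TIFF", path), "nedyn_input_error")
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # collapse RGB planes if present
  })
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  cal <- function(key, default = NULL) {
    if (!is.null(calibration[[key]])) calibration[[key]]
    else if (!is.null(meta[[key]])) meta[[key]]
    else default
  }
  psz <- cal("pixel_size_um")
  if (is.null(psz))
    .stop_class("pixel size not in metadata and no calibration override given",
                "nedyn_config_error")
  if (!is.null(meta$dim)) {
    d <- as.integer(meta$dim)
    arr <- array(0, d)
    i <- 1L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
      arr[t, z, , , ch] <- pages[[i]]
      i <- i + 1L
    }
  } else {
    d <- c(length(pages), 1L, dim(pages[[1]]), 1L)
    arr <- array(0, d)
    for (t in seq_along(pages)) arr[t, 1, , , 1] <- pages[[t]]
  }
  image_stack(arr, channels = cal("channels"), pixel_size_um = psz,
              z_step_um = cal("z_step_um", 1), time_step_s = cal("time_step_s", 1))
}

#' Region of interest in pixel coordinates
#'
#' `region_box()` describes an axis-aligned box by its 0-based top-left
#' corner and size; `region_polygon()` an ordered vertex list (closure
#' implicit, first vertex not repeated).
#'
#' @param x,y 0-based pixel coordinates of the box corner.
#' @param width,height box size in pixels (>= 1).
#' @param frame,z optional 1-based frame / z indices the region refers to.
#' @return An object of class `region_spec`.
#' @export
region_box <- function(x, y, width, height, frame = NA, z = NA) {
  if (width < 1 || height < 1)
    .stop_class("box width and height must be >= 1 pixel", "nedyn_input_error")
  structure(list(kind = "box", x = x, y = y, width = width, height = height,
                 frame = frame, z = z), class = "region_spec")
}

#' @rdname region_box
#' @param vertices n x 2 matrix of 0-based (x, y) vertices, n >= 3.
#' @export
region_polygon <- function(vertices, frame = NA, z = NA) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    .stop_class("polygon needs >= 3 vertices", "nedyn_input_error")
  structure(list(kind = "polygon", vertices = vertices, frame = frame, z = z),
            class = "region_spec")
}

.check_region_in_frame <- function(region, frame_dim) {
  ny <- frame_dim[1]; nx <- frame_dim[2]
  if (region$kind == "box") {
    ok <- region$x >= 0 && region$y >= 0 &&
      region$x + region$width <= nx && region$y + region$height <= ny
  } else {
    v <- region$vertices
    ok <- all(v[, 1] >= 0 & v[, 1] <= nx - 1 & v[, 2] >= 0 & v[, 2] <= ny - 1)
  }
  if (!ok) .stop_class("region lies outside the frame", "nedyn_input_error")
  invisible(TRUE)
}

#' Write labeled polylines/polygons to CSV
#'
#' One row per vertex with columns `object_id`, `slice_or_frame`,
#' `vertex_index`, `x`, `y`, `closed_flag`, `units`. Closed objects store
#' first != last vertex (closure implicit).
#'
#' @param objects list of objects, each a list with elements `id`,
#'   `slice` (integer), `xy` (n x 2 matrix), `closed` (logical).
#' @param path output CSV path.
#' @param units one of `"pixel"`, `"um"`, `"nm"`.
#' @return `path`, invisibly.
#' @export
write_pointlists <- function(objects, path, units = c("pixel", "um", "nm")) {
  units <- match.arg(units)
  rows <- lapply(objects, function(o) {
    xy <- as.matrix(o$xy)
    data.frame(object_id = o$id, slice_or_frame = o$slice,
               vertex_index = seq_len(nrow(xy)) - 1L,
               x = xy[, 1], y = xy[, 2],
               closed_flag = as.integer(isTRUE(o$closed)), units = units)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read labeled polylines/polygons from CSV
#'
#' Inverse of [write_pointlists()]. Vertex order must be strictly
#' increasing within each (object, slice); duplicate vertex indices and
#' mixed units are format errors.
#'
#' @param path CSV path with the [write_pointlists()] schema.
#' @param units expected units; must match the file's `units` column when
#'   present.
#' @return list of objects (`id`, `slice`, `xy`, `closed`, `units`).
#' @export
read_pointlists <- function(path, units = c("pixel", "um", "nm")) {
  units <- match.arg(units)
  if (!file.exists(path))
    .stop_class(sprintf("file '%s' does not exist", path), "nedyn_input_error")
  df <- read.csv(path)
  need <- c("object_id", "slice_or_frame", "vertex_index", "x", "y", "closed_flag")
  if (!all(need %in% names(df)))
    .stop_class("point-list CSV lacks required columns", "nedyn_format_error")
  if ("units" %in% names(df)) {
    u <- unique(df$units)
    if (length(u) > 1)
      .stop_class("mixed units in point-list file", "nedyn_format_error")
    if (u != units)
      .stop_class(sprintf("file units '%s' do not match requested '%s'", u, units),
                  "nedyn_format_error")
  }
  keys <- split(df, list(df$object_id, df$slice_or_frame), drop = TRUE)
  objs <- lapply(keys, function(g) {
    g <- g[order(g$vertex_index), ]
    if (anyDuplicated(g$vertex_index))
      .stop_class(sprintf("duplicate vertex_index in object '%s'", g$object_id[1]),
                  "nedyn_format_error")
    if (any(diff(g$vertex_index) <= 0))
      .stop_class(sprintf("non-monotone vertex_index in object '%s'", g$object_id[1]),
                  "nedyn_format_error")
    closed <- as.logical(g$closed_flag[1])
    xy <- cbind(x = g$x, y = g$y)
    if (closed && nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]  # store closure implicitly
    list(id = g$object_id[1], slice = g$slice_or_frame[1], xy = xy,
         closed = closed, units = units)
  })
  names(objs) <- NULL
  objs[order(vapply(objs, function(o) o$slice, numeric(1)))]
}

#' Read a run configuration JSON
#'
#' Every parameter has a default; keys absent from `defaults` are rejected
#' so typos fail loudly.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param defaults named list of defaults.
#' @return merged named list.
#' @export
read_config <- function(path = NULL, defaults = list()) {
  if (is.null(path)) return(defaults)
  if (!file.exists(path))
    .stop_class(sprintf("config '%s' does not exist", path), "nedyn_input_error")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    .stop_class(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                "nedyn_config_error")
  utils::modifyList(defaults, cfg)
}
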