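#' Extract a wide-line intensity profile
#'
#' Samples the image every pixel along the line from `p1` to `p2`; at each
#' sample the intensity is the mean of `width_px` bilinearly interpolated
#' samples taken perpendicular to the line (a "three-pixel wide" line for
#' the default width).
#'
#' @param image 2-D numeric matrix (y, x).
#' @param p1,p2 line endpoints, 0-based (x, y).
#' @param width_px odd line width in pixels.
#' @param pixel_size_um pixel size (um).
#' @param channel optional channel label stored with the profile.
#' @return object of class `line_profile`: data frame with `pos_um` and
#'   `value`; attributes `raw`, `p1`, `p2`, `width_px`, `pixel_size_um`,
#'   `channel`, `steps` (processing history).
#' @export
extract_profile <- function(image, p1, p2, width_px = 3, pixel_size_um,
                            channel = NA_character_) {
  if (width_px %% 2 == 0 || width_px < 1)
    .stop_class("line width must be odd and >= 1", "nedyn_input_error")
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  L <- sqrt(sum((p2 - p1)^2))
  if (L == 0) .stop_class("degenerate line", "nedyn_geometry_error")
  u <- (p2 - p1) / L
  perp <- c(-u[2], u[1])
  steps <- 0:floor(L)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  xs <- outer(p1[1] + steps * u[1], offs * perp[1], `+`)
  ys <- outer(p1[2] + steps * u[2], offs * perp[2], `+`)
  ny <- nrow(image); nx <- ncol(image)
  if (any(xs < 0 | xs > nx - 1 | ys < 0 | ys > ny - 1))
    .stop_class("line (including its width) exits the image", "nedyn_geometry_error")
  vals <- matrix(.bilinear(image, as.vector(xs), as.vector(ys)), nrow(xs))
  value <- rowMeans(vals)
  structure(data.frame(pos_um = steps * pixel_size_um, value = value),
            class = c("line_profile", "data.frame"),
            raw = value, p1 = p1, p2 = p2, width_px = width_px,
            pixel_size_um = pixel_size_um, channel = channel, steps = "raw")
}

# bilinear interpolation at 0-based (x, y); image indexed (y, x) 1-based
.bilinear <- function(image, x, y) {
  ny <- nrow(image); nx <- ncol(image)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

.update_profile <- function(profile, value, step) {
  profile$value <- value
  attr(profile, "steps") <- c(attr(profile, "steps"), step)
  profile
}

#' Average a line profile with its perpendicular redraw
#'
#' Pointwise mean of two equal-length, equally spaced profiles (the line
#' redrawn perpendicular to the first through the same center).
#'
#' @param p1,p2 [extract_profile()] results of equal length and spacing.
#' @return a `line_profile` with the averaged values.
#' @export
perpendicular_average <- function(p1, p2) {
  if (nrow(p1) != nrow(p2))
    .stop_class("profiles differ in length", "nedyn_input_error")
  if (!isTRUE(all.equal(p1$pos_um, p2$pos_um)))
    .stop_class("profiles differ in spacing", "nedyn_input_error")
  .update_profile(p1, (p1$value + p2$value) / 2, "perpendicular_average")
}

#' Subtract end-point background from a profile
#'
#' The mean of the first `n_end` and last `n_end` samples is subtracted
#' from every sample.
#'
#' @param profile a `line_profile`.
#' @param n_end samples per end used for the background estimate.
#' @return background-corrected `line_profile`.
#' @export
background_correct <- function(profile, n_end = 2) {
  n <- nrow(profile)
  if (n <= 2 * n_end)
    .stop_class("profile too short for end-point background", "nedyn_input_error")
  bg <- mean(c(profile$value[seq_len(n_end)],
               profile$value[(n - n_end + 1):n]))
  .update_profile(profile, profile$value - bg, "background_correct")
}

#' Normalize a profile to its maximum
#'
#' @param profile a `line_profile` with positive maximum.
#' @return `line_profile` with maximum 1.
#' @export
normalize_max <- function(profile) {
  m <- max(profile$value)
  if (m <= 0)
    .stop_class("profile maximum is not positive", "nedyn_normalization_error")
  .update_profile(profile, profile$value / m, "normalize_max")
}

#' NE:cytoplasm and NE:nucleoplasm ratios from a rim profile
#'
#' The NE value is the profile maximum; it is divided by the mean of the
#' first `n_flank` values (cytoplasmic side) and by the mean of the last
#' `n_flank` values (nucleoplasmic side). The line is assumed oriented
#' cytoplasm to nucleoplasm.
#'
#' @param profile a normalized `line_profile`.
#' @param n_flank flank values per side.
#' @return list with `ne_value`, `ne_pos_um`, `ne_cytoplasm`,
#'   `ne_nucleoplasm`.
#' @export
ne_ratios <- function(profile, n_flank = 5) {
  n <- nrow(profile)
  if (n <= 2 * n_flank)
    .stop_class("profile too short for flank ratios", "nedyn_input_error")
  v <- profile$value
  peak_i <- which.max(v)
  cyto <- mean(v[seq_len(n_flank)])
  nucleo <- mean(v[(n - n_flank + 1):n])
  if (cyto == 0 || nucleo == 0)
    .stop_class("zero flank mean: ratio undefined", "nedyn_ratio_error")
  list(ne_value = v[peak_i], ne_pos_um = profile$pos_um[peak_i],
       ne_cytoplasm = v[peak_i] / cyto, ne_nucleoplasm = v[peak_i] / nucleo)
}

#' Compare the peak positions of two channels along the same line
#'
#' @param a,b `line_profile`s with identical geometry.
#' @return list with `peak_a_um`, `peak_b_um`, `offset_um`.
#' @export
overlay_compare <- function(a, b) {
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$pos_um, b$pos_um)))
    .stop_class("profiles do not share geometry", "nedyn_input_error")
  flat <- function(v) diff(range(v)) == 0
  if (flat(a$value) || flat(b$value))
    .stop_class("flat profile: no defined peak", "nedyn_degenerate_error")
  pa <- a$pos_um[which.max(a$value)]
  pb <- b$pos_um[which.max(b$value)]
  list(peak_a_um = pa, peak_b_um = pb, offset_um = abs(pa - pb))
}

#' Rim line-scan presets
#'
#' Runs the full rim recipe on one line and its 90-degree redraw about the
#' line center: extraction, perpendicular averaging, then the
#' preset-specific processing. Preset `"twocell"` subtracts the
#' first/last-two-point background; preset `"if"` subtracts a camera
#' background value, max-normalizes, and reports NE:cytoplasm and
#' NE:nucleoplasm flank ratios.
#'
#' @param image 2-D numeric matrix (y, x).
#' @param p1,p2 primary line endpoints, 0-based (x, y).
#' @param preset `"twocell"` or `"if"`.
#' @param width_px odd line width.
#' @param pixel_size_um pixel size (um).
#' @param camera_bg camera background intensity for the `"if"` preset
#'   (0 to skip correction).
#' @param n_flank flank width for the `"if"` ratios.
#' @return the processed `line_profile`; for `"if"` also attribute
#'   `ratios` (see [ne_ratios()]).
#' @export
rim_linescan <- function(image, p1, p2, preset = c("twocell", "if"),
                         width_px = 3, pixel_size_um, camera_bg = 0,
                         n_flank = 5) {
  preset <- match.arg(preset)
  center <- (as.numeric(p1) + as.numeric(p2)) / 2
  rot <- function(p) center + c(-(p[2] - center[2]), p[1] - center[1])
  prof1 <- extract_profile(image, p1, p2, width_px, pixel_size_um)
  prof2 <- extract_profile(image, rot(as.numeric(p1)), rot(as.numeric(p2)),
                           width_px, pixel_size_um)
  avg <- perpendicular_average(prof1, prof2)
  if (preset == "twocell") return(background_correct(avg, n_end = 2))
  if (camera_bg > 0)
    avg <- .update_profile(avg, avg$value - camera_bg, "camera_background")
  out <- normalize_max(avg)
  attr(out, "ratios") <- ne_ratios(out, n_flank = n_flank)
  out
}
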