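#' Sphere geometry from an equivalent diameter
#'
#' @param diameter_um equivalent diameter (um), >= 0.
#' @param frame,time_s optional provenance.
#' @return list of class `nucleus_geometry`: `diameter_um`, `radius_um`,
#'   `surface_um2` (4 pi r^2), `volume_um3` (4/3 pi r^3), `frame`, `time_s`.
#' @export
nucleus_geometry <- function(diameter_um, frame = NA, time_s = NA) {
  if (diameter_um < 0) .stop_class("diameter must be >= 0", "nedyn_input_error")
  r <- diameter_um / 2
  structure(list(diameter_um = diameter_um, radius_um = r,
                 surface_um2 = 4 * pi * r^2, volume_um3 = 4 / 3 * pi * r^3,
                 frame = frame, time_s = time_s),
            class = "nucleus_geometry")
}

#' Measure the nuclear diameter from a thresholded frame
#'
#' Threshold, binarize, keep the largest connected component, and report
#' the equivalent diameter 2 * sqrt(area / pi) together with the derived
#' sphere surface area and volume.
#'
#' @param frame 2-D numeric matrix (y, x).
#' @param pixel_size_um pixel size (um).
#' @param method threshold method (see [segment_nucleus()]).
#' @param min_area_px minimum component size in pixels.
#' @param frame_index,time_s optional provenance.
#' @return a [nucleus_geometry()].
#' @export
measure_diameter <- function(frame, pixel_size_um, method = "otsu",
                             min_area_px = 20, frame_index = NA, time_s = NA) {
  region <- segment_nucleus(frame, method = method, min_area_px = min_area_px)
  area_px <- attr(region, "area_px")
  d_um <- 2 * sqrt(area_px / pi) * pixel_size_um
  nucleus_geometry(d_um, frame = frame_index, time_s = time_s)
}

#' Polygon area by the shoelace formula
#'
#' Orientation-independent (absolute value). Self-intersecting polygons
#' are rejected.
#'
#' @param vertices n x 2 matrix of ordered (x, y) vertices, n >= 3; the
#'   closing edge is implicit.
#' @return area in squared input units.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) .stop_class("polygon needs >= 3 vertices", "nedyn_geometry_error")
  if (.polygon_self_intersects(v))
    .stop_class("self-intersecting polygon", "nedyn_geometry_error")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# proper crossing test between all non-adjacent edge pairs, vectorized
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (!nrow(idx)) return(FALSE)
  p1 <- a[idx[, 1], , drop = FALSE]; p2 <- b[idx[, 1], , drop = FALSE]
  p3 <- a[idx[, 2], , drop = FALSE]; p4 <- b[idx[, 2], , drop = FALSE]
  d <- function(p, q, r)  # signed area orientation of (p, q, r)
    (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) - (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Construct a contour stack
#'
#' Per-slice closed polygons of one traced object, with a fixed slice
#' spacing.
#'
#' @param slices list of n x 2 vertex matrices (um), one per slice.
#' @param z_index integer slice indices, strictly increasing.
#' @param spacing_um slice spacing (um); default the isotropic light-sheet
#'   spacing 0.1625.
#' @param object_id label.
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(slices, z_index = seq_along(slices),
                          spacing_um = 0.1625, object_id = "object") {
  if (!length(slices))
    .stop_class("contour stack needs >= 1 slice", "nedyn_geometry_error")
  if (length(z_index) != length(slices) || any(diff(z_index) <= 0))
    .stop_class("slice indices must be strictly increasing", "nedyn_geometry_error")
  if (spacing_um <= 0) .stop_class("spacing must be > 0", "nedyn_geometry_error")
  structure(list(slices = lapply(slices, as.matrix), z_index = as.integer(z_index),
                 spacing_um = spacing_um, object_id = object_id),
            class = "contour_stack")
}

#' Integrated volume of a contour stack
#'
#' Plain Riemann sum: the shoelace area of each slice polygon times the
#' slice spacing, summed over slices (no partial end-cap correction).
#'
#' @param stack a [contour_stack()].
#' @return volume (um^3).
#' @export
contour_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  areas <- vapply(seq_along(stack$slices), function(i) {
    tryCatch(polygon_area(stack$slices[[i]]), nedyn_error = function(e)
      .stop_class(sprintf("invalid polygon in slice %d (z index %d): %s",
                          i, stack$z_index[i], conditionMessage(e)),
                  "nedyn_geometry_error"))
  }, numeric(1))
  sum(areas) * stack$spacing_um
}

#' Theoretical sphere volume from the widest slice
#'
#' The largest slice area gives an equivalent radius sqrt(area / pi); the
#' theoretical volume is 4/3 pi r^3.
#'
#' @param stack a [contour_stack()].
#' @return volume (um^3).
#' @export
theoretical_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  areas <- vapply(stack$slices, polygon_area, numeric(1))
  r <- sqrt(max(areas) / pi)
  4 / 3 * pi * r^3
}

#' Sphericity check: integrated versus theoretical volume
#'
#' Compares the contour-integrated volume with the widest-slice theoretical
#' sphere volume; a nucleus traced well within 10% relative deviation is
#' considered spherical.
#'
#' @param stack a [contour_stack()].
#' @param tol_fraction acceptance bound on the relative deviation.
#' @return object of class `volume_result`: list with `v_integrated_um3`,
#'   `v_theoretical_um3`, `deviation` (relative), `within_10pct`.
#' @export
sphericity_check <- function(stack, tol_fraction = 0.10) {
  v_int <- contour_volume(stack)
  v_theo <- theoretical_volume(stack)
  dev <- abs(v_int - v_theo) / v_theo
  structure(list(v_integrated_um3 = v_int, v_theoretical_um3 = v_theo,
                 deviation = dev, within_10pct = dev <= tol_fraction),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> integrated %.2f um^3, theoretical %.2f um^3, deviation %.2f%% (within 10%%: %s)\n",
              x$v_integrated_um3, x$v_theoretical_um3, 100 * x$deviation,
              x$within_10pct))
  invisible(x)
}

#' Nuclear volume expansion rate by ordinary least squares
#'
#' Fits volume ~ time by OLS over the expansion phase; the slope is the
#' expansion rate.
#'
#' @param time_s times (s), >= 3 distinct values.
#' @param volume_um3 volumes (um^3).
#' @return list with `rate_um3_per_s`, `intercept_um3`, `r_squared`, `n`.
#' @export
growth_rate <- function(time_s, volume_um3) {
  ok <- is.finite(time_s) & is.finite(volume_um3)
  time_s <- time_s[ok]; volume_um3 <- volume_um3[ok]
  if (length(time_s) < 3 || length(unique(time_s)) < 3)
    .stop_class("need >= 3 points with distinct times", "nedyn_input_error")
  fit <- lm(volume_um3 ~ time_s)
  tss <- sum((volume_um3 - mean(volume_um3))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  list(rate_um3_per_s = unname(coef(fit)[2]),
       intercept_um3 = unname(coef(fit)[1]),
       r_squared = r2, n = length(time_s))
}
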