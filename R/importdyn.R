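#' Segment the nucleus in a single frame
#'
#' Replaces the manual chromatin trace with a reproducible global threshold:
#' the frame is thresholded (Otsu by default), components smaller than
#' `min_area_px` are removed, and the largest remaining connected component
#' is returned as a polygon [region_spec()] carrying its exact pixel mask.
#'
#' @param frame 2-D numeric matrix (y, x), non-constant.
#' @param method threshold method; currently `"otsu"`.
#' @param min_area_px minimum component area in pixels.
#' @return polygon `region_spec` with attributes `mask` (logical y-x
#'   matrix) and `area_px`.
#' @export
segment_nucleus <- function(frame, method = "otsu", min_area_px = 20) {
  if (!is.matrix(frame)) .stop_class("frame must be a 2-D matrix", "nedyn_input_error")
  rng <- range(frame)
  if (rng[1] == rng[2])
    .stop_class("constant frame: cannot threshold", "nedyn_segmentation_error")
  method <- match.arg(method, "otsu")
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(t(norm))  # EBImage dim order is (x, y)
  th <- EBImage::otsu(img)
  lbl <- EBImage::bwlabel(img > th)
  sizes <- table(as.integer(lbl[lbl > 0]))
  sizes <- sizes[sizes >= min_area_px]
  if (!length(sizes))
    .stop_class(sprintf("no component >= %d px above threshold %.4g",
                        min_area_px, th * (rng[2] - rng[1]) + rng[1]),
                "nedyn_segmentation_error")
  keep <- as.integer(names(sizes)[which.max(sizes)])
  mask_xy <- EBImage::imageData(lbl) == keep
  poly <- EBImage::ocontour(EBImage::Image(mask_xy * 1))[[1]]  # 0-based (x, y)
  region <- region_polygon(poly)
  attr(region, "mask") <- t(mask_xy)  # back to (y, x)
  attr(region, "area_px") <- sum(mask_xy)
  region
}

.box_values <- function(frame, box) {
  .check_region_in_frame(box, dim(frame))
  frame[(box$y + 1):(box$y + box$height), (box$x + 1):(box$x + box$width)]
}

.region_mask <- function(region, frame_dim) {
  m <- attr(region, "mask")
  if (!is.null(m)) return(m)
  if (region$kind == "box") {
    m <- matrix(FALSE, frame_dim[1], frame_dim[2])
    m[(region$y + 1):(region$y + region$height),
      (region$x + 1):(region$x + region$width)] <- TRUE
    return(m)
  }
  v <- region$vertices
  xs <- rep(0:(frame_dim[2] - 1), each = frame_dim[1])
  ys <- rep(0:(frame_dim[1] - 1), times = frame_dim[2])
  matrix(.points_in_polygon(xs, ys, v), frame_dim[1], frame_dim[2])
}

# even-odd rule, vectorized over query points; vertices 0-based (x, y)
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Background-corrected nucleocytoplasmic ratio scaled by nuclear area
#'
#' Computes N = mean reporter intensity inside the nucleus, C = mean inside
#' the cytoplasm box, bg = mean inside the camera-background box, and
#' returns ((N - bg) / (C - bg)) multiplied by the nuclear area. The camera
#' offset cancels in the subtraction and any uniform gain cancels in the
#' ratio, so the value depends only on the underlying contrast and the
#' nuclear area.
#'
#' @param frame 2-D numeric matrix (y, x).
#' @param nucleus nucleus [region_spec()] (polygon from [segment_nucleus()]
#'   or user-supplied).
#' @param cyto_box,bg_box [region_box()] regions for cytoplasm and camera
#'   background; must not overlap the nucleus.
#' @param pixel_size_um pixel size (um).
#' @param area_units `"um2"` (default) scales by physical area;
#'   `"pixel"` by pixel count.
#' @return list with `nc_value`, `ratio` (bare (N-bg)/(C-bg)), `N`, `C`,
#'   `bg`, `area_um2`, `area_px`.
#' @export
nc_ratio <- function(frame, nucleus, cyto_box, bg_box, pixel_size_um,
                     area_units = c("um2", "pixel")) {
  area_units <- match.arg(area_units)
  mask <- .region_mask(nucleus, dim(frame))
  if (!any(mask)) .stop_class("empty nucleus region", "nedyn_input_error")
  for (box in list(cyto_box, bg_box)) {
    bm <- .region_mask(box, dim(frame))
    if (any(bm & mask))
      .stop_class("cytoplasm/background box overlaps the nucleus",
                  "nedyn_config_error")
  }
  N <- mean(frame[mask])
  C <- mean(.box_values(frame, cyto_box))
  bg <- mean(.box_values(frame, bg_box))
  if (C <= bg)
    .stop_class("degenerate contrast: cytoplasm mean <= background mean",
                "nedyn_contrast_error")
  area_px <- sum(mask)
  area_um2 <- area_px * pixel_size_um^2
  ratio <- (N - bg) / (C - bg)
  area <- if (area_units == "um2") area_um2 else area_px
  list(nc_value = ratio * area, ratio = ratio, N = N, C = C, bg = bg,
       area_um2 = area_um2, area_px = area_px)
}

#' Per-frame import trace from a two-channel stack
#'
#' For each time point the nucleus is segmented on the chromatin channel
#' (maximum z projection) and [nc_ratio()] is evaluated on the reporter
#' channel. Times are reported relative to the anchor event frame. Isolated
#' segmentation failures yield missing values; failure on more than half the
#' frames aborts.
#'
#' @param stack two-channel [image_stack()].
#' @param reporter_channel,chromatin_channel channel indices or labels.
#' @param anchor list with `event` (name, e.g. `"furrow"`, `"anaphase"`,
#'   `"pc_regression"`) and `frame` (1-based index of the event).
#' @param cyto_box,bg_box [region_box()] regions (see [nc_ratio()]).
#' @param min_area_px passed to [segment_nucleus()].
#' @param area_units passed to [nc_ratio()].
#' @return object of class `import_trace`: data frame with columns `frame`,
#'   `time_s`, `N`, `C`, `bg`, `area_um2`, `ratio`, `nc_value`, plus
#'   attributes `anchor_event`, `anchor_frame`.
#' @export
import_trace <- function(stack, reporter_channel = "reporter",
                         chromatin_channel = "chromatin",
                         anchor = list(event = "anaphase", frame = 1),
                         cyto_box, bg_box, min_area_px = 20,
                         area_units = "um2") {
  stopifnot(inherits(stack, "image_stack"))
  chan_idx <- function(ch) {
    if (is.character(ch)) match(ch, stack$channels) else as.integer(ch)
  }
  rc <- chan_idx(reporter_channel); cc <- chan_idx(chromatin_channel)
  if (is.na(rc) || is.na(cc)) .stop_class("unknown channel", "nedyn_config_error")
  n_frames <- dim(stack$pixels)[1]
  if (anchor$frame < 1 || anchor$frame > n_frames)
    .stop_class("anchor frame outside the stack", "nedyn_input_error")
  zproj <- function(t, ch) {
    sl <- stack$pixels[t, , , , ch, drop = FALSE]
    apply(array(sl, dim(stack$pixels)[2:4]), c(2, 3), max)
  }
  rows <- lapply(seq_len(n_frames), function(t) {
    res <- tryCatch({
      nuc <- segment_nucleus(zproj(t, cc), min_area_px = min_area_px)
      nc_ratio(zproj(t, rc), nuc, cyto_box, bg_box,
               pixel_size_um = stack$pixel_size_um, area_units = area_units)
    }, nedyn_segmentation_error = function(e) NULL)
    if (is.null(res))
      data.frame(frame = t, N = NA_real_, C = NA_real_, bg = NA_real_,
                 area_um2 = NA_real_, ratio = NA_real_, nc_value = NA_real_)
    else
      data.frame(frame = t, N = res$N, C = res$C, bg = res$bg,
                 area_um2 = res$area_um2, ratio = res$ratio,
                 nc_value = res$nc_value)
  })
  df <- do.call(rbind, rows)
  if (mean(is.na(df$nc_value)) > 0.5)
    .stop_class("segmentation failed on more than half of the frames",
                "nedyn_trace_error")
  df <- cbind(frame = df$frame,
              time_s = (df$frame - anchor$frame) * stack$time_step_s,
              df[, -1, drop = FALSE])
  structure(df, class = c("import_trace", "data.frame"),
            anchor_event = anchor$event, anchor_frame = anchor$frame)
}

#' Detect the onset of nuclear import in a trace
#'
#' Onset is the first time at which `nc_value` exceeds the baseline mean
#' plus `k_sd` baseline standard deviations for `persistence` consecutive
#' frames; the baseline is the first `baseline_n` points.
#'
#' @param trace an [import_trace()] (or data frame with `time_s`,
#'   `nc_value`).
#' @param baseline_n number of baseline points.
#' @param k_sd threshold multiplier.
#' @param persistence required consecutive frames above threshold.
#' @return onset time (s), or `NA_real_` if the threshold is never
#'   exceeded persistently.
#' @export
detect_onset <- function(trace, baseline_n = 3, k_sd = 3, persistence = 2) {
  v <- trace$nc_value; tm <- trace$time_s
  if (length(v) < baseline_n + persistence)
    .stop_class("trace too short for onset detection", "nedyn_input_error")
  base <- v[seq_len(baseline_n)]
  if (anyNA(base)) .stop_class("missing values in the baseline", "nedyn_input_error")
  thr <- mean(base) + k_sd * sd(base)
  above <- !is.na(v) & v > thr
  for (i in (baseline_n + 1):(length(v) - persistence + 1)) {
    if (all(above[i:(i + persistence - 1)])) return(tm[i])
  }
  NA_real_
}

#' Min-max normalize traces and difference the condition average
#'
#' Each trace is rescaled to \[0, 1\] over its own range, traces are
#' averaged pointwise on their common time grid, and the per-interval first
#' differences of the average are returned; the difference curve highlights
#' shifts in the onset of accumulation between conditions.
#'
#' @param traces list of [import_trace()] objects (or data frames with
#'   `time_s`, `nc_value`) sharing a strictly increasing time grid.
#' @return list with `time_s`, `avg_normalized`, `diff_time_s` (interval
#'   end times) and `differences`. Intervals touching a missing value are
#'   `NA`.
#' @export
normalize_and_difference <- function(traces) {
  if (!length(traces)) .stop_class("need at least one trace", "nedyn_input_error")
  grid <- traces[[1]]$time_s
  if (any(diff(grid) <= 0))
    .stop_class("time grid must be strictly increasing", "nedyn_input_error")
  norm <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (!isTRUE(all.equal(tr$time_s, grid)))
      .stop_class("traces are not on a common time grid", "nedyn_input_error")
    v <- tr$nc_value
    rng <- range(v, na.rm = TRUE)
    if (rng[1] == rng[2])
      .stop_class(sprintf("trace %d is constant and cannot be normalized", i),
                  "nedyn_normalization_error")
    (v - rng[1]) / (rng[2] - rng[1])
  })
  avg <- rowMeans(do.call(cbind, norm))
  list(time_s = grid, avg_normalized = avg,
       diff_time_s = grid[-1], differences = diff(avg))
}
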