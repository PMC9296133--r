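#' Simulate a two-channel embryo time-lapse with nuclear import
#'
#' Emulates the structure of the live assay: a reporter channel in which a
#' growing nuclear disk accumulates signal above a constant cytoplasm, and a
#' chromatin channel marking the nucleus for segmentation. The embryo is a
#' disk of cytoplasm on camera background; the nucleus grows linearly in
#' radius and its excess reporter intensity follows the saturating
#' exponential N(t) = C * F * (1 - exp(-k_in * (t - t0))) above the
#' cytoplasmic level, so the true nucleocytoplasmic ratio is
#' 1 + F * (1 - exp(-k_in * (t - t0))).
#'
#' Intensities are rounded to integer camera counts (negative noise draws
#' clipped at zero), so stacks round-trip exactly through [write_stack()].
#'
#' @param n_frames number of time points.
#' @param time_step_s frame interval (s).
#' @param img_px image side length (pixels, square frames).
#' @param pixel_size_um pixel size (um).
#' @param r0_um initial nuclear radius (um).
#' @param growth_um_per_s linear radial growth rate (um/s).
#' @param cyto_mean cytoplasmic mean intensity above camera background.
#' @param bg_offset additive camera background (counts).
#' @param k_in import rate constant (1/s).
#' @param plateau plateau factor F (true ratio saturates at 1 + F).
#' @param import_start_frame frame at which import begins (1-based).
#' @param chromatin_mean chromatin-channel intensity inside the nucleus.
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param seed RNG seed; identical parameters give identical output.
#' @return list with `stack` (two-channel [image_stack()], channels
#'   `reporter`, `chromatin`), `truth` (per-frame data frame: `frame`,
#'   `time_s`, `radius_um`, `area_um2`, `ratio_true`, `nc_value_true`), and
#'   `cyto_box`/`bg_box` ([region_box()]) placed in cytoplasm and vacant
#'   background.
#' @export
gen_embryo_timelapse <- function(n_frames = 60, time_step_s = 20,
                                 img_px = 128, pixel_size_um = 0.2,
                                 r0_um = 2, growth_um_per_s = 0.002,
                                 cyto_mean = 100, bg_offset = 50,
                                 k_in = 0.02, plateau = 3,
                                 import_start_frame = 1,
                                 chromatin_mean = 300,
                                 noise_sd = 0, seed = 1) {
  stopifnot(n_frames >= 1, time_step_s > 0, r0_um > 0, growth_um_per_s >= 0,
            cyto_mean >= 0, bg_offset >= 0, k_in >= 0, plateau >= 0,
            noise_sd >= 0)
  times <- (seq_len(n_frames) - 1) * time_step_s
  radius_um <- r0_um + growth_um_per_s * times
  r_px <- radius_um / pixel_size_um
  embryo_r <- 0.42 * img_px
  cx <- (img_px - 1) / 2; cy <- cx
  if (max(r_px) >= embryo_r - 2)
    .stop_class("nucleus would exceed the embryo/frame; reduce growth or frames",
                "nedyn_param_error")
  t0 <- (import_start_frame - 1) * time_step_s
  excess <- ifelse(times >= t0,
                   cyto_mean * plateau * (1 - exp(-k_in * (times - t0))), 0)
  ratio_true <- 1 + excess / cyto_mean
  set.seed(seed)
  xs <- matrix(rep(0:(img_px - 1), each = img_px), img_px)   # x per column
  ys <- matrix(rep(0:(img_px - 1), times = img_px), img_px)  # y per row
  d2 <- (xs - cx)^2 + (ys - cy)^2
  embryo <- d2 <= embryo_r^2
  arr <- array(0, c(n_frames, 1, img_px, img_px, 2))
  for (f in seq_len(n_frames)) {
    nuc <- d2 <= r_px[f]^2
    rep_ch <- bg_offset + cyto_mean * embryo + excess[f] * nuc
    chr_ch <- bg_offset + chromatin_mean * nuc
    if (noise_sd > 0) {
      rep_ch <- rep_ch + rnorm(length(rep_ch), 0, noise_sd)
      chr_ch <- chr_ch + rnorm(length(chr_ch), 0, noise_sd)
    }
    arr[f, 1, , , 1] <- round(pmax(rep_ch, 0))
    arr[f, 1, , , 2] <- round(pmax(chr_ch, 0))
  }
  stack <- image_stack(arr, channels = c("reporter", "chromatin"),
                       pixel_size_um = pixel_size_um, time_step_s = time_step_s)
  area_um2 <- pi * radius_um^2
  truth <- data.frame(frame = seq_len(n_frames), time_s = times,
                      radius_um = radius_um, area_um2 = area_um2,
                      ratio_true = ratio_true,
                      nc_value_true = ratio_true * area_um2)
  # boxes: cytoplasm midway between the widest nucleus and the embryo edge,
  # background in the top-left corner outside the embryo
  bw <- max(8L, round(img_px / 10))
  gx <- round(cx + (max(r_px) + embryo_r) / 2 - bw / 2)
  cyto_box <- region_box(gx, round(cy - bw / 2), bw, bw)
  bg_box <- region_box(1, 1, bw, bw)
  list(stack = stack, truth = truth, cyto_box = cyto_box, bg_box = bg_box)
}

#' Simulate a FRAP recovery series
#'
#' Prebleach frames sit at `prebleach_value`; post-bleach intensity follows
#' depth + (1 - depth) * A * (1 - exp(-tau * t)) on the prebleach scale,
#' plus Gaussian noise (negative draws clipped at 0). With the default full
#' bleach (depth 0) the post-bleach signal is the printed recovery model
#' f(t) = A * (1 - exp(-tau * t)).
#'
#' @param A true mobile fraction in \[0, 1\].
#' @param tau true recovery rate (1/s), > 0.
#' @param n_prebleach number of prebleach frames (>= 1).
#' @param n_post number of post-bleach frames (>= 4).
#' @param bleach_depth fraction of prebleach signal remaining at t = 0,
#'   in \[0, 1).
#' @param time_step_s frame interval (s).
#' @param prebleach_value raw prebleach intensity scale.
#' @param noise_sd Gaussian noise sd on the prebleach scale.
#' @param seed RNG seed.
#' @return data frame with columns `time_s` (relative to bleach; prebleach
#'   frames negative), `intensity`, `phase` (`"pre"`/`"post"`).
#' @export
gen_frap_curve <- function(A, tau, n_prebleach = 3, n_post = 60,
                           bleach_depth = 0, time_step_s = 10,
                           prebleach_value = 1, noise_sd = 0, seed = 1) {
  if (A < 0 || A > 1) .stop_class("A must be in [0, 1]", "nedyn_param_error")
  if (tau <= 0) .stop_class("tau must be > 0", "nedyn_param_error")
  if (bleach_depth < 0 || bleach_depth >= 1)
    .stop_class("bleach_depth must be in [0, 1)", "nedyn_param_error")
  if (n_post < 4)
    .stop_class("need >= 4 post-bleach frames for a downstream fit",
                "nedyn_param_error")
  if (n_prebleach < 1) .stop_class("need >= 1 prebleach frame", "nedyn_param_error")
  set.seed(seed)
  t_pre <- -rev(seq_len(n_prebleach)) * time_step_s
  t_post <- (seq_len(n_post) - 1) * time_step_s
  model <- bleach_depth + (1 - bleach_depth) * A * (1 - exp(-tau * t_post))
  y <- c(rep(1, n_prebleach), model) * prebleach_value
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd * prebleach_value)
  data.frame(time_s = c(t_pre, t_post), intensity = pmax(y, 0),
             phase = rep(c("pre", "post"), c(n_prebleach, n_post)))
}

#' Generate traced contours of a near-spherical nucleus
#'
#' For every z plane intersecting a sphere of the given radius, a regular
#' `n_vertices`-gon inscribed in the circle of intersection, each vertex
#' radially perturbed by at most `jitter_um`. The slice grid is anchored at
#' the equator (z = k * z_step_um including k = 0), so no slice is tangent.
#'
#' @param radius_um sphere radius (um), > 0.
#' @param z_step_um slice spacing (um); default the isotropic light-sheet
#'   spacing 0.1625.
#' @param n_vertices vertices per contour (>= 8).
#' @param jitter_um maximum radial perturbation per vertex (um).
#' @param seed RNG seed (used only when `jitter_um > 0`).
#' @return A [contour_stack()].
#' @export
gen_sphere_contours <- function(radius_um, z_step_um = 0.1625,
                                n_vertices = 256, jitter_um = 0, seed = 1) {
  if (radius_um <= 0) .stop_class("radius must be > 0", "nedyn_param_error")
  if (n_vertices < 8) .stop_class("need >= 8 vertices", "nedyn_param_error")
  if (z_step_um >= 2 * radius_um)
    .stop_class("z_step >= sphere diameter: no interior slice", "nedyn_param_error")
  set.seed(seed)
  kmax <- ceiling(radius_um / z_step_um)
  ks <- (-kmax):kmax
  ks <- ks[abs(ks * z_step_um) < radius_um]  # strict: drop tangent planes
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  slices <- lapply(ks, function(k) {
    rho <- sqrt(radius_um^2 - (k * z_step_um)^2)
    r_v <- rho + if (jitter_um > 0) runif(n_vertices, -jitter_um, jitter_um) else 0
    cbind(x = r_v * cos(theta), y = r_v * sin(theta))
  })
  contour_stack(slices, z_index = ks, spacing_um = z_step_um,
                object_id = "synthetic_sphere")
}

#' Generate a membrane trace interrupted by gaps of known widths
#'
#' Lays membrane segments of length `flank_nm` along a straight line,
#' separated by gaps of the requested widths, and records the ground truth
#' for each gap. Edges of a tapered gap stay collinear with the flank
#' (terminal perpendicular spread ~ 0); edges of an untapered ("blunt") gap
#' hook away perpendicular to the membrane by `hook_nm` over the terminal 4
#' vertices, emulating a recurved free edge rather than an inner/outer
#' membrane fusion point.
#'
#' @param gap_widths_nm numeric vector of gap widths (nm); may be empty.
#' @param tapered logical vector, one per gap (recycled if length 1).
#' @param flank_nm length of every membrane segment (nm); each gap therefore
#'   has continuous flanks of this arc length on both sides.
#' @param field_area_um2 traced region area (um^2), recorded for densities.
#' @param vertex_spacing_nm spacing of polyline vertices (nm).
#' @param hook_nm perpendicular excursion of blunt edges (nm).
#' @param jitter_nm perpendicular Gaussian jitter on non-terminal vertices.
#' @param seed RNG seed.
#' @return list with `trace` (a [membrane_trace()]) and `truth` (per-gap
#'   data frame: `gap_id`, `width_nm`, `tapered`, `flank_left_nm`,
#'   `flank_right_nm`).
#' @export
gen_membrane_field <- function(gap_widths_nm = numeric(0), tapered = TRUE,
                               flank_nm = 300, field_area_um2 = 0.1,
                               vertex_spacing_nm = 10, hook_nm = 50,
                               jitter_nm = 0, seed = 1) {
  n_gaps <- length(gap_widths_nm)
  tapered <- rep_len(as.logical(tapered), max(n_gaps, 1))[seq_len(n_gaps)]
  if (any(gap_widths_nm <= 0)) .stop_class("gap widths must be > 0", "nedyn_param_error")
  if (flank_nm < 2 * vertex_spacing_nm)
    .stop_class("flank too short for the vertex spacing", "nedyn_param_error")
  if (field_area_um2 <= 0) .stop_class("field area must be > 0", "nedyn_param_error")
  set.seed(seed)
  chains <- list()
  x0 <- 0
  hook_ramp <- function(n_hook) hook_nm * (seq_len(n_hook) - 1) / (n_hook - 1)
  for (i in seq_len(n_gaps + 1)) {
    xs <- seq(x0, x0 + flank_nm, by = vertex_spacing_nm)
    if (xs[length(xs)] < x0 + flank_nm) xs <- c(xs, x0 + flank_nm)
    ys <- rep(0, length(xs))
    if (jitter_nm > 0) {
      mid <- seq_along(ys) > 4 & seq_along(ys) < length(ys) - 3
      ys[mid] <- rnorm(sum(mid), 0, jitter_nm)
    }
    n_hook <- min(4L, length(ys))
    # right end of this segment faces gap i (if any) and hooks when blunt
    if (i <= n_gaps && !tapered[i])
      ys[(length(ys) - n_hook + 1):length(ys)] <- hook_ramp(n_hook)
    # left end faces gap i-1
    if (i > 1 && !tapered[i - 1])
      ys[seq_len(n_hook)] <- ys[seq_len(n_hook)] + rev(hook_ramp(n_hook))
    chains[[i]] <- cbind(x = xs, y = ys)
    x0 <- x0 + flank_nm + if (i <= n_gaps) gap_widths_nm[i] else 0
  }
  truth <- data.frame(gap_id = seq_len(n_gaps),
                      width_nm = gap_widths_nm,
                      tapered = tapered,
                      flank_left_nm = rep(flank_nm, n_gaps),
                      flank_right_nm = rep(flank_nm, n_gaps))
  list(trace = membrane_trace(chains, area_um2 = field_area_um2,
                              label = "synthetic_field"),
       truth = truth)
}
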