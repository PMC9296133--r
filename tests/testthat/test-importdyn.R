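make_disk_frame <- function(img_px = 64, r_px = 20, fg = 200, bg = 50,
                            noise_sd = 0, seed = 1, cx = NULL, cy = NULL) {
  set.seed(seed)
  if (is.null(cx)) cx <- (img_px - 1) / 2
  if (is.null(cy)) cy <- (img_px - 1) / 2
  m <- matrix(bg, img_px, img_px)
  m[disk_mask(img_px, cx, cy, r_px)] <- fg
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  m
}

test_that("segmentation recovers a noisy synthetic disk with high overlap", {
  frame <- make_disk_frame(noise_sd = 5, seed = 4)
  region <- segment_nucleus(frame)
  mask <- attr(region, "mask")
  truth <- disk_mask(64, 31.5, 31.5, 20)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gt(iou, 0.9)
  # polygon vertices stay inside the frame in 0-based coordinates
  v <- region$vertices
  expect_true(all(v >= 0 & v <= 63))
})

test_that("segmentation picks the largest component and flags degenerate input", {
  frame <- matrix(50, 96, 96)
  frame[disk_mask(96, 30, 48, 20)] <- 200
  frame[disk_mask(96, 75, 48, 8)] <- 200
  region <- segment_nucleus(frame)
  expect_equal(attr(region, "area_px"), sum(disk_mask(96, 30, 48, 20)))
  expect_error(segment_nucleus(matrix(7, 32, 32)),
               class = "nedyn_segmentation_error")
  # everything below min_area_px
  tiny <- matrix(50, 32, 32); tiny[16, 16] <- 200
  expect_error(segment_nucleus(tiny, min_area_px = 20),
               class = "nedyn_segmentation_error")
})

test_that("nc_ratio computes the background-corrected area-scaled ratio", {
  # N = 200, C = 100, bg = 50; nuclear area 100 um^2 -> value 300 um^2
  img <- matrix(50, 80, 80)                      # camera background
  img[21:60, 21:60] <- 100                       # cytoplasm
  img[31:50, 31:50] <- 200                       # 20 x 20 px nucleus
  nucleus <- region_box(30, 30, 20, 20)          # 0-based
  cyto <- region_box(22, 22, 6, 6)
  bg <- region_box(2, 2, 10, 10)
  res <- nc_ratio(img, nucleus, cyto, bg, pixel_size_um = 0.5)
  expect_equal(res$N, 200); expect_equal(res$C, 100); expect_equal(res$bg, 50)
  expect_equal(res$area_um2, 400 * 0.25)         # 100 um^2
  expect_equal(res$nc_value, 300)
  expect_equal(res$ratio, 3)
  # pixel-area variant
  expect_equal(nc_ratio(img, nucleus, cyto, bg, 0.5,
                        area_units = "pixel")$nc_value, 3 * 400)
})

test_that("nc_ratio is invariant to camera offset and uniform gain", {
  img <- matrix(60, 80, 80)
  img[21:60, 21:60] <- 110
  img[31:50, 31:50] <- 230
  nucleus <- region_box(30, 30, 20, 20)
  cyto <- region_box(22, 22, 6, 6)
  bg <- region_box(2, 2, 10, 10)
  base <- nc_ratio(img, nucleus, cyto, bg, 0.5)$nc_value
  shifted <- nc_ratio(img + 10, nucleus, cyto, bg, 0.5)$nc_value
  scaled <- nc_ratio(img * 3.7, nucleus, cyto, bg, 0.5)$nc_value
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-12)
  # uniform image: ratio exactly 1, value = area
  flat <- matrix(80, 80, 80); flat[2:13, 2:13] <- 60  # bg box darker
  r <- nc_ratio(flat, nucleus, cyto, region_box(2, 2, 10, 10), 0.5)
  expect_equal(r$ratio, 1)
  expect_equal(r$nc_value, r$area_um2)
})

test_that("nc_ratio rejects degenerate contrast and overlapping regions", {
  img <- matrix(50, 80, 80); img[31:50, 31:50] <- 200
  nucleus <- region_box(30, 30, 20, 20)
  expect_error(nc_ratio(img, nucleus, region_box(2, 2, 6, 6),
                        region_box(60, 60, 10, 10), 0.5),
               class = "nedyn_contrast_error")
  expect_error(nc_ratio(img, nucleus, region_box(35, 35, 6, 6),
                        region_box(2, 2, 6, 6), 0.5),
               class = "nedyn_config_error")
})

test_that("import traces recover the generator truth frame by frame", {
  g <- gen_embryo_timelapse(n_frames = 20, noise_sd = 0)
  tr <- import_trace(g$stack, anchor = list(event = "furrow", frame = 4),
                     cyto_box = g$cyto_box, bg_box = g$bg_box)
  expect_equal(tr$time_s[1], -60)  # (1 - 4) * 20 s
  rel_ratio <- abs(tr$ratio - g$truth$ratio_true) / g$truth$ratio_true
  expect_true(all(rel_ratio < 0.05))
  rel_nc <- abs(tr$nc_value - g$truth$nc_value_true) / g$truth$nc_value_true
  expect_true(all(rel_nc < 0.05))
  expect_error(import_trace(g$stack, anchor = list(event = "furrow", frame = 99),
                            cyto_box = g$cyto_box, bg_box = g$bg_box),
               class = "nedyn_input_error")
})

test_that("onset detection finds a constructed step and ignores flat traces", {
  step2 <- data.frame(time_s = seq(0, 160, 20),
                      nc_value = c(100, 101, 99, 200, 210, 220, 230, 240, 250))
  expect_equal(detect_onset(step2, baseline_n = 3), 60)
  # with the spec's constructed example: flat baseline of 5 then a step
  tr <- data.frame(time_s = seq(0, 140, 20),
                   nc_value = c(100, 101, 99, 100, 101, 200, 205, 210))
  expect_equal(detect_onset(tr, baseline_n = 5), 100)
  flat <- data.frame(time_s = seq(0, 140, 20), nc_value = rep(100, 8))
  expect_true(is.na(detect_onset(flat)))
  expect_error(detect_onset(flat[1:3, ]), class = "nedyn_input_error")
})

test_that("onset detection is monotone in the threshold multiplier", {
  g <- gen_embryo_timelapse(n_frames = 40, import_start_frame = 10,
                            noise_sd = 2, seed = 13)
  tr <- import_trace(g$stack, anchor = list(event = "anaphase", frame = 1),
                     cyto_box = g$cyto_box, bg_box = g$bg_box)
  onsets <- vapply(c(1, 2, 3, 5, 8), function(k)
    detect_onset(tr, baseline_n = 5, k_sd = k), numeric(1))
  expect_true(all(diff(onsets[!is.na(onsets)]) >= 0))
  # and accurate to +/- 1 frame at the default threshold
  onset <- detect_onset(tr, baseline_n = 5)
  truth_t <- (10 - 1) * 20
  expect_lte(abs(onset - truth_t), 20)
})

test_that("normalization and differencing follow the printed recipe", {
  t3 <- data.frame(time_s = c(0, 20, 40), nc_value = c(0, 50, 100))
  nd <- normalize_and_difference(list(t3))
  expect_equal(nd$avg_normalized, c(0, 0.5, 1))
  expect_equal(nd$differences, c(0.5, 0.5))
  # averaging identity for identical traces
  nd2 <- normalize_and_difference(list(t3, t3))
  expect_equal(nd2$avg_normalized, nd$avg_normalized)
  # different scales normalize to the same curve
  a <- data.frame(time_s = c(0, 20), nc_value = c(0, 100))
  b <- data.frame(time_s = c(0, 20), nc_value = c(0, 200))
  nd3 <- normalize_and_difference(list(a, b))
  expect_equal(nd3$avg_normalized, c(0, 1))
  expect_equal(nd3$differences, 1)
  flat <- data.frame(time_s = c(0, 20), nc_value = c(5, 5))
  expect_error(normalize_and_difference(list(flat)),
               class = "nedyn_normalization_error")
})
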