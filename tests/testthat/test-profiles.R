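# image with a vertical Gaussian ridge (a nuclear rim crossed perpendicularly)
ridge_image <- function(nx = 101, ny = 41, x0 = 50, amp = 100, bg = 10,
                        sd_px = 3, cyto = 0, nucleo = 0) {
  xs <- matrix(rep(0:(nx - 1), each = ny), ny)
  img <- bg + amp * exp(-(xs - x0)^2 / (2 * sd_px^2))
  img[, seq_len(x0 - 10)] <- img[, seq_len(x0 - 10)] + cyto
  if (nucleo > 0) img[, (x0 + 12):nx] <- img[, (x0 + 12):nx] + nucleo
  img
}

test_that("profile extraction samples the image along a wide line", {
  const <- matrix(7, 30, 30)
  p <- extract_profile(const, c(2, 15), c(27, 15), width_px = 3,
                       pixel_size_um = 0.1)
  expect_true(all(p$value == 7))
  expect_equal(p$pos_um, (0:25) * 0.1)
  # a bright column crossed perpendicularly gives one peak at the crossing
  img <- matrix(0, 30, 30); img[, 16] <- 50
  p2 <- extract_profile(img, c(5, 14), c(25, 14), width_px = 1,
                        pixel_size_um = 1)
  expect_equal(which.max(p2$value), 11)  # x = 15, sample 11 from x = 5
  expect_equal(sum(p2$value > 0), 1)
  expect_error(extract_profile(const, c(2, 15), c(40, 15), 3, 0.1),
               class = "nedyn_geometry_error")
  expect_error(extract_profile(const, c(2, 15), c(27, 15), width_px = 2,
                               pixel_size_um = 0.1),
               class = "nedyn_input_error")
})

test_that("a synthetic rim peak position is recovered within one pixel", {
  img <- ridge_image()
  p <- extract_profile(img, c(20, 20), c(80, 20), width_px = 3,
                       pixel_size_um = 0.1)
  peak_pos_px <- p$pos_um[which.max(p$value)] / 0.1 + 20
  expect_lte(abs(peak_pos_px - 50), 1)
})

test_that("perpendicular averaging is a commutative, idempotent pointwise mean", {
  img <- ridge_image()
  a <- extract_profile(img, c(20, 20), c(80, 20), 3, 0.1)
  b <- a; b$value <- rev(b$value)
  ab <- perpendicular_average(a, b)
  ba <- perpendicular_average(b, a)
  expect_equal(ab$value, (a$value + b$value) / 2)
  expect_equal(ab$value, ba$value)
  expect_equal(perpendicular_average(a, a)$value, a$value)
  expect_error(perpendicular_average(a, a[1:5, ]), class = "nedyn_input_error")
})

test_that("end-point background correction and max normalization behave as printed", {
  prof <- structure(data.frame(pos_um = 0:4, value = c(1, 1, 5, 1, 1)),
                    class = c("line_profile", "data.frame"), steps = "raw")
  bc <- background_correct(prof, n_end = 2)
  expect_equal(bc$value, c(0, 0, 4, 0, 0))
  flat <- prof; flat$value <- rep(3, 5)
  expect_equal(background_correct(flat, 2)$value, rep(0, 5))
  expect_error(background_correct(prof[1:4, ], n_end = 2),
               class = "nedyn_input_error")
  nm <- normalize_max(structure(data.frame(pos_um = 0:2, value = c(0, 2, 4)),
                                class = c("line_profile", "data.frame"),
                                steps = "raw"))
  expect_equal(nm$value, c(0, 0.5, 1))
  expect_equal(normalize_max(nm)$value, nm$value)  # idempotent
  zero <- nm; zero$value <- rep(0, 3)
  expect_error(normalize_max(zero), class = "nedyn_normalization_error")
})

test_that("NE ratios divide the peak by the flank means", {
  v <- c(0.2, 0.2, 0.2, 0.2, 0.2, 0.6, 1.0, 0.6, 0.5, 0.5, 0.5, 0.5, 0.5)
  prof <- structure(data.frame(pos_um = seq_along(v) - 1, value = v),
                    class = c("line_profile", "data.frame"), steps = "raw")
  r <- ne_ratios(prof, n_flank = 5)
  expect_equal(r$ne_value, 1.0)
  expect_equal(r$ne_cytoplasm, 5.0)
  expect_equal(r$ne_nucleoplasm, 2.0)
  flat <- prof; flat$value <- rep(1, length(v))
  rf <- ne_ratios(flat, 5)
  expect_equal(rf$ne_cytoplasm, 1)
  expect_equal(rf$ne_nucleoplasm, 1)
  zero <- prof; zero$value[1:5] <- 0
  expect_error(ne_ratios(zero, 5), class = "nedyn_ratio_error")
})

test_that("a 4:1 rim-to-cytoplasm contrast yields an NE:cytoplasm ratio of 4", {
  # rim peak 200 over a 50-count cytoplasmic plateau, no camera offset
  img <- ridge_image(amp = 150, bg = 50)
  p <- extract_profile(img, c(25, 20), c(75, 20), 3, 0.1)
  r <- ne_ratios(normalize_max(p), n_flank = 5)
  expect_equal(r$ne_cytoplasm, 4, tolerance = 0.05)
})

test_that("overlay comparison reports the peak offset in physical units", {
  img <- ridge_image()
  a <- extract_profile(img, c(20, 20), c(80, 20), 3, 0.1)
  b <- a; b$value <- c(b$value[-(1:3)], b$value[1:3])  # shift peak by 3 samples
  res <- overlay_compare(a, b)
  expect_equal(res$offset_um, 0.3)
  expect_equal(overlay_compare(a, a)$offset_um, 0)
  flat <- a; flat$value <- rep(1, nrow(a))
  expect_error(overlay_compare(a, flat), class = "nedyn_degenerate_error")
})

test_that("background correction + normalization is invariant to affine intensity maps", {
  img <- ridge_image()
  pipeline <- function(im) {
    p <- extract_profile(im, c(20, 20), c(80, 20), 3, 0.1)
    normalize_max(background_correct(p, 2))$value
  }
  base <- pipeline(img)
  expect_equal(pipeline(img * 2.5 + 40), base, tolerance = 1e-12)
})

test_that("rim line-scan presets run the full printed recipes", {
  img <- ridge_image(nx = 101, ny = 101, x0 = 50)
  ln <- list(p1 = c(20, 50), p2 = c(80, 50))
  two <- rim_linescan(img, ln$p1, ln$p2, preset = "twocell",
                      pixel_size_um = 0.1)
  expect_true("background_correct" %in% attr(two, "steps"))
  iff <- rim_linescan(img, ln$p1, ln$p2, preset = "if", pixel_size_um = 0.1,
                      camera_bg = 10)
  expect_equal(max(iff$value), 1)
  expect_true(!is.null(attr(iff, "ratios")))
})
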