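test_that("white top-hat flattens constants and isolates small bright features", {
  expect_true(all(tophat_transform(matrix(37, 20, 20), 3) == 0))
  # interior spike of height s on constant background survives at full height
  m <- matrix(10, 21, 21)
  m[11, 11] <- 10 + 55
  th <- tophat_transform(m, 2)
  expect_equal(th[11, 11], 55)
  expect_true(all(th[-11, ] == 0) && all(th[11, -11] == 0))
})

test_that("top-hat retains a Gaussian spot on a linear ramp, suppressing the ramp", {
  ny <- 41; nx <- 41
  ramp <- matrix(rep(seq(0, 40, length.out = nx), each = ny), ny, nx)
  img <- add_gauss(ramp, 21, 21, amp = 100, sigma = 1.5)
  th <- tophat_transform(img, 5)
  expect_equal(th[21, 21], 100, tolerance = 0.05)
  # far from the spot only the opening residual of the ramp remains, which is
  # bounded by the ramp rise across one structuring element
  far <- th[1:10, 1:10]
  expect_true(max(far) <= 40 / (nx - 1) * 10 + 1e-9)
  expect_true(all(th >= 0))
})

test_that("top-hat agrees exactly with the brute-force opening oracle", {
  set.seed(101)
  for (n in c(16, 32)) {
    for (r in c(1, 3, 5)) {
      img <- matrix(runif(n * n, 0, 100), n, n)
      expect_equal(tophat_transform(img, r), brute_tophat(img, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("isodata threshold hits the intermeans fixed point", {
  expect_equal(isodata_threshold(c(rep(10, 50), rep(20, 50))), 15)
  expect_equal(isodata_threshold(c(rep(0, 90), rep(100, 10))), 50)
  expect_error(isodata_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("kinetochore mask covers spots, avoids background, ignores offsets", {
  set.seed(7)
  n <- 200
  img <- matrix(5, n, n)
  centers <- cbind(y = sample(20:180, 40), x = sample(20:180, 40))
  while (min(dist(centers)) < 12)
    centers <- cbind(y = sample(20:180, 40), x = sample(20:180, 40))
  for (i in 1:40) img <- add_gauss(img, centers[i, 1], centers[i, 2], 200, 1.8)
  km <- build_kinetochore_mask(img, tophat_radius = 5)
  core <- cbind(rep(centers[, 1], each = 9) + rep(-1:1, 3),
                rep(centers[, 2], each = 9) + rep(rep(-1:1, each = 3), 1))
  expect_gte(mean(km$mask[core]), 0.9)
  bgpix <- km$mask
  bgpix[core] <- NA
  expect_lt(mean(bgpix, na.rm = TRUE), 0.02)
  # threshold is reproducible from the stored top-hat image
  expect_equal(km$threshold_value, isodata_threshold(km$tophat))
  # constant offsets cancel in the top-hat, leaving the mask unchanged
  km2 <- build_kinetochore_mask(img + 1000, tophat_radius = 5)
  expect_identical(km$mask, km2$mask)
  expect_error(build_kinetochore_mask(matrix(0, 32, 32)), "degenerate")
})

test_that("maxima detection recovers spot centres and enforces separation", {
  img <- matrix(1, 64, 64)
  img <- add_gauss(img, 20, 20, 100, 1.8)
  img <- add_gauss(img, 40, 40, 80, 1.8)
  got <- detect_maxima(img, n_spots = 2, min_sep_px = 8)
  expect_equal(nrow(got), 2)
  expect_lte(max(abs(got[1, ] - c(20, 20))), 1)
  expect_lte(max(abs(got[2, ] - c(40, 40))), 1)
  # two spots 4 px apart with min_sep 8: only the brighter is retained
  img2 <- add_gauss(add_gauss(matrix(1, 64, 64), 30, 30, 100, 1.5),
                    30, 34, 60, 1.5)
  got2 <- suppressWarnings(detect_maxima(img2, n_spots = 2, min_sep_px = 8))
  expect_equal(nrow(got2), 1)
  expect_lte(max(abs(got2[1, ] - c(30, 30))), 1)
  # short list downgrades to a warning, not an error
  img3 <- matrix(0, 96, 96)
  cs <- expand.grid(y = c(20, 45, 70), x = c(20, 45, 70, 85))
  for (i in seq_len(12)) img3 <- add_gauss(img3, cs$y[i], cs$x[i], 50, 1.5)
  expect_warning(got3 <- detect_maxima(img3, n_spots = 20, min_sep_px = 8),
                 "only 12")
  expect_equal(nrow(got3), 12)
})

test_that("even-diameter disc ROIs rasterise to the documented pixel counts", {
  roi8 <- build_spot_roi(c(30, 30), diameter_px = 8)
  expect_equal(nrow(roi8$pixels), 52)
  roi2 <- build_spot_roi(c(30, 30), diameter_px = 2)
  expect_equal(nrow(roi2$pixels), 4)
  # centres >= 8 px apart give disjoint diameter-8 ROIs
  a <- build_spot_roi(c(30, 30), 8)$pixels
  b <- build_spot_roi(c(30, 38), 8)$pixels
  expect_equal(nrow(merge(as.data.frame(a), as.data.frame(b))), 0)
  expect_error(build_spot_roi(c(2, 2), 8, image_dim = c(64, 64)), "beyond")
})

test_that("background accrual matches the brute-force sorted oracle", {
  roi <- build_spot_roi(c(32, 32), 8)
  empty <- matrix(FALSE, 64, 64)
  bg <- accrue_background(roi, empty, target_size = 52)
  expect_equal(nrow(bg$pixels), 52)
  expect_identical(bg$pixels, brute_accrue(roi, empty, 52))
  # an annulus of mask pixels at radius 5-7 is skipped entirely
  ann <- empty
  yy <- matrix(1:64, 64, 64); xx <- t(yy)
  d <- sqrt((yy - roi$center[1])^2 + (xx - roi$center[2])^2)
  ann[d >= 5 & d <= 7] <- TRUE
  bg2 <- accrue_background(roi, ann, target_size = 52)
  d_bg <- sqrt((bg2$pixels[, 1] - roi$center[1])^2 +
               (bg2$pixels[, 2] - roi$center[2])^2)
  expect_true(all(!ann[bg2$pixels]))
  expect_true(max(d_bg) > 7)
  expect_identical(bg2$pixels, brute_accrue(roi, ann, 52))
  # random masks, exhaustive agreement
  set.seed(55)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64) < 0.3, 64, 64)
    expect_identical(accrue_background(roi, m, 52)$pixels,
                     brute_accrue(roi, m, 52))
  }
  # not enough eligible pixels
  tiny_roi <- build_spot_roi(c(5, 5), 8)
  expect_error(accrue_background(tiny_roi, matrix(FALSE, 10, 10), 52),
               "insufficient")
})

test_that("spot measurement arithmetic follows the background-and-ratio rules", {
  n <- 64
  roi <- build_spot_roi(c(32, 32), 8)
  bg <- accrue_background(roi, matrix(FALSE, n, n), 52)
  mk <- function(roi_val, bg_val) {
    m <- matrix(bg_val, n, n)
    m[roi$pixels] <- roi_val
    m
  }
  px <- array(0, dim = c(2, 1, n, n))
  px[1, 1, , ] <- mk(30, 0)    # reference: corrected 30
  px[2, 1, , ] <- mk(100, 40)  # measured: corrected 60
  st <- image_stack(px, 0.1, channel_roles = c(reference_kt = 1, measure_1 = 2))
  sm <- measure_spot(st, roi, bg)
  expect_equal(sm$corrected[sm$role == "measure_1"], 60)
  expect_equal(sm$ratio[sm$role == "measure_1"], 2)
  expect_true(attr(sm, "valid"))
  # negative corrected values clamp to zero
  px[2, 1, , ] <- mk(30, 40)
  st2 <- image_stack(px, 0.1, channel_roles = c(reference_kt = 1, measure_1 = 2))
  sm2 <- measure_spot(st2, roi, bg)
  expect_equal(sm2$corrected[sm2$role == "measure_1"], 0)
  # zero reference flags invalid instead of raising
  px[1, 1, , ] <- mk(10, 10)
  st3 <- image_stack(px, 0.1, channel_roles = c(reference_kt = 1, measure_1 = 2))
  expect_false(attr(measure_spot(st3, roi, bg), "valid"))
})

test_that("constant offsets cancel out of corrected spot values", {
  sp <- scene_spec(size_px = 128, n_pairs = 4, nz = 1,
                   chromatin_axes_px = c(40, 50),
                   noise = list(poisson = FALSE, read_sd = 0, offset = 0,
                                gain = 1))
  sc <- render_scene(sp, seed = 21)
  proj <- sum_project(sc$stack)
  ref <- get_channel(proj, "reference_kt")
  km <- build_kinetochore_mask(ref)
  ctr <- detect_maxima(ref, n_spots = 1)
  roi <- build_spot_roi(ctr[1, ], 8, image_dim = dim(ref))
  bg <- accrue_background(roi, km)
  sm <- measure_spot(proj, roi, bg)
  shifted <- proj
  shifted$pixels <- shifted$pixels + 500
  sm2 <- measure_spot(shifted, roi, bg)
  expect_equal(sm2$corrected, sm$corrected, tolerance = 1e-9)
})

test_that("per-cell quantification is linear in the measured amplitude", {
  base <- scene_spec(size_px = 200, nz = 1, n_pairs = 8,
                     chromatin_axes_px = c(60, 80),
                     noise = list(poisson = FALSE, read_sd = 0, offset = 0,
                                  gain = 1))
  f <- 0.25
  scaled <- base
  scaled$condition_factors["measure_1"] <- f
  a <- quantify_cell(render_scene(base, seed = 31)$stack, n_spots = 10)
  b <- quantify_cell(render_scene(scaled, seed = 31)$stack, n_spots = 10)
  expect_equal(b$mean_ratio[["measure_1"]],
               f * a$mean_ratio[["measure_1"]], tolerance = 1e-9)
})

test_that("depletion factor is recovered from a noisy cell within 10%", {
  base <- scene_spec()
  dep <- base
  dep$condition_factors["measure_1"] <- 0.25
  a <- quantify_cell(render_scene(base, seed = 41)$stack)
  b <- quantify_cell(render_scene(dep, seed = 42)$stack)
  expect_equal(b$mean_ratio[["measure_1"]] / a$mean_ratio[["measure_1"]],
               0.25, tolerance = 0.1)
})
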