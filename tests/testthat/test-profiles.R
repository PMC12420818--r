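test_that("line profiles sample closed-form images exactly", {
  m <- matrix(rep(0:15, each = 16), 16, 16)  # I(y, x) = x - 1
  st <- mat_stack(m)
  p <- sample_line_profile(st, c(6, 1), c(6, 11))
  expect_equal(unname(p$samples[1, ]), 0:10)
  expect_equal(length(p$positions_px), ceiling(10) + 1)
  # on I = x the samples along any segment equal the x-coordinate - 1
  pd <- sample_line_profile(st, c(2, 2), c(10, 10))
  tt <- seq(0, 1, length.out = ncol(pd$samples))
  expect_equal(unname(pd$samples[1, ]), (2 + tt * 8) - 1, tolerance = 1e-12)
  expect_error(sample_line_profile(st, c(1, 1), c(1, 40)), "outside")
})

test_that("all channels are sampled at identical coordinates", {
  set.seed(8)
  base <- matrix(runif(400), 20, 20)
  px <- array(0, dim = c(2, 1, 20, 20))
  px[1, 1, , ] <- base
  px[2, 1, , ] <- 3 * base + 7   # affine image of channel 1
  st <- image_stack(px, 0.1, channel_roles = c(reference_kt = 1, measure_1 = 2))
  p <- sample_line_profile(st, c(3.2, 4.1), c(17.6, 15.3))
  expect_equal(unname(p$samples[2, ]), unname(3 * p$samples[1, ] + 7),
               tolerance = 1e-10)
})

test_that("profile sampling is consistent under a 90-degree rotation", {
  set.seed(9)
  m <- matrix(runif(625), 25, 25)
  rot <- t(m)[, 25:1]   # 90-degree rotation
  p1 <- sample_line_profile(mat_stack(m), c(5.3, 7.1), c(19.2, 16.4))
  # (y, x) -> (x, 26 - y) under this rotation
  p2 <- sample_line_profile(mat_stack(rot), c(7.1, 26 - 5.3), c(16.4, 26 - 19.2))
  expect_equal(p1$samples, p2$samples, tolerance = 1e-9)
})

test_that("group normalisation pins the minimum at 0 and the mean peak at 100", {
  st <- mat_stack(matrix(0, 5, 5))
  prof <- structure(list(p0 = c(1, 1), p1 = c(1, 3), width_px = 1L,
                         positions_px = 0:2,
                         samples = matrix(c(5, 10, 105), 1, 3),
                         pixel_size_um = 0.1), class = "LineProfile")
  np <- normalize_profile_group(list(prof))[[1]]
  expect_equal(unname(np$samples[1, ]), c(0, 100 * 5 / 100, 100))
  # a random group: exact pinning of group min and mean-curve max
  set.seed(10)
  profs <- lapply(1:4, function(i) {
    p <- prof; p$samples <- matrix(runif(7, 10, 50), 1, 7); p
  })
  np2 <- normalize_profile_group(profs)
  all_vals <- sapply(np2, function(p) p$samples[1, ])
  expect_equal(min(all_vals), 0)
  expect_equal(max(rowMeans(all_vals)), 100)
  const <- prof; const$samples <- matrix(5, 1, 3)
  expect_error(normalize_profile_group(list(const)), "constant")
})

test_that("alignment resamples to the median length and reports SEM = SD/sqrt(n)", {
  mkprof <- function(v) structure(list(p0 = c(1, 1), p1 = c(1, length(v)),
                                       width_px = 1L,
                                       positions_px = seq_along(v) - 1,
                                       samples = matrix(v, 1),
                                       pixel_size_um = 0.1),
                                  class = "LineProfile")
  a <- mkprof(seq(0, 100, length.out = 21))
  b <- mkprof(seq(5, 95, length.out = 41))
  al <- align_profiles(list(a, b))
  expect_equal(ncol(al$mean), 31)
  # endpoints preserved by the resampling
  expect_equal(al$profiles[[1]]$samples[1, 1], 0)
  expect_equal(al$profiles[[1]]$samples[1, 31], 100)
  expect_equal(al$profiles[[2]]$samples[1, 1], 5)
  # identical profiles give SEM identically zero
  al2 <- align_profiles(list(a, a, a))
  expect_true(all(al2$sem == 0))
  # SEM equals the direct formula
  c3 <- mkprof(seq(10, 60, length.out = 21))
  al3 <- align_profiles(list(a, c3))
  vals <- sapply(al3$profiles, function(p) p$samples[1, ])
  expect_equal(al3$sem[1, ], apply(vals, 1, sd) / sqrt(2))
  expect_error(align_profiles(list(a)), "at least 2")
})

test_that("Gaussian fitting recovers noiseless parameters essentially exactly", {
  x <- 0:40
  y <- 12 * exp(-(x - 10.3)^2 / (2 * 2^2))
  f <- fit_gaussian(y, x)
  expect_equal(f$mean, 10.3, tolerance = 1e-6)
  expect_equal(f$sigma, 2, tolerance = 1e-5)
  y2 <- y + 50
  f2 <- fit_gaussian(y2, x)
  expect_equal(f2$mean, 10.3, tolerance = 1e-6)
  expect_equal(f2$offset, 50, tolerance = 1e-5)
  expect_error(fit_gaussian(rep(3, 10)), "constant")
  expect_error(fit_gaussian(c(1, 2, 3)), "5 samples")
})

test_that("distance primitives follow centre-to-centre geometry", {
  d <- kt_kt_distance(c(10, 10), c(10, 20), 0.05)
  expect_equal(d$value_um, 0.5)
  expect_equal(kt_kt_distance(c(3, 4), c(3, 4), 0.05)$value_um, 0)
  expect_equal(kt_kt_distance(c(10, 20), c(10, 10), 0.05)$value_um,
               d$value_um)
  expect_equal(kt_kt_distance(c(15, 17), c(15, 27), 0.05)$value_um,
               d$value_um)
  x <- 0:30
  fa <- fit_gaussian(10 * exp(-(x - 30 / 3)^2 / 8) + 1, x)
  fa$mean <- 30.0; fb <- fa; fb$mean <- 33.0
  expect_equal(intra_kt_distance(fa, fb, 0.03)$value_um, 0.09)
  expect_equal(intra_kt_distance(fa, fa, 0.03)$value_um, 0)
  fc <- fb; fc$n <- 99L
  expect_error(intra_kt_distance(fa, fc, 0.03), "different length")
})

test_that("Gaussian-fit pair distances beat integer-argmax distances in RMSE", {
  set.seed(12)
  ds <- make_distance_dataset(0.46, n_pairs = 15, seed = 314)
  fit_err <- argmax_err <- numeric(15)
  for (i in 1:15) {
    st <- ds$stacks[[i]]
    fit_err[i] <- measure_pair_distance(st)$value_um - 0.46
    img <- get_channel(sum_project(st), "outer_kt")
    ctr <- detect_maxima(img, n_spots = 2, min_sep_px = 4)
    argmax_err[i] <- kt_kt_distance(ctr[1, ], ctr[2, ],
                                    st$pixel_size_um)$value_um - 0.46
  }
  expect_lt(sqrt(mean(fit_err^2)), sqrt(mean(argmax_err^2)))
})

test_that("noiseless synthetic pairs are recovered to sub-hundredth-pixel accuracy", {
  for (sep in c(0.46, 1.37)) {
    sp <- scene_spec(size_px = 80, nz = 1, pixel_size_um = 0.03,
                     psf_sigma_um = 0.06,
                     channels = list(outer_kt = c(cytoplasm = 5, spot = 100)),
                     n_pairs = 1, separation_um = sep,
                     pairs = data.frame(mid_y = 40.3, mid_x = 40.7,
                                        angle = 0.6),
                     noise = list(poisson = FALSE, read_sd = 0, offset = 0,
                                  gain = 1))
    st <- render_scene(sp)$stack
    d <- measure_pair_distance(st)
    expect_lt(abs(d$value_um - sep), 0.01 * 0.03)
  }
})

test_that("an offset inner marker is recovered from a two-channel profile", {
  # outer spot and an inner marker 0.12 um inward, STED-like sampling
  off_um <- 0.12; pxs <- 0.03
  n <- 64
  outer <- add_gauss(matrix(2, n, n), 32, 40, 100, 2)
  inner <- add_gauss(matrix(2, n, n), 32, 40 - off_um / pxs, 100, 2)
  px <- array(0, dim = c(2, 1, n, n))
  px[1, 1, , ] <- outer; px[2, 1, , ] <- inner
  st <- image_stack(px, pxs, channel_roles = c(outer_kt = 1, measure_1 = 2))
  p <- sample_line_profile(st, c(32, 20), c(32, 60))
  fo <- fit_gaussian(p$samples["outer_kt", ], p$positions_px)
  fi <- fit_gaussian(p$samples["measure_1", ], p$positions_px)
  d <- intra_kt_distance(fo, fi, pxs)
  expect_lt(abs(d$value_um - off_um), 0.02)
})
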