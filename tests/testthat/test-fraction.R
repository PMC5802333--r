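test_that("rigid shifts are exact for identity and whole-pixel translations", {
  set.seed(21)
  img <- sp_image(matrix(runif(30 * 30), 30, 30), spacing = c(2, 2))
  expect_identical(apply_rigid_shift(img, c(0, 0)), img)
  # +2 mm in x is one column to the right (toward patient left)
  out <- apply_rigid_shift(img, c(2, 0))
  expect_equal(out$values[, 2:30], img$values[, 1:29])
  expect_true(all(out$values[, 1] == 0))
  # -4 mm in y is two rows down (toward posterior)
  out2 <- apply_rigid_shift(img, c(0, -4))
  expect_equal(out2$values[3:30, ], img$values[1:28, ])
})

test_that("sub-pixel shifts of a linear ramp reproduce the analytic ramp", {
  n <- 40
  img <- sp_image(matrix(0, n, n), spacing = c(1, 1))
  gx <- t(replicate(n, seq_len(n)))
  x <- (gx - 1) * 1 + img$origin[1]       # physical x of each pixel
  img$values <- 5 + 0.1 * x
  out <- apply_rigid_shift(img, c(0.5, 0))
  # interior: value at x equals the ramp evaluated at x - 0.5
  interior <- out$values[5:(n - 5), 5:(n - 5)]
  want <- (5 + 0.1 * (x - 0.5))[5:(n - 5), 5:(n - 5)]
  expect_equal(interior, want, tolerance = 1e-10)
})

test_that("rotation about the isocenter maps a ramp as expected", {
  n <- 41
  img <- sp_image(matrix(0, n, n), spacing = c(1, 1))
  gc <- expand.grid(i = seq_len(n), j = seq_len(n))
  x <- matrix(img$origin[1] + (gc$j - 1), n, n)
  y <- matrix(img$origin[2] - (gc$i - 1), n, n)
  img$values <- 30 + x        # ramp in x, positive everywhere on the grid
  out <- apply_rigid_shift(img, c(0, 0), rotation = 90)
  # rotating the content 90 deg CCW turns the x-ramp into a y-ramp
  interior <- 8:(n - 8)
  expect_equal(out$values[interior, interior],
               (30 + y)[interior, interior], tolerance = 1e-9)
})

test_that("truncation correction applies the three-way rule", {
  img <- sp_image(matrix(0.7, 40, 40), spacing = c(2, 2))
  body <- matrix(rep(c(TRUE, FALSE), length.out = 40 * 40), 40, 40)
  circ <- scanning_circle(diameter = 50)
  out <- truncation_correct(img, circ, body, fill_sp = 1.0)
  # brute-force per-pixel oracle
  for (i in seq(1, 40, by = 3)) for (j in seq(1, 40, by = 3)) {
    x <- img$origin[1] + (j - 1) * 2
    y <- img$origin[2] - (i - 1) * 2
    inside <- x^2 + y^2 <= 25^2
    want <- if (inside) 0.7 else if (body[i, j]) 1.0 else 0
    expect_identical(out$values[i, j], want)
  }
  # everything inside the circle: image returned unchanged
  big <- scanning_circle(diameter = 1000)
  expect_equal(truncation_correct(img, big, body)$values, img$values)
  expect_error(truncation_correct(img, circ, matrix(TRUE, 3, 3)), "grid")
})

test_that("range-error samples difference WEPL maps pixel by pixel", {
  set.seed(31)
  img <- sp_image(matrix(runif(30 * 30, 0.5, 1.5), 30, 30), spacing = c(1, 1))
  mask <- matrix(FALSE, 30, 30); mask[14:18, 14:18] <- TRUE
  b <- beam_geometry(0, Inf)
  ref <- wepl_map(img, mask, b)
  # identical fraction: all zeros
  s0 <- fraction_range_error(ref, ref, mask)
  expect_true(all(s0$delta_wepl == 0))
  expect_equal(s0$n_pixels, 25)
  # upstream slab of sp-excess +0.5 over 10 mm: +5 mm everywhere
  img2 <- img
  img2$values[2:11, ] <- img$values[2:11, ] + 0.5
  s <- fraction_range_error(ref, wepl_map(img2, mask, b), mask)
  expect_equal(s$delta_wepl, rep(5, 25), tolerance = 1e-10)
  # recomputation oracle on an arbitrary pair
  set.seed(32)
  img3 <- sp_image(matrix(runif(30 * 30, 0.5, 1.5), 30, 30), spacing = c(1, 1))
  s2 <- fraction_range_error(ref, wepl_map(img3, mask, b), mask)
  idx <- which(mask, arr.ind = TRUE)
  want <- vapply(seq_len(nrow(idx)), function(k) {
    trace_effective_depth(img3, idx[k, ], b) -
      trace_effective_depth(img, idx[k, ], b)
  }, numeric(1))
  expect_equal(s2$delta_wepl, want)
  small <- wepl_map(sp_image(matrix(1, 5, 5)), matrix(TRUE, 5, 5), b)
  expect_error(fraction_range_error(ref, small, mask), "different grids")
})

test_that("fraction summaries compute mean, sample SD and a mass-conserving histogram", {
  s <- range_error_sample(c(0, 0, 0, 0))
  sm <- summarize_fraction(s)
  expect_equal(sm$mean, 0); expect_equal(sm$sd, 0)
  expect_equal(sum(sm$histogram$percent_volume), 100)
  expect_equal(max(sm$histogram$percent_volume), 100)
  sm2 <- summarize_fraction(range_error_sample(c(1, 2, 3)))
  expect_equal(sm2$mean, 2); expect_equal(sm2$sd, 1)
  # single pixel: sd undefined, mean still usable
  sm1 <- summarize_fraction(range_error_sample(4.2))
  expect_true(is.na(sm1$sd)); expect_equal(sm1$mean, 4.2)
  # Monte-Carlo oracle: 1e4 normal draws recover the generator parameters
  set.seed(99)
  d <- rnorm(1e4, mean = -1.5, sd = 2.5)
  smc <- summarize_fraction(range_error_sample(d), bin_width = 0.5)
  expect_lt(abs(smc$mean - (-1.5)), 4 * 2.5 / sqrt(1e4))
  expect_lt(abs(smc$sd - 2.5), 4 * 2.5 / sqrt(2 * 1e4))
  # histogram mass is 100% for any bin width
  for (bw in c(0.1, 0.7, 1, 3.3)) {
    expect_equal(sum(summarize_fraction(smc_sample <- range_error_sample(d),
                                        bin_width = bw)$histogram$percent_volume),
                 100, tolerance = 1e-6)
  }
})

test_that("a course of identical fractions yields identically zero summaries", {
  ph <- make_phantom(small_body_spec(60, 60, 2, semiaxes = c(50, 50),
                                     ctv_radius = 8))
  ref <- fraction_record(1, ph$image)
  fr <- list(fraction_record(2, ph$image), fraction_record(3, ph$image))
  res <- run_course(ref, fr, ph$ctv_mask,
                    beams = list(beam_geometry(0, Inf), beam_geometry(90, Inf)))
  expect_equal(nrow(res$summaries), 4)
  expect_true(all(res$summaries$mean_mm == 0))
  expect_true(all(res$summaries$sd_mm == 0))
  # reference self-comparison is exactly zero
  res2 <- run_course(ref, list(ref), ph$ctv_mask, beams = beam_geometry(0, Inf))
  expect_identical(unique(res2$samples[[1]]$delta_wepl), 0)
})

test_that("a recorded couch shift undoes the displacement it corrects", {
  # smooth phantom so interpolation error is benign
  n <- 80
  img <- sp_image(matrix(0, n, n), spacing = c(1.5, 1.5))
  gc <- expand.grid(i = seq_len(n), j = seq_len(n))
  x <- matrix(img$origin[1] + (gc$j - 1) * 1.5, n, n)
  y <- matrix(img$origin[2] - (gc$i - 1) * 1.5, n, n)
  # smooth density inside a body ellipse whose margin exceeds the shift,
  # so the zero fill at the resampling border stays in air
  body <- (x / 45)^2 + (y / 45)^2 <= 1
  img$values <- (1 + 0.5 * exp(-((x - 5)^2 + (y + 8)^2) / (2 * 25^2))) * body
  mask <- matrix(FALSE, n, n); mask[38:44, 38:44] <- TRUE
  delta <- c(2.3, -1.1)
  displaced <- apply_rigid_shift(img, delta)
  ref <- fraction_record(1, img)
  frac <- fraction_record(2, displaced, shift = -delta)
  res <- run_course(ref, frac, mask, beams = beam_geometry(0, Inf))
  expect_lt(abs(res$summaries$mean_mm), 0.1)
})

test_that("adding sp to an upstream slab shifts every delta by thickness times excess", {
  spec <- small_body_spec(100, 100, 1, semiaxes = c(45, 45), ctv_radius = 10)
  ph <- make_phantom(spec)
  mod <- ph$image
  # rows with pixel-centre y in [23.5, 34.5]: 12 rows well inside the body
  # for every CTV ray (|x| <= 10), upstream of the CTV (y <= 10)
  slab_rows <- which((49.5 - (seq_len(100) - 1)) <= 34.5 &
                     (49.5 - (seq_len(100) - 1)) >= 23.5)
  dsp <- 0.3
  mod$values[slab_rows, ] <- mod$values[slab_rows, ] +
    dsp * (ph$image$values[slab_rows, ] > 0)
  res <- run_course(fraction_record(1, ph$image),
                    fraction_record(2, mod), ph$ctv_mask,
                    beams = beam_geometry(0, Inf))
  t_mm <- length(slab_rows) * 1
  expect_equal(res$samples[[1]]$delta_wepl,
               rep(t_mm * dsp, res$samples[[1]]$n_pixels), tolerance = 1e-9)
})

test_that("excluding a slice changes nothing computed on other slices", {
  set.seed(55)
  mk <- function() sp_image(matrix(runif(40 * 40, 0.8, 1.2), 40, 40))
  ref <- fraction_record(1, list(mk(), mk()))
  f_img <- list(mk(), mk())
  mask <- matrix(FALSE, 40, 40); mask[18:22, 18:22] <- TRUE
  b <- beam_geometry(0, Inf)
  full <- run_course(ref, fraction_record(2, f_img), list(mask, mask), beams = b)
  part <- run_course(ref, fraction_record(2, f_img, excluded_slices = 2),
                     list(mask, mask), beams = b)
  n1 <- sum(mask)
  expect_equal(part$samples[[1]]$delta_wepl,
               full$samples[[1]]$delta_wepl[seq_len(n1)])
  expect_match(paste(part$log, collapse = " "), "excluded slice")
})

test_that("unusable fractions are skipped and logged; empty courses error", {
  ph <- make_phantom(small_body_spec(40, 40, 2, semiaxes = c(30, 30),
                                     ctv_radius = 6))
  ref <- fraction_record(1, ph$image)
  bad <- fraction_record(2, ph$image, usable = FALSE)
  res <- run_course(ref, list(bad, fraction_record(3, ph$image)),
                    ph$ctv_mask, beams = beam_geometry(0, Inf))
  expect_equal(res$summaries$fraction, 3)
  expect_match(paste(res$log, collapse = " "), "unusable")
  expect_error(run_course(ref, list(bad), ph$ctv_mask,
                          beams = beam_geometry(0, Inf)), "no usable")
  expect_error(run_course(bad, list(ref), ph$ctv_mask,
                          beams = beam_geometry(0, Inf)), "reference")
})
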