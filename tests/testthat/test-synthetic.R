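test_that("phantoms rasterise with the pixel-centre rule", {
  spec <- small_body_spec(80, 80, 2, semiaxes = c(70, 60), ctv_radius = 15)
  ph <- make_phantom(spec)
  expect_true(all(ph$image$values[ph$body_mask] == 1))
  expect_true(all(ph$image$values[!ph$body_mask] == 0))
  expect_true(all(ph$ctv_mask[40, 40]))
  # disc insert takes exactly its stopping power at in-disc pixel centres
  spec2 <- small_body_spec(80, 80, 2, semiaxes = c(70, 60), ctv_radius = 10,
                           inserts = list(list(shape = "disc",
                                               center = c(30, 20),
                                               size = 12, sp = 1.622)))
  ph2 <- make_phantom(spec2)
  gx <- ph2$image$origin[1] + (seq_len(80) - 1) * 2
  gy <- ph2$image$origin[2] - (seq_len(80) - 1) * 2
  indisc <- outer(gy, gx, function(y, x) (x - 30)^2 + (y - 20)^2 <= 144)
  expect_true(all(ph2$image$values[indisc] == 1.622))
  # rasterised disc area is within the boundary-pixel bound of pi r^2
  n_pix <- sum(indisc)
  area_err <- abs(n_pix * 4 - pi * 12^2)
  expect_lt(area_err, 2 * (2 * pi * 12 / 2) * 4)
  expect_error(phantom_spec(grid = list(shape = c(40, 40), spacing = c(2, 2)),
                            body = list(center = c(0, 0), semiaxes = c(20, 20)),
                            ctv = list(center = c(15, 0), radius = 10)),
               "outside the body")
})

test_that("courses are deterministic in the seed and trivial without motion", {
  spec <- small_body_spec(40, 40, 2, semiaxes = c(30, 30), ctv_radius = 6)
  still <- simulate_course(spec, motion_model(), n_fractions = 4, seed = 1)
  for (f in still$fractions) {
    expect_identical(f$image$values, still$reference$image$values)
    expect_identical(f$shift, c(0, 0))
  }
  mo <- motion_model(setup_sd = 3, residual_after_igrt_sd = 1,
                     relative_insert_motion_sd = 2, erosion_rate = 0.3)
  a <- simulate_course(spec, mo, 6, seed = 42)
  b <- simulate_course(spec, mo, 6, seed = 42)
  expect_identical(lapply(a$fractions, `[[`, "image"),
                   lapply(b$fractions, `[[`, "image"))
  expect_identical(a$truth, b$truth)
  c2 <- simulate_course(spec, mo, 6, seed = 43)
  expect_false(identical(a$truth, c2$truth))
})

test_that("the recorded shift leaves exactly the residual displacement", {
  spec <- small_body_spec(60, 60, 2, semiaxes = c(50, 50), ctv_radius = 8)
  mo <- motion_model(setup_sd = 4, residual_after_igrt_sd = 1.5)
  course <- simulate_course(spec, mo, 5, seed = 10)
  tr <- course$truth[course$truth$fraction > 1, ]
  for (k in seq_along(course$fractions)) {
    expect_equal(course$fractions[[k]]$shift,
                 c(tr$residual_dx[k] - tr$dx[k], tr$residual_dy[k] - tr$dy[k]))
  }
})

test_that("erosion-only courses overshoot by the eroded water-equivalent thickness", {
  spec <- small_body_spec(90, 90, 1, semiaxes = c(42, 42), ctv_radius = 8)
  mo <- motion_model(erosion_rate = 1)   # 1 mm of contour lost per fraction
  course <- simulate_course(spec, mo, 5, seed = 2)
  res <- run_course(course$reference, course$fractions, course$ctv_mask,
                    beams = beam_geometry(0, Inf))
  # per-fraction mean equals -(eroded thickness), monotone, negative;
  # rasterisation quantises the surface at half a pixel
  want <- -(seq_len(4))
  expect_equal(res$summaries$mean_mm, want, tolerance = 0.6)
  expect_true(all(diff(res$summaries$mean_mm) < 0))
  expect_true(all(res$summaries$mean_mm < 0))
  gt <- ground_truth_stats(course, 0)
  expect_equal(mean(res$summaries$mean_mm), gt$m_star, tolerance = 0.5)
  expect_equal(sd(res$summaries$mean_mm), gt$sigma_star, tolerance = 0.5)
})

test_that("analytic ground truth covers the closed-form motion models", {
  spec <- small_body_spec(40, 40, 2, semiaxes = c(30, 30), ctv_radius = 6)
  still <- simulate_course(spec, motion_model(), 3, seed = 1)
  expect_equal(ground_truth_stats(still, 0),
               list(m_star = 0, sigma_star = 0, sigma_w = 0))
  # pure density fluctuation on a slab spanning the beam path:
  # Sigma* = thickness x sp-change SD, m* = 0
  spec2 <- small_body_spec(60, 60, 1, semiaxes = c(28, 28), ctv_radius = 5,
                           inserts = list(list(shape = "slab",
                                               center = c(0, 15),
                                               size = c(40, 8), sp = 1)))
  mo2 <- motion_model(density_fluctuation = list(region = 1, sd = 0.1))
  course2 <- simulate_course(spec2, mo2, 8, seed = 3)
  gt2 <- ground_truth_stats(course2, 0)
  expect_equal(gt2$sigma_star, 8 * 0.1)
  expect_equal(gt2$m_star, 0)
  # and the pipeline recovers it (sample SD of realised means vs truth)
  res2 <- run_course(course2$reference, course2$fractions, course2$ctv_mask,
                     beams = beam_geometry(0, Inf))
  eps <- course2$truth$density_eps[course2$truth$fraction > 1]
  expect_equal(res2$summaries$mean_mm, 8 * eps, tolerance = 1e-9)
  # mixed models have no closed form and say so
  mixed <- simulate_course(spec, motion_model(setup_sd = 2, erosion_rate = 0.5),
                           3, seed = 4)
  expect_error(ground_truth_stats(mixed, 0), "no closed-form")
})

test_that("sample-level generator output matches its declared truth", {
  sim <- simulate_range_error_samples(50, 100, -1.8, 3.4, 3.3, seed = 20)
  expect_length(sim$samples, 50)
  expect_true(all(vapply(sim$samples, `[[`, integer(1), "n_pixels") == 100))
  expect_identical(sim$truth$m_star, -1.8)
  # reproducibility
  sim2 <- simulate_range_error_samples(50, 100, -1.8, 3.4, 3.3, seed = 20)
  expect_identical(sim$samples[[7]]$delta_wepl, sim2$samples[[7]]$delta_wepl)
})

test_that("a lateral beam through moving femoral inserts has larger Sigma than an anterior beam", {
  # scaled-down version of the pelvis phantom ordering check
  spec <- phantom_spec(grid = list(shape = c(70, 100), spacing = c(2, 2)),
                       body = list(center = c(0, 0), semiaxes = c(90, 65)),
                       ctv = list(center = c(0, 0), radius = 12),
                       inserts = list(
                         list(shape = "disc", center = c(-60, 0), size = 14, sp = 1.622),
                         list(shape = "disc", center = c(60, 0), size = 14, sp = 1.622)))
  mo <- motion_model(relative_insert_motion_sd = 3)
  course <- simulate_course(spec, mo, 10, seed = 30)
  res <- run_course(course$reference, course$fractions, course$ctv_mask,
                    beams = list(beam_geometry(0, Inf), beam_geometry(90, Inf)))
  S0 <- systematic_sigma(res$summaries[res$summaries$angle == 0, ])
  S90 <- systematic_sigma(res$summaries[res$summaries$angle == 90, ])
  expect_gt(S90, S0)
})

test_that("built-in phantom configurations load and validate", {
  pr <- prostate_like_phantom()
  expect_s3_class(pr, "phantom_spec")
  expect_length(pr$inserts, 2)
  hn <- head_neck_like_phantom()
  expect_s3_class(hn, "phantom_spec")
  ph <- make_phantom(pr)
  expect_true(sum(ph$ctv_mask) > 100)
  expect_equal(max(ph$image$values), 1.622)
})
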