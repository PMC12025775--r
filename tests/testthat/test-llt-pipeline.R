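test_that("pixel distance is the Euclidean RGB distance", {
  expect_equal(pixel_distance(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(pixel_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(pixel_distance(c(255, 0, 0), c(0, 255, 0)), sqrt(2 * 255^2))
  expect_equal(pixel_distance(c(1, 2, 3), c(7, 8, 9)),
               pixel_distance(c(7, 8, 9), c(1, 2, 3)))
  expect_error(pixel_distance(c(-1, 0, 0), c(0, 0, 0)), "\\[0, 255\\]")
  expect_error(pixel_distance(c(0, 0, 300), c(0, 0, 0)), "\\[0, 255\\]")
})

test_that("pixels classify to the nearest table entry, ties to the smallest", {
  tab <- toy_table()   # (0,0,0)@20, (100,100,100)@80, (200,200,200)@140
  expect_equal(classify_pixel(c(100, 100, 100), tab), 80)
  expect_equal(classify_pixel(c(40, 40, 40), tab), 20)      # 69.3 < 103.9
  expect_equal(classify_pixel(c(50, 50, 50), tab), 20)      # exact tie
  expect_equal(classify_pixel(c(150, 150, 150), tab), 80)   # tie again
})

test_that("vectorized classification equals the scalar brute-force loop", {
  tab <- toy_table()
  set.seed(42)
  for (rep in 1:10) {
    img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
    mask <- matrix(TRUE, 16, 16)
    est <- estimate_raw_llt(img, mask, tab)
    expect_identical(est$thickness_map, brute_force_classify(img, tab))
  }
  # also against a generated table with many entries
  gen <- build_reference_table(seq(10, 160, by = 10))
  img <- array(sample(0:255, 12 * 12 * 3, replace = TRUE), c(12, 12, 3))
  est <- estimate_raw_llt(img, matrix(TRUE, 12, 12), gen)
  expect_identical(est$thickness_map, brute_force_classify(img, gen))
})

test_that("raw LLT is the arithmetic mean of per-pixel classifications", {
  tab <- toy_table()
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 100; img[, , 2] <- 100; img[, , 3] <- 100
  mask <- matrix(TRUE, 10, 10)
  expect_equal(estimate_raw_llt(img, mask, tab)$raw_mean_nm, 80)

  # half the masked pixels at 20 nm's color, half at 80 nm's color
  img2 <- array(0, c(10, 10, 3))
  img2[6:10, , 1] <- 100; img2[6:10, , 2] <- 100; img2[6:10, , 3] <- 100
  expect_equal(estimate_raw_llt(img2, mask, tab)$raw_mean_nm, 50)

  single <- matrix(FALSE, 10, 10); single[3, 7] <- TRUE
  expect_equal(estimate_raw_llt(img2, single, tab)$raw_mean_nm, 20)
})

test_that("calibration is the fixed affine map 0.6 x raw + 10", {
  expect_equal(calibrate_llt(0), 10)
  expect_equal(calibrate_llt(100), 70)
  expect_equal(calibrate_llt(127.35), 86.41)
  expect_error(calibrate_llt(-1), ">= 0")
  # affine maps commute with averaging
  raws <- c(23.4, 81.2, 144.9, 60)
  expect_equal(calibrate_llt(mean(raws)), mean(calibrate_llt(raws)))
})

test_that("section analysis reports the absolute calibrated vertical difference", {
  tab <- reference_table(c(60, 90), rbind(c(0, 0, 0), c(200, 200, 200)))
  field <- generate_thickness_field(c(40, 40), "two_band",
                                    list(upper_value = 60, lower_value = 90,
                                         split_row = 20),
                                    grid_range = c(60, 90))
  img <- render_interferogram(field, tab)
  mask <- matrix(TRUE, 40, 40)
  est <- estimate_raw_llt(img, mask, tab)
  sec <- section_analysis(est$thickness_map, mask)
  expect_equal(sec$upper_section_nm, 0.6 * 60 + 10)
  expect_equal(sec$lower_section_nm, 0.6 * 90 + 10)
  expect_equal(sec$vertical_difference_nm, 18)
  expect_equal(sec$n_pixels_upper + sec$n_pixels_lower, sum(mask))

  # swapping the bands leaves the absolute difference unchanged
  field_sw <- generate_thickness_field(c(40, 40), "two_band",
                                       list(upper_value = 90, lower_value = 60,
                                            split_row = 20),
                                       grid_range = c(60, 90))
  est_sw <- estimate_raw_llt(render_interferogram(field_sw, tab), mask, tab)
  expect_equal(section_analysis(est_sw$thickness_map, mask)$vertical_difference_nm, 18)

  # uniform map: zero difference
  est_u <- estimate_raw_llt(render_interferogram(
    matrix(60, 40, 40), tab), mask, tab)
  expect_equal(section_analysis(est_u$thickness_map, mask)$vertical_difference_nm, 0)
})

test_that("vertical difference ignores pixel order within sections", {
  tab <- toy_table()
  set.seed(7)
  map <- matrix(sample(c(20, 80, 140), 100, replace = TRUE), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  base <- section_analysis(map, mask)
  shuf <- map
  shuf[1:5, ] <- matrix(sample(map[1:5, ]), 5, 10)    # permute upper section
  shuf[6:10, ] <- matrix(sample(map[6:10, ]), 5, 10)  # permute lower section
  expect_equal(section_analysis(shuf, mask)$vertical_difference_nm,
               base$vertical_difference_nm)
})

test_that("the full estimator composes acquisition, classification and calibration", {
  tab <- build_reference_table(seq(10, 160, by = 10))
  roi <- roi_spec(31.5, 20, 30)
  field <- generate_thickness_field(c(64, 64), "uniform", list(value = 100))
  fit <- estimate_llt(render_interferogram(field, tab), tab, roi)
  expect_s3_class(fit, "llt_estimate")
  expect_equal(fit$calibrated_nm, 70)
  expect_equal(fit$raw_mean_nm, 100)
  expect_equal(fit$vertical_difference_nm, 0)
  expect_equal(fit$n_pixels, fit$n_pixels_upper + fit$n_pixels_lower)
  expect_true(is.na(fit$frame_index))

  seq1 <- generate_frame_sequence(field, tab, fps = 30,
                                  blink_frames = list(c(10, 14), c(40, 44)),
                                  n_frames = 90)
  fit_seq <- estimate_llt(seq1, tab, roi)
  expect_equal(fit_seq$frame_index, 60)
  expect_equal(fit_seq$calibrated_nm, 70)

  co <- coef(fit)
  expect_named(co, c("raw_mean_nm", "calibrated_nm", "upper_section_nm",
                     "lower_section_nm", "vertical_difference_nm"))
  expect_output(print(fit), "calibrated LLT: 70.00 nm")
  expect_output(print(summary(fit)), "quantiles")
})

test_that("classification accuracy does not improve with more noise", {
  tab <- build_reference_table(seq(10, 160, by = 10))
  field <- generate_thickness_field(c(48, 48), "vertical_gradient",
                                    list(top = 40, bottom = 130))
  field_grid <- round(field / 10) * 10   # snap to the table grid
  acc <- vapply(c(0, 6, 14, 30), function(sd_noise) {
    hits <- vapply(1:5, function(seed) {
      img <- render_interferogram(field_grid, tab, noise_sd = sd_noise,
                                  seed = seed)
      est <- estimate_raw_llt(img, matrix(TRUE, 48, 48), tab)
      mean(est$thickness_map == field_grid)
    }, 0)
    mean(hits)
  }, 0)
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 1e-12))
})
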