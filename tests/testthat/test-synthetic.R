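test_that("thickness field kinds follow their construction", {
  u <- generate_thickness_field(c(5, 7), "uniform", list(value = 100))
  expect_true(all(u == 100))

  g <- generate_thickness_field(c(100, 10), "vertical_gradient",
                                list(top = 60, bottom = 90))
  expect_equal(mean(g[1, ]), 60)
  expect_equal(mean(g[100, ]), 90)
  expect_equal(rowMeans(g), seq(60, 90, length.out = 100))

  b <- generate_thickness_field(c(10, 4), "two_band",
                                list(upper_value = 50, lower_value = 120,
                                     split_row = 6))
  expect_true(all(b[1:6, ] == 50))   # 0-based rows 0..5
  expect_true(all(b[7:10, ] == 120))

  s1 <- generate_thickness_field(c(32, 32), "smooth_random",
                                 list(mean = 80, amplitude = 15), seed = 1)
  s2 <- generate_thickness_field(c(32, 32), "smooth_random",
                                 list(mean = 80, amplitude = 15), seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1, generate_thickness_field(
    c(32, 32), "smooth_random", list(mean = 80, amplitude = 15), seed = 2)))
  expect_true(all(s1 >= 10 & s1 <= 160))   # clipped to the grid range
  expect_error(generate_thickness_field(c(5, 5), "spots", list()), "unknown")
})

test_that("noise-free rendering is exactly inverted by classification", {
  tab <- build_reference_table(seq(10, 160, by = 10))
  mask <- matrix(TRUE, 30, 30)
  for (field in list(
    generate_thickness_field(c(30, 30), "uniform", list(value = 100)),
    generate_thickness_field(c(30, 30), "two_band",
                             list(upper_value = 40, lower_value = 120,
                                  split_row = 15)),
    matrix(sample(tab$thickness_nm, 900, replace = TRUE), 30, 30))) {
    img <- render_interferogram(field, tab, noise_sd = 0)
    est <- estimate_raw_llt(img, mask, tab)
    expect_identical(est$thickness_map, matrix(as.numeric(field), 30, 30))
    expect_equal(est$raw_mean_nm, mean(field))
  }
})

test_that("rendering maps off-grid thicknesses to the nearest grid color", {
  tab <- toy_table()   # entries 20, 80, 140
  field <- matrix(c(49, 51, 50, 110.0001), 2, 2)   # 50 ties toward 20
  img <- render_interferogram(field, tab)
  est <- estimate_raw_llt(img, matrix(TRUE, 2, 2), tab)
  expect_equal(est$thickness_map, matrix(c(20, 80, 20, 140), 2, 2))
})

test_that("upper occlusion darkens exactly the top half", {
  tab <- toy_table()
  field <- matrix(80, 20, 20)
  img <- render_interferogram(field, tab, occlude_upper = TRUE)
  expect_true(all(img[1:10, , ] <= 10))
  expect_true(all(img[11:20, , ] == 100))
})

test_that("noisy rendering still recovers the true mean thickness", {
  tab <- build_reference_table()
  field <- generate_thickness_field(c(64, 64), "uniform", list(value = 100))
  img <- render_interferogram(field, tab, noise_sd = 8, seed = 7)
  est <- estimate_raw_llt(img, matrix(TRUE, 64, 64), tab)
  expect_lt(abs(est$raw_mean_nm - 100), 2)
})

test_that("frame sequences are reproducible and round-trip through detection", {
  tab <- toy_table()
  field <- matrix(80, 16, 16)
  s1 <- generate_frame_sequence(field, tab, fps = 30,
                                blink_frames = list(c(10, 14), c(40, 44)),
                                n_frames = 90, seed = 3)
  s2 <- generate_frame_sequence(field, tab, fps = 30,
                                blink_frames = list(c(10, 14), c(40, 44)),
                                n_frames = 90, seed = 3)
  expect_identical(s1, s2)
  ev <- detect_blinks(s1)
  expect_equal(ev$end_frame, c(15, 45))
  expect_equal(select_analysis_frame(s1, ev)$index, 60)
  expect_error(generate_frame_sequence(field, tab, blink_frames = list(c(85, 95)),
                                       n_frames = 90), "outside")
})

test_that("cohort generation is seed-deterministic with exact group sizes", {
  params <- study_cohort_params()
  c1 <- generate_cohort(params, seed = 11)
  c2 <- generate_cohort(params, seed = 11)
  expect_identical(c1, c2)
  llt <- c1[c1$parameter == "llt", ]
  expect_equal(sum(llt$group == "CsA-CE"), 94)
  expect_equal(sum(llt$group == "control"), 91)
  expect_equal(nrow(c1), (94 + 91) * 12)   # 12 parameters per eye

  # sample pre means sit within 3 standard errors of the target means
  csa <- llt[llt$group == "CsA-CE", "pre"]
  ctl <- llt[llt$group == "control", "pre"]
  expect_lt(abs(mean(csa) - 70.29), 3 * 23.27 / sqrt(94))
  expect_lt(abs(mean(ctl) - 74.86), 3 * 28.54 / sqrt(91))

  osdi <- c1[c1$parameter == "osdi", ]
  expect_true(all(osdi$pre >= 0 & osdi$pre <= 100))
})

test_that("near-perfect pre/post correlation collapses the change variance", {
  params <- study_cohort_params(rho = 0.999)
  params[params$parameter == "llt" & params$group == "CsA-CE",
         c("post_mean", "post_sd")] <- c(70.29, 23.27)
  co <- generate_cohort(params, seed = 4)
  llt <- co[co$parameter == "llt" & co$group == "CsA-CE", ]
  expect_lt(sd(llt$post - llt$pre), 0.1 * 23.27)
  expect_error(study_cohort_params(rho = 1.2), "rho")
})

test_that("cohort moments converge to the requested parameters", {
  params <- study_cohort_params(n_csa = 10000, n_control = 2)
  params <- params[params$parameter == "llt", , drop = FALSE]
  attr(params, "n") <- c("CsA-CE" = 10000, "control" = 2)
  attr(params, "rho") <- 0.5
  class(params) <- c("cohort_params", "data.frame")
  co <- generate_cohort(params, seed = 5)
  x <- co[co$group == "CsA-CE", ]
  expect_lt(abs(mean(x$pre) / 70.29 - 1), 0.02)
  expect_lt(abs(sd(x$pre) / 23.27 - 1), 0.02)
  expect_lt(abs(mean(x$post) / 86.41 - 1), 0.02)
  expect_lt(abs(sd(x$post) / 21.89 - 1), 0.02)
  expect_lt(abs(cor(x$pre, x$post) - 0.5), 0.03)
})
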