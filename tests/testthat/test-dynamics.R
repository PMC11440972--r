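test_that("TAC extraction averages the mask per frame", {
  ft <- default_timing()
  arr <- array(2.5, dim = c(5, 5, 5, 8))
  ser <- dynamic_series(arr, ft, spacing = c(2, 2, 2))
  m <- mk_mask(array(c(TRUE, rep(FALSE, 124)), dim = c(5, 5, 5)),
               spacing = c(2, 2, 2))
  flat <- extract_tac(ser, m)
  expect_equal(flat$values, rep(2.5, 8))
  expect_equal(flat$mid_min, ft$mid_min)

  # single-voxel mask reads that voxel's frame values
  set.seed(61)
  arr2 <- array(runif(5^3 * 8), dim = c(5, 5, 5, 8))
  ser2 <- dynamic_series(arr2, ft, spacing = c(2, 2, 2))
  expect_equal(extract_tac(ser2, m)$values, arr2[1, 1, 1, ])

  # linear in the image data
  arr3 <- array(runif(5^3 * 8), dim = c(5, 5, 5, 8))
  big <- mk_mask(array(runif(125) < 0.4, dim = c(5, 5, 5)),
                 spacing = c(2, 2, 2))
  t2 <- extract_tac(ser2, big)$values
  t3 <- extract_tac(dynamic_series(arr3, ft, spacing = c(2, 2, 2)),
                    big)$values
  t23 <- extract_tac(dynamic_series(3 * arr2 + 2 * arr3, ft,
                                    spacing = c(2, 2, 2)), big)$values
  expect_equal(t23, 3 * t2 + 2 * t3, tolerance = 1e-12)

  none <- mk_mask(array(FALSE, dim = c(5, 5, 5)), spacing = c(2, 2, 2))
  expect_error(extract_tac(ser, none), "empty")
})

test_that("time-to-peak picks the earliest maximal frame mid-time", {
  ft <- default_timing()
  expect_equal(time_to_peak(tac(ft$mid_min, 1:8)), 37.5)
  expect_equal(time_to_peak(tac(ft$mid_min, c(1, 5, 3, 2, 1, 1, 1, 1))), 7.5)
  expect_equal(time_to_peak(tac(ft$mid_min, rep(2, 8))), 2.5)   # tie rule
  expect_error(time_to_peak(tac(10, 1)), "2 frames")
})

test_that("TTP agreement is graded in frame steps", {
  ft <- default_timing()
  expect_equal(ttp_agreement(12.5, 12.5, ft), "identical")
  expect_equal(ttp_agreement(12.5, 17.5, ft), "within_one_frame")
  expect_equal(ttp_agreement(2.5, 22.5, ft), "discordant")
  expect_error(ttp_agreement(13, 17.5, ft), "mid-time")
})

test_that("pattern rules separate increasing, late-peak and early-peak curves", {
  ft <- default_timing()
  # saturating wash-in: peak at the final frame
  v1 <- 1 - exp(-ft$mid_min / 20)
  c1 <- classify_pattern(tac(ft$mid_min, v1))
  expect_equal(c1$pattern, "I")
  expect_equal(c1$ttp_min, 37.5)

  # peak at 27.5 min, final value 0.93 x peak
  v2 <- c(0.3, 0.5, 0.7, 0.85, 0.95, 1.0, 0.97, 0.93)
  c2 <- classify_pattern(tac(ft$mid_min, v2))
  expect_equal(c2$pattern, "II")
  expect_equal(c2$ttp_min, 27.5)
  expect_equal(c2$end_to_peak_ratio, 0.93)

  # early peak at 7.5 min with monotone descent to 0.6 x peak
  v3 <- c(0.8, 1.0, 0.94, 0.88, 0.81, 0.74, 0.67, 0.6)
  c3 <- classify_pattern(tac(ft$mid_min, v3))
  expect_equal(c3$pattern, "III")
  expect_equal(c3$ttp_min, 7.5)

  # classification is invariant to positive rescaling
  expect_equal(classify_pattern(tac(ft$mid_min, v2 * 37))$pattern, "II")
  expect_equal(classify_pattern(tac(ft$mid_min, v3 * 0.01))$pattern, "III")

  # a flat tail within tolerance of the peak counts as still increasing
  v4 <- c(0.3, 0.5, 0.7, 0.85, 0.95, 1.0, 0.99, 0.97)
  expect_equal(classify_pattern(tac(ft$mid_min, v4))$pattern, "I")

  expect_error(classify_pattern(tac(c(1, 2), c(1, 2))), "3 frames")
})

test_that("smoothing averages interior frames and line-fits the ends", {
  v <- c(1, 2, 6, 2, 1)
  sm <- classify_pattern(tac(seq(2.5, by = 5, length.out = 5), v),
                         smooth = TRUE)
  # peak of the smoothed curve: mean(2, 6, 2) = 10/3 at the middle frame
  expect_equal(sm$peak_value, 10 / 3)
  # final frame: degree-1 fit through the last 3 frames evaluated at the
  # end, (5*v5 + 2*v4 - v3)/6 = (5 + 4 - 6)/6 = 0.5
  expect_equal(sm$end_to_peak_ratio, 0.5 / (10 / 3))

  # a noiseless linear TAC is a fixed point of the smoother
  lin <- classify_pattern(tac(seq(2.5, by = 5, length.out = 5),
                              seq(1, 3, length.out = 5)), smooth = TRUE)
  expect_equal(lin$peak_value, 3)
  expect_equal(lin$end_to_peak_ratio, 1)
})

test_that("phantom TACs reproduce the kinetic generator exactly without noise", {
  spec <- small_spec(lesions = list(lesion_spec(center = c(12, 8, 4),
                                                semi_axes = 9,
                                                kinetic_pattern = "III")))
  dph <- generate_dynamic(spec)
  curve <- extract_tac(dph$series, dph$truth_mask)
  expected <- 2.0 * kinetic_curve("III", list(), dph$series$timing,
                                  normalize_late = TRUE)
  expect_equal(curve$values, expected, tolerance = 1e-12)
  expect_equal(time_to_peak(curve), dph$truth$ttp_min)
  expect_equal(classify_pattern(curve)$pattern, "III")
})

test_that("frame-averaged kinetic curves match numeric integration", {
  ft <- default_timing()
  a <- ft$start_s / 60; b <- (ft$start_s + ft$duration_s) / 60
  # pattern I closed form vs numeric quadrature
  g1 <- kinetic_curve("I", list(wash_in_rate = 0.07), ft)
  f1 <- function(t) 1 - exp(-0.07 * t)
  ref1 <- vapply(1:8, function(i) naive_frame_average(f1, a[i], b[i]),
                 numeric(1))
  expect_equal(g1, ref1, tolerance = 1e-6)
  # pattern II piecewise-linear
  g2 <- kinetic_curve("II", list(peak_min = 26, end_ratio = 0.8), ft)
  f2 <- function(t) ifelse(t <= 26, t / 26, 1 - 0.2 * (t - 26) / 14)
  ref2 <- vapply(1:8, function(i) naive_frame_average(f2, a[i], b[i]),
                 numeric(1))
  expect_equal(g2, ref2, tolerance = 1e-6)
  # late normalization makes the duration-weighted 20-40 min mean 1
  g2n <- kinetic_curve("II", list(peak_min = 26, end_ratio = 0.8), ft,
                       normalize_late = TRUE)
  expect_equal(mean(g2n[5:8]), 1, tolerance = 1e-12)
})
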