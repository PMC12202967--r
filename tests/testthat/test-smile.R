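identity_frame <- function() {
  build_frame(frame_fixture())  # canthi (+-300, 0): u = x + 300, v = y
}

test_that("smile arc consonance follows the curvature-direction rule", {
  f <- identity_frame()
  u <- seq(150, 450, length.out = 9)            # frame coords around u = F
  inc <- cbind(u - 300, -0.002 * (u - 300)^2 + 300)  # image x = u - 300
  lip <- cbind(u - 300, -0.003 * (u - 300)^2 + 320)
  res <- classify_smile_arc(inc, lip, f, flatness_tol = 1e-4)
  expect_identical(res$arc, "consonant")
  expect_equal(res$a_incisal, -0.002, tolerance = 1e-9)

  flat <- cbind(u - 300, rep(300, 9))
  expect_identical(classify_smile_arc(flat, lip, f)$arc, "non_consonant")

  expect_error(classify_smile_arc(inc[1:2, ], lip, f), "insufficient")
  collin <- cbind(rep(0, 5), 1:5)
  expect_error(classify_smile_arc(collin, lip, f), "degenerate fit")
})

test_that("fitted curvature recovers a known parabola from noisy points", {
  set.seed(31)
  f <- identity_frame()
  a_true <- -0.0018
  x <- seq(-80, 80, length.out = 25)
  y <- a_true * x^2 + 305 + stats::rnorm(25, 0, 0.8)
  res <- classify_smile_arc(cbind(x, y), cbind(x, y + 15), f)
  # independent least-squares oracle with its own standard error
  or <- summary(stats::lm(y ~ x + I(x^2)))$coefficients
  expect_equal(res$a_incisal, or["I(x^2)", "Estimate"], tolerance = 1e-9)
  expect_lt(abs(res$a_incisal - a_true), 3 * or["I(x^2)", "Std. Error"])
})

test_that("lip curvature compares corners to the upper-lip centre with a dead band", {
  f <- identity_frame()   # height 400, 2% band = 8 px
  ch_r <- c(-95, 280)
  ch_l <- c(95, 280)
  expect_identical(classify_lip_curvature(ch_r, ch_l, c(0, 300), f), "up")
  expect_identical(classify_lip_curvature(ch_r, ch_l, c(0, 280), f),
                   "straight")
  expect_identical(classify_lip_curvature(ch_r, ch_l, c(0, 260), f), "down")
  # inside the dead band
  expect_identical(classify_lip_curvature(ch_r, ch_l, c(0, 285), f),
                   "straight")
})

test_that("smile line classification and its monotonicity", {
  expect_identical(classify_smile_line(1.0, "continuous_band"), "high")
  expect_identical(classify_smile_line(0.80, "papilla_only"), "medium")
  expect_identical(classify_smile_line(0.50, "none"), "low")
  expect_identical(classify_smile_line(1.1, "papilla_only"), "medium")
  for (disp in c("continuous_band", "papilla_only", "none")) {
    codes <- vapply(seq(0, 1.4, by = 0.05), function(e) {
      match(classify_smile_line(e, disp), c("low", "medium", "high"))
    }, integer(1))
    expect_true(all(diff(codes) >= 0))
  }
})

test_that("smile width maps FDI tooth-type digits and rejects others", {
  expect_identical(classify_smile_width(4), "first_premolar")
  expect_identical(classify_smile_width(5), "second_premolar")
  expect_identical(classify_smile_width(6), "first_molar")
  expect_identical(classify_smile_width(7), "second_molar")
  expect_error(classify_smile_width(3), "unsupported")
})

test_that("tooth shape classes partition DP% with boundaries assigned to oval", {
  expect_identical(tooth_shape(4.2, 10)$shape, "triangular")
  expect_equal(tooth_shape(4.2, 10)$dp_percent, 42)
  expect_identical(tooth_shape(5, 10)$shape, "oval")
  expect_identical(tooth_shape(6, 10)$shape, "square")
  expect_identical(tooth_shape(4.3, 10)$shape, "oval")   # DP = 43
  expect_identical(tooth_shape(5.7, 10)$shape, "oval")   # DP = 57
  # no gaps across a DP grid
  dps <- seq(1, 120, by = 0.5)
  shapes <- vapply(dps, function(dp) tooth_shape(dp, 100)$shape, character(1))
  expect_true(all(shapes %in% c("triangular", "oval", "square")))
  expect_true(all(diff(match(shapes,
                             c("triangular", "oval", "square"))) >= 0))
  # alternative index definition inverts the quotient
  expect_equal(tooth_shape(10, 8.5, dp_definition = "width_over_length")$dp_percent,
               85)
})

test_that("tooth size reports the width-to-length golden percent", {
  res <- tooth_size(10, 11.845)
  expect_equal(res$wl_ratio, 1.1845)
  expect_equal(round(res$wl_golden_percent, 1), 73.2)
  expect_equal(round(tooth_size(10, 10)$wl_golden_percent, 2), 61.80)
  expect_equal(tooth_size(1, 1.618)$wl_golden_percent, 100)
  expect_error(tooth_size(0, 5), "positive")
})

test_that("assess_smile bundles classifiers into one tidy row", {
  s <- symmetric_face("A1")
  row <- assess_smile(s, exposure_fraction = 0.9,
                      gingival_display = "papilla_only",
                      last_visible_tooth = 6, tooth_length = 10.5,
                      tooth_width = 12.4)
  expect_identical(row$arc, "consonant")
  expect_identical(row$smile_line, "medium")
  expect_identical(row$smile_width, "first_molar")
  expect_identical(row$tooth_shape, "square")
  expect_equal(row$wl_ratio, 12.4 / 10.5)
})
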