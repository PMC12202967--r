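test_that("default parameters carry the documented generating values", {
  p <- default_parameters()
  expect_equal(p$rfv_mean[["rfv1"]], 0.9981)
  expect_equal(p$rfv_sd[["rfv1"]], 0.08555)
  expect_equal(p$category_probs_pooled$smile_width[["first_molar"]],
               314 / 637)
  expect_equal(p$sex_proportion_female, 350 / 637)
  for (sex in c("female", "male")) {
    for (blk in p$category_probs[[sex]]) {
      expect_equal(sum(blk), 1, tolerance = 1e-12)
    }
  }
  for (blk in p$category_probs_pooled) {
    expect_equal(sum(blk), 1, tolerance = 1e-12)
  }
  expect_true(all(p$rfv_sd >= 0))
})

test_that("template calibration inverts its own forward map", {
  g <- c(230, 170, 150, 330)
  spans <- c(TR_LC = g[1], LC_LN = g[2], LN_CH = g[3], CH_ME = g[4],
             TR_LN = g[1] + g[2], LC_CH = g[2] + g[3], LN_ME = g[3] + g[4],
             LC_ME = g[2] + g[3] + g[4], TR_ME = sum(g))
  defs <- ratio_definitions()
  dv <- defs[defs$type == "vertical", ]
  targets <- stats::setNames(as.numeric(spans[dv$numerator] /
                                          spans[dv$denominator]), dv$key)
  cal <- calibrate_template(targets, anchor_height = sum(g))
  expect_lt(cal$residual, 1e-10)
  expect_equal(unname(cal$positions - cal$positions[["TR"]]),
               c(0, cumsum(g)), tolerance = 1e-6)

  # over-determined published-style targets: finite positive residual,
  # ordered positions
  p <- default_parameters()
  cal_f <- calibrate_template(p$ratio_targets$female)
  expect_true(is.finite(cal_f$residual) && cal_f$residual > 0)
  expect_true(all(diff(cal_f$positions[c("TR", "LC", "LN", "CH", "ME")]) > 0))
})

test_that("degenerate distributions reproduce the parameter means exactly", {
  p <- clean_parameters()
  p$rfv_sd[] <- 0
  coh <- generate_cohort(p, n = 10, seed = 3)
  an <- run_analyze(coh$landmarks, coh$teeth, coh$smile_observations)
  for (k in 1:5) {
    expect_equal(an$rfv[[paste0("rfv", k)]],
                 rep(p$rfv_mean[[paste0("rfv", k)]], 10), tolerance = 1e-12)
  }
})

test_that("generation is deterministic and prefix-stable in n", {
  p <- default_parameters()
  a <- generate_cohort(p, n = 15, seed = 123)
  b <- generate_cohort(p, n = 15, seed = 123)
  expect_identical(a, b)

  small <- generate_cohort(p, n = 6, seed = 123)
  big_first <- a$ground_truth$subjects[1:6, ]
  expect_identical(small$ground_truth$subjects, big_first)
  expect_identical(small$teeth, a$teeth[1:6, ])
})

test_that("ground truth is consistent with the emitted coordinates", {
  coh <- generate_cohort(clean_parameters(), n = 40, seed = 17)
  an <- run_analyze(coh$landmarks, coh$teeth, coh$smile_observations)
  gt <- coh$ground_truth$subjects
  expect_equal(nrow(an$exclusions), 0)

  m <- merge(an$rfv, gt, by = "subject_id", suffixes = c("", ".gt"))
  for (k in paste0("rfv", 1:5)) {
    expect_equal(m[[k]], m[[paste0(k, ".gt")]], tolerance = 1e-9)
  }
  for (k in paste0("rcv", 1:4)) {
    expect_equal(m[[k]], m[[paste0(k, ".gt")]], tolerance = 1e-9)
  }
  sm <- merge(an$smile, gt, by = "subject_id", suffixes = c("", ".gt"))
  for (k in c("arc", "lip_curvature", "smile_line", "smile_width",
              "tooth_shape")) {
    expect_identical(sm[[k]], sm[[paste0(k, ".gt")]])
  }
  rr <- merge(an$ratios, coh$ground_truth$ratios,
              by = c("subject_id", "key"))
  expect_lt(max(abs(rr$value.x / rr$value.y - 1)), 1e-9)
})

test_that("nuisance transforms change no frame-relative quantity", {
  p <- clean_parameters()
  base <- generate_cohort(p, n = 30, seed = 29)
  pt <- p
  pt$roll_range_deg <- c(-15, 15)
  pt$scale_range <- c(0.5, 2)
  pt$translation_range_px <- c(-400, 400)
  coh <- generate_cohort(pt, n = 30, seed = 29)
  an <- run_analyze(coh$landmarks, coh$teeth, coh$smile_observations)
  gt <- coh$ground_truth$subjects
  m <- merge(an$rfv, gt, by = "subject_id", suffixes = c("", ".gt"))
  for (k in paste0("rfv", 1:5)) {
    expect_equal(m[[k]], m[[paste0(k, ".gt")]], tolerance = 1e-9)
  }
  rr <- merge(an$ratios, coh$ground_truth$ratios,
              by = c("subject_id", "key"))
  expect_lt(max(abs(rr$value.x / rr$value.y - 1)), 1e-9)
  # the underlying faces are the same draws as the un-transformed cohort
  expect_equal(base$ground_truth$subjects$rfv1, gt$rfv1)
})

test_that("tooth realizations stay inside the drawn shape class band", {
  coh <- generate_cohort(default_parameters(), n = 200, seed = 41)
  gt <- coh$ground_truth$subjects
  dp <- 100 * coh$teeth$length / coh$teeth$width
  expect_true(all(dp[gt$tooth_shape == "triangular"] < 43))
  expect_true(all(dp[gt$tooth_shape == "oval"] >= 43 &
                    dp[gt$tooth_shape == "oval"] <= 57))
  expect_true(all(dp[gt$tooth_shape == "square"] > 57))
})

test_that("cohort files round-trip through disk", {
  dir <- file.path(tempdir(), "coh_rt")
  coh <- generate_cohort(default_parameters(), n = 8, seed = 55)
  write_cohort(coh, dir)
  sets <- read_landmark_file(file.path(dir, "landmarks.csv"))
  expect_length(sets, 16)   # two views per subject
  teeth <- read_tooth_file(file.path(dir, "teeth.csv"))
  expect_equal(teeth$length, coh$teeth$length, tolerance = 1e-12)
  demo <- read_demographics_file(file.path(dir, "demographics.csv"))
  expect_identical(demo$sex, coh$demographics$sex)
  obs <- read_smile_observations_file(
    file.path(dir, "smile_observations.csv"))
  expect_equal(obs$exposure_fraction, coh$smile_observations$exposure_fraction,
               tolerance = 1e-12)
})
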