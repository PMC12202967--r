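test_that("frame construction matches the canonical fixture geometry", {
  f <- build_frame(frame_fixture())
  expect_equal(f$width, 600)
  expect_equal(f$F, 300)
  expect_equal(f$height, 400)

  rot <- transform_landmark_set(frame_fixture(), angle_deg = 10,
                                translation = c(137, -42))
  fr <- build_frame(rot)
  expect_equal(fr$width, 600, tolerance = 1e-9)
  expect_equal(fr$height, 400, tolerance = 1e-9)

  bad <- landmark_set("X", "frontal_smile", data.frame(
    landmark = c("LC_R", "LC_L", "CH_R", "CH_L", "N", "PRN", "PHT",
                 "DM", "LLI"),
    x = c(1, 1, -95, 95, 0, 0, 0, 0, 0),
    y = c(2, 2, 280, 280, 40, 180, 250, 290, 400)))
  expect_error(build_frame(bad), "degenerate")

  on_line <- frame_fixture()
  on_line$points$y[on_line$points$landmark == "LLI"] <- 0
  expect_error(build_frame(on_line), "LLI")
})

test_that("u-projection anchors at the lateral borders and ignores rotation", {
  s <- frame_fixture()
  f <- build_frame(s)
  expect_equal(project_u(f, c(0, 123)), f$F)
  expect_equal(project_u(f, landmark_xy(s, "LC_L")), 2 * f$F)
  expect_equal(project_u(f, c(40, -500)), project_u(f, c(40, 700)))

  rot <- transform_landmark_set(s, angle_deg = 10, scale = 1,
                                translation = c(-15, 88))
  fr <- build_frame(rot)
  for (nm in c("N", "PRN", "DM", "CH_R")) {
    expect_equal(project_u(fr, landmark_xy(rot, nm)),
                 project_u(f, landmark_xy(s, nm)), tolerance = 1e-9)
  }
})

test_that("RFVs are 1 in symmetry, linear in displacement, and mirror to 2-rfv", {
  s <- frame_fixture()
  f <- build_frame(s)
  rfv <- compute_rfv(f, s)
  expect_equal(as.numeric(rfv[1, paste0("rfv", 1:5)]), rep(1, 5))

  shifted <- s
  shifted$points$x[shifted$points$landmark == "N"] <- -30  # 0.1 F to the right
  fs <- build_frame(shifted)
  rfv_s <- compute_rfv(fs, shifted)
  expect_equal(rfv_s$rfv1, 0.9)
  expect_equal(as.numeric(rfv_s[1, paste0("rfv", 2:5)]), rep(1, 4))

  set.seed(42)
  for (i in 1:10) {
    face <- random_face(sprintf("R%02d", i))
    rfv0 <- compute_rfv(build_frame(face), face)
    mir <- mirror_landmark_set(face, x0 = 57.3)
    rfv_m <- compute_rfv(build_frame(mir), mir)
    expect_equal(as.numeric(rfv_m[1, paste0("rfv", 1:5)]),
                 2 - as.numeric(rfv0[1, paste0("rfv", 1:5)]),
                 tolerance = 1e-12)
  }
})

test_that("RCVs normalise by the commissure midline and satisfy the identity", {
  s <- frame_fixture()
  # shift commissure midline to u = 1.05 F, keep dental midline at u = F
  s$points$x[s$points$landmark == "CH_R"] <- -95 + 15
  s$points$x[s$points$landmark == "CH_L"] <- 95 + 15
  f <- build_frame(s)
  rcv <- compute_rcv(f, s)
  expect_equal(rcv$rcv4, 1 / 1.05, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    face <- random_face(sprintf("I%02d", i))
    f <- build_frame(face)
    rfv <- compute_rfv(f, face)
    rcv <- compute_rcv(f, face)
    for (k in 1:4) {
      expect_equal(rcv[[paste0("rcv", k)]] * rfv$rfv5,
                   rfv[[paste0("rfv", k)]], tolerance = 1e-12)
    }
  }
})

test_that("coincident landmark u-positions share the same RFV", {
  s <- frame_fixture()
  s$points$x[s$points$landmark %in% c("N", "PRN")] <- -21
  f <- build_frame(s)
  rfv <- compute_rfv(f, s)
  expect_identical(rfv$rfv1, rfv$rfv2)
})

test_that("side classification follows the less/greater-than-1 rule", {
  expect_identical(classify_side(0.98, tol = 0), "right")
  expect_identical(classify_side(1.0, tol = 0), "centered")
  expect_identical(classify_side(1.0, tol = 0.1), "centered")
  expect_identical(classify_side(1.03, tol = 0.05), "centered")
  expect_identical(classify_side(1.06, tol = 0.05), "left")
  expect_identical(classify_side(c(0.9, 1, 1.1)), c("right", "centered", "left"))
})

test_that("landmark hierarchy sorts by mean RFV with canonical tie-break", {
  cohort <- tibble::tibble(rfv1 = 0.9981, rfv2 = 0.9964, rfv3 = 0.9924,
                           rfv4 = 0.9851, rfv5 = 0.9917)
  expect_identical(landmark_hierarchy(cohort),
                   c("nasion", "nose_tip", "philtrum",
                     "commissure_midline", "dental_midline"))

  tied <- tibble::tibble(rfv1 = 1, rfv2 = 1, rfv3 = 1, rfv4 = 1, rfv5 = 1)
  expect_identical(landmark_hierarchy(tied),
                   c("nasion", "nose_tip", "philtrum",
                     "commissure_midline", "dental_midline"))

  two <- tibble::tibble(rfv1 = c(0.95, 0.97), rfv2 = c(1.02, 1.06),
                        rfv3 = c(1.0, 0.98), rfv4 = c(0.9, 0.92),
                        rfv5 = c(1.01, 0.97))
  means <- colMeans(two)                       # brute-force oracle
  labels <- c("nasion", "nose_tip", "philtrum", "dental_midline",
              "commissure_midline")
  expect_identical(landmark_hierarchy(two), labels[order(-means)])

  expect_error(landmark_hierarchy(tibble::tibble()), "empty")
})

test_that("RFV/RCV are invariant under similarity transforms", {
  set.seed(99)
  for (i in 1:10) {
    face <- random_face(sprintf("T%02d", i))
    f0 <- build_frame(face)
    base <- c(as.numeric(compute_rfv(f0, face)[1, -1]),
              as.numeric(compute_rcv(f0, face)[1, -1]))
    tr <- transform_landmark_set(face,
                                 angle_deg = stats::runif(1, -15, 15),
                                 scale = stats::runif(1, 0.5, 2),
                                 translation = stats::runif(2, -500, 500))
    ft <- build_frame(tr)
    after <- c(as.numeric(compute_rfv(ft, tr)[1, -1]),
               as.numeric(compute_rcv(ft, tr)[1, -1]))
    expect_equal(after, base, tolerance = 1e-9)
  }
})
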