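# Fixtures built in code: canonical faces and random asymmetric faces.

# The canonical frame fixture: canthi at (+-300, 0), LLI at (0, 400),
# commissures at (+-95, 280), all midline landmarks on x = 0.
frame_fixture <- function(subject_id = "FIX") {
  landmark_set(subject_id, "frontal_smile", data.frame(
    landmark = c("LC_R", "LC_L", "N", "PRN", "PHT", "DM", "LLI",
                 "CH_R", "CH_L", "ULC"),
    x = c(-300, 300, 0, 0, 0, 0, 0, -95, 95, 0),
    y = c(0, 0, 40, 180, 250, 290, 400, 280, 280, 275)
  ))
}

# A random asymmetric face: midline landmarks displaced horizontally by
# fractions of F, commissure midline offset too. Built directly (not via the
# cohort generator) so frame-module tests stay independent of it.
random_face <- function(subject_id = "RND", f_half = 300) {
  off <- stats::runif(5, -0.15, 0.15)          # u-offsets as fractions of F
  cx <- (1 + off[5]) * f_half
  ch_half <- stats::runif(1, 80, 110)
  landmark_set(subject_id, "frontal_smile", data.frame(
    landmark = c("LC_R", "LC_L", "N", "PRN", "PHT", "DM", "LLI",
                 "CH_R", "CH_L", "ULC"),
    x = c(0, 2 * f_half, (1 + off[1]) * f_half, (1 + off[2]) * f_half,
          (1 + off[3]) * f_half, (1 + off[4]) * f_half, f_half,
          cx - ch_half, cx + ch_half, cx),
    y = c(0, 0, 40, 180, 250, 290, 400, 280, 280, 275)
  ))
}

# Full proportion fixture with prescribed vertical levels and widths.
proportion_fixture <- function(subject_id = "PROP",
                               lev = c(TR = 0, LC = 100, LN = 200,
                                       CH = 280, ME = 400),
                               widths = c(TS = 250, LC = 170, LN = 60,
                                          CH = 95)) {
  landmark_set(subject_id, "frontal_rest", data.frame(
    landmark = c("TR", "ME", "TS_R", "TS_L", "LC_R", "LC_L",
                 "LN_R", "LN_L", "CH_R", "CH_L"),
    x = c(0, 0, -widths[["TS"]], widths[["TS"]], -widths[["LC"]],
          widths[["LC"]], -widths[["LN"]], widths[["LN"]],
          -widths[["CH"]], widths[["CH"]]),
    y = c(lev[["TR"]], lev[["ME"]], rep(lev[["LC"]] - 40, 2),
          rep(lev[["LC"]], 2), rep(lev[["LN"]], 2), rep(lev[["CH"]], 2))
  ))
}

# Noise-free, un-transformed cohort parameters.
clean_parameters <- function() {
  p <- default_parameters()
  p$roll_range_deg <- c(0, 0)
  p$scale_range <- c(1, 1)
  p$translation_range_px <- c(0, 0)
  p$noise_sd_px <- 0
  p
}
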