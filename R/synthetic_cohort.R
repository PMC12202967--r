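# Synthetic photographic-cohort generator: emulates the statistical
# structure of a frontal-photograph study population (midline landmark
# offsets, facial proportions, smile-framework attributes) so the whole
# pipeline is testable without patient images.

#' Default cohort parameters
#'
#' The generating distributions of the synthetic cohort: pooled RFV means
#' and SDs for the five midline landmarks, per-sex facial-proportion ratio
#' targets (used to calibrate the landmark position template), per-sex
#' smile-framework category probabilities, tooth-measurement settings,
#' landmark jitter, and the per-photograph nuisance transform (head roll,
#' scale, translation, pixel noise). The cohort size and 350:287
#' female:male split mirror a typical large clinical photograph study.
#'
#' The RFV defaults are identical for the two sexes: the sex-stratified
#' summary statistics available for these quantities are not mutually
#' consistent with their pooled values (their sample-size-weighted average
#' disagrees with the pooled mean and would invert the landmark hierarchy),
#' so the pooled values are taken as the generating truth; the stratified
#' figures are retained under `reference` for inspection only.
#'
#' @return A list of class `cohort_parameters`.
#' @export
default_parameters <- function() {
  ratio_targets <- list(
    female = c("TR-ME:LC-ME" = 1.69, "LC-ME:TR-LC" = 1.45,
               "TR-LN:LN-ME" = 1.53, "LN-ME:LC-LN" = 2.05,
               "LC-CH:CH-ME" = 1.53, "LC-LN:LN-CH" = 1.25,
               "CH-ME:LN-CH" = 1.47, "CH(r-l):LN(r-l)" = 1.47,
               "LC(r-l):CH(r-l)" = 1.78, "TS(r-l):LC(r-l)" = 1.54),
    male = c("TR-ME:LC-ME" = 1.63, "LC-ME:TR-LC" = 1.59,
             "TR-LN:LN-ME" = 1.35, "LN-ME:LC-LN" = 2.15,
             "LC-CH:CH-ME" = 1.40, "LC-LN:LN-CH" = 1.13,
             "CH-ME:LN-CH" = 1.54, "CH(r-l):LN(r-l)" = 1.46,
             "LC(r-l):CH(r-l)" = 1.66, "TS(r-l):LC(r-l)" = 1.51)
  )
  category_probs <- list(
    female = list(
      arc = c(consonant = 291, non_consonant = 59) / 350,
      lip_curvature = c(up = 185, straight = 101, down = 64) / 350,
      smile_line = c(high = 94, medium = 196, low = 60) / 350,
      smile_width = c(first_premolar = 34, second_premolar = 141,
                      first_molar = 167, second_molar = 8) / 350,
      tooth_shape = c(triangular = 8, oval = 129, square = 213) / 350
    ),
    male = list(
      arc = c(consonant = 234, non_consonant = 53) / 287,
      lip_curvature = c(up = 161, straight = 73, down = 53) / 287,
      smile_line = c(high = 66, medium = 185, low = 36) / 287,
      smile_width = c(first_premolar = 33, second_premolar = 86,
                      first_molar = 155, second_molar = 13) / 287,
      tooth_shape = c(triangular = 20, oval = 129, square = 138) / 287
    )
  )
  category_probs_pooled <- list(
    arc = c(consonant = 527, non_consonant = 110) / 637,
    lip_curvature = c(up = 342, straight = 178, down = 117) / 637,
    smile_line = c(high = 164, medium = 371, low = 102) / 637,
    smile_width = c(first_premolar = 64, second_premolar = 240,
                    first_molar = 314, second_molar = 19) / 637,
    tooth_shape = c(triangular = 21, oval = 248, square = 368) / 637
  )
  params <- list(
    n_subjects = 637L,
    sex_proportion_female = 350 / 637,
    rfv_mean = c(rfv1 = 0.9981, rfv2 = 0.9964, rfv3 = 0.9924,
                 rfv4 = 0.9851, rfv5 = 0.9917),
    rfv_sd = c(rfv1 = 0.08555, rfv2 = 0.07881, rfv3 = 0.07127,
               rfv4 = 0.08949, rfv5 = 0.07433),
    ratio_targets = ratio_targets,
    category_probs = category_probs,
    category_probs_pooled = category_probs_pooled,
    face_height_px = 1000,          # trichion-to-menton template scale
    intercanthal_px = 600,          # outer intercanthal width anchor
    vertical_jitter_sd = 4,         # px, per landmark level
    transverse_jitter_sd = 4,       # px, per right-left width
    tooth_length_mean = 10.5,       # mm, maxillary central clinical crown
    tooth_length_sd = 0.8,
    # DP% (length/width x 100) realization bands per drawn shape class;
    # the square band is centred at 100/1.1845 so the square-majority
    # cohort mean width/length sits near the reference 1.1845
    dp_bands = list(
      triangular = c(mean = 38, sd = 3, lo = 25, hi = 42.9),
      oval = c(mean = 50, sd = 4, lo = 43, hi = 57),
      square = c(mean = 84.42, sd = 10, lo = 57.5, hi = 115)
    ),
    age_mean = 22.13, age_sd = 4.29, age_range = c(18, 40),
    roll_range_deg = c(-5, 5),
    scale_range = c(0.9, 1.1),
    translation_range_px = c(-100, 100),
    noise_sd_px = 0.5,
    seed = NULL,
    reference = list(
      rfv_by_sex = list(
        female = c(0.9994, 0.9950, 0.9912, 0.9853, 0.9910),
        female_sd = c(0.0888, 0.08887, 0.07960, 0.09340, 0.08309),
        male = c(0.9943, 1.0007, 0.9957, 0.9844, 0.9937),
        male_sd = c(0.0755, 0.03707, 0.03851, 0.07767, 0.03986)
      ),
      rcv_mean = c(rcv1 = 1.0153, rcv2 = 1.0039, rcv3 = 0.9987,
                   rcv4 = 0.9902),
      wl_ratio = c(mean = 1.1845, sd = 0.14123)
    )
  )
  params$template <- list(
    female = build_template(params, "female"),
    male = build_template(params, "male")
  )
  class(params) <- "cohort_parameters"
  params
}

#' Calibrate the vertical landmark template from ratio targets
#'
#' Finds the five vertical landmark levels (TR, LC, LN, CH, ME) whose seven
#' vertical span ratios best match the targets, by least squares on the log
#' ratios over the four inter-landmark gaps (the system is over-determined:
#' seven targets, three free gap proportions). The template is scaled so the
#' trichion-menton span equals `anchor_height`, with the menton as anchor.
#'
#' @param target_ratios Named numeric vector of vertical ratio targets
#'   (names as in [ratio_definitions()]).
#' @param anchor_height Trichion-to-menton span of the returned template
#'   (pixels).
#' @return List with `positions` (named levels `TR, LC, LN, CH, ME`, `LC`
#'   at 0 and v increasing downward), `gaps`, `residual` (root sum of
#'   squared log-ratio mismatches) and `convergence`.
#' @export
calibrate_template <- function(target_ratios, anchor_height = 1000) {
  defs <- ratio_definitions()
  keys <- intersect(defs$key[defs$type == "vertical"], names(target_ratios))
  if (length(keys) == 0) stop("no vertical ratio targets supplied")
  targets <- target_ratios[keys]
  if (any(targets <= 0)) stop("ratio targets must be positive")
  spans_from_gaps <- function(g) {
    c(TR_LC = g[1], LC_LN = g[2], LN_CH = g[3], CH_ME = g[4],
      TR_LN = g[1] + g[2], LC_CH = g[2] + g[3], LN_ME = g[3] + g[4],
      LC_ME = g[2] + g[3] + g[4], TR_ME = sum(g))
  }
  d <- defs[defs$key %in% keys, ]
  resid_vec <- function(lg) {
    g <- exp(lg)
    s <- spans_from_gaps(g / sum(g))
    log(s[d$numerator] / s[d$denominator]) - log(targets[d$key])
  }
  obj <- function(lg) sum(resid_vec(lg)^2)
  fit <- stats::optim(log(rep(0.25, 4)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  # Gauss-Newton polish (numerical Jacobian, damped) down to the exact
  # solution when the targets are mutually consistent
  par <- fit$par
  for (it in 1:50) {
    r <- resid_vec(par)
    if (sum(r^2) < 1e-26) break
    J <- vapply(seq_along(par), function(j) {
      h <- 1e-7
      e <- par
      e[j] <- e[j] + h
      (resid_vec(e) - r) / h
    }, numeric(length(r)))
    step <- tryCatch(
      solve(crossprod(J) + 1e-12 * diag(length(par)), crossprod(J, r)),
      error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - as.numeric(step)
    if (obj(cand) >= sum(r^2)) break
    par <- cand
  }
  g <- exp(par)
  g <- g / sum(g) * anchor_height
  positions <- c(TR = -g[1], LC = 0, LN = g[2], CH = g[2] + g[3],
                 ME = g[2] + g[3] + g[4])
  list(positions = positions, gaps = unname(g),
       residual = sqrt(obj(par)), convergence = fit$convergence)
}

# Full per-sex geometric template: vertical levels (LC = 0, v downward)
# and right-left widths solved in closed form from the transverse targets.
build_template <- function(params, sex) {
  tr <- params$ratio_targets[[sex]]
  cal <- calibrate_template(tr, anchor_height = params$face_height_px)
  lc_rl <- params$intercanthal_px
  ch_rl <- lc_rl / tr[["LC(r-l):CH(r-l)"]]
  ln_rl <- ch_rl / tr[["CH(r-l):LN(r-l)"]]
  ts_rl <- lc_rl * tr[["TS(r-l):LC(r-l)"]]
  list(v = cal$positions, residual = cal$residual,
       widths = c(TS_rl = unname(ts_rl), LC_rl = lc_rl,
                  LN_rl = unname(ln_rl), CH_rl = unname(ch_rl)))
}

validate_parameters <- function(params) {
  stopifnot(inherits(params, "cohort_parameters") || is.list(params))
  if (params$n_subjects < 1) stop("n_subjects must be >= 1")
  if (params$sex_proportion_female < 0 || params$sex_proportion_female > 1) {
    stop("sex_proportion_female must be in [0, 1]")
  }
  if (any(params$rfv_sd < 0)) stop("rfv_sd must be non-negative")
  for (sex in c("female", "male")) {
    for (blk in params$category_probs[[sex]]) {
      if (any(blk < 0) || abs(sum(blk) - 1) > 1e-6) {
        stop("each category probability block must sum to 1")
      }
    }
  }
  if (params$noise_sd_px < 0) stop("noise_sd_px must be non-negative")
  invisible(TRUE)
}

draw_in_band <- function(band) {
  repeat {
    x <- stats::rnorm(1, band[["mean"]], band[["sd"]])
    if (x > band[["lo"]] && x < band[["hi"]]) return(x)
  }
}

#' Generate a synthetic landmark cohort
#'
#' Draws, per subject: sex; the five true RFVs (truncated normal at 4 SD);
#' jittered template landmark levels and widths; the five smile-framework
#' categories from the sex-specific multinomials, each realised
#' geometrically so that analysing the noise-free coordinates reproduces
#' the drawn category exactly; and tooth crown measurements realised inside
#' the drawn shape class's DP band. A per-photograph similarity transform
#' (head roll, scale, translation) and Gaussian pixel noise are applied
#' last. Each subject consumes an independent sub-stream derived from the
#' global seed, so earlier subjects are identical across runs with
#' different `n`; an identical seed gives byte-identical output.
#'
#' @param params A `cohort_parameters` list (see [default_parameters()]).
#' @param n Number of subjects (defaults to `params$n_subjects`).
#' @param seed Integer seed (defaults to `params$seed`).
#' @return List of class `synthetic_cohort` with tibbles `landmarks` (long
#'   table mirroring the landmark CSV schema), `teeth`, `demographics`,
#'   `smile_observations`, and `ground_truth` (list with `subjects` and
#'   long `ratios`).
#' @export
generate_cohort <- function(params = default_parameters(),
                            n = params$n_subjects, seed = params$seed) {
  validate_parameters(params)
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2147483646L, n)

  lm_rows <- vector("list", n)
  gt_rows <- vector("list", n)
  ratio_rows <- vector("list", n)
  teeth <- data.frame(subject_id = character(n), length = numeric(n),
                      width = numeric(n))
  demo <- data.frame(subject_id = character(n), sex = character(n),
                     age = numeric(n))
  obs <- data.frame(subject_id = character(n), exposure_fraction = numeric(n),
                    gingival_display = character(n),
                    last_visible_tooth = integer(n))
  width_code <- c(first_premolar = 4L, second_premolar = 5L,
                  first_molar = 6L, second_molar = 7L)

  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    sid <- sprintf("S%04d", i)
    sex <- if (stats::runif(1) < params$sex_proportion_female) "female"
           else "male"
    tmpl <- params$template[[sex]]

    rfv <- rnorm_trunc(5, params$rfv_mean, params$rfv_sd)

    vj <- params$vertical_jitter_sd
    tj <- params$transverse_jitter_sd
    lev <- tmpl$v + c(stats::rnorm(1, 0, vj), 0, stats::rnorm(3, 0, vj))
    widths <- pmax(tmpl$widths + stats::rnorm(4, 0, tj), 10)
    f_half <- widths[["LC_rl"]] / 2
    cx <- rfv[5] * f_half

    # ground-truth proportion distances from the jittered template
    spans <- c(TR_ME = lev[["ME"]] - lev[["TR"]],
               LC_ME = lev[["ME"]] - lev[["LC"]],
               TR_LC = lev[["LC"]] - lev[["TR"]],
               TR_LN = lev[["LN"]] - lev[["TR"]],
               LN_ME = lev[["ME"]] - lev[["LN"]],
               LC_LN = lev[["LN"]] - lev[["LC"]],
               LC_CH = lev[["CH"]] - lev[["LC"]],
               CH_ME = lev[["ME"]] - lev[["CH"]],
               LN_CH = lev[["CH"]] - lev[["LN"]])
    true_ratios <- compute_ratios(c(spans, widths))

    probs <- params$category_probs[[sex]]
    draw_cat <- function(block) sample(names(block), 1, prob = block)
    arc <- draw_cat(probs$arc)
    lip <- draw_cat(probs$lip_curvature)
    line <- draw_cat(probs$smile_line)
    width_cat <- draw_cat(probs$smile_width)
    shape <- draw_cat(probs$tooth_shape)

    v_lli <- lev[["CH"]] + 0.45 * (lev[["ME"]] - lev[["CH"]]) +
      stats::rnorm(1, 0, vj)
    height <- v_lli                       # canthal line is v = 0
    v_dm <- lev[["CH"]] + 0.10 * (v_lli - lev[["CH"]])
    delta <- switch(lip,
      up = stats::runif(1, 0.03, 0.08) * height,
      straight = stats::runif(1, -0.5, 0.5) * 0.02 * height,
      down = -stats::runif(1, 0.03, 0.08) * height)
    v_ulc <- lev[["CH"]] + delta

    # smile-arc curves: quadratics in frame coordinates, vertex above the
    # commissure midline; consonant = both curvatures clearly negative
    w_arc <- 0.35 * widths[["CH_rl"]]
    a_inc <- if (arc == "consonant") -stats::runif(1, 6e-4, 2.5e-3)
             else stats::runif(1, 0, 1.5e-3)
    a_lip <- -stats::runif(1, 6e-4, 2.5e-3)
    u_inc <- seq(cx - w_arc, cx + w_arc, length.out = 7)
    u_lip <- seq(cx - 1.15 * w_arc, cx + 1.15 * w_arc, length.out = 9)
    lip_off <- stats::runif(1, 6, 14)
    inc_pts <- cbind(u_inc, a_inc * (u_inc - cx)^2 + v_dm)
    lip_pts <- cbind(u_lip, a_lip * (u_lip - cx)^2 + v_dm + lip_off)

    exposure <- switch(line,
      high = stats::runif(1, 1.0, 1.3),
      medium = stats::runif(1, 0.75, 0.999),
      low = stats::runif(1, 0.35, 0.745))
    display <- switch(line, high = "continuous_band",
                      medium = "papilla_only", low = "none")

    tooth_len <- rnorm_trunc(1, params$tooth_length_mean,
                             params$tooth_length_sd)
    dp <- draw_in_band(params$dp_bands[[shape]])
    tooth_wid <- 100 * tooth_len / dp

    age <- min(max(rnorm_trunc(1, params$age_mean, params$age_sd),
                   params$age_range[1]), params$age_range[2])

    # untransformed coordinates (frame coordinates: x = u, y = v)
    rest <- rbind(
      TR = c(f_half, lev[["TR"]]),
      TS_R = c(f_half - widths[["TS_rl"]] / 2, 0.55 * lev[["TR"]]),
      TS_L = c(f_half + widths[["TS_rl"]] / 2, 0.55 * lev[["TR"]]),
      LC_R = c(0, 0), LC_L = c(2 * f_half, 0),
      LN_R = c(f_half - widths[["LN_rl"]] / 2, lev[["LN"]]),
      LN_L = c(f_half + widths[["LN_rl"]] / 2, lev[["LN"]]),
      CH_R = c(cx - widths[["CH_rl"]] / 2, lev[["CH"]]),
      CH_L = c(cx + widths[["CH_rl"]] / 2, lev[["CH"]]),
      ME = c(f_half, lev[["ME"]])
    )
    smile <- rbind(
      LC_R = c(0, 0), LC_L = c(2 * f_half, 0),
      N = c(rfv[1] * f_half, 0.18 * lev[["LN"]]),
      PRN = c(rfv[2] * f_half, 0.95 * lev[["LN"]]),
      PHT = c(rfv[3] * f_half,
              lev[["CH"]] - 0.25 * (lev[["CH"]] - lev[["LN"]])),
      DM = c(rfv[4] * f_half, v_dm),
      ULC = c(cx, v_ulc),
      LLI = c(f_half, v_lli),
      CH_R = c(cx - widths[["CH_rl"]] / 2, lev[["CH"]]),
      CH_L = c(cx + widths[["CH_rl"]] / 2, lev[["CH"]])
    )

    nuisance <- function(xy) {
      xy <- similarity_transform(
        xy,
        angle_deg = runif_range(1, params$roll_range_deg),
        scale = runif_range(1, params$scale_range),
        translation = c(runif_range(1, params$translation_range_px),
                        runif_range(1, params$translation_range_px)))
      if (params$noise_sd_px > 0) {
        xy <- xy + stats::rnorm(length(xy), 0, params$noise_sd_px)
      }
      xy
    }
    rest_t <- nuisance(rest)
    smile_all <- rbind(smile, inc_pts, lip_pts)
    smile_all_t <- nuisance(smile_all)
    n_sm <- nrow(smile)
    smile_t <- smile_all_t[seq_len(n_sm), , drop = FALSE]
    inc_t <- smile_all_t[n_sm + seq_len(nrow(inc_pts)), , drop = FALSE]
    lip_t <- smile_all_t[n_sm + nrow(inc_pts) + seq_len(nrow(lip_pts)), ,
                         drop = FALSE]

    lm_rows[[i]] <- data.frame(
      subject_id = sid,
      view = c(rep("frontal_rest", nrow(rest)),
               rep("frontal_smile", n_sm + nrow(inc_pts) + nrow(lip_pts))),
      landmark = c(rownames(rest), rownames(smile),
                   paste0("INC_", seq_len(nrow(inc_pts))),
                   paste0("LIP_", seq_len(nrow(lip_pts)))),
      x = c(rest_t[, 1], smile_t[, 1], inc_t[, 1], lip_t[, 1]),
      y = c(rest_t[, 2], smile_t[, 2], inc_t[, 2], lip_t[, 2])
    )
    teeth[i, ] <- list(sid, tooth_len, tooth_wid)
    demo[i, ] <- list(sid, sex, age)
    obs[i, ] <- list(sid, exposure, display, width_code[[width_cat]])
    gt_rows[[i]] <- data.frame(
      subject_id = sid, sex = sex,
      rfv1 = rfv[1], rfv2 = rfv[2], rfv3 = rfv[3], rfv4 = rfv[4],
      rfv5 = rfv[5],
      rcv1 = rfv[1] / rfv[5], rcv2 = rfv[2] / rfv[5],
      rcv3 = rfv[3] / rfv[5], rcv4 = rfv[4] / rfv[5],
      arc = arc, lip_curvature = lip, smile_line = line,
      smile_width = width_cat, tooth_shape = shape,
      dp_percent = dp, wl_ratio = tooth_wid / tooth_len,
      exposure_fraction = exposure, gingival_display = display,
      last_visible_tooth = width_code[[width_cat]]
    )
    tr <- true_ratios
    tr$subject_id <- sid
    ratio_rows[[i]] <- tr[, c("subject_id", "key", "value", "golden_pct")]
  }

  structure(
    list(
      landmarks = tibble::as_tibble(do.call(rbind, lm_rows)),
      teeth = tibble::as_tibble(teeth),
      demographics = tibble::as_tibble(demo),
      smile_observations = tibble::as_tibble(obs),
      ground_truth = list(
        subjects = tibble::as_tibble(do.call(rbind, gt_rows)),
        ratios = tibble::as_tibble(do.call(rbind, ratio_rows))
      ),
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$demographics), "subjects, seed",
      x$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `landmarks.csv`, `teeth.csv`, `demographics.csv`,
#' `smile_observations.csv` and `ground_truth.json` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$landmarks, file.path(dir, "landmarks.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$teeth, file.path(dir, "teeth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$smile_observations,
                   file.path(dir, "smile_observations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' A perfectly bilaterally symmetric fixture face
#'
#' Canthi at `(±300, 0)`, every midline landmark exactly on the
#' perpendicular bisector of the intercanthal segment, commissures
#' equidistant from it. Analysing this face yields RFV = RCV = 1 for every
#' landmark. Useful as a geometric identity fixture.
#'
#' @param subject_id Subject identifier.
#' @param with_curves Include symmetric incisal-edge and lower-lip curves?
#' @return A `facial_landmark_set` containing the landmarks of all analyses.
#' @export
symmetric_face <- function(subject_id = "SYM", with_curves = TRUE) {
  pts <- data.frame(
    landmark = c("TR", "TS_R", "TS_L", "LC_R", "LC_L", "N", "PRN",
                 "LN_R", "LN_L", "PHT", "CH_R", "CH_L", "DM", "ULC",
                 "LLI", "ME"),
    x = c(0, -462, 462, -300, 300, 0, 0, -115, 115, 0, -169, 169, 0, 0,
          0, 0),
    y = c(-250, -137.5, -137.5, 0, 0, 45, 237.5, 250, 250, 310, 370, 370,
          383.5, 370, 430.75, 707)
  )
  curves <- NULL
  if (with_curves) {
    u <- seq(-59, 59, length.out = 7)
    inc <- cbind(u, -0.0015 * u^2 + 383.5)
    ul <- seq(-68, 68, length.out = 9)
    lip <- cbind(ul, -0.002 * ul^2 + 393.5)
    return(landmark_set(subject_id, "frontal_smile", pts,
                        incisal_edge = inc, lower_lip = lip))
  }
  landmark_set(subject_id, "frontal_smile", pts)
}

#' Convert a long landmark table to landmark sets
#'
#' Accepts the in-memory analogue of the landmark CSV (columns
#' `subject_id, view, landmark, x, y`) and builds one
#' `facial_landmark_set` per (subject, view), preserving curve-point order.
#'
#' @param landmarks Data frame in the landmark CSV schema.
#' @return List of `facial_landmark_set`.
#' @export
landmarks_to_sets <- function(landmarks) {
  df <- as.data.frame(landmarks)
  build_one <- function(block) {
    is_inc <- grepl("^INC_[0-9]+$", block$landmark)
    is_lip <- grepl("^LIP_[0-9]+$", block$landmark)
    curve <- function(sel, prefix) {
      if (!any(sel)) return(NULL)
      b <- block[sel, , drop = FALSE]
      b <- b[order(as.integer(sub(paste0(prefix, "_"), "", b$landmark))), ]
      cbind(x = b$x, y = b$y)
    }
    landmark_set(block$subject_id[1], block$view[1],
                 data.frame(landmark = block$landmark[!is_inc & !is_lip],
                            x = block$x[!is_inc & !is_lip],
                            y = block$y[!is_inc & !is_lip]),
                 incisal_edge = curve(is_inc, "INC"),
                 lower_lip = curve(is_lip, "LIP"))
  }
  key <- paste(df$subject_id, df$view, sep = "\r")
  blocks <- split(df, key)
  first <- vapply(blocks, function(b)
    min(match(paste(b$subject_id, b$view, sep = "\r"), key)), integer(1))
  unname(lapply(blocks[order(first)], build_one))
}
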