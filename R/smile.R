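# The smile framework: smile arc, upper lip curvature, smile line, smile
# width, tooth shape (DP%) and tooth size versus the golden ratio.

#' Classify the smile arc
#'
#' The smile arc is the relationship between the curvature of the maxillary
#' incisal-edge line (canine to canine) and the curvature of the lower lip's
#' upper border in a posed smile. A least-squares quadratic
#' `v = a*u^2 + b*u + c` is fitted to each point list in frame coordinates
#' (v increasing downward): both curves dipping centrally — both curvature
#' coefficients `a` below `-flatness_tol` — is a consonant arc; anything
#' else (a flat or reverse incisal line, or a flat lip) is non-consonant.
#' Curvature direction alone decides; magnitudes need not match.
#'
#' @param incisal_points,lower_lip_points n-by-2 matrices of image
#'   coordinates (at least 3 points each).
#' @param frame A `beauty_frame` used to express the points in
#'   head-roll-free frame coordinates.
#' @param flatness_tol Curvature threshold in 1/px below which an arc is
#'   considered flat (default `1e-4`).
#' @return List with `arc` (`"consonant"` or `"non_consonant"`) and the two
#'   fitted curvature coefficients `a_incisal`, `a_lip`.
#' @export
classify_smile_arc <- function(incisal_points, lower_lip_points, frame,
                               flatness_tol = 1e-4) {
  fit_a <- function(pts, what) {
    pts <- as.matrix(pts)
    if (nrow(pts) < 3) stop("insufficient points for ", what,
                            " curve (need >= 3)")
    u <- project_u(frame, pts)
    v <- project_v(frame, pts)
    if (length(unique(round(u, 9))) < 3) {
      stop("degenerate fit: ", what, " points collinear in u")
    }
    uc <- u - mean(u)  # centred for numerical stability; a is unchanged
    unname(stats::lm.fit(cbind(1, uc, uc^2), v)$coefficients[3])
  }
  a_inc <- fit_a(incisal_points, "incisal-edge")
  a_lip <- fit_a(lower_lip_points, "lower-lip")
  consonant <- (a_inc < -flatness_tol) && (a_lip < -flatness_tol)
  list(arc = if (consonant) "consonant" else "non_consonant",
       a_incisal = a_inc, a_lip = a_lip)
}

#' Classify the upper lip curvature
#'
#' Upwards, straight or downwards from the position of the mouth corners
#' relative to the centre of the upper lip's lower margin (ULC): with v
#' increasing downward, `delta = v(ULC) - mean(v(CH_R), v(CH_L))` is
#' positive when the corners sit above the lip centre (an upward smile).
#' Categories flip only when `|delta|` exceeds `tol_frac` of the frame
#' height, so sub-pixel differences stay "straight".
#'
#' @param ch_r,ch_l,ulc `c(x, y)` image coordinates of the two mouth corners
#'   and the upper-lip centre.
#' @param frame A `beauty_frame`.
#' @param tol_frac Dead-band as a fraction of frame height (default 0.02).
#' @return `"up"`, `"straight"` or `"down"`.
#' @export
classify_lip_curvature <- function(ch_r, ch_l, ulc, frame, tol_frac = 0.02) {
  stopifnot(tol_frac >= 0, tol_frac < 1)
  delta <- project_v(frame, ulc) -
    mean(c(project_v(frame, ch_r), project_v(frame, ch_l)))
  band <- tol_frac * frame$height
  if (delta > band) "up" else if (delta < -band) "down" else "straight"
}

#' Classify the smile line
#'
#' High if the entire clinical crown is revealed together with a continuous
#' band of gingiva; medium if 75%-100% of the crown (interdental papilla
#' only); low if less than 75% of the crown shows.
#'
#' @param exposure_fraction Visible fraction of the maxillary central
#'   incisor's clinical crown (>= 0; values above 1 mean gingival display).
#' @param gingival_display One of `"continuous_band"`, `"papilla_only"`,
#'   `"none"`.
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
classify_smile_line <- function(exposure_fraction, gingival_display) {
  stopifnot(exposure_fraction >= 0)
  gingival_display <- match.arg(gingival_display,
                                c("continuous_band", "papilla_only", "none"))
  if (exposure_fraction >= 1 && gingival_display == "continuous_band") {
    "high"
  } else if (exposure_fraction >= 0.75) {
    "medium"
  } else {
    "low"
  }
}

#' Classify the smile width
#'
#' Smile width is the most posterior maxillary tooth type exposed during the
#' posed smile, coded by the FDI tooth-type digit: 4 = first premolar,
#' 5 = second premolar, 6 = first molar, 7 = second molar. Smiles exposing
#' only anterior teeth are not modelled.
#'
#' @param last_visible_tooth Integer code in 4..7.
#' @return One of `"first_premolar"`, `"second_premolar"`, `"first_molar"`,
#'   `"second_molar"`.
#' @export
classify_smile_width <- function(last_visible_tooth) {
  if (!last_visible_tooth %in% 4:7) {
    stop("unsupported smile-width category: tooth code ", last_visible_tooth,
         " (expected FDI tooth-type digit 4-7)")
  }
  c(`4` = "first_premolar", `5` = "second_premolar",
    `6` = "first_molar", `7` = "second_molar")[[as.character(last_visible_tooth)]]
}

#' Tooth shape from the DP index
#'
#' `DP% = length / width * 100` on the maxillary right central incisor,
#' classified triangular (< 43), oval (43-57, boundaries inclusive) or
#' square (> 57). The `width_over_length` switch inverts the quotient for
#' analysts who prefer the conventional crown width-to-length index; the
#' printed definition is the default.
#'
#' @param length Incisocervical crown length (> 0).
#' @param width Maximum mesiodistal crown width (> 0, same units).
#' @param dp_definition `"as_printed"` (length/width) or
#'   `"width_over_length"`.
#' @return List with `dp_percent` and `shape`.
#' @export
tooth_shape <- function(length, width,
                        dp_definition = c("as_printed", "width_over_length")) {
  dp_definition <- match.arg(dp_definition)
  if (!is.finite(length) || length <= 0 || !is.finite(width) || width <= 0) {
    stop("tooth length and width must be positive")
  }
  dp <- if (dp_definition == "as_printed") length / width * 100
        else width / length * 100
  # 1e-9 guard: a measurement quotient landing exactly on a printed class
  # boundary must not be pushed across it by floating-point rounding
  eps <- 1e-9
  shape <- if (dp < 43 - eps) "triangular"
           else if (dp > 57 + eps) "square"
           else "oval"
  list(dp_percent = dp, shape = shape)
}

#' Tooth size relative to the golden ratio
#'
#' The crown width-to-length ratio and its percent of the divine
#' proportion (1.618 = 100%).
#'
#' @inheritParams tooth_shape
#' @return List with `wl_ratio` and `wl_golden_percent`.
#' @export
tooth_size <- function(length, width) {
  if (!is.finite(length) || length <= 0 || !is.finite(width) || width <= 0) {
    stop("tooth length and width must be positive")
  }
  wl <- width / length
  list(wl_ratio = wl, wl_golden_percent = golden_percent(wl))
}

#' Full smile-framework assessment for one subject
#'
#' Bundles the five categorical smile classifiers and the two tooth metrics
#' into a single tidy row.
#'
#' @param set Smile-view `facial_landmark_set` with `CH_R`, `CH_L`, `ULC`
#'   and the incisal-edge and lower-lip point lists.
#' @param exposure_fraction,gingival_display See [classify_smile_line()].
#' @param last_visible_tooth See [classify_smile_width()].
#' @param tooth_length,tooth_width Crown measurements (see [tooth_shape()]).
#' @param frame Optional pre-built `beauty_frame` (built from `set` if
#'   omitted).
#' @param config An [analysis_config()] list of tolerances.
#' @return One-row tibble with the assessment.
#' @export
assess_smile <- function(set, exposure_fraction, gingival_display,
                         last_visible_tooth, tooth_length, tooth_width,
                         frame = NULL, config = analysis_config()) {
  val <- validate_for(set, "smile")
  if (!val$ok) stop("invalid landmark set for smile analysis: ",
                    paste(val$reasons, collapse = "; "))
  if (is.null(frame)) frame <- build_frame(set)
  arc <- classify_smile_arc(set$incisal_edge, set$lower_lip, frame,
                            flatness_tol = config$flatness_tol)
  lip <- classify_lip_curvature(landmark_xy(set, "CH_R"),
                                landmark_xy(set, "CH_L"),
                                landmark_xy(set, "ULC"), frame,
                                tol_frac = config$lip_tol_frac)
  shp <- tooth_shape(tooth_length, tooth_width,
                     dp_definition = config$dp_definition)
  siz <- tooth_size(tooth_length, tooth_width)
  tibble::new_tibble(list(
    subject_id = set$subject_id,
    arc = arc$arc,
    lip_curvature = lip,
    smile_line = classify_smile_line(exposure_fraction, gingival_display),
    smile_width = classify_smile_width(last_visible_tooth),
    dp_percent = shp$dp_percent,
    tooth_shape = shp$shape,
    wl_ratio = siz$wl_ratio,
    wl_golden_percent = siz$wl_golden_percent
  ), nrow = 1L)
}
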