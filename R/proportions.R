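# Vertical and transverse facial proportions and their relation to the
# divine (golden) ratio 1.618.

#' The divine-proportion constant
#'
#' Fixed at 1.618 exactly (not phi to machine precision), matching the
#' arithmetic convention of clinical golden-ratio analyses.
#' @export
GOLDEN_RATIO <- 1.618

#' Facial proportion ratio definitions
#'
#' The ten ratios of the proportion analysis: seven vertical (between spans
#' of the trichion TR, external canthus LC, lateral nose border LN, mouth
#' corner CH and menton ME levels) and three transverse (between the
#' right-left widths at CH, LN, LC and temporal soft tissue TS).
#'
#' @return Tibble with columns `key` (e.g. `"TR-ME:LC-ME"`), `numerator`,
#'   `denominator` (distance names) and `type`.
#' @export
ratio_definitions <- function() {
  tibble::tibble(
    key = c("TR-ME:LC-ME", "LC-ME:TR-LC", "TR-LN:LN-ME", "LN-ME:LC-LN",
            "LC-CH:CH-ME", "LC-LN:LN-CH", "CH-ME:LN-CH",
            "CH(r-l):LN(r-l)", "LC(r-l):CH(r-l)", "TS(r-l):LC(r-l)"),
    numerator = c("TR_ME", "LC_ME", "TR_LN", "LN_ME", "LC_CH", "LC_LN",
                  "CH_ME", "CH_rl", "LC_rl", "TS_rl"),
    denominator = c("LC_ME", "TR_LC", "LN_ME", "LC_LN", "CH_ME", "LN_CH",
                    "LN_CH", "LN_rl", "CH_rl", "LC_rl"),
    type = c(rep("vertical", 7), rep("transverse", 3))
  )
}

#' Measure the facial proportion distances
#'
#' Vertical distances are perpendicular separations along the canthal-frame
#' v-axis (head-roll corrected; on an un-rotated photograph this equals the
#' raw vertical pixel distance). Bilateral landmarks contribute the mean v of
#' their pair. Transverse distances are straight Euclidean distances between
#' the right and left member of each pair.
#'
#' @param set A `facial_landmark_set` with the proportion landmarks
#'   (`TR`, `ME`, bilateral `TS`, `LC`, `LN`, `CH`).
#' @return Object of class `proportion_distances`: a list with named numeric
#'   vectors `vertical` (TR_ME, LC_ME, TR_LC, TR_LN, LN_ME, LC_LN, LC_CH,
#'   CH_ME, LN_CH) and `transverse` (CH_rl, LC_rl, TS_rl, LN_rl), in pixels.
#' @export
measure_distances <- function(set) {
  val <- validate_for(set, "proportions")
  if (!val$ok) stop("invalid landmark set for proportion analysis: ",
                    paste(val$reasons, collapse = "; "))
  lcr <- landmark_xy(set, "LC_R")
  lcl <- landmark_xy(set, "LC_L")
  u <- lcl - lcr
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2], u[1])
  me <- landmark_xy(set, "ME")
  v_axis <- perp * sign(sum((me - lcr) * perp))  # menton defines "down"
  v_of <- function(nm) sum((landmark_xy(set, nm) - lcr) * v_axis)
  pair_v <- function(nm) (v_of(paste0(nm, "_R")) + v_of(paste0(nm, "_L"))) / 2
  lev <- c(TR = v_of("TR"), ME = v_of("ME"), LC = pair_v("LC"),
           LN = pair_v("LN"), CH = pair_v("CH"))
  span <- function(a, b) abs(lev[[a]] - lev[[b]])
  pair_dist <- function(nm) {
    d <- landmark_xy(set, paste0(nm, "_L")) - landmark_xy(set, paste0(nm, "_R"))
    sqrt(sum(d^2))
  }
  structure(
    list(
      vertical = c(TR_ME = span("TR", "ME"), LC_ME = span("LC", "ME"),
                   TR_LC = span("TR", "LC"), TR_LN = span("TR", "LN"),
                   LN_ME = span("LN", "ME"), LC_LN = span("LC", "LN"),
                   LC_CH = span("LC", "CH"), CH_ME = span("CH", "ME"),
                   LN_CH = span("LN", "CH")),
      transverse = c(CH_rl = pair_dist("CH"), LC_rl = pair_dist("LC"),
                     TS_rl = pair_dist("TS"), LN_rl = pair_dist("LN"))
    ),
    class = "proportion_distances"
  )
}

#' Compute the ten facial proportion ratios
#'
#' @param d A `proportion_distances` object (or a named numeric vector
#'   holding all distance names used by [ratio_definitions()]).
#' @return Tibble `key, value, golden_pct` — the ratio and its percent of
#'   the divine proportion (1.618 = 100%).
#' @export
compute_ratios <- function(d) {
  dists <- if (inherits(d, "proportion_distances")) {
    c(d$vertical, d$transverse)
  } else {
    d
  }
  defs <- ratio_definitions()
  num <- dists[defs$numerator]
  den <- dists[defs$denominator]
  if (any(!is.finite(num)) || any(!is.finite(den)) || any(num <= 0)) {
    stop("degenerate measurement: non-positive distance")
  }
  if (any(den <= 0)) stop("degenerate measurement: zero denominator")
  value <- as.numeric(num / den)
  tibble::new_tibble(list(key = defs$key, type = defs$type, value = value,
                          golden_pct = golden_percent(value)),
                     nrow = length(value))
}

#' Percent of the divine proportion
#'
#' Expresses a ratio as a percentage of the golden constant:
#' `ratio / 1.618 * 100`, so 1.618 maps to exactly 100.
#'
#' @param ratio Non-negative numeric vector.
#' @return Numeric vector of percents.
#' @export
golden_percent <- function(ratio) {
  stopifnot(all(ratio >= 0))
  ratio / GOLDEN_RATIO * 100
}

#' Signed percent deviation from the divine proportion
#'
#' @inheritParams golden_percent
#' @return `golden_percent(ratio) - 100`.
#' @export
golden_deviation <- function(ratio) {
  golden_percent(ratio) - 100
}
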