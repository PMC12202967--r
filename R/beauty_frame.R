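# The beauty frame: the canthal-aligned rectangle that operationalises the
# facial midline, and the RFV/RCV relative midline values computed in it.

#' Construct the beauty frame
#'
#' The aesthetic rectangle bounded above by the intercanthal line (external
#' canthus to external canthus), laterally by perpendiculars through each
#' canthus, and below by the parallel line through the lowest point of the
#' lower lip (LLI). Its vertical bisector is the operational facial midline.
#' The subject-right lateral border (through `LC_R`) is the measurement
#' origin; `F = width / 2` is the half-frame constant all RFVs divide by.
#'
#' @param set A `facial_landmark_set` containing at least the frame
#'   landmarks (`LC_R`, `LC_L`, `CH_R`, `CH_L`, `N`, `PRN`, `PHT`, `DM`,
#'   `LLI`).
#' @return An object of class `beauty_frame` with fields `origin`, `u_axis`,
#'   `v_axis` (orthonormal, `v` pointing toward the lower boundary), `width`,
#'   `F` and `height`.
#' @export
build_frame <- function(set) {
  val <- validate_for(set, "frame")
  if (!val$ok) stop("invalid landmark set for frame analysis: ",
                    paste(val$reasons, collapse = "; "))
  lcr <- landmark_xy(set, "LC_R")
  lcl <- landmark_xy(set, "LC_L")
  d <- lcl - lcr
  width <- sqrt(sum(d^2))
  if (width <= .Machine$double.eps * 100) {
    stop("degenerate frame: coincident external canthi")
  }
  u_axis <- d / width
  perp <- c(-u_axis[2], u_axis[1])
  lli <- landmark_xy(set, "LLI")
  h <- sum((lli - lcr) * perp)
  if (abs(h) <= width * 1e-9) {
    stop("frame geometry error: LLI lies on the canthal line")
  }
  v_axis <- perp * sign(h)
  # the mouth must lie on the same (lower) side as LLI
  ch_mid <- (landmark_xy(set, "CH_R") + landmark_xy(set, "CH_L")) / 2
  if (sum((ch_mid - lcr) * v_axis) <= 0) {
    stop("frame geometry error: commissures above the canthal line")
  }
  structure(
    list(origin = lcr, u_axis = u_axis, v_axis = v_axis,
         width = width, F = width / 2, height = abs(h)),
    class = "beauty_frame"
  )
}

#' @export
print.beauty_frame <- function(x, ...) {
  cat(sprintf("<beauty_frame> width %.2f px (F = %.2f), height %.2f px\n",
              x$width, x$F, x$height))
  invisible(x)
}

#' Project points onto the frame axes
#'
#' `project_u` returns the perpendicular distance from the subject-right
#' lateral border (so `u(LC_R) = 0`, `u(LC_L) = 2F`, and the facial midline
#' is `u = F`); `project_v` the distance below the canthal line. Both are
#' vectorised over the rows of a two-column matrix.
#'
#' @param frame A `beauty_frame`.
#' @param point Numeric `c(x, y)` or an n-by-2 matrix.
#' @return Numeric vector of coordinates (pixels).
#' @export
project_u <- function(frame, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  as.numeric((p[, 1] - frame$origin[1]) * frame$u_axis[1] +
             (p[, 2] - frame$origin[2]) * frame$u_axis[2])
}

#' @rdname project_u
#' @export
project_v <- function(frame, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  as.numeric((p[, 1] - frame$origin[1]) * frame$v_axis[1] +
             (p[, 2] - frame$origin[2]) * frame$v_axis[2])
}

rfv_landmark_names <- c("nasion", "nose_tip", "philtrum",
                        "dental_midline", "commissure_midline")

#' Relative facial-midline values (RFV)
#'
#' Each landmark's perpendicular distance from the subject-right frame
#' border, divided by the half-frame constant `F`. A value of exactly 1
#' means coincidence with the facial midline; values below 1 lie toward the
#' subject's right, above 1 toward the left. `rfv1..rfv4` are the nasion,
#' nose tip, philtrum tip and dental midline; `rfv5` is the commissure
#' midline (midpoint of the two mouth corners).
#'
#' @param frame A `beauty_frame`.
#' @param set The `facial_landmark_set` the frame was built from.
#' @return One-row tibble `subject_id, rfv1..rfv5`.
#' @export
compute_rfv <- function(frame, set) {
  for (nm in c("N", "PRN", "PHT", "DM", "CH_R", "CH_L")) {
    if (!nm %in% set$points$landmark) {
      stop("missing landmark required for RFV: ", nm)
    }
  }
  cx <- project_u(frame, (landmark_xy(set, "CH_R") +
                          landmark_xy(set, "CH_L")) / 2)
  tibble::new_tibble(list(
    subject_id = set$subject_id,
    rfv1 = project_u(frame, landmark_xy(set, "N")) / frame$F,
    rfv2 = project_u(frame, landmark_xy(set, "PRN")) / frame$F,
    rfv3 = project_u(frame, landmark_xy(set, "PHT")) / frame$F,
    rfv4 = project_u(frame, landmark_xy(set, "DM")) / frame$F,
    rfv5 = cx / frame$F
  ), nrow = 1L)
}

#' Relative commissural-midline values (RCV)
#'
#' The same four landmark positions normalised by the commissure-midline
#' position `Cx` instead of `F`: `rcv_i = u(landmark_i) / Cx`. A value of 1
#' means coincidence with the mouth midline. By construction
#' `rcv_i * rfv5 = rfv_i` exactly.
#'
#' @inheritParams compute_rfv
#' @return One-row tibble `subject_id, rcv1..rcv4`.
#' @export
compute_rcv <- function(frame, set) {
  for (nm in c("N", "PRN", "PHT", "DM", "CH_R", "CH_L")) {
    if (!nm %in% set$points$landmark) {
      stop("missing landmark required for RCV: ", nm)
    }
  }
  cx <- project_u(frame, (landmark_xy(set, "CH_R") +
                          landmark_xy(set, "CH_L")) / 2)
  if (cx <= frame$width * 1e-12) {
    stop("degenerate RCV denominator: commissure midline on the ",
         "subject-right lateral border")
  }
  tibble::new_tibble(list(
    subject_id = set$subject_id,
    rcv1 = project_u(frame, landmark_xy(set, "N")) / cx,
    rcv2 = project_u(frame, landmark_xy(set, "PRN")) / cx,
    rcv3 = project_u(frame, landmark_xy(set, "PHT")) / cx,
    rcv4 = project_u(frame, landmark_xy(set, "DM")) / cx
  ), nrow = 1L)
}

#' Classify the side of a midline deviation
#'
#' An RFV or RCV below `1 - tol` indicates deviation toward the subject's
#' right, above `1 + tol` toward the left, and values inside the band are
#' centered. The default `tol = 0` is the strict reading (any deviation
#' counts); a positive tolerance absorbs digitisation jitter.
#'
#' @param value Numeric vector of RFV/RCV values (> 0).
#' @param tol Non-negative dimensionless tolerance.
#' @return Character vector in `{"right", "centered", "left"}`.
#' @export
classify_side <- function(value, tol = 0) {
  stopifnot(tol >= 0, all(value > 0))
  out <- rep("centered", length(value))
  out[value < 1 - tol] <- "right"
  out[value > 1 + tol] <- "left"
  out
}

#' Landmark hierarchy by mean RFV
#'
#' Orders the five midline landmarks by their cohort mean RFV, descending —
#' i.e. from the most leftward-lying to the most rightward-lying relative to
#' the facial midline. Exact ties are broken by the canonical order (nasion,
#' nose tip, philtrum, commissure midline, dental midline).
#'
#' @param rfv Tibble with columns `rfv1..rfv5` (one row per subject).
#' @return Character vector of the five landmark names, ordered.
#' @export
landmark_hierarchy <- function(rfv) {
  if (NROW(rfv) == 0) stop("empty RFV collection")
  means <- vapply(paste0("rfv", 1:5), function(k) mean(rfv[[k]]), numeric(1))
  # canonical tie-break rank: nasion, nose tip, philtrum, commissure, dental
  canonical <- c(1, 2, 3, 5, 4)
  rfv_landmark_names[order(-means, canonical)]
}
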