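# Geometry and sampling helpers shared by the generator and the tests.

#' Apply a similarity transform to 2-D points
#'
#' Rotation (degrees, about the origin, raster convention with y downward),
#' uniform scaling, then translation. All frame-relative quantities of the
#' pipeline are invariant under this transform.
#'
#' @param xy n-by-2 matrix of coordinates.
#' @param angle_deg Rotation angle in degrees.
#' @param scale Positive scale factor.
#' @param translation Length-2 numeric offset.
#' @return Transformed n-by-2 matrix.
#' @export
similarity_transform <- function(xy, angle_deg = 0, scale = 1,
                                 translation = c(0, 0)) {
  stopifnot(scale > 0)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- scale * (as.matrix(xy) %*% t(R))
  out[, 1] <- out[, 1] + translation[1]
  out[, 2] <- out[, 2] + translation[2]
  out
}

#' Apply a similarity transform to a landmark set
#'
#' Transforms every landmark and curve point of a `facial_landmark_set`
#' with [similarity_transform()].
#'
#' @param set A `facial_landmark_set`.
#' @inheritParams similarity_transform
#' @return A transformed `facial_landmark_set`.
#' @export
transform_landmark_set <- function(set, angle_deg = 0, scale = 1,
                                   translation = c(0, 0)) {
  tf <- function(m) {
    if (is.null(m)) return(NULL)
    similarity_transform(m, angle_deg, scale, translation)
  }
  pts <- tf(cbind(set$points$x, set$points$y))
  landmark_set(set$subject_id, set$view,
               data.frame(landmark = set$points$landmark,
                          x = pts[, 1], y = pts[, 2]),
               incisal_edge = tf(set$incisal_edge),
               lower_lip = tf(set$lower_lip),
               calibration_mm_per_px = set$calibration_mm_per_px)
}

#' Mirror a landmark set about a vertical image axis
#'
#' Reflects every coordinate about the vertical line `x = x0` and swaps the
#' `_R`/`_L` landmark labels: the mirrored subject's anatomical right side
#' is the original's left. (Reflecting coordinates alone would be an
#' isometry that leaves every frame-relative distance unchanged.) On a
#' frame-analysed face this sends every RFV to `2 - RFV`.
#'
#' @param set A `facial_landmark_set`.
#' @param x0 Image x of the mirror line (default 0).
#' @return Mirrored `facial_landmark_set`.
#' @export
mirror_landmark_set <- function(set, x0 = 0) {
  mir <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    m[, 1] <- 2 * x0 - m[, 1]
    m
  }
  nm <- set$points$landmark
  swapped <- sub("_R$", "_X", nm)
  swapped <- sub("_L$", "_R", swapped)
  swapped <- sub("_X$", "_L", swapped)
  landmark_set(set$subject_id, set$view,
               data.frame(landmark = swapped,
                          x = 2 * x0 - set$points$x, y = set$points$y),
               incisal_edge = mir(set$incisal_edge),
               lower_lip = mir(set$lower_lip),
               calibration_mm_per_px = set$calibration_mm_per_px)
}

# Normal draw truncated at +/- n_sd standard deviations (simple rejection;
# guards the generator against anatomically impossible geometry).
rnorm_trunc <- function(n, mean, sd, n_sd = 4) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- sd > 0 & abs(x - mean) > n_sd * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
    bad <- sd > 0 & abs(x - mean) > n_sd * sd
  }
  x
}

# Uniform draw from a length-2 range (degenerate ranges allowed).
runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else stats::runif(n, range[1], range[2])
}
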