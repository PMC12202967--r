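# Landmark vocabulary, landmark-set container, validation and file I/O.

#' Landmark vocabulary
#'
#' The controlled vocabulary of 2-D photographic landmarks used throughout the
#' package, with the anatomical side each name implies. Sides are carried by
#' the landmark NAME (`_R`/`_L` meaning the subject's right/left), never
#' inferred from coordinate ordering, so mirrored or rotated images need no
#' special handling.
#'
#' @return A tibble with columns `name` and `side`
#'   (one of `"right"`, `"left"`, `"midline"`).
#' @export
landmark_vocabulary <- function() {
  midline <- c("TR", "ME", "N", "PRN", "PHT", "DM", "LLI", "ULC")
  paired  <- c("TS", "LC", "LN", "CH")
  tibble::tibble(
    name = c(midline, paste0(paired, "_R"), paste0(paired, "_L")),
    side = c(rep("midline", length(midline)),
             rep("right", length(paired)),
             rep("left", length(paired)))
  )
}

#' Landmarks required for each analysis
#'
#' @param analysis One of `"proportions"` (vertical/transverse facial
#'   proportions), `"frame"` (beauty-frame RFV/RCV analysis) or `"smile"`
#'   (smile-framework classification).
#' @return Character vector of required landmark names.
#' @export
required_landmarks <- function(analysis = c("proportions", "frame", "smile")) {
  analysis <- match.arg(analysis)
  switch(analysis,
    proportions = c("TR", "ME", "TS_R", "TS_L", "LC_R", "LC_L",
                    "LN_R", "LN_L", "CH_R", "CH_L"),
    frame = c("LC_R", "LC_L", "CH_R", "CH_L", "N", "PRN", "PHT", "DM", "LLI"),
    smile = c("CH_R", "CH_L", "ULC")
  )
}

#' Construct a facial landmark set
#'
#' The atomic input of the pipeline: the named, sided 2-D points digitised on
#' one photograph of one subject. Coordinates are in pixels with `y`
#' increasing downward (raster convention). All downstream ratios, RFVs, RCVs
#' and classifications are scale-free; the optional calibration applies only
#' when absolute distances are reported.
#'
#' @param subject_id Opaque subject identifier.
#' @param view One of `"frontal_rest"`, `"frontal_smile"`, `"intraoral"`.
#' @param points Data frame with columns `landmark`, `x`, `y` (one row per
#'   landmark; names from [landmark_vocabulary()]).
#' @param incisal_edge Optional ordered two-column matrix (or data frame) of
#'   points along the maxillary canine-to-canine incisal edges (smile view).
#' @param lower_lip Optional ordered two-column matrix of points along the
#'   lower lip's upper vermilion border (smile view).
#' @param calibration_mm_per_px Optional positive scale factor.
#' @return An object of class `facial_landmark_set`.
#' @export
landmark_set <- function(subject_id, view, points,
                         incisal_edge = NULL, lower_lip = NULL,
                         calibration_mm_per_px = NULL) {
  view <- match.arg(view, c("frontal_rest", "frontal_smile", "intraoral"))
  points <- as.data.frame(points)
  stopifnot(all(c("landmark", "x", "y") %in% names(points)))
  vocab <- landmark_vocabulary()
  unknown <- setdiff(points$landmark, vocab$name)
  if (length(unknown) > 0) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(points$landmark)) {
    dup <- unique(points$landmark[duplicated(points$landmark)])
    stop("duplicate landmark(s) for subject ", subject_id, ": ",
         paste(dup, collapse = ", "))
  }
  xy <- cbind(as.numeric(points$x), as.numeric(points$y))
  if (!all(is.finite(xy))) stop("non-finite landmark coordinate")
  if (!is.null(calibration_mm_per_px) &&
      (!is.numeric(calibration_mm_per_px) || calibration_mm_per_px <= 0)) {
    stop("calibration_mm_per_px must be a positive number")
  }
  as_curve <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(as.data.frame(m))
    storage.mode(m) <- "double"
    stopifnot(ncol(m) == 2, all(is.finite(m)))
    colnames(m) <- c("x", "y")
    m
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      view = view,
      points = tibble::new_tibble(
        list(landmark = points$landmark, x = xy[, 1], y = xy[, 2],
             side = vocab$side[match(points$landmark, vocab$name)]),
        nrow = nrow(points)
      ),
      incisal_edge = as_curve(incisal_edge),
      lower_lip = as_curve(lower_lip),
      calibration_mm_per_px = calibration_mm_per_px
    ),
    class = "facial_landmark_set"
  )
}

#' @export
print.facial_landmark_set <- function(x, ...) {
  cat("<facial_landmark_set> subject", x$subject_id, "view", x$view, "with",
      nrow(x$points), "landmarks")
  if (!is.null(x$incisal_edge)) cat(",", nrow(x$incisal_edge), "incisal points")
  if (!is.null(x$lower_lip)) cat(",", nrow(x$lower_lip), "lip points")
  cat("\n")
  invisible(x)
}

#' Retrieve one landmark's coordinates
#'
#' @param set A `facial_landmark_set`.
#' @param name Landmark name.
#' @return Numeric length-2 vector `c(x, y)`.
#' @export
landmark_xy <- function(set, name) {
  i <- match(name, set$points$landmark)
  if (is.na(i)) stop("landmark ", name, " absent from set ", set$subject_id)
  c(set$points$x[i], set$points$y[i])
}

#' Validate a landmark set for a given analysis
#'
#' Never raises: returns a report with `ok`, the missing landmark names and
#' human-readable reasons. Validation is monotone — adding a landmark can
#' never turn an `ok` set invalid.
#'
#' @param set A `facial_landmark_set`.
#' @param analysis See [required_landmarks()].
#' @return List with elements `ok`, `missing`, `reasons`.
#' @export
validate_for <- function(set, analysis = c("proportions", "frame", "smile")) {
  analysis <- match.arg(analysis)
  need <- required_landmarks(analysis)
  missing <- setdiff(need, set$points$landmark)
  reasons <- character(0)
  if (length(missing) > 0) {
    reasons <- paste("missing landmark(s):", paste(missing, collapse = ", "))
  }
  if (all(c("LC_R", "LC_L") %in% set$points$landmark)) {
    d <- landmark_xy(set, "LC_L") - landmark_xy(set, "LC_R")
    if (sqrt(sum(d^2)) <= 0) reasons <- c(reasons, "degenerate canthal axis")
  }
  if (analysis == "smile") {
    if (is.null(set$incisal_edge) || nrow(set$incisal_edge) < 3) {
      reasons <- c(reasons, "fewer than 3 incisal-edge points")
    }
    if (is.null(set$lower_lip) || nrow(set$lower_lip) < 3) {
      reasons <- c(reasons, "fewer than 3 lower-lip points")
    }
  }
  list(ok = length(reasons) == 0, missing = missing, reasons = reasons)
}

curve_rows <- function(prefix, m, subject_id, view) {
  if (is.null(m) || nrow(m) == 0) return(NULL)
  data.frame(subject_id = subject_id, view = view,
             landmark = paste0(prefix, "_", seq_len(nrow(m))),
             x = m[, 1], y = m[, 2])
}

#' Write landmark sets to a CSV or JSON file
#'
#' CSV schema: `subject_id,view,landmark,x,y` with ordered curve points
#' emitted as `INC_1..INC_k` (incisal edges) and `LIP_1..LIP_m` (lower lip).
#' The JSON dialect mirrors the same fields, one object per subject/view.
#'
#' @param sets A `facial_landmark_set` or list of them.
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the file extension).
#' @return `path`, invisibly.
#' @export
write_landmark_file <- function(sets, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (inherits(sets, "facial_landmark_set")) sets <- list(sets)
  if (format == "csv") {
    rows <- lapply(sets, function(s) {
      rbind(
        data.frame(subject_id = s$subject_id, view = s$view,
                   landmark = s$points$landmark,
                   x = s$points$x, y = s$points$y),
        curve_rows("INC", s$incisal_edge, s$subject_id, s$view),
        curve_rows("LIP", s$lower_lip, s$subject_id, s$view)
      )
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    objs <- lapply(sets, function(s) {
      o <- list(subject_id = s$subject_id, view = s$view,
                points = as.data.frame(s$points[, c("landmark", "x", "y")]))
      if (!is.null(s$incisal_edge)) o$incisal_edge <- unname(s$incisal_edge)
      if (!is.null(s$lower_lip)) o$lower_lip <- unname(s$lower_lip)
      if (!is.null(s$calibration_mm_per_px)) {
        o$calibration_mm_per_px <- s$calibration_mm_per_px
      }
      o
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read landmark sets from a CSV or JSON file
#'
#' Parsing is lossless to the printed decimal precision of the file. Schema
#' violations fail loudly: a missing required column is named, a non-numeric
#' coordinate is reported with its row number, and a duplicated
#' (subject, view, landmark) triple is a duplication error.
#'
#' @inheritParams write_landmark_file
#' @param path Input path.
#' @return List of `facial_landmark_set` objects, one per (subject, view).
#' @export
read_landmark_file <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    objs <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
    if (is.data.frame(objs)) objs <- split(objs, seq_len(nrow(objs)))
    sets <- lapply(seq_along(objs), function(i) {
      o <- as.list(objs[[i]])
      pts <- as.data.frame(o$points)
      if (is.list(pts$x)) pts$x <- unlist(pts$x)
      landmark_set(o$subject_id, o$view, pts,
                   incisal_edge = o$incisal_edge, lower_lip = o$lower_lip,
                   calibration_mm_per_px = o$calibration_mm_per_px)
    })
    return(sets)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("subject_id", "view", "landmark", "x", "y")
  for (col in needed) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    stop("non-numeric coordinate at row ", bad[1] + 1L, " of ", path)
  }
  df$x <- x
  df$y <- y
  key <- paste(df$subject_id, df$view, df$landmark, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate landmark ", d$landmark, " for subject ", d$subject_id,
         " view ", d$view)
  }
  landmarks_to_sets(df)
}

#' Read tooth crown measurements
#'
#' CSV schema `subject_id,length,width`: incisocervical crown length and
#' maximum mesiodistal crown width of the maxillary right central incisor,
#' in the same (arbitrary) units — only their quotient is ever used.
#'
#' @param path CSV path.
#' @return Tibble with columns `subject_id`, `length`, `width`.
#' @export
read_tooth_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "length", "width")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  if (any(!is.finite(df$length)) || any(df$length <= 0) ||
      any(!is.finite(df$width)) || any(df$width <= 0)) {
    stop("tooth length and width must be positive numbers")
  }
  tibble::as_tibble(df[, c("subject_id", "length", "width")])
}

#' Read subject demographics
#'
#' CSV schema `subject_id,sex,age` with `sex` in `{female, male}`.
#'
#' @param path CSV path.
#' @return Tibble with columns `subject_id`, `sex`, `age`.
#' @export
read_demographics_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "sex", "age")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  if (!all(df$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  tibble::as_tibble(df[, c("subject_id", "sex", "age")])
}

#' Read smile-framework clinical observations
#'
#' The two smile attributes that are observations rather than landmark
#' geometry: the smile-line crown exposure (`exposure_fraction`, fraction of
#' the maxillary central's clinical crown visible, with `gingival_display`
#' one of `continuous_band`, `papilla_only`, `none`) and the smile width
#' (`last_visible_tooth`, FDI tooth-type digit 4-7).
#'
#' @param path CSV path with columns
#'   `subject_id,exposure_fraction,gingival_display,last_visible_tooth`.
#' @return Tibble.
#' @export
read_smile_observations_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "exposure_fraction", "gingival_display",
              "last_visible_tooth")
  for (col in needed) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  if (!all(df$gingival_display %in% c("continuous_band", "papilla_only",
                                      "none"))) {
    stop("invalid gingival_display value")
  }
  tibble::as_tibble(df[, needed])
}
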