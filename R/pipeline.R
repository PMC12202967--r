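# Pipeline assembly: configuration, per-subject analysis over a cohort, and
# the cohort report tables.

#' Analysis configuration
#'
#' Tolerances and switches of the analysis stage.
#'
#' @param classification_tol Dead-band for [classify_side()] (default 0,
#'   the strict reading: any deviation from 1 counts).
#' @param flatness_tol Smile-arc curvature threshold in 1/px (default
#'   `1e-4`).
#' @param lip_tol_frac Lip-curvature dead-band as a fraction of frame
#'   height (default 0.02).
#' @param dp_definition `"as_printed"` (DP% = length/width) or
#'   `"width_over_length"`.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(classification_tol = 0, flatness_tol = 1e-4,
                            lip_tol_frac = 0.02,
                            dp_definition = c("as_printed",
                                              "width_over_length")) {
  stopifnot(classification_tol >= 0, flatness_tol >= 0,
            lip_tol_frac >= 0, lip_tol_frac < 1)
  structure(
    list(classification_tol = classification_tol,
         flatness_tol = flatness_tol, lip_tol_frac = lip_tol_frac,
         dp_definition = match.arg(dp_definition)),
    class = "analysis_config"
  )
}

as_landmark_sets <- function(landmarks) {
  if (is.character(landmarks)) return(read_landmark_file(landmarks))
  if (inherits(landmarks, "facial_landmark_set")) return(list(landmarks))
  if (is.data.frame(landmarks)) return(landmarks_to_sets(landmarks))
  if (is.list(landmarks)) return(landmarks)
  stop("cannot interpret 'landmarks' input")
}

as_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x) else tibble::as_tibble(x)
}

#' Run the per-subject analysis over a cohort
#'
#' For every subject: the facial-proportion ratios from the rest view, the
#' beauty-frame RFV/RCV values and side classifications from the smile
#' view, and the smile-framework assessment from the smile view plus the
#' clinical observations and tooth measurements. Subjects failing
#' validation for an analysis are skipped for that analysis and listed in
#' the exclusions table with a reason, so every (subject, analysis) pair
#' appears exactly once across results and exclusions.
#'
#' @param landmarks Landmark CSV/JSON path, long landmark table, or list of
#'   `facial_landmark_set`.
#' @param teeth Optional tooth CSV path or table (`subject_id,length,width`).
#' @param smile_observations Optional smile-observation CSV path or table.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory to write `rfv.csv`, `ratios.csv`,
#'   `smile.csv`, `exclusions.csv`.
#' @return List of class `cohort_analysis` with tibbles `rfv`, `ratios`,
#'   `smile`, `exclusions`.
#' @export
run_analyze <- function(landmarks, teeth = NULL, smile_observations = NULL,
                        config = analysis_config(), out_dir = NULL) {
  sets <- as_landmark_sets(landmarks)
  teeth <- as_table(teeth, read_tooth_file)
  obs <- as_table(smile_observations, read_smile_observations_file)

  sids_all <- vapply(sets, function(s) s$subject_id, character(1))
  subj_views <- split(sets, sids_all)
  subj_views <- subj_views[unique(sids_all)]

  rfv_rows <- list()
  ratio_rows <- list()
  smile_rows <- list()
  excl <- list()
  note_excl <- function(sid, analysis, reason) {
    excl[[length(excl) + 1]] <<- tibble::tibble(
      subject_id = sid, analysis = analysis, reason = reason)
  }

  for (sid in names(subj_views)) {
    views <- subj_views[[sid]]
    vnames <- vapply(views, function(s) s$view, character(1))
    rest <- if ("frontal_rest" %in% vnames) {
      views[[match("frontal_rest", vnames)]]
    } else {
      NULL
    }
    smile <- if ("frontal_smile" %in% vnames) {
      views[[match("frontal_smile", vnames)]]
    } else {
      NULL
    }

    # proportions (rest view)
    if (is.null(rest)) {
      note_excl(sid, "proportions", "no frontal_rest view")
    } else {
      val <- validate_for(rest, "proportions")
      if (!val$ok) {
        note_excl(sid, "proportions", paste(val$reasons, collapse = "; "))
      } else {
        r <- compute_ratios(measure_distances(rest))
        r$subject_id <- sid
        ratio_rows[[length(ratio_rows) + 1]] <-
          r[, c("subject_id", "key", "type", "value", "golden_pct")]
      }
    }

    # beauty frame (smile view)
    frame <- NULL
    if (is.null(smile)) {
      note_excl(sid, "frame", "no frontal_smile view")
    } else {
      val <- validate_for(smile, "frame")
      if (!val$ok) {
        note_excl(sid, "frame", paste(val$reasons, collapse = "; "))
      } else {
        frame <- build_frame(smile)
        rfv <- compute_rfv(frame, smile)
        rcv <- compute_rcv(frame, smile)
        sides <- classify_side(as.numeric(rfv[1, paste0("rfv", 1:5)]),
                               tol = config$classification_tol)
        row <- cbind(rfv, rcv[, paste0("rcv", 1:4)])
        for (k in 1:5) row[[paste0("side_rfv", k)]] <- sides[k]
        rfv_rows[[length(rfv_rows) + 1]] <- tibble::as_tibble(row)
      }
    }

    # smile framework (smile view + observations + tooth)
    o <- if (!is.null(obs)) obs[obs$subject_id == sid, ] else NULL
    t <- if (!is.null(teeth)) teeth[teeth$subject_id == sid, ] else NULL
    if (is.null(smile) || is.null(o) || nrow(o) == 0 ||
        is.null(t) || nrow(t) == 0) {
      note_excl(sid, "smile",
                "missing smile view, observations or tooth measurements")
    } else {
      val <- validate_for(smile, "smile")
      can_frame <- !is.null(frame)
      if (!val$ok || !can_frame) {
        reason <- if (!val$ok) paste(val$reasons, collapse = "; ")
                  else "no valid beauty frame for smile geometry"
        note_excl(sid, "smile", reason)
      } else {
        smile_rows[[length(smile_rows) + 1]] <- assess_smile(
          smile, o$exposure_fraction[1], o$gingival_display[1],
          o$last_visible_tooth[1], t$length[1], t$width[1],
          frame = frame, config = config)
      }
    }
  }

  empty <- function(rows, proto) {
    if (length(rows) > 0) dplyr::bind_rows(rows) else proto
  }
  out <- structure(list(
    rfv = empty(rfv_rows, tibble::tibble(subject_id = character(0))),
    ratios = empty(ratio_rows, tibble::tibble(subject_id = character(0))),
    smile = empty(smile_rows, tibble::tibble(subject_id = character(0))),
    exclusions = empty(excl, tibble::tibble(
      subject_id = character(0), analysis = character(0),
      reason = character(0)))
  ), class = "cohort_analysis")
  if (nrow(out$rfv) == 0 && nrow(out$ratios) == 0 && nrow(out$smile) == 0) {
    stop("empty cohort: no subject passed validation")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$rfv, file.path(out_dir, "rfv.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ratios, file.path(out_dir, "ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(out$smile, file.path(out_dir, "smile.csv"),
                     row.names = FALSE)
    utils::write.csv(out$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  out
}

#' Build the cohort report tables
#'
#' Cohort roll-ups in the shape of a clinical paper's tables: the facial
#' proportions (per-sex mean, SD, percent of the divine ratio computed
#' from the unrounded mean, Mann-Whitney p), the RFV/RCV midline values
#' (total and per-sex mean and SD, Mann-Whitney p), the smile-framework
#' categorical attributes (counts, grand-total percents, per-sex within-sex
#' percents, chi-square/Fisher p), and the landmark hierarchy string. With
#' a single-sex cohort the sex-comparison columns are `NA`.
#'
#' @param analysis A `cohort_analysis` from [run_analyze()] (or a directory
#'   containing its CSVs).
#' @param demographics Demographics CSV path or table
#'   (`subject_id,sex,age`).
#' @param out_dir Optional directory for `table_proportions.csv`,
#'   `table_midlines.csv`, `table_smile.csv`, `report.json`.
#' @return List of class `cohort_report` with tibbles `proportions`,
#'   `midlines`, `smile`, plus `hierarchy` (character vector) and `n`.
#' @export
run_report <- function(analysis, demographics, out_dir = NULL) {
  if (is.character(analysis)) {
    analysis <- structure(list(
      rfv = tibble::as_tibble(utils::read.csv(
        file.path(analysis, "rfv.csv"), stringsAsFactors = FALSE)),
      ratios = tibble::as_tibble(utils::read.csv(
        file.path(analysis, "ratios.csv"), stringsAsFactors = FALSE)),
      smile = tibble::as_tibble(utils::read.csv(
        file.path(analysis, "smile.csv"), stringsAsFactors = FALSE)),
      exclusions = tibble::as_tibble(utils::read.csv(
        file.path(analysis, "exclusions.csv"), stringsAsFactors = FALSE))
    ), class = "cohort_analysis")
  }
  demo <- as_table(demographics, read_demographics_file)
  sexes <- sort(unique(demo$sex))
  two_sex <- length(sexes) == 2

  sex_of <- function(ids) demo$sex[match(ids, demo$subject_id)]

  # --- proportions table (one row per ratio per group) ---------------------
  rat <- analysis$ratios
  rat$sex <- sex_of(rat$subject_id)
  prop_rows <- list()
  for (key in unique(rat$key)) {
    sub <- rat[rat$key == key, ]
    groups <- if (two_sex) c("total", sexes) else "total"
    p <- if (two_sex) {
      continuous_sex_test(sub$value[sub$sex == sexes[1]],
                          sub$value[sub$sex == sexes[2]])$p
    } else {
      NA_real_
    }
    for (g in groups) {
      v <- if (g == "total") sub$value else sub$value[sub$sex == g]
      prop_rows[[length(prop_rows) + 1]] <- tibble::tibble(
        ratio = key, group = g, n = length(v), mean = mean(v),
        sd = stats::sd(v), golden_pct_of_mean = golden_percent(mean(v)),
        p = if (g == "total") NA_real_ else p)
    }
  }

  # --- midline (RFV/RCV) table --------------------------------------------
  rfv <- analysis$rfv
  rfv$sex <- sex_of(rfv$subject_id)
  mid_rows <- list()
  for (key in c(paste0("rfv", 1:5), paste0("rcv", 1:4))) {
    v <- rfv[[key]]
    p <- if (two_sex) {
      continuous_sex_test(v[rfv$sex == sexes[1]],
                          v[rfv$sex == sexes[2]])$p
    } else {
      NA_real_
    }
    row <- tibble::tibble(value = key, mean = mean(v), sd = stats::sd(v))
    for (s in sexes) {
      row[[paste0("mean_", s)]] <- mean(v[rfv$sex == s])
      row[[paste0("sd_", s)]] <- stats::sd(v[rfv$sex == s])
    }
    row$p <- p
    mid_rows[[length(mid_rows) + 1]] <- row
  }

  # --- smile framework table ----------------------------------------------
  smi <- analysis$smile
  smi$sex <- sex_of(smi$subject_id)
  levels_of <- list(
    arc = c("consonant", "non_consonant"),
    lip_curvature = c("up", "straight", "down"),
    smile_line = c("high", "medium", "low"),
    smile_width = c("first_premolar", "second_premolar", "first_molar",
                    "second_molar"),
    tooth_shape = c("triangular", "oval", "square")
  )
  smile_rows <- lapply(names(levels_of), function(attr) {
    summarize_categorical(smi, attr, levels = levels_of[[attr]])
  })
  smile_tbl <- dplyr::bind_rows(smile_rows)

  hierarchy <- landmark_hierarchy(rfv)

  out <- structure(list(
    proportions = dplyr::bind_rows(prop_rows),
    midlines = dplyr::bind_rows(mid_rows),
    smile = smile_tbl,
    hierarchy = hierarchy,
    n = length(unique(demo$subject_id))
  ), class = "cohort_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$proportions,
                     file.path(out_dir, "table_proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(out$midlines, file.path(out_dir, "table_midlines.csv"),
                     row.names = FALSE)
    utils::write.csv(out$smile, file.path(out_dir, "table_smile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n = out$n, hierarchy = out$hierarchy,
           proportions = out$proportions, midlines = out$midlines,
           smile = out$smile),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", x$n, "subjects\n")
  cat("landmark hierarchy (most leftward first):",
      paste(x$hierarchy, collapse = ", "), "\n")
  invisible(x)
}
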