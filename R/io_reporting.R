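# Cohort CSV readers/writers, per-athlete and team reports, and report
# serialisation.
#
# Cohort CSV schema (one row per measurement session, UTF-8, mandatory
# header, '.' decimal separator):
#   athlete_id, sex, birth_date (ISO 8601), obs_date, standing_height_cm,
#   sitting_height_cm, weight_kg, source, mother_height_cm, father_height_cm

COHORT_COLUMNS <- c("athlete_id", "sex", "birth_date", "obs_date",
                    "standing_height_cm", "sitting_height_cm", "weight_kg",
                    "source", "mother_height_cm", "father_height_cm")

#' Read a cohort CSV
#'
#' Reads and validates a cohort file against the package schema. Validation
#' is fail-soft: offending rows are dropped and collected (with their file
#' line numbers and the violated fields) in the `row_errors` attribute of
#' the result; set `strict = TRUE` to stop on the first bad row. A malformed
#' header is always an error.
#'
#' @param path Path to a cohort CSV.
#' @param strict Stop on any row-level violation instead of collecting it.
#' @return A data.frame of valid session rows with attribute `row_errors`
#'   (data.frame `line`, `message`; zero rows when the file is clean).
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(sort(names(df)), sort(COHORT_COLUMNS))) {
    stop("malformed cohort header; expected columns: ",
         paste(COHORT_COLUMNS, collapse = ", "), call. = FALSE)
  }
  df <- df[, COHORT_COLUMNS, drop = FALSE]
  errors <- list()
  keep <- rep(TRUE, nrow(df))
  num_cols <- c("standing_height_cm", "sitting_height_cm", "weight_kg",
                "mother_height_cm", "father_height_cm")
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    row <- df[i, ]
    probs <- character(0)
    nums <- suppressWarnings(lapply(row[num_cols], as.numeric))
    if (!(row$sex %in% SEXES)) probs <- c(probs, "sex")
    if (!(row$source %in% SOURCES)) probs <- c(probs, "source")
    bd <- suppressWarnings(as.Date(row$birth_date))
    od <- suppressWarnings(as.Date(row$obs_date))
    if (is.na(bd)) probs <- c(probs, "birth_date")
    if (is.na(od)) probs <- c(probs, "obs_date")
    if (!is.na(bd) && !is.na(od) && od < bd) {
      probs <- c(probs, "obs_date < birth_date")
    }
    ht <- nums$standing_height_cm
    sh <- nums$sitting_height_cm
    wt <- nums$weight_kg
    if (is.na(ht) || ht <= 0) probs <- c(probs, "standing_height_cm")
    if (is.na(sh) || sh <= 0) probs <- c(probs, "sitting_height_cm")
    if (!is.na(ht) && !is.na(sh) && sh >= ht) {
      probs <- c(probs, "sitting_height_cm >= standing_height_cm")
    }
    if (is.na(wt) || wt <= 0) probs <- c(probs, "weight_kg")
    for (pc in c("mother_height_cm", "father_height_cm")) {
      v <- nums[[pc]]
      if (nzchar(row[[pc]]) && !is.na(v) && (v < 120 || v > 220)) {
        probs <- c(probs, pc)
      }
    }
    if (length(probs) > 0) {
      msg <- sprintf("line %d: invalid field(s) %s", line,
                     paste(probs, collapse = ", "))
      if (strict) stop(msg, call. = FALSE)
      errors[[length(errors) + 1L]] <- data.frame(
        line = line, message = msg, stringsAsFactors = FALSE)
      keep[i] <- FALSE
    }
  }
  out <- df[keep, , drop = FALSE]
  for (col in num_cols) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  rownames(out) <- NULL
  attr(out, "row_errors") <- if (length(errors) > 0) {
    do.call(rbind, errors)
  } else {
    data.frame(line = integer(0), message = character(0))
  }
  out
}

#' Write a cohort CSV
#'
#' @param cohort A cohort data.frame (schema columns) or a
#'   [generate_cohort()] result, whose `sessions` are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort_records(cohort)
  utils::write.csv(df[, COHORT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Normalise cohort input (data.frame or synthetic_cohort) to a schema
# data.frame.
cohort_records <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$sessions
  if (!is.data.frame(cohort) || !all(COHORT_COLUMNS %in% names(cohort))) {
    stop("cohort must be a data.frame with the cohort CSV schema columns",
         call. = FALSE)
  }
  cohort
}

# Run the maturation pipeline on every session row. Fail-soft: rows whose
# assessment errors are skipped and reported in the `errors` attribute.
assess_cohort_records <- function(recs, cfg = classification_config(),
                                  pah_table = pah_coefficients()) {
  out <- vector("list", nrow(recs))
  errs <- list()
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    res <- tryCatch({
      prof <- athlete_profile(
        r$athlete_id, r$sex, r$birth_date,
        mother_height_cm = if (is.na(r$mother_height_cm)) NA_real_ else
          r$mother_height_cm,
        father_height_cm = if (is.na(r$father_height_cm)) NA_real_ else
          r$father_height_cm)
      sess <- measurement_session(r$obs_date, r$standing_height_cm,
                                  r$sitting_height_cm, r$weight_kg,
                                  source = r$source)
      a <- suppressWarnings(
        assess_maturity(prof, sess, cfg = cfg, pah_table = pah_table,
                        age_policy = "warn"))
      data.frame(athlete_id = a$athlete_id, sex = a$sex,
                 date = as.character(a$date), source = a$source,
                 decimal_age_yr = a$decimal_age_yr,
                 maturity_offset_yr = a$maturity_offset_yr,
                 phv_age_yr = a$phv_age_yr,
                 predicted_adult_height_cm = a$predicted_adult_height_cm,
                 percent_adult_height = a$percent_adult_height,
                 standing_height_cm = sess$standing_height_cm,
                 sitting_height_cm = sess$sitting_height_cm,
                 weight_kg = sess$weight_kg,
                 status = a$status, timing = a$timing,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        athlete_id = r$athlete_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- res
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  attr(res, "errors") <- if (length(errs) > 0) do.call(rbind, errs) else
    data.frame(athlete_id = character(0), message = character(0))
  res
}

#' Build individual and team reports
#'
#' Runs the maturation pipeline on every session and aggregates the results
#' into one report per athlete (full assessment history, ordered by date,
#' plus the latest assessment) and one team report (status and timing
#' counts over athletes, distribution summaries of maturity offset, PHV age
#' and percent of adult height). An athlete's team-level status/timing is
#' taken from their latest session (ties broken in favour of the expert
#' source). Processing is fail-soft: per-session assessment errors are
#' collected in the returned `errors` element without aborting the batch.
#'
#' @param cohort A cohort data.frame or [generate_cohort()] result.
#' @param cfg A [classification_config()].
#' @param pah_table Coefficient table for [predicted_adult_height()].
#' @param team_id Label for the team report.
#' @return A list of class `report_bundle`: `individual` (named list of
#'   `individual_report`), `team` (`team_report`), `errors` (data.frame).
#' @export
build_reports <- function(cohort, cfg = classification_config(),
                          pah_table = pah_coefficients(),
                          team_id = "team") {
  recs <- cohort_records(cohort)
  if (nrow(recs) == 0) stop("empty cohort", call. = FALSE)
  assessed <- assess_cohort_records(recs, cfg, pah_table)
  errors <- attr(assessed, "errors")

  src_rank <- match(assessed$source, SOURCES)  # expert before app
  ord <- order(assessed$athlete_id, assessed$date, src_rank)
  assessed <- assessed[ord, , drop = FALSE]

  ids <- unique(assessed$athlete_id)
  individual <- lapply(ids, function(id) {
    hist <- assessed[assessed$athlete_id == id, , drop = FALSE]
    rownames(hist) <- NULL
    # latest = max-date entry; on same-date expert/app pairs the expert
    # measurement is preferred
    cand <- hist[hist$date == max(hist$date), , drop = FALSE]
    latest <- cand[order(match(cand$source, SOURCES)), , drop = FALSE][1, ]
    structure(
      list(athlete_id = id,
           sex = latest$sex,
           latest = as.list(latest),
           history = hist,
           trajectory = hist[, c("date", "source", "status", "timing")]),
      class = "individual_report")
  })
  names(individual) <- ids

  latest_per_athlete <- do.call(rbind, lapply(individual, function(r) {
    h <- r$history
    last_date <- max(h$date)
    cand <- h[h$date == last_date, , drop = FALSE]
    cand[order(match(cand$source, SOURCES)), , drop = FALSE][1, ]
  }))

  num_summary <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  team <- structure(
    list(team_id = team_id,
         n_athletes = length(ids),
         status_counts = as.list(table(factor(latest_per_athlete$status,
                                              levels = STATUS_LEVELS))),
         timing_counts = as.list(table(factor(latest_per_athlete$timing,
                                              levels = TIMING_LEVELS))),
         maturity_offset_yr = num_summary(
           latest_per_athlete$maturity_offset_yr),
         phv_age_yr = num_summary(latest_per_athlete$phv_age_yr),
         percent_adult_height = num_summary(
           latest_per_athlete$percent_adult_height)),
    class = "team_report")

  structure(list(individual = individual, team = team, errors = errors),
            class = "report_bundle")
}

#' @export
print.team_report <- function(x, ...) {
  cat(sprintf("<team_report> %s: %d athletes\n", x$team_id, x$n_athletes))
  cat("  status:", paste(names(x$status_counts), unlist(x$status_counts),
                         sep = "=", collapse = "  "), "\n")
  cat("  timing:", paste(names(x$timing_counts), unlist(x$timing_counts),
                         sep = "=", collapse = "  "), "\n")
  cat(sprintf("  MO %.2f (%.2f) yr, PHV age %.2f (%.2f) yr\n",
              x$maturity_offset_yr[["mean"]], x$maturity_offset_yr[["sd"]],
              x$phv_age_yr[["mean"]], x$phv_age_yr[["sd"]]))
  invisible(x)
}

#' @export
print.individual_report <- function(x, ...) {
  cat(sprintf("<individual_report> %s (%s), %d assessment(s)\n",
              x$athlete_id, x$sex, nrow(x$history)))
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Reports round-trip losslessly: serialise, parse, serialise is
#' byte-stable. Rendered numeric values keep full precision in JSON.
#'
#' @param x A `report_bundle`, `agreement_report`, `individual_report` or
#'   `team_report`.
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(x, path = NULL) {
  payload <- unclass_deep(x)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (inherits(x, "crosstab")) {
    x <- unclass(x)
    x$counts <- as.data.frame.matrix(x$counts)
  }
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    if (is.data.frame(x)) return(x)
    return(lapply(x, unclass_deep))
  }
  x
}

#' Write an agreement report as a flat CSV
#'
#' One row per continuous metric with the columns
#' `metric, n, mean_diff, sd_diff, icc, ci_low, ci_high, a_tem, r_tem`,
#' rounded to 3 decimals (the granularity of printed agreement tables).
#'
#' @param report An [agreement_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  df <- report$metrics
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a keypoints JSON file
#'
#' Parses the keypoints interchange format: a single object or an array of
#' objects `{athlete_id, posture, top_px: [x, y], bottom_px: [x, y],
#' camera: {focal_px, wall_distance_cm, camera_height_cm,
#' principal_point_px, image_size_px}}`.
#'
#' @param path Path to the JSON file.
#' @return A list of entries, each `list(athlete_id, kp, cam)` with a
#'   [keypoint_set()] and a [camera_setup()].
#' @export
read_keypoints_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$athlete_id)) raw <- list(raw)
  lapply(raw, function(e) {
    cam <- e$camera
    cam_obj <- camera_setup(
      focal_px = cam$focal_px,
      wall_distance_cm = if (is.null(cam$wall_distance_cm)) 200 else
        cam$wall_distance_cm,
      camera_height_cm = if (is.null(cam$camera_height_cm)) 100 else
        cam$camera_height_cm,
      image_size_px = unlist(cam$image_size_px),
      principal_point_px = if (is.null(cam$principal_point_px)) {
        unlist(cam$image_size_px) / 2
      } else {
        unlist(cam$principal_point_px)
      })
    list(athlete_id = e$athlete_id,
         kp = keypoint_set(e$posture, unlist(e$top_px), unlist(e$bottom_px)),
         cam = cam_obj)
  })
}

#' Write keypoints JSON
#'
#' @param entries List of `list(athlete_id, kp, cam)` entries.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoints_json <- function(entries, path) {
  payload <- lapply(entries, function(e) {
    list(athlete_id = e$athlete_id,
         posture = e$kp$posture,
         top_px = e$kp$top_px,
         bottom_px = e$kp$bottom_px,
         camera = list(
           focal_px = e$cam$focal_px,
           wall_distance_cm = e$cam$wall_distance_cm,
           camera_height_cm = e$cam$camera_height_cm,
           principal_point_px = e$cam$principal_point_px,
           image_size_px = e$cam$image_size_px))
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Load a classification configuration from JSON
#'
#' JSON shape: `{"pre_threshold_yr": -1, "post_threshold_yr": 1,
#' "timing_norms": {"male": {"mean": 13.8, "sd": 1.0}, "female": ...},
#' "timing_band_sd": 1}`. Missing fields fall back to the defaults of
#' [classification_config()].
#'
#' @param path Path to a config JSON file.
#' @return A [classification_config()].
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- classification_config()
  norms <- defaults$timing_norms
  if (!is.null(cfg$timing_norms)) {
    for (sx in names(cfg$timing_norms)) {
      norms[[sx]] <- c(mean = cfg$timing_norms[[sx]][["mean"]],
                       sd = cfg$timing_norms[[sx]][["sd"]])
    }
  }
  classification_config(
    pre_threshold_yr = if (is.null(cfg$pre_threshold_yr))
      defaults$pre_threshold_yr else cfg$pre_threshold_yr,
    post_threshold_yr = if (is.null(cfg$post_threshold_yr))
      defaults$post_threshold_yr else cfg$post_threshold_yr,
    timing_norms = norms,
    timing_band_sd = if (is.null(cfg$timing_band_sd))
      defaults$timing_band_sd else cfg$timing_band_sd)
}
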