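# Maturation assessment engine: maturity offset, PHV age, predicted adult
# height, percent of adult height, and status/timing classification.

.somamat_cache <- new.env(parent = emptyenv())

#' Maturity-offset regression coefficients
#'
#' Sex-specific coefficients for the anthropometric maturity-offset
#' regression (interaction-term form: leg length x sitting height,
#' age x leg length, age x sitting height, age x weight for females only,
#' and weight/height x 100). Packaged as CSV under `inst/extdata`.
#'
#' @param path Optional path to an alternative coefficient CSV with columns
#'   `sex, intercept, ll_sh, age_ll, age_sh, age_wt, wt_ht`.
#' @return A data.frame with one row per sex.
#' @export
mo_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.somamat_cache$mo_coef)) return(.somamat_cache$mo_coef)
    path <- system.file("extdata", "maturity_offset_coefficients.csv",
                        package = "somamat", mustWork = TRUE)
    coef <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    .somamat_cache$mo_coef <- coef
    return(coef)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Maturity offset (years from peak height velocity)
#'
#' Predicted signed time in years from the measurement occasion to peak
#' height velocity (PHV); negative values are pre-PHV. Implements the
#' sex-specific interaction-term regression on leg length, sitting height,
#' age and the weight-to-height ratio. The male equation has no age x weight
#' term; the female equation does. Coefficients are packaged verbatim, never
#' re-fitted.
#'
#' The regression is validated for ages in `validated_range` (default
#' \[8, 18\] years). Outside it, `age_policy = "warn"` (default) computes a
#' best-effort value with a warning, `"error"` stops, `"ignore"` is silent.
#'
#' @param sex `"male"` or `"female"`.
#' @param anthro A [derive_anthro()] result.
#' @param session The [measurement_session()] the anthropometrics came from.
#' @param age_policy Out-of-range handling: `"warn"`, `"error"` or `"ignore"`.
#' @param validated_range Length-2 numeric, validated age range in years.
#'
#' @return Maturity offset in years (scalar).
#' @export
#' @examples
#' p <- athlete_profile("A1", "male", "2011-01-01")
#' s <- measurement_session("2024-01-01", 160, 82, 48)
#' maturity_offset("male", derive_anthro(p, s), s)
maturity_offset <- function(sex, anthro, session,
                            age_policy = c("warn", "error", "ignore"),
                            validated_range = c(8, 18)) {
  sex <- match.arg(sex, SEXES)
  age_policy <- match.arg(age_policy)
  stopifnot(inherits(anthro, "derived_anthro"))
  age <- anthro$decimal_age_yr
  if (age < validated_range[1] || age > validated_range[2]) {
    msg <- sprintf(
      "decimal age %.2f outside validated range [%g, %g] for maturity offset",
      age, validated_range[1], validated_range[2])
    if (age_policy == "error") stop(msg, call. = FALSE)
    if (age_policy == "warn") warning(msg, call. = FALSE)
  }
  sh <- session$sitting_height_cm
  if (is.null(sh) || is.na(sh)) {
    stop("sitting height is required for maturity offset", call. = FALSE)
  }
  ll <- anthro$leg_length_cm
  wt <- session$weight_kg
  wh <- anthro$weight_by_height_ratio
  b <- mo_coefficients()
  b <- b[b$sex == sex, , drop = FALSE]
  stopifnot(nrow(b) == 1L)
  b$intercept +
    b$ll_sh * ll * sh +
    b$age_ll * age * ll +
    b$age_sh * age * sh +
    b$age_wt * age * wt +
    b$wt_ht * wh
}

#' Age at peak height velocity
#'
#' The defining identity: PHV age = chronological (decimal) age minus
#' maturity offset.
#'
#' @param decimal_age_yr Decimal age at measurement, years.
#' @param mo Maturity offset, years.
#' @return PHV age in years.
#' @export
phv_age <- function(decimal_age_yr, mo) decimal_age_yr - mo

#' Predicted-adult-height coefficient table
#'
#' Loads an age- and sex-indexed coefficient table for the linear
#' predicted-adult-height model
#' `PAH = b0 + b1 * stature + b2 * weight + b3 * midparent stature`
#' (the Khamis-Roche functional form), tabulated on a half-year age grid
#' over \[4.0, 17.5\] years.
#'
#' The packaged default (`pah_coefficients_synthetic.csv`) is a SYNTHETIC
#' stand-in: a smooth, internally calibrated table with the published
#' method's structure (stature coefficient rising with age, midparent
#' coefficient falling towards zero at maturity, all midparent coefficients
#' positive). It is suitable for testing pipelines and demonstrating the
#' method, not for clinical prediction; supply a transcription of the
#' published coefficients via `path` for real use.
#'
#' @param path Optional path to a CSV with columns
#'   `sex, age_yr, b0, b1, b2, b3`.
#' @return A data.frame keyed by (sex, age_yr).
#' @export
pah_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.somamat_cache$pah_coef)) return(.somamat_cache$pah_coef)
    path <- system.file("extdata", "pah_coefficients_synthetic.csv",
                        package = "somamat", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    .somamat_cache$pah_coef <- tab
    return(tab)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Predicted adult height
#'
#' Linear forecast of adult stature from current stature, weight and
#' midparent stature, with sex- and age-specific coefficients looked up at
#' the nearest tabulated half-year age (ties round to the younger row);
#' optional linear interpolation between the two bracketing rows.
#'
#' @param sex `"male"` or `"female"`.
#' @param anthro A [derive_anthro()] result; `midparent_height_cm` must be
#'   present.
#' @param session The [measurement_session()] supplying stature and weight.
#' @param table A coefficient table from [pah_coefficients()].
#' @param interpolate Linearly interpolate coefficients between the two
#'   bracketing half-year rows instead of nearest-row lookup.
#'
#' @return Predicted adult height in cm.
#' @export
predicted_adult_height <- function(sex, anthro, session,
                                   table = pah_coefficients(),
                                   interpolate = FALSE) {
  sex <- match.arg(sex, SEXES)
  stopifnot(inherits(anthro, "derived_anthro"))
  if (is.na(anthro$midparent_height_cm)) {
    stop("midparent height absent: both parental statures are required ",
         "for predicted adult height", call. = FALSE)
  }
  rows <- table[table$sex == sex, , drop = FALSE]
  rows <- rows[order(rows$age_yr), , drop = FALSE]
  age <- anthro$decimal_age_yr
  if (age < min(rows$age_yr) || age > max(rows$age_yr)) {
    stop(sprintf("age %.2f outside coefficient table range [%g, %g]",
                 age, min(rows$age_yr), max(rows$age_yr)), call. = FALSE)
  }
  if (interpolate) {
    b <- vapply(c("b0", "b1", "b2", "b3"), function(col) {
      stats::approx(rows$age_yr, rows[[col]], xout = age)$y
    }, numeric(1))
  } else {
    i <- which.min(abs(rows$age_yr - age))
    b <- unlist(rows[i, c("b0", "b1", "b2", "b3")])
  }
  unname(b[1] + b[2] * session$standing_height_cm +
           b[3] * session$weight_kg + b[4] * anthro$midparent_height_cm)
}

#' Percent of predicted adult height
#'
#' Current stature as a percentage of predicted adult height; the standard
#' maturity-status index of the predicted-adult-height family.
#'
#' @param current Current standing height, cm.
#' @param pah Predicted adult height, cm; must be positive.
#' @return Percentage (e.g. 90.4).
#' @export
percent_adult_height <- function(current, pah) {
  if (any(!is.finite(pah)) || any(pah <= 0)) {
    stop("predicted adult height must be positive", call. = FALSE)
  }
  100 * current / pah
}

#' Classification configuration
#'
#' Thresholds and population norms for status and timing classification.
#' Status is keyed to maturity offset: below `pre_threshold_yr` is
#' pre-pubertal, above `post_threshold_yr` post-pubertal, the closed band
#' between them (boundaries included) pubertal. Timing compares PHV age with
#' sex-specific population norms: more than `timing_band_sd` SDs below the
#' mean is early, above is late, else average.
#'
#' Default timing norms (PHV age 13.8 +/- 1.0 yr for boys, 11.8 +/- 1.0 yr
#' for girls) are the values conventionally cited for Western adolescent
#' populations; override them for other reference populations.
#'
#' @param pre_threshold_yr,post_threshold_yr Status cut-offs on maturity
#'   offset, years (defaults -1 and +1: a circa-PHV band of one year each
#'   side).
#' @param timing_norms Named list `list(male = c(mean=, sd=),
#'   female = c(mean=, sd=))` of PHV-age norms in years.
#' @param timing_band_sd Half-width of the "average" timing band in SD units.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(pre_threshold_yr = -1.0,
                                  post_threshold_yr = 1.0,
                                  timing_norms = list(
                                    male = c(mean = 13.8, sd = 1.0),
                                    female = c(mean = 11.8, sd = 1.0)),
                                  timing_band_sd = 1.0) {
  if (!(pre_threshold_yr < post_threshold_yr)) {
    stop("pre_threshold_yr must be < post_threshold_yr", call. = FALSE)
  }
  for (sx in names(timing_norms)) {
    n <- timing_norms[[sx]]
    if (!all(c("mean", "sd") %in% names(n)) || n[["sd"]] <= 0) {
      stop("timing norms need positive 'sd' and a 'mean' for sex ", sx,
           call. = FALSE)
    }
  }
  structure(
    list(pre_threshold_yr = pre_threshold_yr,
         post_threshold_yr = post_threshold_yr,
         timing_norms = timing_norms,
         timing_band_sd = timing_band_sd),
    class = "classification_config"
  )
}

STATUS_LEVELS <- c("pre_pubertal", "pubertal", "post_pubertal")
TIMING_LEVELS <- c("early", "average", "late")

#' Maturity status from maturity offset
#'
#' Total, monotone partition of the maturity-offset axis: pre-pubertal below
#' the lower threshold, post-pubertal above the upper, pubertal in the closed
#' band between (boundaries belong to pubertal). Vectorised.
#'
#' @param mo Maturity offset(s), years.
#' @param cfg A [classification_config()].
#' @return Character vector over `"pre_pubertal"`, `"pubertal"`,
#'   `"post_pubertal"`.
#' @export
classify_status <- function(mo, cfg = classification_config()) {
  stopifnot(inherits(cfg, "classification_config"), all(is.finite(mo)))
  ifelse(mo < cfg$pre_threshold_yr, "pre_pubertal",
         ifelse(mo > cfg$post_threshold_yr, "post_pubertal", "pubertal"))
}

#' Maturity timing from PHV age
#'
#' Earliness/lateness of PHV relative to sex-specific population norms:
#' early below `mean - band * sd`, late above `mean + band * sd`, else
#' average. Vectorised over `phv_age`.
#'
#' @param phv_age PHV age(s), years.
#' @param sex `"male"` or `"female"`.
#' @param cfg A [classification_config()] carrying the norms.
#' @return Character vector over `"early"`, `"average"`, `"late"`.
#' @export
classify_timing <- function(phv_age, sex, cfg = classification_config()) {
  sex <- match.arg(sex, SEXES)
  norms <- cfg$timing_norms[[sex]]
  if (is.null(norms)) {
    stop("no timing norms configured for sex ", sex, call. = FALSE)
  }
  lo <- norms[["mean"]] - cfg$timing_band_sd * norms[["sd"]]
  hi <- norms[["mean"]] + cfg$timing_band_sd * norms[["sd"]]
  ifelse(phv_age < lo, "early", ifelse(phv_age > hi, "late", "average"))
}

#' Default training-recommendation mapping
#'
#' A 3x3 lookup from (status, timing) to a coarse training-recommendation
#' category. The shipped mapping is documentation of the mechanism, not
#' sports-science advice; practitioners should supply their own table.
#'
#' @return A data.frame with columns `status`, `timing`, `category`.
#' @export
default_recommendation_table <- function() {
  expand <- expand.grid(status = STATUS_LEVELS, timing = TIMING_LEVELS,
                        stringsAsFactors = FALSE)
  expand$category <- c(
    # status rows: pre, pubertal, post; timing columns via expand.grid order
    "monitor_growth_spurt",  # pre  x early
    "reduce_load",           # pub  x early
    "emphasize_recovery",    # post x early
    "standard_progression",  # pre  x average
    "monitor_growth_spurt",  # pub  x average
    "standard_progression",  # post x average
    "standard_progression",  # pre  x late
    "monitor_growth_spurt",  # pub  x late
    "standard_progression"   # post x late
  )
  expand
}

#' Training-recommendation category
#'
#' Deterministic lookup of a (status, timing) pair in a mapping table.
#'
#' @param status One of the status levels.
#' @param timing One of the timing levels.
#' @param table Mapping data.frame (`status`, `timing`, `category`).
#' @return The mapped category string.
#' @export
recommend <- function(status, timing, table = default_recommendation_table()) {
  hit <- table$status == status & table$timing == timing
  if (sum(hit) != 1L) {
    stop(sprintf("no recommendation mapped for (%s, %s)", status, timing),
         call. = FALSE)
  }
  table$category[hit]
}

#' Full maturity assessment for one session
#'
#' Runs the whole pipeline for one athlete-session: derived anthropometrics,
#' maturity offset, PHV age, predicted adult height (when midparent stature
#' is available and age is inside the coefficient table), percent of adult
#' height, and status/timing classification.
#'
#' @param profile An [athlete_profile()].
#' @param session A [measurement_session()].
#' @param cfg A [classification_config()].
#' @param pah_table Coefficient table for [predicted_adult_height()].
#' @param age_policy Passed to [maturity_offset()].
#' @return An object of class `maturity_assessment` (a named list).
#' @export
assess_maturity <- function(profile, session,
                            cfg = classification_config(),
                            pah_table = pah_coefficients(),
                            age_policy = "warn") {
  anthro <- derive_anthro(profile, session)
  mo <- maturity_offset(profile$sex, anthro, session, age_policy = age_policy)
  phv <- phv_age(anthro$decimal_age_yr, mo)
  pah <- NA_real_
  pct <- NA_real_
  if (!is.na(anthro$midparent_height_cm)) {
    pah <- tryCatch(
      predicted_adult_height(profile$sex, anthro, session, table = pah_table),
      error = function(e) NA_real_)
    if (!is.na(pah)) {
      pct <- percent_adult_height(session$standing_height_cm, pah)
    }
  }
  status <- classify_status(mo, cfg)
  timing <- classify_timing(phv, profile$sex, cfg)
  structure(
    list(athlete_id = profile$athlete_id,
         sex = profile$sex,
         date = session$date,
         source = session$source,
         decimal_age_yr = anthro$decimal_age_yr,
         leg_length_cm = anthro$leg_length_cm,
         maturity_offset_yr = mo,
         phv_age_yr = phv,
         predicted_adult_height_cm = pah,
         percent_adult_height = pct,
         status = status,
         timing = timing),
    class = "maturity_assessment"
  )
}

#' @export
print.maturity_assessment <- function(x, ...) {
  cat(sprintf(
    "<maturity_assessment> %s  age=%.2f  MO=%+.2f yr  PHV age=%.2f  %s/%s\n",
    x$athlete_id, x$decimal_age_yr, x$maturity_offset_yr, x$phv_age_yr,
    x$status, x$timing))
  if (!is.na(x$predicted_adult_height_cm)) {
    cat(sprintf("  PAH=%.1f cm (%.1f%% attained)\n",
                x$predicted_adult_height_cm, x$percent_adult_height))
  }
  invisible(x)
}
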