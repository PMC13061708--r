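# Core domain types and derived anthropometrics.
#
# All lengths are centimetres, masses kilogrammes, ages decimal years.
# Unit conversion, when needed, happens at I/O boundaries only.

DAYS_PER_YEAR <- 365.2425  # mean Gregorian year

SEXES <- c("male", "female")
SOURCES <- c("expert", "app")

#' Athlete profile
#'
#' An identity-free demographic record. The athlete identifier is an opaque
#' caller-supplied key; names, institutions and consent records are out of
#' scope by design.
#'
#' @param athlete_id Opaque identifier (length-1 character).
#' @param sex `"male"` or `"female"`.
#' @param birth_date Birth date (`Date` or ISO-8601 string).
#' @param mother_height_cm,father_height_cm Parental statures in cm, or `NA`
#'   when unknown. When present each must lie in \[120, 220\] cm.
#'
#' @return An object of class `athlete_profile`.
#' @export
#' @examples
#' athlete_profile("A001", "male", "2010-03-15",
#'                 mother_height_cm = 165, father_height_cm = 179)
athlete_profile <- function(athlete_id, sex, birth_date,
                            mother_height_cm = NA_real_,
                            father_height_cm = NA_real_) {
  stopifnot(is.character(athlete_id), length(athlete_id) == 1L,
            nzchar(athlete_id))
  sex <- match.arg(sex, SEXES)
  birth_date <- as.Date(birth_date)
  if (is.na(birth_date)) stop("birth_date is not a valid date", call. = FALSE)
  for (h in list(mother = mother_height_cm, father = father_height_cm)) {
    if (!is.na(h) && (h < 120 || h > 220)) {
      stop("parental height out of plausible range [120, 220] cm: ", h,
           call. = FALSE)
    }
  }
  structure(
    list(athlete_id = athlete_id, sex = sex, birth_date = birth_date,
         mother_height_cm = as.numeric(mother_height_cm),
         father_height_cm = as.numeric(father_height_cm)),
    class = "athlete_profile"
  )
}

#' Measurement session
#'
#' One dated anthropometric observation (standing height, sitting height,
#' weight), tagged by the method that produced it (`"expert"` manual
#' measurement or `"app"` automated estimate).
#'
#' @param date Observation date (`Date` or ISO-8601 string).
#' @param standing_height_cm Standing height, cm.
#' @param sitting_height_cm Sitting height, cm; must be strictly less than
#'   standing height.
#' @param weight_kg Body mass, kg, strictly positive.
#' @param source `"expert"` or `"app"`.
#'
#' @return An object of class `measurement_session`.
#' @export
measurement_session <- function(date, standing_height_cm, sitting_height_cm,
                                weight_kg, source = "expert") {
  date <- as.Date(date)
  if (is.na(date)) stop("session date is not a valid date", call. = FALSE)
  source <- match.arg(source, SOURCES)
  if (!is.finite(standing_height_cm) || standing_height_cm <= 0) {
    stop("standing_height_cm must be positive", call. = FALSE)
  }
  if (!is.finite(sitting_height_cm) || sitting_height_cm <= 0 ||
      sitting_height_cm >= standing_height_cm) {
    stop("sitting height must satisfy 0 < sitting < standing; got sitting = ",
         sitting_height_cm, ", standing = ", standing_height_cm,
         call. = FALSE)
  }
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  structure(
    list(date = date,
         standing_height_cm = as.numeric(standing_height_cm),
         sitting_height_cm = as.numeric(sitting_height_cm),
         weight_kg = as.numeric(weight_kg),
         source = source),
    class = "measurement_session"
  )
}

#' Decimal age between two dates
#'
#' Elapsed time from `birth_date` to `obs_date` in fractional years, using the
#' mean Gregorian year of 365.2425 days. This convention is deterministic and
#' leap-year-robust; it makes decimal age exactly additive over
#' concatenated intervals.
#'
#' @param birth_date,obs_date Dates (`Date` or ISO-8601 strings);
#'   `obs_date` must not precede `birth_date`.
#'
#' @return Age in decimal years, full precision.
#' @export
#' @examples
#' decimal_age("2010-01-01", "2023-01-01")  # 4748 days -> 12.9996 yr
decimal_age <- function(birth_date, obs_date) {
  birth_date <- as.Date(birth_date)
  obs_date <- as.Date(obs_date)
  if (anyNA(birth_date) || anyNA(obs_date)) {
    stop("invalid date input", call. = FALSE)
  }
  days <- as.numeric(obs_date - birth_date, units = "days")
  if (any(days < 0)) {
    stop("obs_date precedes birth_date", call. = FALSE)
  }
  days / DAYS_PER_YEAR
}

#' Derived anthropometrics
#'
#' Computes the derived predictors shared by the maturation equations:
#' decimal age at the session date, leg length (standing minus sitting
#' height), the weight-to-height ratio scaled by 100, and midparent height
#' (mean of the two parental statures, `NA` unless both are present; one
#' missing parent yields an absent midparent rather than an imputed one).
#'
#' @param profile An [athlete_profile()].
#' @param session A [measurement_session()].
#'
#' @return An object of class `derived_anthro` with fields `decimal_age_yr`,
#'   `leg_length_cm`, `midparent_height_cm`, `weight_by_height_ratio`.
#' @export
derive_anthro <- function(profile, session) {
  stopifnot(inherits(profile, "athlete_profile"),
            inherits(session, "measurement_session"))
  if (session$date < profile$birth_date) {
    stop("session date precedes birth date for athlete ", profile$athlete_id,
         call. = FALSE)
  }
  leg <- session$standing_height_cm - session$sitting_height_cm
  if (leg <= 0) {
    stop("sitting height >= standing height: inconsistent measurement",
         call. = FALSE)
  }
  mid <- if (!is.na(profile$mother_height_cm) &&
             !is.na(profile$father_height_cm)) {
    (profile$mother_height_cm + profile$father_height_cm) / 2
  } else {
    NA_real_
  }
  structure(
    list(decimal_age_yr = decimal_age(profile$birth_date, session$date),
         leg_length_cm = leg,
         midparent_height_cm = mid,
         weight_by_height_ratio =
           session$weight_kg / session$standing_height_cm * 100),
    class = "derived_anthro"
  )
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> %s  sex=%s  born=%s  mother=%s  father=%s\n",
              x$athlete_id, x$sex, format(x$birth_date),
              format(x$mother_height_cm), format(x$father_height_cm)))
  invisible(x)
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf(
    "<measurement_session> %s  ht=%.1f cm  sh=%.1f cm  wt=%.1f kg  [%s]\n",
    format(x$date), x$standing_height_cm, x$sitting_height_cm, x$weight_kg,
    x$source))
  invisible(x)
}
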