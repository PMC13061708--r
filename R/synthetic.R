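# Synthetic adolescent cohorts with known growth truths and paired
# expert/app measurement noise, so the whole pipeline is testable without
# external data.
#
# Truth curves use Preece-Baines model 1 (PB1), the standard five-parameter
# parametric human growth curve with an explicit adolescent spurt. Priors
# are loosely anthropometric defaults, clearly synthetic: they produce
# realistic-looking cohorts, not population reference data.

#' Preece-Baines model 1 stature
#'
#' `h(t) = h1 - 2 (h1 - h_theta) / (exp(s0 (t - theta)) + exp(s1 (t - theta)))`
#'
#' where `h1` is adult stature, `h_theta` stature at the timing parameter
#' `theta`, and `s0 < s1` are rate constants. At `t = theta` the denominator
#' is exactly 2, so `h(theta) = h_theta`; as `t` grows, `h -> h1`.
#'
#' @param age Age(s), years, positive.
#' @param p A [growth_curve_params()].
#' @return Stature(s) in cm.
#' @export
pb1_height <- function(age, p) {
  stopifnot(inherits(p, "growth_curve_params"), all(age > 0))
  x <- age - p$theta
  p$h1 - 2 * (p$h1 - p$h_theta) / (exp(p$s0 * x) + exp(p$s1 * x))
}

#' Preece-Baines model 1 growth velocity
#'
#' Analytic derivative of [pb1_height()] with respect to age, cm/yr.
#'
#' @inheritParams pb1_height
#' @return Velocity in cm/yr.
#' @export
pb1_velocity <- function(age, p) {
  stopifnot(inherits(p, "growth_curve_params"))
  x <- age - p$theta
  e0 <- exp(p$s0 * x)
  e1 <- exp(p$s1 * x)
  2 * (p$h1 - p$h_theta) * (p$s0 * e0 + p$s1 * e1) / (e0 + e1)^2
}

#' Growth-curve parameters
#'
#' PB1 parameter bundle with validity checks: `0 < s0 < s1`,
#' `h_theta < h1`, `theta` in \[10, 16\] years.
#'
#' @param h1 Adult stature, cm.
#' @param h_theta Stature at age `theta`, cm.
#' @param s0,s1 Rate constants, 1/yr.
#' @param theta Curve timing parameter, yr.
#' @return An object of class `growth_curve_params`.
#' @export
growth_curve_params <- function(h1, h_theta, s0, s1, theta) {
  if (!(s0 > 0 && s0 < s1)) stop("need 0 < s0 < s1", call. = FALSE)
  if (!(h_theta < h1)) stop("need h_theta < h1", call. = FALSE)
  if (theta < 10 || theta > 16) stop("theta must lie in [10, 16] yr",
                                     call. = FALSE)
  structure(list(h1 = h1, h_theta = h_theta, s0 = s0, s1 = s1,
                 theta = theta),
            class = "growth_curve_params")
}

#' True age at peak height velocity of a PB1 curve
#'
#' Numerically locates the adolescent velocity peak: a dense grid
#' (step 0.01 yr) over `theta` +/- 4 years followed by local refinement with
#' [stats::optimize()] (tolerance 1e-6 yr, well inside the documented 1e-4 yr
#' accuracy). The window excludes the curve's early-childhood branch, where
#' PB1 velocity rises again going backwards in time. The grid argmax must be
#' interior to the window; an edge argmax means the spurt is not resolved
#' and raises an error.
#'
#' @param p A [growth_curve_params()].
#' @return PHV age in years.
#' @export
true_phv_age <- function(p) {
  stopifnot(inherits(p, "growth_curve_params"))
  grid <- seq(p$theta - 4, p$theta + 4, by = 0.01)
  v <- pb1_velocity(grid, p)
  i <- which.max(v)
  if (i == 1L || i == length(grid)) {
    stop("velocity peak at window edge: adolescent spurt not resolved ",
         "for these parameters", call. = FALSE)
  }
  opt <- stats::optimize(function(t) pb1_velocity(t, p),
                         interval = c(grid[i - 1], grid[i + 1]),
                         maximum = TRUE, tol = 1e-6)
  opt$maximum
}

#' Measurement error model
#'
#' Noise and bias applied to the truth when emitting the paired expert and
#' app measurement arms. Defaults emulate careful manual anthropometry
#' (0.3 cm SD) against a slightly noisier, slightly biased automated
#' estimate (0.5 cm SD, +0.2 cm bias); weight is measured with a scale in
#' both arms (0.1 kg SD).
#'
#' @param expert_sd_cm Expert-arm height noise SD, cm.
#' @param app_sd_cm App-arm height noise SD, cm.
#' @param app_bias_cm App-arm systematic height bias, cm.
#' @param weight_sd_kg Weight noise SD, kg (both arms).
#' @return An object of class `error_model`.
#' @export
error_model <- function(expert_sd_cm = 0.3, app_sd_cm = 0.5,
                        app_bias_cm = 0.2, weight_sd_kg = 0.1) {
  stopifnot(expert_sd_cm >= 0, app_sd_cm >= 0, weight_sd_kg >= 0)
  structure(list(expert_sd_cm = expert_sd_cm, app_sd_cm = app_sd_cm,
                 app_bias_cm = app_bias_cm, weight_sd_kg = weight_sd_kg),
            class = "error_model")
}

#' Default growth-curve priors
#'
#' Sex-specific normal priors for PB1 parameters, truncated by redraw to the
#' validity region (`s0` in \[0.08, 0.13\], `s1` in \[0.9, 1.4\], `theta` in
#' \[10, 16\], positive spurt gain). Loosely anthropometric: adult statures
#' around 178 cm (male) / 164 cm (female), spurt timing around 14 / 12 yr.
#'
#' @return Named list of per-sex prior specifications.
#' @export
default_growth_priors <- function() {
  list(
    male = list(h1_mean = 178, h1_sd = 6.5,
                gain_mean = 15, gain_sd = 2,      # h1 - h_theta
                s0_mean = 0.11, s0_sd = 0.012,
                s1_mean = 1.1, s1_sd = 0.10,
                theta_mean = 14.0, theta_sd = 0.9),
    female = list(h1_mean = 164, h1_sd = 6.0,
                  gain_mean = 13, gain_sd = 2,
                  s0_mean = 0.10, s0_sd = 0.012,
                  s1_mean = 1.0, s1_sd = 0.10,
                  theta_mean = 12.0, theta_sd = 0.9)
  )
}

# Per-athlete RNG stream: a deterministic seed derived from the cohort seed
# and the athlete index, so per-athlete results do not depend on cohort
# ordering or size. Stays below 2^31 - 1.
athlete_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + index * 10007) %% 2147483647)
}

draw_curve_params <- function(prior) {
  for (attempt in 1:1000) {
    h1 <- stats::rnorm(1, prior$h1_mean, prior$h1_sd)
    gain <- stats::rnorm(1, prior$gain_mean, prior$gain_sd)
    s0 <- stats::rnorm(1, prior$s0_mean, prior$s0_sd)
    s1 <- stats::rnorm(1, prior$s1_mean, prior$s1_sd)
    theta <- stats::rnorm(1, prior$theta_mean, prior$theta_sd)
    ok <- gain > 5 && s0 >= 0.08 && s0 <= 0.13 && s1 >= 0.9 && s1 <= 1.4 &&
      theta >= 10 && theta <= 16
    if (ok) {
      return(growth_curve_params(h1, h1 - gain, s0, s1, theta))
    }
  }
  stop("could not draw valid growth-curve parameters from the prior",
       call. = FALSE)
}

# Age-dependent sitting-height fraction of stature: a simple documented
# linear stand-in (0.53 at age 10 falling to 0.52 at 18), no claim of
# auxological accuracy.
sitting_fraction <- function(age) 0.53 - 0.01 * (age - 10) / 8

#' Generate a synthetic paired-measurement cohort
#'
#' Simulates a cross-sectional cohort of adolescent athletes with known PB1
#' growth truths and paired expert/app measurement sessions. Defaults
#' reproduce a 144-athlete validation design: 76 males and 68 females aged
#' 10 to 17 years, one measurement wave, both arms observed on the same day.
#'
#' Per athlete: curve parameters are drawn from sex-specific priors, an
#' observation age uniformly from `age_range`, true standing height from
#' [pb1_height()], sitting height as an age-dependent fraction of stature
#' plus N(0, 0.5 cm) individual variation, and weight from a
#' stature-indexed normal (BMI around 18.5 + 0.35 per year over age 10,
#' SD 1.8). Expert and app sessions are the truth plus source-specific
#' noise/bias from the [error_model()]. Draws violating the measurement
#' invariants (sitting < standing, positive weight) are redrawn and counted.
#'
#' All randomness flows from `seed` through a per-athlete stream, so the
#' same seed is byte-identical and per-athlete values do not depend on
#' cohort ordering.
#'
#' @param n_male,n_female Athlete counts (defaults 76 and 68).
#' @param age_range Observation-age range in years (default `c(10, 17)`).
#' @param priors Growth-curve priors, see [default_growth_priors()].
#' @param err An [error_model()].
#' @param seed Integer seed.
#' @param waves Number of measurement waves (default 1).
#' @param wave_interval_yr Spacing between waves, years.
#' @param reference_date Observation date of the first wave.
#' @return An object of class `synthetic_cohort`: `sessions` (data.frame in
#'   the cohort CSV schema, two rows per athlete-wave), `truths` (data.frame
#'   `athlete_id, sex, h1, h_theta, s0, s1, theta, true_phv_age_yr`), and
#'   `redraws` (count of constraint-violating draws discarded).
#' @export
generate_cohort <- function(n_male = 76, n_female = 68,
                            age_range = c(10, 17),
                            priors = default_growth_priors(),
                            err = error_model(),
                            seed = 20260101,
                            waves = 1,
                            wave_interval_yr = 0.5,
                            reference_date = as.Date("2024-06-01")) {
  stopifnot(n_male >= 0, n_female >= 0, waves >= 1,
            inherits(err, "error_model"),
            length(age_range) == 2L, age_range[1] < age_range[2])
  reference_date <- as.Date(reference_date)
  sexes <- rep(c("male", "female"), c(n_male, n_female))
  n <- length(sexes)
  sessions <- vector("list", n)
  truths <- vector("list", n)
  redraws <- 0L

  for (i in seq_len(n)) {
    set.seed(athlete_seed(seed, i))
    sex <- sexes[i]
    p <- draw_curve_params(priors[[sex]])
    id <- sprintf("S%04d", i)

    age0 <- stats::runif(1, age_range[1], age_range[2])
    birth <- reference_date - round(age0 * DAYS_PER_YEAR)

    mother <- min(max(stats::rnorm(1, 163, 5.5), 125), 215)
    father <- min(max(stats::rnorm(1, 177, 6.0), 125), 215)

    wave_rows <- vector("list", waves)
    for (w in seq_len(waves)) {
      obs_date <- reference_date + round((w - 1) * wave_interval_yr *
                                           DAYS_PER_YEAR)
      age <- decimal_age(birth, obs_date)
      ht <- pb1_height(age, p)
      sh <- sitting_fraction(age) * ht + stats::rnorm(1, 0, 0.5)
      bmi <- stats::rnorm(1, 18.5 + 0.35 * (age - 10), 1.8)
      wt <- max(bmi, 12) * (ht / 100)^2

      emit <- function(source) {
        for (attempt in 1:100) {
          if (source == "expert") {
            ht_m <- ht + stats::rnorm(1, 0, err$expert_sd_cm)
            sh_m <- sh + stats::rnorm(1, 0, err$expert_sd_cm)
          } else {
            ht_m <- ht + err$app_bias_cm + stats::rnorm(1, 0, err$app_sd_cm)
            sh_m <- sh + err$app_bias_cm + stats::rnorm(1, 0, err$app_sd_cm)
          }
          wt_m <- wt + stats::rnorm(1, 0, err$weight_sd_kg)
          if (sh_m > 0 && sh_m < ht_m && wt_m > 0) {
            return(data.frame(
              athlete_id = id, sex = sex,
              birth_date = format(birth), obs_date = format(obs_date),
              standing_height_cm = ht_m, sitting_height_cm = sh_m,
              weight_kg = wt_m, source = source,
              mother_height_cm = mother, father_height_cm = father,
              stringsAsFactors = FALSE))
          }
          redraws <<- redraws + 1L
        }
        stop("could not satisfy measurement invariants after 100 redraws",
             call. = FALSE)
      }
      wave_rows[[w]] <- rbind(emit("expert"), emit("app"))
    }
    sessions[[i]] <- do.call(rbind, wave_rows)
    truths[[i]] <- data.frame(
      athlete_id = id, sex = sex, h1 = p$h1, h_theta = p$h_theta,
      s0 = p$s0, s1 = p$s1, theta = p$theta,
      true_phv_age_yr = true_phv_age(p),
      stringsAsFactors = FALSE)
  }

  structure(
    list(sessions = do.call(rbind, c(sessions,
                                     list(make.row.names = FALSE))),
         truths = do.call(rbind, c(truths, list(make.row.names = FALSE))),
         redraws = redraws,
         seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d athletes (%d male, %d female), %d sessions, seed %s\n",
    nrow(x$truths), sum(x$truths$sex == "male"),
    sum(x$truths$sex == "female"), nrow(x$sessions), format(x$seed)))
  invisible(x)
}

#' Project a subject height into image keypoints
#'
#' Inverse of the photogrammetry geometry: places the floor keypoint at the
#' pixel row whose back-projected world height is zero and the head keypoint
#' at world height equal to the true stature, optionally adding isotropic
#' Gaussian pixel noise. With zero noise, [vertical_extent_cm()] recovers
#' the input height exactly.
#'
#' @param true_height_cm Subject stature, cm.
#' @param cam A [camera_setup()].
#' @param pixel_noise_sd Keypoint noise SD in pixels (default 0).
#' @param seed Optional seed for the noise draw.
#' @return A standing [keypoint_set()].
#' @export
project_keypoints <- function(true_height_cm, cam, pixel_noise_sd = 0,
                              seed = NULL) {
  stopifnot(inherits(cam, "camera_setup"), true_height_cm > 0)
  scale <- cam$focal_px / cam$wall_distance_cm  # px per cm at the wall
  py <- cam$principal_point_px[2]
  px <- cam$principal_point_px[1]
  floor_y <- py + cam$camera_height_cm * scale
  head_y <- py + (cam$camera_height_cm - true_height_cm) * scale
  if (head_y < 0 || floor_y > cam$image_size_px[2]) {
    stop(sprintf(
      "subject (%.0f cm) outside the field of view for this camera setup",
      true_height_cm), call. = FALSE)
  }
  if (pixel_noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    head_y <- head_y + stats::rnorm(1, 0, pixel_noise_sd)
    floor_y <- floor_y + stats::rnorm(1, 0, pixel_noise_sd)
  }
  keypoint_set("standing", top_px = c(px, head_y), bottom_px = c(px, floor_y))
}
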