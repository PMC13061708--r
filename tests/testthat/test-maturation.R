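test_that("maturity offset matches a term-by-term hand evaluation", {
  # independent oracle: evaluate each published term explicitly
  male_oracle <- function(age, ht, sh, wt) {
    ll <- ht - sh
    -9.236 + 0.0002708 * ll * sh - 0.001663 * age * ll +
      0.007216 * age * sh + 0.02292 * (wt / ht * 100)
  }
  female_oracle <- function(age, ht, sh, wt) {
    ll <- ht - sh
    -9.376 + 0.0001882 * ll * sh + 0.0022 * age * ll +
      0.005841 * age * sh - 0.002658 * age * wt +
      0.07693 * (wt / ht * 100)
  }
  mo_m <- maturity_offset("male", exact_anthro(13, 160, 82, 48),
                          fixture_session(160, 82, 48))
  expect_equal(mo_m, male_oracle(13, 160, 82, 48), tolerance = 1e-6)
  expect_equal(mo_m, -0.810, tolerance = 1e-3)

  mo_f <- maturity_offset("female", exact_anthro(12, 155, 81, 45),
                          fixture_session(155, 81, 45))
  expect_equal(mo_f, female_oracle(12, 155, 81, 45), tolerance = 1e-6)
  expect_equal(mo_f, 0.181, tolerance = 5e-3)
})

test_that("maturity offset depends only on the measurements, not the source", {
  an <- exact_anthro(13, 160, 82, 48)
  expect_identical(
    maturity_offset("male", an, fixture_session(160, 82, 48, "expert")),
    maturity_offset("male", an, fixture_session(160, 82, 48, "app")))
})

test_that("out-of-range ages follow the configured policy", {
  an <- exact_anthro(6, 120, 66, 22)
  s <- fixture_session(120, 66, 22)
  expect_warning(maturity_offset("male", an, s), "validated range")
  expect_error(maturity_offset("male", an, s, age_policy = "error"),
               "validated range")
  expect_silent(maturity_offset("male", an, s, age_policy = "ignore"))
})

test_that("maturity offset responds continuously to small perturbations", {
  base <- maturity_offset("male", exact_anthro(13, 160, 82, 48),
                          fixture_session(160, 82, 48))
  eps <- 1e-3
  pert <- maturity_offset("male", exact_anthro(13, 160, 82, 48 + eps),
                          fixture_session(160, 82, 48 + eps))
  # only the weight/height term moves: |coef| * (eps/ht*100)
  expect_lt(abs(pert - base), 0.02292 * (eps / 160 * 100) + 1e-12)
})

test_that("PHV age is the exact identity age minus offset", {
  expect_equal(phv_age(13.0, -0.81), 13.81)
  expect_equal(phv_age(12.0, 0.0), 12.0)
  expect_equal(phv_age(15.5, 1.7), 13.8)
  set.seed(404)
  ages <- runif(50, 8, 18)
  mo <- rnorm(50)
  expect_equal(phv_age(ages, mo) + mo, ages, tolerance = 1e-12)
})

test_that("predicted adult height is the tabulated linear form", {
  tab <- data.frame(sex = "male", age_yr = 13.0,
                    b0 = 10, b1 = 0.9, b2 = 0.1, b3 = 0.1)
  an <- exact_anthro(13.0, 150, 80, 40, midparent = 170)
  s <- fixture_session(150, 80, 40)
  expect_equal(predicted_adult_height("male", an, s, table = tab),
               10 + 0.9 * 150 + 0.1 * 40 + 0.1 * 170)  # = 166
  # nearest-half-year lookup picks the right row
  tab2 <- rbind(tab, data.frame(sex = "male", age_yr = 13.5,
                                b0 = 20, b1 = 0.9, b2 = 0.1, b3 = 0.1))
  an_late <- exact_anthro(13.4, 150, 80, 40, midparent = 170)
  expect_equal(predicted_adult_height("male", an_late, s, table = tab2),
               176)
  expect_error(
    predicted_adult_height("male", exact_anthro(3, 95, 55, 15,
                                                midparent = 170),
                           fixture_session(95, 55, 15)),
    "outside coefficient table range")
  expect_error(
    predicted_adult_height("male", exact_anthro(13, 150, 80, 40), s),
    "midparent")
})

test_that("packaged PAH table: PAH strictly increases in midparent stature", {
  tab <- pah_coefficients()
  expect_true(all(tab$b3 > 0))
  s <- fixture_session(150, 80, 40)
  for (sex in c("male", "female")) {
    for (age in c(6, 10.2, 13.7, 17.2)) {
      lo <- predicted_adult_height(
        sex, exact_anthro(age, 150, 80, 40, midparent = 160), s)
      hi <- predicted_adult_height(
        sex, exact_anthro(age, 150, 80, 40, midparent = 180), s)
      expect_gt(hi, lo)
    }
  }
})

test_that("interpolated lookup agrees with nearest at tabulated ages", {
  s <- fixture_session(150, 80, 40)
  an <- exact_anthro(12.5, 150, 80, 40, midparent = 170)
  expect_equal(
    predicted_adult_height("female", an, s, interpolate = TRUE),
    predicted_adult_height("female", an, s, interpolate = FALSE))
})

test_that("percent of adult height is a guarded ratio", {
  expect_equal(percent_adult_height(150, 166), 100 * 150 / 166)
  expect_equal(percent_adult_height(166, 166), 100)
  expect_equal(percent_adult_height(83, 166), 50)
  expect_error(percent_adult_height(150, 0), "positive")
})

test_that("status classification partitions the offset axis", {
  cfg <- classification_config()
  expect_equal(classify_status(-1.5, cfg), "pre_pubertal")
  expect_equal(classify_status(-1.0, cfg), "pubertal")  # boundary: pubertal
  expect_equal(classify_status(1.0, cfg), "pubertal")
  expect_equal(classify_status(1.2, cfg), "post_pubertal")
  # total and monotone over a fine grid
  mo <- seq(-4, 4, by = 0.01)
  st <- classify_status(mo, cfg)
  expect_true(all(st %in% c("pre_pubertal", "pubertal", "post_pubertal")))
  rank <- match(st, c("pre_pubertal", "pubertal", "post_pubertal"))
  expect_true(all(diff(rank) >= 0))
})

test_that("timing classification uses sex-specific norms and band", {
  cfg <- classification_config(timing_norms = list(
    male = c(mean = 13.8, sd = 1.0), female = c(mean = 11.8, sd = 1.0)))
  expect_equal(classify_timing(12.5, "male", cfg), "early")
  expect_equal(classify_timing(13.8, "male", cfg), "average")
  expect_equal(classify_timing(15.1, "male", cfg), "late")
  expect_equal(classify_timing(12.5, "female", cfg), "average")
  cfg2 <- classification_config(timing_norms = list(
    male = c(mean = 13.8, sd = 1.0)))
  expect_error(classify_timing(12, "female", cfg2), "norms")
})

test_that("recommendation mapping is a total configurable lookup", {
  expect_equal(recommend("pubertal", "early"), "reduce_load")
  expect_equal(recommend("pre_pubertal", "average"), "standard_progression")
  truncated <- default_recommendation_table()[1:3, ]
  expect_error(recommend("post_pubertal", "late", table = truncated),
               "no recommendation")
})

test_that("assess_maturity bundles the pipeline consistently", {
  p <- athlete_profile("A1", "male", "2011-01-01", 165, 179)
  s <- fixture_session(160, 82, 48)
  a <- assess_maturity(p, s)
  expect_s3_class(a, "maturity_assessment")
  expect_equal(a$phv_age_yr + a$maturity_offset_yr, a$decimal_age_yr)
  expect_false(is.na(a$predicted_adult_height_cm))
  expect_true(a$percent_adult_height > 0 && a$percent_adult_height <= 110)
  # no parents -> PAH absent, everything else still computed
  p2 <- athlete_profile("A2", "male", "2011-01-01")
  a2 <- assess_maturity(p2, s)
  expect_true(is.na(a2$predicted_adult_height_cm))
  expect_false(is.na(a2$maturity_offset_yr))
})
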