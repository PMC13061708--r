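test_that("paired-difference summary uses expert-minus-app orientation", {
  p <- paired_continuous(c(1, 3, 5), c(2, 3, 4))
  md <- mean_diff_sd(p)
  expect_equal(md$mean_diff, 0)      # diffs -1, 0, 1
  expect_equal(md$sd_diff, 1)
  same <- mean_diff_sd(paired_continuous(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  swapped <- mean_diff_sd(paired_continuous(c(2, 3, 4), c(1, 3, 5)))
  expect_equal(swapped$mean_diff, -md$mean_diff)
  expect_equal(swapped$sd_diff, md$sd_diff)
  expect_error(mean_diff_sd(paired_continuous(1, 2)), "at least 2")
  expect_error(paired_continuous(1:3, 1:2), "equal length")
  expect_error(paired_continuous(c(1, NA), c(1, 2)), "missing")
})

test_that("TEM follows the 2n-denominator formula and scales homogeneously", {
  expect_equal(tem(paired_continuous(c(5, 5), c(5, 5)))$a_tem, 0)
  p <- paired_continuous(c(11, 9), c(10, 10))  # diffs +1, -1
  expect_equal(tem(p)$a_tem, sqrt(2 / 4))
  expect_equal(tem(p)$r_tem_pct, 100 * sqrt(0.5) / 10)
  c_scale <- 3.7
  p2 <- paired_continuous(c(11, 9) * c_scale, c(10, 10) * c_scale)
  expect_equal(tem(p2)$a_tem, c_scale * tem(p)$a_tem)
  expect_equal(tem(p2)$r_tem_pct, tem(p)$r_tem_pct)
  expect_warning(t0 <- tem(paired_continuous(c(-1, 1), c(1, -1))),
                 "grand mean")
  expect_true(is.na(t0$r_tem_pct))
  expect_equal(t0$a_tem, sqrt(8 / 4))
})

test_that("ICC matches the two-way ANOVA oracle and known fixtures", {
  # 4-subject fixture, checked against an external mixed-effects
  # implementation: ICC(A,1) = 0.945455, 95% CI ~ (0.56, 1.00)
  r <- icc_absolute_agreement(paired_continuous(c(1, 2, 3, 4),
                                                c(1, 2, 3, 5)))
  expect_equal(r$icc, icc_oracle_aov(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               tolerance = 1e-12)
  expect_equal(r$icc, 0.9454545454545, tolerance = 1e-10)
  expect_equal(round(r$ci_low, 2), 0.56)
  expect_equal(round(r$ci_high, 2), 1.00)

  # 20-subject fixture frozen from the same external implementation
  a <- c(4.825165, 9.724561, 15.405406, 11.70873, 13.515462, 11.585333,
         9.372511, 12.699887, 9.442834, 9.037947, 9.929735, 4.191977,
         14.802728, 5.814687, 12.630661, 10.573343, 15.45598, 9.781753,
         10.057939, 10.721786)
  b <- c(8.260764, 8.13504, 15.793714, 10.925448, 12.586934, 11.592251,
         8.529248, 11.733072, 11.840124, 8.814652, 10.82411, 5.950259,
         14.10477, 8.542077, 13.019245, 10.325556, 14.233939, 7.031917,
         9.780922, 12.497684)
  r20 <- icc_absolute_agreement(paired_continuous(a, b))
  expect_equal(r20$icc, 0.855797461937, tolerance = 1e-10)
  expect_equal(round(r20$ci_low, 2), 0.67)
  expect_equal(round(r20$ci_high, 2), 0.94)
})

test_that("ICC equals the brute-force oracle on 200 random small instances", {
  set.seed(20260930)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    t <- rnorm(n, 0, sample(c(0.5, 1, 3), 1))
    a <- t + rnorm(n, 0, 0.5)
    b <- t + rnorm(n, sample(c(0, 0.3), 1), 0.5)
    got <- icc_absolute_agreement(paired_continuous(a, b))$icc
    expect_equal(got, icc_oracle_aov(a, b), tolerance = 1e-10)
  }
})

test_that("ICC absolute-agreement properties hold", {
  a <- c(1, 2, 3, 4, 6)
  r1 <- icc_absolute_agreement(paired_continuous(a, a))
  expect_equal(r1$icc, 1.0)
  b <- c(1.2, 1.9, 3.3, 4.1, 5.6)
  base <- icc_absolute_agreement(paired_continuous(a, b))$icc
  both <- icc_absolute_agreement(paired_continuous(a + 7, b + 7))$icc
  expect_equal(both, base, tolerance = 1e-12)
  one <- icc_absolute_agreement(paired_continuous(a, b + 2))$icc
  expect_lt(one, base)
  expect_error(icc_absolute_agreement(paired_continuous(c(5, 5, 5),
                                                        c(5, 5, 5))),
               "undefined")
  expect_error(icc_absolute_agreement(paired_continuous(c(1, 2), c(1, 2))),
               "at least 3")
})

test_that("crosstab counts, margins, percent agreement and kappa", {
  ct <- crosstab_agreement(c("P", "P", "Q", "Q"), c("P", "Q", "Q", "Q"),
                           categories = c("P", "Q"))
  expect_equal(ct$percent_agree, 75)
  expect_equal(ct$kappa, 0.5)  # p_o 0.75, p_e 0.5 by hand
  expect_equal(unname(rowSums(ct$counts)), c(2, 2))  # method-A margins
  expect_equal(unname(colSums(ct$counts)), c(1, 3))  # method-B margins
  perfect <- crosstab_agreement(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$percent_agree, 100)
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))
  expect_error(crosstab_agreement(c("a", "b"), c("a", "x"),
                                  categories = c("a", "b")), "not in")
  expect_error(crosstab_agreement(c("a", "b"), "a"), "length")
})

test_that("kappa agrees with an independent implementation and is ~0 under
           independence", {
  skip_if_not_installed("e1071")
  l <- table3_labels()
  ct <- crosstab_agreement(l$expert, l$app)
  ref <- e1071::classAgreement(table(l$expert, l$app))
  expect_equal(ct$kappa, ref$kappa, tolerance = 1e-12)

  set.seed(77)
  n <- 10000
  x <- sample(c("pre", "pub", "post"), n, replace = TRUE,
              prob = c(0.4, 0.35, 0.25))
  y <- sample(x)  # independent shuffle preserving margins
  k <- crosstab_agreement(x, y)$kappa
  expect_lt(abs(k), 0.05)
})

test_that("agreement report on a zero-noise cohort is perfect and
           deterministic", {
  co <- generate_cohort(n_male = 12, n_female = 10,
                        err = error_model(0, 0, 0, 0), seed = 5)
  e <- co$sessions[co$sessions$source == "expert", ]
  a <- co$sessions[co$sessions$source == "app", ]
  expect_equal(e$standing_height_cm, a$standing_height_cm)
  rep1 <- agreement_report(co)
  expect_equal(rep1$metrics$icc, rep(1, 3))
  expect_equal(rep1$metrics$a_tem, rep(0, 3))
  expect_equal(rep1$status_crosstab$kappa, 1)
  rep2 <- agreement_report(generate_cohort(n_male = 12, n_female = 10,
                                           err = error_model(0, 0, 0, 0),
                                           seed = 5))
  expect_identical(report_to_json(rep1), report_to_json(rep2))
})

test_that("unpaired athletes are named in the pairing error", {
  co <- generate_cohort(n_male = 4, n_female = 3, seed = 9)
  sess <- co$sessions
  drop <- sess$athlete_id == "S0002" & sess$source == "app"
  expect_error(agreement_report(sess[!drop, ]), "S0002")
})
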