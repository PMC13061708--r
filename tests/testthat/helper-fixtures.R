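# Shared fixtures and independent oracles for the test suite.

# Anthro bundle with exact (not date-derived) decimal age, for worked
# examples whose inputs are stated at round ages.
exact_anthro <- function(age, standing, sitting, weight, midparent = NA) {
  structure(
    list(decimal_age_yr = age,
         leg_length_cm = standing - sitting,
         midparent_height_cm = midparent,
         weight_by_height_ratio = weight / standing * 100),
    class = "derived_anthro")
}

fixture_session <- function(standing, sitting, weight, source = "expert",
                            date = "2024-01-01") {
  measurement_session(date, standing, sitting, weight, source = source)
}

# Independent ICC(A,1) oracle: mean squares from a two-way ANOVA fitted with
# stats::aov (a different computational route than the closed-form sums in
# the implementation), then the absolute-agreement formula.
icc_oracle_aov <- function(a, b) {
  n <- length(a)
  dat <- data.frame(y = c(a, b),
                    subj = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(c("a", "b"), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = dat))[[1]]
  ms_r <- tab["subj", "Mean Sq"]
  ms_c <- tab["rater", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- 2
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

# The paired status labels implied by the published contingency table of
# expert vs automated maturity classifications: full agreement for 39
# post-pubertal and 52 pre-pubertal athletes; of 50 expert-pubertal
# athletes, 47 agree and 3 are called pre-pubertal by the automated method.
# Note the printed cells sum to 141 although the table's grand total and the
# surrounding text say 144; the three remaining athletes appear in no cell,
# so the reproduction is of the 141 printed pairs.
table3_labels <- function() {
  expert <- c(rep("post_pubertal", 39), rep("pre_pubertal", 52),
              rep("pubertal", 50))
  app <- c(rep("post_pubertal", 39), rep("pre_pubertal", 52),
           rep("pre_pubertal", 3), rep("pubertal", 47))
  list(expert = expert, app = app)
}
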