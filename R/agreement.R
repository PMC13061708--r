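# Method-agreement battery for two-method comparisons: paired-difference
# summary, two-way absolute-agreement ICC with an F-based confidence
# interval, technical error of measurement, and categorical cross-tabulation
# with Cohen's kappa.

#' Paired continuous measurements
#'
#' A container for n paired observations of one metric by two methods.
#' Differences are oriented `method_a - method_b`; by package convention
#' method A is the expert/reference method.
#'
#' @param a,b Equal-length numeric vectors with no missing values.
#' @param metric_label Name of the metric (e.g. `"maturity_offset_yr"`).
#' @return An object of class `paired_continuous`.
#' @export
paired_continuous <- function(a, b, metric_label = "metric") {
  if (length(a) != length(b)) {
    stop("paired methods must have equal length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values in paired data",
                                 call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 metric_label = metric_label),
            class = "paired_continuous")
}

#' Mean and SD of paired differences
#'
#' Bland-Altman-style summary of the differences `d_i = a_i - b_i`: the mean
#' difference (systematic bias of method B relative to A) and the sample SD
#' of the differences (n - 1 denominator).
#'
#' @param pairs A [paired_continuous()] with at least 2 pairs.
#' @return Named list `mean_diff`, `sd_diff`.
#' @export
mean_diff_sd <- function(pairs) {
  stopifnot(inherits(pairs, "paired_continuous"))
  d <- pairs$a - pairs$b
  if (length(d) < 2L) stop("need at least 2 pairs", call. = FALSE)
  list(mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Technical error of measurement
#'
#' Classic paired-replicate TEM: `sqrt(sum(d_i^2) / (2n))` in the metric's
#' units, and relative TEM as a percentage of the grand mean of all 2n
#' values. The grand-mean denominator is one of several conventions in use;
#' it is the one adopted here and stated in output.
#'
#' @param pairs A [paired_continuous()].
#' @return Named list `a_tem` (absolute), `r_tem_pct` (relative, %; `NA`
#'   with a warning when the grand mean is zero).
#' @export
tem <- function(pairs) {
  stopifnot(inherits(pairs, "paired_continuous"))
  d <- pairs$a - pairs$b
  n <- length(d)
  if (n < 1L) stop("need at least 1 pair", call. = FALSE)
  a_tem <- sqrt(sum(d^2) / (2 * n))
  grand <- mean(c(pairs$a, pairs$b))
  if (grand == 0) {
    warning("grand mean is zero: relative TEM undefined", call. = FALSE)
    r_tem <- NA_real_
  } else {
    r_tem <- 100 * a_tem / grand
  }
  list(a_tem = a_tem, r_tem_pct = r_tem)
}

#' Two-way absolute-agreement ICC (single measures)
#'
#' Intraclass correlation for agreement between k = 2 methods rating n
#' subjects, from the two-way ANOVA decomposition. With `MS_R` the
#' between-subject (rows), `MS_C` the between-method (columns) and `MS_E`
#' the residual mean square:
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#'
#' This is the single-measure absolute-agreement form (ICC(A,1) in the
#' McGraw-Wong taxonomy, ICC(2,1) in Shrout-Fleiss); it penalises systematic
#' offsets between methods, unlike the consistency form. The two-sided
#' confidence interval uses the standard F-based construction with
#' Satterthwaite degrees of freedom for this form.
#'
#' @param pairs A [paired_continuous()] with n >= 3 subjects.
#' @param alpha Two-sided error rate for the CI (default 0.05).
#' @return Named list `icc`, `ci_low`, `ci_high`, plus the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`) and metadata (`model`, `ci_method`).
#' @export
icc_absolute_agreement <- function(pairs, alpha = 0.05) {
  stopifnot(inherits(pairs, "paired_continuous"))
  x <- cbind(pairs$a, pairs$b)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) stop("need at least 3 subjects for the ICC", call. = FALSE)

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))

  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (denom <= .Machine$double.eps * max(1, abs(ms_r))) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  icc <- (ms_r - ms_e) / denom

  # F-based CI (McGraw & Wong construction for ICC(A,1)), with a
  # Satterthwaite approximation for the denominator degrees of freedom.
  if (ms_e == 0 && ms_c == 0) {
    ci <- c(1, 1)  # perfect agreement: interval degenerates
  } else {
    r <- max(min(icc, 1 - 1e-12), -1 + 1e-12)
    aa <- (k * r) / (n * (1 - r))
    bb <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v_num <- (aa * ms_c + bb * ms_e)^2
    v_den <- (aa * ms_c)^2 / (k - 1) + (bb * ms_e)^2 / ((n - 1) * (k - 1))
    v <- if (v_den > 0) v_num / v_den else Inf
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms_r - f_l * ms_e) /
      (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
    hi <- n * (f_u * ms_r - ms_e) /
      (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
       model = "two-way, absolute agreement, single measures",
       ci_method = "F-based (Satterthwaite df)", alpha = alpha)
}

#' Cross-tabulation of two classifications
#'
#' Square contingency table of paired categorical labels from two methods,
#' with agreement counts, percent agreement and unweighted Cohen's kappa
#' (`(p_o - p_e) / (1 - p_e)`, expected agreement from marginal products).
#' Kappa is a derived statistic offered alongside the raw table.
#'
#' @param labels_a,labels_b Equal-length label vectors (method A rows,
#'   method B columns).
#' @param categories Ordered category list; every label must appear in it.
#' @return An object of class `crosstab` with fields `categories`, `counts`
#'   (square matrix, A in rows), `n_total`, `n_agree`, `percent_agree`,
#'   `kappa`.
#' @export
crosstab_agreement <- function(labels_a, labels_b,
                               categories = sort(unique(c(labels_a,
                                                          labels_b)))) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  unknown <- setdiff(unique(c(labels_a, labels_b)), categories)
  if (length(unknown) > 0) {
    stop("labels not in category list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fa <- factor(labels_a, levels = categories)
  fb <- factor(labels_b, levels = categories)
  counts <- table(fa, fb)
  counts <- matrix(as.integer(counts), nrow = length(categories),
                   dimnames = list(method_a = categories,
                                   method_b = categories))
  n_total <- sum(counts)
  n_agree <- sum(diag(counts))
  p_o <- n_agree / n_total
  p_e <- sum(rowSums(counts) * colSums(counts)) / n_total^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(categories = categories, counts = counts, n_total = n_total,
         n_agree = n_agree, percent_agree = 100 * p_o, kappa = kappa),
    class = "crosstab"
  )
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab> n=%d  agree=%d (%.1f%%)  kappa=%.3f\n",
              x$n_total, x$n_agree, x$percent_agree, x$kappa))
  print(x$counts)
  invisible(x)
}

#' Full agreement report for a paired cohort
#'
#' Pairs each athlete's expert- and app-source sessions (by date order
#' within athlete), runs the maturation pipeline on both arms, and bundles
#' the continuous-agreement battery per metric with the status
#' cross-tabulation into one serialisable report. Difference orientation is
#' expert minus app throughout.
#'
#' @param cohort A cohort data.frame in the package CSV schema (see
#'   [read_cohort()]), containing one expert and one app session per athlete
#'   per wave.
#' @param metrics Character vector of continuous metrics to compare; any of
#'   `"maturity_offset_yr"`, `"phv_age_yr"`, `"standing_height_cm"`,
#'   `"sitting_height_cm"`, `"weight_kg"`, `"predicted_adult_height_cm"`,
#'   `"percent_adult_height"`.
#' @param cfg A [classification_config()].
#' @param alpha CI error rate for the ICC.
#' @return An object of class `agreement_report`: per-metric statistics
#'   (mean diff, SD, ICC + CI, absolute and relative TEM), the status
#'   crosstab, and metadata.
#' @export
agreement_report <- function(cohort,
                             metrics = c("maturity_offset_yr", "phv_age_yr",
                                         "standing_height_cm"),
                             cfg = classification_config(),
                             alpha = 0.05) {
  recs <- cohort_records(cohort)
  per_source <- assess_cohort_records(recs, cfg)

  expert <- per_source[per_source$source == "expert", , drop = FALSE]
  app <- per_source[per_source$source == "app", , drop = FALSE]
  expert <- expert[order(expert$athlete_id, expert$date), , drop = FALSE]
  app <- app[order(app$athlete_id, app$date), , drop = FALSE]

  key_e <- paste(expert$athlete_id, ave(seq_len(nrow(expert)),
                                        expert$athlete_id, FUN = seq_along))
  key_a <- paste(app$athlete_id, ave(seq_len(nrow(app)),
                                     app$athlete_id, FUN = seq_along))
  if (!identical(sort(key_e), sort(key_a))) {
    bad <- c(setdiff(expert$athlete_id, app$athlete_id),
             setdiff(app$athlete_id, expert$athlete_id))
    if (length(bad) == 0) {
      tab_e <- table(expert$athlete_id)
      tab_a <- table(app$athlete_id)
      ids <- union(names(tab_e), names(tab_a))
      bad <- ids[vapply(ids, function(i) {
        isTRUE(tab_e[i] != tab_a[i]) || is.na(tab_e[i]) || is.na(tab_a[i])
      }, logical(1))]
    }
    stop("unpaired expert/app sessions for athlete(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  app <- app[match(key_e, key_a), , drop = FALSE]

  metric_stats <- lapply(metrics, function(m) {
    va <- expert[[m]]
    vb <- app[[m]]
    keep <- !is.na(va) & !is.na(vb)
    p <- paired_continuous(va[keep], vb[keep], metric_label = m)
    md <- mean_diff_sd(p)
    tm <- tem(p)
    ic <- icc_absolute_agreement(p, alpha = alpha)
    data.frame(metric = m, n = sum(keep),
               mean_diff = md$mean_diff, sd_diff = md$sd_diff,
               icc = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
               a_tem = tm$a_tem, r_tem = tm$r_tem_pct)
  })
  metric_table <- do.call(rbind, metric_stats)

  ct <- crosstab_agreement(expert$status, app$status,
                           categories = STATUS_LEVELS)

  structure(
    list(metrics = metric_table,
         status_crosstab = ct,
         n_athletes = length(unique(expert$athlete_id)),
         meta = list(
           difference_orientation = "expert - app",
           icc_model = "two-way, absolute agreement, single measures",
           icc_ci = "F-based (Satterthwaite df)",
           kappa_note = "derived statistic, computed from the crosstab",
           r_tem_denominator = "grand mean of both methods")),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d athletes, expert vs app\n",
              x$n_athletes))
  df <- x$metrics
  df[, -1] <- lapply(df[, -1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  print(x$status_crosstab)
  invisible(x)
}
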