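#' Paired trial errors for one variable
#'
#' Matches two wide measurement tables on `image_id` and extracts the pairs
#' for which `variable` is present in both; pairs with a missing side are
#' excluded and counted.
#'
#' @param t1,t2 Measurement tables (data frames with `image_id` and the
#'   variable column).
#' @param variable Variable name (e.g. `"ARA"`).
#' @return A list with class `"error_series"`: `variable`, `image_ids`,
#'   `t1`, `t2`, `errors` (t1 - t2), `n_pairs`, `n_excluded`.
#' @export
paired_errors <- function(t1, t2, variable) {
  for (tb in list(t1, t2)) {
    if (!is.data.frame(tb) || !"image_id" %in% names(tb)) {
      cm_stop("measurement tables need an image_id column", "validation_error")
    }
  }
  if (!(variable %in% names(t1)) || !(variable %in% names(t2))) {
    cm_stop(sprintf("variable '%s' absent from one of the tables", variable),
            "validation_error")
  }
  shared <- intersect(t1$image_id, t2$image_id)
  v1 <- t1[[variable]][match(shared, t1$image_id)]
  v2 <- t2[[variable]][match(shared, t2$image_id)]
  ok <- is.finite(v1) & is.finite(v2)
  n_excluded <- length(shared) - sum(ok)
  if (sum(ok) < 2L) {
    cm_stop(sprintf("variable '%s': fewer than 2 complete pairs", variable),
            "insufficient_data")
  }
  structure(list(variable = variable,
                 image_ids = shared[ok],
                 t1 = v1[ok], t2 = v2[ok],
                 errors = v1[ok] - v2[ok],
                 n_pairs = sum(ok),
                 n_excluded = n_excluded),
            class = "error_series")
}

#' Summary error statistics of a paired series
#'
#' RMSE is `sqrt(mean(e^2))`; `std_err` is the sample (n-1) standard
#' deviation of the signed errors.  The decomposition
#' `rmse^2 = mean_signed^2 + ((n-1)/n) * std^2` holds exactly.
#'
#' @param es An [paired_errors()] series.
#' @return Named list: `mean_abs_err`, `mean_signed_err`, `std_err`, `rmse`.
#' @export
error_summary <- function(es) {
  stopifnot(inherits(es, "error_series"))
  e <- es$errors
  if (length(e) < 2L) {
    cm_stop("error_summary needs at least 2 pairs", "insufficient_data")
  }
  list(mean_abs_err = mean(abs(e)),
       mean_signed_err = mean(e),
       std_err = stats::sd(e),
       rmse = sqrt(mean(e^2)))
}

two_way_mean_squares <- function(x1, x2) {
  n <- length(x1)
  k <- 2
  m <- cbind(x1, x2)
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  list(n = n, k = k,
       msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' Intraclass correlation coefficient for two repeated trials
#'
#' Single-measure ICC from the two-way mean squares with k = 2 raters.  The
#' default is ICC(2,1) — two-way random effects, absolute agreement — the
#' standard strict choice for test–retest reliability.  The consistency
#' variant ICC(3,1) (two-way mixed) is also available.  The 95% confidence
#' interval uses the standard F-based construction; when the interval is
#' undefined (e.g. zero residual variance under perfect agreement) its bounds
#' are `NA`.
#'
#' @param x1,x2 Paired numeric vectors (same images, two trials).
#' @param model `"two_way_random_absolute"` (ICC(2,1), default) or
#'   `"two_way_mixed_consistency"` (ICC(3,1)).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Named list: `estimate` (clamped to [-1, 1]), `ci_low`, `ci_high`,
#'   `model`.
#' @export
icc <- function(x1, x2,
                model = c("two_way_random_absolute",
                          "two_way_mixed_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  if (length(x1) != length(x2)) {
    cm_stop("icc: trials have different lengths", "validation_error")
  }
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 3L) {
    cm_stop("icc needs at least 3 complete pairs", "insufficient_data")
  }
  ms <- two_way_mean_squares(x1, x2)
  n <- ms$n; k <- ms$k
  if (ms$msr < 1e-14 && ms$mse < 1e-14) {
    cm_stop("icc undefined: no between-subject and no residual variance",
            "undefined_statistic")
  }
  alpha <- 1 - conf_level
  if (model == "two_way_random_absolute") {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    ci <- icc_a1_ci(ms, est, alpha)
  } else {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    ci <- icc_c1_ci(ms, alpha)
  }
  list(estimate = max(-1, min(1, est)), ci_low = ci[1], ci_high = ci[2],
       model = model)
}

# F-based interval for ICC(2,1) (two-way random, absolute agreement, single).
icc_a1_ci <- function(ms, r, alpha) {
  n <- ms$n; k <- ms$k
  if (!is.finite(r) || r >= 1 || ms$mse < 1e-14) return(c(NA_real_, NA_real_))
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) return(c(NA_real_, NA_real_))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  c(max(-1, min(1, lo)), max(-1, min(1, hi)))
}

# F-based interval for ICC(3,1) (two-way mixed, consistency, single).
icc_c1_ci <- function(ms, alpha) {
  n <- ms$n; k <- ms$k
  if (ms$mse < 1e-14) return(c(NA_real_, NA_real_))
  fobs <- ms$msr / ms$mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  c(max(-1, min(1, (fl - 1) / (fl + k - 1))),
    max(-1, min(1, (fu - 1) / (fu + k - 1))))
}

#' Coefficient of determination between two trials
#'
#' R-squared of the ordinary least-squares fit `x2 = a + b * x1`; for simple
#' regression this equals the squared Pearson correlation, so it is symmetric
#' in its arguments.
#'
#' @param x1,x2 Paired numeric vectors.
#' @return R-squared in [0, 1].
#' @export
r_squared <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 3L) {
    cm_stop("r_squared needs at least 3 complete pairs", "insufficient_data")
  }
  if (stats::sd(x1) < 1e-14 || stats::sd(x2) < 1e-14) {
    cm_stop("r_squared undefined: zero variance in a series",
            "undefined_statistic")
  }
  # squared Pearson correlation == OLS R^2 for simple regression; identical
  # series short-circuit to exactly 1 (cor() carries float round-off)
  if (all(x1 == x2)) return(1)
  stats::cor(x1, x2)^2
}

#' Reliability band of an R-squared value
#'
#' Bands used to group variables by how cleanly a second annotation
#' reproduces the first: super-clean (R² ≥ 0.90), clean (0.75 ≤ R² < 0.90),
#' semi-clean (0.50 ≤ R² < 0.75), unreliable (R² < 0.50).
#'
#' @param r2 Numeric vector of R-squared values in [0, 1].
#' @return Character vector of band labels.
#' @export
classify_r2 <- function(r2) {
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    cm_stop("classify_r2: values must lie in [0, 1]", "validation_error")
  }
  ifelse(r2 >= 0.90, "super-clean",
         ifelse(r2 >= 0.75, "clean",
                ifelse(r2 >= 0.50, "semi-clean", "unreliable")))
}

#' Effect-size label of an R-squared value
#'
#' Conventional interpretation scale: none/very-weak (< 0.3), weak
#' [0.3, 0.5), moderate [0.5, 0.7), strong [0.7, 1), perfect (= 1).
#'
#' @param r2 Numeric vector of R-squared values in [0, 1].
#' @return Character vector of labels.
#' @export
effect_size_label <- function(r2) {
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    cm_stop("effect_size_label: values must lie in [0, 1]", "validation_error")
  }
  ifelse(r2 == 1, "perfect",
         ifelse(r2 >= 0.7, "strong",
                ifelse(r2 >= 0.5, "moderate",
                       ifelse(r2 >= 0.3, "weak", "none/very-weak"))))
}

agreement_row <- function(t1, t2, variable, comparison, stratum) {
  row <- data.frame(comparison = comparison, stratum = stratum,
                    variable = variable, n_pairs = NA_integer_,
                    n_excluded = NA_integer_,
                    mean_abs_err = NA_real_, mean_signed_err = NA_real_,
                    std_err = NA_real_, rmse = NA_real_,
                    icc = NA_real_, icc_ci_low = NA_real_,
                    icc_ci_high = NA_real_, r2 = NA_real_,
                    r2_class = NA_character_, effect_size = NA_character_,
                    stringsAsFactors = FALSE)
  es <- tryCatch(paired_errors(t1, t2, variable),
                 cervimetrics_insufficient_data = function(e) NULL)
  if (is.null(es)) return(row)
  row$n_pairs <- es$n_pairs
  row$n_excluded <- es$n_excluded
  sm <- error_summary(es)
  row$mean_abs_err <- sm$mean_abs_err
  row$mean_signed_err <- sm$mean_signed_err
  row$std_err <- sm$std_err
  row$rmse <- sm$rmse
  ic <- tryCatch(icc(es$t1, es$t2),
                 cervimetrics_error = function(e) NULL)
  if (!is.null(ic)) {
    row$icc <- ic$estimate
    row$icc_ci_low <- ic$ci_low
    row$icc_ci_high <- ic$ci_high
  }
  r2 <- tryCatch(r_squared(es$t1, es$t2),
                 cervimetrics_error = function(e) NA_real_)
  if (is.finite(r2)) {
    r2 <- max(0, min(1, r2))
    row$r2 <- r2
    row$r2_class <- classify_r2(r2)
    row$effect_size <- effect_size_label(r2)
  }
  row
}

#' Per-variable agreement report between two measurement tables
#'
#' One row per alignment variable shared by both tables: paired-error
#' summaries (mean absolute and signed error, SD of errors, RMSE), ICC(2,1)
#' with its 95% CI, regression R² with its reliability band and effect-size
#' label.  Pairs with a missing value are dropped per variable, not listwise.
#'
#' @param t1,t2 Wide measurement tables sharing at least 3 `image_id`s.
#' @param label Comparison label (e.g. `"US1 vs US2"`).
#' @param strata Optional name of a metadata column present in `t1`; when
#'   given, per-stratum rows are appended after the pooled (`"all"`) rows.
#' @return Data frame with class `"reliability_report"`.
#' @export
reliability_report <- function(t1, t2, label, strata = NULL) {
  shared <- intersect(t1$image_id, t2$image_id)
  if (length(shared) < 3L) {
    cm_stop("reliability_report: tables overlap on fewer than 3 images",
            "insufficient_data")
  }
  vars <- intersect(MEASUREMENT_VARS, intersect(names(t1), names(t2)))
  build <- function(a, b, stratum) {
    do.call(rbind, lapply(vars, function(v) {
      agreement_row(a, b, v, comparison = label, stratum = stratum)
    }))
  }
  out <- build(t1, t2, "all")
  if (!is.null(strata)) {
    if (!strata %in% names(t1)) {
      cm_stop(sprintf("strata column '%s' absent from first table", strata),
              "validation_error")
    }
    for (g in unique(t1[[strata]])) {
      ids <- t1$image_id[t1[[strata]] == g]
      out <- rbind(out, build(t1[t1$image_id %in% ids, ],
                              t2[t2$image_id %in% ids, ],
                              as.character(g)))
    }
  }
  class(out) <- c("reliability_report", class(out))
  out
}

#' Published concurrent-validity R-squared values
#'
#' Reference R-squared values, as published for the 18 cervical alignment
#' variables in a CNN-annotator versus expert-human concurrent-validity
#' comparison on 254 lateral radiographs, together with the reliability band
#' each variable was assigned to.  Useful for checking [classify_r2()]
#' against an external grouping.
#'
#' @return Data frame with columns `variable`, `r2`, `published_group`.
#' @export
published_validity_r2 <- function() {
  path <- system.file("extdata", "published_validity_r2.csv",
                      package = "cervimetrics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a reliability report to CSV
#'
#' @param report A [reliability_report()].
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_report_csv <- function(report, dest) {
  utils::write.csv(as.data.frame(report), dest, row.names = FALSE, na = "")
  invisible(dest)
}
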