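#' Recovery statistics
#'
#' Per-sample recovery is `100 * predicted / actual` (%). The summary uses
#' the sample (n-1) standard deviation and the relative standard deviation
#' `100 * sd / mean`.
#'
#' @param predicted Predicted concentrations (ug/mL).
#' @param actual Nominal concentrations (ug/mL); all strictly positive.
#' @return An object of class `recovery_stats`: list with `recoveries`,
#'   `mean`, `sd`, `rsd`.
#' @examples
#' r <- recovery_stats(c(5.1, 4.9, 5.0), c(5, 5, 5))
#' r$mean
#' @export
recovery_stats <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  if (any(actual <= 0)) stop("actual concentrations must be strictly positive")
  rec <- 100 * predicted / actual
  m <- mean(rec)
  s <- stats::sd(rec)
  structure(
    list(recoveries = rec, mean = m, sd = s, rsd = 100 * s / m),
    class = "recovery_stats"
  )
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("<recovery_stats> n = %d, mean %.2f%%, SD %.3f, RSD %.3f%%\n",
              length(x$recoveries), x$mean, x$sd, x$rsd))
  invisible(x)
}

#' Prediction-error metrics
#'
#' With residuals `e = predicted - actual` over m samples:
#' \itemize{
#'   \item RMSEP = sqrt(sum(e^2) / m) (prediction set);
#'   \item RMSEC = sqrt(sum(e^2) / (n - n_lv - 1)) (calibration set,
#'     degrees of freedom corrected for the fitted latent variables);
#'   \item RRMSEP = 100 * RMSEP / mean(actual) (%);
#'   \item BCMSEP = mean((e - mean(e))^2), the bias-corrected (variance)
#'     part of the mean squared prediction error.
#' }
#'
#' @param predicted,actual Concentration vectors (ug/mL) of equal length.
#' @param n_lv Number of latent variables; required for RMSEC.
#' @param role `"prediction"` (default) returns RMSEP/RRMSEP/BCMSEP;
#'   `"calibration"` additionally returns RMSEC.
#' @return A named list of the metrics.
#' @examples
#' error_metrics(c(5.1, 4.9, 5.1, 4.9), c(5, 5, 5, 5))$rmsep  # 0.1
#' @export
error_metrics <- function(predicted, actual, n_lv = NULL,
                          role = c("prediction", "calibration")) {
  role <- match.arg(role)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  e <- predicted - actual
  m <- length(e)
  out <- list(
    rmsep = sqrt(sum(e^2) / m),
    rrmsep = 100 * sqrt(sum(e^2) / m) / mean(actual),
    bcmsep = mean((e - mean(e))^2)
  )
  if (role == "calibration") {
    if (is.null(n_lv)) stop("n_lv is required for RMSEC")
    if (m <= n_lv + 1) {
      stop("RMSEC is undefined when the sample count is at most n_lv + 1")
    }
    out$rmsec <- sqrt(sum(e^2) / (m - n_lv - 1))
  }
  out
}

#' Multivariate detection and quantitation limits
#'
#' Net-analyte-signal formulation: the Euclidean norm of the PLS regression
#' vector is the reciprocal NAS sensitivity, so
#' \deqn{LOD = 3.3 \sigma \|b\|_2, \qquad LOQ = 10 \sigma \|b\|_2}
#' with sigma the spectral noise level in AU. When `noise_sigma` is not
#' supplied it is estimated from the model's calibration spectral residuals
#' (`x_residual_sd`).
#'
#' @param model A fitted `pls1_model`.
#' @param noise_sigma Absorbance noise SD (AU); must be positive.
#' @return A list with `lod` and `loq` (ug/mL); their ratio is always
#'   10 / 3.3.
#' @export
lod_loq <- function(model, noise_sigma = NULL) {
  if (!inherits(model, "pls1_model")) stop("model must be a fitted pls1_model")
  if (is.null(noise_sigma)) noise_sigma <- model$x_residual_sd
  if (is.null(noise_sigma) || noise_sigma <= 0) {
    stop("noise_sigma must be positive (or estimable from the model residuals)")
  }
  sens <- sqrt(sum(model$regression_vector^2))
  list(lod = 3.3 * noise_sigma * sens, loq = 10 * noise_sigma * sens)
}

#' Linearity of predicted versus actual concentrations
#'
#' Ordinary least-squares fit of predicted on actual; slope near 1,
#' intercept near 0 and coefficient of determination near 1 indicate an
#' accurate calibration.
#'
#' @param predicted,actual Concentration vectors (>= 3 points,
#'   non-constant `actual`).
#' @return A list with `slope`, `intercept`, `r2`.
#' @export
linearity_fit <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  if (length(actual) < 3) stop("at least 3 points are required")
  if (stats::var(actual) == 0) stop("actual concentrations must not be constant")
  fit <- stats::lm(predicted ~ actual)
  # r2 computed directly; summary.lm warns on exact fits
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((predicted - mean(predicted))^2)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = if (tss == 0) 1 else 1 - rss / tss
  )
}

#' Two-sample method comparison (t-test and F-test from summaries)
#'
#' Pooled-variance two-sample Student t-test on the mean recoveries and a
#' variance-ratio F-test (larger variance over smaller), both against
#' two-sided critical values at the given confidence level: t with
#' `n_a + n_b - 2` degrees of freedom, F with `(n-1, n-1)` degrees of
#' freedom (upper 5% point for 95% confidence). The verdict is "no
#' significant difference" when both statistics stay below their critical
#' values.
#'
#' @param mean_a,var_a,n_a Summary of method A (mean %, variance, n).
#' @param mean_b,var_b,n_b Summary of method B.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `method_comparison` with the statistics,
#'   critical values and verdict.
#' @examples
#' cmp <- compare_methods(99.51, 2.705, 5, 99.77, 1.009, 5)
#' cmp$f_stat  # about 2.68
#' @export
compare_methods <- function(mean_a, var_a, n_a, mean_b, var_b, n_b,
                            conf = 0.95) {
  if (n_a < 2 || n_b < 2) stop("both methods need at least 2 measurements")
  if (var_a == 0 && var_b == 0) {
    stop("both variances are zero; the comparison is undefined")
  }
  sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / (n_a + n_b - 2)
  t_stat <- abs(mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  f_stat <- max(var_a, var_b) / min(var_a, var_b)
  df_num <- if (var_a >= var_b) n_a - 1 else n_b - 1
  df_den <- if (var_a >= var_b) n_b - 1 else n_a - 1
  t_critical <- stats::qt(1 - (1 - conf) / 2, df = n_a + n_b - 2)
  f_critical <- stats::qf(conf, df_num, df_den)
  structure(
    list(
      n_a = n_a, n_b = n_b, mean_a = mean_a, mean_b = mean_b,
      var_a = var_a, var_b = var_b,
      t_stat = t_stat, f_stat = f_stat,
      t_critical = t_critical, f_critical = f_critical,
      no_significant_difference = t_stat <= t_critical && f_stat <= f_critical
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> t = %.3f (crit %.3f), F = %.3f (crit %.3f): %s\n",
    x$t_stat, x$t_critical, x$f_stat, x$f_critical,
    if (x$no_significant_difference) "no significant difference"
    else "significant difference"
  ))
  invisible(x)
}

#' Standard-addition recovery
#'
#' Recovery of a known spike on top of an already-analyzed sample:
#' `100 * (total_found - base_found) / added` (%). Being a difference, the
#' result is invariant to any constant offset shared by base and total.
#'
#' @param base_found Concentration found before spiking (ug/mL).
#' @param added Spiked amount (ug/mL); strictly positive.
#' @param total_found Concentration found after spiking (ug/mL).
#' @return Recovery in percent (vectorized).
#' @examples
#' standard_addition(3.04, 3, 5.97)  # 97.67
#' @export
standard_addition <- function(base_found, added, total_found) {
  if (any(added <= 0)) stop("added amount must be strictly positive")
  100 * (total_found - base_found) / added
}

#' Assemble a full validation report for one analyte
#'
#' Computes the complete assay-validation metric set from calibration and
#' prediction-set results: linearity (slope/intercept/r2 of predicted vs
#' actual on the calibration set), NAS-based LOD/LOQ, RMSEC, RMSEP, RRMSEP,
#' BCMSEP, RMSECV, and recovery statistics for both sets.
#'
#' @param model The fitted `pls1_model`.
#' @param cal_actual,cal_predicted Calibration concentrations and
#'   predictions (ug/mL).
#' @param val_actual,val_predicted Prediction-set concentrations and
#'   predictions.
#' @param rmsecv Cross-validated RMSECV at the model's size (from
#'   [loo_cv()]), or `NA`.
#' @param noise_sigma Spectral noise SD for [lod_loq()]; default estimates
#'   it from the model residuals.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(model, cal_actual, cal_predicted,
                              val_actual, val_predicted, rmsecv = NA_real_,
                              noise_sigma = NULL) {
  lin <- linearity_fit(cal_predicted, cal_actual)
  lims <- lod_loq(model, noise_sigma)
  cal_err <- error_metrics(cal_predicted, cal_actual, n_lv = model$n_lv,
                           role = "calibration")
  val_err <- error_metrics(val_predicted, val_actual)
  structure(
    list(
      analyte = model$analyte, n_lv = model$n_lv,
      slope = lin$slope, intercept = lin$intercept, r2 = lin$r2,
      lod = lims$lod, loq = lims$loq,
      rmsec = cal_err$rmsec, rmsep = val_err$rmsep,
      rrmsep = val_err$rrmsep, bcmsep = val_err$bcmsep, rmsecv = rmsecv,
      calibration = recovery_stats(cal_predicted, cal_actual),
      validation = recovery_stats(val_predicted, val_actual)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%d LVs)\n", x$analyte, x$n_lv))
  cat(sprintf("  slope %.4f  intercept %.4f  r2 %.4f\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  LOD %.4f  LOQ %.4f ug/mL\n", x$lod, x$loq))
  cat(sprintf("  RMSEC %.4f  RMSEP %.4f  RRMSEP %.3f%%  BCMSEP %.5f  RMSECV %s\n",
              x$rmsec, x$rmsep, x$rrmsep, x$bcmsep,
              if (is.na(x$rmsecv)) "NA" else sprintf("%.4f", x$rmsecv)))
  cat(sprintf("  calibration recovery %.2f%% (RSD %.2f%%); validation %.2f%% (RSD %.2f%%)\n",
              x$calibration$mean, x$calibration$rsd,
              x$validation$mean, x$validation$rsd))
  invisible(x)
}

#' Serialize a validation report to JSON or a metric-sheet CSV
#'
#' @param report A `validation_report`.
#' @param path Optional file path.
#' @return For `report_to_json`, the JSON string; for `write_report_csv`,
#'   `path` invisibly (a two-column metric sheet).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    analyte = report$analyte, n_lv = report$n_lv,
    slope = report$slope, intercept = report$intercept, r2 = report$r2,
    lod = report$lod, loq = report$loq,
    rmsec = report$rmsec, rmsep = report$rmsep, rrmsep = report$rrmsep,
    bcmsep = report$bcmsep, rmsecv = report$rmsecv,
    calibration = unclass(report$calibration),
    validation = unclass(report$validation)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @export
write_report_csv <- function(report, path) {
  rows <- data.frame(
    parameter = c("n_lv", "slope", "intercept", "r2", "lod", "loq", "rmsec",
                  "rmsep", "rrmsep", "bcmsep", "rmsecv",
                  "calibration_mean_recovery", "calibration_rsd",
                  "validation_mean_recovery", "validation_rsd"),
    value = c(report$n_lv, report$slope, report$intercept, report$r2,
              report$lod, report$loq, report$rmsec, report$rmsep,
              report$rrmsep, report$bcmsep, report$rmsecv,
              report$calibration$mean, report$calibration$rsd,
              report$validation$mean, report$validation$rsd)
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
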