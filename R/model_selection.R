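#' Leave-one-out cross-validation of a PLS1 model
#'
#' For every candidate number of latent variables, each sample is removed in
#' turn, the model is refit on the remainder and the held-out concentration
#' predicted. PRESS(a) is the sum of squared held-out residuals at `a`
#' latent variables, and RMSECV(a) = sqrt(PRESS(a) / n) (plain-n
#' denominator, the standard chemometric definition).
#'
#' @param X Calibration spectral matrix.
#' @param y Calibration concentrations (ug/mL).
#' @param max_lv Largest model size examined; default `min(8, n - 2)`.
#' @param variable_mask Optional logical wavelength mask (see [fit_pls1()]).
#' @param analyte Name carried in the result.
#'
#' @return An object of class `cv_result`: list with `analyte`, `press`,
#'   `rmsecv` (vectors over 1..max_lv), `n` and `max_lv`.
#' @examples
#' d <- fcm_design()
#' X <- simulate_mixtures(d, default_overlap_profiles(),
#'                        noise_model(0.002, seed = 1))
#' cal <- d$role == "calibration"
#' cv <- loo_cv(X[cal, ], design_concentrations(d, "calibration")[, "CEF"])
#' haaland_thomas_select(cv)
#' @export
loo_cv <- function(X, y, max_lv = NULL, variable_mask = NULL, analyte = "") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (is.null(max_lv)) max_lv <- min(8, n - 2)
  if (max_lv > n - 2) stop("max_lv must be at most n - 2")
  if (max_lv < 1) stop("max_lv must be at least 1")
  press <- numeric(max_lv)
  for (i in seq_len(n)) {
    for (a in seq_len(max_lv)) {
      # rank-deficient folds (e.g. noiseless low-rank data) are scored with
      # the largest attainable model, so PRESS plateaus instead of erroring
      m <- .fit_capped(X[-i, , drop = FALSE], y[-i], a, variable_mask)
      if (is.null(m)) stop("data cannot support even a 1-LV model")
      press[a] <- press[a] + (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }
  }
  structure(
    list(analyte = analyte, press = press, rmsecv = sqrt(press / n),
         n = n, max_lv = max_lv),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: n = %d\n",
              if (nzchar(x$analyte)) x$analyte else "(unnamed)", x$n))
  print(data.frame(lv = seq_along(x$press), press = x$press,
                   rmsecv = x$rmsecv), row.names = FALSE)
  invisible(x)
}

#' Haaland-Thomas latent-variable selection
#'
#' Selects the most parsimonious model whose cross-validation error is not
#' statistically worse than the best one: with \eqn{a^* = \arg\min
#' \mathrm{PRESS}}, the chosen size is the smallest \eqn{a \le a^*} whose
#' F-ratio \eqn{\mathrm{PRESS}(a)/\mathrm{PRESS}(a^*)} falls below the
#' critical value of an F distribution with \eqn{(n, n)} degrees of freedom
#' at probability \eqn{1 - \alpha}.
#'
#' @param cv A `cv_result` from [loo_cv()], or a bare PRESS vector (then
#'   `n` must be given).
#' @param alpha Test level; the conventional choice 0.25 is the default.
#' @param n Number of calibration samples (taken from `cv` when it is a
#'   `cv_result`).
#' @return The selected number of latent variables (integer).
#' @examples
#' haaland_thomas_select(c(100, 10, 9.9, 9.8), n = 13)  # 2
#' @export
haaland_thomas_select <- function(cv, alpha = 0.25, n = NULL) {
  if (inherits(cv, "cv_result")) {
    press <- cv$press
    n <- cv$n
  } else {
    press <- as.numeric(cv)
    if (is.null(n)) stop("n must be supplied when cv is a bare PRESS vector")
  }
  if (length(press) == 0) stop("PRESS vector is empty")
  if (any(press < 0)) stop("PRESS values must be non-negative")
  a_star <- which.min(press)
  f_crit <- stats::qf(1 - alpha, n, n)
  if (press[a_star] == 0) {
    # degenerate noiseless case: any PRESS of exactly 0 ties the minimum
    ratio <- ifelse(press == 0, 1, Inf)
  } else {
    ratio <- press / press[a_star]
  }
  candidates <- which(seq_along(press) <= a_star & ratio < f_crit)
  as.integer(min(candidates))
}

#' One-call latent-variable selection
#'
#' Runs [loo_cv()] and [haaland_thomas_select()] and returns the completed
#' `cv_result` with the chosen size in `selected_lv`.
#'
#' @inheritParams loo_cv
#' @inheritParams haaland_thomas_select
#' @return A `cv_result` with an additional `selected_lv` element.
#' @export
select_lv <- function(X, y, max_lv = NULL, variable_mask = NULL,
                      alpha = 0.25, analyte = "") {
  cv <- loo_cv(X, y, max_lv = max_lv, variable_mask = variable_mask,
               analyte = analyte)
  cv$selected_lv <- haaland_thomas_select(cv, alpha = alpha)
  cv
}

#' Export a cross-validation curve as CSV
#'
#' @param cv A `cv_result`.
#' @param path File path; columns `lv`, `press`, `rmsecv`.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  utils::write.csv(
    data.frame(lv = seq_along(cv$press), press = cv$press, rmsecv = cv$rmsecv),
    path, row.names = FALSE
  )
  invisible(path)
}
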