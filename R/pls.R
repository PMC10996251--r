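#' Fit a PLS1 calibration model (NIPALS)
#'
#' Partial least squares regression with a single response, computed by
#' NIPALS-style deflation on mean-centered data. For one response the weight
#' vector of each component is available in closed form
#' (\eqn{w = X^T y / \|X^T y\|}), so no within-component iteration is
#' needed. Components are extracted sequentially:
#' \deqn{t = X w, \quad p = X^T t / t^T t, \quad q = y^T t / t^T t, \quad
#'       X \leftarrow X - t p^T}
#' and the regression vector in the original variable space is
#' \eqn{b = W (P^T W)^{-1} q}. Only `X` is deflated; `y` is not (equivalent
#' for PLS1). Data are column-mean-centered, never variance-scaled --
#' absorbances on a common AU scale do not warrant scaling.
#'
#' @param X Spectral matrix (samples x wavelengths), e.g. from
#'   [simulate_mixtures()].
#' @param y Concentrations (ug/mL), one per row of `X`.
#' @param n_lv Number of latent variables (>= 1, at most the rank of the
#'   centered masked `X`).
#' @param variable_mask Logical vector over the wavelength variables
#'   selecting which enter the model; `NULL` means all (full-spectrum PLS).
#' @param analyte Name stored in the model.
#'
#' @return An object of class `pls1_model` with elements `analyte`, `n_lv`,
#'   `x_mean`, `y_mean`, `weights`, `loadings_x`, `loadings_y`, `scores`,
#'   `regression_vector` (full length, zero outside the mask),
#'   `variable_mask`, `x_residual_sd` (per-point SD of the deflated spectral
#'   residual, usable as a noise estimate for [lod_loq()]) and `grid` when
#'   `X` carries one.
#' @examples
#' d <- fcm_design()
#' X <- simulate_mixtures(d, default_overlap_profiles(), noise_model(0))
#' cal <- d$role == "calibration"
#' m <- fit_pls1(X[cal, ], design_concentrations(d, "calibration")[, "FPV"],
#'               n_lv = 3, analyte = "FPV")
#' range(predict(m, X[cal, ]) - design_concentrations(d, "calibration")[, "FPV"])
#' @export
fit_pls1 <- function(X, y, n_lv, variable_mask = NULL, analyte = "") {
  X <- as.matrix(X)
  n <- nrow(X)
  p_all <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (n < 2) stop("at least 2 samples are required")
  if (n_lv < 1) stop("n_lv must be at least 1")
  if (is.null(variable_mask)) variable_mask <- rep(TRUE, p_all)
  if (length(variable_mask) != p_all) {
    stop("variable_mask length must match the number of wavelength variables")
  }
  if (sum(variable_mask) < n_lv) {
    stop("variable_mask must select at least n_lv variables")
  }
  if (n_lv > n - 1) stop("n_lv exceeds the rank allowed by the sample count")

  Xm <- X[, variable_mask, drop = FALSE]
  x_mean_m <- colMeans(Xm)
  y_mean <- mean(y)
  E <- sweep(Xm, 2, x_mean_m)
  yc <- y - y_mean
  p_m <- ncol(Xm)

  W <- P <- matrix(0, p_m, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  ss0 <- sum(E^2)
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ss0))) {
      stop(sprintf("n_lv = %d exceeds the rank of the centered data", n_lv))
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) {
      stop(sprintf("n_lv = %d exceeds the rank of the centered data", n_lv))
    }
    p <- crossprod(E, t) / tt
    q[a] <- sum(yc * t) / tt
    E <- E - t %*% t(p)
    W[, a] <- w
    P[, a] <- p
    Tm[, a] <- t
  }
  b_m <- W %*% solve(crossprod(P, W), q)

  x_mean <- numeric(p_all)
  x_mean[variable_mask] <- x_mean_m
  b <- numeric(p_all)
  b[variable_mask] <- b_m

  structure(
    list(
      analyte = analyte, n_lv = n_lv,
      x_mean = x_mean, y_mean = y_mean,
      weights = W, loadings_x = P, loadings_y = q, scores = Tm,
      regression_vector = b, variable_mask = variable_mask,
      x_residual_sd = sqrt(sum(E^2) / length(E)),
      grid = attr(X, "grid")
    ),
    class = "pls1_model"
  )
}

#' Predict concentrations from a fitted PLS1 model
#'
#' Applies \eqn{\hat y = \bar y + (x - \bar x)^T b} row by row. Masked-out
#' wavelengths carry zero regression weight, so full-grid spectra can be
#' passed to a windowed (GA-selected) model unchanged.
#'
#' @param object A `pls1_model`.
#' @param newdata Spectral matrix on the same wavelength grid (samples x
#'   wavelengths), or a single spectrum vector.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ug/mL).
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$regression_vector)) {
    stop("newdata has a different number of wavelength variables than the model")
  }
  drop(object$y_mean +
         sweep(newdata, 2, object$x_mean) %*% object$regression_vector)
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf(
    "<pls1_model> %s: %d LV(s), %d/%d wavelengths in model\n",
    if (nzchar(x$analyte)) x$analyte else "(unnamed)",
    x$n_lv, sum(x$variable_mask), length(x$variable_mask)
  ))
  invisible(x)
}

#' @export
coef.pls1_model <- function(object, ...) object$regression_vector

#' Serialize a PLS1 model to JSON
#'
#' All model fields plus metadata (package version, timestamp, optional
#' seed) are written so a model can be archived next to its predictions.
#'
#' @param model A `pls1_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param seed Optional seed to record in the metadata.
#' @param timestamp Set `FALSE` to omit the timestamp, making the output a
#'   pure function of the model (used for byte-identical pipeline reruns).
#' @return The JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL, seed = NULL, timestamp = TRUE) {
  payload <- list(
    analyte = model$analyte, n_lv = model$n_lv,
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, loadings_x = model$loadings_x,
    loadings_y = model$loadings_y,
    regression_vector = model$regression_vector,
    variable_mask = model$variable_mask,
    x_residual_sd = model$x_residual_sd,
    grid = if (!is.null(model$grid)) {
      model$grid[c("start", "stop", "step", "points")]
    },
    metadata = list(
      package = "specalib",
      version = as.character(utils::packageVersion("specalib")),
      seed = seed,
      timestamp = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
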