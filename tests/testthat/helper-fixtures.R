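# Shared builders for synthetic test problems.

# Noiseless mixture spectra over the reference design with the default
# overlap profiles; returns calibration/validation blocks and Y matrices.
reference_blocks <- function(noise = noise_model(sigma_abs = 0)) {
  d <- fcm_design()
  X <- simulate_mixtures(d, default_overlap_profiles(), noise)
  cal <- d$role == "calibration"
  list(
    design = d,
    Xcal = X[cal, , drop = FALSE], Xval = X[!cal, , drop = FALSE],
    Ycal = design_concentrations(d, "calibration"),
    Yval = design_concentrations(d, "validation")
  )
}

# Toy wavelength-selection problem: 40 variables in 20 width-2 windows,
# with all predictive signal confined to windows 10-13 (one independent
# concentration per window; y is their sum) and pure noise elsewhere.
toy_window_problem <- function(seed, n = 15, n_val = 12, noise_sd = 0.05) {
  set.seed(seed)
  nv <- 40
  make_block <- function(C) {
    m <- nrow(C)
    X <- matrix(rnorm(m * nv, 0, noise_sd), m)
    prof <- c(0.8, 1.0)
    for (j in 1:4) {
      idx <- (9 + j - 1) * 2 + 1:2
      X[, idx] <- X[, idx] + C[, j] %o% prof
    }
    X
  }
  C <- matrix(runif(4 * n, 3, 7), n)
  Cv <- matrix(runif(4 * n_val, 3, 7), n_val)
  list(
    X = make_block(C), y = rowSums(C),
    X_val = make_block(Cv), y_val = rowSums(Cv),
    informative_windows = 10:13
  )
}

# Independent naive PLS oracle: minimum-norm least squares via the SVD
# pseudoinverse on centered data.
pinv_predict <- function(X, y, X_new, tol = 1e-10) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  s <- svd(Xc)
  keep <- s$d > tol * s$d[1]
  b <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y - ym)) / s$d[keep])
  drop(ym + sweep(as.matrix(X_new), 2, xm) %*% b)
}
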