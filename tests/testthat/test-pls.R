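test_that("rank-1 single-analyte data is fit exactly with one latent variable", {
  g <- wavelength_grid()
  p <- make_component_spectrum(list(spectral_band(300, 25, 0.1)), g)
  conc <- c(3, 4, 5, 6, 7)
  X <- conc %o% p$absorptivity
  m <- fit_pls1(X, conc, n_lv = 1)
  expect_equal(predict(m, X), conc, tolerance = 1e-8)
})

test_that("noiseless three-analyte mixtures are recovered exactly at 3 LVs", {
  blocks <- reference_blocks()
  for (an in colnames(blocks$Ycal)) {
    m <- fit_pls1(blocks$Xcal, blocks$Ycal[, an], n_lv = 3, analyte = an)
    rec_cal <- recovery_stats(predict(m, blocks$Xcal), blocks$Ycal[, an])
    expect_lt(abs(rec_cal$mean - 100), 0.01)
    expect_lt(rec_cal$sd, 0.01)
    rec_val <- recovery_stats(predict(m, blocks$Xval), blocks$Yval[, an])
    expect_true(all(abs(rec_val$recoveries - 100) < 0.1))
  }
})

test_that("PLS1 at full rank matches the pseudoinverse least-squares oracle", {
  set.seed(11)
  n <- 10
  X <- matrix(rnorm(n * 30), n)
  y <- rnorm(n)
  m <- fit_pls1(X, y, n_lv = n - 1)
  expect_equal(predict(m, X), pinv_predict(X, y, X), tolerance = 1e-6)
  X_new <- matrix(rnorm(5 * 30), 5)
  expect_equal(predict(m, X_new), pinv_predict(X, y, X_new), tolerance = 1e-6)
})

test_that("score vectors are orthogonal and residuals non-increasing in LVs", {
  blocks <- reference_blocks(noise_model(0.002, seed = 2))
  y <- blocks$Ycal[, "MFX"]
  m <- fit_pls1(blocks$Xcal, y, n_lv = 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(sqrt(diag(crossprod(m$weights))), rep(1, 6), tolerance = 1e-10)

  res <- vapply(1:6, function(a) {
    mm <- fit_pls1(blocks$Xcal, y, n_lv = a)
    sum((y - predict(mm, blocks$Xcal))^2)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-10))
})

test_that("fit is invariant to sample order; constant columns get zero weight", {
  blocks <- reference_blocks(noise_model(0.002, seed = 3))
  y <- blocks$Ycal[, "FPV"]
  m <- fit_pls1(blocks$Xcal, y, n_lv = 3)
  perm <- c(5, 1, 13, 7, 2, 9, 3, 11, 6, 10, 4, 12, 8)
  m_perm <- fit_pls1(blocks$Xcal[perm, ], y[perm], n_lv = 3)
  expect_equal(m_perm$regression_vector, m$regression_vector,
               tolerance = 1e-8)
  vperm <- c(3, 1, 12, 5, 2, 9, 7, 11, 6, 10, 4, 8)
  expect_equal(predict(m, blocks$Xval[vperm, ]),
               predict(m, blocks$Xval)[vperm])

  X_aug <- cbind(blocks$Xcal, 7)  # constant absorbance channel
  m_aug <- fit_pls1(unclass(X_aug), y, n_lv = 3)
  expect_lt(abs(m_aug$regression_vector[202]), 1e-8)
})

test_that("predicting the training-mean spectrum returns the training mean", {
  blocks <- reference_blocks()
  y <- blocks$Ycal[, "CEF"]
  m <- fit_pls1(blocks$Xcal, y, n_lv = 2)
  expect_equal(predict(m, colMeans(blocks$Xcal)), mean(y))
})

test_that("ill-posed fits are rejected", {
  blocks <- reference_blocks()
  y <- blocks$Ycal[, "FPV"]
  expect_error(fit_pls1(blocks$Xcal, y, n_lv = 13), "rank|sample")
  expect_error(fit_pls1(blocks$Xcal[1, , drop = FALSE], y[1], 1), "2 samples")
  expect_error(fit_pls1(blocks$Xcal, y, n_lv = 3,
                        variable_mask = rep(c(TRUE, FALSE), c(2, 199))),
               "at least n_lv")
  # noiseless 3-component data has rank 3: asking for 5 LVs must fail
  expect_error(fit_pls1(blocks$Xcal, y, n_lv = 5), "rank")
  m <- fit_pls1(blocks$Xcal, y, n_lv = 3)
  expect_error(predict(m, blocks$Xval[, 1:100]), "different number")
})

test_that("models serialize to JSON and back-read fields agree", {
  blocks <- reference_blocks()
  m <- fit_pls1(blocks$Xcal, blocks$Ycal[, "FPV"], n_lv = 3, analyte = "FPV")
  js <- jsonlite::fromJSON(model_to_json(m, seed = 99))
  expect_equal(js$analyte, "FPV")
  expect_equal(js$n_lv, 3)
  expect_equal(js$regression_vector, unname(m$regression_vector))
  expect_equal(js$metadata$seed, 99)
})
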