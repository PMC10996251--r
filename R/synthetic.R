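#' Gaussian absorption band
#'
#' Parametric building block for synthetic pure-component spectra. A band is
#' a Gaussian in wavelength with a molar-absorptivity-like amplitude, so that
#' `amplitude * concentration` is the peak absorbance contributed by a
#' solution of that concentration (Beer-Lambert, 1 cm path).
#'
#' @param center Band maximum (nm).
#' @param width Gaussian sigma (nm); must be positive.
#' @param amplitude Peak absorptivity (AU mL / ug); must be non-negative.
#'
#' @return An object of class `spectral_band`.
#' @export
spectral_band <- function(center, width, amplitude) {
  if (width <= 0) stop("band width must be positive")
  if (amplitude < 0) stop("band amplitude must be non-negative")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "spectral_band")
}

#' Build a pure-component spectrum from Gaussian bands
#'
#' Evaluates the sum of Gaussian bands at every grid point:
#' \deqn{a(\lambda) = \sum_b A_b \exp\{-(\lambda - c_b)^2 / (2 w_b^2)\}}
#' The result is the absorptivity profile of one analyte, i.e. the absorbance
#' of a 1 ug/mL solution.
#'
#' @param bands A list of [spectral_band()] objects (at least one).
#' @param grid A [wavelength_grid()].
#' @param name Analyte name carried in the result.
#'
#' @return An object of class `pure_spectrum`: list with `analyte`, `grid`
#'   and the `absorptivity` vector (length `grid$points`, all non-negative).
#' @examples
#' g <- wavelength_grid()
#' p <- make_component_spectrum(list(spectral_band(300, 10, 0.1)), g)
#' g$wavelengths[which.max(p$absorptivity)]  # 300
#' @export
make_component_spectrum <- function(bands, grid, name = "analyte") {
  if (!is_wavelength_grid(grid)) stop("grid must be a wavelength_grid")
  if (inherits(bands, "spectral_band")) bands <- list(bands)
  if (length(bands) < 1) stop("at least one band is required")
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (!inherits(b, "spectral_band")) stop("bands must be spectral_band objects")
    if (b$center < grid$start || b$center > grid$stop) {
      stop(sprintf(
        "band %d (center %g nm) lies outside the grid %g-%g nm",
        i, b$center, grid$start, grid$stop
      ))
    }
  }
  wl <- grid$wavelengths
  a <- rep(0, grid$points)
  for (b in bands) {
    a <- a + b$amplitude * exp(-(wl - b$center)^2 / (2 * b$width^2))
  }
  structure(list(analyte = name, grid = grid, absorptivity = a),
            class = "pure_spectrum")
}

#' @export
print.pure_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pure_spectrum> %s: %d points, max absorptivity %.4f AU.mL/ug at %g nm\n",
    x$analyte, x$grid$points, max(x$absorptivity),
    x$grid$wavelengths[which.max(x$absorptivity)]
  ))
  invisible(x)
}

# Frozen band constants for the three default profiles. They target the
# qualitative structure of the favipiravir / cefixime / moxifloxacin UV
# spectra -- broad, severely overlapping bands between 230 and 340 nm with
# pairwise correlations above 0.5 and 5 ug/mL peak absorbances of roughly
# 0.5-0.6 AU -- not any measured curve.
.default_band_sets <- function() {
  list(
    FPV = list(spectral_band(238, 18, 0.050), spectral_band(312, 26, 0.100)),
    CEF = list(spectral_band(287, 26, 0.115), spectral_band(235, 15, 0.040)),
    MFX = list(spectral_band(294, 20, 0.095), spectral_band(332, 24, 0.050),
               spectral_band(243, 14, 0.035))
  )
}

#' Default severely-overlapping pure spectra
#'
#' Three fixed synthetic absorptivity profiles emulating the severe spectral
#' overlap of favipiravir (FPV), cefixime (CEF) and moxifloxacin (MFX) in the
#' UV region: every pair of profiles has Pearson correlation at least 0.5
#' over the grid, and a 5 ug/mL solution of each peaks between 0.2 and
#' 1.2 AU. The band constants are documented package defaults, not fits to
#' measured spectra.
#'
#' @param grid A [wavelength_grid()]; defaults to 200--400 nm at 1 nm.
#'
#' @return A named list of three `pure_spectrum` objects (FPV, CEF, MFX).
#' @examples
#' pures <- default_overlap_profiles()
#' sapply(pures, function(p) length(p$absorptivity))  # 201 201 201
#' @export
default_overlap_profiles <- function(grid = wavelength_grid()) {
  sets <- .default_band_sets()
  out <- lapply(names(sets), function(nm) {
    make_component_spectrum(sets[[nm]], grid, name = nm)
  })
  names(out) <- names(sets)
  out
}

#' Instrument noise model for simulated spectra
#'
#' @param sigma_abs Standard deviation of additive i.i.d. Gaussian absorbance
#'   noise (AU). Default 0.002 AU, a typical photometric noise level for a
#'   double-beam UV-Vis instrument in the 0-1 AU range.
#' @param baseline_amplitude Bound (AU) on the coefficients of a random
#'   degree-2 polynomial baseline drift added per spectrum. 0 disables drift.
#' @param interferent_scale Dimensionless multiplier for a fixed broad
#'   Gaussian background band (center 280 nm, sigma 40 nm, unit amplitude
#'   0.05 AU) standing in for plasma protein residue or tablet excipients.
#' @param seed Integer seed making the simulation reproducible; `NULL` draws
#'   from the current RNG stream.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_abs = 0.002, baseline_amplitude = 0,
                        interferent_scale = 0, seed = NULL) {
  if (sigma_abs < 0) stop("sigma_abs must be non-negative")
  if (baseline_amplitude < 0) stop("baseline_amplitude must be non-negative")
  if (interferent_scale < 0) stop("interferent_scale must be non-negative")
  structure(
    list(sigma_abs = sigma_abs, baseline_amplitude = baseline_amplitude,
         interferent_scale = interferent_scale, seed = seed),
    class = "noise_model"
  )
}

# Fixed interferent band: broad protein/excipient-like background.
.interferent_profile <- function(grid) {
  0.05 * exp(-(grid$wavelengths - 280)^2 / (2 * 40^2))
}

#' Simulate mixture spectra by Beer-Lambert additivity
#'
#' Each simulated spectrum is the concentration-weighted sum of the pure
#' absorptivity profiles, plus (optionally) a random low-order polynomial
#' baseline, a scaled broad interferent band, and i.i.d. Gaussian absorbance
#' noise:
#' \deqn{x_i = \sum_k c_{ik} p_k + b_i + s g + \epsilon_i}
#'
#' @param design A [mixture_design][fcm_design()] (or any data frame with
#'   concentration columns `conc_*`), supplying one row per spectrum.
#' @param pures A list of `pure_spectrum` objects, one per analyte, all on
#'   the same grid; length must match the number of concentration columns.
#' @param noise A [noise_model()]. The default is noiseless.
#'
#' @return A numeric matrix (samples x wavelengths) of class
#'   `spectral_matrix`, with the grid attached as attribute `grid`, column
#'   names the wavelengths and row names the design run ids.
#' @examples
#' d <- fcm_design()
#' X <- simulate_mixtures(d, default_overlap_profiles(), noise_model(0))
#' dim(X)  # 25 x 201
#' @export
simulate_mixtures <- function(design, pures,
                              noise = noise_model(sigma_abs = 0)) {
  conc <- design_concentrations(design)
  if (any(conc < 0)) stop("design concentrations must be non-negative")
  if (length(pures) != ncol(conc)) {
    stop("number of pure spectra must match the number of analytes")
  }
  grid <- pures[[1]]$grid
  for (p in pures[-1]) {
    if (!same_grid(grid, p$grid)) stop("all pure spectra must share one grid")
  }
  P <- vapply(pures, function(p) p$absorptivity, numeric(grid$points))
  X <- conc %*% t(P)

  with_seed(noise$seed, {
    n <- nrow(X)
    if (noise$baseline_amplitude > 0) {
      # degree-2 polynomial in scaled wavelength s in [-1, 1], coefficients
      # uniform in [-A, A] per spectrum
      s <- 2 * (grid$wavelengths - grid$start) / (grid$stop - grid$start) - 1
      B <- cbind(1, s, s^2)
      coefs <- matrix(
        stats::runif(3 * n, -noise$baseline_amplitude, noise$baseline_amplitude),
        nrow = n
      )
      X <- X + coefs %*% t(B)
    }
    if (noise$interferent_scale > 0) {
      X <- X + noise$interferent_scale *
        matrix(.interferent_profile(grid), n, grid$points, byrow = TRUE)
    }
    if (noise$sigma_abs > 0) {
      X <- X + matrix(stats::rnorm(length(X), 0, noise$sigma_abs), nrow = n)
    }
  })

  dimnames(X) <- list(
    if (!is.null(design$run)) as.character(design$run) else seq_len(nrow(X)),
    as.character(grid$wavelengths)
  )
  structure(X, grid = grid, class = c("spectral_matrix", "matrix", "array"))
}

#' Write / read spectra as CSV
#'
#' The on-disk layout is one row per wavelength: first column
#' `wavelength_nm`, then one column per sample ('.' decimal separator,
#' UTF-8). This is the transposed orientation of the in-memory samples x
#' wavelengths matrix.
#'
#' @param x A samples x wavelengths matrix as returned by
#'   [simulate_mixtures()].
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectral_matrix` with its reconstructed grid.
#' @export
write_spectra_csv <- function(x, path) {
  wl <- as.numeric(colnames(x))
  df <- data.frame(wavelength_nm = wl, t(unclass(x)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1] != "wavelength_nm") {
    stop("spectra CSV must have wavelength_nm as its first column")
  }
  wl <- df$wavelength_nm
  step <- unique(round(diff(wl), 10))
  if (length(step) != 1) stop("wavelength grid in CSV is not equally spaced")
  grid <- wavelength_grid(min(wl), max(wl), step)
  X <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(X) <- as.character(wl)
  structure(X, grid = grid, class = c("spectral_matrix", "matrix", "array"))
}
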