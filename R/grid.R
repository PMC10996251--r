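#' Wavelength grid
#'
#' Defines the fixed wavelength axis on which all spectra in a calibration
#' live. The default is the 200--400 nm range at 1 nm spacing used by
#' conventional UV-Vis spectrophotometers, giving 201 measurement variables.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm).
#' @param step Spacing between adjacent points (nm).
#'
#' @return An object of class `wavelength_grid`: a list with elements
#'   `start`, `stop`, `step`, `points` and the expanded `wavelengths` vector.
#' @examples
#' g <- wavelength_grid()
#' g$points  # 201
#' @export
wavelength_grid <- function(start = 200, stop = 400, step = 1) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("grid parameters must be numeric")
  }
  if (start >= stop) stop("grid start must be strictly below stop")
  if (step <= 0) stop("grid step must be positive")
  n <- (stop - start) / step + 1
  if (abs(n - round(n)) > 1e-8) {
    stop("grid span (stop - start) must be an integer multiple of step")
  }
  n <- as.integer(round(n))
  structure(
    list(
      start = start, stop = stop, step = step, points = n,
      wavelengths = seq(start, stop, by = step)
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
    x$start, x$stop, x$step, x$points
  ))
  invisible(x)
}

is_wavelength_grid <- function(x) inherits(x, "wavelength_grid")

same_grid <- function(a, b) {
  is_wavelength_grid(a) && is_wavelength_grid(b) &&
    a$start == b$start && a$stop == b$stop && a$step == b$step
}

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}
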