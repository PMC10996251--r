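#' Published recovery tables of the FPV/CEF/MFX chemometric assay
#'
#' Per-mixture percentage recoveries reported for the full-spectrum PLS and
#' GA-PLS models of the simultaneous favipiravir/cefixime/moxifloxacin UV
#' determination, transcribed verbatim: 13 calibration mixtures, 12
#' validation mixtures, and the five spiked-human-plasma levels
#' (each plasma recovery is itself the mean of five determinations). These
#' serve as worked-example inputs for [recovery_stats()] -- the published
#' summary rows (mean 100.09, SD 1.813 for the PLS/FPV calibration column,
#' etc.) are reproduced from them -- not as outputs of this package's
#' models.
#'
#' @return A data frame with one column per model/analyte combination
#'   (`PLS_FPV`, `PLS_CEF`, `PLS_MFX`, `GAPLS_FPV`, `GAPLS_CEF`,
#'   `GAPLS_MFX`).
#' @examples
#' recovery_stats(reference_calibration_recoveries()$PLS_FPV,
#'                rep(100, 13))$mean  # 100.09
#' @export
reference_calibration_recoveries <- function() {
  data.frame(
    PLS_FPV = c(103.13, 101.52, 101.32, 97.86, 100.98, 97.87, 99.72,
                99.96, 101.00, 96.91, 100.81, 101.51, 98.58),
    PLS_CEF = c(101.68, 99.42, 100.36, 98.09, 97.66, 99.81, 100.59,
                99.14, 97.09, 101.18, 102.93, 97.71, 102.34),
    PLS_MFX = c(100.64, 100.37, 98.83, 100.89, 101.59, 100.90, 99.73,
                100.47, 99.96, 98.74, 100.04, 99.64, 97.28),
    GAPLS_FPV = c(102.91, 100.49, 100.54, 97.93, 101.10, 98.35, 99.35,
                  100.48, 101.83, 97.46, 101.06, 101.29, 98.72),
    GAPLS_CEF = c(101.28, 98.81, 100.91, 98.22, 98.98, 100.77, 99.54,
                  99.44, 97.18, 101.36, 102.29, 96.96, 101.20),
    GAPLS_MFX = c(99.88, 100.33, 99.71, 100.15, 100.72, 99.63, 100.40,
                  100.41, 101.77, 98.98, 99.82, 99.61, 99.10)
  )
}

#' @rdname reference_calibration_recoveries
#' @export
reference_validation_recoveries <- function() {
  data.frame(
    PLS_FPV = c(101.48, 98.45, 98.50, 100.20, 95.73, 96.29, 100.17,
                96.75, 97.10, 101.50, 97.35, 102.17),
    PLS_CEF = c(101.99, 95.82, 95.13, 100.25, 99.62, 98.39, 97.71,
                103.46, 98.69, 104.26, 102.20, 104.50),
    PLS_MFX = c(96.26, 101.77, 98.55, 102.03, 102.73, 101.71, 98.13,
                97.40, 96.13, 98.27, 98.51, 99.18),
    GAPLS_FPV = c(99.63, 99.57, 99.69, 100.39, 96.43, 96.54, 100.60,
                  96.32, 96.85, 101.07, 97.33, 101.32),
    GAPLS_CEF = c(95.70, 96.50, 96.27, 100.66, 100.84, 99.26, 98.24,
                  102.57, 98.02, 102.39, 100.90, 102.26),
    GAPLS_MFX = c(101.05, 100.91, 96.70, 100.64, 101.87, 100.47, 97.99,
                  98.08, 96.79, 100.11, 98.26, 101.26)
  )
}

#' @rdname reference_calibration_recoveries
#' @export
reference_plasma_recoveries <- function() {
  data.frame(
    PLS_FPV = c(94.46, 94.39, 96.80, 93.93, 96.80),
    PLS_CEF = c(96.84, 93.34, 95.09, 98.10, 97.08),
    PLS_MFX = c(92.85, 97.16, 96.74, 93.74, 96.91),
    GAPLS_FPV = c(92.12, 95.01, 96.75, 93.90, 96.85),
    GAPLS_CEF = c(92.91, 95.49, 94.46, 97.18, 96.86),
    GAPLS_MFX = c(96.66, 94.65, 96.55, 94.20, 97.08)
  )
}

#' Published method-comparison summaries (tablet assay)
#'
#' Mean percentage recovery, variance and measurement count reported for
#' the PLS and GA-PLS determinations of each drug in its tablet form and
#' for the corresponding previously reported comparator method (n = 5
#' throughout). Worked-example inputs for [compare_methods()].
#'
#' @return A data frame with columns `analyte`, `method`, `mean`, `var`,
#'   `n`.
#' @examples
#' s <- reference_method_comparison()
#' cef <- s[s$analyte == "CEF", ]
#' compare_methods(cef$mean[cef$method == "PLS"],
#'                 cef$var[cef$method == "PLS"], 5,
#'                 cef$mean[cef$method == "reported"],
#'                 cef$var[cef$method == "reported"], 5)$f_stat
#' @export
reference_method_comparison <- function() {
  data.frame(
    analyte = rep(c("FPV", "CEF", "MFX"), each = 3),
    method = rep(c("PLS", "GAPLS", "reported"), 3),
    mean = c(99.91, 99.73, 100.33,
             99.51, 100.42, 99.77,
             100.45, 100.15, 99.36),
    var = c(1.952, 0.892, 0.828,
            2.705, 1.603, 1.009,
            1.400, 1.413, 0.808),
    n = rep(5L, 9)
  )
}
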