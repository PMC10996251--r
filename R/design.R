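#' Construct a mixture design
#'
#' A mixture design holds, for each experimental run, the coded factor
#' levels, the concentrations in ug/mL obtained by the affine map
#' `conc = center + step * coded`, and the run's role (calibration or
#' validation).
#'
#' @param coded Integer matrix (runs x factors) of coded levels.
#' @param center,step Affine map parameters (ug/mL); scalars or one value
#'   per analyte.
#' @param role Character vector of per-run roles in
#'   `c("calibration", "validation")`, or `NA` before splitting.
#' @param analytes Analyte names (one per factor column).
#'
#' @return A data frame of class `mixture_design` with columns `run`,
#'   `role`, `coded_<analyte>` and `conc_<analyte>`, and attributes `center`,
#'   `step`, `analytes`.
#' @export
mixture_design <- function(coded, center = 5, step = 1, role = NA_character_,
                           analytes = c("FPV", "CEF", "MFX")) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  if (length(analytes) != k) stop("one analyte name per factor is required")
  center <- rep_len(center, k)
  step <- rep_len(step, k)
  conc <- sweep(sweep(coded, 2, step, `*`), 2, center, `+`)
  if (any(conc <= 0)) stop("all concentrations must be positive")
  role <- rep_len(role, nrow(coded))
  bad <- !is.na(role) & !role %in% c("calibration", "validation")
  if (any(bad)) stop("roles must be 'calibration' or 'validation'")
  df <- data.frame(run = seq_len(nrow(coded)), role = role)
  for (j in seq_len(k)) df[[paste0("coded_", analytes[j])]] <- coded[, j]
  for (j in seq_len(k)) df[[paste0("conc_", analytes[j])]] <- conc[, j]
  structure(df, center = center, step = step, analytes = analytes,
            class = c("mixture_design", "data.frame"))
}

#' Extract the concentration (Y) block of a design
#'
#' @param design A `mixture_design` (or data frame with `conc_*` columns).
#' @param role Optional filter: `"calibration"` or `"validation"`.
#' @return A numeric matrix (runs x analytes) of concentrations in ug/mL.
#' @export
design_concentrations <- function(design, role = NULL) {
  if (!is.null(role)) design <- design[design$role %in% role, , drop = FALSE]
  cols <- grep("^conc_", names(design), value = TRUE)
  if (length(cols) == 0) stop("design has no concentration columns")
  m <- as.matrix(design[, cols, drop = FALSE])
  colnames(m) <- sub("^conc_", "", cols)
  m
}

# Reference 25-run design for the FPV/CEF/MFX calibration study, transcribed
# verbatim: 13 calibration then 12 validation mixtures, concentrations in
# ug/mL over 3-7 with center 5.
.fcm_concentrations <- function() {
  cal <- matrix(c(
    5, 5, 5,
    3, 3, 7,
    7, 4, 7,
    7, 5, 4,
    4, 4, 6,
    6, 7, 6,
    6, 5, 7,
    7, 7, 3,
    3, 6, 3,
    3, 5, 6,
    6, 6, 4,
    4, 3, 4,
    4, 5, 3
  ), ncol = 3, byrow = TRUE)
  val <- matrix(c(
    5, 3, 3,
    3, 7, 4,
    4, 7, 5,
    5, 4, 4,
    4, 6, 7,
    7, 6, 5,
    5, 7, 7,
    7, 3, 6,
    6, 3, 5,
    5, 6, 6,
    6, 4, 3,
    3, 4, 5
  ), ncol = 3, byrow = TRUE)
  list(cal = cal, val = val)
}

#' Reference mixture design of the FPV/CEF/MFX assay
#'
#' The published five-level, three-factor partial factorial design used to
#' calibrate the simultaneous favipiravir (FPV), cefixime (CEF) and
#' moxifloxacin (MFX) UV assay: 25 mixtures spanning 3--7 ug/mL per analyte
#' around a 5 ug/mL center, split into 13 calibration and 12 validation
#' runs. Shipped as an immutable fixture; every balance and orthogonality
#' property of [multilevel_partial_factorial()] holds for it.
#'
#' @return A `mixture_design` with 25 rows: runs 1--13 labelled
#'   `"calibration"`, runs 14--25 `"validation"`.
#' @examples
#' d <- fcm_design()
#' table(d$role)
#' design_concentrations(d, "calibration")[1, ]  # 5 5 5
#' @export
fcm_design <- function() {
  cm <- .fcm_concentrations()
  conc <- rbind(cm$cal, cm$val)
  mixture_design(
    coded = conc - 5, center = 5, step = 1,
    role = rep(c("calibration", "validation"), c(nrow(cm$cal), nrow(cm$val)))
  )
}

#' Generate a balanced multilevel partial factorial design
#'
#' Constructs a 25-run five-level, three-factor design by a cyclic-difference
#' scheme: with row indices \eqn{(i, j)} running over the 5 x 5 full
#' factorial of the first two factors, the third factor is
#' \eqn{(i + 2j + 1) \bmod 5}. The construction guarantees that each coded
#' level \eqn{\{-2,...,+2\}} appears exactly 5 times in every factor column,
#' that the coded columns are mutually orthogonal (zero cross-products), and
#' that the all-center run is included. Run order is randomized when a seed
#' is given (order carries no information).
#'
#' @param levels Number of levels; only 5 is supported.
#' @param factors Number of factors; only 3 is supported.
#' @param center,step Affine coded-to-concentration map (ug/mL).
#' @param seed Optional seed for run-order shuffling.
#'
#' @return An unsplit `mixture_design` with 25 runs (`role` all `NA`; see
#'   [split_design()]).
#' @export
multilevel_partial_factorial <- function(levels = 5, factors = 3,
                                         center = 5, step = 1, seed = NULL) {
  if (levels != 5 || factors != 3) {
    stop("unsupported design size: only levels = 5, factors = 3 is implemented")
  }
  ij <- expand.grid(i = 0:4, j = 0:4)
  x3 <- (ij$i + 2 * ij$j + 1) %% 5
  coded <- cbind(ij$i, ij$j, x3) - 2
  if (any(center + step * (-2) <= 0)) {
    stop("center/step admit non-positive concentrations at the low level")
  }
  ord <- with_seed(seed, if (is.null(seed)) seq_len(25) else sample(25))
  mixture_design(coded[ord, , drop = FALSE], center = center, step = step)
}

#' Split a design into calibration and validation sets
#'
#' @param design A `mixture_design`.
#' @param n_calibration Number of calibration runs (default 13).
#' @param policy `"reference"` reproduces the shipped reference assignment
#'   (first 13 runs of [fcm_design()] are the calibration set); `"random"`
#'   draws a seeded random split that always keeps the all-center run in the
#'   calibration set.
#' @param seed Seed for the random policy.
#'
#' @return The design with its `role` column filled.
#' @export
split_design <- function(design, n_calibration = 13,
                         policy = c("reference", "random"), seed = NULL) {
  policy <- match.arg(policy)
  n <- nrow(design)
  if (n_calibration >= n) stop("n_calibration must be below the number of runs")
  if (n_calibration < 1) stop("n_calibration must be at least 1")
  coded <- as.matrix(design[, grep("^coded_", names(design)), drop = FALSE])
  if (policy == "reference") {
    ref <- fcm_design()
    if (n != nrow(ref) || n_calibration != 13) {
      stop("the reference split is defined for the 25-run design with 13 calibration runs")
    }
    design$role <- ref$role
  } else {
    center_run <- which(rowSums(coded != 0) == 0)
    cal <- with_seed(seed, {
      pool <- seq_len(n)
      pick <- integer(0)
      if (length(center_run) > 0) {
        pick <- center_run[1]
        pool <- setdiff(pool, pick)
      }
      c(pick, sample(pool, n_calibration - length(pick)))
    })
    design$role <- ifelse(seq_len(n) %in% cal, "calibration", "validation")
  }
  design
}

#' Write / read a mixture design as CSV
#'
#' Columns: `run`, `role`, `coded_*`, `conc_*`; analyte names and the
#' center/step map travel in `#`-prefixed header comments.
#'
#' @param design A `mixture_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns the reconstructed `mixture_design`.
#' @export
write_design_csv <- function(design, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# analytes: %s",
                     paste(attr(design, "analytes"), collapse = ",")), con)
  writeLines(sprintf("# center: %s",
                     paste(attr(design, "center"), collapse = ",")), con)
  writeLines(sprintf("# step: %s",
                     paste(attr(design, "step"), collapse = ",")), con)
  utils::write.csv(as.data.frame(design), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    strsplit(sub(sprintf("^# %s: *", key), "", ln[1]), ",")[[1]]
  }
  df <- utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
  coded <- as.matrix(df[, grep("^coded_", names(df)), drop = FALSE])
  analytes <- meta("analytes")
  if (is.null(analytes)) analytes <- sub("^coded_", "", colnames(coded))
  center <- as.numeric(meta("center"))
  step <- as.numeric(meta("step"))
  d <- mixture_design(coded, center = center, step = step,
                      role = df$role, analytes = analytes)
  d$run <- df$run
  d
}
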