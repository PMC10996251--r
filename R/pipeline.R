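#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the wavelength grid,
#' the synthetic pure spectra and noise model, the mixture design, the
#' latent-variable search, the GA configuration, and the master seed from
#' which all stage seeds are derived.
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it and records it.
#' @param grid A [wavelength_grid()].
#' @param profiles Named list of `pure_spectrum` objects (default
#'   [default_overlap_profiles()]).
#' @param noise A [noise_model()]; its `seed` field is overridden by the
#'   derived stage seed.
#' @param design A split `mixture_design`; default [fcm_design()].
#' @param max_lv Largest latent-variable count examined by [loo_cv()].
#' @param alpha Haaland-Thomas test level.
#' @param run_ga Run the GA wavelength-selection stage?
#' @param ga Template [ga_config()] for the GA stage.
#' @param ga_max_lv Named per-analyte latent-variable caps used inside the
#'   GA fitness (default 2 for FPV, 3 for CEF and MFX).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, grid = wavelength_grid(),
                            profiles = default_overlap_profiles(grid),
                            noise = noise_model(sigma_abs = 0.002),
                            design = fcm_design(), max_lv = 6, alpha = 0.25,
                            run_ga = TRUE, ga = ga_config(),
                            ga_max_lv = c(FPV = 2, CEF = 3, MFX = 3)) {
  if (any(is.na(design$role))) {
    stop("the pipeline design must already be split into calibration/validation")
  }
  structure(
    list(seed = seed, grid = grid, profiles = profiles, noise = noise,
         design = design, max_lv = max_lv, alpha = alpha, run_ga = run_ga,
         ga = ga, ga_max_lv = ga_max_lv),
    class = "pipeline_config"
  )
}

# Stable hash of the configuration for provenance stamping.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::serializeJSON(
    config[setdiff(names(config), "profiles")], digits = 12
  )), tf)
  unname(tools::md5sum(tf))
}

#' Run the full chemometric pipeline
#'
#' Executes, in order: spectra simulation over the design, per-analyte
#' full-spectrum PLS (leave-one-out cross-validation, Haaland-Thomas
#' latent-variable selection, fit, prediction-set validation), optionally
#' GA wavelength selection with a re-selected masked model, and the
#' greenness assessment. All randomness derives from `config$seed`, so a
#' rerun with the same configuration reproduces every number and artifact
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written (design, spectra, CV curves, models, reports, GA results,
#'   greenness, and a manifest embedding seed, config hash and package
#'   version).
#' @return A list of class `pipeline_result` with elements `design`,
#'   `spectra`, `full_pls` and (when enabled) `ga_pls` (per-analyte lists
#'   holding `cv`, `model`, `report` and, for the GA, `ga`), `greenness`,
#'   `seed`, `config_hash`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1, run_ga = FALSE))
#' res$full_pls$FPV$report$validation$mean
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- "setup"
  result <- tryCatch({
    design <- config$design
    analytes <- attr(design, "analytes")
    cfg_hash <- .config_hash(config)

    stage <- "simulate"
    noise <- config$noise
    noise$seed <- config$seed
    spectra <- simulate_mixtures(design, config$profiles, noise)
    cal <- design$role == "calibration"
    Xcal <- spectra[cal, , drop = FALSE]
    Xval <- spectra[!cal, , drop = FALSE]
    Ycal <- design_concentrations(design, "calibration")
    Yval <- design_concentrations(design, "validation")
    noise_sigma <- if (noise$sigma_abs > 0) noise$sigma_abs else NULL

    full_pls <- list()
    ga_pls <- list()
    for (k in seq_along(analytes)) {
      an <- analytes[k]

      stage <- paste0("full-pls:", an)
      cv <- loo_cv(Xcal, Ycal[, an], max_lv = config$max_lv, analyte = an)
      lv <- haaland_thomas_select(cv, alpha = config$alpha)
      model <- .fit_capped(Xcal, Ycal[, an], lv)
      model$analyte <- an
      report <- validation_report(
        model, Ycal[, an], predict(model, Xcal),
        Yval[, an], predict(model, Xval),
        rmsecv = cv$rmsecv[lv], noise_sigma = noise_sigma
      )
      full_pls[[an]] <- list(cv = cv, selected_lv = lv, model = model,
                             report = report)

      if (config$run_ga) {
        stage <- paste0("ga-pls:", an)
        gcfg <- config$ga
        gcfg$max_lv <- if (an %in% names(config$ga_max_lv)) {
          unname(config$ga_max_lv[an])
        } else {
          config$ga$max_lv
        }
        gcfg$seed <- (config$seed + 1000003 * k) %% .Machine$integer.max
        ga <- ga_evolve(Xcal, Ycal[, an], gcfg)
        cv_ga <- loo_cv(Xcal, Ycal[, an], max_lv = gcfg$max_lv,
                        variable_mask = ga$selected_variables, analyte = an)
        lv_ga <- haaland_thomas_select(cv_ga, alpha = config$alpha)
        model_ga <- .fit_capped(Xcal, Ycal[, an], lv_ga,
                                mask = ga$selected_variables)
        model_ga$analyte <- an
        report_ga <- validation_report(
          model_ga, Ycal[, an], predict(model_ga, Xcal),
          Yval[, an], predict(model_ga, Xval),
          rmsecv = cv_ga$rmsecv[lv_ga], noise_sigma = noise_sigma
        )
        ga_pls[[an]] <- list(ga = ga, cv = cv_ga, selected_lv = lv_ga,
                             model = model_ga, report = report_ga)
      }
    }

    stage <- "greenness"
    greenness <- list(
      ecoscale_pharma = ecoscale_score(ecoscale_profile("proposed_pharma")),
      ecoscale_plasma = ecoscale_score(ecoscale_profile("proposed_plasma")),
      gapi_pharma = gapi_summary(gapi_profile("pharma")),
      gapi_plasma = gapi_summary(gapi_profile("plasma"))
    )

    structure(
      list(design = design, spectra = spectra, full_pls = full_pls,
           ga_pls = if (config$run_ga) ga_pls,
           greenness = greenness, seed = config$seed,
           config_hash = cfg_hash,
           package_version = as.character(utils::packageVersion("specalib"))),
      class = "pipeline_result"
    )
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) .write_pipeline_artifacts(result, out_dir)
  result
}

.write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = result$seed, config_hash = result$config_hash,
                package = "specalib", version = result$package_version)
  write_design_csv(result$design, file.path(out_dir, "design.csv"))
  write_spectra_csv(result$spectra, file.path(out_dir, "spectra.csv"))
  for (an in names(result$full_pls)) {
    fp <- result$full_pls[[an]]
    write_cv_csv(fp$cv, file.path(out_dir, sprintf("cv_full_%s.csv", an)))
    model_to_json(fp$model, file.path(out_dir, sprintf("model_full_%s.json", an)),
                  seed = result$seed, timestamp = FALSE)
    report_to_json(fp$report,
                   file.path(out_dir, sprintf("report_full_%s.json", an)))
  }
  for (an in names(result$ga_pls)) {
    gp <- result$ga_pls[[an]]
    ga_result_to_json(gp$ga, file.path(out_dir, sprintf("ga_%s.json", an)))
    model_to_json(gp$model, file.path(out_dir, sprintf("model_ga_%s.json", an)),
                  seed = result$seed, timestamp = FALSE)
    report_to_json(gp$report,
                   file.path(out_dir, sprintf("report_ga_%s.json", an)))
  }
  greenness_to_json(result$greenness$ecoscale_pharma, gapi_profile("pharma"),
                    file.path(out_dir, "greenness_pharma.json"))
  greenness_to_json(result$greenness$ecoscale_plasma, gapi_profile("plasma"),
                    file.path(out_dir, "greenness_plasma.json"))
  writeLines(
    as.character(jsonlite::toJSON(stamp, auto_unbox = TRUE, null = "null")),
    file.path(out_dir, "manifest.json")
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %s, %d analyte(s)%s\n",
              x$seed, length(x$full_pls),
              if (!is.null(x$ga_pls)) ", GA enabled" else ""))
  for (an in names(x$full_pls)) {
    r <- x$full_pls[[an]]$report
    cat(sprintf("  %s: %d LV(s), validation recovery %.2f%% (RSD %.2f%%)\n",
                an, x$full_pls[[an]]$selected_lv,
                r$validation$mean, r$validation$rsd))
  }
  invisible(x)
}
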