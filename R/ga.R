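#' Genetic-algorithm configuration for wavelength selection
#'
#' Defaults follow the optimized GA parameter set used for the FPV/CEF/MFX
#' calibration: population 64, at most 100 generations, per-gene mutation
#' rate 0.005, 20% of wavelength windows switched on at initiation, window
#' width 2 wavelengths, double (two-point) crossover, convergence when 80%
#' of the population matches the best fitness, random cross-validation with
#' 13 subsets and 2 CV iterations per generation, and a per-analyte cap on
#' latent variables (2 for an FPV-like analyte, 3 otherwise).
#'
#' @param population_size Chromosomes per generation (even).
#' @param max_generations Generation cap.
#' @param mutation_rate Per-gene flip probability in (0, 1).
#' @param init_fraction Probability that a window starts switched on.
#' @param window_width Wavelengths per gene window.
#' @param convergence_pct Stop when this percentage of the population is
#'   within `1e-9` of the best fitness.
#' @param crossover Crossover type; `"double"` (two-point) is the only
#'   implemented scheme.
#' @param max_lv Latent-variable cap used inside the fitness.
#' @param cv_subsets Number of cross-validation subsets (13 subsets on 13
#'   calibration samples makes the random CV leave-one-out).
#' @param cv_iterations Random CV repetitions per fitness evaluation.
#' @param elitism Number of elite chromosomes carried over (default 1).
#' @param seed Seed governing the whole GA run.
#'
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 64, max_generations = 100,
                      mutation_rate = 0.005, init_fraction = 0.20,
                      window_width = 2, convergence_pct = 80,
                      crossover = "double", max_lv = 3, cv_subsets = 13,
                      cv_iterations = 2, elitism = 1, seed = NULL) {
  if (population_size < 2 || population_size %% 2 != 0) {
    stop("population_size must be an even number of at least 2")
  }
  if (mutation_rate <= 0 || mutation_rate >= 1) {
    stop("mutation_rate must lie strictly between 0 and 1")
  }
  if (init_fraction <= 0 || init_fraction > 1) {
    stop("init_fraction must lie in (0, 1]")
  }
  if (!identical(crossover, "double")) {
    stop("only 'double' (two-point) crossover is implemented")
  }
  if (convergence_pct <= 0 || convergence_pct > 100) {
    stop("convergence_pct must lie in (0, 100]")
  }
  structure(
    list(population_size = population_size,
         max_generations = max_generations, mutation_rate = mutation_rate,
         init_fraction = init_fraction, window_width = window_width,
         convergence_pct = convergence_pct, crossover = crossover,
         max_lv = max_lv, cv_subsets = cv_subsets,
         cv_iterations = cv_iterations, elitism = elitism, seed = seed),
    class = "ga_config"
  )
}

#' Partition wavelength variables into GA windows
#'
#' Genes operate on consecutive non-overlapping windows of wavelengths
#' rather than single points (a Leardi-style encoding that favours
#' contiguous informative regions). When the variable count is not a
#' multiple of the width, the terminal window is shorter: 201 variables at
#' width 2 give 100 two-point windows plus one final single-point window
#' (101 genes).
#'
#' @param n_variables Number of wavelength variables.
#' @param window_width Window width (>= 1).
#'
#' @return A list with `n_windows`, `assignment` (window index per
#'   variable) and `windows` (list of variable-index vectors).
#' @examples
#' make_windows(201, 2)$n_windows  # 101
#' @export
make_windows <- function(n_variables, window_width = 2) {
  if (window_width < 1) stop("window_width must be at least 1")
  if (n_variables < window_width) {
    stop("n_variables must be at least window_width")
  }
  assignment <- ceiling(seq_len(n_variables) / window_width)
  windows <- split(seq_len(n_variables), assignment)
  list(n_windows = length(windows), assignment = assignment,
       windows = unname(windows))
}

#' Expand a window chromosome to a wavelength mask
#'
#' @param chromosome Logical vector over windows.
#' @param windows A window map from [make_windows()].
#' @return Logical vector over wavelength variables.
#' @export
windows_to_mask <- function(chromosome, windows) {
  if (length(chromosome) != windows$n_windows) {
    stop("chromosome length must equal the number of windows")
  }
  as.logical(chromosome)[windows$assignment]
}

#' Initialize a GA population
#'
#' Each gene is switched on independently with probability
#' `config$init_fraction`; chromosomes that come out all-off are redrawn so
#' every member encodes a usable model.
#'
#' @param n_windows Number of genes.
#' @param config A [ga_config()]; its `seed` (when set) makes the draw
#'   reproducible.
#' @return A logical matrix (population x windows).
#' @export
init_population <- function(n_windows, config = ga_config()) {
  with_seed(config$seed, .draw_population(n_windows, config))
}

.draw_population <- function(n_windows, config) {
  pop <- matrix(
    stats::runif(config$population_size * n_windows) < config$init_fraction,
    nrow = config$population_size
  )
  empty <- rowSums(pop) == 0
  while (any(empty)) {
    pop[empty, ] <- matrix(
      stats::runif(sum(empty) * n_windows) < config$init_fraction,
      nrow = sum(empty)
    )
    empty <- rowSums(pop) == 0
  }
  pop
}

# Worst-possible fitness returned for an empty chromosome: large but finite
# so roulette weighting stays well defined.
.GA_WORST <- 1e6

#' Cross-validated PLS fitness of a chromosome
#'
#' The fitness (an error, lower is better) is the RMSECV of a PLS1 model
#' restricted to the chromosome's wavelengths, at
#' `min(config$max_lv, attainable rank)` latent variables, averaged over
#' `config$cv_iterations` random partitions of the samples into
#' `config$cv_subsets` groups. When the subset count equals the sample count
#' the partition is leave-one-out and every iteration is identical (still
#' executed as configured). An all-off chromosome scores the worst possible
#' value rather than erroring, so the GA can discard it by selection.
#'
#' @param chromosome Logical vector over windows.
#' @param X,y Calibration data.
#' @param config A [ga_config()].
#' @param windows Window map from [make_windows()]; defaults to the map for
#'   `ncol(X)` at the configured width.
#' @return The cross-validated error (ug/mL).
#' @export
ga_fitness <- function(chromosome, X, y, config = ga_config(),
                       windows = make_windows(ncol(X), config$window_width)) {
  if (!any(chromosome)) return(.GA_WORST)
  mask <- windows_to_mask(chromosome, windows)
  .masked_cv_rmse(X, y, mask, config)
}

# Fit at the requested size, falling back to smaller models when the masked
# data cannot support it (rank deficiency); NULL when even 1 LV fails.
# Shared by the GA fitness and loo_cv.
.fit_capped <- function(X, y, n_lv, mask = NULL) {
  for (a in rev(seq_len(n_lv))) {
    m <- tryCatch(fit_pls1(X, y, n_lv = a, variable_mask = mask),
                  error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  NULL
}

.masked_cv_rmse <- function(X, y, mask, config) {
  n <- nrow(X)
  n_lv <- min(config$max_lv, sum(mask), n - 2)
  total <- 0
  for (it in seq_len(config$cv_iterations)) {
    groups <- if (config$cv_subsets >= n) {
      seq_len(n)
    } else {
      sample(rep_len(seq_len(config$cv_subsets), n))
    }
    press <- 0
    for (g in unique(groups)) {
      hold <- groups == g
      a <- min(n_lv, sum(!hold) - 1)
      m <- .fit_capped(X[!hold, , drop = FALSE], y[!hold], a, mask)
      if (is.null(m)) return(.GA_WORST)
      press <- press + sum((y[hold] - predict(m, X[hold, , drop = FALSE]))^2)
    }
    total <- total + sqrt(press / n)
  }
  total / config$cv_iterations
}

#' Run the genetic algorithm for wavelength selection
#'
#' A generational GA over window chromosomes: fitness-proportional
#' (roulette) parent selection on the error scores, two-point ("double")
#' crossover, independent per-gene mutation, and elitism re-inserting the
#' best chromosome ever seen. The run stops at `max_generations` or as soon
#' as at least `convergence_pct`% of the population lies within `1e-9` of
#' the best fitness. The returned mask is the best chromosome ever
#' evaluated, expanded to wavelength variables.
#'
#' @param X Calibration spectral matrix.
#' @param y Calibration concentrations (ug/mL).
#' @param config A [ga_config()]; `config$seed` makes the run fully
#'   deterministic.
#'
#' @return An object of class `ga_result`: `selected_windows`,
#'   `selected_variables`, `n_selected`, `pct_selected`,
#'   `best_fitness_per_generation` (non-increasing under elitism),
#'   `generations_run`, `converged`, `config` and `seed`.
#' @export
ga_evolve <- function(X, y, config = ga_config()) {
  X <- as.matrix(X)
  if (all(apply(X, 2, stats::var) < .Machine$double.eps)) {
    stop("X is degenerate: every wavelength has zero variance")
  }
  windows <- make_windows(ncol(X), config$window_width)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evaluate <- function(chr) {
    if (!any(chr)) return(.GA_WORST)
    key <- paste(which(chr), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- ga_fitness(chr, X, y, config, windows)
    cache[[key]] <- f
    f
  }

  with_seed(config$seed, {
    pop <- .draw_population(windows$n_windows, config)
    fit <- apply(pop, 1, evaluate)
    best_chr <- pop[which.min(fit), ]
    best_fit <- min(fit)
    trajectory <- numeric(0)
    converged <- FALSE
    gen <- 0

    while (gen < config$max_generations) {
      gen <- gen + 1
      trajectory[gen] <- best_fit
      share <- mean(abs(fit - best_fit) <= 1e-9)
      if (share >= config$convergence_pct / 100) {
        converged <- TRUE
        break
      }

      # roulette weights: linear inversion of the error scores
      spread <- max(fit) - min(fit)
      w <- (max(fit) - fit) + 0.05 * spread + 1e-12
      parents <- sample.int(config$population_size, config$population_size,
                            replace = TRUE, prob = w)
      nxt <- pop
      for (i in seq(1, config$population_size, by = 2)) {
        a <- pop[parents[i], ]
        b <- pop[parents[i + 1], ]
        if (windows$n_windows >= 2) {
          cut <- sort(sample.int(windows$n_windows - 1, 2, replace = TRUE))
          seg <- (cut[1] + 1):cut[2]
          if (cut[1] < cut[2]) {
            tmp <- a[seg]
            a[seg] <- b[seg]
            b[seg] <- tmp
          }
        }
        nxt[i, ] <- a
        nxt[i + 1, ] <- b
      }
      flips <- matrix(
        stats::runif(length(nxt)) < config$mutation_rate, nrow = nrow(nxt)
      )
      nxt <- xor(nxt, flips)
      if (config$elitism > 0) nxt[1, ] <- best_chr
      pop <- nxt
      fit <- apply(pop, 1, evaluate)
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_chr <- pop[which.min(fit), ]
      }
    }
    if (!converged) trajectory[gen + 1] <- best_fit

    mask <- windows_to_mask(best_chr, windows)
    structure(
      list(
        selected_windows = as.logical(best_chr),
        selected_variables = mask,
        n_selected = sum(mask),
        pct_selected = 100 * sum(mask) / length(mask),
        best_fitness_per_generation = trajectory,
        generations_run = gen,
        converged = converged,
        config = config,
        seed = config$seed
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d/%d wavelengths selected (%.1f%%), %d generation(s)%s\n",
    x$n_selected, length(x$selected_variables), x$pct_selected,
    x$generations_run, if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' Selection frequency over repeated GA runs
#'
#' Leardi-style aggregation: the GA is run `runs` times with derived seeds
#' and each window's selection frequency across the run-best chromosomes is
#' tabulated; windows selected in at least `threshold` of the runs form the
#' consensus mask. The single-run [ga_evolve()] best chromosome remains the
#' package default for the final model.
#'
#' @inheritParams ga_evolve
#' @param runs Number of independent GA runs.
#' @param threshold Minimum selection frequency (fraction of runs) for a
#'   window to enter the consensus mask.
#' @return A list with `frequency` (per window), `consensus_windows`,
#'   `consensus_variables` and the per-run `results`.
#' @export
ga_selection_frequency <- function(X, y, config = ga_config(), runs = 5,
                                   threshold = 0.5) {
  base_seed <- if (is.null(config$seed)) 0 else config$seed
  results <- lapply(seq_len(runs), function(r) {
    cfg <- config
    cfg$seed <- (base_seed + 7919 * r) %% .Machine$integer.max
    ga_evolve(X, y, cfg)
  })
  freq <- Reduce(`+`, lapply(results, function(r) r$selected_windows)) / runs
  windows <- make_windows(ncol(X), config$window_width)
  consensus <- freq >= threshold
  list(
    frequency = freq,
    consensus_windows = consensus,
    consensus_variables = windows_to_mask(consensus, windows),
    results = results
  )
}

#' Serialize a GA result to JSON
#'
#' @param result A `ga_result`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
ga_result_to_json <- function(result, path = NULL) {
  payload <- list(
    selected_windows = result$selected_windows,
    selected_variables = result$selected_variables,
    n_selected = result$n_selected,
    pct_selected = result$pct_selected,
    best_fitness_per_generation = result$best_fitness_per_generation,
    generations_run = result$generations_run,
    converged = result$converged,
    config = unclass(result$config),
    seed = result$seed,
    metadata = list(
      package = "specalib",
      version = as.character(utils::packageVersion("specalib"))
    )
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
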