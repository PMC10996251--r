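test_that("window maps tile the variable axis with a short terminal window", {
  w <- make_windows(201, 2)
  expect_equal(w$n_windows, 101)
  expect_equal(lengths(w$windows), c(rep(2, 100), 1))
  expect_equal(make_windows(200, 2)$n_windows, 100)
  expect_equal(make_windows(5, 5)$n_windows, 1)
  expect_error(make_windows(10, 0), "at least 1")
  expect_error(make_windows(3, 5), "at least window_width")

  mask <- windows_to_mask(c(TRUE, rep(FALSE, 99), TRUE), w)
  expect_equal(which(mask), c(1, 2, 201))
})

test_that("population initialization honours size, rate, and seed", {
  cfg <- ga_config(seed = 8)
  pop <- init_population(101, cfg)
  expect_equal(dim(pop), c(64, 101))
  expect_true(all(rowSums(pop) > 0))
  p_hat <- mean(pop)
  se <- sqrt(0.2 * 0.8 / length(pop))
  expect_lt(abs(p_hat - 0.2), 3 * se + 1e-12)
  expect_identical(init_population(101, cfg), pop)
})

test_that("invalid GA configurations are rejected", {
  expect_error(ga_config(population_size = 63), "even")
  expect_error(ga_config(mutation_rate = 0), "mutation_rate")
  expect_error(ga_config(init_fraction = 0), "init_fraction")
  expect_error(ga_config(crossover = "single"), "double")
})

test_that("fitness reduces to LOO RMSECV when subsets equal the sample count", {
  blocks <- reference_blocks(noise_model(0.002, seed = 9))
  y <- blocks$Ycal[, "MFX"]
  cfg <- ga_config(max_lv = 3, cv_subsets = 13, cv_iterations = 2)
  w <- make_windows(201, 2)
  chr <- rep(FALSE, 101)
  chr[30:60] <- TRUE
  f <- ga_fitness(chr, blocks$Xcal, y, cfg, w)
  cv <- loo_cv(blocks$Xcal, y, max_lv = 3,
               variable_mask = windows_to_mask(chr, w))
  expect_equal(f, cv$rmsecv[3])
})

test_that("an all-on chromosome on noiseless data scores near zero;
           an empty one scores worst without erroring", {
  blocks <- reference_blocks()
  y <- blocks$Ycal[, "FPV"]
  cfg <- ga_config(max_lv = 3, cv_subsets = 13, cv_iterations = 1)
  w <- make_windows(201, 2)
  expect_lt(ga_fitness(rep(TRUE, 101), blocks$Xcal, y, cfg, w), 1e-6)
  expect_equal(ga_fitness(rep(FALSE, 101), blocks$Xcal, y, cfg, w), 1e6)
})

test_that("adding pure-noise windows does not improve an informative chromosome", {
  better <- 0
  for (s in 1:10) {
    prob <- toy_window_problem(500 + s)
    cfg <- ga_config(max_lv = 4, cv_subsets = 15, cv_iterations = 1)
    w <- make_windows(40, 2)
    informative <- rep(FALSE, 20)
    informative[10:13] <- TRUE
    set.seed(s)
    noisy <- informative
    noisy[sample(which(!informative), 4)] <- TRUE
    f_inf <- ga_fitness(informative, prob$X, prob$y, cfg, w)
    f_noisy <- ga_fitness(noisy, prob$X, prob$y, cfg, w)
    if (f_noisy < f_inf - 1e-3) better <- better + 1
  }
  expect_lte(better, 1)
})

test_that("the GA is deterministic given a seed and respects elitism", {
  prob <- toy_window_problem(77)
  cfg <- ga_config(population_size = 16, max_generations = 10,
                   mutation_rate = 0.02, max_lv = 4, cv_subsets = 15,
                   cv_iterations = 1, seed = 13)
  r1 <- ga_evolve(prob$X, prob$y, cfg)
  r2 <- ga_evolve(prob$X, prob$y, cfg)
  expect_identical(r1$selected_variables, r2$selected_variables)
  expect_identical(r1$best_fitness_per_generation,
                   r2$best_fitness_per_generation)
  expect_true(all(diff(r1$best_fitness_per_generation) <= 1e-12))
  expect_equal(r1$pct_selected, 100 * r1$n_selected / 40)
})

test_that("selection percentages follow the published variable arithmetic", {
  # 66, 50 and 46 of 201 variables correspond to roughly 33%, 25% and 23%
  expect_equal(round(100 * 66 / 201), 33)
  expect_equal(round(100 * 50 / 201), 25)
  expect_equal(round(100 * 46 / 201), 23)
})

test_that("a mutation-free uniform all-on population is a fixed point", {
  blocks <- reference_blocks(noise_model(0.002, seed = 10))
  y <- blocks$Ycal[, "FPV"]
  # mutation_rate must be positive by construction; make it negligible and
  # start from an all-on population via init_fraction = 1
  cfg <- ga_config(population_size = 8, max_generations = 3,
                   mutation_rate = 1e-12, init_fraction = 1, max_lv = 2,
                   cv_subsets = 13, cv_iterations = 1, seed = 2)
  r <- ga_evolve(blocks$Xcal, y, cfg)
  expect_true(all(r$selected_variables))
  expect_true(r$converged)
})

test_that("GA results serialize to JSON with their configuration echo", {
  prob <- toy_window_problem(5)
  cfg <- ga_config(population_size = 8, max_generations = 3, max_lv = 4,
                   cv_subsets = 15, cv_iterations = 1, seed = 1)
  r <- ga_evolve(prob$X, prob$y, cfg)
  js <- jsonlite::fromJSON(ga_result_to_json(r))
  expect_equal(js$n_selected, r$n_selected)
  expect_equal(js$config$population_size, 8)
  expect_equal(js$seed, 1)
})
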