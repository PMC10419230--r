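# Toys are small enough that exhaustive subset search is a usable oracle.

toy_cv <- function(seed = 2) cv_config(5, shuffle_seed = seed,
                                       max_components = 4)

test_that("informative subsets are fitter than random noise subsets", {
  toy <- make_toy_regression(n = 30, p = 10, noise_sd = 0.2, seed = 3)
  cv <- toy_cv()
  f_true <- fitness(toy$x, toy$y, c(3, 7), cv)
  set.seed(8)
  f_rand <- fitness(toy$x, toy$y, sample(c(1, 2, 4, 5, 6), 2), cv)
  expect_lt(f_true, f_rand)
  expect_identical(f_true, fitness(toy$x, toy$y, c(3, 7), cv))
  expect_error(fitness(toy$x, toy$y, integer(0), cv), "at least one")
})

test_that("GA finds the informative variable and keeps its population size", {
  beta <- numeric(10); beta[4] <- 2
  toy <- make_toy_regression(n = 30, p = 10, beta = beta,
                             noise_sd = 0.2, seed = 11)
  cv <- toy_cv()
  cfg <- ga_config(population_size = 20, deletion_group = 4,
                   max_iterations = 25, seed = 13)
  res <- select_ga(toy$x, toy$y, cfg, cv)
  expect_true(4 %in% res$selected_indices)
  # oracle agreement: the exhaustive best subset also contains variable 4
  oracle <- exhaustive_best_rmsecv(toy$x, toy$y, cv)
  expect_true(4 %in% oracle$best_subset)
  expect_length(res$rmsecv_trace, 25)
  expect_true(all(diff(res$rmsecv_trace) <= 1e-12))  # elitist: best never worsens
  res2 <- select_ga(toy$x, toy$y, cfg, cv)
  expect_identical(res2$selected_indices, res$selected_indices)
  expect_identical(res2$rmsecv_trace, res$rmsecv_trace)
})

test_that("SA recovers a two-variable signal found by exhaustive search", {
  toy <- make_toy_regression(n = 30, p = 12, noise_sd = 0.15, seed = 17)
  cv <- toy_cv()
  cfg <- sa_config(window_start_width = 2, window_end_width = 2, seed = 19)
  res <- select_sa(toy$x, toy$y, cfg, cv)
  oracle <- exhaustive_best_rmsecv(toy$x, toy$y, cv, size = 2)
  expect_setequal(res$selected_indices, c(3, 7))
  expect_setequal(oracle$best_subset, c(3, 7))
  # best-so-far bookkeeping: returned energy is the trace minimum
  expect_equal(res$best_rmsecv, min(res$rmsecv_trace))
  expect_lte(res$best_rmsecv, res$rmsecv_trace[1])
  res2 <- select_sa(toy$x, toy$y, cfg, cv)
  expect_identical(res2$selected_indices, res$selected_indices)
  expect_error(
    select_sa(toy$x, toy$y, sa_config(window_end_width = 50), cv),
    "exceeds")
})

test_that("Metropolis rule accepts all improvements and cools correctly", {
  expect_true(metropolis_accept(-1, 5))
  expect_true(metropolis_accept(0, 5))
  # at vanishing temperature, worsening moves are never accepted
  set.seed(1)
  accepts <- replicate(1000, metropolis_accept(0.5, 1e-12))
  expect_equal(sum(accepts), 0)
  # acceptance frequency matches exp(-dE/T) within 3 standard errors
  d_e <- 0.8; temp <- 2
  p_expect <- exp(-d_e / temp)
  set.seed(42)
  acc <- mean(replicate(1e4, metropolis_accept(d_e, temp)))
  se <- sqrt(p_expect * (1 - p_expect) / 1e4)
  expect_lt(abs(acc - p_expect), 3 * se)
})

test_that("ACO concentrates pheromone on the informative variable", {
  beta <- numeric(10); beta[6] <- 2
  toy <- make_toy_regression(n = 30, p = 10, beta = beta,
                             noise_sd = 0.2, seed = 23)
  cv <- toy_cv()
  cfg <- aco_config(population_size = 15, max_cycles = 2,
                    max_iterations = 10, expected_subset_size = 3,
                    seed = 29)
  res <- suppressWarnings(select_aco(toy$x, toy$y, cfg, cv))
  tau <- res$frequency_or_pheromone
  expect_true(all(is.finite(tau)) && all(tau > 0))
  expect_equal(which.max(tau), 6L)
  expect_true(6 %in% res$selected_indices)
  # oracle agreement on the ranking target
  oracle <- exhaustive_best_rmsecv(toy$x, toy$y, cv)
  expect_true(6 %in% oracle$best_subset)
  res2 <- suppressWarnings(select_aco(toy$x, toy$y, cfg, cv))
  expect_identical(res2$selected_indices, res$selected_indices)
})

test_that("CARS follows its exponential-decay retention schedule", {
  p <- 60; n_runs <- 25
  r <- cars_retention_schedule(p, n_runs)
  expect_equal(r[1], 1)                       # all variables live at run 1
  expect_true(all(diff(r) < 0))
  counts <- cars_retention_counts(p, n_runs)
  expect_equal(counts[1], p)                  # all live at run 1
  expect_equal(counts[n_runs], 2L)            # two variables at the last run
  toy <- make_toy_regression(n = 40, p = p, beta = {
    b <- numeric(p); b[c(10, 40)] <- c(2, -1.5); b
  }, noise_sd = 0.2, seed = 31)
  cfg <- cars_config(n_monte_carlo_runs = n_runs, max_components = 5,
                     seed = 37)
  res <- select_cars(toy$x, toy$y, cfg, toy_cv())
  expect_equal(res$schedule_sizes[1], p)
  expect_true(all(diff(res$schedule_sizes) <= 0))
  expect_true(all(diff(res$live_sizes) <= 0))
  expect_true(all(res$selected_indices %in% 1:p))
  expect_true(all(c(10, 40) %in% res$selected_indices))
  res2 <- select_cars(toy$x, toy$y, cfg, toy_cv())
  expect_identical(res2$selected_indices, res$selected_indices)
})

test_that("run_all_selectors shares folds and isolates failures", {
  toy <- make_toy_regression(n = 30, p = 12, noise_sd = 0.2, seed = 41)
  cv <- toy_cv()
  configs <- list(
    ga = ga_config(population_size = 10, deletion_group = 2,
                   max_iterations = 5, seed = 1),
    sa = sa_config(window_start_width = 2, window_end_width = 3, seed = 1),
    aco = aco_config(population_size = 8, max_cycles = 1,
                     max_iterations = 4, expected_subset_size = 3,
                     seed = 1),
    cars = cars_config(n_monte_carlo_runs = 10, max_components = 4,
                       seed = 1))
  res <- suppressWarnings(run_all_selectors(toy$x, toy$y, configs, cv))
  expect_named(res, c("GA", "SA", "ACO", "CARS"))
  for (r in res) {
    expect_s3_class(r, "selection_result")
    expect_true(all(r$selected_indices %in% seq_len(12)))
    expect_gt(length(r$selected_indices), 0)
  }
  # a failing selector (window wider than p) is reported, others proceed
  configs$sa <- sa_config(window_start_width = 50, window_end_width = 50)
  res2 <- suppressWarnings(run_all_selectors(toy$x, toy$y, configs, cv))
  expect_s3_class(res2$SA, "error")
  expect_s3_class(res2$GA, "selection_result")
  expect_s3_class(res2$CARS, "selection_result")
})
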