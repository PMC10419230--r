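# Wrapper variable selection around a shared PLS/RMSECV fitness.
#
# Four metaheuristics -- genetic algorithm (GA), simulated annealing (SA),
# ant colony optimization (ACO) and competitive adaptive reweighted
# sampling (CARS) -- search the flattened feature space for subsets that
# minimise k-fold RMSECV.  All four share one fold assignment (the
# cv_config seed), so fitness values are comparable across algorithms.

#' Subset fitness: cross-validated RMSE
#'
#' The shared objective of all selectors: minimum k-fold RMSECV over the
#' component counts allowed by `cv`.  Lower is fitter.
#'
#' @param features n x p matrix.
#' @param labels Length-n response.
#' @param subset Non-empty column index vector.
#' @param cv A [cv_config()].
#' @return Scalar RMSECV (response units).
#' @export
fitness <- function(features, labels, subset, cv) {
  kfold_rmsecv(features, labels, subset, cv)$best_rmsecv
}

selection_result <- function(algorithm, selected, trace, scores, config,
                             seed, extra = list()) {
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0L) stop("empty selection from ", algorithm)
  structure(
    c(list(algorithm = algorithm, selected_indices = selected,
           rmsecv_trace = trace, frequency_or_pheromone = scores,
           config_used = config, seed = seed),
      extra),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$algorithm, "-",
      length(x$selected_indices), "variables, final RMSECV",
      sprintf("%.4f", min(x$rmsecv_trace, na.rm = TRUE)), "\n")
  invisible(x)
}

# ---------------------------------------------------------------- GA ----

#' Genetic-algorithm configuration
#'
#' Defaults follow the published settings: 30 initial chromosomes, a
#' deletion group of 5 (the five worst chromosomes are replaced by
#' offspring each generation), mutation rate 0.01, crossover probability
#' 0.5, 100 iterations.
#'
#' @param population_size Number of chromosomes (default 30).
#' @param deletion_group Chromosomes replaced per generation (default 5).
#' @param mutation_rate Per-bit flip probability (default 0.01).
#' @param crossover_probability Probability an offspring is produced by
#'   uniform crossover rather than cloning (default 0.5).
#' @param max_iterations Generations (default 100).
#' @param frequency_threshold Final-population inclusion frequency at or
#'   above which a variable is selected (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, deletion_group = 5L,
                      mutation_rate = 0.01, crossover_probability = 0.5,
                      max_iterations = 100L, frequency_threshold = 0.5,
                      seed = 1L) {
  stopifnot(population_size > deletion_group, deletion_group >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_probability >= 0, crossover_probability <= 1,
            frequency_threshold > 0, frequency_threshold <= 1,
            max_iterations >= 1L)
  structure(list(population_size = as.integer(population_size),
                 deletion_group = as.integer(deletion_group),
                 mutation_rate = mutation_rate,
                 crossover_probability = crossover_probability,
                 max_iterations = as.integer(max_iterations),
                 frequency_threshold = frequency_threshold,
                 seed = as.integer(seed)),
            class = "ga_config")
}

repair_chromosome <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Genetic-algorithm variable selection
#'
#' Binary-mask chromosomes over the p features; tournament (size 2) parent
#' choice, uniform crossover, bitwise mutation; each generation the
#' `deletion_group` worst chromosomes are replaced by offspring while the
#' rest survive unchanged (elitist remainder).  After `max_iterations`
#' generations, variables whose inclusion frequency across the final
#' population reaches `frequency_threshold` are returned.
#'
#' @param features n x p matrix.
#' @param labels Length-n response.
#' @param config A [ga_config()].
#' @param cv A [cv_config()] (shared fitness folds).
#' @return A `selection_result`.
#' @export
select_ga <- function(features, labels, config = ga_config(),
                      cv = cv_config()) {
  stopifnot(inherits(config, "ga_config"))
  p <- ncol(features)
  with_seed(config$seed, {
    pop <- matrix(stats::runif(config$population_size * p) < 0.5,
                  config$population_size, p)
    for (i in seq_len(nrow(pop))) pop[i, ] <- repair_chromosome(pop[i, ])
    fit <- apply(pop, 1L, function(m) fitness(features, labels, which(m), cv))
    trace <- numeric(config$max_iterations)
    tournament <- function() {
      cand <- sample.int(config$population_size, 2L)
      cand[which.min(fit[cand])]
    }
    for (gen in seq_len(config$max_iterations)) {
      kids <- matrix(FALSE, config$deletion_group, p)
      for (j in seq_len(config$deletion_group)) {
        p1 <- pop[tournament(), ]
        if (stats::runif(1) < config$crossover_probability) {
          p2 <- pop[tournament(), ]
          pick <- stats::runif(p) < 0.5
          child <- ifelse(pick, p1, p2)
        } else {
          child <- p1
        }
        flip <- stats::runif(p) < config$mutation_rate
        child <- xor(child, flip)
        kids[j, ] <- repair_chromosome(child)
      }
      worst <- order(fit, decreasing = TRUE)[seq_len(config$deletion_group)]
      pop[worst, ] <- kids
      fit[worst] <- apply(kids, 1L,
                          function(m) fitness(features, labels, which(m), cv))
      trace[gen] <- min(fit)
    }
    freq <- colMeans(pop)
    selected <- which(freq >= config$frequency_threshold)
    if (length(selected) == 0L) {
      warning("no variable reached the GA frequency threshold; ",
              "returning the most frequent variables")
      selected <- which(freq == max(freq))
    }
    selection_result("GA", selected, trace, freq, config, config$seed)
  })
}

# ---------------------------------------------------------------- SA ----

#' Simulated-annealing configuration
#'
#' Defaults follow the published settings: initial temperature 10, end
#' temperature 1, Markov chain length 10, cooling coefficient 0.95, window
#' widths 10 to 20 in steps of 1, two points exchanged per move, at most
#' 12 PLS components.
#'
#' @param initial_temperature,end_temperature Annealing schedule bounds.
#' @param markov_chain_length Moves attempted per temperature.
#' @param cooling_coefficient Geometric cooling factor in (0, 1).
#' @param window_start_width,window_end_width,window_step Selected-set
#'   sizes tried: one annealing pass per width.
#' @param swap_count_per_step Selected/unselected indices exchanged per
#'   move.
#' @param max_components PLS component cap for the fitness (default 12).
#' @param seed Integer seed.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(initial_temperature = 10, end_temperature = 1,
                      markov_chain_length = 10L, cooling_coefficient = 0.95,
                      window_start_width = 10L, window_end_width = 20L,
                      window_step = 1L, swap_count_per_step = 2L,
                      max_components = 12L, seed = 1L) {
  stopifnot(cooling_coefficient > 0, cooling_coefficient < 1,
            end_temperature > 0, end_temperature < initial_temperature,
            window_start_width >= 1L,
            window_end_width >= window_start_width,
            window_step >= 1L, markov_chain_length >= 1L,
            swap_count_per_step >= 1L, max_components >= 1L)
  structure(list(initial_temperature = initial_temperature,
                 end_temperature = end_temperature,
                 markov_chain_length = as.integer(markov_chain_length),
                 cooling_coefficient = cooling_coefficient,
                 window_start_width = as.integer(window_start_width),
                 window_end_width = as.integer(window_end_width),
                 window_step = as.integer(window_step),
                 swap_count_per_step = as.integer(swap_count_per_step),
                 max_components = as.integer(max_components),
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Metropolis acceptance rule
#'
#' Accept an energy change `delta_e` at temperature `temperature`:
#' improving or neutral moves always, worsening moves with probability
#' `exp(-delta_e / temperature)`.
#'
#' @param delta_e Energy (RMSECV) change of the proposed move.
#' @param temperature Current annealing temperature (> 0).
#' @return Logical: accept the move.  Consumes one uniform draw for a
#'   worsening move.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (delta_e <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_e / temperature)
}

#' Simulated-annealing variable selection
#'
#' For each window width from `window_start_width` to `window_end_width`,
#' one annealing pass runs: the state is a set of that many selected
#' indices, initialised as a random contiguous window; each move exchanges
#' `swap_count_per_step` selected indices for unselected ones chosen
#' uniformly; moves are accepted by the Metropolis criterion on the RMSECV
#' change while the temperature cools geometrically from
#' `initial_temperature` to `end_temperature`.  The best state ever
#' visited across all widths is returned.
#'
#' @inheritParams select_ga
#' @param config An [sa_config()].
#' @return A `selection_result`.
#' @export
select_sa <- function(features, labels, config = sa_config(),
                      cv = cv_config()) {
  stopifnot(inherits(config, "sa_config"))
  p <- ncol(features)
  if (config$window_end_width > p) {
    stop("window width ", config$window_end_width,
         " exceeds the number of variables (", p, ")")
  }
  cv <- cv_config(cv$n_folds, cv$shuffle_seed,
                  min(cv$max_components, config$max_components))
  widths <- seq(config$window_start_width, config$window_end_width,
                by = config$window_step)
  with_seed(config$seed, {
    best_state <- NULL
    best_e <- Inf
    trace <- numeric(0)
    visits <- numeric(p)
    for (w in widths) {
      start <- sample.int(p - w + 1L, 1L)
      state <- seq.int(start, start + w - 1L)
      e <- fitness(features, labels, state, cv)
      if (e < best_e) { best_e <- e; best_state <- state }
      temp <- config$initial_temperature
      while (temp > config$end_temperature) {
        for (j in seq_len(config$markov_chain_length)) {
          k <- min(config$swap_count_per_step, w, p - w)
          if (k < 1L) break
          out_idx <- sample(state, k)
          pool <- setdiff(seq_len(p), state)
          in_idx <- if (length(pool) == 1L) pool else sample(pool, k)
          cand <- c(setdiff(state, out_idx), in_idx)
          e_cand <- fitness(features, labels, cand, cv)
          if (metropolis_accept(e_cand - e, temp)) {
            state <- cand
            e <- e_cand
          }
          visits[state] <- visits[state] + 1
          if (e < best_e) { best_e <- e; best_state <- state }
        }
        trace <- c(trace, best_e)
        temp <- temp * config$cooling_coefficient
      }
    }
    selection_result("SA", best_state, trace, visits / max(visits, 1),
                     config, config$seed,
                     extra = list(best_rmsecv = best_e))
  })
}

# --------------------------------------------------------------- ACO ----

#' Ant-colony-optimization configuration
#'
#' Defaults follow the published settings: 50 ants, at most 10 cycles of at
#' most 50 iterations each, variable selection probability threshold
#' P = 0.3, significance factor Q = 0.01.  Evaporation rate (0.1) and the
#' expected ant subset size (50) are package defaults.
#'
#' @param population_size Ants per iteration (default 50).
#' @param max_cycles Outer restarts sharing pheromone (default 10).
#' @param max_iterations Iterations per cycle (default 50).
#' @param selection_probability_threshold_P Final inclusion-probability
#'   cut-off for selection (default 0.3).
#' @param significance_factor_Q Pheromone deposit scale: each ant deposits
#'   `Q / RMSECV` on its variables (default 0.01).
#' @param evaporation_rate Fraction of pheromone lost per iteration
#'   (default 0.1).
#' @param expected_subset_size Target mean number of variables per ant
#'   (default 50).
#' @param seed Integer seed.
#' @return A list of class `aco_config`.
#' @export
aco_config <- function(population_size = 50L, max_cycles = 10L,
                       max_iterations = 50L,
                       selection_probability_threshold_P = 0.3,
                       significance_factor_Q = 0.01,
                       evaporation_rate = 0.1,
                       expected_subset_size = 50L, seed = 1L) {
  stopifnot(population_size >= 1L, max_cycles >= 1L, max_iterations >= 1L,
            selection_probability_threshold_P > 0,
            selection_probability_threshold_P < 1,
            significance_factor_Q > 0,
            evaporation_rate > 0, evaporation_rate < 1,
            expected_subset_size >= 1L)
  structure(list(population_size = as.integer(population_size),
                 max_cycles = as.integer(max_cycles),
                 max_iterations = as.integer(max_iterations),
                 selection_probability_threshold_P =
                   selection_probability_threshold_P,
                 significance_factor_Q = significance_factor_Q,
                 evaporation_rate = evaporation_rate,
                 expected_subset_size = as.integer(expected_subset_size),
                 seed = as.integer(seed)),
            class = "aco_config")
}

# per-variable inclusion probability implied by the pheromone field
aco_inclusion_prob <- function(tau, k) {
  pmin(1, k * tau / sum(tau))
}

#' Ant-colony-optimization variable selection
#'
#' Per-variable pheromone starts uniform.  Each iteration, every ant draws
#' a subset by including variable i with probability
#' `min(1, k * tau_i / sum(tau))` (k = `expected_subset_size`), pheromone
#' evaporates by `evaporation_rate`, and each ant deposits
#' `Q / RMSECV(subset)` on its variables.  Cycles restart the iteration
#' loop while keeping pheromone.  Variables whose final inclusion
#' probability reaches `selection_probability_threshold_P` are returned; if
#' none does, the top variables by pheromone (mean ant subset size of them)
#' are returned with a warning.
#'
#' @inheritParams select_ga
#' @param config An [aco_config()].
#' @return A `selection_result`.
#' @export
select_aco <- function(features, labels, config = aco_config(),
                       cv = cv_config()) {
  stopifnot(inherits(config, "aco_config"))
  p <- ncol(features)
  with_seed(config$seed, {
    tau <- rep(1, p)
    trace <- numeric(0)
    subset_sizes <- numeric(0)
    for (cycle in seq_len(config$max_cycles)) {
      for (iter in seq_len(config$max_iterations)) {
        prob <- aco_inclusion_prob(tau, config$expected_subset_size)
        ants <- vector("list", config$population_size)
        e_ants <- numeric(config$population_size)
        for (a in seq_len(config$population_size)) {
          sel <- which(stats::runif(p) < prob)
          if (length(sel) == 0L) {
            sel <- sample.int(p, 1L, prob = tau)
          }
          ants[[a]] <- sel
          e_ants[a] <- fitness(features, labels, sel, cv)
        }
        tau <- (1 - config$evaporation_rate) * tau
        for (a in seq_len(config$population_size)) {
          tau[ants[[a]]] <- tau[ants[[a]]] +
            config$significance_factor_Q / e_ants[a]
        }
        trace <- c(trace, min(e_ants))
        subset_sizes <- c(subset_sizes, mean(lengths(ants)))
      }
    }
    prob <- aco_inclusion_prob(tau, config$expected_subset_size)
    selected <- which(prob >= config$selection_probability_threshold_P)
    if (length(selected) == 0L) {
      k <- max(1L, round(mean(subset_sizes)))
      warning("no variable reached the ACO selection probability ",
              "threshold; returning the top ", k, " by pheromone")
      selected <- order(tau, decreasing = TRUE)[seq_len(k)]
    }
    selection_result("ACO", selected, trace, tau, config, config$seed)
  })
}

# -------------------------------------------------------------- CARS ----

#' CARS configuration
#'
#' Defaults follow the published settings: at most 15 PLS components,
#' 5-fold cross-validation, 2000 Monte Carlo sampling runs.  The per-run
#' calibration fraction (0.8) is a package default.
#'
#' @param max_components PLS component cap (default 15).
#' @param n_folds Cross-validation folds for the per-run RMSECV record
#'   (default 5).
#' @param n_monte_carlo_runs Number of sampling runs N (default 2000).
#' @param calibration_fraction_per_run Fraction of samples drawn for each
#'   run's model fit (default 0.8).
#' @param seed Integer seed.
#' @return A list of class `cars_config`.
#' @export
cars_config <- function(max_components = 15L, n_folds = 5L,
                        n_monte_carlo_runs = 2000L,
                        calibration_fraction_per_run = 0.8, seed = 1L) {
  stopifnot(n_monte_carlo_runs >= 2L, n_folds >= 2L, max_components >= 1L,
            calibration_fraction_per_run > 0,
            calibration_fraction_per_run < 1)
  structure(list(max_components = as.integer(max_components),
                 n_folds = as.integer(n_folds),
                 n_monte_carlo_runs = as.integer(n_monte_carlo_runs),
                 calibration_fraction_per_run = calibration_fraction_per_run,
                 seed = as.integer(seed)),
            class = "cars_config")
}

#' CARS exponential-decay retention schedule
#'
#' Retention ratio `r_i = a * exp(-k * i)` with boundary conditions
#' `r_1 = 1` (all p variables live at run 1) and `r_N = 2/p` (two variables
#' at the last run), i.e. `a = (p/2)^(1/(N-1))`, `k = log(p/2) / (N-1)`.
#'
#' @param p Number of variables.
#' @param n_runs Number of Monte Carlo runs N.
#' @return Numeric vector of length `n_runs`: the retention ratio per run.
#' @export
cars_retention_schedule <- function(p, n_runs) {
  stopifnot(p >= 2L, n_runs >= 2L)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  # a * exp(-k * i), evaluated in log form so r_1 is exactly 1
  exp((1 - seq_len(n_runs)) * k)
}

#' Forced live-set sizes of the CARS schedule
#'
#' `ceiling(r_i * p)` per run, evaluated with a tolerance for the
#' floating-point representation of the decay ratios, so the boundary
#' conditions give exactly `p` variables at run 1 and 2 at run `n_runs`.
#'
#' @inheritParams cars_retention_schedule
#' @return Integer vector of length `n_runs`.
#' @export
cars_retention_counts <- function(p, n_runs) {
  as.integer(ceiling(cars_retention_schedule(p, n_runs) * p - 1e-9))
}

#' Competitive adaptive reweighted sampling
#'
#' At run i, a PLS model (components chosen by RMSECV, capped at
#' `max_components`) is fitted on a Monte Carlo subsample of the rows using
#' the currently live variables; the exponential-decay schedule
#' ([cars_retention_schedule()]) forces the live set down to
#' `ceiling(r_i * p)` variables of largest absolute (autoscaled)
#' regression coefficient, and adaptive reweighted sampling (weighted
#' resampling by |coefficient|) picks the run's live set.  Each run's set is
#' scored by `n_folds` RMSECV on all rows; the best-scoring set over all
#' runs is returned.
#'
#' @inheritParams select_ga
#' @param config A [cars_config()].
#' @return A `selection_result` with extra fields `schedule_sizes`
#'   (forced live-set size per run) and `live_sizes` (after resampling).
#' @export
select_cars <- function(features, labels, config = cars_config(),
                        cv = cv_config()) {
  stopifnot(inherits(config, "cars_config"))
  x <- as.matrix(features)
  p <- ncol(x)
  n <- nrow(x)
  n_runs <- config$n_monte_carlo_runs
  counts <- cars_retention_counts(p, n_runs)
  cv_run <- cv_config(config$n_folds, cv$shuffle_seed,
                      config$max_components)
  with_seed(config$seed, {
    live <- seq_len(p)
    run_sets <- vector("list", n_runs)
    run_rmsecv <- rep(NA_real_, n_runs)
    schedule_sizes <- integer(0)
    live_sizes <- integer(0)
    live_count <- integer(p)
    for (i in seq_len(n_runs)) {
      n_sub <- max(round(config$calibration_fraction_per_run * n), 4L)
      rows <- sample.int(n, n_sub)
      sub_cv <- cv_config(config$n_folds, cv$shuffle_seed,
                          config$max_components)
      ncomp <- tryCatch(
        kfold_rmsecv(x[rows, , drop = FALSE], labels[rows], live,
                     sub_cv)$best_components,
        error = function(e) 1L)
      ncomp <- min(ncomp, n_sub - 1L, length(live))
      fitm <- fit_pls(x[rows, live, drop = FALSE], labels[rows], ncomp,
                      feature_indices = live)
      # coefficient magnitudes on the autoscaled scale: comparable across
      # channels with different units
      wt <- abs(fitm$coefficients * fitm$scale)
      keep_n <- min(counts[i], length(live))
      if (keep_n < 2L) break
      ord <- order(wt, decreasing = TRUE)
      forced <- live[ord[seq_len(keep_n)]]
      forced_wt <- wt[ord[seq_len(keep_n)]]
      schedule_sizes <- c(schedule_sizes, keep_n)
      if (all(forced_wt == 0)) forced_wt <- rep(1, keep_n)
      draw <- sample(forced, size = keep_n, replace = TRUE,
                     prob = forced_wt)
      live <- sort(unique(draw))
      if (length(live) < 2L) break
      live_sizes <- c(live_sizes, length(live))
      live_count[live] <- live_count[live] + 1L
      run_sets[[i]] <- live
      run_rmsecv[i] <- fitness(x, labels, live, cv_run)
    }
    valid <- which(!is.na(run_rmsecv))
    if (length(valid) == 0L) stop("CARS produced no valid run")
    best <- valid[which.min(run_rmsecv[valid])]
    selection_result("CARS", run_sets[[best]], run_rmsecv, live_count,
                     config, config$seed,
                     extra = list(schedule_sizes = schedule_sizes,
                                  live_sizes = live_sizes,
                                  best_run = best))
  })
}

# --------------------------------------------------------------- all ----

#' Run all four selectors on one dataset
#'
#' GA, SA, ACO and CARS run with a shared [cv_config()] (identical folds),
#' each under its own config and seed.  A failure in one algorithm is
#' captured and reported without aborting the others.
#'
#' @inheritParams select_ga
#' @param configs Named list with elements `ga`, `sa`, `aco`, `cars`
#'   (defaults: the published parameter settings).
#' @return Named list of `selection_result` objects (or `try-error`s for
#'   algorithms that failed).
#' @export
run_all_selectors <- function(features, labels,
                              configs = list(ga = ga_config(),
                                             sa = sa_config(),
                                             aco = aco_config(),
                                             cars = cars_config()),
                              cv = cv_config()) {
  runners <- list(GA = function() select_ga(features, labels, configs$ga, cv),
                  SA = function() select_sa(features, labels, configs$sa, cv),
                  ACO = function() select_aco(features, labels, configs$aco,
                                              cv),
                  CARS = function() select_cars(features, labels,
                                                configs$cars, cv))
  lapply(runners, function(f) tryCatch(f(), error = function(e) e))
}
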