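# shared fixtures, all built in code

# small regression toy: y = x %*% beta + noise, gaussian features
make_toy_regression <- function(n = 30, p = 10, beta = NULL,
                                noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) {
    beta <- numeric(p)
    beta[3] <- 1.5
    if (p >= 7) beta[7] <- -2
  }
  y <- as.vector(x %*% beta) + rnorm(n, 0, noise_sd)
  list(x = x, y = y, beta = beta)
}

# full-scale simulation config with an embedded 10-index sparse signal
# (the parameter-recovery study conditions: 72 samples x 3000 features,
# label noise sd 0.3)
embedded_config <- function(seed, n_informative = 10, label_noise_sd = 0.3) {
  base <- warehouse_sim_config(seed = seed)
  sig <- default_embedded_signal(base, n_informative)
  warehouse_sim_config(
    seed = seed, embed_signal = TRUE,
    informative_indices = sig$informative_indices,
    informative_coefficients = sig$informative_coefficients,
    label_intercept = sig$label_intercept,
    label_noise_sd = label_noise_sd
  )
}

# reduced selector settings used for desk-scale selector comparisons
test_scale_configs <- function(seed) {
  list(ga = ga_config(max_iterations = 15L, seed = seed),
       sa = sa_config(window_start_width = 10L, window_end_width = 12L,
                      seed = seed),
       aco = aco_config(population_size = 20L, max_cycles = 2L,
                        max_iterations = 5L, seed = seed),
       cars = cars_config(n_monte_carlo_runs = 50L, seed = seed))
}

# exhaustive best-subset oracle on the shared RMSECV fitness; `size = NULL`
# scans every non-empty subset, otherwise only subsets of that size
exhaustive_best_rmsecv <- function(x, y, cv, size = NULL) {
  p <- ncol(x)
  subsets <- if (is.null(size)) {
    lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  } else {
    utils::combn(p, size, simplify = FALSE)
  }
  vals <- vapply(subsets, function(s) fitness(x, y, s, cv), numeric(1))
  best <- which.min(vals)
  list(best_rmsecv = vals[best], best_subset = subsets[[best]])
}

# a noiseless acquisition config (instant plateau, zero sensor noise)
noiseless_config <- function(...) {
  warehouse_sim_config(rise_time_constant = 0, noise_sd = 0, ...)
}
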