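REF_COEF <- c(0.3264, 0.3708, 0.0248, 0.0363, -0.0008, -0.0005, -0.0014,
              0.4734, 0.3338, 0.0248, -0.0136, -0.0118, -0.0132, 0.3407,
              -1.9581, 0.3719, 0.5173, -1.9010, 0.0013, -0.0009)
REF_IDX <- c(228, 309, 622, 726, 1064, 1126, 1188, 1526, 1538, 1861, 1889,
             1894, 1974, 2001, 2159, 2163, 2274, 2561, 2758, 2965)

test_that("the reference model carries the published 41 numbers", {
  m <- paper_reference_model()
  expect_length(m$variable_indices, 20)
  expect_length(m$coefficients, 20)
  expect_identical(m$variable_indices, as.integer(REF_IDX))
  expect_identical(m$coefficients, REF_COEF)
  expect_identical(m$intercept, 38.9899)
})

test_that("reference indices partition across channels as published", {
  m <- paper_reference_model()
  attribution <- index_to_channel(m$variable_indices)
  counts <- table(attribution$channel)
  expect_equal(counts[["Temperature"]], 2L)
  expect_equal(counts[["Humidity"]], 2L)
  expect_equal(counts[["CO2"]], 3L)
  expect_equal(counts[["C2H4"]], 6L)
  expect_equal(counts[["O2"]], 4L)
  expect_equal(counts[["VOC"]], 3L)
  eth <- attribution$index[attribution$channel == "C2H4"]
  expect_equal(max(eth), 1974)
})

test_that("scoring is the sparse linear combination", {
  m <- paper_reference_model()
  expect_equal(score_sample(m, numeric(3000)), 38.9899)
  x <- numeric(3000); x[228] <- 1
  expect_equal(score_sample(m, x), 38.9899 + 0.3264)
  # linearity: score(a x) - score(0) = a (score(x) - score(0))
  set.seed(6)
  xr <- rnorm(3000)
  s0 <- score_sample(m, numeric(3000))
  expect_equal(score_sample(m, 2.5 * xr) - s0,
               2.5 * (score_sample(m, xr) - s0), tolerance = 1e-10)
  expect_error(score_sample(m, numeric(100)), "does not cover")
  named <- stats::setNames(rep(1, 20), as.character(REF_IDX))
  expect_equal(score_sample(m, named), 38.9899 + sum(REF_COEF))
  expect_error(score_sample(m, named[-1]), "missing")
})

test_that("grade bands follow the published ranges with midpoint edges", {
  m <- paper_reference_model()
  g <- grade_score(m, c(1.5, 3.2, 5.5, 7.5))
  expect_equal(g$grade, c("fresh", "mild spoilage", "medium spoilage",
                          "severe spoilage"))
  expect_true(all(g$in_range))
  out <- grade_score(m, c(0.2, 38.99))
  expect_equal(out$grade, c("fresh", "severe spoilage"))
  expect_false(any(out$in_range))
  # monotone: higher score never yields a less severe band
  ys <- seq(-2, 12, by = 0.1)
  sev <- match(grade_score(m, ys)$grade, default_grade_bands()$label)
  expect_true(all(diff(sev) >= 0))
  expect_error(grade_score(m, c(1, NA)), "finite")
  expect_error(grade_score(m, Inf), "finite")
})

test_that("refitting on the true indices recovers an embedded signal", {
  base <- warehouse_sim_config(seed = 47)
  sig <- default_embedded_signal(base, 8)
  cfg <- warehouse_sim_config(
    seed = 47, embed_signal = TRUE,
    informative_indices = sig$informative_indices,
    informative_coefficients = sig$informative_coefficients,
    label_intercept = sig$label_intercept, label_noise_sd = 0)
  sim <- simulate_dataset(cfg)
  wm <- build_warning_model(sim$dataset, sig$informative_indices,
                            cv_config(5, 3, 10))
  expect_length(wm$coefficients, 8)
  expect_equal(wm$coefficients, sig$informative_coefficients,
               tolerance = 1e-6)
  expect_equal(wm$intercept, sig$label_intercept, tolerance = 1e-6)
  expect_error(build_warning_model(sim$dataset, 5000, cv_config()),
               "absent")
})

test_that("provenance records the selecting algorithm and seed", {
  toy <- make_toy_regression(n = 30, p = 12, noise_sd = 0.2, seed = 53)
  cv <- cv_config(5, 2, 4)
  sel <- select_sa(toy$x, toy$y,
                   sa_config(window_start_width = 2, window_end_width = 2,
                             seed = 59), cv)
  ds <- sensor_dataset(toy$x, day = rep(1:6, 5), label = toy$y)
  wm <- build_warning_model(ds, sel, cv)
  expect_match(wm$provenance, "SA-PLS")
  expect_match(wm$provenance, "59")
  expect_length(wm$coefficients, length(sel$selected_indices))
})

test_that("model JSON round trips exactly and rejects tampering", {
  m <- paper_reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  export_model(m, path)
  back <- import_model(path)
  expect_identical(back$variable_indices, m$variable_indices)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  expect_equal(back$grade_bands$label, m$grade_bands$label)
  expect_equal(score_sample(back, numeric(3000)), 38.9899)
  # tamper: drop one coefficient
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$coefficients <- doc$coefficients[-1]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(import_model(bad), "19 indices|malformed|19")
  expect_error(warning_model(1:3, 1:2, 0), "equal length")
})

test_that("the equation rendering lists coefficients in term order", {
  m <- paper_reference_model()
  eq <- render_model_equation(m)
  expect_match(eq, "^Y = 0.3264 X1 ", fixed = FALSE)
  expect_match(eq, "38.9899$")
  # every printed coefficient magnitude appears, in order
  pos <- vapply(sprintf("%.4f", abs(REF_COEF)), function(s) {
    regexpr(s, eq, fixed = TRUE)[1]
  }, numeric(1))
  expect_true(all(diff(pos[!duplicated(pos)]) > 0))
  expect_true(all(pos > 0))
})
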