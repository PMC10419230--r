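# Partial least squares regression (single response, NIPALS with
# deflation), k-fold cross-validation, calibration/prediction splitting and
# the four evaluation statistics (Rc, RMSEC, Rp, RMSEP) plus RMSECV.
#
# Features and response are autoscaled (mean-centred, unit variance)
# internally -- the six channels carry incommensurate units (degC, %rh,
# ppm, %VOL) -- and coefficients are folded back to the original scale, so
# a fitted model is just an affine map on raw sensor values.

#' Fit a PLS regression model
#'
#' Single-response NIPALS: each component's weight vector is the (normalised)
#' covariance between the deflated predictors and response; scores, loadings
#' and deflation follow, and the final regression coefficients
#' `W (P'W)^{-1} q` are rescaled to the original units.
#'
#' @param features Numeric matrix, n x p (no missing values).
#' @param labels Numeric response, length n, non-constant.
#' @param n_components Number of latent components, in
#'   `1..min(n - 1, p)`. If the predictor matrix runs out of rank earlier,
#'   the fit stops at the last usable component.
#' @param feature_indices Optional integer vector recording which flattened
#'   indices the columns of `features` correspond to (stored for
#'   bookkeeping; defaults to `1:p`).
#' @return An object of class `pls_model` with elements `coefficients`
#'   (original scale, per column), `intercept`, `n_components` (used),
#'   `center`, `scale`, `feature_indices`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- 3 * x[, 1] - x[, 2] + 1
#' m <- fit_pls(x, y, n_components = 2)
#' max(abs(predict(m, x) - y)) < 1e-8
#' @export
fit_pls <- function(features, labels, n_components,
                    feature_indices = seq_len(ncol(features))) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(x); p <- ncol(x)
  if (n != length(y)) stop("features and labels disagree on n")
  if (n < 2L) stop("PLS needs at least two samples")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(y) == 0) stop("labels are constant; nothing to regress on")
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L ||
      n_components > min(n - 1L, p)) {
    stop("n_components must lie in 1..min(n - 1, p) = 1..", min(n - 1L, p))
  }
  xm <- colMeans(x)
  xs <- apply(x, 2L, stats::sd)
  xs[xs == 0] <- 1
  ym <- mean(y); ys <- stats::sd(y)
  e <- sweep(sweep(x, 2L, xm), 2L, xs, "/")
  f <- (y - ym) / ys

  a_max <- n_components
  w_mat <- matrix(0, p, a_max)
  p_mat <- matrix(0, p, a_max)
  q_vec <- numeric(a_max)
  used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(e, f)                 # p x 1 covariance direction
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                # rank exhausted
    w <- w / wn
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(e, t_sc) / tt
    q <- sum(f * t_sc) / tt
    e <- e - tcrossprod(t_sc, p_load)
    f <- f - as.vector(t_sc) * q
    w_mat[, a] <- w; p_mat[, a] <- p_load; q_vec[a] <- q
    used <- a
  }
  if (used == 0L) stop("no usable PLS component; predictors are degenerate")
  w_u <- w_mat[, seq_len(used), drop = FALSE]
  p_u <- p_mat[, seq_len(used), drop = FALSE]
  b_scaled <- w_u %*% solve(crossprod(p_u, w_u), q_vec[seq_len(used)])
  coef <- ys * as.vector(b_scaled) / xs
  intercept <- ym - sum(coef * xm)
  structure(
    list(coefficients = coef, intercept = intercept,
         n_components = used, center = xm, scale = xs,
         feature_indices = as.integer(feature_indices)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", length(x$coefficients), "features,",
      x$n_components, "components\n")
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Numeric matrix with the model's feature columns (n x p).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$coefficients)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$coefficients))
  }
  as.vector(x %*% object$coefficients) + object$intercept
}

#' Pearson correlation between reference and predicted values
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return Scalar correlation in \[-1, 1\].
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("correlation needs at least two points")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(y_true, y_pred)
}

#' Root mean square error
#'
#' Divisor n (not n - 1), the convention used for RMSEC/RMSEP/RMSECV.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Non-negative scalar in response units.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 5).
#' @param shuffle_seed Seed for the fold assignment.
#' @param max_components Upper bound on PLS components scanned (default 10).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, shuffle_seed = 1L, max_components = 10L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  structure(list(n_folds = n_folds, shuffle_seed = as.integer(shuffle_seed),
                 max_components = as.integer(max_components)),
            class = "cv_config")
}

# seeded fold assignment: shuffle then deal round-robin
fold_assignment <- function(n, cv) {
  if (cv$n_folds > n) stop("n_folds (", cv$n_folds, ") exceeds samples (",
                           n, ")")
  with_seed(cv$shuffle_seed, {
    perm <- sample.int(n)
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(cv$n_folds), n)
    folds
  })
}

#' K-fold RMSECV over a feature subset
#'
#' For each component count up to `cv$max_components` (bounded by fold size
#' and subset width), fits PLS on the training folds, pools the out-of-fold
#' predictions, and reports the pooled RMSE.  Fold assignment is seeded by
#' `cv$shuffle_seed`, so every selector evaluating subsets under the same
#' `cv_config` sees identical folds.
#'
#' @param features n x p matrix.
#' @param labels Length-n response.
#' @param subset Column indices into `features` (at least one).
#' @param cv A [cv_config()].
#' @return A list: `rmsecv` (named by component count), `best_components`,
#'   `best_rmsecv`, `folds`.
#' @export
kfold_rmsecv <- function(features, labels, subset, cv) {
  stopifnot(inherits(cv, "cv_config"))
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must contain at least one variable")
  x <- as.matrix(features)[, subset, drop = FALSE]
  y <- as.numeric(labels)
  n <- nrow(x)
  folds <- fold_assignment(n, cv)
  min_train <- n - max(tabulate(folds, cv$n_folds))
  a_max <- min(cv$max_components, min_train - 1L, ncol(x))
  a_max <- max(a_max, 1L)
  preds <- matrix(NA_real_, n, a_max)
  for (k in seq_len(cv$n_folds)) {
    tr <- folds != k
    # fit once with the largest component count; per-component predictions
    # come from truncating the same NIPALS sequence
    fits <- pls_component_path(x[tr, , drop = FALSE], y[tr], a_max)
    xte <- x[!tr, , drop = FALSE]
    for (a in seq_len(length(fits))) {
      preds[!tr, a] <- as.vector(xte %*% fits[[a]]$coef) + fits[[a]]$intercept
    }
    if (length(fits) < a_max) {
      for (a in seq.int(length(fits) + 1L, a_max)) {
        preds[!tr, a] <- preds[!tr, length(fits)]
      }
    }
  }
  rmsecv <- apply(preds, 2L, function(yp) rmse(y, yp))
  names(rmsecv) <- seq_len(a_max)
  best <- which.min(rmsecv)
  list(rmsecv = rmsecv, best_components = as.integer(best),
       best_rmsecv = unname(rmsecv[best]), folds = folds)
}

# internal: NIPALS path giving original-scale (coef, intercept) for each
# component count 1..a_max (truncations of one deflation sequence)
pls_component_path <- function(x, y, a_max) {
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x)
  xs <- apply(x, 2L, stats::sd); xs[xs == 0] <- 1
  ym <- mean(y); ys <- stats::sd(y)
  if (ys == 0) {  # constant training labels: constant predictor
    return(list(list(coef = numeric(p), intercept = ym)))
  }
  e <- sweep(sweep(x, 2L, xm), 2L, xs, "/")
  f <- (y - ym) / ys
  a_max <- min(a_max, n - 1L, p)
  w_mat <- matrix(0, p, a_max); p_mat <- matrix(0, p, a_max)
  q_vec <- numeric(a_max)
  out <- vector("list", 0L)
  for (a in seq_len(a_max)) {
    w <- crossprod(e, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(e, t_sc) / tt
    q <- sum(f * t_sc) / tt
    e <- e - tcrossprod(t_sc, p_load)
    f <- f - as.vector(t_sc) * q
    w_mat[, a] <- w; p_mat[, a] <- p_load; q_vec[a] <- q
    w_u <- w_mat[, seq_len(a), drop = FALSE]
    p_u <- p_mat[, seq_len(a), drop = FALSE]
    b <- try(w_u %*% solve(crossprod(p_u, w_u), q_vec[seq_len(a)]),
             silent = TRUE)
    if (inherits(b, "try-error")) break
    coef <- ys * as.vector(b) / xs
    out[[a]] <- list(coef = coef, intercept = ym - sum(coef * xm))
  }
  if (length(out) == 0L) out <- list(list(coef = numeric(p), intercept = ym))
  out
}

#' Split a dataset into calibration and prediction sets
#'
#' Stratified by day label: within each day the samples are shuffled
#' (seeded) and split so each day contributes proportionally to both sets.
#'
#' @param dataset A [sensor_dataset()].
#' @param ratio Calibration fraction in (0, 1) (default 2/3).
#' @param seed Seed for the within-day shuffles.
#' @return The dataset with its `split` field populated.
#' @export
split_calibration_prediction <- function(dataset, ratio = 2 / 3, seed = 1L) {
  stopifnot(inherits(dataset, "sensor_dataset"))
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1")
  }
  n <- nrow(dataset$features)
  split <- rep(NA_character_, n)
  with_seed(seed, {
    for (d in sort(unique(dataset$day))) {
      rows <- which(dataset$day == d)
      if (length(rows) < 2L) {
        stop("day ", d, " has fewer than 2 samples; cannot stratify")
      }
      rows <- rows[sample.int(length(rows))]
      n_cal <- round(ratio * length(rows))
      n_cal <- min(max(n_cal, 1L), length(rows) - 1L)
      split[rows[seq_len(n_cal)]] <- "calibration"
      split[rows[-seq_len(n_cal)]] <- "prediction"
    }
  })
  dataset$split <- split
  dataset
}

#' Evaluate a linear model on a split dataset
#'
#' Computes Rc/RMSEC on the calibration rows and Rp/RMSEP on the prediction
#' rows.
#'
#' @param model A `pls_model` or [warning_model()] (anything with
#'   `coefficients`/`intercept` over `feature_indices`, or a full-width
#'   `pls_model`).
#' @param dataset A [sensor_dataset()] with both split tags present.
#' @return A list of class `evaluation_report`: `r_calibration`,
#'   `rmse_calibration`, `r_prediction`, `rmse_prediction`.
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(inherits(dataset, "sensor_dataset"))
  cal <- which(!is.na(dataset$split) & dataset$split == "calibration")
  pre <- which(!is.na(dataset$split) & dataset$split == "prediction")
  if (length(cal) == 0L || length(pre) == 0L) {
    stop("dataset must contain both calibration and prediction rows")
  }
  pred_rows <- function(rows) {
    x <- dataset$features[rows, , drop = FALSE]
    if (inherits(model, "warning_model")) {
      apply(x, 1L, function(v) score_sample(model, v))
    } else if (inherits(model, "pls_model")) {
      predict(model, x[, model$feature_indices, drop = FALSE])
    } else {
      stop("unsupported model class: ", paste(class(model), collapse = "/"))
    }
  }
  y_cal <- dataset$label[cal]; p_cal <- pred_rows(cal)
  y_pre <- dataset$label[pre]; p_pre <- pred_rows(pre)
  structure(
    list(r_calibration = pearson_r(y_cal, p_cal),
         rmse_calibration = rmse(y_cal, p_cal),
         r_prediction = pearson_r(y_pre, p_pre),
         rmse_prediction = rmse(y_pre, p_pre)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Rc = %.3f  RMSEC = %.3f  Rp = %.3f  RMSEP = %.3f\n",
              x$r_calibration, x$rmse_calibration,
              x$r_prediction, x$rmse_prediction))
  invisible(x)
}
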