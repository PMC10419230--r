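# The sparse linear early-warning model: construction from a selection
# result, the published 20-term reference model, scoring, spoilage
# grading, and JSON serialization.
#
# A warning model scores a flattened acquisition as
#   Y = intercept + sum(coefficients * x[variable_indices])
# and interprets Y through ordered grade bands: fresh (1-2), mild spoilage
# (3-4), medium spoilage (5-6), severe spoilage (7-8).  The published
# ranges leave gaps (2-3, 4-5, 6-7); bands use midpoint boundaries so that
# every finite score is classifiable, and scores outside [1, 8] are
# assigned the nearest band with an out-of-range flag.

#' Default spoilage grade bands
#'
#' @return A data.frame with columns `label`, `lower`, `upper` (half-open
#'   band boundaries, outermost bands unbounded) and `printed_range` (the
#'   published integer range each band interprets).
#' @export
default_grade_bands <- function() {
  data.frame(
    label = c("fresh", "mild spoilage", "medium spoilage",
              "severe spoilage"),
    lower = c(-Inf, 2.5, 4.5, 6.5),
    upper = c(2.5, 4.5, 6.5, Inf),
    printed_range = c("1-2", "3-4", "5-6", "7-8"),
    stringsAsFactors = FALSE
  )
}

#' Construct a warning model
#'
#' @param variable_indices Distinct flattened indices in 1..3000.
#' @param coefficients Matching weights (response units per channel unit).
#' @param intercept Model constant (response units).
#' @param grade_bands Band table as in [default_grade_bands()].
#' @param provenance Free-text origin note (e.g. `"SA-PLS refit, seed 1"`).
#' @return An object of class `warning_model`.
#' @export
warning_model <- function(variable_indices, coefficients, intercept,
                          grade_bands = default_grade_bands(),
                          provenance = "") {
  variable_indices <- as.integer(variable_indices)
  coefficients <- as.numeric(coefficients)
  if (length(variable_indices) != length(coefficients)) {
    stop("variable_indices (", length(variable_indices),
         ") and coefficients (", length(coefficients),
         ") must have equal length")
  }
  if (anyDuplicated(variable_indices) || any(variable_indices < 1L)) {
    stop("variable_indices must be distinct positive integers")
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (is.unsorted(grade_bands$lower)) {
    stop("grade bands must be ordered by score")
  }
  structure(
    list(variable_indices = variable_indices,
         coefficients = coefficients,
         intercept = as.numeric(intercept),
         grade_bands = grade_bands,
         provenance = provenance),
    class = "warning_model"
  )
}

#' @export
print.warning_model <- function(x, ...) {
  cat("<warning_model>", length(x$variable_indices), "terms, intercept",
      format(x$intercept), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' The published 20-term reference warning model
#'
#' Parses the coefficient table shipped with the package (20 flattened
#' sensor indices with their weights, plus the constant 38.9899) into a
#' [warning_model()].  The indices cover all six channels: 2 temperature,
#' 2 humidity, 3 CO2, 6 C2H4, 4 O2 and 3 VOC timepoints.
#'
#' @return A `warning_model` with provenance `"published reference model"`.
#' @examples
#' m <- paper_reference_model()
#' score_sample(m, numeric(3000))  # 38.9899: the model constant
#' @export
paper_reference_model <- function() {
  path <- system.file("extdata", "reference_warning_model.csv",
                      package = "spoilwarn", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ic <- tab$term == "intercept"
  if (sum(ic) != 1L) stop("reference table must have one intercept row")
  warning_model(
    variable_indices = tab$variable_index[!ic],
    coefficients = tab$coefficient[!ic],
    intercept = tab$coefficient[ic],
    provenance = "published reference model"
  )
}

#' Score a flattened sample with a warning model
#'
#' @param model A [warning_model()].
#' @param x Numeric feature vector covering the model's indices (length
#'   3000 for the default feature space), or a named vector supplying at
#'   least those indices as names.
#' @return Scalar warning score Y.
#' @export
score_sample <- function(model, x) {
  stopifnot(inherits(model, "warning_model"))
  if (!is.null(names(x))) {
    need <- as.character(model$variable_indices)
    if (!all(need %in% names(x))) {
      stop("named input is missing required indices: ",
           paste(setdiff(need, names(x)), collapse = ", "))
    }
    vals <- as.numeric(x[need])
  } else {
    if (length(x) < max(model$variable_indices)) {
      stop("feature vector of length ", length(x),
           " does not cover model index ", max(model$variable_indices))
    }
    vals <- as.numeric(x[model$variable_indices])
  }
  if (anyNA(vals)) stop("missing values at model indices")
  model$intercept + sum(model$coefficients * vals)
}

#' Grade a warning score
#'
#' Maps a score Y to its spoilage grade band.  Scores outside the
#' operational range \[1, 8\] are assigned the nearest band and flagged.
#'
#' @param model A [warning_model()] (supplies the bands).
#' @param y Numeric score (vectorised).
#' @return A data.frame with columns `score`, `grade`, `in_range`.
#' @export
grade_score <- function(model, y) {
  stopifnot(inherits(model, "warning_model"))
  if (any(!is.finite(y))) stop("scores must be finite")
  bands <- model$grade_bands
  idx <- findInterval(y, bands$lower)  # lower[1] = -Inf, so idx >= 1
  data.frame(
    score = y,
    grade = bands$label[idx],
    in_range = y >= 1 & y <= 8,
    stringsAsFactors = FALSE
  )
}

#' Build a warning model from a variable selection
#'
#' Fits PLS on the selected variables over the dataset's calibration rows
#' (all rows when no split is tagged), choosing the component count by
#' RMSECV capped at `max_components`, and folds the coefficients back to
#' original sensor units.
#'
#' @param dataset A [sensor_dataset()].
#' @param selection A `selection_result` (or a bare integer index vector).
#' @param cv A [cv_config()].
#' @param max_components Component cap (default 12, the cap used for the
#'   SA-wrapped fits).
#' @param grade_bands Band table (default [default_grade_bands()]).
#' @return A [warning_model()] whose provenance records the algorithm and
#'   seed.
#' @export
build_warning_model <- function(dataset, selection, cv = cv_config(),
                                max_components = 12L,
                                grade_bands = default_grade_bands()) {
  stopifnot(inherits(dataset, "sensor_dataset"))
  if (inherits(selection, "selection_result")) {
    idx <- selection$selected_indices
    prov <- paste0(selection$algorithm, "-PLS refit, seed ",
                   selection$seed)
  } else {
    idx <- sort(unique(as.integer(selection)))
    prov <- "manual index refit"
  }
  if (length(idx) == 0L) stop("selection is empty")
  if (max(idx) > ncol(dataset$features)) {
    stop("selected index ", max(idx), " is absent from the dataset (",
         ncol(dataset$features), " features)")
  }
  rows <- which(!is.na(dataset$split) & dataset$split == "calibration")
  if (length(rows) == 0L) rows <- seq_len(nrow(dataset$features))
  x <- dataset$features[rows, , drop = FALSE]
  y <- dataset$label[rows]
  cv2 <- cv_config(cv$n_folds, cv$shuffle_seed,
                   min(cv$max_components, max_components))
  ncomp <- kfold_rmsecv(x, y, idx, cv2)$best_components
  fitm <- fit_pls(x[, idx, drop = FALSE], y, ncomp, feature_indices = idx)
  warning_model(idx, fitm$coefficients, fitm$intercept,
                grade_bands = grade_bands, provenance = prov)
}

#' Export a warning model to JSON
#'
#' Versioned schema: indices, coefficients at full precision, intercept,
#' grade bands, provenance.
#'
#' @param model A [warning_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "warning_model"))
  bands <- model$grade_bands
  # JSON has no Inf; band edges are stored as strings and parsed back
  bands$lower <- as.character(bands$lower)
  bands$upper <- as.character(bands$upper)
  doc <- list(
    schema = "spoilwarn-warning-model/1",
    variable_indices = model$variable_indices,
    coefficients = model$coefficients,
    intercept = model$intercept,
    grade_bands = bands,
    provenance = model$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Import a warning model from JSON
#'
#' @param path File written by [export_model()].
#' @return A [warning_model()].
#' @export
import_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !startsWith(doc$schema,
                                         "spoilwarn-warning-model/")) {
    stop("not a warning-model document: ", path)
  }
  if (length(doc$variable_indices) != length(doc$coefficients)) {
    stop("malformed model document: ", length(doc$variable_indices),
         " indices vs ", length(doc$coefficients), " coefficients")
  }
  bands <- as.data.frame(doc$grade_bands, stringsAsFactors = FALSE)
  bands$lower <- as.numeric(bands$lower)
  bands$upper <- as.numeric(bands$upper)
  warning_model(doc$variable_indices, doc$coefficients, doc$intercept,
                grade_bands = bands, provenance = doc$provenance %||% "")
}

#' Render a warning model as its scoring equation
#'
#' @param model A [warning_model()].
#' @return A single string of the form
#'   `"Y = 0.3264 X1 + 0.3708 X2 + ... + 38.9899"`, terms in index order.
#' @export
render_model_equation <- function(model) {
  stopifnot(inherits(model, "warning_model"))
  co <- model$coefficients
  terms <- sprintf("%s%s X%d",
                   ifelse(seq_along(co) == 1L,
                          ifelse(co < 0, "-", ""),
                          ifelse(co < 0, "- ", "+ ")),
                   format(abs(co), trim = TRUE, scientific = FALSE),
                   seq_along(co))
  paste0("Y = ", paste(terms, collapse = " "),
         ifelse(model$intercept < 0, " - ", " + "),
         format(abs(model$intercept), trim = TRUE, scientific = FALSE))
}
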