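# CSV readers/writers for acquisition records and sample-by-feature
# datasets, plus the JSON ground-truth sidecar.
#
# Acquisition dialect: '#'-prefixed metadata lines (warehouse, day), then a
# header row naming the channels, then one row per second.  Columns are
# matched by name, not position, so a file written with a different channel
# order reads back canonically.

acq_header <- function() {
  ch <- sensor_channels()
  paste0(ch$name, " (", ch$unit, ")")
}

#' Write an acquisition record to CSV
#'
#' @param record An [acquisition_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acquisition_csv <- function(record, path) {
  stopifnot(inherits(record, "acquisition_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# warehouse: ", record$warehouse_id),
    paste0("# day: ", record$day)
  ), con)
  df <- as.data.frame(record$values)
  names(df) <- acq_header()
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an acquisition record from CSV
#'
#' Columns are matched to channels by header name (the unit suffix is
#' optional), so files with permuted columns load canonically.
#'
#' @param path CSV file written by [write_acquisition_csv()] or following
#'   the same dialect.
#' @param n_timepoints Expected row count, default 500.
#' @return An [acquisition_record()].
#' @export
read_acquisition_csv <- function(path, n_timepoints = 500L) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) != 1L) stop("missing '", key, "' metadata line in ", path)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit))
  }
  warehouse <- get_meta("warehouse")
  day <- as.integer(get_meta("day"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  # strip " (unit)" suffixes; match by channel name
  names(df) <- sub("\\s*\\(.*\\)\\s*$", "", names(df))
  missing <- setdiff(CHANNEL_NAMES, names(df))
  if (length(missing)) {
    stop("acquisition file ", path, " is missing channel column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[CHANNEL_NAMES]
  if (nrow(df) != n_timepoints) {
    stop("acquisition file ", path, " has ", nrow(df),
         " data rows; expected ", n_timepoints)
  }
  for (nm in CHANNEL_NAMES) {
    if (!is.numeric(df[[nm]])) {
      stop("non-numeric values in column '", nm, "' of ", path)
    }
  }
  acquisition_record(as.matrix(df), warehouse, day,
                     n_timepoints = n_timepoints)
}

#' Construct a sensor dataset
#'
#' Container for n flattened samples: an n x p feature matrix plus per-sample
#' day labels (1-8), the numeric response used for regression (equal to the
#' day unless a synthetic signal was embedded), sample identifiers, and an
#' optional calibration/prediction split tag.
#'
#' @param features Numeric matrix, n x p.
#' @param day Integer vector of day labels in 1..8.
#' @param label Numeric response vector (defaults to `day`).
#' @param sample_id Character vector of unique identifiers.
#' @param split Optional character vector of `"calibration"`/`"prediction"`
#'   tags (NA allowed).
#' @return An object of class `sensor_dataset`.
#' @export
sensor_dataset <- function(features, day, label = as.numeric(day),
                           sample_id = paste0("S", seq_len(nrow(features))),
                           split = rep(NA_character_, nrow(features))) {
  features <- as.matrix(features)
  n <- nrow(features)
  day <- as.integer(day)
  if (length(day) != n || length(label) != n || length(sample_id) != n ||
      length(split) != n) {
    stop("day, label, sample_id and split must each have one entry per row")
  }
  if (any(is.na(day)) || any(day < 1L) || any(day > 8L)) {
    stop("day labels must lie in 1..8; offending values: ",
         paste(unique(day[is.na(day) | day < 1L | day > 8L]), collapse = ", "))
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  ok_split <- is.na(split) | split %in% c("calibration", "prediction")
  if (!all(ok_split)) {
    stop("split tags must be 'calibration', 'prediction' or NA")
  }
  structure(
    list(features = features, day = day, label = as.numeric(label),
         sample_id = as.character(sample_id), split = as.character(split)),
    class = "sensor_dataset"
  )
}

#' @export
print.sensor_dataset <- function(x, ...) {
  cat("<sensor_dataset>", nrow(x$features), "samples x",
      ncol(x$features), "features; days",
      paste(range(x$day), collapse = "-"), "\n")
  if (!all(is.na(x$split))) {
    cat("  split:", sum(x$split == "calibration", na.rm = TRUE),
        "calibration /", sum(x$split == "prediction", na.rm = TRUE),
        "prediction\n")
  }
  invisible(x)
}

#' Write a sensor dataset to CSV
#'
#' One row per sample: `sample_id`, `day`, `label`, `split`, then the
#' feature columns `V1..Vp` (flattened index order).
#'
#' @param dataset A [sensor_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "sensor_dataset"))
  df <- data.frame(
    sample_id = dataset$sample_id,
    day = dataset$day,
    label = dataset$label,
    split = dataset$split,
    stringsAsFactors = FALSE
  )
  feat <- as.data.frame(dataset$features)
  names(feat) <- paste0("V", seq_len(ncol(feat)))
  utils::write.csv(cbind(df, feat), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sensor dataset from CSV
#'
#' @param path File written by [write_dataset_csv()].
#' @return A [sensor_dataset()].
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character",
                                       split = "character"))
  need <- c("sample_id", "day", "label", "split")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("dataset file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  featcols <- setdiff(names(df), need)
  split <- df$split
  split[!is.na(split) & split == ""] <- NA_character_
  sensor_dataset(
    features = as.matrix(df[featcols]),
    day = df$day,
    label = df$label,
    sample_id = df$sample_id,
    split = split
  )
}

#' Write the ground-truth sidecar of a simulated dataset
#'
#' @param truth The `ground_truth` element returned by [simulate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path JSON path written by [write_ground_truth_json()].
#' @return A list with `informative_indices`, `coefficients`, `intercept`,
#'   `day_of_sample`.
#' @export
read_ground_truth_json <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$informative_indices <- as.integer(gt$informative_indices)
  gt
}
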