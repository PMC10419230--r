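# Sensor channel metadata and the flattened-index <-> channel map.
#
# An acquisition is a timepoints x 6 matrix (default 500 x 6, one row per
# second).  Flattening is sensor-major: the full Temperature trace first,
# then Humidity, CO2, C2H4, O2, VOC, giving a length-3000 feature vector
# whose 1-based index space is tiled 1-500, 501-1000, ..., 2501-3000.

CHANNEL_NAMES <- c("Temperature", "Humidity", "CO2", "C2H4", "O2", "VOC")

#' Sensor channel specification table
#'
#' Metadata for the six monitored channels: unit, detection range,
#' resolution, and the inclusive 1-based interval each channel occupies in
#' the flattened feature vector.
#'
#' @param n_timepoints Number of timepoints per acquisition (tile width).
#'   The deployed prototype records 500 s at 1 Hz, so the default tiling is
#'   1-500 (Temperature), 501-1000 (Humidity), 1001-1500 (CO2),
#'   1501-2000 (C2H4), 2001-2500 (O2), 2501-3000 (VOC).
#' @return A data.frame with one row per channel: `name`, `unit`,
#'   `range_min`, `range_max`, `resolution`, `flat_start`, `flat_end`.
#' @examples
#' sensor_channels()
#' @export
sensor_channels <- function(n_timepoints = 500L) {
  n_timepoints <- as.integer(n_timepoints)
  stopifnot(n_timepoints >= 1L)
  ch <- data.frame(
    name       = CHANNEL_NAMES,
    unit       = c("degC", "%rh", "ppm", "ppm", "%VOL", "ppm"),
    range_min  = c(-20, 0, 0, 0, 0, 0),
    range_max  = c(80, 100, 5000, 100, 30, 50),
    resolution = c(0.1, 0.1, 1, 0.1, 0.1, 0.001),
    stringsAsFactors = FALSE
  )
  ch$flat_start <- (seq_len(6L) - 1L) * n_timepoints + 1L
  ch$flat_end   <- seq_len(6L) * n_timepoints
  ch
}

#' Map a flattened feature index to its sensor channel and timepoint
#'
#' @param index 1-based flattened index (vectorised).
#' @param n_timepoints Tile width (timepoints per channel), default 500.
#' @return A data.frame with columns `index`, `channel`, `timepoint`
#'   (1-based within the channel trace).
#' @examples
#' index_to_channel(228)   # Temperature, timepoint 228
#' index_to_channel(2001)  # O2, timepoint 1
#' @export
index_to_channel <- function(index, n_timepoints = 500L) {
  n_timepoints <- as.integer(n_timepoints)
  index <- as.integer(index)
  p <- 6L * n_timepoints
  if (any(is.na(index)) || any(index < 1L) || any(index > p)) {
    stop("flattened index out of range 1..", p, ": ",
         paste(index[is.na(index) | index < 1L | index > p], collapse = ", "))
  }
  slot <- (index - 1L) %/% n_timepoints + 1L
  data.frame(
    index = index,
    channel = CHANNEL_NAMES[slot],
    timepoint = index - (slot - 1L) * n_timepoints,
    stringsAsFactors = FALSE
  )
}

#' Construct an acquisition record
#'
#' One gas-sensor recording: `n_timepoints` rows (1 Hz samples) by six
#' channel columns, with warehouse and day metadata.
#'
#' @param values Numeric matrix, timepoints x 6, columns in canonical
#'   channel order.
#' @param warehouse_id Warehouse identifier (scalar).
#' @param day Acquisition day label, integer 1-8.
#' @param n_timepoints Expected row count (default 500).
#' @return An object of class `acquisition_record`.
#' @export
acquisition_record <- function(values, warehouse_id, day, n_timepoints = 500L) {
  values <- as.matrix(values)
  if (nrow(values) != n_timepoints || ncol(values) != 6L) {
    stop("acquisition must be ", n_timepoints, " x 6, got ",
         nrow(values), " x ", ncol(values))
  }
  if (any(!is.finite(values))) stop("acquisition contains non-finite values")
  colnames(values) <- CHANNEL_NAMES
  structure(
    list(values = values, timestamps = seq_len(nrow(values)) - 1L,
         warehouse_id = as.character(warehouse_id), day = as.integer(day)),
    class = "acquisition_record"
  )
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat("<acquisition_record> warehouse", x$warehouse_id, "day", x$day, "-",
      nrow(x$values), "timepoints x", ncol(x$values), "channels\n")
  invisible(x)
}

#' Flatten an acquisition record into a feature vector
#'
#' Sensor-major flattening: the output concatenates the six channel traces
#' in canonical channel order, each in time order, so a 500 x 6 recording
#' becomes a length-3000 vector whose tiles line up with
#' [sensor_channels()].
#'
#' @param record An [acquisition_record()].
#' @return Numeric vector of length `n_timepoints * 6`.
#' @export
flatten_record <- function(record) {
  stopifnot(inherits(record, "acquisition_record"))
  as.vector(record$values)  # column-major = sensor-major, time within channel
}

#' Unflatten a feature vector back into a timepoints x 6 matrix
#'
#' Exact inverse of [flatten_record()].
#'
#' @param x Numeric vector, length divisible into 6 equal channel tiles
#'   (3000 for the default 500-timepoint acquisition).
#' @param n_timepoints Tile width, default 500.
#' @return Numeric matrix, `n_timepoints` x 6, canonical column order.
#' @export
unflatten <- function(x, n_timepoints = 500L) {
  p <- 6L * as.integer(n_timepoints)
  if (length(x) != p) {
    stop("feature vector must have length ", p, ", got ", length(x))
  }
  m <- matrix(as.numeric(x), nrow = n_timepoints, ncol = 6L)
  colnames(m) <- CHANNEL_NAMES
  m
}
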