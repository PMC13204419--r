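#' Telemetry CSV schema
#'
#' Column names of the synchronized optical/thermal telemetry interchange
#' format: `timestamp_s`, `wavelength_nm`, `detector_id` ("near"/"far"),
#' `distance_mm`, `flux` (arbitrary linear units), `gain`,
#' `integration_ms`, `temp_c` (NA on purely optical frames).
#'
#' @return Character vector of column names.
#' @export
telemetry_columns <- function() {
  c("timestamp_s", "wavelength_nm", "detector_id", "distance_mm", "flux",
    "gain", "integration_ms", "temp_c")
}

#' Write a telemetry stream to CSV
#'
#' Full float precision (the CSV round trip is lossless for simulator
#' output).
#'
#' @param telemetry Telemetry `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(telemetry, path) {
  stopifnot(all(telemetry_columns() %in% names(telemetry)))
  df <- telemetry[, telemetry_columns()]
  # format() at 17 significant digits keeps doubles exact through the CSV
  for (col in c("timestamp_s", "distance_mm", "flux", "temp_c")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a telemetry stream
#'
#' Checks the mandatory columns, drops malformed rows (non-finite or
#' negative flux on optical rows, non-positive distances) with a logged
#' count, and re-sorts by timestamp with a warning when the file is out of
#' order.
#'
#' @param path CSV path.
#' @return Validated telemetry `data.frame`, time-ordered, with attribute
#'   `n_skipped` giving the number of dropped rows.
#' @export
read_telemetry <- function(path) {
  if (!file.exists(path)) stop("telemetry file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(telemetry_columns(), names(raw))
  if (length(missing_cols)) {
    stop("telemetry file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("empty telemetry file: ", path)
  suppress <- function(x) suppressWarnings(as.numeric(x))
  raw$timestamp_s <- suppress(raw$timestamp_s)
  raw$flux <- suppress(raw$flux)
  raw$distance_mm <- suppress(raw$distance_mm)
  raw$temp_c <- suppress(raw$temp_c)
  ok <- is.finite(raw$timestamp_s) &
    is.finite(raw$flux) & raw$flux >= 0 &
    is.finite(raw$distance_mm) & raw$distance_mm > 0
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(sprintf("read_telemetry: skipped %d malformed row(s)", n_skipped))
  }
  out <- raw[ok, ]
  if (is.unsorted(out$timestamp_s)) {
    warning("telemetry timestamps out of order: re-sorted")
    out <- out[order(out$timestamp_s), ]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Over-temperature safety monitor
#'
#' Scans a surface-temperature stream against a shutoff threshold. An event
#' is emitted at the first sample *strictly* exceeding the threshold of
#' each contiguous excursion (at most one event per excursion); everything
#' from the first event onward is marked source-off, emulating the
#' wearable's automatic LED shutoff.
#'
#' @param temp_stream `data.frame` with columns `timestamp_s`, `temp_c`, or
#'   a numeric temperature vector (then indexed 0, 1, ...).
#' @param threshold Shutoff threshold, degC (finite). Default 43, a common
#'   hyperthermia damage reference.
#' @return List with `events` (`data.frame`: `index`, `timestamp_s`,
#'   `temp_c`) and `stream` (the input with a logical `source_off` column).
#' @export
safety_monitor <- function(temp_stream, threshold = 43) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is.numeric(temp_stream)) {
    temp_stream <- data.frame(timestamp_s = seq_along(temp_stream) - 1,
                              temp_c = temp_stream)
  }
  stopifnot(all(c("timestamp_s", "temp_c") %in% names(temp_stream)))
  over <- temp_stream$temp_c > threshold
  over[is.na(over)] <- FALSE
  # rising edges: first over-threshold sample of each contiguous excursion
  rising <- which(over & !c(FALSE, over[-length(over)]))
  events <- data.frame(index = rising,
                       timestamp_s = temp_stream$timestamp_s[rising],
                       temp_c = temp_stream$temp_c[rising])
  temp_stream$source_off <- FALSE
  if (nrow(events) > 0) {
    temp_stream$source_off[seq(events$index[1], nrow(temp_stream))] <- TRUE
  }
  list(events = events, stream = temp_stream)
}
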