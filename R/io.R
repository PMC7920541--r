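# On-disk session container: flat little-endian binary samples plus a JSON
# sidecar describing shape/dtype, and a plain CSV event table. The float64
# dtype round-trips bit exactly; float32 is offered for compactness and
# round-trips to single precision.

EVENTS_COLUMNS <- c("trial_id", "start_time_s", "response_time_s",
                    "trial_type", "outcome")

#' Write a session to disk
#'
#' Writes `data.bin` (channel-major little-endian samples), `header.json`
#' (sampling rate, labels, shape, dtype) and `events.csv` under `path`.
#'
#' @param recording an `lfp_recording` (see [generate_session()]).
#' @param events event table with columns
#'   `trial_id, start_time_s, response_time_s, trial_type, outcome`.
#' @param path directory to create/write into.
#' @param dtype `"float64"` (bit-exact round trip, default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, events, path, dtype = c("float64",
                                                             "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(recording, "lfp_recording"),
            all(EVENTS_COLUMNS %in% names(events)))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0) stop("unwritable path: ", path)
  size <- if (dtype == "float32") 4L else 8L
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # column-major matrix dump: channels vary fastest within each sample
  writeBin(as.vector(recording$data), con, size = size, endian = "little")
  header <- list(format = "oscnet-recording", version = 1L,
                 fs = recording$fs, labels = recording$labels,
                 n_channels = nrow(recording$data),
                 n_samples = ncol(recording$data),
                 dtype = dtype, byte_order = "little")
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(events[, EVENTS_COLUMNS], file.path(path, "events.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path directory containing `data.bin`, `header.json`, `events.csv`.
#' @return list with `recording` and `events`, as in [generate_session()].
#' @export
read_session <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  size <- if (identical(header$dtype, "float32")) 4L else 8L
  n <- header$n_channels * header$n_samples
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, what = "numeric", n = n, size = size, endian = "little")
  if (length(x) != n) stop("data.bin truncated: expected ", n, " samples")
  data <- matrix(x, header$n_channels, header$n_samples)
  events <- read_events(file.path(path, "events.csv"))
  recording <- structure(list(data = data, fs = header$fs,
                              labels = header$labels),
                         class = "lfp_recording")
  list(recording = recording, events = events)
}

#' Read and validate an event table
#'
#' @param file CSV file with header
#'   `trial_id,start_time_s,response_time_s,trial_type,outcome`.
#' @return validated data frame.
#' @export
read_events <- function(file) {
  events <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing <- setdiff(EVENTS_COLUMNS, names(events))
  if (length(missing))
    stop("events table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!all(events$trial_type %in% c("go", "wait")))
    stop("trial_type must be 'go' or 'wait'")
  if (!all(events$outcome %in% c("correct", "incorrect")))
    stop("outcome must be 'correct' or 'incorrect'")
  if (is.unsorted(events$start_time_s, strictly = TRUE))
    stop("start_time_s must be strictly increasing")
  events
}
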