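#' Read and write the tabular dataset files
#'
#' Tables are tab-separated UTF-8 with a header row; missing values are
#' empty strings. Loading validates the schema and the table invariants
#' (e.g. `output_position` present exactly for recalled items) and fails
#' naming the offending file and rule.
#'
#' @param events,electrodes,cohort Tibbles to write.
#' @param path File path.
#' @return The read functions return validated tibbles.
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
write_events_tsv <- function(events, path) {
  assert_events(events)
  readr::write_tsv(events, path, na = "")
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject = "c", session = "c", task_variant = "c", list = "i",
      serial_position = "i", item = "c", category = "i", recalled = "l",
      output_position = "i"
    ),
    na = ""
  )
  tryCatch(
    assert_events(ev),
    error = function(e) {
      abort(paste0("Invalid events file '", path, "': ", conditionMessage(e)))
    }
  )
  if (!all(ev$task_variant %in% c("unrelated", "categorized"))) {
    abort(paste0("Invalid events file '", path, "': unknown task_variant."))
  }
  ranks_ok <- ev |>
    filter(.data$recalled) |>
    summarise(
      ok = setequal(.data$output_position, seq_len(n())),
      .by = c("subject", "session", "list")
    )
  if (!all(ranks_ok$ok)) {
    abort(paste0(
      "Invalid events file '", path,
      "': output positions of a list must form 1..k."
    ))
  }
  ev
}

#' @rdname dataset_io
#' @export
write_electrodes_tsv <- function(electrodes, path) {
  assert_electrodes(electrodes)
  readr::write_tsv(electrodes, path, na = "")
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_electrodes_tsv <- function(path) {
  el <- readr::read_tsv(
    path,
    col_types = readr::cols(channel = "c", region = "c", excluded = "l"),
    na = ""
  )
  tryCatch(
    assert_electrodes(el),
    error = function(e) {
      abort(paste0("Invalid electrode file '", path, "': ", conditionMessage(e)))
    }
  )
  el
}

#' @rdname dataset_io
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path, na = "")
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_cohort_tsv <- function(path) {
  co <- readr::read_tsv(path, show_col_types = FALSE, na = "")
  if (!all(c("subject", "group") %in% names(co))) {
    abort(paste0("Invalid cohort file '", path, "': needs subject and group."))
  }
  co
}

#' Write / read an epoch tensor container
#'
#' The voltage array is stored as a flat little-endian float64 binary file in
#' item-major order (item, then channel, then sample), described by a JSON
#' sidecar (`<path>.json`) holding dimensions, axis order, dtype, sampling
#' rate, epoch start time, buffer and channel labels.
#'
#' @param epochs An [epoch_tensor()].
#' @param path Path of the binary file; the sidecar gets `.json` appended.
#' @return `read_epochs_bin()` returns the reconstructed [epoch_tensor()].
#' @export
write_epochs_bin <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  d <- dim(epochs$data)
  # item-major: sample varies fastest
  flat <- as.numeric(aperm(epochs$data, c(3, 2, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 8, endian = "little")
  sidecar <- list(
    dims = d, axes = c("item", "channel", "sample"), dtype = "float64",
    byte_order = "little", fs = epochs$fs, t_start = epochs$t_start,
    buffer = epochs$buffer, channels = epochs$channels
  )
  jsonlite::write_json(
    sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_epochs_bin
#' @export
read_epochs_bin <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(sidecar$dims)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(flat) != n) {
    abort(paste0("Epoch file '", path, "' is shorter than its sidecar dims."))
  }
  data <- aperm(array(flat, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  epoch_tensor(
    data,
    fs = sidecar$fs, t_start = sidecar$t_start,
    buffer = sidecar$buffer, channels = sidecar$channels
  )
}

#' Write a simulated dataset to a directory
#'
#' Writes `events.tsv`, `electrodes.tsv`, `epochs.bin` (+ JSON sidecar) and
#' `truth.json` under `dir`.
#'
#' @param dataset A [simulate_subject()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(dataset$events, file.path(dir, "events.tsv"))
  write_electrodes_tsv(dataset$electrodes, file.path(dir, "electrodes.tsv"))
  write_epochs_bin(dataset$epochs, file.path(dir, "epochs.bin"))
  truth <- unclass(dataset$truth)
  jsonlite::write_json(
    truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a dataset directory
#'
#' Loads the files written by [write_dataset()] and re-checks the cross-file
#' invariants: the epoch item axis must align 1:1 with the events rows and
#' every epoch channel must appear in the electrode table.
#'
#' @param dir Directory containing `events.tsv`, `electrodes.tsv`,
#'   `epochs.bin`.
#' @return A list with `events`, `electrodes`, `epochs`.
#' @export
read_dataset <- function(dir) {
  events <- read_events_tsv(file.path(dir, "events.tsv"))
  electrodes <- read_electrodes_tsv(file.path(dir, "electrodes.tsv"))
  epochs <- read_epochs_bin(file.path(dir, "epochs.bin"))
  if (dim(epochs$data)[1] != nrow(events)) {
    abort(sprintf(
      "Epochs (%d items) do not align with events (%d rows).",
      dim(epochs$data)[1], nrow(events)
    ))
  }
  if (!all(epochs$channels %in% electrodes$channel)) {
    abort("Epoch channels missing from the electrode table.")
  }
  list(events = events, electrodes = electrodes, epochs = epochs)
}
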