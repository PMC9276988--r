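# Dataset I/O: delimited-text channels-x-samples matrices, a JSON manifest
# tying files to subject / trial / label, and JSON + CSV evaluation reports.
# Numeric output is printed with 17 significant digits ("%.17g") so every
# write/read round trip reproduces the doubles exactly.

#' Read one trial's matrix from a delimited-text file
#'
#' The file holds one channel per row and one sample per column, with no
#' header by default; `transpose = TRUE` accepts samples-in-rows files
#' explicitly (orientation is never guessed).
#'
#' @param path Path to the CSV/TSV file.
#' @param subject_id,trial_id,label,sample_rate_hz Metadata for the
#'   resulting recording (see [recording()]).
#' @param channel_count If given, the parsed channel count must match it
#'   (consistency check against a manifest).
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param row_names If TRUE the first column holds channel names.
#' @param transpose If TRUE the file is samples-in-rows and is transposed
#'   after parsing.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, subject_id, trial_id, label = NULL,
                           sample_rate_hz = 128, channel_count = NULL,
                           sep = ",", row_names = FALSE, transpose = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format(sprintf("empty matrix file: %s", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop_format(sprintf(
      "ragged rows in %s: row 1 has %d fields but row %d has %d",
      path, widths[1L], which(widths != widths[1L])[1L],
      widths[widths != widths[1L]][1L]))
  channel_names <- NULL
  if (row_names) {
    channel_names <- vapply(fields, `[[`, character(1), 1L)
    fields <- lapply(fields, `[`, -1L)
  }
  mat <- matrix(NA_real_, nrow = length(fields), ncol = length(fields[[1L]]))
  for (i in seq_along(fields)) {
    row <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop_parse(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                         fields[[i]][j], i, j, path))
    }
    mat[i, ] <- row
  }
  if (transpose) {
    mat <- t(mat)
    channel_names <- NULL
  }
  if (!is.null(channel_count) && nrow(mat) != channel_count)
    stop_consistency(sprintf(
      "%s has %d channels but the manifest declares %d",
      path, nrow(mat), channel_count))
  recording(mat, subject_id = subject_id, trial_id = trial_id, label = label,
            sample_rate_hz = sample_rate_hz, channel_names = channel_names)
}

#' Write a recording as a delimited-text matrix file
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @param row_names If TRUE, prepend the channel name to each row.
#' @export
write_recording <- function(rec, path, sep = ",", row_names = FALSE) {
  stopifnot(inherits(rec, "spsp_recording"))
  rows <- apply(rec$data, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  if (row_names) rows <- paste(rec$channel_names, rows, sep = sep)
  writeLines(rows, path)
  invisible(path)
}

#' Write a dataset manifest as JSON
#'
#' @param entries Data frame (or list of lists) with columns `file_path`,
#'   `subject_id`, `trial_id`, `label`.
#' @param path Output path for the manifest JSON.
#' @param channel_count Number of channels every referenced file must have.
#' @param sample_rate_hz Sampling rate shared by all trials.
#' @param extra Optional named list merged into the manifest (e.g., the
#'   generator seed).
#' @export
write_manifest <- function(entries, path, channel_count, sample_rate_hz,
                           extra = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("file_path", "subject_id", "trial_id", "label")
  if (!all(need %in% names(entries)))
    stop_manifest(sprintf("manifest entries need columns {%s}",
                          paste(need, collapse = ", ")))
  manifest <- c(list(channel_count = channel_count,
                     sample_rate_hz = sample_rate_hz,
                     entries = entries[need]),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a dataset described by a JSON manifest
#'
#' Reads the manifest, validates it (unique (subject, trial) pairs, all
#' referenced files present), and returns one recording per entry in
#' manifest order, with labels attached.  Relative `file_path`s are resolved
#' against the manifest's directory.
#'
#' @param manifest_path Path to the manifest JSON.
#' @param sep,row_names,transpose Passed to [read_recording()].
#' @return List of [recording()] objects, with the parsed manifest attached
#'   as attribute `"manifest"`.
#' @export
load_dataset <- function(manifest_path, sep = ",", row_names = FALSE,
                         transpose = FALSE) {
  if (!file.exists(manifest_path))
    stop_io(sprintf("manifest not found: %s", manifest_path))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (fld in c("channel_count", "sample_rate_hz"))
    if (is.null(manifest[[fld]]))
      stop_manifest(sprintf("manifest lacks required field '%s'", fld))
  entries <- manifest$entries
  if (is.null(entries) || NROW(entries) == 0L) {
    out <- list()
    attr(out, "manifest") <- manifest
    return(out)
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  key <- paste(entries$subject_id, entries$trial_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), , drop = FALSE][1L, ]
    stop_manifest(sprintf("duplicate (subject, trial) pair: ('%s', '%s')",
                          dup$subject_id, dup$trial_id))
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", entries$file_path),
                  entries$file_path, file.path(base, entries$file_path))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_io(sprintf("manifest references missing file(s): %s",
                    paste(missing, collapse = ", ")))
  out <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    lab <- entries$label[i]
    if (is.null(lab) || is.na(lab)) lab <- NULL
    out[[i]] <- read_recording(
      paths[i], subject_id = entries$subject_id[i],
      trial_id = entries$trial_id[i], label = lab,
      sample_rate_hz = manifest$sample_rate_hz,
      channel_count = manifest$channel_count,
      sep = sep, row_names = row_names, transpose = transpose)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Write an evaluation report as JSON plus a confusion-matrix CSV
#'
#' The JSON file holds labels, confusion counts, per-class / per-subject /
#' total accuracies and the fold count; a CSV rendering of the confusion
#' matrix (target rows, predicted columns) is written alongside with suffix
#' `_confusion.csv`.
#'
#' @param report An `spsp_eval_report` from [loso_evaluate()].
#' @param path Output path for the JSON report.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "spsp_eval_report"))
  payload <- list(
    labels = report$labels,
    confusion = unname(apply(report$confusion, 1L, as.integer, simplify = FALSE)),
    per_class_accuracy = as.numeric(report$per_class_accuracy),
    per_subject_accuracy = as.list(report$per_subject_accuracy),
    total_accuracy_mean_subject = report$total_accuracy_mean_subject,
    total_accuracy_micro = report$total_accuracy_micro,
    n_folds = report$n_folds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- paste0(tools::file_path_sans_ext(path), "_confusion.csv")
  header <- paste(c("target", report$labels), collapse = ",")
  body <- vapply(seq_along(report$labels), function(i)
    paste(c(report$labels[i], report$confusion[i, ]), collapse = ","),
    character(1))
  writeLines(c(header, body), csv_path)
  invisible(c(path, csv_path))
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return An `spsp_eval_report` equal (up to the unserialised `folds`
#'   detail) to the one written.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("report not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  confusion <- matrix(as.integer(p$confusion), nrow = length(p$labels),
                      dimnames = list(target = p$labels, predicted = p$labels))
  structure(
    list(labels = p$labels, confusion = confusion,
         per_class_accuracy = stats::setNames(as.numeric(p$per_class_accuracy),
                                              p$labels),
         per_subject_accuracy = unlist(p$per_subject_accuracy),
         total_accuracy_mean_subject = p$total_accuracy_mean_subject,
         total_accuracy_micro = p$total_accuracy_micro,
         n_folds = p$n_folds, folds = NULL),
    class = "spsp_eval_report"
  )
}

#' Convert a trials-x-channels-x-samples array to recordings
#'
#' Adapter for datasets distributed as one 3-D array per subject (40 trials
#' x 40 channels x 8064 samples in the DEAP preprocessed release): only the
#' first `n_channels` rows of the channel axis are kept (the EEG channels
#' precede the peripheral ones), and the trial-to-label mapping must be
#' supplied explicitly because no public enumeration of which trials carry
#' which discrete labels exists.
#'
#' @param arr 3-D numeric array, trials x channels x samples.
#' @param subject_id Subject identifier for all trials in the array.
#' @param labels Named character vector mapping trial index (as written by
#'   `as.character(i)`) to class label; trials without an entry are dropped.
#' @param sample_rate_hz Sampling rate (default 128).
#' @param n_channels Leading channels to keep (default 32).
#' @return List of [recording()] objects, one per labelled trial.
#' @export
subject_array_to_recordings <- function(arr, subject_id, labels,
                                        sample_rate_hz = 128,
                                        n_channels = 32L) {
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop_domain("'arr' must be a 3-D array (trials x channels x samples)")
  if (dim(arr)[2L] < n_channels)
    stop_domain(sprintf("array has %d channels, fewer than the %d requested",
                        dim(arr)[2L], n_channels))
  if (is.null(names(labels)) || !is.character(labels))
    stop_domain("'labels' must be a named character vector keyed by trial index")
  out <- list()
  for (key in names(labels)) {
    i <- as.integer(key)
    if (is.na(i) || i < 1L || i > dim(arr)[1L])
      stop_domain(sprintf("label mapping names trial '%s' outside 1..%d",
                          key, dim(arr)[1L]))
    out[[length(out) + 1L]] <- recording(
      matrix(arr[i, seq_len(n_channels), ], nrow = n_channels),
      subject_id = subject_id, trial_id = sprintf("trial%02d", i),
      label = unname(labels[[key]]), sample_rate_hz = sample_rate_hz)
  }
  out
}
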