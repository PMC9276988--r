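#' Construct a multichannel recording
#'
#' A recording is one trial's channels-by-samples numeric matrix together
#' with its identifying metadata.  Rows are channels, columns are samples;
#' the instantaneous column vector is later interpreted as one point of the
#' channel-space trajectory.
#'
#' @param data Numeric matrix, M channels in rows by N samples in columns
#'   (M >= 1, N >= 2, all values finite).
#' @param subject_id,trial_id Character scalars identifying the trial.
#' @param label Optional character class label (e.g., an emotion name), or
#'   `NULL` when unlabelled.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param channel_names Character vector of M unique channel names; defaults
#'   to `ch1..chM`.
#' @return An object of class `spsp_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(8), 2, 4), "s1", "t1", label = "happy")
#' n_channels(rec)
#' n_samples(rec)
#' @export
recording <- function(data, subject_id, trial_id, label = NULL,
                      sample_rate_hz = 128, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_domain("'data' must be a numeric matrix (channels x samples)")
  M <- nrow(data); N <- ncol(data)
  if (M < 1L || N < 2L)
    stop_domain(sprintf("recording needs M >= 1 channels and N >= 2 samples, got %d x %d", M, N))
  if (!all(is.finite(data)))
    stop_domain("recording matrix contains non-finite values")
  if (!is_string(subject_id) || !is_string(trial_id))
    stop_domain("'subject_id' and 'trial_id' must be single strings")
  if (!is.null(label) && !is_string(label))
    stop_domain("'label' must be NULL or a single string")
  if (!is_number(sample_rate_hz) || sample_rate_hz <= 0)
    stop_domain("'sample_rate_hz' must be a positive number")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(M))
  if (length(channel_names) != M || anyDuplicated(channel_names))
    stop_domain("'channel_names' must have one unique name per channel")
  dimnames(data) <- NULL
  structure(
    list(subject_id = subject_id, trial_id = trial_id, label = label,
         sample_rate_hz = sample_rate_hz,
         channel_names = as.character(channel_names), data = data),
    class = "spsp_recording"
  )
}

#' @rdname recording
#' @param x An `spsp_recording`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "spsp_recording"))
  nrow(x$data)
}

#' @rdname recording
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spsp_recording"))
  ncol(x$data)
}

#' @export
print.spsp_recording <- function(x, ...) {
  cat(sprintf("<spsp_recording> subject=%s trial=%s label=%s\n",
              x$subject_id, x$trial_id, x$label %||% "<none>"))
  cat(sprintf("  %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
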