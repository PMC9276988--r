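#' Run configuration for the symbolisation / evaluation pipeline
#'
#' @param epsilon_h Entropy-increment threshold in bits, open interval
#'   (0, 1); default 0.2, the value at which equal-frequency coding of a
#'   long tie-free series settles on an 8-symbol alphabet.
#' @param S_override If set, skip alphabet-size selection and use this S.
#' @param partition_scheme `"max_entropy"` (default) or `"uniform"` -- how
#'   each trial's distance series is binned once S is fixed.
#' @param k_max Cap on the alphabet-size search (default 64).
#' @param S_selection `"average"` (default): entropy increments are computed
#'   per trial and averaged across trials before thresholding, giving one
#'   global S; `"first_trial"`: S is selected from the first trial alone.
#' @param index_weighting `"per_trial"` (default): class templates average
#'   all training trials with equal weight; `"per_subject"`: trials are
#'   first averaged within subject, then across subjects.
#' @param seed Integer seed recorded in run metadata (the pipeline itself is
#'   deterministic; the seed feeds the `simulate` command).
#' @return An `spsp_config`.
#' @export
run_config <- function(epsilon_h = 0.2, S_override = NULL,
                       partition_scheme = c("max_entropy", "uniform"),
                       k_max = 64L,
                       S_selection = c("average", "first_trial"),
                       index_weighting = c("per_trial", "per_subject"),
                       seed = 1L) {
  if (!is_number(epsilon_h) || epsilon_h <= 0 || epsilon_h >= 1)
    stop_config("'epsilon_h' must lie in the open interval (0, 1)")
  if (!is.null(S_override) && !is_count(S_override, min = 2L))
    stop_config("'S_override' must be NULL or an integer >= 2")
  if (!is_count(k_max, min = 2L)) stop_config("'k_max' must be an integer >= 2")
  if (!is_count(seed, min = 0L)) stop_config("'seed' must be a nonnegative integer")
  structure(list(epsilon_h = epsilon_h,
                 S_override = if (!is.null(S_override)) as.integer(S_override),
                 partition_scheme = match.arg(partition_scheme),
                 k_max = as.integer(k_max),
                 S_selection = match.arg(S_selection),
                 index_weighting = match.arg(index_weighting),
                 seed = as.integer(seed)),
            class = "spsp_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Unknown fields raise a configuration error naming the field.  YAML files
#' need the optional `yaml` package.
#'
#' @param path Path to the config file (`.json`, `.yaml` or `.yml`).
#' @return An `spsp_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("YAML config given but the 'yaml' package is not installed")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop_config(sprintf("unknown config field '%s'", unknown[1L]))
  do.call(run_config, vals)
}

#' Symbolise a set of recordings
#'
#' Runs the full symbolisation front end: per trial, build the
#' channel-space trajectory, its centre, and the radial-distance series;
#' select one global alphabet size S by the entropy-increment rule (per
#' `config`, or take `S_override`); then fit the configured partition per
#' trial and emit its symbol sequence.  Partitioning is always refitted per
#' trial, so the coding adapts to each trial's own distance distribution.
#'
#' @param recordings List of [recording()] objects.
#' @param config An [run_config()].
#' @return List with `sequences` (one `spsp_symbol_sequence` per
#'   recording, same order), `S`, `S_source` (`"selected"` or
#'   `"override"`), `profiles` (per-trial entropy profiles, NULL under
#'   `S_override`), and `mean_h` (across-trial mean increment per k, NULL
#'   under `S_override`).
#' @export
symbolize_recordings <- function(recordings, config = run_config()) {
  if (!is.list(recordings) || length(recordings) == 0L ||
      !all(vapply(recordings, inherits, logical(1), "spsp_recording")))
    stop_domain("'recordings' must be a non-empty list of spsp_recording objects")
  if (!inherits(config, "spsp_config")) stop_config("'config' must be an spsp_config")
  dists <- lapply(recordings, function(rec) radial_distances(build_trajectory(rec)))
  profiles <- NULL; mean_h <- NULL
  if (!is.null(config$S_override)) {
    S <- config$S_override; S_source <- "override"
  } else {
    use <- if (config$S_selection == "first_trial") dists[1L] else dists
    profiles <- lapply(use, entropy_profile, k_max = config$k_max,
                       epsilon_h = config$epsilon_h)
    mean_h <- rowMeans(vapply(profiles, `[[`, numeric(config$k_max), "h"))
    below <- which(!is.na(mean_h) & mean_h < config$epsilon_h)
    if (!length(below))
      stop_not_converged(sprintf(
        "mean entropy increment never fell below epsilon_h = %g by k_max = %d",
        config$epsilon_h, config$k_max))
    S <- as.integer(min(below)); S_source <- "selected"
  }
  fit <- switch(config$partition_scheme,
                max_entropy = max_entropy_partition,
                uniform = uniform_partition)
  sequences <- lapply(dists, function(d) assign_symbols(d, fit(d, S)))
  list(sequences = sequences, S = S, S_source = S_source,
       profiles = profiles, mean_h = mean_h)
}

#' Symbolise and evaluate a labelled dataset end to end
#'
#' Convenience wrapper: [symbolize_recordings()] followed by
#' [loso_evaluate()] on the resulting sequences.
#'
#' @param recordings List of labelled [recording()] objects covering >= 2
#'   subjects.
#' @param class_labels Ordered class labels (default: all labels present,
#'   in order of first appearance).
#' @param config An [run_config()].
#' @return The `spsp_eval_report`, with the selected `S` attached as
#'   attribute `"S"`.
#' @export
evaluate_recordings <- function(recordings, class_labels = NULL,
                                config = run_config()) {
  sym <- symbolize_recordings(recordings, config)
  if (is.null(class_labels)) {
    labs <- vapply(recordings, function(r) r$label %||% NA_character_, character(1))
    class_labels <- unique(labs[!is.na(labs)])
  }
  report <- loso_evaluate(sym$sequences, class_labels,
                          weighting = config$index_weighting)
  attr(report, "S") <- sym$S
  report
}
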