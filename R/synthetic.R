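# Synthetic multichannel datasets with class-conditional radial structure.
#
# The generative model places the class signal exactly where the spherical
# symbolisation looks: channel m of a trial of class c is
#
#   x_m(n) = a_c(n) * g_m(n) + noise_sd * eps_m(n)
#
# with g_m a smooth per-subject base waveform (moving-average-filtered
# Gaussian noise, shared by all of that subject's trials), eps white
# Gaussian noise drawn per trial, and a_c(n) = 1 + separation * i_c * w(n)
# a class-specific radial envelope built from a fixed slow modulation
# w(n) = (1 + sin(2*pi*3*n/N)) / 2 in [0, 1] (i_c is the 0-based class
# index).  Classes therefore differ in how the trajectory's distance from
# its centre is distributed over time -- the exact quantity the method
# symbolises -- while at separation = 0 the class label carries no
# information at all.

#' Specification of a synthetic dataset
#'
#' Defaults give the test-scale world (8 subjects, 32 channels, N = 2048 at
#' 128 Hz, one trial per class); the full-size geometry of a 32-subject,
#' N = 8064 EEG study is available by overriding `n_subjects` and `N`.
#'
#' @param n_subjects Number of subjects (>= 2, default 8).
#' @param class_labels Character vector of class labels (default
#'   `c("happy", "sad")`).
#' @param trials_per_class Trials per subject per class (default 1).
#' @param M Channels (default 32).
#' @param N Samples per trial (default 2048).
#' @param sample_rate_hz Sampling rate (default 128).
#' @param separation Class separation delta >= 0 scaling the radial
#'   envelope (default 1); 0 makes classes exchangeable.
#' @param subject_variability Amplitude of the subject-specific component of
#'   the base waveforms relative to the shared component (default 0.5).
#' @param noise_sd Standard deviation of the additive white noise
#'   (default 1).
#' @param seed Integer seed making the dataset fully reproducible.
#' @return An `spsp_synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 8L, class_labels = c("happy", "sad"),
                           trials_per_class = 1L, M = 32L, N = 2048L,
                           sample_rate_hz = 128, separation = 1,
                           subject_variability = 0.5, noise_sd = 1,
                           seed = 1L) {
  if (!is_count(n_subjects, min = 2L)) stop_domain("'n_subjects' must be an integer >= 2")
  if (!is.character(class_labels) || length(class_labels) < 1L ||
      anyDuplicated(class_labels))
    stop_domain("'class_labels' must be distinct non-empty strings")
  if (!is_count(trials_per_class)) stop_domain("'trials_per_class' must be a positive integer")
  if (!is_count(M)) stop_domain("'M' must be a positive integer")
  if (!is_count(N, min = 2L)) stop_domain("'N' must be an integer >= 2")
  if (!is_number(sample_rate_hz) || sample_rate_hz <= 0)
    stop_domain("'sample_rate_hz' must be positive")
  if (!is_number(separation) || separation < 0)
    stop_domain("'separation' must be >= 0")
  if (!is_number(subject_variability) || subject_variability < 0)
    stop_domain("'subject_variability' must be >= 0")
  if (!is_number(noise_sd) || noise_sd <= 0)
    stop_domain("'noise_sd' must be positive")
  if (!is_count(seed, min = 0L)) stop_domain("'seed' must be a nonnegative integer")
  structure(list(n_subjects = as.integer(n_subjects),
                 class_labels = class_labels,
                 trials_per_class = as.integer(trials_per_class),
                 M = as.integer(M), N = as.integer(N),
                 sample_rate_hz = sample_rate_hz, separation = separation,
                 subject_variability = subject_variability,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spsp_synthetic_spec")
}

# Smooth unit-sd waveform: white Gaussian noise convolved with a boxcar of
# `window` samples (circular padding avoids edge NAs), rescaled to sd 1.
smooth_waveform <- function(n, window) {
  z <- stats::rnorm(n + window)
  s <- stats::filter(z, rep(1 / window, window), sides = 2L)
  s <- s[!is.na(s)][seq_len(n)]
  as.numeric(s) / stats::sd(s)
}

#' Generate a synthetic dataset
#'
#' Draws the dataset described by `spec` (see the model at the top of this
#' file).  All randomness flows from `spec$seed` through pre-drawn
#' sub-seeds, so the same spec yields a bit-identical dataset every time.
#'
#' @param spec An [synthetic_spec()].
#' @param dir If non-NULL, the trials are also written as CSV matrix files
#'   plus a `manifest.json` in this directory (created if needed).
#' @return List of [recording()] objects (one per subject x class x trial),
#'   with the manifest entry data frame attached as attribute `"entries"`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  if (!inherits(spec, "spsp_synthetic_spec"))
    stop_domain("'spec' must be an spsp_synthetic_spec")
  n_trials <- spec$n_subjects * length(spec$class_labels) * spec$trials_per_class
  set.seed(spec$seed)
  seed_cap <- 2147483646L
  common_seed <- sample.int(seed_cap, 1L)
  subject_seeds <- sample.int(seed_cap, spec$n_subjects)
  trial_seeds <- sample.int(seed_cap, n_trials)
  window <- max(2L, spec$N %/% 64L)

  set.seed(common_seed)
  base <- t(vapply(seq_len(spec$M), function(m) smooth_waveform(spec$N, window),
                   numeric(spec$N)))
  w <- (1 + sin(2 * pi * 3 * seq_len(spec$N) / spec$N)) / 2

  recs <- vector("list", n_trials)
  entries <- data.frame(file_path = character(n_trials),
                        subject_id = character(n_trials),
                        trial_id = character(n_trials),
                        label = character(n_trials),
                        stringsAsFactors = FALSE)
  k <- 0L; t_idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%02d", s)
    set.seed(subject_seeds[s])
    subj_dev <- t(vapply(seq_len(spec$M),
                         function(m) smooth_waveform(spec$N, window),
                         numeric(spec$N)))
    g <- base + spec$subject_variability * subj_dev
    for (c_i in seq_along(spec$class_labels)) {
      envelope <- 1 + spec$separation * (c_i - 1L) * w
      for (r in seq_len(spec$trials_per_class)) {
        k <- k + 1L; t_idx <- t_idx + 1L
        set.seed(trial_seeds[t_idx])
        noise <- matrix(stats::rnorm(spec$M * spec$N, sd = spec$noise_sd),
                        spec$M, spec$N)
        x <- g * rep(envelope, each = spec$M) + noise
        tid <- sprintf("%s_r%02d", spec$class_labels[c_i], r)
        recs[[k]] <- recording(x, subject_id = sid, trial_id = tid,
                               label = spec$class_labels[c_i],
                               sample_rate_hz = spec$sample_rate_hz)
        entries$file_path[k] <- sprintf("%s_%s.csv", sid, tid)
        entries$subject_id[k] <- sid
        entries$trial_id[k] <- tid
        entries$label[k] <- spec$class_labels[c_i]
      }
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(recs))
      write_recording(recs[[i]], file.path(dir, entries$file_path[i]))
    write_manifest(entries, file.path(dir, "manifest.json"),
                   channel_count = spec$M,
                   sample_rate_hz = spec$sample_rate_hz,
                   extra = list(seed = spec$seed))
  }
  attr(recs, "entries") <- entries
  recs
}

#' Generate a tie-free random distance series
#'
#' Fixture generator: n i.i.d. uniform(0, 1) draws, which are tie-free with
#' probability 1, packaged as a distance series for the symbolisation
#' routines.
#'
#' @param n Length (integer >= 2).
#' @param seed Integer seed.
#' @return An `spsp_distance_series`.
#' @export
generate_distance_series <- function(n, seed = 1L) {
  if (!is_count(n, min = 2L)) stop_domain("'n' must be an integer >= 2")
  if (!is_count(seed, min = 0L)) stop_domain("'seed' must be a nonnegative integer")
  set.seed(seed)
  distance_series(stats::runif(n), subject_id = "synthetic",
                  trial_id = sprintf("u%d", seed))
}
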