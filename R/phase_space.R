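#' Build the channel-space trajectory of a recording
#'
#' Each sample n of an M-channel recording is read as one point
#' x(n) = (x_1(n), ..., x_M(n)) in M-dimensional space; the trajectory is the
#' ordered set of all N such points, stored as the M x N matrix of the
#' recording itself.  No resampling and no time-delay embedding is applied:
#' the phase space is the instantaneous channel vector.
#'
#' @param rec An [recording()] object.
#' @return An object of class `spsp_trajectory` with fields `points`
#'   (M x N matrix), `subject_id`, `trial_id`, `label`.
#' @seealso [compute_center()], [radial_distances()]
#' @export
build_trajectory <- function(rec) {
  if (!inherits(rec, "spsp_recording"))
    stop_domain("'rec' must be an spsp_recording")
  structure(
    list(points = rec$data, subject_id = rec$subject_id,
         trial_id = rec$trial_id, label = rec$label),
    class = "spsp_trajectory"
  )
}

#' Centre of the trajectory's bounding hypersphere
#'
#' The centre is the mean point of the trajectory: coordinate i is the
#' arithmetic mean of channel i over all N samples.
#'
#' @param trajectory An `spsp_trajectory`.
#' @return An `spsp_center`: list with `coordinates`, a length-M numeric
#'   vector.
#' @export
compute_center <- function(trajectory) {
  if (!inherits(trajectory, "spsp_trajectory"))
    stop_domain("'trajectory' must be an spsp_trajectory")
  if (ncol(trajectory$points) < 1L)
    stop_domain("cannot compute the centre of an empty trajectory")
  structure(list(coordinates = rowMeans(trajectory$points)),
            class = "spsp_center")
}

#' Radial distances of trajectory points from a centre
#'
#' Computes, for every sample n, the Euclidean (L2) distance of the
#' trajectory point x(n) from the centre; concentric shells around this
#' centre are what the symbolisation step partitions.
#'
#' @param trajectory An `spsp_trajectory` with M rows.
#' @param center An `spsp_center` of dimension M (defaults to
#'   `compute_center(trajectory)`).
#' @return An `spsp_distance_series`: list with `values` (nonnegative,
#'   length N), `center`, `subject_id`, `trial_id`, `label`.
#' @export
radial_distances <- function(trajectory, center = compute_center(trajectory)) {
  if (!inherits(trajectory, "spsp_trajectory"))
    stop_domain("'trajectory' must be an spsp_trajectory")
  if (!inherits(center, "spsp_center"))
    stop_domain("'center' must be an spsp_center")
  ctr <- center$coordinates
  if (length(ctr) != nrow(trajectory$points))
    stop_domain(sprintf(
      "centre dimension (%d) does not match trajectory dimension (%d)",
      length(ctr), nrow(trajectory$points)))
  d <- sqrt(colSums((trajectory$points - ctr)^2))
  distance_series(d, center = center, subject_id = trajectory$subject_id,
                  trial_id = trajectory$trial_id, label = trajectory$label)
}

#' Construct a radial-distance series
#'
#' Low-level constructor used by [radial_distances()] and by the synthetic
#' fixture generator; `values` must be nonnegative and finite.
#'
#' @param values Nonnegative numeric vector (length N >= 1).
#' @param center Optional `spsp_center` the distances were measured from.
#' @param subject_id,trial_id,label Optional provenance metadata.
#' @return An `spsp_distance_series`.
#' @export
distance_series <- function(values, center = NULL, subject_id = NA_character_,
                            trial_id = NA_character_, label = NULL) {
  if (!is.numeric(values) || length(values) < 1L)
    stop_domain("'values' must be a non-empty numeric vector")
  if (!all(is.finite(values)) || any(values < 0))
    stop_domain("distance values must be finite and nonnegative")
  structure(
    list(values = as.numeric(values), center = center,
         subject_id = subject_id, trial_id = trial_id, label = label),
    class = "spsp_distance_series"
  )
}

#' @export
print.spsp_distance_series <- function(x, ...) {
  cat(sprintf("<spsp_distance_series> n=%d range=[%g, %g] subject=%s trial=%s\n",
              length(x$values), min(x$values), max(x$values),
              x$subject_id, x$trial_id))
  invisible(x)
}

#' Write a distance series as a one-column CSV
#'
#' One value per line, printed with 17 significant digits so the written
#' file reproduces the doubles bit-faithfully on re-read.
#'
#' @param d An `spsp_distance_series`.
#' @param path Output file path.
#' @export
write_distance_series <- function(d, path) {
  stopifnot(inherits(d, "spsp_distance_series"))
  writeLines(sprintf("%.17g", d$values), path)
  invisible(path)
}
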