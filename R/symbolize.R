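#' Partition specifications
#'
#' A partition of the distance axis into S ordered bins, described by S-1
#' strictly increasing interior edges.  Bin j is the interval
#' (e_(j-1), e_j], open at minus infinity below the first edge and at plus
#' infinity above the last: a value equal to an edge belongs to the lower
#' bin.  This matches the equal-frequency construction in which the first
#' floor(N/S) sorted points form the first bin, so an edge (itself a data
#' point) closes the bin it terminates.
#'
#' @param scheme `"uniform"` or `"max_entropy"`.
#' @param S Alphabet size, integer >= 1.
#' @param edges Strictly increasing numeric vector of length S - 1.
#' @param subject_id,trial_id Provenance of the series the partition was
#'   fitted on.
#' @return An `spsp_partition`.
#' @export
partition_spec <- function(scheme, S, edges,
                           subject_id = NA_character_, trial_id = NA_character_) {
  scheme <- match.arg(scheme, c("uniform", "max_entropy"))
  if (!is_count(S)) stop_domain("'S' must be a positive integer")
  edges <- as.numeric(edges)
  if (length(edges) != S - 1L)
    stop_domain(sprintf("expected %d edges for S = %d, got %d",
                        S - 1L, S, length(edges)))
  if (length(edges) > 1L && any(diff(edges) <= 0))
    stop_domain("partition edges must be strictly increasing")
  structure(list(scheme = scheme, S = as.integer(S), edges = edges,
                 subject_id = subject_id, trial_id = trial_id),
            class = "spsp_partition")
}

#' @export
print.spsp_partition <- function(x, ...) {
  cat(sprintf("<spsp_partition> scheme=%s S=%d\n", x$scheme, x$S))
  if (length(x$edges)) cat("  edges:", format(x$edges, digits = 6), "\n")
  invisible(x)
}

#' Uniform (equal-width) partitioning of a distance series
#'
#' Splits the range between the minimum and maximum of the series into S
#' equal-width regions; the S - 1 interior edges are equally spaced strictly
#' between min and max.
#'
#' @param d An `spsp_distance_series`.
#' @param S Alphabet size, integer >= 2.
#' @return An `spsp_partition` with scheme `"uniform"`.
#' @export
uniform_partition <- function(d, S) {
  if (!inherits(d, "spsp_distance_series"))
    stop_domain("'d' must be an spsp_distance_series")
  if (!is_count(S, min = 2L)) stop_domain("'S' must be an integer >= 2")
  lo <- min(d$values); hi <- max(d$values)
  if (hi <= lo)
    stop_degenerate(paste0(
      "distance series is constant (max == min); uniform partitioning is ",
      "undefined -- a single-symbol alphabet (S = 1) is the only valid coding"))
  edges <- lo + seq_len(S - 1L) * (hi - lo) / S
  partition_spec("uniform", S, edges, d$subject_id, d$trial_id)
}

#' Maximum-entropy (equal-frequency) partitioning of a distance series
#'
#' Sorts the N values ascending and places edge j (j = 1..S-1) at the order
#' statistic of rank floor(j * N / S).  On tie-free data every symbol then
#' occurs floor(N/S) or ceiling(N/S) times, so the empirical symbol
#' distribution is as close to uniform -- and the symbol-sequence entropy as
#' close to its log2(S) maximum -- as the sample allows.
#'
#' @param d An `spsp_distance_series` of length N >= S.
#' @param S Alphabet size, integer >= 2.
#' @return An `spsp_partition` with scheme `"max_entropy"`.
#' @export
max_entropy_partition <- function(d, S) {
  if (!inherits(d, "spsp_distance_series"))
    stop_domain("'d' must be an spsp_distance_series")
  if (!is_count(S, min = 2L)) stop_domain("'S' must be an integer >= 2")
  N <- length(d$values)
  if (N < S)
    stop_domain(sprintf("need at least S = %d values for ME partitioning, got N = %d", S, N))
  v <- sort(d$values)
  ranks <- floor(seq_len(S - 1L) * N / S)
  edges <- v[ranks]
  if (anyDuplicated(edges)) {
    dup <- unique(edges[duplicated(edges)])
    stop_degenerate(sprintf(
      "fewer than %d distinct values: partition edges collapse at {%s}",
      S, paste(format(dup, digits = 10), collapse = ", ")))
  }
  partition_spec("max_entropy", S, edges, d$subject_id, d$trial_id)
}

#' Code a distance series as a symbol sequence
#'
#' Maps each value to the index (1..S) of the bin it falls in:
#' symbol(v) = 1 + #\{edges < v\}.  Every real value maps to exactly one
#' symbol and the map is order preserving; a value exactly equal to an edge
#' takes the lower symbol (see [partition_spec()]).
#'
#' @param d An `spsp_distance_series`.
#' @param partition An `spsp_partition`.
#' @return An `spsp_symbol_sequence`: integer vector `symbols` in 1..S plus
#'   alphabet size `S` and provenance.
#' @export
assign_symbols <- function(d, partition) {
  if (!inherits(d, "spsp_distance_series"))
    stop_domain("'d' must be an spsp_distance_series")
  if (!inherits(partition, "spsp_partition"))
    stop_domain("'partition' must be an spsp_partition")
  sym <- findInterval(d$values, partition$edges, left.open = TRUE) + 1L
  symbol_sequence(sym, S = partition$S, subject_id = d$subject_id,
                  trial_id = d$trial_id, label = d$label)
}

#' Construct a symbol sequence
#'
#' @param symbols Integer vector with values in 1..S.
#' @param S Alphabet size.
#' @param subject_id,trial_id,label Provenance metadata.
#' @return An `spsp_symbol_sequence`.
#' @export
symbol_sequence <- function(symbols, S, subject_id = NA_character_,
                            trial_id = NA_character_, label = NULL) {
  if (!is_count(S)) stop_domain("'S' must be a positive integer")
  symbols <- as.integer(symbols)
  if (length(symbols) < 1L) stop_domain("symbol sequence must be non-empty")
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > S))
    stop_domain(sprintf("symbols must be integers in 1..%d", S))
  structure(list(symbols = symbols, S = as.integer(S),
                 subject_id = subject_id, trial_id = trial_id, label = label),
            class = "spsp_symbol_sequence")
}

#' @export
print.spsp_symbol_sequence <- function(x, ...) {
  cat(sprintf("<spsp_symbol_sequence> n=%d S=%d subject=%s trial=%s label=%s\n",
              length(x$symbols), x$S, x$subject_id, x$trial_id,
              x$label %||% "<none>"))
  invisible(x)
}

#' Shannon entropy of a symbol sequence, in bits
#'
#' H = -sum_i p_i log2 p_i over the symbols that occur, with p_i the
#' empirical frequency.  A sequence using a single symbol has H = 0; the
#' maximum over an alphabet of size S is log2(S), attained at equal
#' frequencies.
#'
#' @param seq An `spsp_symbol_sequence`.
#' @return Entropy in bits (numeric scalar).
#' @export
shannon_entropy <- function(seq) {
  if (!inherits(seq, "spsp_symbol_sequence"))
    stop_domain("'seq' must be an spsp_symbol_sequence")
  counts <- tabulate(seq$symbols, nbins = seq$S)
  p <- counts[counts > 0L] / length(seq$symbols)
  -sum(p * log2(p)) + 0  # "+ 0" folds IEEE -0 (single-symbol case) into 0
}

#' Entropy profile over candidate alphabet sizes
#'
#' For each k = 2..k_max, fits a maximum-entropy partition with k symbols,
#' codes the series, and records the sequence entropy H(k) in bits together
#' with the entropy increment h(k) = H(k) - H(k-1), taking H(1) = 0.  Under
#' exact equal-frequency coding H(k) ~= log2(k), so h(k) ~= log2(k/(k-1))
#' decays towards 0; the selected alphabet size is the smallest k whose
#' increment falls strictly below `epsilon_h`.
#'
#' @param d An `spsp_distance_series` with at least `k_max` values.
#' @param k_max Largest alphabet size examined (integer >= 2, default 64).
#' @param epsilon_h Increment threshold in bits, in the open interval (0, 1);
#'   default 0.2.
#' @return An `spsp_entropy_profile`: list with `k` (1..k_max), `H` (bits,
#'   `H[1] = 0`), `h` (NA at k = 1, increments elsewhere), `epsilon_h`, and
#'   `selected_S` (integer, or NA if no increment dropped below the
#'   threshold by `k_max`).
#' @export
entropy_profile <- function(d, k_max = 64L, epsilon_h = 0.2) {
  if (!inherits(d, "spsp_distance_series"))
    stop_domain("'d' must be an spsp_distance_series")
  if (!is_number(epsilon_h) || epsilon_h <= 0 || epsilon_h >= 1)
    stop_config("'epsilon_h' must lie in the open interval (0, 1)")
  if (!is_count(k_max, min = 2L)) stop_config("'k_max' must be an integer >= 2")
  if (length(d$values) < k_max)
    stop_domain(sprintf("series length %d is smaller than k_max = %d",
                        length(d$values), k_max))
  H <- numeric(k_max)
  for (k in 2:k_max) {
    part <- tryCatch(max_entropy_partition(d, k), spsp_degenerate_error = function(e) {
      stop_degenerate(sprintf("at k = %d: %s", k, conditionMessage(e)))
    })
    H[k] <- shannon_entropy(assign_symbols(d, part))
  }
  h <- c(NA_real_, diff(H))
  below <- which(!is.na(h) & h < epsilon_h)
  structure(
    list(k = seq_len(k_max), H = H, h = h, epsilon_h = epsilon_h,
         selected_S = if (length(below)) as.integer(min(below)) else NA_integer_,
         subject_id = d$subject_id, trial_id = d$trial_id),
    class = "spsp_entropy_profile"
  )
}

#' @export
print.spsp_entropy_profile <- function(x, ...) {
  cat(sprintf("<spsp_entropy_profile> k_max=%d epsilon_h=%g selected_S=%s\n",
              max(x$k), x$epsilon_h,
              if (is.na(x$selected_S)) "<none>" else x$selected_S))
  invisible(x)
}

#' Select the alphabet size by the entropy-increment rule
#'
#' Starting at k = 2, grows the maximum-entropy alphabet until the entropy
#' increment h(k) = H(k) - H(k-1) first drops strictly below `epsilon_h`,
#' and returns that k.  The loop is capped at `k_max` to guarantee
#' termination; failing to converge by then raises an error reporting the
#' final increment.
#'
#' @inheritParams entropy_profile
#' @return The selected alphabet size S (integer scalar).
#' @export
select_symbol_count <- function(d, epsilon_h = 0.2, k_max = 64L) {
  if (!inherits(d, "spsp_distance_series"))
    stop_domain("'d' must be an spsp_distance_series")
  if (!is_number(epsilon_h) || epsilon_h <= 0 || epsilon_h >= 1)
    stop_config("'epsilon_h' must lie in the open interval (0, 1)")
  if (!is_count(k_max, min = 2L)) stop_config("'k_max' must be an integer >= 2")
  H_prev <- 0
  for (k in 2:k_max) {
    H_k <- shannon_entropy(assign_symbols(d, max_entropy_partition(d, k)))
    h_k <- H_k - H_prev
    if (h_k < epsilon_h) return(as.integer(k))
    H_prev <- H_k
  }
  stop_not_converged(sprintf(
    "entropy increment never fell below epsilon_h = %g by k_max = %d (final h = %.6g bits)",
    epsilon_h, k_max, h_k), final_h = h_k)
}

#' Histogram of symbol words
#'
#' Classical symbolic analysis groups consecutive symbols into words and
#' tabulates their occurrence; this helper counts all `word_length`-grams
#' taken every `stride` symbols.
#'
#' @param seq An `spsp_symbol_sequence` of length N.
#' @param word_length Word length (1 <= word_length <= N).
#' @param stride Step between successive window starts (>= 1, default 1).
#' @return Named integer vector; names are words written as
#'   hyphen-separated symbols (e.g., `"1-2-1"`), values are counts summing
#'   to `floor((N - word_length)/stride) + 1`.
#' @export
word_histogram <- function(seq, word_length, stride = 1L) {
  if (!inherits(seq, "spsp_symbol_sequence"))
    stop_domain("'seq' must be an spsp_symbol_sequence")
  N <- length(seq$symbols)
  if (!is_count(word_length) || word_length > N)
    stop_domain(sprintf("'word_length' must be an integer in 1..%d", N))
  if (!is_count(stride)) stop_domain("'stride' must be a positive integer")
  starts <- seq.int(1L, N - word_length + 1L, by = stride)
  words <- vapply(starts, function(i)
    paste(seq$symbols[i:(i + word_length - 1L)], collapse = "-"), character(1))
  tab <- table(words)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Write a symbol sequence as a single-line CSV of integers
#'
#' @param seq An `spsp_symbol_sequence`.
#' @param path Output file path.
#' @export
write_symbol_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "spsp_symbol_sequence"))
  writeLines(paste(seq$symbols, collapse = ","), path)
  invisible(path)
}

#' Write an entropy profile as CSV with columns k, H, h
#'
#' @param profile An `spsp_entropy_profile`.
#' @param path Output file path.
#' @export
write_entropy_profile <- function(profile, path) {
  stopifnot(inherits(profile, "spsp_entropy_profile"))
  lines <- c("k,H,h",
             sprintf("%d,%.17g,%s", profile$k, profile$H,
                     ifelse(is.na(profile$h), "NA", sprintf("%.17g", profile$h))))
  writeLines(lines, path)
  invisible(path)
}
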