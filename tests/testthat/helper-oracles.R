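# Independent oracles: deliberately naive re-implementations used to check
# the package's vectorised code paths.

# Equal-frequency edges by full sort and direct rank lookup.
oracle_me_edges <- function(values, S) {
  v <- sort(values)
  n <- length(values)
  sapply(seq_len(S - 1L), function(j) v[floor(j * n / S)])
}

# Linear scan over bins, edge value belongs to the lower bin.
oracle_assign <- function(values, edges) {
  vapply(values, function(v) {
    sym <- 1L
    for (e in edges) if (v > e) sym <- sym + 1L
    sym
  }, integer(1))
}

oracle_entropy <- function(symbols) {
  p <- as.numeric(table(symbols)) / length(symbols)
  -sum(p * log2(p))
}

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# 99% two-sided check that replicate accuracies are centred on p0.  The
# trials inside one replicate share templates, so they are positively
# correlated and a plain binomial band on the pooled count under-covers;
# the t-interval on the iid replicate means is the honest version.
expect_chance <- function(accs, p0) {
  R <- length(accs)
  half <- stats::qt(0.995, R - 1) * stats::sd(accs) / sqrt(R)
  testthat::expect_lte(abs(mean(accs) - p0), half)
}

# Shorthand constructors for classifier tests.
seq_of <- function(symbols, S, subject = "s1", trial = "t1", label = NULL) {
  symbol_sequence(symbols, S = S, subject_id = subject, trial_id = trial,
                  label = label)
}

# A toy labelled sequence set: each class has a distinct deterministic
# motif per subject, plus optional per-trial jitter via flipping entries.
toy_sequences <- function(n_subjects, class_motifs, S, len = 24L) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (lab in names(class_motifs)) {
      motif <- rep_len(class_motifs[[lab]], len)
      out[[length(out) + 1L]] <- seq_of(motif, S,
                                        subject = sprintf("sub%02d", s),
                                        trial = paste0(lab, "_r01"),
                                        label = lab)
    }
  }
  out
}
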