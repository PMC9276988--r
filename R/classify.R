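#' Cosine similarity between two numeric vectors
#'
#' The inner product of the two vectors divided by the product of their
#' Euclidean norms; lies in \[-1, 1\], is symmetric, and is invariant to
#' positive rescaling of either argument, so it compares direction only.
#'
#' @param A,B Numeric vectors of equal length with nonzero norm.
#' @return Numeric scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(A, B) {
  if (!is.numeric(A) || !is.numeric(B))
    stop_domain("'A' and 'B' must be numeric vectors")
  if (length(A) != length(B))
    stop_domain(sprintf("length mismatch: %d vs %d", length(A), length(B)))
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0)
    stop_domain("cosine similarity is undefined for a zero-norm vector")
  sum(A * B) / (na * nb)
}

#' Build per-class template (index) vectors from training sequences
#'
#' The template of a class is the elementwise arithmetic mean of the symbol
#' vectors (integers 1..S treated as ordinal numeric codes) of all training
#' trials carrying that label, with equal weight per trial.  Every template
#' entry therefore lies in \[1, S\].
#'
#' @param training List of `spsp_symbol_sequence` objects, all of the same
#'   length and alphabet, each with a non-NULL label.
#' @param class_labels Optional character vector fixing which labels get a
#'   template (each must have at least one training sequence); defaults to
#'   all labels present, in order of first appearance.
#' @param weighting `"per_trial"` (default): every training trial counts
#'   equally; `"per_subject"`: trials are first averaged within subject,
#'   then subject means are averaged, so subjects with many trials do not
#'   dominate the template.
#' @return Named list of `spsp_class_index` objects (fields `label`,
#'   `template`, `n_contributors`), one per class label, in `class_labels`
#'   order.
#' @export
build_class_indices <- function(training, class_labels = NULL,
                                weighting = c("per_trial", "per_subject")) {
  weighting <- match.arg(weighting)
  if (!is.list(training) || length(training) == 0L)
    stop_domain("'training' must be a non-empty list of symbol sequences")
  if (!all(vapply(training, inherits, logical(1), "spsp_symbol_sequence")))
    stop_domain("every element of 'training' must be an spsp_symbol_sequence")
  labs <- vapply(training, function(s) s$label %||% NA_character_, character(1))
  if (anyNA(labs)) stop_domain("every training sequence must carry a label")
  lens <- vapply(training, function(s) length(s$symbols), integer(1))
  if (length(unique(lens)) != 1L)
    stop_domain(sprintf("training sequences have mixed lengths: {%s}",
                        paste(sort(unique(lens)), collapse = ", ")))
  Ss <- vapply(training, function(s) s$S, integer(1))
  if (length(unique(Ss)) != 1L)
    stop_domain("training sequences have mixed alphabet sizes")
  if (is.null(class_labels)) class_labels <- unique(labs)
  indices <- lapply(class_labels, function(lab) {
    members <- training[labs == lab]
    if (length(members) == 0L)
      stop_domain(sprintf("class '%s' has no training sequence", lab))
    if (weighting == "per_subject") {
      sids <- vapply(members, function(s) s$subject_id, character(1))
      members <- lapply(unique(sids), function(sid) {
        grp <- members[sids == sid]
        list(symbols = Reduce(`+`, lapply(grp, function(s)
          as.numeric(s$symbols))) / length(grp))
      })
    }
    acc <- Reduce(`+`, lapply(members, function(s) as.numeric(s$symbols)))
    structure(list(label = lab, template = acc / length(members),
                   n_contributors = length(members)),
              class = "spsp_class_index")
  })
  names(indices) <- class_labels
  indices
}

#' Classify a symbol sequence against class templates
#'
#' Scores the sequence (as its raw integer vector) against every class
#' template with [cosine_similarity()] and predicts the class attaining the
#' maximum.  Exact ties are broken deterministically in favour of the label
#' that comes first in the template order, with a warning.
#'
#' @param seq An `spsp_symbol_sequence`.
#' @param indices Named list of `spsp_class_index` templates (>= 2 classes),
#'   as built by [build_class_indices()].
#' @return An `spsp_similarity`: list with `per_label` (named numeric
#'   scores), `predicted` (label), `tie_flag` (TRUE iff the maximum was
#'   attained by two or more labels).
#' @export
classify_sequence <- function(seq, indices) {
  if (!inherits(seq, "spsp_symbol_sequence"))
    stop_domain("'seq' must be an spsp_symbol_sequence")
  if (!is.list(indices) || length(indices) < 2L)
    stop_domain("'indices' must contain at least two class templates")
  x <- as.numeric(seq$symbols)
  scores <- vapply(indices, function(idx) {
    if (length(idx$template) != length(x))
      stop_domain(sprintf(
        "sequence length %d does not match template length %d for class '%s'",
        length(x), length(idx$template), idx$label))
    cosine_similarity(x, idx$template)
  }, numeric(1))
  winners <- which(scores == max(scores))
  tie <- length(winners) > 1L
  if (tie)
    warning(sprintf("similarity tie between {%s}; predicting '%s'",
                    paste(names(scores)[winners], collapse = ", "),
                    names(scores)[winners[1L]]), call. = FALSE)
  structure(list(per_label = scores, predicted = names(scores)[winners[1L]],
                 tie_flag = tie),
            class = "spsp_similarity")
}

#' Leave-one-subject-out evaluation
#'
#' For every subject in turn, class templates are built from all remaining
#' subjects' trials and each of the held-out subject's trials is classified
#' by maximum cosine similarity.  Confusion counts are accumulated over all
#' folds; trials whose label is not in `class_labels` are ignored.
#'
#' @param sequences List of `spsp_symbol_sequence` objects, each with
#'   `subject_id` and `label` set.
#' @param class_labels Ordered character vector of class labels (>= 2); the
#'   order fixes the confusion-matrix layout and the tie-break preference.
#' @param details If TRUE the returned report additionally carries a `folds`
#'   list with each fold's templates and per-trial predictions (used, e.g.,
#'   to audit that held-out data never reaches training).
#' @param weighting Template weighting, passed to [build_class_indices()].
#' @return An `spsp_eval_report`: `labels`, `confusion` (target rows x
#'   predicted columns), `per_class_accuracy`, `per_subject_accuracy`
#'   (named), `total_accuracy_mean_subject` (mean of per-subject
#'   accuracies), `total_accuracy_micro` (trace/total), `n_folds`.
#' @export
loso_evaluate <- function(sequences, class_labels, details = FALSE,
                          weighting = c("per_trial", "per_subject")) {
  weighting <- match.arg(weighting)
  if (!is.list(sequences) ||
      !all(vapply(sequences, inherits, logical(1), "spsp_symbol_sequence")))
    stop_domain("'sequences' must be a list of spsp_symbol_sequence objects")
  if (!is.character(class_labels) || length(class_labels) < 2L ||
      anyDuplicated(class_labels))
    stop_protocol("'class_labels' must be >= 2 distinct labels")
  labs <- vapply(sequences, function(s) s$label %||% NA_character_, character(1))
  keep <- !is.na(labs) & labs %in% class_labels
  sequences <- sequences[keep]; labs <- labs[keep]
  subjects <- vapply(sequences, function(s) s$subject_id, character(1))
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 2L)
    stop_protocol("leave-one-subject-out requires at least 2 subjects")
  for (sid in subj_ids) {
    missing <- setdiff(class_labels, labs[subjects == sid])
    if (length(missing))
      stop_protocol(sprintf("subject '%s' has no trial for class '%s'",
                            sid, missing[1L]))
  }
  confusion <- matrix(0L, length(class_labels), length(class_labels),
                      dimnames = list(target = class_labels,
                                      predicted = class_labels))
  per_subject <- stats::setNames(numeric(length(subj_ids)), subj_ids)
  folds <- if (details) stats::setNames(vector("list", length(subj_ids)), subj_ids)
  for (sid in subj_ids) {
    train <- sequences[subjects != sid]
    test  <- sequences[subjects == sid]
    indices <- build_class_indices(train, class_labels, weighting = weighting)
    preds <- character(length(test))
    for (i in seq_along(test)) {
      res <- classify_sequence(test[[i]], indices)
      preds[i] <- res$predicted
      confusion[test[[i]]$label, res$predicted] <-
        confusion[test[[i]]$label, res$predicted] + 1L
    }
    per_subject[sid] <-
      mean(preds == vapply(test, function(s) s$label, character(1)))
    if (details)
      folds[[sid]] <- list(indices = indices, predicted = preds,
                           truth = vapply(test, function(s) s$label, character(1)))
  }
  acc <- accuracy_from_confusion(confusion)
  structure(
    list(labels = class_labels, confusion = confusion,
         per_class_accuracy = acc$per_class,
         per_subject_accuracy = per_subject,
         total_accuracy_mean_subject = mean(per_subject),
         total_accuracy_micro = acc$micro,
         n_folds = length(subj_ids),
         folds = if (details) folds),
    class = "spsp_eval_report"
  )
}

#' Per-class and micro accuracy from a confusion matrix
#'
#' @param confusion Square nonnegative integer matrix, targets in rows and
#'   predictions in columns, with at least one positive row sum.
#' @return List with `per_class` (diagonal over row sums, NA for empty
#'   rows) and `micro` (trace over total count).
#' @export
accuracy_from_confusion <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop_domain("'confusion' must be a square matrix")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop_domain("'confusion' must contain nonnegative integers")
  rs <- rowSums(confusion)
  if (sum(rs) <= 0) stop_domain("'confusion' has no observations")
  per_class <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  names(per_class) <- rownames(confusion)
  list(per_class = per_class, micro = sum(diag(confusion)) / sum(confusion))
}

#' @export
print.spsp_eval_report <- function(x, ...) {
  cat(sprintf("<spsp_eval_report> %d classes, %d folds\n",
              length(x$labels), x$n_folds))
  print(x$confusion)
  cat(sprintf("  micro accuracy: %.4f | mean per-subject accuracy: %.4f\n",
              x$total_accuracy_micro, x$total_accuracy_mean_subject))
  invisible(x)
}
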