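test_that("cosine similarity matches hand values and rejects bad input", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2)
  expect_error(cosine_similarity(1:3, 1:4), class = "spsp_domain_error")
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "spsp_domain_error")
})

test_that("cosine similarity is bounded, symmetric, scale invariant, and oracle-exact", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    a <- rnorm(n); b <- rnorm(n); c <- runif(1, 1e-3, 1e3)
    s <- cosine_similarity(a, b)
    expect_lte(abs(s), 1 + 1e-12)
    expect_equal(s, cosine_similarity(b, a))
    expect_equal(s, cosine_similarity(a, c * b), tolerance = 1e-12)
    expect_equal(s, oracle_cosine(a, b))
  }
})

test_that("class templates are equal-weight elementwise means of symbol vectors", {
  s1 <- seq_of(c(1L, 1L), S = 3, label = "a")
  s2 <- seq_of(c(3L, 3L), S = 3, subject = "s2", label = "a")
  idx <- build_class_indices(list(s1, s2))
  expect_equal(idx$a$template, c(2, 2))
  expect_equal(idx$a$n_contributors, 2L)
  expect_equal(build_class_indices(list(s1, s1))$a$template, c(1, 1))

  # random sequences vs independent accumulation oracle
  set.seed(21)
  seqs <- lapply(1:6, function(i)
    seq_of(sample(1:4, 30, TRUE), S = 4, subject = paste0("s", i),
           label = if (i %% 2) "x" else "y"))
  idx <- build_class_indices(seqs)
  expect_identical(names(idx), c("x", "y"))
  for (lab in c("x", "y")) {
    members <- Filter(function(s) s$label == lab, seqs)
    acc <- rep(0, 30)
    for (s in members) for (j in 1:30) acc[j] <- acc[j] + s$symbols[j]
    expect_equal(idx[[lab]]$template, acc / length(members))
    expect_true(all(idx[[lab]]$template >= 1 & idx[[lab]]$template <= 4))
  }

  expect_error(build_class_indices(list(s1, seq_of(1:3, S = 3, label = "a"))),
               "mixed lengths", class = "spsp_domain_error")
  expect_error(build_class_indices(list(s1), class_labels = c("a", "ghost")),
               "ghost", class = "spsp_domain_error")
})

test_that("per-subject weighting averages within subject before across subjects", {
  # subject s1 contributes two trials, s2 one; per-trial weighting tilts the
  # template towards s1, per-subject weighting does not
  seqs <- list(seq_of(c(1L, 1L), S = 4, subject = "s1", trial = "t1", label = "a"),
               seq_of(c(1L, 1L), S = 4, subject = "s1", trial = "t2", label = "a"),
               seq_of(c(4L, 4L), S = 4, subject = "s2", trial = "t1", label = "a"))
  expect_equal(build_class_indices(seqs)$a$template, c(2, 2))
  expect_equal(build_class_indices(seqs, weighting = "per_subject")$a$template,
               c(2.5, 2.5))
})

test_that("classification takes the argmax with deterministic tie-breaks", {
  train <- list(seq_of(c(1L, 1L, 4L, 4L), S = 4, label = "a"),
                seq_of(c(4L, 4L, 1L, 1L), S = 4, subject = "s2", label = "b"))
  idx <- build_class_indices(train)
  res <- classify_sequence(train[[1]], idx)
  expect_identical(res$predicted, "a")
  expect_equal(res$per_label[["a"]], 1)
  expect_false(res$tie_flag)

  # 3-class toy with hand-computed cosines on length-4 vectors
  idx3 <- list(
    a = structure(list(label = "a", template = c(1, 2, 1, 2), n_contributors = 1L),
                  class = "spsp_class_index"),
    b = structure(list(label = "b", template = c(2, 1, 2, 1), n_contributors = 1L),
                  class = "spsp_class_index"),
    c = structure(list(label = "c", template = c(1, 1, 1, 2), n_contributors = 1L),
                  class = "spsp_class_index"))
  q <- seq_of(c(1L, 2L, 1L, 2L), S = 2)
  res3 <- classify_sequence(q, idx3)
  hand <- c(a = 10 / sqrt(10 * 10), b = 8 / sqrt(10 * 10),
            c = 8 / sqrt(10 * 7))
  expect_equal(res3$per_label, hand)
  expect_identical(res3$predicted, "a")

  # forced tie -> first label in template order wins, flag set, warning
  tie_idx <- idx3[c("a", "b")]
  tie_idx$b$template <- tie_idx$a$template
  expect_warning(res_tie <- classify_sequence(q, tie_idx), "tie")
  expect_true(res_tie$tie_flag)
  expect_identical(res_tie$predicted, "a")

  expect_error(classify_sequence(seq_of(1:3, S = 4), idx),
               class = "spsp_domain_error")
})

test_that("LOSO separates perfectly separable classes and enforces protocol", {
  seqs <- toy_sequences(4, list(happy = c(1L, 1L, 4L), sad = c(4L, 4L, 1L)), S = 4)
  rep <- loso_evaluate(seqs, c("happy", "sad"))
  expect_equal(rep$total_accuracy_micro, 1)
  expect_equal(rep$total_accuracy_mean_subject, 1)
  expect_equal(unname(diag(rep$confusion)), c(4L, 4L))
  expect_equal(sum(rep$confusion), length(seqs))   # conservation
  expect_equal(rep$n_folds, 4L)

  # subject missing a class -> protocol error naming both
  expect_error(loso_evaluate(seqs[-1], c("happy", "sad")),
               "sub01.*happy", class = "spsp_protocol_error")
  expect_error(loso_evaluate(seqs[1:2], c("happy", "sad")),
               class = "spsp_protocol_error")
  # trials with labels outside class_labels are ignored
  extra <- c(seqs, list(seq_of(rep(2L, 24), S = 4, subject = "sub01",
                               label = "other")))
  expect_equal(loso_evaluate(extra, c("happy", "sad"))$confusion,
               rep$confusion)
})

test_that("LOSO never leaks the held-out subject into training", {
  set.seed(22)
  seqs <- lapply(seq_len(4 * 2), function(i)
    seq_of(sample(1:4, 32, TRUE), S = 4,
           subject = sprintf("sub%02d", (i - 1) %/% 2 + 1),
           trial = paste0("t", i),
           label = c("a", "b")[(i - 1) %% 2 + 1]))
  clean <- loso_evaluate(seqs, c("a", "b"), details = TRUE)
  # corrupt subject 1's sequences wholesale; its own fold must be unchanged
  corrupted <- seqs
  for (i in 1:2) corrupted[[i]]$symbols <- rep(c(1L, 4L), 16)
  dirty <- loso_evaluate(corrupted, c("a", "b"), details = TRUE)
  for (lab in c("a", "b"))
    expect_identical(dirty$folds$sub01$indices[[lab]]$template,
                     clean$folds$sub01$indices[[lab]]$template)
})

test_that("LOSO on permuted labels is indistinguishable from chance", {
  set.seed(23)
  n_subj <- 16L
  accs <- vapply(1:100, function(r) {
    labels <- c("a", "b")
    seqs <- list()
    for (s in seq_len(n_subj)) {
      labs <- sample(labels)  # random assignment: label carries no signal
      for (j in 1:2)
        seqs[[length(seqs) + 1L]] <-
          seq_of(sample(1:4, 48, TRUE), S = 4,
                 subject = sprintf("sub%02d", s), trial = paste0("t", j),
                 label = labs[j])
    }
    loso_evaluate(seqs, labels)$total_accuracy_micro
  }, numeric(1))
  expect_chance(accs, 0.5)
})

test_that("confusion-matrix arithmetic is exact", {
  expect_equal(accuracy_from_confusion(diag(c(5, 5)))$per_class, c(1, 1),
               ignore_attr = TRUE)
  expect_equal(accuracy_from_confusion(diag(c(5, 5)))$micro, 1)
  m <- matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE)
  out <- accuracy_from_confusion(m)
  expect_equal(unname(out$per_class), c(0.75, NA_real_))
  expect_equal(out$micro, 0.75)
  expect_error(accuracy_from_confusion(matrix(0L, 2, 2)),
               class = "spsp_domain_error")
  expect_error(accuracy_from_confusion(matrix(1:6, 2, 3)),
               class = "spsp_domain_error")
})
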