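test_that("uniform partitioning spaces edges equally across the range", {
  d <- distance_series(c(0, 1.3, 2.2, 3.7, 4))
  expect_equal(uniform_partition(d, 4)$edges, c(1, 2, 3))
  expect_equal(uniform_partition(d, 2)$edges, 2)
  set.seed(1)
  dr <- distance_series(runif(200, 3, 11))
  for (S in c(2L, 5L, 9L)) {
    p <- uniform_partition(dr, S)
    widths <- diff(c(min(dr$values), p$edges, max(dr$values)))
    expect_equal(widths, rep((max(dr$values) - min(dr$values)) / S, S),
                 tolerance = 1e-12)
  }
  expect_error(uniform_partition(distance_series(rep(2, 10)), 4),
               class = "spsp_degenerate_error")
})

test_that("ME partitioning places edges at rank floor(j*N/S) order statistics", {
  d8 <- distance_series(1:8)
  p8 <- max_entropy_partition(d8, 4)
  expect_equal(p8$edges, c(2, 4, 6))
  expect_equal(tabulate(assign_symbols(d8, p8)$symbols, 4), c(2L, 2L, 2L, 2L))

  d10 <- distance_series(1:10)
  p10 <- max_entropy_partition(d10, 4)
  expect_equal(p10$edges, c(2, 5, 7))
  expect_equal(tabulate(assign_symbols(d10, p10)$symbols, 4), c(2L, 3L, 2L, 3L))

  expect_error(max_entropy_partition(distance_series(1:3), 4),
               class = "spsp_domain_error")
  expect_error(max_entropy_partition(distance_series(rep(c(1, 2), 10)), 4),
               class = "spsp_degenerate_error")
})

test_that("ME matches the exhaustive quantile oracle and stays within +/-1 occupancy", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(10:100, 1)
    S <- sample(2:min(8, n), 1)
    vals <- runif(n)
    d <- distance_series(vals)
    p <- max_entropy_partition(d, S)
    expect_equal(p$edges, oracle_me_edges(vals, S))
    occ <- tabulate(assign_symbols(d, p)$symbols, S)
    expect_true(all(abs(occ - n / S) <= 1))
  }
})

test_that("ME symbolisation concentrates occupancy evenly where uniform does not", {
  # uniformly sampled sine: uniform bins pile mass at the extremes, ME does not
  d <- distance_series(1 + sin(2 * pi * seq(0, 1, length.out = 1024)))
  occ_me <- tabulate(assign_symbols(d, max_entropy_partition(d, 4))$symbols, 4)
  occ_un <- tabulate(assign_symbols(d, uniform_partition(d, 4))$symbols, 4)
  expect_true(all(abs(occ_me - 256) <= 1))
  # arcsine law: an extreme equal-width bin holds >= 1/3 of the mass (vs 1/4)
  expect_gt(max(occ_un), 1.25 * 256)
})

test_that("symbol assignment is a total, order-preserving map with ties going down", {
  p <- partition_spec("uniform", 4, c(1, 2, 3))
  sym <- function(v) assign_symbols(distance_series(v), p)$symbols
  expect_equal(sym(c(2.5, 0.2, 9)), c(3L, 1L, 4L))
  expect_equal(sym(c(1, 2, 3)), c(1L, 2L, 3L))  # edge value -> lower bin

  set.seed(8)
  for (i in 1:40) {
    edges <- sort(runif(sample(1:6, 1), -2, 2))
    edges <- edges[!duplicated(edges)]
    pp <- partition_spec("uniform", length(edges) + 1L, edges)
    v <- runif(50, -3, 3)
    got <- assign_symbols(distance_series(v - min(v)), pp)$symbols
    # shift to satisfy nonnegativity, then compare against brute force
    expect_equal(got, oracle_assign(v - min(v), edges))
    ord <- order(v)
    expect_true(all(diff(got[ord]) >= 0))
  }
})

test_that("ME symbolisation is invariant to positive rescaling", {
  set.seed(9)
  vals <- runif(300)
  for (c in c(1e-6, 0.5, 3, 1e7)) {
    a <- assign_symbols(distance_series(vals),
                        max_entropy_partition(distance_series(vals), 6))
    b <- assign_symbols(distance_series(c * vals),
                        max_entropy_partition(distance_series(c * vals), 6))
    expect_identical(a$symbols, b$symbols)
  }
})

test_that("Shannon entropy matches closed forms and the oracle", {
  expect_equal(shannon_entropy(seq_of(rep(1L, 100), S = 1)), 0)
  expect_equal(shannon_entropy(seq_of(rep(1:4, 25), S = 4)), 2)
  expect_equal(shannon_entropy(seq_of(c(1, 1, 2, 3), S = 3)), 1.5)
  set.seed(10)
  s <- seq_of(sample(1:5, 200, TRUE), S = 5)
  expect_equal(shannon_entropy(s), oracle_entropy(s$symbols))
  expect_lte(shannon_entropy(s), log2(5))
  expect_error(symbol_sequence(integer(0), S = 3), class = "spsp_domain_error")
})

test_that("entropy profile has H(1)=0, h=diff(H), h(2)=1 and decays monotonically", {
  d <- generate_distance_series(4096, seed = 11)
  prof <- entropy_profile(d, k_max = 16, epsilon_h = 0.2)
  expect_equal(prof$H[1], 0)
  expect_true(is.na(prof$h[1]))
  expect_equal(prof$h[-1], diff(prof$H))
  expect_equal(prof$h[2], 1, tolerance = 1e-3)       # log2(2) under ME
  expect_true(all(diff(prof$h[-1]) < 0))             # strictly decreasing
  expect_true(all(diff(prof$H) > 0))                 # monotone refinement
  expect_equal(prof$H, log2(prof$k), tolerance = 0.01)
  expect_equal(prof$selected_S, 8L)
})

test_that("alphabet-size selection follows the strict threshold rule", {
  d <- generate_distance_series(8064, seed = 12)
  expect_identical(select_symbol_count(d, 0.5), 4L)  # smallest k: log2(k/(k-1)) < 0.5
  expect_identical(select_symbol_count(d, 0.9), 3L)  # h(2)=1 >= 0.9, h(3)~0.585
  # no convergence by k_max -> error reporting the final increment
  expect_error(select_symbol_count(d, 0.05, k_max = 4L),
               "k_max", class = "spsp_not_converged_error")
  expect_error(select_symbol_count(d, 1.2), class = "spsp_config_error")
})

test_that("word histograms agree with exhaustive window enumeration", {
  s <- seq_of(c(1L, 2L, 1L, 2L), S = 2)
  h <- word_histogram(s, 2)
  expect_equal(h[["1-2"]], 2L)
  expect_equal(h[["2-1"]], 1L)

  # word_length 1 recovers symbol frequencies
  set.seed(13)
  r <- seq_of(sample(1:3, 60, TRUE), S = 3)
  h1 <- word_histogram(r, 1)
  expect_equal(unname(h1[as.character(1:3)]), tabulate(r$symbols, 3))

  for (wl in c(2L, 3L)) for (stride in c(1L, 2L)) {
    h <- word_histogram(r, wl, stride)
    starts <- seq(1L, 60L - wl + 1L, by = stride)
    expect_equal(sum(h), length(starts))
    expect_equal(sum(h), (60L - wl) %/% stride + 1L)
    words <- sapply(starts, function(i)
      paste(r$symbols[i:(i + wl - 1L)], collapse = "-"))
    expect_equal(h[sort(unique(words))],
                 vapply(sort(unique(words)),
                        function(w) sum(words == w), integer(1)))
  }
  expect_error(word_histogram(r, 61L), class = "spsp_domain_error")
})

test_that("symbol sequences and entropy profiles export to CSV", {
  dir <- withr::local_tempdir()
  s <- seq_of(c(3L, 1L, 2L), S = 3)
  f <- file.path(dir, "sym.csv")
  write_symbol_sequence(s, f)
  expect_identical(readLines(f), "3,1,2")
  d <- generate_distance_series(256, seed = 14)
  pf <- file.path(dir, "prof.csv")
  write_entropy_profile(entropy_profile(d, k_max = 8, epsilon_h = 0.2), pf)
  tab <- read.csv(pf)
  expect_identical(names(tab), c("k", "H", "h"))
  expect_equal(nrow(tab), 8L)
})
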