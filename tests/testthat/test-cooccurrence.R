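# Document-frequency counting, PMI, and thresholded network construction.

test_that("frequency counts match the definitional examples", {
  bin <- bin_from_token_sets(list(c("a", "b"), "a", c("b", "c")))
  ft <- count_frequencies(bin)
  expect_identical(ft$counts, c(a = 2L, b = 2L, c = 1L))
  expect_identical(ft$n, 3L)

  empty <- bin_from_token_sets(list())
  ft0 <- count_frequencies(empty)
  expect_identical(length(ft0$counts), 0L)
  expect_identical(ft0$n, 0L)
})

test_that("pair counts match the definitional examples", {
  bin <- bin_from_token_sets(list(c("a", "b"), c("a", "b"), "a"))
  ct <- count_pair_frequencies(bin, c("a", "b"))
  expect_identical(ct$count, 2L)
  expect_identical(ct$word_a, "a")
  expect_identical(ct$word_b, "b")
  expect_identical(attr(ct, "n"), 3L)

  disj <- bin_from_token_sets(list("a", "b"))
  expect_identical(nrow(count_pair_frequencies(disj, c("a", "b"))), 0L)
})

test_that("frequency and pair tables equal brute-force recounts on random bins", {
  set.seed(202)
  for (rep in 1:30) {
    sets <- random_token_sets(n_docs = sample(20:200, 1),
                              vocab_size = sample(10:30, 1))
    bin <- bin_from_token_sets(sets)
    ft <- count_frequencies(bin)
    expect_identical(ft$counts, oracle_frequencies(sets))

    vocab <- sample(sort(unique(unlist(sets))),
                    min(20, length(unique(unlist(sets)))))
    ct <- count_pair_frequencies(bin, vocab)
    oc <- oracle_pair_frequencies(sets, vocab)
    expect_equal(as.data.frame(ct), oc, ignore_attr = TRUE)
    # invariant: f(A,B) <= min(f(A), f(B))
    expect_true(all(ct$count <= pmin(ft$counts[ct$word_a],
                                     ft$counts[ct$word_b])))
  }
})

test_that("PMI analytic limits hold exactly", {
  # independence: f_ab/n == (f_a/n)(f_b/n)
  expect_identical(pmi_bits(10, 10, 1, 100), 0)
  # perfect co-occurrence equals a word's self-information -log2 p(A)
  expect_identical(pmi_bits(2, 2, 2, 8), 2)
  expect_identical(pmi_bits(2, 2, 2, 8), -log2(2 / 8))
  # f_ab = 0 is an undefined sentinel, not -Inf
  expect_true(is.na(pmi_bits(5, 5, 0, 50)))
  expect_equal(pmi_bits(4, 5, 3, 20), log2(3))
})

test_that("PMI rejects inconsistent counts", {
  expect_error(pmi_bits(0, 5, 0, 10), "f_a")
  expect_error(pmi_bits(5, 5, 6, 10), "f_ab")
  expect_error(pmi_bits(5, 11, 2, 10), "f_a")
  expect_error(pmi_bits(1, 1, 0, 0), "n")
})

test_that("PMI is symmetric, monotone in f_ab, and bounded by self-information", {
  set.seed(303)
  for (rep in 1:300) {
    n <- sample(2:5000, 1)
    f_a <- sample.int(n, 1); f_b <- sample.int(n, 1)
    f_ab <- sample.int(min(f_a, f_b), 1)
    v <- pmi_bits(f_a, f_b, f_ab, n)
    expect_identical(v, pmi_bits(f_b, f_a, f_ab, n))
    ub <- min(-log2(f_a / n), -log2(f_b / n))
    expect_lte(v, ub + 1e-12)
    if (f_ab == min(f_a, f_b)) expect_equal(v, ub)
    if (f_ab > 1) expect_gt(v, pmi_bits(f_a, f_b, f_ab - 1L, n))
  }
})

test_that("network construction applies strict thresholds", {
  # N=16, f(x)=f(y)=4, f(x,y)=4 -> PMI exactly 2 bits
  sets <- c(replicate(4, c("x", "y"), simplify = FALSE),
            replicate(12, "z", simplify = FALSE))
  bin <- bin_from_token_sets(sets)
  ft <- count_frequencies(bin)
  ct <- count_pair_frequencies(bin, c("x", "y"))

  g <- build_word_network(ft, ct, min_word_count = 3,
                          pmi_threshold_bits = 1.5)
  expect_identical(sort(igraph::V(g)$name), c("x", "y", "z"))
  expect_identical(as.integer(igraph::ecount(g)), 1L)
  expect_identical(igraph::E(g)$pmi_bits, 2)

  # strict edge threshold: 2.0 <= 2.8 drops the edge, keeps the nodes
  g2 <- build_word_network(ft, ct, min_word_count = 3,
                           pmi_threshold_bits = 2.8)
  expect_identical(as.integer(igraph::ecount(g2)), 0L)
  expect_identical(as.integer(igraph::vcount(g2)), 3L)

  # strict node threshold: f = 4 is excluded at min_word_count = 4
  g3 <- build_word_network(ft, ct, min_word_count = 4,
                           pmi_threshold_bits = 0)
  expect_identical(igraph::V(g3)$name, "z")

  # all counts below the threshold -> empty graph
  g4 <- build_word_network(ft, ct, min_word_count = 100,
                           pmi_threshold_bits = 0)
  expect_identical(as.integer(igraph::vcount(g4)), 0L)

  # mismatched N is a consistency error
  other <- bin_from_token_sets(list(c("x", "y")))
  expect_error(build_word_network(ft, count_pair_frequencies(other, c("x", "y"))),
               "disagree")
})

test_that("network equals brute-force construction and is monotone in thresholds", {
  set.seed(404)
  for (rep in 1:10) {
    sets <- random_token_sets(n_docs = 120, vocab_size = 18)
    bin <- bin_from_token_sets(sets)
    ft <- count_frequencies(bin)
    vocab <- names(ft$counts)
    ct <- count_pair_frequencies(bin, vocab)
    mwc <- sample(5:30, 1)
    thr <- runif(1, -1, 2)
    g <- build_word_network(ft, ct, min_word_count = mwc,
                            pmi_threshold_bits = thr)

    # brute force over all word pairs
    keep <- names(ft$counts)[ft$counts > mwc]
    exp_edges <- character(0)
    for (a in keep) for (b in keep) {
      if (a < b) {
        fab <- sum(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
        if (fab > 0) {
          v <- oracle_pmi(ft$counts[[a]], ft$counts[[b]], fab, ft$n)
          if (v > thr) exp_edges <- c(exp_edges, paste(a, b))
        }
      }
    }
    el <- igraph::as_edgelist(g)
    got <- if (nrow(el)) sort(paste(pmin(el[, 1], el[, 2]),
                                    pmax(el[, 1], el[, 2]))) else character(0)
    expect_identical(got, sort(exp_edges))
    expect_setequal(igraph::V(g)$name, keep)

    # raising either threshold never adds nodes or edges
    g_hi <- build_word_network(ft, ct, min_word_count = mwc + 2,
                               pmi_threshold_bits = thr + 0.5)
    expect_true(all(igraph::V(g_hi)$name %in% igraph::V(g)$name))
    el_hi <- igraph::as_edgelist(g_hi)
    got_hi <- if (nrow(el_hi)) paste(pmin(el_hi[, 1], el_hi[, 2]),
                                     pmax(el_hi[, 1], el_hi[, 2])) else character(0)
    expect_true(all(got_hi %in% got))
  }
})

test_that("edge-list writer is sorted and byte-stable", {
  sets <- random_token_sets(50, 12)
  bin <- bin_from_token_sets(sets)
  ft <- count_frequencies(bin)
  ct <- count_pair_frequencies(bin, names(ft$counts))
  g <- build_word_network(ft, ct, min_word_count = 2, pmi_threshold_bits = 0)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f1); write_edge_list(g, f2)
  expect_identical(readLines(f1), readLines(f2))
  body <- utils::read.delim(f1)
  expect_true(all(body$word_a < body$word_b))
  expect_false(is.unsorted(paste(body$word_a, body$word_b)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  expect_true(file.size(gml) > 0)
})
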