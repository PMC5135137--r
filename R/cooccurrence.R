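# Per-bin document-frequency counting, pointwise mutual information, and
# construction of the thresholded weighted word network.

#' Count per-word document frequencies in a bin
#'
#' `f(w)` is the number of documents in the bin whose token set contains
#' word `w` (document-level presence, not raw occurrences).
#'
#' @param bin A `corpus_bin` from [bin_corpus()], or a plain list of
#'   documents.
#' @return A `freq_table`: list with `counts` (named integer vector,
#'   sorted by word) and `n` (number of documents in the bin).
#' @export
count_frequencies <- function(bin) {
  docs <- if (inherits(bin, "corpus_bin")) bin$documents else bin
  n <- length(docs)
  toks <- unlist(lapply(docs, function(d) unique(d$tokens)), use.names = FALSE)
  counts <- if (length(toks)) {
    tab <- table(toks)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  counts <- counts[order(names(counts))]
  structure(list(counts = counts, n = n), class = "freq_table")
}

#' Count pair document co-occurrences in a bin
#'
#' `f(A, B)` is the number of documents containing both `A` and `B`, for
#' unordered pairs of words drawn from `vocabulary`. Only pairs observed
#' at least once are stored. Internally a sparse document-by-word
#' incidence matrix is cross-multiplied; tests compare the result against
#' a naive all-pairs recount.
#'
#' @param bin A `corpus_bin` or list of documents.
#' @param vocabulary Character vector of words to count pairs over
#'   (typically the words passing the node threshold).
#' @return A `cooc_table`: data.frame with columns `word_a`, `word_b`
#'   (with `word_a < word_b`), `count`; attribute `n` holds the bin size.
#' @export
count_pair_frequencies <- function(bin, vocabulary) {
  docs <- if (inherits(bin, "corpus_bin")) bin$documents else bin
  n <- length(docs)
  vocab <- sort(unique(as.character(vocabulary)))
  empty <- data.frame(word_a = character(0), word_b = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (!length(vocab) || !n) {
    return(structure(empty, n = n, class = c("cooc_table", "data.frame")))
  }
  per_doc <- lapply(docs, function(d) {
    m <- match(d$tokens, vocab)
    m[!is.na(m)]
  })
  lens <- lengths(per_doc)
  if (!sum(lens)) {
    return(structure(empty, n = n, class = c("cooc_table", "data.frame")))
  }
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_along(per_doc), lens),
    j = unlist(per_doc, use.names = FALSE),
    x = 1,
    dims = c(length(per_doc), length(vocab))
  )
  cp <- Matrix::crossprod(inc)                  # word x word co-occurrence
  cp <- methods::as(Matrix::triu(cp, k = 1), "TsparseMatrix")
  keep <- cp@x >= 1
  df <- data.frame(
    word_a = vocab[cp@i[keep] + 1L],
    word_b = vocab[cp@j[keep] + 1L],
    count = as.integer(cp@x[keep]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$word_a, df$word_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n = n, class = c("cooc_table", "data.frame"))
}

#' Pointwise mutual information between two words, in bits
#'
#' PMI(A, B) = log2( p(A,B) / (p(A) p(B)) ) = log2( f(A,B) N / (f(A) f(B)) ),
#' where all frequencies count documents in one time bin. It is zero when
#' the two words are independent and equals a word's self-information
#' (-log2 p(A)) under perfect co-occurrence. For `f_ab = 0` the PMI is
#' undefined and `NA` is returned (no edge), never -Inf.
#'
#' All arguments are vectorized and recycled.
#'
#' @param f_a,f_b Document frequencies of the two words (1 <= f <= n).
#' @param f_ab Joint document frequency (0 <= f_ab <= min(f_a, f_b)).
#' @param n Number of documents in the bin (>= 1).
#' @return Numeric vector of PMI values in bits (`NA` where `f_ab` is 0).
#' @examples
#' pmi_bits(10, 10, 1, 100)   # independence: 0 bits
#' pmi_bits(2, 2, 2, 8)       # perfect co-occurrence: -log2(2/8) = 2 bits
#' @export
pmi_bits <- function(f_a, f_b, f_ab, n) {
  k <- max(length(f_a), length(f_b), length(f_ab), length(n))
  f_a <- rep_len(as.numeric(f_a), k); f_b <- rep_len(as.numeric(f_b), k)
  f_ab <- rep_len(as.numeric(f_ab), k); n <- rep_len(as.numeric(n), k)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (any(f_a < 1 | f_a > n) || any(f_b < 1 | f_b > n)) {
    stop("'f_a' and 'f_b' must satisfy 1 <= f <= n", call. = FALSE)
  }
  if (any(f_ab < 0 | f_ab > pmin(f_a, f_b))) {
    stop("'f_ab' must satisfy 0 <= f_ab <= min(f_a, f_b)", call. = FALSE)
  }
  out <- log2(f_ab * n / (f_a * f_b))
  out[f_ab == 0] <- NA_real_
  out
}

#' Build the thresholded weighted word network for one bin
#'
#' Nodes are the words whose document frequency strictly exceeds
#' `min_word_count`; edges join surviving word pairs whose PMI is defined
#' and strictly exceeds `pmi_threshold_bits`, and carry the PMI as weight.
#' Defaults mirror a corpus-scale analysis (words in more than 2000
#' abstracts, edges above 2.8 bits); small corpora need smaller
#' `min_word_count`.
#'
#' @param freq A `freq_table` from [count_frequencies()].
#' @param cooc A `cooc_table` from [count_pair_frequencies()] with the
#'   same `n`.
#' @param min_word_count Node threshold: keep words with
#'   `f(word) > min_word_count` (strict).
#' @param pmi_threshold_bits Edge threshold in bits (strict).
#' @param interval Optional label stored as provenance.
#' @return An [igraph][igraph::igraph-package] graph of class
#'   `word_network`: vertex attribute `doc_frequency`, edge attribute
#'   `pmi_bits`, graph attributes `interval`, `n_documents`,
#'   `min_word_count`, `pmi_threshold_bits`. Vertices are in sorted word
#'   order and edges in sorted `(word_a, word_b)` order.
#' @export
build_word_network <- function(freq, cooc, min_word_count = 2000,
                               pmi_threshold_bits = 2.8, interval = NA) {
  stopifnot(inherits(freq, "freq_table"), inherits(cooc, "cooc_table"))
  n <- freq$n
  if (!identical(as.integer(n), as.integer(attr(cooc, "n")))) {
    stop("frequency and co-occurrence tables disagree on N (",
         n, " vs ", attr(cooc, "n"), ")", call. = FALSE)
  }
  keep <- freq$counts[freq$counts > min_word_count]
  words <- sort(names(keep))
  edges <- data.frame(word_a = character(0), word_b = character(0),
                      pmi_bits = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cooc) && length(words)) {
    sub <- cooc[cooc$word_a %in% words & cooc$word_b %in% words, , drop = FALSE]
    if (nrow(sub)) {
      pmi <- pmi_bits(keep[sub$word_a], keep[sub$word_b], sub$count, n)
      sel <- !is.na(pmi) & pmi > pmi_threshold_bits
      edges <- data.frame(word_a = sub$word_a[sel], word_b = sub$word_b[sel],
                          pmi_bits = pmi[sel], stringsAsFactors = FALSE)
      edges <- edges[order(edges$word_a, edges$word_b), , drop = FALSE]
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = words,
                          doc_frequency = as.integer(keep[words]),
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "interval", as.character(interval))
  g <- igraph::set_graph_attr(g, "n_documents", as.integer(n))
  g <- igraph::set_graph_attr(g, "min_word_count", min_word_count)
  g <- igraph::set_graph_attr(g, "pmi_threshold_bits", pmi_threshold_bits)
  class(g) <- c("word_network", class(g))
  g
}

#' @export
print.word_network <- function(x, ...) {
  cat(sprintf("Word network [%s]: %d words, %d edges (f > %s, PMI > %s bits, N = %d)\n",
              igraph::graph_attr(x, "interval"),
              igraph::vcount(x), igraph::ecount(x),
              format(igraph::graph_attr(x, "min_word_count")),
              format(igraph::graph_attr(x, "pmi_threshold_bits")),
              igraph::graph_attr(x, "n_documents")))
  invisible(x)
}

#' Write a word network as a sorted TSV edge list
#'
#' Columns `word_a`, `word_b`, `pmi_bits` with `word_a < word_b`, sorted
#' lexicographically; PMI serialized to 6 decimal places so files are
#' byte-stable across runs.
#'
#' @param graph A `word_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  pmi <- igraph::edge_attr(graph, "pmi_bits")
  lines <- "word_a\tword_b\tpmi_bits"
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    lines <- c(lines, sprintf("%s\t%s\t%.6f", a[o], b[o], pmi[o]))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a word network as GraphML
#'
#' @param graph A `word_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- graph
  class(g) <- setdiff(class(g), "word_network")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
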