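# Independent brute-force oracles and random-instance generators used
# across the suite. Everything here is deliberately naive and shares no
# code path with the package implementation.

# exact PMI via a reduced integer fraction: log2(p) - log2(q)
oracle_pmi <- function(f_a, f_b, f_ab, n) {
  if (f_ab == 0) return(NA_real_)
  num <- as.numeric(f_ab) * n
  den <- as.numeric(f_a) * f_b
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(num, den)
  log2(num / d) - log2(den / d)
}

# per-word document frequencies by an explicit per-word loop
oracle_frequencies <- function(token_sets) {
  words <- sort(unique(unlist(token_sets)))
  counts <- vapply(words, function(w) {
    sum(vapply(token_sets, function(s) w %in% s, logical(1)))
  }, integer(1))
  stats::setNames(counts, words)
}

# pair co-occurrence by an all-pairs double loop over the vocabulary
oracle_pair_frequencies <- function(token_sets, vocab) {
  vocab <- sort(vocab)
  out <- list()
  for (i in seq_along(vocab)) {
    for (j in seq_along(vocab)) {
      if (i >= j) next
      cnt <- sum(vapply(token_sets, function(s) {
        (vocab[i] %in% s) && (vocab[j] %in% s)
      }, logical(1)))
      if (cnt >= 1) {
        out[[length(out) + 1L]] <- data.frame(
          word_a = vocab[i], word_b = vocab[j], count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(word_a = character(0), word_b = character(0),
                      count = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$word_a, df$word_b), , drop = FALSE]
}

# maximal cliques by testing every vertex subset (adjacency matrix input;
# feasible only for small n)
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  names <- rownames(adj)
  is_clique <- function(idx) {
    if (length(idx) <= 1L) return(TRUE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx) || !is_clique(idx)) next
    cliques[[length(cliques) + 1L]] <- idx
  }
  maximal <- Filter(function(c1) {
    !any(vapply(cliques, function(c2) {
      length(c2) > length(c1) && all(c1 %in% c2)
    }, logical(1)))
  }, cliques)
  out <- lapply(maximal, function(idx) sort(names[idx]))
  out[order(vapply(out, paste, character(1), collapse = ""))]
}

# direct k-clique percolation: enumerate every k-clique, link pairs
# sharing k-1 nodes, and union connected components by BFS
oracle_cpm <- function(adj, k) {
  n <- nrow(adj)
  names <- rownames(adj)
  if (n < k) return(list())
  combos <- utils::combn(n, k)
  pair_rows <- utils::combn(k, 2)
  is_clique <- rep(TRUE, ncol(combos))
  for (p in seq_len(ncol(pair_rows))) {
    is_clique <- is_clique &
      adj[cbind(combos[pair_rows[1, p], ], combos[pair_rows[2, p], ])] == 1
  }
  kc <- combos[, is_clique, drop = FALSE]
  m <- ncol(kc)
  if (!m) return(list())
  nbr <- vector("list", m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j && length(intersect(kc[, i], kc[, j])) == k - 1L) {
        nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
      }
    }
  }
  seen <- logical(m)
  comms <- list()
  for (s in seq_len(m)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, kc[, cur])
      for (nb in nbr[[cur]]) {
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    comms[[length(comms) + 1L]] <- sort(unique(names[members]))
  }
  keys <- vapply(comms, paste, character(1), collapse = " ")
  comms[order(-lengths(comms), keys)]
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# --- random instance generators ------------------------------------------

# Erdos-Renyi graph with letter-ish vertex names, as igraph + adjacency
random_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  rownames(adj) <- colnames(adj) <- igraph::V(g)$name
  list(graph = g, adj = adj)
}

# random bag-of-words bin: documents as random subsets of a vocabulary
random_token_sets <- function(n_docs, vocab_size, max_len = 8) {
  vocab <- sprintf("w%03d", seq_len(vocab_size))
  lapply(seq_len(n_docs), function(i) {
    sort(sample(vocab, sample.int(min(max_len, vocab_size), 1)))
  })
}

corpus_from_token_sets <- function(token_sets, year = 2000L) {
  medwordnet::make_corpus(sprintf("d%04d", seq_along(token_sets)),
                          rep(year, length(token_sets)),
                          tokens = token_sets)
}

bin_from_token_sets <- function(token_sets, year = 2000L) {
  corp <- corpus_from_token_sets(token_sets, year)
  medwordnet::bin_corpus(corp, list(c(year, year + 5L)))[[1]]
}

# small named graph from an edge list given as "a-b" strings
graph_from_edges <- function(edges, isolates = character(0)) {
  parts <- strsplit(edges, "-", fixed = TRUE)
  el <- do.call(rbind, parts)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (length(isolates)) {
    g <- igraph::add_vertices(g, length(isolates), name = isolates)
  }
  g
}

adjacency_of <- function(g) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  rownames(adj) <- colnames(adj) <- igraph::V(g)$name
  adj
}
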