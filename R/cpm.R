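# k-clique percolation (CPM) overlapping community detection.
#
# A k-clique is a set of k pairwise-connected nodes; two k-cliques are
# neighbors when they share k-1 nodes; a k-clique community is the union of
# all k-cliques reachable through chains of neighboring k-cliques.
# Communities may overlap in nodes. Rather than enumerating every k-clique,
# the implementation enumerates maximal cliques once and joins two maximal
# cliques of size >= k whenever they share >= k-1 nodes; the connected
# components of that clique-overlap relation induce exactly the CPM
# communities (any pair of neighboring k-cliques lies in maximal cliques
# overlapping in >= k-1 nodes, and conversely two maximal cliques with such
# an overlap are bridged by a pair of neighboring k-cliques).

#' Enumerate the maximal cliques of a graph
#'
#' @param graph A simple undirected igraph graph.
#' @return A list of character vectors, each a maximal clique with members
#'   sorted; the list itself is sorted lexicographically, so the output is
#'   deterministic.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' enumerate_maximal_cliques(g)
#' @export
enumerate_maximal_cliques <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(graph)))
  }
  cl <- igraph::max_cliques(graph)
  cl <- lapply(cl, function(v) sort(nm[as.integer(v)]))
  keys <- vapply(cl, paste, character(1), collapse = "")
  cl[order(keys)]
}

#' k-clique percolation communities
#'
#' Extracts the overlapping community cover of a graph at clique size `k`.
#' Nodes belonging to no k-clique are left uncovered. Edge weights are
#' ignored; thresholding during network construction is the only place
#' weights act.
#'
#' @param graph A simple undirected igraph graph.
#' @param k Clique size (integer >= 2). At `k = 2` the cover equals the
#'   connected components restricted to non-isolated nodes.
#' @return A `community_cover`: list with `k`, `communities` (list of
#'   sorted node-name vectors, ordered by decreasing size then by smallest
#'   member), and `node_index` (named list mapping each covered node to
#'   the integer ids of the communities containing it).
#' @examples
#' # two triangles sharing one node overlap in that node at k = 3
#' g <- igraph::graph_from_literal(a - b - c - a, c - d - e - c, d - e)
#' cpm_communities(g, k = 3)$communities
#' @export
cpm_communities <- function(graph, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2", call. = FALSE)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  mc <- igraph::max_cliques(graph, min = k)
  if (!length(mc)) return(new_community_cover(k, list()))
  nv <- igraph::vcount(graph)
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_along(mc), lengths(mc)),
    j = unlist(lapply(mc, as.integer), use.names = FALSE),
    x = 1, dims = c(length(mc), nv))
  ov <- Matrix::tcrossprod(inc)            # clique-pair overlap sizes
  ov <- methods::as(Matrix::triu(ov, k = 1), "TsparseMatrix")
  adj <- ov@x >= (k - 1)
  cg <- igraph::graph_from_edgelist(
    cbind(ov@i[adj] + 1L, ov@j[adj] + 1L), directed = FALSE)
  cg <- igraph::add_vertices(cg, max(0L, length(mc) - igraph::vcount(cg)))
  memb <- igraph::components(cg)$membership
  names_all <- igraph::V(graph)$name
  comms <- lapply(split(seq_along(mc), memb), function(ids) {
    sort(unique(names_all[unlist(lapply(mc[ids], as.integer),
                                 use.names = FALSE)]))
  })
  new_community_cover(k, unname(comms))
}

new_community_cover <- function(k, communities) {
  if (length(communities)) {
    # size descending, then lexicographic on the sorted membership (refines
    # "smallest member first" to a total order when smallest members tie)
    keys <- vapply(communities, paste, character(1), collapse = " ")
    communities <- communities[order(-lengths(communities), keys)]
  }
  node_index <- list()
  for (i in seq_along(communities)) {
    for (w in communities[[i]]) node_index[[w]] <- c(node_index[[w]], i)
  }
  if (length(node_index)) node_index <- node_index[order(names(node_index))]
  structure(list(k = k, communities = communities,
                 node_index = node_index),
            class = "community_cover")
}

#' @export
print.community_cover <- function(x, ...) {
  cat(sprintf("k-clique community cover (k = %d): %d communities\n",
              x$k, length(x$communities)))
  sz <- lengths(x$communities)
  if (length(sz)) {
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
    ov <- sum(lengths(x$node_index) > 1L)
    cat(sprintf("  covered nodes: %d (%d in >1 community)\n",
                length(x$node_index), ov))
  }
  invisible(x)
}

#' Select the critical clique size k
#'
#' Scans `k` from `k_min` upward and returns the smallest value for which
#' communities exist but none is "giant", i.e. none covers at least
#' `giant_fraction` of the graph's nodes. Below the critical k a giant
#' community smears many small communities together; above it the cover
#' thins out.
#'
#' @param graph A simple undirected igraph graph.
#' @param giant_fraction A community is giant when its size is >=
#'   `giant_fraction * vcount(graph)`; in (0, 1].
#' @param k_min,k_max Inclusive search range; `k_max` defaults to the size
#'   of the largest clique.
#' @return A `critical_k` object: list with `k` (selected value, or `NA`),
#'   `status` (`"ok"`, `"giant_at_all_k"` when every k that yields
#'   communities yields a giant one, or `"no_communities"` when no k in
#'   range yields any community), and `table` (per-k community count and
#'   largest-community fraction).
#' @export
select_critical_k <- function(graph, giant_fraction = 0.5, k_min = 3L,
                              k_max = NULL) {
  if (!(giant_fraction > 0 && giant_fraction <= 1)) {
    stop("'giant_fraction' must be in (0, 1]", call. = FALSE)
  }
  k_min <- as.integer(k_min)
  if (is.na(k_min) || k_min < 2L) stop("'k_min' must be >= 2", call. = FALSE)
  if (is.null(k_max)) {
    k_max <- max(k_min, suppressWarnings(igraph::clique_num(graph)))
  }
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < k_min) {
    stop("'k_max' must be >= 'k_min'", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  ks <- k_min:k_max
  n_comm <- integer(0)
  frac <- numeric(0)
  hit <- NULL
  for (i in seq_along(ks)) {
    cov <- cpm_communities(graph, ks[i])
    n_comm[i] <- length(cov$communities)
    frac[i] <- if (n_comm[i] && n > 0) max(lengths(cov$communities)) / n else 0
    if (n_comm[i] > 0L && frac[i] < giant_fraction) {
      hit <- list(k = ks[i], cover = cov)
      break     # smallest admissible k found; larger k cannot precede it
    }
  }
  tab <- data.frame(k = ks[seq_along(n_comm)], n_communities = n_comm,
                    largest_fraction = frac)
  if (!is.null(hit)) {
    out <- list(k = hit$k, status = "ok", table = tab, cover = hit$cover)
  } else if (all(n_comm == 0L)) {
    out <- list(k = NA_integer_, status = "no_communities", table = tab,
                cover = NULL)
  } else {
    out <- list(k = NA_integer_, status = "giant_at_all_k", table = tab,
                cover = NULL)
  }
  structure(out, class = "critical_k")
}

#' @export
print.critical_k <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Critical k = %d\n", x$k))
  } else {
    cat(sprintf("No critical k found (status: %s)\n", x$status))
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a community cover as JSON
#'
#' Layout: `{"k": k, "communities": [[sorted words], ...]}`.
#'
#' @param cover A `community_cover`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cover_json <- function(cover, path) {
  jsonlite::write_json(list(k = cover$k, communities = cover$communities),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a community cover as a two-column TSV
#'
#' Columns `word`, `community_id`; a word in several communities appears
#' on several rows.
#'
#' @param cover A `community_cover`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cover_tsv <- function(cover, path) {
  lines <- "word\tcommunity_id"
  for (i in seq_along(cover$communities)) {
    lines <- c(lines, sprintf("%s\t%d", cover$communities[[i]], i))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
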