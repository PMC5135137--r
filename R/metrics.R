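# Connectivity statistics of a word network: giant component size, number
# of components, and mean shortest-path distance within the largest
# component (unweighted hop counts).

#' Connectivity report for a network
#'
#' Computes the number of connected components, the size of the giant
#' (largest) component, and the average shortest-path distance, in hops,
#' over unordered node pairs of the largest component. Components and
#' distances use the unweighted undirected skeleton of the graph; edge
#' weights never enter. Ties for the largest component are broken by the
#' lexicographically smallest member node.
#'
#' @param graph An igraph graph (e.g. a `word_network`).
#' @return A `connectivity_report`: list with `n_nodes`, `n_components`,
#'   `giant_component_size`, `average_distance_largest` (`NA` when the
#'   largest component has fewer than 2 nodes).
#' @examples
#' g <- igraph::make_graph(~ a - b - c)
#' connectivity_report(g)$average_distance_largest  # (1 + 1 + 2) / 3
#' @export
connectivity_report <- function(graph) {
  n <- as.integer(igraph::vcount(graph))
  if (n == 0L) {
    return(structure(list(n_nodes = 0L, n_components = 0L,
                          giant_component_size = 0L,
                          average_distance_largest = NA_real_),
                     class = "connectivity_report"))
  }
  comp <- igraph::components(graph, mode = "weak")
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # tie-break: component whose smallest member name sorts first
    nm <- igraph::V(graph)$name
    if (is.null(nm)) nm <- as.character(seq_len(n))
    firsts <- vapply(big, function(ci) min(nm[comp$membership == ci]),
                     character(1))
    big <- big[order(firsts)][1L]
  } else {
    big <- big[1L]
  }
  members <- which(comp$membership == big)
  avg <- NA_real_
  if (length(members) >= 2L) {
    sub <- igraph::induced_subgraph(graph, members)
    d <- igraph::distances(sub, weights = NA)
    avg <- mean(d[upper.tri(d)])
  }
  structure(list(n_nodes = n, n_components = as.integer(comp$no),
                 giant_component_size = length(members),
                 average_distance_largest = avg),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf(
    "Connectivity: %d nodes, %d components, giant component %d, mean distance %s\n",
    x$n_nodes, x$n_components, x$giant_component_size,
    if (is.na(x$average_distance_largest)) "NA"
    else sprintf("%.4f", x$average_distance_largest)))
  invisible(x)
}

#' Write a connectivity report as JSON
#'
#' @param report A `connectivity_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Summarise connectivity across bins as a TSV
#'
#' @param reports Named list of `connectivity_report`s (names = interval
#'   labels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(reports, path) {
  lines <- "interval\tn_nodes\tn_components\tgiant_component_size\taverage_distance_largest"
  for (lab in names(reports)) {
    r <- reports[[lab]]
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\t%s", lab, r$n_nodes,
                              r$n_components, r$giant_component_size,
                              if (is.na(r$average_distance_largest)) "NA"
                              else sprintf("%.6f", r$average_distance_largest)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
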