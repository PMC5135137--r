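# End-to-end orchestration: corpus -> per-bin network -> connectivity
# metrics -> community cover -> cross-bin life-cycle events, with
# deterministic file outputs and a run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validated defaults. The
#' corpus-scale defaults (`min_word_count = 2000`,
#' `pmi_threshold_bits = 2.8`; 4.0 is the sparser "overview" resolution)
#' suit millions of abstracts; small corpora need a smaller
#' `min_word_count`.
#'
#' @param input Path to a corpus file, or `NULL` when documents are passed
#'   directly.
#' @param format Corpus format for [read_documents()].
#' @param intervals List of half-open year ranges (see [bin_corpus()]).
#' @param tokenizer A [tokenizer_config()].
#' @param min_word_count Node threshold (strict document-frequency
#'   minimum).
#' @param pmi_threshold_bits Edge threshold in bits.
#' @param k Clique size for community extraction: an integer >= 2 or
#'   `"auto"` to select the critical k per run (see Details).
#' @param giant_fraction Giant-community fraction for
#'   [select_critical_k()].
#' @param k_min,k_max Search range for `k = "auto"`; `k_max = NULL` scans
#'   up to each bin's largest clique.
#' @param overlap_threshold Jaccard threshold for [match_communities()].
#' @param growth_tolerance Size-change tolerance for [classify_events()].
#' @param output_dir Directory for [run_pipeline()] outputs.
#' @param seed Seed recorded for synthetic runs.
#' @details With `k = "auto"` a critical k is selected independently for
#'   every bin and the maximum over bins is used for all of them, so one
#'   clique size — the most conservative resolution any interval demands —
#'   applies across the whole timeline and communities are comparable
#'   between bins.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            format = c("jsonl", "tsv", "medline_xml"),
                            intervals,
                            tokenizer = tokenizer_config(),
                            min_word_count = 2000,
                            pmi_threshold_bits = 2.8,
                            k = "auto",
                            giant_fraction = 0.5,
                            k_min = 3L,
                            k_max = NULL,
                            overlap_threshold = 0.1,
                            growth_tolerance = 0.25,
                            output_dir = "mwn_output",
                            seed = 1L) {
  format <- match.arg(format)
  if (min_word_count < 0) stop("'min_word_count' must be >= 0", call. = FALSE)
  if (!(giant_fraction > 0 && giant_fraction <= 1)) {
    stop("'giant_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (!(overlap_threshold > 0 && overlap_threshold <= 1)) {
    stop("'overlap_threshold' must be in (0, 1]", call. = FALSE)
  }
  if (growth_tolerance < 0) stop("'growth_tolerance' must be >= 0", call. = FALSE)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (is.na(k) || k < 2L) stop("'k' must be >= 2 or \"auto\"", call. = FALSE)
  }
  structure(
    list(input = input, format = format, intervals = intervals,
         tokenizer = tokenizer, min_word_count = min_word_count,
         pmi_threshold_bits = pmi_threshold_bits, k = k,
         giant_fraction = giant_fraction, k_min = as.integer(k_min),
         k_max = if (is.null(k_max)) NULL else as.integer(k_max),
         overlap_threshold = overlap_threshold,
         growth_tolerance = growth_tolerance,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Analyse a corpus in memory
#'
#' Runs the full analysis without touching the filesystem: bins the
#' documents, builds the per-bin PMI network, computes connectivity
#' metrics, extracts the k-clique community cover (selecting the critical
#' k when `config$k == "auto"`), and classifies life-cycle events across
#' consecutive bins.
#'
#' @param documents An `mwn_corpus` or list of documents.
#' @param config A [pipeline_config()] (its `input`/`output_dir` fields
#'   are ignored here).
#' @return An `mwn_analysis`: list with `bins`, `networks`, `reports`,
#'   `covers` (all named by interval label), `k_used`, `k_selection`
#'   (per-bin `critical_k` objects when k was auto), and `timeline`.
#' @export
analyze_corpus <- function(documents, config) {
  stopifnot(inherits(config, "pipeline_config"))
  bins <- bin_corpus(documents, config$intervals)
  labs <- vapply(bins, function(b) b$label, character(1))
  networks <- list(); reports <- list()
  for (i in seq_along(bins)) {
    freq <- count_frequencies(bins[[i]])
    vocab <- names(freq$counts[freq$counts > config$min_word_count])
    cooc <- count_pair_frequencies(bins[[i]], vocab)
    g <- build_word_network(freq, cooc,
                            min_word_count = config$min_word_count,
                            pmi_threshold_bits = config$pmi_threshold_bits,
                            interval = labs[i])
    networks[[labs[i]]] <- g
    reports[[labs[i]]] <- connectivity_report(g)
  }
  k_selection <- NULL
  if (identical(config$k, "auto")) {
    k_selection <- lapply(networks, function(g) {
      if (igraph::ecount(g) == 0L) return(NULL)
      select_critical_k(g, giant_fraction = config$giant_fraction,
                        k_min = config$k_min, k_max = config$k_max)
    })
    ks <- vapply(k_selection, function(s) {
      if (is.null(s)) NA_integer_ else s$k
    }, integer(1))
    statuses <- vapply(k_selection, function(s) {
      if (is.null(s)) "no_communities" else s$status
    }, character(1))
    if (any(statuses == "giant_at_all_k")) {
      stop("critical-k selection failed: a giant community persists at ",
           "every k in bin(s) ",
           paste(names(statuses)[statuses == "giant_at_all_k"],
                 collapse = ", "),
           "; raise pmi_threshold_bits or giant_fraction", call. = FALSE)
    }
    if (all(is.na(ks))) {
      k_used <- NA_integer_
    } else {
      k_used <- max(ks, na.rm = TRUE)
    }
  } else {
    k_used <- config$k
  }
  covers <- lapply(networks, function(g) {
    if (is.na(k_used)) new_community_cover(config$k_min, list())
    else cpm_communities(g, k_used)
  })
  timeline <- community_timeline(covers,
                                 overlap_threshold = config$overlap_threshold,
                                 growth_tolerance = config$growth_tolerance)
  structure(list(bins = stats::setNames(bins, labs), networks = networks,
                 reports = reports, covers = covers, k_used = k_used,
                 k_selection = k_selection, timeline = timeline,
                 config = config),
            class = "mwn_analysis")
}

#' @export
print.mwn_analysis <- function(x, ...) {
  cat(sprintf("Medical-words-network analysis over %d bins (k = %s)\n",
              length(x$bins),
              if (is.na(x$k_used)) "none" else x$k_used))
  for (lab in names(x$networks)) {
    g <- x$networks[[lab]]
    cat(sprintf("  %s: %d docs, %d words, %d edges, %d communities\n",
                lab, x$bins[[lab]]$n_documents, igraph::vcount(g),
                igraph::ecount(g), length(x$covers[[lab]]$communities)))
  }
  invisible(x)
}

#' @export
summary.mwn_analysis <- function(object, ...) {
  print(object)
  if (length(object$timeline$events)) {
    cat("Events:\n")
    print(object$timeline)
  }
  invisible(object)
}

#' Run the pipeline and write all outputs
#'
#' Reads (or accepts) a corpus, analyses it with [analyze_corpus()], and
#' writes, per bin, the edge list (TSV), GraphML, connectivity report
#' (JSON) and community cover (JSON + TSV); across bins, the event stream
#' (JSONL + TSV) and a connectivity trend TSV; plus `manifest.json`
#' recording the configuration and an MD5 checksum of every output file.
#' Rerunning with an identical configuration reproduces byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()] with `input` set, unless
#'   `documents` is supplied.
#' @param documents Optional in-memory corpus overriding `config$input`.
#' @return The manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, documents = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(documents)) {
    if (is.null(config$input)) {
      stop("config$input is NULL and no documents were supplied",
           call. = FALSE)
    }
    documents <- read_documents(config$input, config$format,
                                config$tokenizer)
  }
  if (length(documents) == 0L) {
    warning("empty corpus: writing empty outputs", call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  an <- analyze_corpus(documents, config)
  files <- character(0)
  out <- function(...) file.path(config$output_dir, sprintf(...))
  for (lab in names(an$networks)) {
    files <- c(files,
               write_edge_list(an$networks[[lab]], out("edges_%s.tsv", lab)),
               write_graphml(an$networks[[lab]], out("network_%s.graphml", lab)),
               write_connectivity_json(an$reports[[lab]],
                                       out("connectivity_%s.json", lab)),
               write_cover_json(an$covers[[lab]], out("communities_%s.json", lab)),
               write_cover_tsv(an$covers[[lab]], out("communities_%s.tsv", lab)))
  }
  files <- c(files,
             write_connectivity_tsv(an$reports, out("connectivity_trend.tsv")),
             write_events_jsonl(an$timeline, out("events.jsonl"),
                                out("events.tsv")))
  files <- c(files, out("events.tsv"))
  files <- sort(unique(normalizePath(files)))
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("medwordnet")),
    config = manifest_config(config),
    n_documents = length(documents),
    n_dropped = attr(an$bins, "dropped") %||% 0L,
    bins = lapply(an$bins, function(b) {
      list(label = b$label, n_documents = b$n_documents)
    }),
    k_used = an$k_used,
    events = lapply(an$timeline$events, function(ev) as.list(table(ev$event))),
    checksums = checksums,
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

manifest_config <- function(config) {
  cf <- unclass(config)
  cf$tokenizer <- unclass(cf$tokenizer)
  cf$intervals <- lapply(cf$intervals, as.integer)
  cf
}
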