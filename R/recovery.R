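# Evaluating pipeline output against a synthetic scenario's ground truth:
# best-Jaccard recovery of planted topic communities and exact comparison
# of the classified event sequence with the planted one.

#' Pipeline configuration adapted to a synthetic scenario
#'
#' Derives thresholds from the generator's design rather than the
#' corpus-scale defaults: the node threshold is set to one fifth of the
#' smallest per-topic document count (well below the expected member-word
#' frequency `p_in * n_docs`, far above the expected background frequency),
#' and the edge threshold to 0.5 bits, between the within-topic PMI
#' (about `-log2` of the topic's document share, >= 1 bit for <= half-share
#' topics) and cross-topic PMI (negative).
#'
#' @param scenario A [scenario_spec()].
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A [pipeline_config()] with `intervals` taken from the scenario
#'   and `k = "auto"`.
#' @export
scenario_pipeline_config <- function(scenario, ...) {
  min_docs <- min(vapply(scenario$roster, min, numeric(1)))
  defaults <- list(
    intervals = scenario$intervals,
    min_word_count = max(5, round(0.2 * min_docs)),
    pmi_threshold_bits = 0.5,
    k = "auto",
    seed = scenario$seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(pipeline_config, args)
}

#' Score recovery of planted communities and events
#'
#' Generates the scenario's corpus, runs the full analysis, maps every
#' recovered community to its best-Jaccard ground-truth topic, and checks
#' whether the classified event sequence — rewritten in topic ids through
#' that mapping — equals the planted one exactly.
#'
#' @param scenario A [scenario_spec()].
#' @param config A [pipeline_config()]; defaults to
#'   [scenario_pipeline_config()] on the scenario.
#' @return A list with `jaccard` (per bin, named vector: best Jaccard per
#'   planted topic), `min_jaccard`, `events_recovered` (TRUE when every
#'   transition's classified events equal the planted events), `analysis`
#'   (the underlying `mwn_analysis`) and `ground_truth`.
#' @export
evaluate_recovery <- function(scenario,
                              config = scenario_pipeline_config(scenario)) {
  gen <- generate_corpus(scenario)
  an <- analyze_corpus(gen$documents, config)
  truth <- gen$ground_truth

  jaccard <- list()
  mapping <- list()   # per bin: recovered community id -> topic id
  for (lab in names(truth$membership)) {
    topics <- truth$membership[[lab]]
    comms <- an$covers[[lab]]$communities
    jac <- vapply(topics, function(words) {
      if (!length(comms)) return(0)
      max(vapply(comms, function(cm) {
        length(intersect(words, cm)) / length(union(words, cm))
      }, numeric(1)))
    }, numeric(1))
    jaccard[[lab]] <- jac
    mapping[[lab]] <- vapply(comms, function(cm) {
      scores <- vapply(topics, function(words) {
        length(intersect(words, cm)) / length(union(words, cm))
      }, numeric(1))
      if (!length(scores) || max(scores) == 0) NA_character_
      else names(topics)[which.max(scores)]
    }, character(1))
  }

  canon <- function(event, preds, succs) {
    paste(event,
          paste(sort(preds), collapse = ","),
          paste(sort(succs), collapse = ","), sep = "|")
  }
  events_ok <- TRUE
  labs <- names(truth$membership)
  for (t in seq_len(length(labs) - 1L)) {
    key <- sprintf("%s -> %s", labs[t], labs[t + 1L])
    planted <- vapply(truth$events[[key]] %||% list(), function(ev) {
      canon(ev$event, ev$predecessors, ev$successors)
    }, character(1))
    ev <- an$timeline$events[[key]]
    got <- vapply(seq_len(nrow(ev)), function(r) {
      canon(ev$event[r],
            mapping[[labs[t]]][ev$predecessors[[r]]],
            mapping[[labs[t + 1L]]][ev$successors[[r]]])
    }, character(1))
    if (!identical(sort(planted), sort(got))) events_ok <- FALSE
  }

  list(jaccard = jaccard,
       min_jaccard = min(unlist(jaccard)),
       events_recovered = events_ok,
       analysis = an,
       ground_truth = truth)
}
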