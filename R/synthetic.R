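# Synthetic bag-of-words corpora with planted, time-evolving topic
# communities and exported ground truth. Each document is drawn from one
# topic: it includes each topic member word independently with probability
# p_in and each background word with probability p_bg (Bernoulli presence;
# PMI depends only on document-level presence, so no length model is
# needed). A mixing probability lets a document draw from a second topic,
# creating genuinely shared nodes between planted communities.

#' Construct a synthetic scenario specification
#'
#' A scenario fixes the time bins, the planted topics (word sets), the
#' per-bin topic roster with document counts, the background vocabulary,
#' and the planted life-cycle events between consecutive bins.
#'
#' @param intervals List of half-open year ranges `c(start, end)`, one per
#'   bin, in order.
#' @param topics Named list: topic id -> character vector of member words.
#' @param roster Named list keyed by bin label (`"start-end"`): each entry
#'   a named integer vector, topic id -> number of documents drawn from
#'   that topic in that bin.
#' @param events Named list keyed by transition label
#'   (`"bin1 -> bin2"`): each entry a list of planted events, each a list
#'   with `event` (one of growth, contraction, merging, splitting,
#'   appearance, disappearance, continuation), `predecessors` and
#'   `successors` (character vectors of topic ids).
#' @param background_vocabulary Character vector of background words.
#' @param in_topic_word_probability Per-document inclusion probability of
#'   each member word of the document's topic, in (0, 1].
#' @param background_word_probability Per-document inclusion probability
#'   of each background word, in [0, 1).
#' @param mixing_probability Probability that a document also includes a
#'   second topic's member words (at `in_topic_word_probability`).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated object of class `scenario_spec`.
#' @export
scenario_spec <- function(intervals, topics, roster, events = list(),
                          background_vocabulary = character(0),
                          in_topic_word_probability = 0.9,
                          background_word_probability = 0.01,
                          mixing_probability = 0,
                          seed = 1L) {
  sc <- structure(
    list(intervals = lapply(intervals, as.integer),
         topics = lapply(topics, function(w) sort(unique(as.character(w)))),
         roster = roster, events = events,
         background_vocabulary = sort(unique(as.character(background_vocabulary))),
         in_topic_word_probability = in_topic_word_probability,
         background_word_probability = background_word_probability,
         mixing_probability = mixing_probability,
         seed = as.integer(seed)),
    class = "scenario_spec")
  validate_scenario(sc)
  sc
}

bin_label <- function(iv) sprintf("%d-%d", iv[1], iv[2])

#' Validate a scenario specification
#'
#' Checks probability ranges, roster/topic consistency, and that every
#' planted event references topics present on the correct side of its
#' transition.
#'
#' @param scenario A `scenario_spec` (or plain list with the same fields).
#' @return The scenario, invisibly; stops with a message listing every
#'   violation otherwise.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  bad <- character(0)
  p_in <- sc$in_topic_word_probability
  p_bg <- sc$background_word_probability
  if (!(p_in > 0 && p_in <= 1)) {
    bad <- c(bad, "in_topic_word_probability must be in (0, 1]")
  }
  if (!(p_bg >= 0 && p_bg < 1)) {
    bad <- c(bad, "background_word_probability must be in [0, 1)")
  }
  if (!(sc$mixing_probability >= 0 && sc$mixing_probability < 1)) {
    bad <- c(bad, "mixing_probability must be in [0, 1)")
  }
  labs <- vapply(sc$intervals, bin_label, character(1))
  if (!setequal(names(sc$roster), labs)) {
    bad <- c(bad, "roster keys must be exactly the bin labels")
  }
  for (lab in names(sc$roster)) {
    r <- sc$roster[[lab]]
    unknown <- setdiff(names(r), names(sc$topics))
    if (length(unknown)) {
      bad <- c(bad, sprintf("bin %s rosters unknown topics: %s", lab,
                            paste(unknown, collapse = ", ")))
    }
    if (any(r < 1)) bad <- c(bad, sprintf("bin %s has non-positive counts", lab))
  }
  for (key in names(sc$events)) {
    parts <- strsplit(key, " -> ", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% labs)) {
      bad <- c(bad, sprintf("event key '%s' does not name two bins", key))
      next
    }
    prev_topics <- names(sc$roster[[parts[1]]])
    next_topics <- names(sc$roster[[parts[2]]])
    for (ev in sc$events[[key]]) {
      if (!all(ev$predecessors %in% prev_topics)) {
        bad <- c(bad, sprintf("%s %s: predecessors not in bin %s roster",
                              key, ev$event, parts[1]))
      }
      if (!all(ev$successors %in% next_topics)) {
        bad <- c(bad, sprintf("%s %s: successors not in bin %s roster",
                              key, ev$event, parts[2]))
      }
    }
  }
  if (length(bad)) {
    stop("invalid scenario:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(scenario)
}

#' Generate a synthetic corpus from a scenario
#'
#' Fully reproducible from `scenario$seed` (Mersenne-Twister with
#' inversion for normals and rejection sampling, set explicitly so the
#' stream does not depend on the session's RNG defaults). Document years
#' are uniform within their bin.
#'
#' @param scenario A `scenario_spec`.
#' @return A list with `documents` (an `mwn_corpus`) and `ground_truth`
#'   (list with `membership`: per-bin mapping topic id -> member words,
#'   and `events`: the planted event list per transition).
#' @export
generate_corpus <- function(scenario) {
  validate_scenario(scenario)
  sc <- scenario
  set.seed(sc$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  p_in <- sc$in_topic_word_probability
  p_bg <- sc$background_word_probability
  bg <- sc$background_vocabulary
  docs <- list()
  membership <- list()
  for (iv in sc$intervals) {
    lab <- bin_label(iv)
    roster <- sc$roster[[lab]]
    membership[[lab]] <- sc$topics[names(roster)]
    span <- iv[2] - iv[1]
    for (tid in names(roster)) {
      members <- sc$topics[[tid]]
      others <- setdiff(names(roster), tid)
      for (d in seq_len(roster[[tid]])) {
        toks <- members[stats::runif(length(members)) < p_in]
        if (length(others) && sc$mixing_probability > 0 &&
            stats::runif(1) < sc$mixing_probability) {
          second <- sc$topics[[others[sample.int(length(others), 1L)]]]
          toks <- c(toks, second[stats::runif(length(second)) < p_in])
        }
        if (length(bg) && p_bg > 0) {
          toks <- c(toks, bg[stats::runif(length(bg)) < p_bg])
        }
        year <- iv[1] + sample.int(span, 1L) - 1L
        docs[[length(docs) + 1L]] <- new_document(
          sprintf("%s_%s_%04d", lab, tid, d), year,
          sort(unique(toks)))
      }
    }
  }
  documents <- structure(docs, skipped = 0L, class = "mwn_corpus")
  list(documents = documents,
       ground_truth = list(membership = membership, events = sc$events))
}

preset_bins <- list(c(2005L, 2010L), c(2010L, 2015L))

topic_words <- function(stem, n) sprintf("%s%02d", stem, seq_len(n))

#' Built-in evolution scenarios
#'
#' Named scenarios exercising the community life-cycle taxonomy, each over
#' two consecutive five-year bins. Every scenario carries two stable
#' ten-word "context" topics in addition to its focal topics, so the
#' network always contains several communities and critical-k selection
#' is well posed. Focal structure per scenario:
#' \describe{
#'   \item{`static_two_topics`}{Two disjoint eight-word topics persist
#'     unchanged (continuation).}
#'   \item{`merge`}{Two six-word topics fuse into their twelve-word union
#'     in the second bin (one merging event).}
#'   \item{`split`}{A twelve-word topic separates into its two six-word
#'     halves (one splitting event).}
#'   \item{`disappearance`}{One of two eight-word topics stops publishing
#'     in the second bin (one disappearance).}
#'   \item{`shared_node_overlap`}{Two eight-word topics share exactly one
#'     word ("anaemia"-style bridge) and persist; communities overlap in
#'     that node.}
#' }
#'
#' @param n_docs_per_topic Documents drawn per topic per bin.
#' @param in_topic_word_probability,background_word_probability Passed to
#'   [scenario_spec()].
#' @param seed Integer seed stored in each scenario.
#' @return Named list of `scenario_spec`s.
#' @export
preset_scenarios <- function(n_docs_per_topic = 250L,
                             in_topic_word_probability = 0.9,
                             background_word_probability = 0.01,
                             seed = 1L) {
  bg <- topic_words("bg", 40)
  context <- list(immunology = topic_words("immuno", 10),
                  neuroscience = topic_words("neuro", 10))
  labs <- vapply(preset_bins, bin_label, character(1))
  nd <- as.integer(n_docs_per_topic)

  mk <- function(topics, roster_prev, roster_next, focal_events) {
    topics <- c(topics, context)
    roster_prev <- c(roster_prev,
                     stats::setNames(rep(nd, 2), names(context)))
    roster_next <- c(roster_next,
                     stats::setNames(rep(nd, 2), names(context)))
    key <- sprintf("%s -> %s", labs[1], labs[2])
    ctx_events <- lapply(names(context), function(tid) {
      list(event = "continuation", predecessors = tid, successors = tid)
    })
    scenario_spec(
      intervals = preset_bins, topics = topics,
      roster = stats::setNames(list(roster_prev, roster_next), labs),
      events = stats::setNames(list(c(focal_events, ctx_events)), key),
      background_vocabulary = bg,
      in_topic_word_probability = in_topic_word_probability,
      background_word_probability = background_word_probability,
      seed = seed)
  }

  cardiac6 <- topic_words("cardiac", 6)
  metabolic6 <- topic_words("metab", 6)
  gastro12 <- c(topic_words("hepato", 6), topic_words("luminal", 6))
  hema <- c("anaemia", topic_words("hema", 7))
  onco <- c("anaemia", topic_words("onco", 7))

  list(
    static_two_topics = mk(
      list(endocrine = topic_words("endo", 8), renal = topic_words("renal", 8)),
      c(endocrine = nd, renal = nd), c(endocrine = nd, renal = nd),
      list(list(event = "continuation", predecessors = "endocrine",
                successors = "endocrine"),
           list(event = "continuation", predecessors = "renal",
                successors = "renal"))),
    merge = mk(
      list(cardiac = cardiac6, metabolic = metabolic6,
           cardiometabolic = sort(c(cardiac6, metabolic6))),
      c(cardiac = nd, metabolic = nd), c(cardiometabolic = 2L * nd),
      list(list(event = "merging",
                predecessors = c("cardiac", "metabolic"),
                successors = "cardiometabolic"))),
    split = mk(
      list(gastroenterology = gastro12,
           hepatology = topic_words("hepato", 6),
           luminal = topic_words("luminal", 6)),
      c(gastroenterology = 2L * nd), c(hepatology = nd, luminal = nd),
      list(list(event = "splitting", predecessors = "gastroenterology",
                successors = c("hepatology", "luminal")))),
    disappearance = mk(
      list(autonomic = topic_words("autonomic", 8),
           pulmonary = topic_words("pulmo", 8)),
      c(autonomic = nd, pulmonary = nd), c(pulmonary = nd),
      list(list(event = "disappearance", predecessors = "autonomic",
                successors = character(0)),
           list(event = "continuation", predecessors = "pulmonary",
                successors = "pulmonary"))),
    shared_node_overlap = mk(
      list(hematology = hema, oncology = onco),
      c(hematology = nd, oncology = nd), c(hematology = nd, oncology = nd),
      list(list(event = "continuation", predecessors = "hematology",
                successors = "hematology"),
           list(event = "continuation", predecessors = "oncology",
                successors = "oncology")))
  )
}

#' Write / read a scenario as JSON
#'
#' The on-disk schema mirrors the fields of [scenario_spec()].
#'
#' @param scenario A `scenario_spec`.
#' @param path File path.
#' @return `path` ([write_scenario_json()]) or a `scenario_spec`
#'   ([read_scenario_json()]).
#' @export
write_scenario_json <- function(scenario, path) {
  out <- unclass(scenario)
  out$roster <- lapply(out$roster, as.list)   # keep topic names as JSON keys
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  scenario_spec(
    intervals = lapply(raw$intervals, function(iv) unlist(iv)),
    topics = lapply(raw$topics, function(w) unlist(w)),
    roster = lapply(raw$roster, function(r) vapply(r, as.integer, integer(1))),
    events = lapply(raw$events, function(trans) {
      lapply(trans, function(ev) {
        list(event = ev$event,
             predecessors = as.character(unlist(ev$predecessors)),
             successors = as.character(unlist(ev$successors)))
      })
    }),
    background_vocabulary = unlist(raw$background_vocabulary),
    in_topic_word_probability = raw$in_topic_word_probability,
    background_word_probability = raw$background_word_probability,
    mixing_probability = raw$mixing_probability,
    seed = raw$seed)
}
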