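# Tracking community covers across consecutive time bins and classifying
# life-cycle events: growth, contraction, merging, splitting, appearance,
# disappearance, continuation.

#' Match communities across two consecutive covers
#'
#' Scores every cross-bin community pair by Jaccard overlap
#' |A intersect B| / |A union B| and keeps pairs scoring at least
#' `overlap_threshold`.
#'
#' @param cover_prev,cover_next `community_cover`s for bins t and t+1.
#' @param overlap_threshold Minimum Jaccard overlap in (0, 1].
#' @return A data.frame with columns `prev` and `next_` (integer community
#'   ids into the respective covers) and `score`, ordered by
#'   `(prev, next_)`.
#' @export
match_communities <- function(cover_prev, cover_next,
                              overlap_threshold = 0.1) {
  stopifnot(inherits(cover_prev, "community_cover"),
            inherits(cover_next, "community_cover"))
  if (!(overlap_threshold > 0 && overlap_threshold <= 1)) {
    stop("'overlap_threshold' must be in (0, 1]", call. = FALSE)
  }
  prev <- cover_prev$communities
  nxt <- cover_next$communities
  out <- data.frame(prev = integer(0), next_ = integer(0),
                    score = numeric(0))
  for (i in seq_along(prev)) {
    for (j in seq_along(nxt)) {
      inter <- length(intersect(prev[[i]], nxt[[j]]))
      if (inter == 0L) next
      score <- inter / length(union(prev[[i]], nxt[[j]]))
      if (score >= overlap_threshold) {
        out <- rbind(out, data.frame(prev = i, next_ = j, score = score))
      }
    }
  }
  out <- out[order(out$prev, out$next_), , drop = FALSE]
  rownames(out) <- NULL
  out
}

community_fingerprint <- function(comm) paste(comm, collapse = "")

#' Classify community life-cycle events between two bins
#'
#' Resolves the match relation into a forest of stars — each predecessor
#' community either continues into exactly one successor, splits into
#' several, or takes part in a merge into one successor — and labels every
#' community on either side with exactly one event:
#' \itemize{
#'   \item unmatched predecessor: `disappearance`; unmatched successor:
#'     `appearance`;
#'   \item one predecessor, several successors: `splitting`; several
#'     predecessors, one successor: `merging`;
#'   \item one-to-one: `growth` when the size ratio |next| / |prev|
#'     exceeds `1 + growth_tolerance`, `contraction` when it falls below
#'     `1 / (1 + growth_tolerance)` (so reversing time maps growth to
#'     contraction exactly), else `continuation`.
#' }
#' Many-to-many conflicts are resolved greedily by descending match score,
#' with a deterministic, time-symmetric tie-break on the member sets of
#' the two communities.
#'
#' @param matches Output of [match_communities()] on the same covers.
#' @param cover_prev,cover_next The two covers.
#' @param growth_tolerance Relative size change treated as continuation
#'   (default 0.25: changes below +-25 percent).
#' @return A data.frame of events with columns `event`, `predecessors`,
#'   `successors` (list columns of integer ids), `scores` (list column).
#' @export
classify_events <- function(matches, cover_prev, cover_next,
                            growth_tolerance = 0.25) {
  stopifnot(is.data.frame(matches),
            all(c("prev", "next_", "score") %in% names(matches)))
  np <- length(cover_prev$communities)
  nn <- length(cover_next$communities)
  if (nrow(matches)) {
    if (any(matches$prev < 1 | matches$prev > np) ||
        any(matches$next_ < 1 | matches$next_ > nn)) {
      stop("match relation refers to community ids outside the covers",
           call. = FALSE)
    }
  }
  fp_prev <- vapply(cover_prev$communities, community_fingerprint, character(1))
  fp_next <- vapply(cover_next$communities, community_fingerprint, character(1))

  # order candidate edges: best score first; ties broken by the unordered
  # pair of community fingerprints so reversed input gives mirrored output
  if (nrow(matches)) {
    a <- fp_prev[matches$prev]; b <- fp_next[matches$next_]
    o <- order(-matches$score, pmin(a, b), pmax(a, b))
    matches <- matches[o, , drop = FALSE]
  }

  # accept edges greedily while keeping every connected component a star
  succ_of <- vector("list", np)   # accepted successors per predecessor
  pred_of <- vector("list", nn)   # accepted predecessors per successor
  score_of <- list()
  for (r in seq_len(nrow(matches))) {
    i <- matches$prev[r]; j <- matches$next_[r]
    dp <- length(succ_of[[i]]); dn <- length(pred_of[[j]])
    accept <- FALSE
    if (dp == 0L && dn == 0L) {
      accept <- TRUE
    } else if (dn == 0L && dp > 0L) {
      # extend a split: allowed only if i is a star center (all its
      # successors are matched to i alone)
      accept <- all(vapply(succ_of[[i]],
                           function(j2) length(pred_of[[j2]]) == 1L,
                           logical(1)))
    } else if (dp == 0L && dn > 0L) {
      accept <- all(vapply(pred_of[[j]],
                           function(i2) length(succ_of[[i2]]) == 1L,
                           logical(1)))
    }
    if (accept) {
      succ_of[[i]] <- c(succ_of[[i]], j)
      pred_of[[j]] <- c(pred_of[[j]], i)
      score_of[[paste(i, j)]] <- matches$score[r]
    }
  }

  events <- list()
  add_event <- function(event, predecessors, successors, scores) {
    events[[length(events) + 1L]] <<- list(
      event = event, predecessors = predecessors, successors = successors,
      scores = scores)
  }
  done_next <- logical(nn)
  for (i in seq_len(np)) {
    js <- sort(unlist(succ_of[[i]]))
    if (!length(js)) {
      add_event("disappearance", i, integer(0), numeric(0))
    } else if (length(js) > 1L) {
      add_event("splitting", i, js,
                vapply(js, function(j) score_of[[paste(i, j)]], numeric(1)))
      done_next[js] <- TRUE
    } else {
      j <- js
      is_ <- sort(unlist(pred_of[[j]]))
      if (length(is_) > 1L) {
        if (i == is_[1L]) {   # emit the merge once, at its first predecessor
          add_event("merging", is_, j,
                    vapply(is_, function(i2) score_of[[paste(i2, j)]],
                           numeric(1)))
          done_next[j] <- TRUE
        }
      } else {
        ratio <- length(cover_next$communities[[j]]) /
          length(cover_prev$communities[[i]])
        ev <- if (ratio > 1 + growth_tolerance) "growth"
              else if (ratio < 1 / (1 + growth_tolerance)) "contraction"
              else "continuation"
        add_event(ev, i, j, score_of[[paste(i, j)]])
        done_next[j] <- TRUE
      }
    }
  }
  for (j in seq_len(nn)) {
    if (!done_next[j]) add_event("appearance", integer(0), j, numeric(0))
  }
  data.frame(
    event = vapply(events, `[[`, character(1), "event"),
    predecessors = I(lapply(events, `[[`, "predecessors")),
    successors = I(lapply(events, `[[`, "successors")),
    scores = I(lapply(events, `[[`, "scores")),
    stringsAsFactors = FALSE
  )
}

#' Build a community timeline across ordered bins
#'
#' Runs [match_communities()] and [classify_events()] on every consecutive
#' pair of covers.
#'
#' @param covers Named list of `community_cover`s in bin order (names are
#'   interval labels).
#' @param overlap_threshold Passed to [match_communities()].
#' @param growth_tolerance Passed to [classify_events()].
#' @return A `community_timeline`: list with `bins` (labels), `covers`,
#'   `matches` (one match relation per transition) and `events` (one event
#'   data.frame per transition, named "label1 -> label2").
#' @export
community_timeline <- function(covers, overlap_threshold = 0.1,
                               growth_tolerance = 0.25) {
  labs <- names(covers)
  if (is.null(labs)) labs <- as.character(seq_along(covers))
  matches <- list(); events <- list()
  if (length(covers) >= 2L) {
    for (t in seq_len(length(covers) - 1L)) {
      key <- sprintf("%s -> %s", labs[t], labs[t + 1L])
      m <- match_communities(covers[[t]], covers[[t + 1L]], overlap_threshold)
      matches[[key]] <- m
      events[[key]] <- classify_events(m, covers[[t]], covers[[t + 1L]],
                                       growth_tolerance)
    }
  }
  structure(list(bins = labs, covers = covers, matches = matches,
                 events = events),
            class = "community_timeline")
}

#' @export
print.community_timeline <- function(x, ...) {
  cat(sprintf("Community timeline over %d bins: %s\n",
              length(x$bins), paste(x$bins, collapse = ", ")))
  for (key in names(x$events)) {
    tab <- table(x$events[[key]]$event)
    cat(sprintf("  %s: %s\n", key,
                paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a timeline's events as JSON lines and a TSV summary
#'
#' One JSON object per event:
#' `{"bin_pair": ..., "event": ..., "predecessors": [...],
#' "successors": [...], "scores": [...]}`.
#'
#' @param timeline A `community_timeline`.
#' @param jsonl_path Path for the JSONL event stream.
#' @param tsv_path Optional path for a human-readable TSV summary.
#' @return `jsonl_path`, invisibly.
#' @export
write_events_jsonl <- function(timeline, jsonl_path, tsv_path = NULL) {
  lines <- character(0)
  tsv <- "bin_pair\tevent\tpredecessors\tsuccessors"
  for (key in names(timeline$events)) {
    ev <- timeline$events[[key]]
    for (r in seq_len(nrow(ev))) {
      lines <- c(lines, as.character(jsonlite::toJSON(
        list(bin_pair = key, event = ev$event[r],
             predecessors = as.integer(ev$predecessors[[r]]),
             successors = as.integer(ev$successors[[r]]),
             scores = round(as.numeric(ev$scores[[r]]), 6)),
        auto_unbox = TRUE, digits = NA)))
      tsv <- c(tsv, sprintf("%s\t%s\t%s\t%s", key, ev$event[r],
                            paste(ev$predecessors[[r]], collapse = ","),
                            paste(ev$successors[[r]], collapse = ",")))
    }
  }
  writeLines(lines, jsonl_path, useBytes = TRUE)
  if (!is.null(tsv_path)) writeLines(tsv, tsv_path, useBytes = TRUE)
  invisible(jsonl_path)
}
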