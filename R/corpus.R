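# Corpus ingestion: reading, tokenizing and time-binning abstract collections.
# The counting unit throughout the package is the document (abstract): a word
# contributes at most once per document, so every token set is a set.

#' Default English stopword list
#'
#' A small list of English function words removed by the default tokenizer
#' configuration. It is deliberately minimal; callers with domain-specific
#' needs should supply their own list via [tokenizer_config()].
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "but", "by", "can",
    "could", "did", "do", "does", "for", "from", "had", "has", "have", "if",
    "in", "into", "is", "it", "its", "may", "might", "no", "not", "of", "on",
    "or", "our", "should", "such", "than", "that", "the", "their", "then",
    "there", "these", "this", "those", "to", "was", "we", "were", "which",
    "while", "will", "with", "would")
}

#' Tokenizer configuration
#'
#' Controls how abstract text is turned into a set of word tokens. The
#' defaults lowercase the text, replace punctuation by whitespace, drop
#' tokens shorter than `min_token_length`, and remove a small packaged
#' English function-word list.
#'
#' @param lowercase Lowercase the text before splitting.
#' @param strip_punctuation Replace every non-alphanumeric character by a
#'   space before splitting.
#' @param min_token_length Minimum number of characters a token must have
#'   to be kept (must be >= 1).
#' @param stopword_list Character vector of tokens to discard after
#'   case-folding. Use `character(0)` to keep everything.
#' @return An object of class `tokenizer_config`.
#' @seealso [tokenize()]
#' @export
tokenizer_config <- function(lowercase = TRUE,
                             strip_punctuation = TRUE,
                             min_token_length = 2L,
                             stopword_list = default_stopwords()) {
  min_token_length <- as.integer(min_token_length)
  if (is.na(min_token_length) || min_token_length < 1L) {
    stop("'min_token_length' must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      lowercase = isTRUE(lowercase),
      strip_punctuation = isTRUE(strip_punctuation),
      min_token_length = min_token_length,
      stopword_list = as.character(stopword_list)
    ),
    class = "tokenizer_config"
  )
}

#' Tokenize text into a set of word tokens
#'
#' Deterministically maps a text string to a sorted set of unique tokens
#' (document-level presence: multiplicity within the text is discarded).
#'
#' @param text A character string (an abstract). `NA` is treated as "".
#' @param config A [tokenizer_config()].
#' @return Sorted character vector of unique tokens; `character(0)` for
#'   empty input.
#' @examples
#' tokenize("Liver cirrhosis and liver fibrosis.")
#' @export
tokenize <- function(text, config = tokenizer_config()) {
  stopifnot(inherits(config, "tokenizer_config"))
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  text <- as.character(text)[1L]
  if (config$lowercase) text <- tolower(text)
  if (config$strip_punctuation) text <- gsub("[^[:alnum:]]+", " ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks) & nchar(toks) >= config$min_token_length]
  if (length(config$stopword_list)) {
    toks <- toks[!(toks %in% config$stopword_list)]
  }
  sort(unique(toks))
}

new_document <- function(doc_id, year, tokens) {
  structure(
    list(doc_id = as.character(doc_id), year = as.integer(year),
         tokens = tokens),
    class = "mwn_document"
  )
}

#' Read a document corpus
#'
#' Reads documents from one of the accepted on-disk formats and tokenizes
#' each abstract. Records without abstract text are skipped and counted in
#' the `skipped` attribute of the result.
#'
#' Formats:
#' \describe{
#'   \item{`jsonl`}{One JSON object per line with keys `doc_id`, `year`,
#'     `text`.}
#'   \item{`tsv`}{Tab-separated with a header row naming columns `doc_id`,
#'     `year`, `text`.}
#'   \item{`medline_xml`}{PubMed/MEDLINE XML: one `PubmedArticle` (or
#'     `MedlineCitation`) per record; only `AbstractText` and the
#'     publication year are extracted, the PMID is used as `doc_id`.}
#' }
#'
#' @param path Path to the corpus file.
#' @param format One of `"jsonl"`, `"tsv"`, `"medline_xml"`.
#' @param config A [tokenizer_config()] applied to each abstract.
#' @return A list of documents (class `mwn_corpus`), each with fields
#'   `doc_id`, `year` and `tokens`; the integer attribute `skipped` counts
#'   records dropped for lack of abstract text.
#' @export
read_documents <- function(path, format = c("jsonl", "tsv", "medline_xml"),
                           config = tokenizer_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- switch(format,
    jsonl = read_records_jsonl(path),
    tsv = read_records_tsv(path),
    medline_xml = read_records_medline(path)
  )
  keep <- vapply(recs, function(r) !is.na(r$text) && nzchar(trimws(r$text)),
                 logical(1))
  docs <- lapply(recs[keep], function(r) {
    new_document(r$doc_id, r$year, tokenize(r$text, config))
  })
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(docs, skipped = sum(!keep), class = "mwn_corpus")
}

read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop("malformed JSONL at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$doc_id) || is.null(rec$year)) {
      stop("JSONL record at line ", i, " lacks doc_id or year", call. = FALSE)
    }
    list(doc_id = rec$doc_id, year = rec$year,
         text = if (is.null(rec$text)) NA_character_ else as.character(rec$text))
  })
}

read_records_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("doc_id", "year", "text")
  if (!all(need %in% names(df))) {
    stop("TSV must have header columns doc_id, year, text; got: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    list(doc_id = df$doc_id[i], year = as.integer(df$year[i]),
         text = df$text[i])
  })
}

read_records_medline <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("malformed MEDLINE XML: ", conditionMessage(e),
                         call. = FALSE)
                  })
  arts <- xml2::xml_find_all(doc, "//PubmedArticle | //MedlineCitation[not(parent::PubmedArticle)]")
  lapply(seq_along(arts), function(i) {
    art <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//PMID"))
    if (is.na(pmid) || !nzchar(pmid)) pmid <- sprintf("record_%d", i)
    abs_nodes <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    text <- if (length(abs_nodes)) {
      paste(xml2::xml_text(abs_nodes), collapse = " ")
    } else NA_character_
    year <- xml2::xml_text(xml2::xml_find_first(
      art, ".//JournalIssue/PubDate/Year | .//PubDate/Year"))
    if (is.na(year)) {
      mdate <- xml2::xml_text(xml2::xml_find_first(
        art, ".//PubDate/MedlineDate"))
      year <- regmatches(mdate, regexpr("[0-9]{4}", mdate))
      if (!length(year)) year <- NA_character_
    }
    if (is.na(year)) {
      stop("MEDLINE record ", i, " (PMID ", pmid, ") has no publication year",
           call. = FALSE)
    }
    list(doc_id = pmid, year = as.integer(year), text = text)
  })
}

#' Construct documents from in-memory text
#'
#' Convenience constructor used by the synthetic generator and by tests:
#' builds the same document objects [read_documents()] produces, from
#' vectors already in memory.
#'
#' @param doc_id Character vector of unique identifiers.
#' @param year Integer vector of calendar years.
#' @param tokens A list of character vectors (already-tokenized sets), or
#'   `NULL` to tokenize `text`.
#' @param text Optional character vector of raw abstracts (used when
#'   `tokens` is `NULL`).
#' @param config Tokenizer configuration for `text`.
#' @return An `mwn_corpus` list of documents.
#' @export
make_corpus <- function(doc_id, year, tokens = NULL, text = NULL,
                        config = tokenizer_config()) {
  if (is.null(tokens)) {
    stopifnot(!is.null(text), length(text) == length(doc_id))
    tokens <- lapply(text, tokenize, config = config)
  }
  stopifnot(length(doc_id) == length(year), length(doc_id) == length(tokens))
  if (anyDuplicated(doc_id)) stop("doc_id values must be unique", call. = FALSE)
  docs <- lapply(seq_along(doc_id), function(i) {
    new_document(doc_id[i], year[i], sort(unique(as.character(tokens[[i]]))))
  })
  structure(docs, skipped = 0L, class = "mwn_corpus")
}

#' @export
print.mwn_corpus <- function(x, ...) {
  yrs <- vapply(x, function(d) d$year, integer(1))
  cat(sprintf("Corpus of %d documents (%s skipped on read)\n",
              length(x), attr(x, "skipped") %||% 0L))
  if (length(x)) cat(sprintf("  years: %d-%d\n", min(yrs), max(yrs)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group documents into half-open time intervals
#'
#' Each document is assigned to the unique interval `[start, end)` that
#' contains its year; documents falling in no interval are dropped and
#' counted in the `dropped` attribute. Consecutive intervals such as
#' 1980-1985 / 1985-1990 therefore never double-count a year.
#'
#' @param documents An `mwn_corpus` or plain list of documents.
#' @param intervals A list of length-2 numeric vectors `c(start, end)`,
#'   each a half-open year range; intervals must be pairwise disjoint.
#' @return A list of bins (class `corpus_bin` each) in the given interval
#'   order, with fields `interval`, `label`, `documents`, `n_documents`;
#'   attribute `dropped` counts out-of-range documents.
#' @examples
#' corp <- make_corpus(c("d1", "d2", "d3"), c(1980L, 1984L, 1985L),
#'                     tokens = list("a", "b", "c"))
#' bins <- bin_corpus(corp, list(c(1980, 1985), c(1985, 1990)))
#' vapply(bins, function(b) b$n_documents, integer(1))
#' @export
bin_corpus <- function(documents, intervals) {
  intervals <- lapply(intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv) || iv[1] >= iv[2]) {
      stop("each interval must be c(start, end) with start < end",
           call. = FALSE)
    }
    iv
  })
  if (length(intervals) > 1L) {
    for (i in seq_along(intervals)) {
      for (j in seq_along(intervals)) {
        if (i < j && intervals[[i]][1] < intervals[[j]][2] &&
            intervals[[j]][1] < intervals[[i]][2]) {
          stop("intervals overlap: [", paste(intervals[[i]], collapse = ","),
               ") and [", paste(intervals[[j]], collapse = ")"), ")",
               call. = FALSE)
        }
      }
    }
  }
  years <- vapply(documents, function(d) d$year, integer(1))
  assign_to <- rep(NA_integer_, length(documents))
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    hit <- years >= iv[1] & years < iv[2]
    assign_to[hit] <- k
  }
  bins <- lapply(seq_along(intervals), function(k) {
    iv <- intervals[[k]]
    docs <- documents[which(assign_to == k)]
    structure(
      list(interval = iv, label = sprintf("%d-%d", iv[1], iv[2]),
           documents = docs, n_documents = length(docs)),
      class = "corpus_bin"
    )
  })
  structure(bins, dropped = sum(is.na(assign_to)))
}

#' @export
print.corpus_bin <- function(x, ...) {
  cat(sprintf("Corpus bin [%d, %d): %d documents\n",
              x$interval[1], x$interval[2], x$n_documents))
  invisible(x)
}

#' Write documents as JSONL
#'
#' Emits one JSON object per line with keys `doc_id`, `year`, `text`,
#' where `text` is the space-joined token set (the format
#' [read_documents()] accepts).
#'
#' @param documents An `mwn_corpus` or list of documents.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_documents_jsonl <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    jsonlite::toJSON(
      list(doc_id = d$doc_id, year = d$year,
           text = paste(d$tokens, collapse = " ")),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
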