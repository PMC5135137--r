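# Corpus ingestion: readers, tokenizer, and time binning.

test_that("jsonl reader returns one document per well-formed record and tallies skips", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"doc_id": "d1", "year": 1990, "text": "liver cirrhosis study"}',
    '{"doc_id": "d2", "year": 1991, "text": "platelet aggregation"}',
    '{"doc_id": "d3", "year": 1992, "text": "cortisol response"}'
  ), path)
  corp <- read_documents(path, "jsonl")
  expect_length(corp, 3L)
  expect_identical(attr(corp, "skipped"), 0L)
  expect_identical(corp[[1]]$tokens, c("cirrhosis", "liver", "study"))

  writeLines(c(
    '{"doc_id": "d1", "year": 1990, "text": "liver cirrhosis"}',
    '{"doc_id": "d2", "year": 1991}',
    '{"doc_id": "d3", "year": 1992, "text": "cortisol response"}'
  ), path)
  corp <- read_documents(path, "jsonl")
  expect_length(corp, 2L)
  expect_identical(attr(corp, "skipped"), 1L)
})

test_that("malformed input fails with a record-naming parse error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id": "d1", "year": 1990, "text": "ok"}',
               '{not json'), path)
  expect_error(read_documents(path, "jsonl"), "line 2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tyr\tbody", "d1\t1990\thello"), tsv)
  expect_error(read_documents(tsv, "tsv"), "doc_id")
})

test_that("tsv reader round-trips documents", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\tyear\ttext",
               "d1\t1985\tliver cirrhosis and fibrosis",
               "d2\t1987\t"), path)
  corp <- read_documents(path, "tsv")
  expect_length(corp, 1L)
  expect_identical(attr(corp, "skipped"), 1L)
  expect_identical(corp[[1]]$year, 1985L)
  # "and" is stoplisted by default
  expect_identical(corp[[1]]$tokens, c("cirrhosis", "fibrosis", "liver"))
})

test_that("pubmed xml fixture round-trips abstracts and years", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>111</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>1992</Year></PubDate></JournalIssue></Journal>",
    "<Abstract><AbstractText>Hepatic fibrosis models.</AbstractText></Abstract>",
    "</Article></MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>222</PMID><Article>",
    "<Journal><JournalIssue><PubDate><MedlineDate>1995 Jan-Feb</MedlineDate></PubDate></JournalIssue></Journal>",
    "<Abstract><AbstractText>Cardiac output.</AbstractText>",
    "<AbstractText>Measured invasively.</AbstractText></Abstract>",
    "</Article></MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>333</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>1999</Year></PubDate></JournalIssue></Journal>",
    "</Article></MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  corp <- read_documents(path, "medline_xml")
  expect_length(corp, 2L)
  expect_identical(attr(corp, "skipped"), 1L)   # record without abstract
  expect_identical(vapply(corp, function(d) d$doc_id, character(1)),
                   c("111", "222"))
  expect_identical(vapply(corp, function(d) d$year, integer(1)),
                   c(1992L, 1995L))
  expect_true("invasively" %in% corp[[2]]$tokens)
})

test_that("tokenizer respects its configuration and is deterministic", {
  expect_identical(tokenize("Liver cirrhosis and liver fibrosis."),
                   c("cirrhosis", "fibrosis", "liver"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("a of the"), character(0))
  keep_all <- tokenizer_config(stopword_list = character(0),
                               min_token_length = 1)
  expect_identical(tokenize("A of the", keep_all), c("a", "of", "the"))
  no_case <- tokenizer_config(lowercase = FALSE)
  expect_identical(tokenize("Liver liver", no_case), c("Liver", "liver"))
  expect_error(tokenizer_config(min_token_length = 0))

  set.seed(42)
  texts <- replicate(200, paste(sample(c(letters, LETTERS, ".", ",", "5"),
                                       30, replace = TRUE), collapse = ""))
  expect_identical(lapply(texts, tokenize), lapply(texts, tokenize))
})

test_that("tokenization is idempotent on alphanumeric token sets", {
  set.seed(11)
  for (rep in 1:20) {
    toks <- sort(unique(replicate(
      10, paste(sample(letters, 6, replace = TRUE), collapse = ""))))
    toks <- setdiff(toks, default_stopwords())
    expect_identical(tokenize(paste(toks, collapse = " ")), toks)
  }
})

test_that("binning follows the half-open convention and conserves documents", {
  corp <- make_corpus(c("d1", "d2", "d3"), c(1980L, 1984L, 1985L),
                      tokens = list("a", "b", "c"))
  bins <- bin_corpus(corp, list(c(1980, 1985), c(1985, 1990)))
  expect_identical(vapply(bins, function(b) b$n_documents, integer(1)),
                   c(2L, 1L))
  expect_identical(attr(bins, "dropped"), 0L)

  corp2 <- make_corpus("x", 1979L, tokens = list("a"))
  bins2 <- bin_corpus(corp2, list(c(1980, 1985)))
  expect_identical(bins2[[1]]$n_documents, 0L)
  expect_identical(attr(bins2, "dropped"), 1L)

  expect_error(bin_corpus(corp, list(c(1980, 1986), c(1985, 1990))),
               "overlap")
})

test_that("binning conserves documents on random inputs (brute-force recount)", {
  set.seed(101)
  intervals <- list(c(1980, 1985), c(1985, 1990), c(1995, 2000))
  for (rep in 1:25) {
    yrs <- sample(1975:2005, 60, replace = TRUE)
    corp <- make_corpus(sprintf("d%02d", seq_along(yrs)), yrs,
                        tokens = as.list(letters[seq_along(yrs) %% 5 + 1]))
    bins <- bin_corpus(corp, intervals)
    in_range <- sum(vapply(yrs, function(y) {
      any(vapply(intervals, function(iv) y >= iv[1] && y < iv[2], logical(1)))
    }, logical(1)))
    expect_identical(sum(vapply(bins, function(b) b$n_documents, integer(1))),
                     in_range)
    expect_identical(sum(vapply(bins, function(b) b$n_documents, integer(1))) +
                       attr(bins, "dropped"), length(yrs))
    for (b in bins) {
      for (d in b$documents) {
        expect_true(d$year >= b$interval[1] && d$year < b$interval[2])
      }
    }
  }
})

test_that("duplicate doc ids are rejected", {
  expect_error(make_corpus(c("d1", "d1"), c(1990L, 1991L),
                           tokens = list("a", "b")), "unique")
})
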