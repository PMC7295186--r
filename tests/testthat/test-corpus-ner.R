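test_that("tokenize applies the normalization rules", {
  expect_identical(tokenize("Type 2 Diabetes."), c("type", "2", "diabetes"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize(NA_character_), character(0))
  expect_identical(tokenize("β cell function (HOMA-IR)"),
                   c("β", "cell", "function", "homa-ir"))
  expect_identical(tokenize("insulin, glucose; and -fat-"),
                   c("insulin", "glucose", "and", "fat"))
})

test_that("tokenize is idempotent on its own output", {
  texts <- c("Type 2 Diabetes.", "β cell function (HOMA-IR)",
             "GLP-1/GIP co-agonists: a review!", "  spaced   out  ",
             "digits 123 and α-synuclein")
  for (tx in texts) {
    once <- tokenize(tx)
    twice <- tokenize(paste(once, collapse = " "))
    expect_identical(twice, once)
  }
})

test_that("entity matching collapses duplicates and prefers longest match", {
  dict <- small_dict()
  hits <- match_entities(tokenize("insulin improves insulin sensitivity"),
                         dict)
  expect_identical(hits$entity_id, "INS")
  # longest match wins: "insulin receptor" must not also yield INS
  hits2 <- match_entities(c("insulin", "receptor"), dict)
  expect_identical(hits2$entity_id, "INSR")
  expect_identical(nrow(match_entities(c("no", "entities", "here"), dict)),
                   0L)
})

test_that("dictionary construction rejects ambiguous synonyms", {
  expect_error(entity_dictionary(c("A", "B"), c("protein", "protein"),
                                 c("insulin", "insulin")),
               "multiple entity ids")
  expect_error(entity_dictionary(character(), character(), character()),
               "at least one entry")
})

test_that("corpus-level NER equals the brute-force matcher", {
  dict <- small_dict()
  for (seed in 1:4) {
    corpus <- random_entity_corpus(30, dict$entries, seed = seed)
    fast <- corpus_mentions(corpus, dict)
    for (k in seq_len(nrow(corpus))) {
      expected <- bf_match_entities(corpus$tokens[[k]], dict$entries)
      got <- fast[doc_id == corpus$doc_id[k], .(entity_id, entity_class)]
      setorder(got, entity_id)
      expect_equal(as.data.frame(got), as.data.frame(expected),
                   ignore_attr = TRUE)
    }
  }
})

test_that("mentions are invariant to duplicated sentences", {
  dict <- small_dict()
  base <- "leptin modulates insulin receptor signalling in t2d"
  c1 <- make_corpus(base)
  c2 <- make_corpus(paste(base, base, base))
  m1 <- corpus_mentions(c1, dict)
  m2 <- corpus_mentions(c2, dict)
  expect_identical(m1$entity_id, m2$entity_id)
})

test_that("jsonl corpora round-trip and records missing fields are skipped", {
  corpus <- make_corpus(c("alpha beta gamma", "delta epsilon"),
                        weeks = c(3L, 7L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus(path, "records_jsonl")
  expect_identical(back$doc_id, corpus$doc_id)
  expect_identical(back$week, corpus$week)
  expect_identical(back$tokens, corpus$tokens)
  expect_identical(attr(back, "skipped"), 0L)

  # add a record with an empty abstract: must be skipped and counted
  lines <- readLines(path)
  lines <- c(lines,
             '{"doc_id":"bad1","week":2,"title":"only a title","abstract":""}')
  writeLines(lines, path)
  expect_message(back2 <- read_corpus(path, "records_jsonl"), "skipped")
  expect_identical(nrow(back2), 2L)
  expect_identical(attr(back2, "skipped"), 1L)

  # empty file gives an empty corpus
  writeLines(character(0), path)
  expect_identical(nrow(read_corpus(path, "records_jsonl")), 0L)
})

test_that("MEDLINE XML records parse with ISO week derivation", {
  xml <- paste0(
    '<PubmedArticleSet>',
    '<PubmedArticle><MedlineCitation><PMID>101</PMID>',
    '<DateRevised><Year>2018</Year><Month>5</Month><Day>28</Day></DateRevised>',
    '<Article><ArticleTitle>A title</ArticleTitle>',
    '<Abstract><AbstractText>Insulin resistance rises.</AbstractText></Abstract>',
    '</Article></MedlineCitation></PubmedArticle>',
    '<PubmedArticle><MedlineCitation><PMID>102</PMID>',
    '<DateRevised><Year>2018</Year><Month>6</Month><Day>4</Day></DateRevised>',
    '<Article><ArticleTitle>No abstract here</ArticleTitle></Article>',
    '</MedlineCitation></PubmedArticle>',
    '</PubmedArticleSet>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_message(corpus <- read_corpus(path, "medline_xml"), "skipped")
  expect_identical(corpus$doc_id, "101")
  expect_identical(corpus$week, week_index(as.Date("2018-05-28")))
  expect_identical(attr(corpus, "skipped"), 1L)
  # malformed file names the problem
  writeLines("<PubmedArticleSet><PubmedArticle></PubmedArticle>", path)
  expect_error(read_corpus(path, "medline_xml"), "malformed")
})

test_that("week_index maps Mondays to week starts monotonically", {
  expect_identical(week_index(as.Date("1970-01-05")), 0L)
  expect_identical(week_index(as.Date("1970-01-11")), 0L)
  expect_identical(week_index(as.Date("1970-01-12")), 1L)
  dates <- as.Date("2015-01-01") + seq(0, 900, by = 13)
  idx <- week_index(dates)
  expect_true(all(diff(idx) >= 0))
})
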