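#' Map a calendar date to a global ISO week index
#'
#' Weeks are the natural batching unit for literature surveillance: articles
#' are grouped by the week they entered the database. When a record carries a
#' date instead of a week index, the date is mapped to the number of complete
#' ISO-8601 weeks (Monday-started) elapsed since Monday 1970-01-05, giving a
#' single monotone integer axis across years.
#'
#' @param date A `Date` vector, or something `as.Date()` understands.
#' @return Integer week indices (week 0 starts on 1970-01-05).
#' @examples
#' week_index(as.Date("1970-01-05"))  # 0
#' week_index(as.Date("2018-05-28"))
#' @export
week_index <- function(date) {
  d <- as.integer(as.Date(date))
  idx <- as.integer((d - 4L) %/% 7L)
  if (any(idx < 0L, na.rm = TRUE))
    warning("dates before 1970-01-05 yield negative week indices")
  idx
}

#' Build a corpus object from record fields
#'
#' A corpus is a `data.table` with one row per document and columns
#' `doc_id`, `week`, `title`, `abstract` and a `tokens` list-column holding
#' the normalized token stream of title and abstract concatenated.
#'
#' @param doc_id Character identifiers (unique).
#' @param week Integer week indices (all `>= 0`).
#' @param title,abstract Character vectors.
#' @return A `lit_corpus` (also a `data.table`), keyed by `doc_id`.
#' @export
as_corpus <- function(doc_id, week, title, abstract) {
  stopifnot(length(doc_id) == length(week),
            length(doc_id) == length(title),
            length(doc_id) == length(abstract))
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) stop("duplicate doc_id in corpus")
  week <- as.integer(week)
  if (length(week) && any(is.na(week) | week < 0L))
    stop("week indices must be non-negative integers")
  corpus <- data.table(
    doc_id = doc_id, week = week,
    title = as.character(title), abstract = as.character(abstract),
    tokens = tokenize_many(paste(title, abstract))
  )
  setkey(corpus, doc_id)
  setattr(corpus, "class", c("lit_corpus", class(corpus)))
  corpus[]
}

#' @export
print.lit_corpus <- function(x, ...) {
  cat(sprintf("<lit_corpus> %d documents, weeks %s-%s\n", nrow(x),
              if (nrow(x)) min(x$week) else NA, if (nrow(x)) max(x$week) else NA))
  NextMethod()
}

#' Read a corpus of dated abstracts
#'
#' Supports two dialects: `records_jsonl` (one JSON object per line with
#' fields `doc_id`, `week`, `title`, `abstract`) and `medline_xml`
#' (PubMed `PubmedArticle` records; the PMID is the identifier, the week is
#' derived from `DateRevised` via [week_index()]). Only records having both
#' a title and an abstract are mined; records lacking either are skipped and
#' counted in the `skipped` attribute of the result (and reported via
#' `message()`).
#'
#' @param path Path to the corpus file.
#' @param format `"records_jsonl"` or `"medline_xml"`.
#' @return A `lit_corpus`; attribute `skipped` holds the skip count.
#' @export
read_corpus <- function(path, format = c("records_jsonl", "medline_xml")) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  format <- match.arg(format)
  recs <- switch(format,
    records_jsonl = read_records_jsonl(path),
    medline_xml = read_medline_xml(path)
  )
  has_title <- !is.na(recs$title) & nzchar(trimws(recs$title))
  has_abs <- !is.na(recs$abstract) & nzchar(trimws(recs$abstract))
  keep <- has_title & has_abs
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message(n_skip, " record(s) skipped (missing title or abstract)")
  corpus <- as_corpus(recs$doc_id[keep], recs$week[keep],
                      recs$title[keep], recs$abstract[keep])
  setattr(corpus, "skipped", n_skip)
  corpus
}

read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.table(doc_id = character(), week = integer(),
                      title = character(), abstract = character()))
  recs <- lapply(seq_along(lines), function(k) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[k]]),
                    error = function(e) stop("malformed JSONL record at line ",
                                             k, ": ", conditionMessage(e)))
    if (is.null(rec$doc_id) || is.null(rec$week))
      stop("malformed JSONL record at line ", k,
           ": fields 'doc_id' and 'week' are required")
    data.table(doc_id = as.character(rec$doc_id),
               week = as.integer(rec$week),
               title = if (is.null(rec$title)) NA_character_ else as.character(rec$title),
               abstract = if (is.null(rec$abstract)) NA_character_ else as.character(rec$abstract))
  })
  rbindlist(recs)
}

read_medline_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MEDLINE XML: ",
                                           conditionMessage(e)))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0L)
    return(data.table(doc_id = character(), week = integer(),
                      title = character(), abstract = character()))
  one <- function(k) {
    a <- arts[[k]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    if (is.na(pmid) || !nzchar(pmid))
      stop("malformed MEDLINE record #", k, ": missing PMID")
    dr <- xml2::xml_find_first(a, ".//DateRevised")
    if (inherits(dr, "xml_missing"))
      stop("malformed MEDLINE record #", k, " (PMID ", pmid,
           "): missing DateRevised")
    y <- xml2::xml_text(xml2::xml_find_first(dr, "./Year"))
    m <- xml2::xml_text(xml2::xml_find_first(dr, "./Month"))
    d <- xml2::xml_text(xml2::xml_find_first(dr, "./Day"))
    date <- as.Date(sprintf("%s-%02d-%02d", y, as.integer(m), as.integer(d)))
    if (is.na(date))
      stop("malformed MEDLINE record #", k, " (PMID ", pmid,
           "): bad DateRevised")
    ttl <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abs_txt <- if (length(abs_nodes)) paste(xml2::xml_text(abs_nodes),
                                            collapse = " ") else NA_character_
    data.table(doc_id = pmid, week = suppressWarnings(week_index(date)),
               title = ttl, abstract = abs_txt)
  }
  rbindlist(lapply(seq_along(arts), one))
}

#' Write a corpus in the line-delimited record format
#'
#' @param corpus A `lit_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(k) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[k], week = corpus$week[k],
                          title = corpus$title[k],
                          abstract = corpus$abstract[k]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
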