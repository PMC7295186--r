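#' Default English stopword list
#'
#' Read the packaged plain-text stopword list (one word per line), or a
#' user-supplied file of the same shape. Stopwords are only used at n-gram
#' boundaries: a phrase may contain `"of"` but may not start or end with it.
#'
#' @param path Optional path to a custom stopword file.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords_en.txt", package = "litjump")
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Extract frequent n-grams from a corpus
#'
#' Enumerates every contiguous token window whose length lies in `n_range`,
#' keeps windows that neither start nor end with a stopword, and retains
#' those present in at least `min_df` distinct documents. Counting is by
#' document presence, not token frequency, to match the document-level
#' statistics used downstream. Exact posting lists (the set of documents
#' containing each n-gram) are kept so that later co-occurrence counts are
#' exact rather than approximate.
#'
#' @param corpus A `lit_corpus`.
#' @param n_range Integer vector of n-gram lengths, within 1..8
#'   (default `2:6`; unigrams are covered by entity recognition and are
#'   excluded by default).
#' @param min_df Minimum document frequency (default 5).
#' @param stopwords Character vector of boundary stopwords.
#' @return An `ngram_catalog`: list with `ngrams`
#'   (`data.table(ngram, n, df)`), `postings` (`data.table(ngram, doc_id)`),
#'   and `D` (corpus size).
#' @export
extract_ngrams <- function(corpus, n_range = 2:6, min_df = 5L,
                           stopwords = default_stopwords()) {
  n_range <- sort(unique(as.integer(n_range)))
  if (length(n_range) == 0L || min(n_range) < 1L || max(n_range) > 8L)
    stop("n_range must lie within [1, 8]")
  if (min_df < 1L) stop("min_df must be >= 1")
  D <- nrow(corpus)
  empty <- new_catalog(
    data.table(ngram = character(), n = integer(), df = integer()),
    data.table(ngram = character(), doc_id = character()), D)
  if (D == 0L) return(empty)
  long <- corpus[, .(token = tokens[[1L]]), by = doc_id]
  if (nrow(long) == 0L) return(empty)
  post_list <- vector("list", length(n_range))
  for (k in seq_along(n_range)) {
    n <- n_range[k]
    if (n == 1L) {
      key <- long$token
      valid <- rep(TRUE, nrow(long))
      lastv <- key
    } else {
      shifted <- lapply(0:(n - 1L), function(s)
        long[, shift(token, -s), by = doc_id]$V1)
      key <- do.call(paste, shifted)
      valid <- !Reduce(`|`, lapply(shifted, is.na))
      lastv <- shifted[[n]]
    }
    ok <- valid & !(long$token %chin% stopwords) & !(lastv %chin% stopwords)
    if (!any(ok)) next
    post_list[[k]] <- unique(data.table(ngram = key[ok], n = n,
                                        doc_id = long$doc_id[ok]))
  }
  postings <- rbindlist(post_list[!vapply(post_list, is.null, logical(1))])
  if (is.null(postings) || nrow(postings) == 0L) return(empty)
  ngrams <- postings[, .(n = n[1L], df = .N), by = ngram]
  keep <- ngrams[df >= min_df, ngram]
  ngrams <- ngrams[ngram %chin% keep]
  postings <- postings[ngram %chin% keep, .(ngram, doc_id)]
  setorder(ngrams, ngram)
  setorder(postings, ngram, doc_id)
  new_catalog(ngrams, postings, D)
}

new_catalog <- function(ngrams, postings, D, disease_df = NULL) {
  structure(list(ngrams = ngrams, postings = postings, D = D,
                 disease_df = disease_df),
            class = "ngram_catalog")
}

#' @export
print.ngram_catalog <- function(x, ...) {
  cat(sprintf("<ngram_catalog> %d n-grams over %d documents\n",
              nrow(x$ngrams), x$D))
  invisible(x)
}

#' Keep n-grams over-represented in disease-mentioning documents
#'
#' An n-gram survives when (i) it co-occurs with the disease in at least
#' `min_co` documents, (ii) its over-representation ratio
#' `obs_co * D / (df * disease_df)` is at least `min_ratio`, and (iii) a
#' one-sided Fisher test of the co-occurrence is significant at `alpha`.
#' The ratio compares the observed co-document count with the count expected
#' if the n-gram and the disease were mentioned independently.
#'
#' @param catalog An `ngram_catalog`.
#' @param disease_doc_ids Character vector of documents mentioning the
#'   disease (subset of the corpus).
#' @param min_co Minimum co-document count (default 3).
#' @param min_ratio Minimum over-representation ratio (default 2).
#' @param alpha Significance level for the Fisher filter (default 0.01).
#' @return A filtered `ngram_catalog` whose `ngrams` table gains columns
#'   `disease_co`, `ratio`, `p_value`; `disease_df` is recorded.
#' @export
disease_overrepresented <- function(catalog, disease_doc_ids, min_co = 3L,
                                    min_ratio = 2, alpha = 0.01) {
  stopifnot(inherits(catalog, "ngram_catalog"))
  disease_doc_ids <- unique(as.character(disease_doc_ids))
  disease_df <- length(disease_doc_ids)
  if (disease_df == 0L)
    stop("configuration error: no documents mention the disease")
  D <- catalog$D
  co <- catalog$postings[doc_id %chin% disease_doc_ids, .N, by = ngram]
  ngrams <- copy(catalog$ngrams)
  ngrams[, disease_co := 0L]
  ngrams[co, disease_co := i.N, on = "ngram"]
  ngrams[, ratio := (as.numeric(disease_co) * D) /
           (as.numeric(df) * disease_df)]
  ngrams[, p_value := fisher_greater_vec(disease_co, df - disease_co,
                                         disease_df - disease_co,
                                         D - df - disease_df + disease_co)]
  kept <- ngrams[disease_co >= min_co & ratio >= min_ratio & p_value <= alpha]
  postings <- catalog$postings[ngram %chin% kept$ngram]
  new_catalog(kept[], postings, D, disease_df = disease_df)
}

#' Write an n-gram catalog as TSV
#'
#' @param catalog An `ngram_catalog` (filtered or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ngram_tsv <- function(catalog, path) {
  fwrite(catalog$ngrams, path, sep = "\t")
  invisible(path)
}
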