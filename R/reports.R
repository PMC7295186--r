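#' Explain an article's relevance score
#'
#' Lists, for one document, every semantic concept found in it, the member
#' n-grams that matched, each concept's weight, and the total score — the
#' markup-style explanation that makes the scoring transparent: the score
#' is nothing but the sum of the listed weights.
#'
#' @param doc_id Document identifier.
#' @param scores An `article_scores` object from [score_articles()], or an
#'   artifact directory written by [run_stage()] (the `score-articles`
#'   stage must have run there).
#' @return List with `doc_id`, `score`, and `contributions`
#'   (`data.table(concept_id, weight, matched)` sorted by descending
#'   weight, `matched` the pipe-joined member n-grams found).
#' @export
explain_article <- function(doc_id, scores) {
  if (is.character(scores)) {
    path <- file.path(scores, "article_scores.rds")
    if (!file.exists(path))
      stop("no scoring artifacts in '", scores,
           "': run stage 'score-articles' first")
    scores <- readRDS(path)
  }
  id <- doc_id
  row <- scores[scores$doc_id == id]
  if (nrow(row) == 0L) stop("unknown doc_id: ", id)
  contrib <- attr(scores, "contributions")
  contrib <- contrib[contrib$doc_id == id]
  if (nrow(contrib)) {
    detail <- contrib[, .(weight = weight[1L],
                          matched = paste(sort(unique(ngram)),
                                          collapse = "|")),
                      by = concept_id]
    setorder(detail, -weight, concept_id)
  } else {
    detail <- data.table(concept_id = character(), weight = numeric(),
                         matched = character())
  }
  list(doc_id = id, score = row$score[1L], contributions = detail)
}

#' Summary of a manual inspection of top-scoring abstracts
#'
#' Given per-article flags from a manual review — does the abstract mention
#' the disease explicitly, and does it carry the disease's curation tag —
#' counts the four cells of interest, in particular the complement: the
#' articles ranked highly although neither the text nor the tagging links
#' them to the disease explicitly.
#'
#' @param explicit Logical vector: explicit disease mention in the
#'   abstract.
#' @param tagged Logical vector (same length): tagged with the disease's
#'   curation term.
#' @return List with `n`, `explicit`, `tagged`, `overlap`, and
#'   `complement` (`n` minus the union of the two flags).
#' @export
inspection_summary <- function(explicit, tagged) {
  stopifnot(length(explicit) == length(tagged))
  explicit <- as.logical(explicit); tagged <- as.logical(tagged)
  list(n = length(explicit),
       explicit = sum(explicit),
       tagged = sum(tagged),
       overlap = sum(explicit & tagged),
       complement = sum(!explicit & !tagged))
}
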