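#' Pointwise mutual information of observed vs expected co-mentioning
#'
#' `log10(observed / expected)`, the building block of concept weights: a
#' value of 1 means the concept and the protein are co-mentioned ten times
#' as often as expected if they were mentioned independently. A zero
#' observed count is floored at `floor0` (default 0.5 documents) so the
#' logarithm stays finite; the floor is applied only when `observed == 0`.
#'
#' @param observed Observed co-document counts (vector ok).
#' @param expected Expected co-document counts under independence,
#'   `df_concept * df_protein / D`; must be positive.
#' @param floor0 Count substituted for an observed zero (default 0.5).
#' @return `log10` ratios, finite.
#' @export
pmi_weight <- function(observed, expected, floor0 = 0.5) {
  if (any(expected <= 0)) stop("expected counts must be positive")
  num <- ifelse(observed == 0, floor0, observed)
  log10(num / expected)
}

#' Weight semantic concepts by co-mentioning with the core proteins
#'
#' For every concept and every core protein, the observed number of
#' documents containing both a member n-gram of the concept and the protein
#' is compared with the count expected under independence, log-transformed
#' ([pmi_weight()]), and the concept's weight is the arithmetic mean of
#' these pointwise mutual information values across all K core proteins.
#' Concepts used in the same articles as the core proteins — and the more
#' exclusively so, the better — therefore get high weights.
#'
#' @param concepts A `semantic_concepts` object.
#' @param catalog The `ngram_catalog` with exact postings for the members.
#' @param core A `core_protein_set` (or character vector of protein ids).
#' @param mentions Long mention table from [corpus_mentions()].
#' @param D Corpus size (number of documents).
#' @return `data.table(concept_id, weight)`; the per-protein PMI matrix
#'   (concepts x proteins) is attached as attribute `pmi`.
#' @export
concept_weights <- function(concepts, catalog, core, mentions, D) {
  core_ids <- if (inherits(core, "core_protein_set")) core$protein_id
              else as.character(core)
  K <- length(core_ids)
  if (K == 0L) stop("core protein set is empty")
  doc_con <- unique(catalog$postings[concepts$members, on = "ngram",
                                     allow.cartesian = TRUE
                                     ][!is.na(doc_id), .(doc_id, concept_id)])
  cids <- sort(unique(concepts$members$concept_id))
  prot_men <- unique(mentions[entity_id %chin% core_ids,
                              .(doc_id, protein_id = entity_id)])
  df_p <- prot_men[, .N, by = protein_id]
  missing_p <- setdiff(core_ids, df_p$protein_id)
  if (length(missing_p))
    stop("configuration error: core protein(s) unseen in the corpus: ",
         paste(head(missing_p, 5), collapse = ", "))
  docs <- sort(unique(c(doc_con$doc_id, prot_men$doc_id)))
  Xc <- Matrix::sparseMatrix(i = match(doc_con$doc_id, docs),
                             j = match(doc_con$concept_id, cids),
                             x = 1, dims = c(length(docs), length(cids)))
  Xp <- Matrix::sparseMatrix(i = match(prot_men$doc_id, docs),
                             j = match(prot_men$protein_id, core_ids),
                             x = 1, dims = c(length(docs), K))
  obs <- as.matrix(Matrix::crossprod(Xc, Xp))     # concepts x proteins
  df_c <- Matrix::colSums(Xc)
  expd <- outer(as.numeric(df_c),
                as.numeric(df_p$N[match(core_ids, df_p$protein_id)])) / D
  pmi <- pmi_weight(obs, expd)
  dimnames(pmi) <- list(cids, core_ids)
  out <- data.table(concept_id = cids, weight = rowMeans(pmi))
  setattr(out, "pmi", pmi)
  out[]
}

# documents x concepts presence: scan each document's token windows for
# member n-grams (works for any corpus, including articles newer than the
# catalog the concepts were learned from)
doc_concepts <- function(corpus, concepts) {
  members <- concepts$members
  member_n <- nchar(members$ngram) - nchar(gsub(" ", "", members$ngram,
                                                fixed = TRUE)) + 1L
  lens <- sort(unique(member_n))
  long <- corpus[, .(token = tokens[[1L]]), by = doc_id]
  hits <- list()
  for (n in lens) {
    if (nrow(long) == 0L) break
    if (n == 1L) {
      key <- long$token
      valid <- rep(TRUE, nrow(long))
    } else {
      shifted <- lapply(0:(n - 1L), function(s)
        long[, shift(token, -s), by = doc_id]$V1)
      key <- do.call(paste, shifted)
      valid <- !Reduce(`|`, lapply(shifted, is.na))
    }
    idx <- which(valid & key %chin% members[member_n == n, ngram])
    if (length(idx))
      hits[[as.character(n)]] <- data.table(doc_id = long$doc_id[idx],
                                            ngram = key[idx])
  }
  if (length(hits) == 0L)
    return(data.table(doc_id = character(), concept_id = character(),
                      ngram = character()))
  hits <- unique(rbindlist(hits))
  out <- members[hits, on = "ngram"][, .(doc_id, concept_id, ngram)]
  setorder(out, doc_id, concept_id, ngram)
  out[]
}

#' Score articles by summing the weights of their semantic concepts
#'
#' Each concept contributes its weight once per article — however many of
#' its member n-grams occur — and the article score is the sum over the
#' distinct concepts present. The matched members and per-concept
#' contributions are retained so every score can be explained
#' ([explain_article()]).
#'
#' @param corpus A `lit_corpus`.
#' @param concepts A `semantic_concepts` object.
#' @param weights `data.table(concept_id, weight)` from [concept_weights()].
#' @return An `article_scores` object: `data.table(doc_id, week, score)`
#'   for every document (score 0 when no concept is present), with the
#'   match table `data.table(doc_id, concept_id, ngram, weight)` as
#'   attribute `contributions`.
#' @export
score_articles <- function(corpus, concepts, weights) {
  dc <- doc_concepts(corpus, concepts)
  dc <- weights[dc, on = "concept_id"]
  per_doc <- unique(dc[, .(doc_id, concept_id, weight)])[
    , .(score = sum(weight)), by = doc_id]
  out <- corpus[, .(doc_id, week)]
  out <- per_doc[out, on = "doc_id"]
  out[is.na(score), score := 0]
  setcolorder(out, c("doc_id", "week", "score"))
  setorder(out, doc_id)
  setattr(out, "contributions",
          dc[, .(doc_id, concept_id, ngram, weight)][order(doc_id, -weight,
                                                           concept_id)])
  setattr(out, "class", c("article_scores", class(out)))
  out[]
}

#' Weekly protein scores: the best article mentioning each protein
#'
#' A protein's score in a week is the maximum relevance score among that
#' week's articles mentioning it; proteins not mentioned in a week are
#' absent (they count as 0 inside sliding windows).
#'
#' @param article_scores An `article_scores` table (or any
#'   `data.table(doc_id, week, score)`).
#' @param mentions Long mention table; only rows with
#'   `entity_class == "protein"` are used if the column is present.
#' @return `data.table(protein_id, week, score, top_doc)` where `top_doc`
#'   is the doc id of the maximising article (ties: lowest doc id).
#' @export
weekly_protein_scores <- function(article_scores, mentions) {
  men <- if ("entity_class" %in% names(mentions))
    mentions[entity_class == "protein"] else copy(mentions)
  men <- men[, .(doc_id, protein_id = entity_id)]
  joined <- article_scores[men, on = "doc_id", nomatch = NULL]
  if (nrow(joined) == 0L)
    return(data.table(protein_id = character(), week = integer(),
                      score = numeric(), top_doc = character()))
  setorder(joined, protein_id, week, -score, doc_id)
  out <- joined[, .(score = score[1L], top_doc = doc_id[1L]),
                by = .(protein_id, week)]
  out[]
}

# linearly decreasing top-M weights u_i = (M+1-i) / sum_j (M+1-j)
topm_weights <- function(M) {
  u <- (M + 1 - seq_len(M))
  u / sum(u)
}

#' Combined windowed relevance score
#'
#' Takes the weekly scores of the `W` weeks ending at the evaluation week
#' (missing weeks count as 0), keeps the `M` highest, and returns their
#' weighted sum with linearly decreasing weights summing to one, so the
#' highest weekly score contributes most but no single week can dominate:
#' contributions have to be spread out over time.
#'
#' @param scores Numeric vector of weekly scores inside the window (length
#'   at most `W`; shorter vectors are zero-padded). Order is irrelevant.
#' @param W Window length in weeks (default 260, i.e. five years).
#' @param M Number of top weeks combined (default 40).
#' @return The combined score (scalar).
#' @export
combined_relevance <- function(scores, W = 260L, M = 40L) {
  if (W < M) stop("configuration error: window W must be >= M")
  if (length(scores) > W)
    stop("more scores than window weeks; pass at most W values")
  x <- c(scores, rep(0, W - length(scores)))
  top <- sort(x, decreasing = TRUE)[seq_len(M)]
  sum(topm_weights(M) * top)
}

#' Per-protein combined scores and ranks over time
#'
#' Evaluates [combined_relevance()] for every protein at every week and
#' ranks the proteins within each week (rank 1 = most relevant; ties broken
#' by ascending protein id).
#'
#' @param weekly Output of [weekly_protein_scores()].
#' @param proteins Character vector: the protein universe to rank (proteins
#'   never mentioned get combined score 0).
#' @param weeks Integer vector of evaluation weeks (default: all weeks from
#'   the minimum to the maximum seen in `weekly`).
#' @param W,M Window parameters, see [combined_relevance()].
#' @return `data.table(protein_id, week, combined, rank)`.
#' @export
relevance_series <- function(weekly, proteins, weeks = NULL,
                             W = 260L, M = 40L) {
  if (W < M) stop("configuration error: window W must be >= M")
  proteins <- sort(unique(as.character(proteins)))
  if (is.null(weeks)) {
    if (nrow(weekly) == 0L) stop("no weekly scores and no weeks given")
    weeks <- seq(min(weekly$week), max(weekly$week))
  }
  weeks <- sort(unique(as.integer(weeks)))
  all_weeks <- seq(min(c(weeks, weekly$week)), max(weeks))
  mat <- matrix(0, nrow = length(proteins), ncol = length(all_weeks),
                dimnames = list(proteins, as.character(all_weeks)))
  wk <- weekly[protein_id %chin% proteins & week %in% all_weeks]
  if (nrow(wk))
    mat[cbind(match(wk$protein_id, proteins),
              match(wk$week, all_weeks))] <- wk$score
  u <- topm_weights(M)
  res <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    w <- weeks[k]
    cols <- which(all_weeks > w - W & all_weeks <= w)
    sub <- mat[, cols, drop = FALSE]
    comb <- apply(sub, 1L, function(x) {
      x <- c(x, rep(0, W - length(x)))
      sum(u * sort(x, decreasing = TRUE)[seq_len(M)])
    })
    res[[k]] <- data.table(protein_id = proteins, week = w, combined = comb,
                           rank = rank_proteins(setNames(comb, proteins)))
  }
  rbindlist(res)
}

#' Rank proteins by combined score
#'
#' Rank 1 is the highest score; ties are broken by ascending protein id so
#' rankings are a deterministic permutation of `1..N`.
#'
#' @param scores Named numeric vector (names = protein ids).
#' @return Integer ranks, named like `scores`.
#' @export
rank_proteins <- function(scores) {
  if (length(scores) == 0L) stop("at least one scored protein is required")
  ord <- order(-scores, names(scores))
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  names(rk) <- names(scores)
  rk
}

#' Fold improvement between two ranks
#'
#' `initial_rank / final_rank`, rounded half-up to one decimal: the factor
#' by which a protein improved its position.
#'
#' @param initial_rank,final_rank Ranks, `>= 1`.
#' @return The fold change at one decimal.
#' @examples
#' rank_fold_change(125, 24)  # 5.2
#' @export
rank_fold_change <- function(initial_rank, final_rank) {
  stopifnot(all(initial_rank >= 1), all(final_rank >= 1))
  x <- initial_rank / final_rank
  floor(x * 10 + 0.5) / 10
}

#' ROC curve and AUC for recovering a benchmark protein set
#'
#' The AUC is computed with the rank-sum (Mann-Whitney) formulation using
#' midranks, so tied scores count half; the emitted ROC points trace the
#' curve over distinct score thresholds.
#'
#' @param scores Named numeric vector of protein scores.
#' @param positives Character vector of benchmark (positive) protein ids;
#'   must be a non-empty strict subset of `names(scores)`.
#' @return List with `auc` and `points`
#'   (`data.table(threshold, fpr, tpr)`).
#' @export
evaluate_roc <- function(scores, positives) {
  labels <- names(scores) %in% positives
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate benchmark: positives must be a non-empty strict subset")
  r <- rank(scores)                      # midranks for ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  points <- data.table(threshold = s[last],
                       fpr = fp[last] / n0, tpr = tp[last] / n1)
  points <- rbind(data.table(threshold = Inf, fpr = 0, tpr = 0), points)
  list(auc = auc, points = points)
}
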