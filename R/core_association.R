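#' Document-level 2x2 co-mention contingency table
#'
#' Counts documents by presence/absence of two entities: `a` mention both,
#' `b` only `A`, `c` only `B`, `d` neither, so `a + b + c + d` equals the
#' corpus size. Presence is document-level (a repeated mention counts once).
#'
#' @param mentions Long mention table from [corpus_mentions()] (columns
#'   `doc_id`, `entity_id`).
#' @param n_docs Total number of documents in the corpus.
#' @param A,B Entity ids.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
comention_table <- function(mentions, n_docs, A, B) {
  stopifnot(n_docs >= 1L)
  docs_A <- unique(mentions[entity_id == A, doc_id])
  docs_B <- unique(mentions[entity_id == B, doc_id])
  a <- length(intersect(docs_A, docs_B))
  b <- length(docs_A) - a
  cc <- length(docs_B) - a
  d <- n_docs - a - b - cc
  if (d < 0L) stop("n_docs smaller than the number of mentioning documents")
  c(a = a, b = b, c = cc, d = d)
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' The one-sided (`greater`) test asks whether the two entities are
#' co-mentioned more often than expected under independence of the margins —
#' the direction that defines a positive literature association. Computed
#' from the hypergeometric tail; `two_sided` delegates to
#' [stats::fisher.test()]. Degenerate margins (an entity mentioned in no
#' document) give `p = 1` by convention, with a message.
#'
#' @param tab Named vector or list with elements `a`, `b`, `c`, `d`
#'   (as from [comention_table()]).
#' @param side `"greater"` (default) or `"two_sided"`.
#' @return A p-value in `(0, 1]`.
#' @export
fisher_exact_p <- function(tab, side = c("greater", "two_sided")) {
  side <- match.arg(side)
  a <- as.numeric(tab[["a"]]); b <- as.numeric(tab[["b"]])
  cc <- as.numeric(tab[["c"]]); d <- as.numeric(tab[["d"]])
  if (any(c(a, b, cc, d) < 0)) stop("contingency counts must be non-negative")
  if ((a + b) == 0 || (a + cc) == 0) {
    message("degenerate margin (entity never mentioned): p = 1")
    return(1)
  }
  if (side == "greater") {
    fisher_greater_vec(a, b, cc, d)
  } else {
    stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))$p.value
  }
}

# vectorized hypergeometric upper tail P(X >= a) with margins
# (a+b) A-docs, (c+d) non-A docs, (a+c) B-docs drawn
fisher_greater_vec <- function(a, b, cc, d) {
  p <- stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Select the core protein set for a disease
#'
#' Every protein mentioned in the corpus is tested for over-co-mentioning
#' with the disease (one-sided Fisher) and the `K` most significant become
#' the "core proteins" that anchor concept weighting downstream. Ties are
#' broken by ascending protein id so the selection is reproducible.
#'
#' @param corpus A `lit_corpus`.
#' @param dict An `entity_dictionary` containing the proteins (and
#'   the disease, unless `mentions` is supplied).
#' @param disease_id Entity id of the disease.
#' @param K Target size of the core set (default 100).
#' @param mentions Optional precomputed [corpus_mentions()] table.
#' @return A `core_protein_set`: `data.table(rank, protein_id, a, b, c, d,
#'   p_value)` ordered by ascending p, at most `K` rows; attribute `K`.
#' @export
select_core_proteins <- function(corpus, dict, disease_id, K = 100L,
                                 mentions = NULL) {
  stopifnot(K >= 1L)
  if (is.null(mentions)) mentions <- corpus_mentions(corpus, dict)
  n_docs <- nrow(corpus)
  disease_docs <- unique(mentions[entity_id == disease_id, doc_id])
  n_dis <- length(disease_docs)
  prot <- mentions[entity_class == "protein" & entity_id != disease_id]
  if (nrow(prot) == 0L) stop("no protein mentions found in the corpus")
  counts <- prot[, .(df = uniqueN(doc_id),
                     a = sum(unique(doc_id) %chin% disease_docs)),
                 by = .(protein_id = entity_id)]
  counts[, `:=`(b = df - a, c = n_dis - a, d = n_docs - df - (n_dis - a))]
  counts[, p_value := fisher_greater_vec(a, b, c, d)]
  if (n_dis == 0L) counts[, p_value := 1]
  setorder(counts, p_value, protein_id)
  if (nrow(counts) < K)
    warning(sprintf("only %d proteins mentioned; returning all (K = %d)",
                    nrow(counts), K))
  out <- head(counts, K)[, .(protein_id, a, b, c, d, p_value)]
  out[, rank := seq_len(.N)]
  setcolorder(out, c("rank", "protein_id", "a", "b", "c", "d", "p_value"))
  setattr(out, "class", c("core_protein_set", class(out)))
  setattr(out, "K", as.integer(K))
  out[]
}

#' @export
print.core_protein_set <- function(x, ...) {
  cat(sprintf("<core_protein_set> %d proteins (K = %d)\n", nrow(x),
              attr(x, "K")))
  NextMethod()
}
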