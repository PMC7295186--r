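#' String similarity between two n-grams
#'
#' Order-invariant token-set similarity designed to absorb the two ways a
#' phrase is commonly re-spelled in abstracts: word rearrangement
#' (`"type 2 diabetes"` / `"diabetes type 2"`) and small spelling variation
#' or numeral aliasing (`"ii"` vs `"2"`). Two tokens match when they are
#' equal after roman/arabic numeral normalization, or differ by a single
#' edit when both have at least 4 characters. The similarity is the size of
#' a maximum one-to-one token matching divided by the longer phrase length,
#' hence symmetric and in `[0, 1]`.
#'
#' @param a,b Character vectors of normalized tokens (or single strings,
#'   which are split on spaces).
#' @return Similarity in `[0, 1]`.
#' @examples
#' string_similarity("type 2 diabetes", "diabetes type ii")  # 1
#' @export
string_similarity <- function(a, b) {
  a <- as_token_vec(a); b <- as_token_vec(b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  an <- normalize_numerals(a); bn <- normalize_numerals(b)
  m <- token_match_matrix(an, bn)
  max_bipartite_matching(m) / max(length(a), length(b))
}

as_token_vec <- function(x) {
  if (length(x) == 1L && grepl(" ", x, fixed = TRUE))
    x <- strsplit(x, " ", fixed = TRUE)[[1L]]
  x[nzchar(x)]
}

roman_map <- c(i = "1", ii = "2", iii = "3", iv = "4", v = "5", vi = "6",
               vii = "7", viii = "8", ix = "9", x = "10")

normalize_numerals <- function(tokens) {
  hit <- tokens %in% names(roman_map)
  tokens[hit] <- roman_map[tokens[hit]]
  tokens
}

token_match_matrix <- function(a, b) {
  eq <- outer(a, b, `==`)
  long_a <- nchar(a) >= 4L
  long_b <- nchar(b) >= 4L
  if (any(long_a) && any(long_b)) {
    ed <- utils::adist(a, b)
    eq <- eq | (ed <= 1L & outer(long_a, long_b, `&`))
  }
  eq
}

# Kuhn's augmenting-path maximum bipartite matching; token counts are tiny
max_bipartite_matching <- function(adj) {
  nr <- nrow(adj); nc <- ncol(adj)
  match_col <- rep(0L, nc)
  augment <- function(r, seen_env) {
    for (cidx in which(adj[r, ])) {
      if (!seen_env$seen[cidx]) {
        seen_env$seen[cidx] <- TRUE
        if (match_col[cidx] == 0L || augment(match_col[cidx], seen_env)) {
          match_col[cidx] <<- r
          return(TRUE)
        }
      }
    }
    FALSE
  }
  total <- 0L
  for (r in seq_len(nr)) {
    env <- new.env(parent = emptyenv())
    env$seen <- rep(FALSE, nc)
    if (augment(r, env)) total <- total + 1L
  }
  total
}

#' Pairwise co-occurrence over-representation matrix
#'
#' For a catalog with exact posting lists, cell `(i, j)` holds
#' `co_docs(i, j) * D / (df_i * df_j)`: how many times more often the two
#' n-grams appear in the same document than expected if they were mentioned
#' independently. Cells with no co-occurrence are (structurally) zero, and
#' the diagonal equals `D / df_i`. Rows of this matrix characterize the
#' context an n-gram is used in.
#'
#' @param catalog An `ngram_catalog` (typically disease-filtered).
#' @return A symmetric sparse `Matrix` with n-grams as dimnames.
#' @export
context_overrepresentation_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "ngram_catalog"))
  ngrams <- catalog$ngrams$ngram
  M <- length(ngrams)
  post <- catalog$postings
  docs <- sort(unique(post$doc_id))
  X <- Matrix::sparseMatrix(
    i = match(post$doc_id, docs),
    j = match(post$ngram, ngrams),
    x = 1, dims = c(length(docs), M),
    dimnames = list(docs, ngrams))
  C <- Matrix::crossprod(X)            # co-document counts; diagonal = df
  df <- catalog$ngrams$df
  scale <- Matrix::Diagonal(x = 1 / df)
  R <- catalog$D * (scale %*% C %*% scale)
  dimnames(R) <- list(ngrams, ngrams)
  R
}

#' Context similarity of two rows of the over-representation matrix
#'
#' Cosine similarity of rows `i` and `j` after a `log1p` transform (which
#' damps the heavy right tail of over-representation ratios), excluding
#' columns `i` and `j` themselves so the comparison reflects only the
#' *shared third-party* context: two phrases that are never co-mentioned
#' with each other can still be perfectly context-similar.
#'
#' @param R Matrix from [context_overrepresentation_matrix()].
#' @param i,j Row names or indices.
#' @return Similarity in `[0, 1]`; 0 for an all-zero (excluded) row.
#' @export
context_similarity <- function(R, i, j) {
  if (is.character(i)) i <- match(i, rownames(R))
  if (is.character(j)) j <- match(j, rownames(R))
  L <- log1p(as.matrix(R[c(i, j), , drop = FALSE]))
  li <- L[1L, ]; lj <- L[2L, ]
  li[c(i, j)] <- 0; lj[c(i, j)] <- 0
  ni <- sqrt(sum(li^2)); nj <- sqrt(sum(lj^2))
  if (ni == 0 || nj == 0) {
    message("all-zero context row: similarity 0")
    return(0)
  }
  min(1, max(0, sum(li * lj) / (ni * nj)))
}

# dense all-pairs version of context_similarity, used by the graph builder
context_similarity_matrix <- function(R) {
  L <- as.matrix(log1p(R))
  M <- nrow(L)
  dg <- diag(L)
  S <- L %*% L                       # full row dot products (L symmetric)
  rs2 <- rowSums(L^2)
  dotM <- S - L * (matrix(dg, M, M) + matrix(dg, M, M, byrow = TRUE))
  ni2 <- matrix(rs2 - dg^2, M, M) - L^2
  nj2 <- t(ni2)
  denom <- sqrt(pmax(ni2, 0) * pmax(nj2, 0))
  sim <- ifelse(denom > 0, dotM / denom, 0)
  sim[!is.finite(sim)] <- 0
  sim <- pmin(pmax(sim, 0), 1)
  diag(sim) <- ifelse(rs2 - dg^2 > 0, 1, 0)
  dimnames(sim) <- dimnames(R)
  sim
}

#' Build the n-gram similarity graph
#'
#' Realizes the "both measures simultaneously" clustering input: an
#' undirected edge is created whenever the string similarity reaches
#' `string_threshold` *or* the context similarity reaches
#' `context_threshold`; both weights are stored on the edge together with
#' the convex combination `w_combined = lambda * w_string +
#' (1 - lambda) * w_context` that the Markov clustering operates on.
#'
#' @param catalog A disease-filtered `ngram_catalog`.
#' @param string_threshold Edge threshold on string similarity (default 0.8).
#' @param context_threshold Edge threshold on context similarity
#'   (default 0.5).
#' @param lambda Mixing weight of the string component in `w_combined`
#'   (default 0.5).
#' @return A `similarity_graph`: list with `nodes`
#'   (`data.table(ngram, df)`) and `edges` (`data.table(i, j, w_string,
#'   w_context, w_combined)` with `i < j` lexicographically).
#' @export
build_similarity_graph <- function(catalog, string_threshold = 0.8,
                                   context_threshold = 0.5, lambda = 0.5) {
  stopifnot(string_threshold >= 0, string_threshold <= 1,
            context_threshold >= 0, context_threshold <= 1,
            lambda >= 0, lambda <= 1)
  ngrams <- catalog$ngrams$ngram
  M <- length(ngrams)
  nodes <- catalog$ngrams[, .(ngram, df)]
  if (M < 2L)
    return(new_similarity_graph(nodes, empty_edges(), lambda))
  R <- context_overrepresentation_matrix(catalog)
  wc <- context_similarity_matrix(R)
  toks <- lapply(strsplit(ngrams, " ", fixed = TRUE), normalize_numerals)
  pairs <- candidate_string_pairs(toks, M)
  ws <- matrix(0, M, M)
  if (nrow(pairs)) {
    sims <- vapply(seq_len(nrow(pairs)), function(k) {
      string_similarity(toks[[pairs$i[k]]], toks[[pairs$j[k]]])
    }, numeric(1))
    ws[cbind(pairs$i, pairs$j)] <- sims
    ws[cbind(pairs$j, pairs$i)] <- sims
  }
  sel <- which(upper.tri(ws) & (ws >= string_threshold | wc >= context_threshold),
               arr.ind = TRUE)
  if (nrow(sel) == 0L)
    return(new_similarity_graph(nodes, empty_edges(), lambda))
  edges <- data.table(
    i = ngrams[sel[, 1L]], j = ngrams[sel[, 2L]],
    w_string = ws[sel], w_context = wc[sel])
  edges[, w_combined := lambda * w_string + (1 - lambda) * w_context]
  swap <- edges$i > edges$j
  if (any(swap)) edges[swap, c("i", "j") := .(j, i)]
  setorder(edges, i, j)
  new_similarity_graph(nodes, edges, lambda)
}

empty_edges <- function() {
  data.table(i = character(), j = character(), w_string = numeric(),
             w_context = numeric(), w_combined = numeric())
}

new_similarity_graph <- function(nodes, edges, lambda) {
  structure(list(nodes = nodes, edges = edges, lambda = lambda),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges (lambda = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$lambda))
  invisible(x)
}

# all pairs for small graphs; token-sharing blocking for large ones (a pair
# whose every token differs is not a spelling variant in practice)
candidate_string_pairs <- function(toks, M, all_pairs_limit = 800L) {
  if (M <= all_pairs_limit) {
    idx <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
    return(data.table(i = idx[, 1L], j = idx[, 2L]))
  }
  long <- data.table(idx = rep(seq_len(M), lengths(toks)),
                     token = unlist(toks))
  long <- unique(long)
  pairs <- long[long, on = "token", allow.cartesian = TRUE
                ][idx < i.idx, .(i = idx, j = i.idx)]
  unique(pairs)
}
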