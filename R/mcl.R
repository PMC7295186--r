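#' Markov clustering of the n-gram similarity graph
#'
#' Runs the MCL flow simulation on the combined-weight adjacency matrix:
#' self-loops are added (each node's loop weight is its maximum incident
#' edge weight, or 1 for an isolated node), columns are normalized to sum
#' one, and then expansion (matrix squaring) alternates with inflation
#' (entry-wise power followed by column re-normalization) until the matrix
#' change falls below `tol` or `max_iter` iterations have run. The
#' attractor structure of the limit matrix defines a hard partition of the
#' nodes into semantic concepts; singleton concepts are allowed. Each
#' concept is represented by its most frequent member n-gram (highest
#' document frequency, ties broken lexicographically).
#'
#' @param graph A `similarity_graph`.
#' @param inflation Inflation exponent, `> 1` (default 2).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence threshold on the maximum absolute entry change
#'   of the column-stochastic matrix (default 1e-6).
#' @return A `semantic_concepts` object: list with `concepts`
#'   (`data.table(concept_id, representative, size)`), `members`
#'   (`data.table(concept_id, ngram)`), and `diagnostics` (iterations run,
#'   converged flag, maximum deviation of any column sum from 1 observed
#'   after normalization steps).
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  nodes <- graph$nodes
  M <- nrow(nodes)
  if (M == 0L) stop("graph is empty")
  A <- matrix(0, M, M, dimnames = list(nodes$ngram, nodes$ngram))
  if (nrow(graph$edges)) {
    ei <- match(graph$edges$i, nodes$ngram)
    ej <- match(graph$edges$j, nodes$ngram)
    A[cbind(ei, ej)] <- graph$edges$w_combined
    A[cbind(ej, ei)] <- graph$edges$w_combined
  }
  loop <- apply(A, 2L, max)
  loop[loop <= 0] <- 1
  diag(A) <- loop
  normalize <- function(m) sweep(m, 2L, colSums(m), "/")
  Mcur <- normalize(A)
  max_colsum_dev <- max(abs(colSums(Mcur) - 1))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Mexp <- Mcur %*% Mcur
    Minf <- Mexp^inflation
    Mnew <- normalize(Minf)
    Mnew[Mnew < 1e-12] <- 0
    Mnew <- normalize(Mnew)
    max_colsum_dev <- max(max_colsum_dev, abs(colSums(Mnew) - 1))
    delta <- max(abs(Mnew - Mcur))
    Mcur <- Mnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; using the current partition")
  # clusters = connected components of the limit matrix support; distinct
  # attractor systems have disjoint support, so components are exact
  support <- (Mcur > 1e-5)
  support <- (support | t(support)) * 1
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  members <- data.table(ngram = nodes$ngram, cluster = comp,
                        df = nodes$df)
  reps <- members[order(-df, ngram), .(representative = ngram[1L],
                                       size = .N), by = cluster]
  setorder(reps, -size, representative)
  reps[, concept_id := sprintf("C%04d", seq_len(.N))]
  members <- reps[, .(cluster, concept_id)][members, on = "cluster"]
  concepts <- reps[, .(concept_id, representative, size)]
  members <- members[, .(concept_id, ngram)]
  setorder(members, concept_id, ngram)
  structure(list(concepts = concepts, members = members,
                 diagnostics = list(iterations = iters, converged = converged,
                                    max_colsum_dev = max_colsum_dev)),
            class = "semantic_concepts")
}

#' @export
print.semantic_concepts <- function(x, ...) {
  cat(sprintf("<semantic_concepts> %d concepts over %d n-grams\n",
              nrow(x$concepts), nrow(x$members)))
  invisible(x)
}

#' Concept summary table
#'
#' Joins each concept with its abstract count (documents containing any
#' member n-gram) and, when weights have been computed, its weight — the
#' layout of the ranked concept reports.
#'
#' @param concepts A `semantic_concepts` object.
#' @param catalog The `ngram_catalog` the concepts were clustered from.
#' @param weights Optional `data.table(concept_id, weight)` from
#'   [concept_weights()].
#' @return `data.table(rank, concept_id, representative, weight?,
#'   abstract_count, size, members)` ordered by descending weight (or
#'   abstract count when no weights are given).
#' @export
concept_table <- function(concepts, catalog, weights = NULL) {
  post <- catalog$postings[concepts$members, on = "ngram",
                           allow.cartesian = TRUE]
  ac <- post[, .(abstract_count = uniqueN(doc_id)), by = concept_id]
  tab <- copy(concepts$concepts)
  tab <- ac[tab, on = "concept_id"]
  tab[is.na(abstract_count), abstract_count := 0L]
  tab[, members := vapply(concept_id, function(cid)
    paste(concepts$members[concept_id == cid, ngram], collapse = "|"),
    character(1))]
  if (!is.null(weights)) {
    tab <- weights[tab, on = "concept_id"]
    setorder(tab, -weight, concept_id)
  } else {
    setorder(tab, -abstract_count, concept_id)
  }
  tab[, rank := seq_len(.N)]
  cols <- c("rank", "concept_id", "representative",
            if (!is.null(weights)) "weight", "abstract_count", "size",
            "members")
  setcolorder(tab, cols)
  tab[]
}
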