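# Small fixtures built in code, shared across test files.

make_corpus <- function(abstracts, weeks = NULL, titles = NULL) {
  n <- length(abstracts)
  if (is.null(weeks)) weeks <- rep(1L, n)
  if (is.null(titles)) titles <- sprintf("title %d", seq_len(n))
  as_corpus(sprintf("doc%02d", seq_len(n)), weeks, titles, abstracts)
}

small_dict <- function() {
  entity_dictionary(
    entity_id = c("INS", "INSR", "LEP", "T2D", "T2D"),
    entity_class = c("protein", "protein", "protein", "disease", "disease"),
    synonym = c("insulin", "insulin receptor", "leptin",
                "type 2 diabetes", "t2d"))
}

# a random corpus of filler words with planted entity tokens, for
# property-style NER comparisons
random_entity_corpus <- function(n_docs, dict_entries, seed) {
  set.seed(seed)
  vocab <- sprintf("f%02d", 1:40)
  syn_tokens <- strsplit(dict_entries$synonym, " ", fixed = TRUE)
  abstracts <- vapply(seq_len(n_docs), function(k) {
    toks <- sample(vocab, sample(8:20, 1), replace = TRUE)
    n_ins <- sample(0:3, 1)
    for (z in seq_len(n_ins)) {
      syn <- syn_tokens[[sample(length(syn_tokens), 1)]]
      at <- sample(0:length(toks), 1)
      toks <- append(toks, syn, after = at)
    }
    paste(toks, collapse = " ")
  }, character(1))
  make_corpus(abstracts, weeks = sample(1:5, n_docs, replace = TRUE))
}

# mention table built directly (bypassing NER) for scoring-side tests
manual_mentions <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r)
    data.table(doc_id = r[[1]], entity_id = r[[2]],
               entity_class = if (length(r) > 2) r[[3]] else "protein")))
}

# concepts object built by hand: members is a list concept_id -> ngrams
manual_concepts <- function(member_list, df = NULL) {
  members <- rbindlist(lapply(names(member_list), function(cid)
    data.table(concept_id = cid, ngram = member_list[[cid]])))
  concepts <- members[, .(representative = ngram[1L], size = .N),
                      by = concept_id]
  structure(list(concepts = concepts[, .(concept_id, representative, size)],
                 members = members,
                 diagnostics = list(iterations = 0L, converged = TRUE,
                                    max_colsum_dev = 0)),
            class = "semantic_concepts")
}

# similarity graph built by hand from an edge list
manual_graph <- function(nodes, edges_df, lambda = 0.5) {
  nodes <- data.table(ngram = nodes,
                      df = rev(seq_along(nodes)))
  edges <- as.data.table(edges_df)
  if (nrow(edges) == 0L)
    edges <- data.table(i = character(), j = character(),
                        w_combined = numeric())
  if (!"w_string" %in% names(edges)) edges[, w_string := w_combined]
  if (!"w_context" %in% names(edges)) edges[, w_context := w_combined]
  structure(list(nodes = nodes, edges = edges, lambda = lambda),
            class = "similarity_graph")
}

# adjacency matrix of a similarity graph (combined weights, no self loops)
graph_adjacency <- function(graph) {
  M <- nrow(graph$nodes)
  A <- matrix(0, M, M, dimnames = list(graph$nodes$ngram, graph$nodes$ngram))
  if (nrow(graph$edges)) {
    ei <- match(graph$edges$i, graph$nodes$ngram)
    ej <- match(graph$edges$j, graph$nodes$ngram)
    A[cbind(ei, ej)] <- graph$edges$w_combined
    A[cbind(ej, ei)] <- graph$edges$w_combined
  }
  A
}

# shared small synthetic run used by several test files (cached per session)
small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(small_sim_cache[[key]])) return(small_sim_cache[[key]])
  cfg <- generator_config(n_weeks = 30L, docs_per_week = 30L,
                          jumper = list(protein_id = "PJUMP", week = 25L,
                                        boost = 6L),
                          seed = seed)
  sim <- generate_corpus(cfg)
  sim$cfg <- cfg
  sim$mentions <- corpus_mentions(sim$corpus, sim$dictionary)
  small_sim_cache[[key]] <- sim
  sim
}
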