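test_that("string similarity absorbs rearrangement, numerals and typos", {
  expect_equal(string_similarity("type 2 diabetes", "diabetes type ii"), 1)
  expect_equal(string_similarity("glucose homeostasis",
                                 "glucose homeostasis"), 1)
  expect_equal(string_similarity("glucose homeostasis", "leptin treatment"),
               0)
  # one-letter edit counts for tokens of length >= 4 only
  expect_equal(string_similarity("insulin resistance",
                                 "insulin resistence"), 1)
  expect_equal(string_similarity("ob ob mice", "of of mice"), 1 / 3)
  # partial overlap scales by the longer phrase
  expect_equal(string_similarity("impaired glucose homeostasis",
                                 "glucose homeostasis"), 2 / 3)
  # symmetry
  pairs <- list(c("beta cell function", "function beta cell mass"),
                c("type ii diabetes", "type 2 diabetes mellitus"),
                c("insulin", "insulin signalling"))
  for (p in pairs)
    expect_equal(string_similarity(p[1], p[2]), string_similarity(p[2], p[1]))
})

test_that("co-occurrence matrix matches the stated arithmetic and oracle", {
  # df_i = df_j = co = 10, D = 100 -> ratio 10
  post <- data.table(ngram = rep(c("a b", "c d"), each = 10),
                     doc_id = rep(sprintf("d%02d", 1:10), 2))
  catalog <- litjump:::new_catalog(
    data.table(ngram = c("a b", "c d"), n = 2L, df = 10L), post, 100L)
  R <- context_overrepresentation_matrix(catalog)
  expect_equal(R["a b", "c d"], 10)
  expect_equal(R["a b", "a b"], 10)   # diagonal D / df

  # independent postings give ratio ~ 1; brute-force recount on a
  # synthetic catalog
  sim <- small_sim(2L)
  catalog2 <- extract_ngrams(sim$corpus[1:120], n_range = 2:3, min_df = 3L)
  take <- head(catalog2$ngrams$ngram, 40L)
  catalog2$ngrams <- catalog2$ngrams[ngram %in% take]
  catalog2$postings <- catalog2$postings[ngram %in% take]
  R2 <- as.matrix(context_overrepresentation_matrix(catalog2))
  expect_equal(R2, bf_cooccurrence(catalog2), tolerance = 1e-12)
})

test_that("context similarity sees shared third-party context only", {
  # rows i and j identical except for columns i, j: similarity 1 even
  # though i and j never co-occur
  docs <- c(sprintf("p%d", 1:6), sprintf("q%d", 1:6))
  post <- rbind(
    data.table(ngram = "left phrase", doc_id = sprintf("p%d", 1:6)),
    data.table(ngram = "right phrase", doc_id = sprintf("q%d", 1:6)),
    data.table(ngram = "partner one", doc_id = c("p1", "p2", "p3",
                                                 "q1", "q2", "q3")),
    data.table(ngram = "partner two", doc_id = c("p4", "p5", "p6",
                                                 "q4", "q5", "q6")),
    data.table(ngram = "solo phrase", doc_id = sprintf("r%d", 1:5)))
  ng <- post[, .(n = 2L, df = .N), by = ngram]
  setcolorder(ng, c("ngram", "n", "df"))
  catalog <- litjump:::new_catalog(ng[order(ngram)],
                                   post[order(ngram, doc_id)], 40L)
  R <- context_overrepresentation_matrix(catalog)
  expect_equal(R["left phrase", "right phrase"], 0)  # never co-mentioned
  expect_equal(context_similarity(R, "left phrase", "right phrase"), 1)
  # a phrase co-occurring with nothing is orthogonal to everything
  expect_message(
    expect_equal(context_similarity(R, "solo phrase", "left phrase"), 0),
    "all-zero")
  # identical row with itself
  expect_equal(context_similarity(R, "partner one", "partner one"), 1)
})

test_that("the dense pairwise context similarity equals the scalar form", {
  sim <- small_sim(1L)
  catalog <- extract_ngrams(sim$corpus[1:150], n_range = 2L, min_df = 3L)
  take <- head(catalog$ngrams$ngram, 25L)
  catalog$ngrams <- catalog$ngrams[ngram %in% take]
  catalog$postings <- catalog$postings[ngram %in% take]
  R <- context_overrepresentation_matrix(catalog)
  SM <- litjump:::context_similarity_matrix(R)
  for (k in 1:15) {
    i <- sample(nrow(SM), 1); j <- sample(nrow(SM), 1)
    if (i == j) next
    expect_equal(SM[i, j],
                 suppressMessages(context_similarity(R, i, j)),
                 tolerance = 1e-10)
  }
})

test_that("graph edges follow the union-of-thresholds rule", {
  sim <- small_sim(1L)
  catalog <- extract_ngrams(sim$corpus)
  ddocs <- unique(sim$mentions[entity_id == "T2D", doc_id])
  filt <- disease_overrepresented(catalog, ddocs)
  g <- build_similarity_graph(filt)
  expect_true(all(g$edges$w_string >= 0.8 | g$edges$w_context >= 0.5))
  expect_equal(g$edges$w_combined,
               0.5 * g$edges$w_string + 0.5 * g$edges$w_context)
  expect_true(all(g$edges$i < g$edges$j))      # undirected, no self edges
  # impossible thresholds give an edgeless graph
  g0 <- build_similarity_graph(filt, string_threshold = 1,
                               context_threshold = 1)
  expect_true(all(g0$edges$w_string == 1 | g0$edges$w_context == 1))
})

test_that("MCL separates disconnected cliques and keeps singletons", {
  # two disconnected triangles
  tri <- manual_graph(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    data.frame(i = c("a1", "a1", "a2", "b1", "b1", "b2"),
               j = c("a2", "a3", "a3", "b2", "b3", "b3"),
               w_combined = 1))
  con <- mcl_cluster(tri)
  expect_identical(nrow(con$concepts), 2L)
  lab <- setNames(con$members$concept_id, con$members$ngram)
  expect_identical(uniqueN(lab[c("a1", "a2", "a3")]), 1L)
  expect_identical(uniqueN(lab[c("b1", "b2", "b3")]), 1L)
  expect_false(lab[["a1"]] == lab[["b1"]])

  single <- mcl_cluster(manual_graph("only", data.frame()[0, ]))
  expect_identical(nrow(single$concepts), 1L)
  expect_identical(single$concepts$representative, "only")
})

test_that("MCL agrees with an independent reference on a weak barbell", {
  # two 5-cliques joined by one weak edge
  nodes <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  e <- list()
  for (s in c("a", "b"))
    for (x in 1:4) for (y in (x + 1):5)
      e[[length(e) + 1]] <- data.frame(i = paste0(s, x), j = paste0(s, y),
                                       w_combined = 1)
  e[[length(e) + 1]] <- data.frame(i = "a1", j = "b1", w_combined = 0.05)
  g <- manual_graph(nodes, do.call(rbind, e))
  con <- mcl_cluster(g, inflation = 2)
  expect_identical(nrow(con$concepts), 2L)
  lab <- setNames(con$members$concept_id, con$members$ngram)
  expect_identical(uniqueN(lab[sprintf("a%d", 1:5)]), 1L)
  expect_identical(uniqueN(lab[sprintf("b%d", 1:5)]), 1L)
  ref <- ref_mcl(graph_adjacency(g), inflation = 2)
  expect_equal(ari_index(lab[nodes], ref), 1)
})

test_that("MCL output is a partition with stochastic iterates", {
  sim <- small_sim(1L)
  catalog <- extract_ngrams(sim$corpus)
  ddocs <- unique(sim$mentions[entity_id == "T2D", doc_id])
  filt <- disease_overrepresented(catalog, ddocs)
  g <- build_similarity_graph(filt)
  con <- mcl_cluster(g)
  # every n-gram in exactly one concept
  expect_setequal(con$members$ngram, g$nodes$ngram)
  expect_identical(anyDuplicated(con$members$ngram), 0L)
  # column sums stayed 1 throughout the iteration
  expect_lt(con$diagnostics$max_colsum_dev, 1e-9)
  expect_true(con$diagnostics$converged)
  # representative is a member with maximal df
  dfs <- setNames(g$nodes$df, g$nodes$ngram)
  for (cid in con$concepts$concept_id) {
    mem <- con$members[concept_id == cid, ngram]
    expect_identical(dfs[[con$concepts[concept_id == cid, representative]]],
                     max(dfs[mem]))
  }
})

test_that("more inflation never merges clusters on fixture graphs", {
  fixtures <- lapply(1:5, function(s) {
    set.seed(s)
    n <- 12L
    nodes <- sprintf("n%02d", 1:n)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- idx[runif(nrow(idx)) < 0.3, , drop = FALSE]
    if (nrow(pick) == 0) pick <- idx[1, , drop = FALSE]
    manual_graph(nodes, data.frame(i = nodes[pick[, 1]],
                                   j = nodes[pick[, 2]],
                                   w_combined = runif(nrow(pick), 0.3, 1)))
  })
  for (g in fixtures) {
    sizes <- vapply(c(1.5, 2, 4), function(infl)
      nrow(mcl_cluster(g, inflation = infl)$concepts), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})
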