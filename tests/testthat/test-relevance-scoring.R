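test_that("PMI weights follow the log10 contract", {
  # observed = 10 x expected for every core protein -> weight 1
  expect_equal(mean(pmi_weight(rep(20, 100), rep(2, 100))), 1)
  # observed = expected -> 0
  expect_equal(pmi_weight(5, 5), 0)
  # half at ratio 100, half at ratio 1 -> mean 1
  expect_equal(mean(pmi_weight(c(rep(100, 5), rep(1, 5)), rep(1, 10))), 1)
  # uniform ratio r gives exactly log10(r)
  for (r in c(2, 10, 31.6)) {
    expect_equal(mean(pmi_weight(rep(3 * r, 7), rep(3, 7))), log10(r))
  }
  # zero observations are floored, not -Inf
  expect_true(is.finite(pmi_weight(0, 4)))
  expect_equal(pmi_weight(0, 4), log10(0.5 / 4))
  expect_error(pmi_weight(3, 0), "positive")
})

test_that("corpus-level concept weights reproduce hand-built ratios", {
  # one concept present in docs 1..10; protein in docs 6..15 of 100:
  # observed co-docs 5, expected 10*10/100 = 1 -> pmi log10(5)
  docs <- sprintf("d%03d", 1:100)
  con <- manual_concepts(list(C1 = "marker phrase"))
  catalog <- litjump:::new_catalog(
    data.table(ngram = "marker phrase", n = 2L, df = 10L),
    data.table(ngram = "marker phrase", doc_id = docs[1:10]), 100L)
  men <- data.table(doc_id = docs[6:15], entity_id = "P1",
                    entity_class = "protein")
  w <- concept_weights(con, catalog, "P1", men, D = 100L)
  expect_equal(w$weight, log10(5))
  pmi <- attr(w, "pmi")
  expect_identical(dim(pmi), c(1L, 1L))
  # a core protein missing from the corpus is a configuration error
  expect_error(concept_weights(con, catalog, c("P1", "GHOST"), men, 100L),
               "unseen")
})

test_that("article scores sum distinct concept weights once", {
  con <- manual_concepts(list(C1 = c("glucose homeostasis",
                                     "homeostasis glucose"),
                              C2 = "leptin treatment"))
  w <- data.table(concept_id = c("C1", "C2"), weight = c(1.2, 0.8))
  corpus <- make_corpus(c(
    "glucose homeostasis and leptin treatment results",
    "glucose homeostasis then homeostasis glucose again",
    "nothing relevant at all"))
  sc <- score_articles(corpus, con, w)
  expect_equal(sc$score, c(2.0, 1.2, 0))
  contrib <- attr(sc, "contributions")
  # two member n-grams of the same concept: concept counted once
  expect_identical(nrow(unique(contrib[doc_id == "doc02",
                                       .(doc_id, concept_id)])), 1L)
})

test_that("article scores equal a brute-force member scan", {
  sim <- small_sim(1L)
  corpus <- sim$corpus[1:20]
  con <- manual_concepts(split(sim$truth$families$phrase,
                               sim$truth$families$family))
  w <- data.table(concept_id = sort(unique(sim$truth$families$family)))
  w[, weight := seq_len(.N) / 10]
  sc <- score_articles(corpus, con, w)
  for (k in seq_len(nrow(corpus))) {
    txt <- paste(corpus$tokens[[k]], collapse = " ")
    present <- vapply(w$concept_id, function(cid) {
      any(vapply(con$members[concept_id == cid, ngram], function(g)
        grepl(paste0("(^| )", g, "( |$)"), txt), logical(1)))
    }, logical(1))
    expect_equal(sc[doc_id == corpus$doc_id[k], score],
                 sum(w$weight[present]))
  }
})

test_that("adding one n-gram of a new concept adds exactly its weight", {
  con <- manual_concepts(list(C1 = "alpha beta", C2 = "gamma delta"))
  w <- data.table(concept_id = c("C1", "C2"), weight = c(0.7, 1.3))
  base <- "alpha beta filler words"
  s1 <- score_articles(make_corpus(base), con, w)$score
  s2 <- score_articles(make_corpus(paste(base, "gamma delta")), con, w)$score
  expect_equal(s2 - s1, 1.3)
})

test_that("weekly protein scores are per-week maxima over articles", {
  scores <- data.table(doc_id = c("d1", "d2", "d3", "d4"),
                       week = c(1L, 1L, 2L, 2L),
                       score = c(3.1, 5.4, 2.0, 7.7))
  men <- manual_mentions(list("d1", "P1"), list("d2", "P1"), list("d3", "P1"),
                         list("d4", "P2"))
  wk <- weekly_protein_scores(scores, men)
  expect_equal(wk[protein_id == "P1" & week == 1L, score], 5.4)
  expect_equal(wk[protein_id == "P1" & week == 2L, score], 2.0)
  expect_identical(nrow(wk[protein_id == "P2" & week == 1L]), 0L)
  expect_identical(wk[protein_id == "P2" & week == 2L, top_doc], "d4")

  # random fixture vs brute-force group-by-max
  set.seed(9)
  scores2 <- data.table(doc_id = sprintf("d%02d", 1:40),
                        week = sample(1:6, 40, TRUE),
                        score = round(runif(40), 3))
  men2 <- rbindlist(lapply(sprintf("P%d", 1:8), function(p)
    data.table(doc_id = sample(scores2$doc_id, 12), entity_id = p,
               entity_class = "protein")))
  got <- weekly_protein_scores(scores2, men2)[, .(protein_id, week, score)]
  want <- bf_weekly_max(scores2, men2)
  setkey(got, protein_id, week); setkey(want, protein_id, week)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("combined relevance weights the top weeks as specified", {
  # constant series: weights sum to one
  expect_equal(combined_relevance(rep(3.3, 260)), 3.3)
  # single nonzero week contributes u1 = 40/820 of its score
  expect_equal(combined_relevance(c(rep(0, 100), 5)), 5 * 40 / 820)
  expect_equal(combined_relevance(7), 7 * 40 / 820)
  # order invariance
  set.seed(3)
  x <- rexp(260)
  expect_equal(combined_relevance(x), combined_relevance(sample(x)))
  # monotone in every weekly score
  y <- x; y[17] <- y[17] + 2
  expect_gte(combined_relevance(y), combined_relevance(x))
  # configuration errors
  expect_error(combined_relevance(1, W = 10, M = 40), "configuration")
  expect_error(combined_relevance(rep(1, 300)), "at most W")
})

test_that("weekly rankings are deterministic permutations", {
  rk <- rank_proteins(c(A = 5, B = 3, C = 3))
  expect_identical(rk, c(A = 1L, B = 2L, C = 3L))
  expect_identical(rank_proteins(c(only = 1.5)), c(only = 1L))
  set.seed(21)
  sc <- setNames(round(runif(100), 2), sprintf("P%03d", 1:100))
  rk2 <- rank_proteins(sc)
  expect_identical(sort(unname(rk2)), 1:100)
  # agrees with a reference sort
  ref <- order(-sc, names(sc))
  expect_identical(names(rk2)[order(rk2)], names(sc)[ref])
})

test_that("relevance series windows only look back W weeks", {
  weekly <- data.table(protein_id = "P1", week = c(1L, 5L),
                       score = c(10, 1), top_doc = "d")
  ser <- relevance_series(weekly, c("P1", "P2"), weeks = 1:9, W = 4L, M = 2L)
  u1 <- 2 / 3
  expect_equal(ser[protein_id == "P1" & week == 4L, combined], 10 * u1)
  # week 5: the window 2..5 no longer contains the week-1 score
  expect_equal(ser[protein_id == "P1" & week == 5L, combined], 1 * u1)
  expect_equal(ser[protein_id == "P2", unique(combined)], 0)
  # ranks are a permutation each week
  expect_true(all(ser[, sort(rank) == seq_len(.N), by = week]$V1))
})

test_that("rank fold changes round half-up to one decimal", {
  expect_equal(rank_fold_change(125, 24), 5.2)
  expect_equal(rank_fold_change(100, 100), 1.0)
  expect_equal(rank_fold_change(322, 55), 5.9)
  expect_equal(rank_fold_change(25, 1000), 0.0)
  expect_equal(rank_fold_change(15, 100), 0.2)  # 0.15 rounds up
})

test_that("ROC AUC matches the midrank formula and pair counting", {
  expect_equal(evaluate_roc(c(a = 3, b = 2, c = 1), c("a"))$auc, 1)
  expect_equal(evaluate_roc(c(a = 1, b = 1, c = 1), c("a", "b"))$auc, 0.5)
  expect_error(evaluate_roc(c(a = 1, b = 2), c("a", "b")), "degenerate")
  set.seed(13)
  scores <- setNames(sample(round(runif(60), 1), 200, TRUE),
                     sprintf("P%03d", 1:200))
  pos <- sample(names(scores), 40)
  got <- evaluate_roc(scores, pos)
  expect_equal(got$auc, bf_auc(scores, names(scores) %in% pos))
  # ROC points rise monotonically from (0,0) to (1,1)
  expect_equal(got$points$fpr[1], 0)
  expect_equal(got$points$tpr[nrow(got$points)], 1)
  expect_true(all(diff(got$points$fpr) >= 0))
  expect_true(all(diff(got$points$tpr) >= 0))
})

test_that("top-1000 inspection arithmetic adds up", {
  flags <- data.frame(explicit = rep(FALSE, 1000), tagged = rep(FALSE, 1000))
  flags$explicit[1:406] <- TRUE
  flags$tagged[c(1:168, 407:419)] <- TRUE
  s <- inspection_summary(flags$explicit, flags$tagged)
  expect_identical(s$explicit, 406L)
  expect_identical(s$tagged, 181L)
  expect_identical(s$overlap, 168L)
  expect_identical(s$complement, 581L)
})
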