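# Independent brute-force oracles used to verify the optimized
# implementations on small fixtures. These deliberately use naive loops and
# closed forms, not the code paths they check.

library(data.table)

# hypergeometric upper tail by direct enumeration with choose()
bf_fisher_greater <- function(a, b, cc, d) {
  m <- a + b          # docs mentioning A
  nn <- cc + d        # docs not mentioning A
  k <- a + cc         # docs mentioning B
  xs <- max(0, k - nn):min(m, k)
  pmf <- choose(m, xs) * choose(nn, k - xs) / choose(m + nn, k)
  sum(pmf[xs >= a])
}

# longest-match scan written as the naive position-by-position loop
bf_match_entities <- function(tokens, entries) {
  # entries: data.table(entity_id, entity_class, synonym, n_tokens)
  found <- list()
  i <- 1L
  nt <- length(tokens)
  while (i <= nt) {
    best <- NULL
    for (L in sort(unique(entries$n_tokens), decreasing = TRUE)) {
      if (i + L - 1L > nt) next
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      hit <- entries[entries$synonym == key]
      if (nrow(hit)) { best <- list(hit = hit[1L], L = L); break }
    }
    if (is.null(best)) {
      i <- i + 1L
    } else {
      found[[length(found) + 1L]] <-
        best$hit[, .(entity_id, entity_class)]
      i <- i + best$L
    }
  }
  if (length(found) == 0L)
    return(data.table(entity_id = character(), entity_class = character()))
  out <- unique(rbindlist(found))
  setorder(out, entity_id)
  out
}

# n-gram catalog by nested loops over documents and window starts
bf_extract_ngrams <- function(corpus, n_range, min_df, stopwords) {
  rows <- list()
  for (k in seq_len(nrow(corpus))) {
    toks <- corpus$tokens[[k]]
    for (n in n_range) {
      if (length(toks) < n) next
      for (s in 1:(length(toks) - n + 1L)) {
        w <- toks[s:(s + n - 1L)]
        if (w[1L] %in% stopwords || w[n] %in% stopwords) next
        rows[[length(rows) + 1L]] <-
          data.table(ngram = paste(w, collapse = " "), n = n,
                     doc_id = corpus$doc_id[k])
      }
    }
  }
  if (length(rows) == 0L)
    return(list(ngrams = data.table(ngram = character(), n = integer(),
                                    df = integer()),
                postings = data.table(ngram = character(),
                                      doc_id = character())))
  post <- unique(rbindlist(rows))
  ng <- post[, .(n = n[1L], df = .N), by = ngram][df >= min_df]
  post <- post[ngram %in% ng$ngram, .(ngram, doc_id)]
  setorder(ng, ngram)
  setorder(post, ngram, doc_id)
  list(ngrams = ng, postings = post)
}

# pairwise co-occurrence ratios by double loop over n-grams
bf_cooccurrence <- function(catalog) {
  ngrams <- catalog$ngrams$ngram
  M <- length(ngrams)
  posts <- lapply(ngrams, function(g)
    catalog$postings[catalog$postings$ngram == g, doc_id])
  df <- catalog$ngrams$df
  out <- matrix(0, M, M, dimnames = list(ngrams, ngrams))
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      co <- length(intersect(posts[[a]], posts[[b]]))
      out[a, b] <- co * catalog$D / (df[a] * df[b])
    }
  }
  out
}

# AUC by O(n^2) pair counting with half-credit for ties
bf_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# weekly per-protein maximum by explicit group loops
bf_weekly_max <- function(article_scores, mentions) {
  men <- mentions[mentions$entity_class == "protein"]
  out <- list()
  for (p in sort(unique(men$entity_id))) {
    docs <- men[men$entity_id == p, doc_id]
    sub <- article_scores[article_scores$doc_id %in% docs]
    for (w in sort(unique(sub$week))) {
      ss <- sub[sub$week == w]
      out[[length(out) + 1L]] <- data.table(protein_id = p, week = w,
                                            score = max(ss$score))
    }
  }
  rbindlist(out)
}

# pooled historical jumps by explicit filtering
bf_pooled_jumps <- function(obs, r, h) {
  sel <- obs$initial_rank >= r - h & obs$initial_rank <= r + h
  obs$jump[sel]
}

# independent dense MCL reference: explicit column loops and
# attractor-based cluster readout
ref_mcl <- function(adj, inflation, max_iter = 200, tol = 1e-6) {
  M <- nrow(adj)
  A <- adj
  for (v in seq_len(M)) {
    inc <- max(A[, v])
    A[v, v] <- if (inc > 0) inc else 1
  }
  for (v in seq_len(M)) A[, v] <- A[, v] / sum(A[, v])
  for (it in seq_len(max_iter)) {
    B <- A %*% A
    B <- B^inflation
    for (v in seq_len(M)) B[, v] <- B[, v] / sum(B[, v])
    if (max(abs(B - A)) < tol) { A <- B; break }
    A <- B
  }
  attractors <- which(diag(A) > 0.1)
  labels <- rep(NA_integer_, M)
  cl <- 0L
  for (at in attractors) {
    if (!is.na(labels[at])) next
    cl <- cl + 1L
    members <- which(A[at, ] > 1e-4 | A[, at] > 1e-4)
    members <- union(members, at)
    # merge overlapping attractor systems
    prev <- unique(labels[members[!is.na(labels[members])]])
    if (length(prev)) {
      labels[labels %in% prev] <- cl
    }
    labels[members] <- cl
  }
  labels[is.na(labels)] <- seq.int(cl + 1L, length.out = sum(is.na(labels)))
  match(labels, unique(labels))
}

# adjusted Rand index between two labelings
ari_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expect <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expect) return(1)
  (a - expect) / (maxi - expect)
}
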