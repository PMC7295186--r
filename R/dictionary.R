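#' Build an entity dictionary from synonym entries
#'
#' An entity dictionary maps synonym token sequences to `(entity_id,
#' entity_class)` pairs, with `entity_class` one of `"protein"` or
#' `"disease"`. Synonyms are normalized through [tokenize()] when matching is
#' case-insensitive (the default); with `case_insensitive = FALSE` synonyms
#' are split on whitespace verbatim, which lets short case-sensitive gene
#' symbols be listed as distinct entries.
#'
#' @param entity_id,entity_class,synonym Character vectors of equal length.
#' @param case_insensitive Normalize synonyms through the tokenizer?
#' @return An `entity_dictionary` object.
#' @export
entity_dictionary <- function(entity_id, entity_class, synonym,
                              case_insensitive = TRUE) {
  stopifnot(length(entity_id) == length(entity_class),
            length(entity_id) == length(synonym))
  if (length(entity_id) == 0L) stop("dictionary must have at least one entry")
  if (!all(entity_class %in% c("protein", "disease")))
    stop("entity_class must be 'protein' or 'disease'")
  toks <- if (case_insensitive) tokenize_many(synonym)
          else strsplit(trimws(synonym), "\\s+")
  nt <- lengths(toks)
  if (any(nt == 0L)) stop("every synonym must have at least one token")
  key <- vapply(toks, paste, character(1), collapse = " ")
  entries <- data.table(entity_id = as.character(entity_id),
                        entity_class = as.character(entity_class),
                        synonym = key, n_tokens = nt)
  entries <- unique(entries)
  clash <- entries[, .(ids = uniqueN(entity_id)), by = synonym][ids > 1L]
  if (nrow(clash))
    stop("synonym maps to multiple entity ids: ",
         paste(head(clash$synonym, 5), collapse = ", "))
  setkey(entries, synonym)
  structure(list(entries = entries, case_insensitive = case_insensitive),
            class = "entity_dictionary")
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary> %d synonyms, %d entities (%s)\n",
              nrow(x$entries), uniqueN(x$entries$entity_id),
              if (x$case_insensitive) "case-insensitive" else "case-sensitive"))
  invisible(x)
}

#' Read an entity dictionary from a TSV file
#'
#' The file must have a header row and the columns `entity_id`,
#' `entity_class`, `synonym`.
#'
#' @param path TSV file path.
#' @inheritParams entity_dictionary
#' @return An `entity_dictionary`.
#' @export
read_dictionary <- function(path, case_insensitive = TRUE) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("entity_id", "entity_class", "synonym")
  if (!all(need %in% names(tab)))
    stop("dictionary TSV must have columns: ", paste(need, collapse = ", "))
  entity_dictionary(tab$entity_id, tab$entity_class, tab$synonym,
                    case_insensitive = case_insensitive)
}

#' Find dictionary entities in one token stream
#'
#' Scans left to right; at each position the longest synonym starting there
#' is taken and the scan resumes after it (longest-match, leftmost,
#' non-overlapping). Because all downstream statistics are document-level
#' co-mentionings, the result is a set: repeated mentions collapse.
#'
#' @param tokens Character vector of normalized tokens.
#' @param dict An `entity_dictionary`.
#' @return A `data.table` with columns `entity_id`, `entity_class` (unique
#'   rows, ordered by `entity_id`).
#' @export
match_entities <- function(tokens, dict) {
  stopifnot(inherits(dict, "entity_dictionary"))
  entries <- dict$entries
  lens <- sort(unique(entries$n_tokens), decreasing = TRUE)
  nt <- length(tokens)
  hit_id <- character(0); hit_cl <- character(0)
  i <- 1L
  while (i <= nt) {
    advanced <- FALSE
    for (L in lens) {
      if (i + L - 1L > nt) next
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      m <- entries[.(key), nomatch = NULL]
      if (nrow(m)) {
        hit_id <- c(hit_id, m$entity_id[1L])
        hit_cl <- c(hit_cl, m$entity_class[1L])
        i <- i + L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  out <- unique(data.table(entity_id = hit_id, entity_class = hit_cl))
  setorder(out, entity_id)
  out[]
}

#' Find dictionary entities in every document of a corpus
#'
#' Vectorized equivalent of applying [match_entities()] to each document:
#' candidate matches for every synonym length are located with shifted
#' token-window joins, then resolved per document by the same longest-match,
#' leftmost, non-overlapping rule.
#'
#' @param corpus A `lit_corpus`.
#' @param dict An `entity_dictionary`.
#' @return A `data.table` with columns `doc_id`, `entity_id`, `entity_class`
#'   (one row per document-level mention).
#' @export
corpus_mentions <- function(corpus, dict) {
  stopifnot(inherits(dict, "entity_dictionary"))
  empty <- data.table(doc_id = character(), entity_id = character(),
                      entity_class = character())
  if (nrow(corpus) == 0L) return(empty)
  long <- corpus[, .(token = tokens[[1L]]), by = doc_id]
  if (nrow(long) == 0L) return(empty)
  long[, pos := seq_len(.N), by = doc_id]
  entries <- dict$entries
  cand <- list()
  for (L in sort(unique(entries$n_tokens))) {
    if (L == 1L) {
      key <- long$token
      valid <- rep(TRUE, nrow(long))
    } else {
      shifted <- lapply(0:(L - 1L), function(k)
        long[, shift(token, -k), by = doc_id]$V1)
      key <- do.call(paste, shifted)
      valid <- !Reduce(`|`, lapply(shifted, is.na))
    }
    idx <- which(valid & key %chin% entries[n_tokens == L, synonym])
    if (length(idx))
      cand[[as.character(L)]] <- data.table(doc_id = long$doc_id[idx],
                                            start = long$pos[idx],
                                            len = L, synonym = key[idx])
  }
  if (length(cand) == 0L) return(empty)
  cand <- rbindlist(cand)
  setorder(cand, doc_id, start, -len)
  cand[, keep := resolve_longest_leftmost(start, len), by = doc_id]
  hits <- cand[keep == TRUE]
  hits <- entries[hits, on = "synonym"][, .(doc_id, entity_id, entity_class)]
  out <- unique(hits)
  setorder(out, doc_id, entity_id)
  out[]
}

# greedy scan over candidates sorted by (start asc, len desc): take the
# longest candidate at each uncovered position, skip candidates starting
# inside an accepted match
resolve_longest_leftmost <- function(start, len) {
  n <- length(start)
  keep <- logical(n)
  covered_until <- 0L
  for (k in seq_len(n)) {
    if (start[k] > covered_until) {
      keep[k] <- TRUE
      covered_until <- start[k] + len[k] - 1L
    }
  }
  keep
}

#' Attach document-level mention sets to a corpus
#'
#' @param corpus A `lit_corpus`.
#' @param dict An `entity_dictionary`.
#' @return The corpus with an added `mentions` list-column of
#'   `data.table(entity_id, entity_class)`.
#' @export
annotate_corpus <- function(corpus, dict) {
  men <- corpus_mentions(corpus, dict)
  out <- copy(corpus)
  split_men <- split(men[, .(entity_id, entity_class)], men$doc_id)
  emptym <- data.table(entity_id = character(), entity_class = character())
  out[, mentions := lapply(doc_id, function(d) {
    m <- split_men[[d]]
    if (is.null(m)) emptym else m
  })]
  out[]
}
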