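#' Normalize free text into word tokens
#'
#' Lowercases the text, treats punctuation as token boundaries, and strips
#' any residual punctuation from token edges. Characters that carry meaning
#' inside biomedical terms are preserved: Greek letters stay as-is and
#' hyphens are kept when internal to a token (`"HOMA-IR"` becomes
#' `"homa-ir"`), as are digits (`"type 2 diabetes"` keeps the `"2"`).
#' The function is deterministic and idempotent: tokenizing the
#' concatenation of its own output returns the same tokens.
#'
#' @param text A character scalar (possibly empty or `NA`).
#' @return A character vector of tokens; empty input gives `character(0)`.
#' @examples
#' tokenize("Type 2 Diabetes.")
#' tokenize("β cell function (HOMA-IR)")
#' @export
tokenize <- function(text) {
  tokenize_many(text)[[1L]]
}

#' Tokenize many texts at once
#'
#' Vectorized form of [tokenize()]; used internally when reading corpora.
#'
#' @param texts Character vector.
#' @return A list of token character vectors, one per input element.
#' @export
tokenize_many <- function(texts) {
  if (length(texts) == 0L) return(list())
  x <- tolower(as.character(texts))
  x[is.na(x)] <- ""
  # punctuation other than hyphen splits tokens; hyphens are resolved at the
  # token-edge cleanup below so internal hyphens survive
  x <- gsub("[^\\p{L}\\p{N}\\-]+", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), " +", fixed = FALSE)
  lapply(toks, function(tk) {
    if (length(tk) == 0L || identical(tk, "")) return(character(0))
    tk <- gsub("^-+|-+$", "", tk)
    tk[nzchar(tk)]
  })
}
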