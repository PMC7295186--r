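#' Signed weekly rank jump
#'
#' `initial_rank - new_rank`: positive when the protein moved up the
#' ranking (toward rank 1), negative when it dropped.
#'
#' @param initial_rank,new_rank Ranks, `>= 1` (vectors ok).
#' @return Signed jumps.
#' @examples
#' rank_jump(17955, 9310)  # 8645
#' @export
rank_jump <- function(initial_rank, new_rank) {
  stopifnot(all(initial_rank >= 1), all(new_rank >= 1))
  initial_rank - new_rank
}

# pooling half-width: wide far down the list where thousand-place jumps are
# routine, tight near the top where a 3-place jump is already rare
default_rank_window <- function(r) pmax(5, round(0.1 * r))

#' Empirical distribution of historical weekly rank jumps
#'
#' Collects one jump observation per protein per consecutive pair of weeks
#' in the rank history, strictly before the evaluation week (the week being
#' tested never contributes to its own null). When a jump is later tested
#' at initial rank `r`, the null is the pooled multiset of historical jumps
#' whose initial rank lies in `[r - h(r), r + h(r)]` — the sliding-window
#' smoothing that compensates for ranks with few direct observations.
#'
#' @param ranks Rank history: `data.table(protein_id, week, rank)` with
#'   each week a complete ranking.
#' @param eval_week Evaluation week; only jumps landing strictly before it
#'   are used (default: `max(week) + 1`, i.e. use the whole history).
#' @param rank_window Function mapping initial rank to pooling half-width
#'   (default `max(5, round(0.1 * r))`).
#' @return A `jump_distribution`: list with `observations`
#'   (`data.table(protein_id, week, initial_rank, new_rank, jump)`) and the
#'   `rank_window` function.
#' @export
build_jump_distribution <- function(ranks, eval_week = NULL,
                                    rank_window = default_rank_window) {
  stopifnot(all(c("protein_id", "week", "rank") %in% names(ranks)))
  if (is.null(eval_week)) eval_week <- max(ranks$week) + 1L
  hist_ranks <- ranks[week < eval_week]
  weeks <- sort(unique(hist_ranks$week))
  if (length(weeks) < 2L)
    stop("insufficient rank history (< 2 weeks before the evaluation week);",
         " a burn-in period is required before jumps can be tested")
  hr <- copy(hist_ranks)
  setorder(hr, protein_id, week)
  hr[, `:=`(prev_rank = shift(rank), prev_week = shift(week)),
     by = protein_id]
  step <- diff(weeks)
  consec <- data.table(prev_week = weeks[-length(weeks)][step == 1L],
                       week = weeks[-1L][step == 1L])
  obs <- hr[!is.na(prev_rank)][consec, on = c("prev_week", "week"),
                               nomatch = NULL]
  obs <- obs[, .(protein_id, week, initial_rank = prev_rank,
                 new_rank = rank, jump = prev_rank - rank)]
  setorder(obs, week, protein_id)
  structure(list(observations = obs, rank_window = rank_window),
            class = "jump_distribution")
}

#' @export
print.jump_distribution <- function(x, ...) {
  cat(sprintf("<jump_distribution> %d observations over %d weeks\n",
              nrow(x$observations), uniqueN(x$observations$week)))
  invisible(x)
}

# the pooled multiset of historical jumps relevant to initial rank r
pooled_jumps <- function(dist, r) {
  h <- dist$rank_window(r)
  obs <- dist$observations
  obs$jump[obs$initial_rank >= r - h & obs$initial_rank <= r + h]
}

#' Pooled empirical jump probabilities at an initial rank
#'
#' @param dist A `jump_distribution`.
#' @param initial_rank The initial rank whose null is wanted.
#' @return `data.table(jump, prob)`; probabilities sum to 1.
#' @export
jump_distribution_probs <- function(dist, initial_rank) {
  pool <- pooled_jumps(dist, initial_rank)
  if (length(pool) == 0L)
    return(data.table(jump = integer(), prob = numeric()))
  tab <- data.table(jump = pool)[, .(prob = .N / length(pool)), by = jump]
  setorder(tab, jump)
  tab[]
}

#' Empirical p-value for an upward rank jump
#'
#' One-sided: the probability, under the pooled historical null for this
#' initial rank, of a jump at least as large as the observed one, with the
#' add-one correction `p = (1 + #\{jumps >= observed\}) / (1 + N)` so no
#' jump ever gets p = 0. Monotone non-increasing in the jump size.
#'
#' @param dist A `jump_distribution`.
#' @param initial_rank Initial rank of the tested protein.
#' @param jump Observed signed jump.
#' @return p-value in `(0, 1]`.
#' @export
jump_pvalue <- function(dist, initial_rank, jump) {
  pool <- pooled_jumps(dist, initial_rank)
  if (length(pool) == 0L) {
    warning("no historical jumps pooled at initial rank ", initial_rank,
            "; p = 1")
    return(1)
  }
  (1 + sum(pool >= jump)) / (1 + length(pool))
}

#' Weekly high-jumper report
#'
#' Tests every protein whose rank improved this week against the empirical
#' jump null and reports those with `p <= alpha`, most significant first.
#' When weekly scores are supplied, each entry carries the id of the week's
#' top-scoring article mentioning the protein — the abstract that caused
#' the jump. Downward moves are never flagged (the typical weekly change is
#' a 1-place slip caused by someone else's upward jump).
#'
#' @param prev_ranks,new_ranks Named integer vectors over the same protein
#'   universe (names = protein ids), e.g. two weeks of [rank_proteins()].
#' @param dist A `jump_distribution` whose history ends before the new
#'   week.
#' @param alpha Significance level (default 0.05). No multiple-testing
#'   correction is applied.
#' @param weekly Optional [weekly_protein_scores()] table for the new week
#'   (supplies `top_doc`).
#' @return `data.table(protein_id, initial_rank, new_rank, jump, p_value,
#'   top_doc)` sorted by ascending p.
#' @export
weekly_high_jumpers <- function(prev_ranks, new_ranks, dist, alpha = 0.05,
                                weekly = NULL) {
  ids <- names(prev_ranks)
  if (!setequal(ids, names(new_ranks)))
    stop("prev_ranks and new_ranks must cover the same protein universe")
  new_ranks <- new_ranks[ids]
  out <- data.table(protein_id = ids,
                    initial_rank = as.integer(prev_ranks),
                    new_rank = as.integer(new_ranks))
  out[, jump := initial_rank - new_rank]
  out <- out[jump > 0L]
  if (nrow(out) == 0L) return(empty_jumper_report())
  out[, p_value := vapply(seq_len(.N), function(k)
    jump_pvalue(dist, initial_rank[k], jump[k]), numeric(1))]
  out <- out[p_value <= alpha]
  if (nrow(out) == 0L) return(empty_jumper_report())
  out[, top_doc := NA_character_]
  if (!is.null(weekly) && nrow(weekly))
    out[weekly, top_doc := i.top_doc, on = "protein_id"]
  setorder(out, p_value, protein_id)
  out[]
}

empty_jumper_report <- function() {
  data.table(protein_id = character(), initial_rank = integer(),
             new_rank = integer(), jump = integer(), p_value = numeric(),
             top_doc = character())
}
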