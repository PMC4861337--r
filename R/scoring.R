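#' Per-criterion percentage score for one question
#'
#' The criterion score is 100 times the mean point value (Yes = 1,
#' Undecided = 0.5, No = 0) over the experts who gave a substantive answer
#' for that question under that criterion.  Missing answers and absent
#' records carry no points and do not enter the denominator, so partial
#' completers contribute wherever they answered and responder counts vary
#' by cell.
#'
#' @param matrix A [response_matrix].
#' @param question_id,criterion_id Identifiers from the design.
#' @return List with `score` (percentage in \[0, 100\], `NA` when the cell
#'   has no substantive responder) and `n_responders`.
#' @export
#' @examples
#' d <- survey_design("q1", "c1")
#' a <- data.frame(expert_id = c("e1", "e2", "e3", "e4"),
#'                 question_id = "q1", criterion_id = "c1",
#'                 response = c("yes", "undecided", "no", "missing"))
#' criterion_score(response_matrix(d, a), "q1", "c1")  # 50, 3 responders
criterion_score <- function(matrix, question_id, criterion_id) {
  arr <- response_array(matrix)
  j <- cell_index(arr, question_id, criterion_id)
  pts <- c(NA_real_, 1, 0, 0.5, NA_real_)[arr[, j] + 1L]
  n <- sum(!is.na(pts))
  list(score = if (n == 0) NA_real_ else 100 * mean(pts, na.rm = TRUE),
       n_responders = n)
}

#' Research Priority Score from criterion scores
#'
#' The RPS of a question is the weighted mean of its per-criterion
#' percentage scores; with equal weights (the default, and the published
#' convention when the weighting stage is omitted) it is the plain mean.
#' Weights are renormalised over the criteria whose score is defined, so a
#' question left unanswered under one criterion is averaged over the rest
#' rather than silently penalised.
#'
#' @param criterion_scores Numeric vector of percentage scores (`NA` =
#'   undefined).
#' @param weights Optional non-negative weights, recycled/renormalised as
#'   `w / sum(w)` over the defined scores.  `NULL` means equal weights.
#' @return RPS percentage in \[0, 100\]; `NA` if every score is undefined.
#' @export
#' @examples
#' research_priority_score(c(93.8, 93.8, 85.7))  # 91.1 at one decimal
research_priority_score <- function(criterion_scores, weights = NULL) {
  s <- as.numeric(criterion_scores)
  if (is.null(weights)) weights <- rep(1, length(s))
  if (length(weights) != length(s)) {
    stop_validation("weights must match criterion scores in length")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_validation("weights must be non-negative with positive sum")
  }
  ok <- !is.na(s)
  if (!any(ok)) return(NA_real_)
  sum(weights[ok] * s[ok]) / sum(weights[ok])
}

# Column-wise scores over an integer code matrix (see response_array).
# Returns list(score, n) of length Q*C.  The workhorse shared by
# score_all() and the bootstrap, where the rows are resampled experts.
array_scores <- function(arr) {
  pts <- matrix(c(NA_real_, 1, 0, 0.5, NA_real_)[arr + 1L], nrow = nrow(arr))
  n <- colSums(!is.na(pts))
  tot <- colSums(pts, na.rm = TRUE)
  score <- ifelse(n > 0, 100 * tot / n, NA_real_)
  list(score = score, n = n)
}

# Assemble a score_table from per-cell scores (criterion-major layout).
build_score_table <- function(design, cell_scores, weights) {
  qids <- design$questions$question_id
  cids <- design$criteria$criterion_id
  nq <- length(qids); nc <- length(cids)
  smat <- matrix(cell_scores$score, nrow = nq, ncol = nc)
  nmat <- matrix(cell_scores$n, nrow = nq, ncol = nc)
  w <- if (is.null(weights)) rep(1, nc) else weights
  wmat <- matrix(rep(w, each = nq), nrow = nq)
  wmat[is.na(smat)] <- 0
  wsum <- rowSums(wmat)
  rps <- ifelse(wsum > 0, rowSums(wmat * smat, na.rm = TRUE) / wsum, NA_real_)

  out <- tibble::tibble(question_id = qids)
  for (k in seq_len(nc)) out[[paste0("score_", cids[k])]] <- smat[, k]
  for (k in seq_len(nc)) out[[paste0("n_", cids[k])]] <- as.integer(nmat[, k])
  out$rps <- rps
  structure(out, class = c("score_table", class(out)),
            criterion_ids = cids,
            weights = w,
            rps_range = suppressWarnings(range(rps, na.rm = TRUE)))
}

#' Score every question in a survey
#'
#' Computes every criterion score, its responder count and the (optionally
#' weighted) Research Priority Score for each question.
#'
#' @param matrix A [response_matrix].
#' @param weights Optional per-criterion weights; defaults to the design's
#'   weights, or equal weights when the design has none.
#' @return A `score_table` tibble with one row per question: `question_id`,
#'   one `score_<criterion>` and `n_<criterion>` column per criterion, and
#'   `rps`.  The RPS range is attached as attribute `rps_range`.
#' @export
score_all <- function(matrix, weights = NULL) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (is.null(weights)) weights <- matrix$design$weights
  if (!is.null(weights) &&
      length(weights) != nrow(matrix$design$criteria)) {
    stop_validation("weights must have one entry per criterion")
  }
  arr <- response_array(matrix)
  build_score_table(matrix$design, array_scores(arr), weights)
}

#' @export
print.score_table <- function(x, ...) {
  rng <- attr(x, "rps_range")
  cat(sprintf("<score_table> %d questions; RPS range %.1f to %.1f\n",
              nrow(x), rng[1], rng[2]))
  NextMethod()
}

#' Rank questions by Research Priority Score
#'
#' Questions are ordered by descending RPS on the full-precision values
#' (display rounding never affects ranks).  Ties are broken by higher
#' Average Expert Agreement when an agreement table is supplied, then by
#' design order.  Ranks are dense (1, 2, 3, ...); questions with undefined
#' RPS are flagged with rank `NA` and excluded.
#'
#' @param table A `score_table` from [score_all()] (or any data frame with
#'   `question_id` and `rps`, rows in design order).
#' @param agreement Optional `agreement_table` from [agreement_all()] used
#'   for tie-breaking.
#' @return The table with a `rank` column, sorted by rank.
#' @export
rank_questions <- function(table, agreement = NULL) {
  if (nrow(table) == 0) stop_validation("cannot rank an empty score table")
  if (all(is.na(table$rps))) {
    stop_validation("no question has a defined RPS")
  }
  aea <- rep(0, nrow(table))
  if (!is.null(agreement)) {
    m <- match(table$question_id, agreement$question_id)
    aea <- agreement$aea[m]
    aea[is.na(aea)] <- 0
  }
  ord <- order(-table$rps, -aea, seq_len(nrow(table)), na.last = TRUE)
  out <- table[ord, ]
  out$rank <- NA_integer_
  out$rank[!is.na(out$rps)] <- seq_len(sum(!is.na(out$rps)))
  out
}
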