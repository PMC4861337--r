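# Independent brute-force implementations of the CHNRI statistics, working
# directly on the long answer table.  These never touch the package's
# internal array representation; they are the oracle the implementation is
# checked against.

oracle_points <- c(yes = 1, no = 0, undecided = 0.5, missing = NA_real_)

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_criterion_score <- function(answers, q, c) {
  rows <- answers[answers$question_id == q & answers$criterion_id == c, ]
  pts <- oracle_points[rows$response]
  pts <- pts[!is.na(pts)]
  if (length(pts) == 0) {
    list(score = NA_real_, n = 0L)
  } else {
    list(score = 100 * sum(pts) / length(pts), n = length(pts))
  }
}

oracle_rps <- function(answers, q, criteria, weights = NULL) {
  s <- vapply(criteria, function(c) oracle_criterion_score(answers, q, c)$score,
              numeric(1))
  if (is.null(weights)) weights <- rep(1, length(criteria))
  ok <- !is.na(s)
  if (!any(ok)) return(NA_real_)
  sum(weights[ok] * s[ok]) / sum(weights[ok])
}

oracle_modal_fraction <- function(answers, q, c) {
  rows <- answers[answers$question_id == q & answers$criterion_id == c, ]
  sub <- rows$response[rows$response %in% c("yes", "no", "undecided")]
  if (length(sub) == 0) return(NA_real_)
  max(table(factor(sub, levels = c("yes", "no", "undecided")))) / length(sub)
}

oracle_aea <- function(answers, q, criteria) {
  fr <- vapply(criteria, function(c) oracle_modal_fraction(answers, q, c),
               numeric(1))
  if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
}

# --- panel builders -------------------------------------------------------

# Long answer table from a named list: cells[[expert]][[question]][[criterion]]
# values are canonical labels; NULL cells stay absent.
make_answers <- function(expert_ids, question_ids, criterion_ids, labels) {
  # labels: character vector in expert-major, question-, then criterion-
  # order; NA entries become absent cells.
  grid <- expand.grid(criterion_id = criterion_ids,
                      question_id = question_ids,
                      expert_id = expert_ids,
                      stringsAsFactors = FALSE)
  grid$response <- labels
  grid <- grid[!is.na(grid$response),
               c("expert_id", "question_id", "criterion_id", "response")]
  grid
}

toy_design <- function(nq = 2, nc = 2) {
  survey_design(sprintf("q%d", seq_len(nq)),
                sprintf("c%d", seq_len(nc)))
}

# Random small panel: each cell uniform over the 4 categories plus absent.
random_small_panel <- function(ne = 3, nq = 2, nc = 2) {
  d <- toy_design(nq, nc)
  opts <- c("yes", "no", "undecided", "missing", NA)
  labels <- sample(opts, ne * nq * nc, replace = TRUE)
  a <- make_answers(sprintf("e%d", seq_len(ne)), d$questions$question_id,
                    d$criteria$criterion_id, labels)
  list(design = d, answers = a,
       matrix = response_matrix(d, a, experts = sprintf("e%d", seq_len(ne))))
}

# One-criterion single-question panel from a vector of labels.
cell_panel <- function(labels) {
  d <- survey_design("q1", "c1")
  a <- data.frame(expert_id = sprintf("e%d", seq_along(labels)),
                  question_id = "q1", criterion_id = "c1",
                  response = labels, stringsAsFactors = FALSE)
  response_matrix(d, a)
}

# Unanimous panel: every expert answers `label` everywhere.
unanimous_panel <- function(ne = 5, nq = 3, nc = 3, label = "yes") {
  d <- toy_design(nq, nc)
  a <- make_answers(sprintf("e%d", seq_len(ne)), d$questions$question_id,
                    d$criteria$criterion_id, rep(label, ne * nq * nc))
  response_matrix(d, a)
}

published_top10 <- function() wasting_stunting_top10()
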