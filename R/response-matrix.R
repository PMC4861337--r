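#' Construct a response matrix
#'
#' The response matrix is the pipeline's only raw input: one categorical
#' answer per expert x question x criterion cell.  Cells with no record at
#' all (an expert who stopped early or skipped a query) are distinguished
#' from an explicit `missing` answer ("insufficiently informed"); both are
#' excluded from every score, but they are preserved distinctly in I/O
#' because non-participation and a considered "I don't know" are different
#' survey facts.
#'
#' @param design A [survey_design].
#' @param answers Data frame with columns `expert_id`, `question_id`,
#'   `criterion_id`, `response` (canonical or survey labels; see
#'   [normalize_response()]).
#' @param experts Optional ordered character vector of expert ids; defaults
#'   to first appearance order in `answers`.  May include experts with no
#'   answers (invitees who never responded).
#' @return An object of class `response_matrix`.
#' @export
#' @examples
#' d <- survey_design("q1", c("c1", "c2"))
#' a <- data.frame(expert_id = "e1", question_id = "q1",
#'                 criterion_id = c("c1", "c2"), response = c("yes", "no"))
#' response_matrix(d, a)
response_matrix <- function(design, answers, experts = NULL) {
  stopifnot(inherits(design, "survey_design"))
  answers <- tibble::as_tibble(answers)
  need <- c("expert_id", "question_id", "criterion_id", "response")
  if (!all(need %in% names(answers))) {
    stop_validation("answers need columns: %s", paste(need, collapse = ", "))
  }
  answers <- answers[, need]
  answers$expert_id    <- as.character(answers$expert_id)
  answers$question_id  <- as.character(answers$question_id)
  answers$criterion_id <- as.character(answers$criterion_id)
  answers$response     <- normalize_response(answers$response)

  bad_q <- setdiff(answers$question_id, design$questions$question_id)
  if (length(bad_q)) stop_validation("unknown question id(s): %s",
                                     paste(bad_q, collapse = ", "))
  bad_c <- setdiff(answers$criterion_id, design$criteria$criterion_id)
  if (length(bad_c)) stop_validation("unknown criterion id(s): %s",
                                     paste(bad_c, collapse = ", "))
  key <- paste(answers$expert_id, answers$question_id, answers$criterion_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_validation("duplicated (expert, question, criterion) record: %s",
                    gsub("\r", " / ", dup))
  }
  if (is.null(experts)) {
    experts <- unique(answers$expert_id)
  } else {
    experts <- as.character(experts)
    if (anyDuplicated(experts)) stop_validation("duplicated expert ids")
    bad_e <- setdiff(answers$expert_id, experts)
    if (length(bad_e)) stop_validation("answers from unknown expert(s): %s",
                                       paste(bad_e, collapse = ", "))
  }
  structure(list(design = design, experts = experts, answers = answers),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d experts, %d questions x %d criteria, %d records\n",
              length(x$experts), nrow(x$design$questions),
              nrow(x$design$criteria), nrow(x$answers)))
  invisible(x)
}

#' Read expert responses from a long-format CSV
#'
#' The canonical interchange format is a tidy CSV with a header row and one
#' record per (expert, question, criterion): columns `expert_id`,
#' `question_id`, `criterion_id`, `response`.  Response labels are matched
#' case-insensitively; `"Insufficiently informed"` maps to the `missing`
#' category.
#'
#' @param path CSV file path.
#' @param design A [survey_design] the records are validated against.
#' @return A [response_matrix].
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path)) stop_validation("responses file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("expert_id", "question_id", "criterion_id", "response")
  if (!all(need %in% names(df))) {
    stop_validation("responses file needs columns: %s",
                    paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop_validation("responses file is empty: %s", path)
  response_matrix(design, df)
}

#' Write expert responses to a long-format CSV
#'
#' Explicit `missing` answers are preserved as rows; absent cells stay
#' absent, so `read_responses(write_responses(m), design)` reproduces `m`
#' exactly.
#'
#' @param matrix A [response_matrix].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (nrow(matrix$answers) == 0) {
    stop_validation("refusing to write a response matrix with no records")
  }
  utils::write.csv(as.data.frame(matrix$answers), path, row.names = FALSE)
  invisible(path)
}

#' Summarise survey participation and completion
#'
#' @param matrix A [response_matrix].
#' @param panel_size Number of experts invited to the survey.
#' @return List with `n_took_part` (experts with at least one recorded
#'   answer, including explicit missing), `n_complete` (experts with a
#'   record for every question x criterion query) and `participation_pct`
#'   (rounded to the nearest integer).
#' @export
#' @examples
#' # 18 of 25 invited experts responding reports 72% participation
completion_summary <- function(matrix, panel_size) {
  stopifnot(inherits(matrix, "response_matrix"))
  responders <- unique(matrix$answers$expert_id)
  n_took_part <- length(responders)
  if (panel_size < n_took_part) {
    stop_validation("panel_size (%d) smaller than number of responders (%d)",
                    panel_size, n_took_part)
  }
  n_cells <- nrow(matrix$design$questions) * nrow(matrix$design$criteria)
  per_expert <- table(matrix$answers$expert_id)
  n_complete <- sum(per_expert == n_cells)
  list(
    n_took_part = n_took_part,
    n_complete = as.integer(n_complete),
    participation_pct = as.numeric(round_half_up(100 * n_took_part / panel_size, 0))
  )
}

# Internal dense representation: integer matrix experts x (Q*C) cells with
# codes 0 = absent, 1 = yes, 2 = no, 3 = undecided, 4 = missing.  Cells are
# laid out criterion-major (all questions under criterion 1, then 2, ...),
# mirroring the canonical survey ordering.  All scoring and agreement
# statistics are computed from this array; the long answer table remains
# the I/O representation.
response_array <- function(matrix) {
  d <- matrix$design
  qids <- d$questions$question_id
  cids <- d$criteria$criterion_id
  nq <- length(qids); nc <- length(cids); ne <- length(matrix$experts)
  arr <- matrix(0L, nrow = ne, ncol = nq * nc,
                dimnames = list(matrix$experts, NULL))
  a <- matrix$answers
  ei <- match(a$expert_id, matrix$experts)
  qi <- match(a$question_id, qids)
  ci <- match(a$criterion_id, cids)
  code <- match(a$response, response_levels())
  arr[cbind(ei, (ci - 1L) * nq + qi)] <- code
  structure(arr, question_ids = qids, criterion_ids = cids)
}

cell_index <- function(arr, question_id, criterion_id) {
  qi <- match(question_id, attr(arr, "question_ids"))
  ci <- match(criterion_id, attr(arr, "criterion_ids"))
  if (is.na(qi)) stop_validation("unknown question id: %s", question_id)
  if (is.na(ci)) stop_validation("unknown criterion id: %s", criterion_id)
  (ci - 1L) * length(attr(arr, "question_ids")) + qi
}
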