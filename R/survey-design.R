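#' Response categories and their point values
#'
#' CHNRI experts answer every question x criterion query with one of four
#' categories.  `Yes` scores 1 point, `No` 0 points, `Undecided` 0.5 points
#' and `Insufficiently informed` is treated as missing input: it carries no
#' point value and is excluded from every mean.
#'
#' @return Named numeric vector mapping the canonical labels
#'   (`yes`, `no`, `undecided`, `missing`) to point values; `missing` maps
#'   to `NA`.
#' @export
#' @examples
#' response_points()
response_points <- function() {
  c(yes = 1, no = 0, undecided = 0.5, missing = NA_real_)
}

response_levels <- function() c("yes", "no", "undecided", "missing")

#' Normalise response labels to the canonical categories
#'
#' Labels are trimmed and matched case-insensitively.  `"insufficiently
#' informed"` (the survey wording for missing input) and `"missing"` both
#' map to the `missing` category.  Unknown labels are rejected, never
#' coerced.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_response(c("Yes", " NO ", "Insufficiently informed"))
normalize_response <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  lab[lab == "insufficiently informed"] <- "missing"
  bad <- !(lab %in% response_levels())
  if (any(bad)) {
    stop_validation("unknown response label(s): %s",
                    paste(unique(x[bad]), collapse = ", "))
  }
  lab
}

#' Construct a survey design
#'
#' A survey design holds the ordered question list, the ordered judging
#' criteria and optional per-criterion weights.  Identifier order here (not
#' file order) defines the canonical ordering used everywhere downstream,
#' including tie-breaking of ranks.
#'
#' @param questions Character vector of question ids, or a data frame with
#'   columns `question_id` and optionally `text` and `theme`.
#' @param criteria Character vector of criterion ids, or a data frame with
#'   columns `criterion_id` and optionally `text`.
#' @param weights Optional non-negative numeric vector of per-criterion
#'   weights (same length as `criteria`, sum > 0).  `NULL` means equal
#'   weights, the unweighted mean used by most CHNRI exercises.
#' @return An object of class `survey_design`.
#' @export
#' @examples
#' survey_design(c("q1", "q2"), c("answerability", "usefulness", "impact"))
survey_design <- function(questions, criteria, weights = NULL) {
  questions <- as_id_table(questions, "question_id", extra = "theme")
  criteria  <- as_id_table(criteria, "criterion_id")
  if (nrow(questions) < 1 || nrow(criteria) < 1) {
    stop_validation("a design needs at least 1 question and 1 criterion")
  }
  if (anyDuplicated(questions$question_id)) {
    stop_validation("duplicated question ids")
  }
  if (anyDuplicated(criteria$criterion_id)) {
    stop_validation("duplicated criterion ids")
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(criteria)) {
      stop_validation("weights must have one entry per criterion")
    }
    if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
      stop_validation("weights must be non-negative with positive sum")
    }
    names(weights) <- criteria$criterion_id
  }
  structure(list(questions = questions, criteria = criteria,
                 weights = weights),
            class = "survey_design")
}

as_id_table <- function(x, id_col, extra = character()) {
  if (is.character(x)) {
    x <- tibble::tibble(id = x)
    names(x) <- id_col
  }
  x <- tibble::as_tibble(x)
  if (!id_col %in% names(x)) {
    stop_validation("missing column '%s'", id_col)
  }
  x[[id_col]] <- as.character(x[[id_col]])
  if ("text" %in% names(x)) x$text <- as.character(x$text) else x$text <- x[[id_col]]
  for (e in extra) if (!e %in% names(x)) x[[e]] <- NA_character_
  x[, c(id_col, "text", extra)]
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("<survey_design> %d questions x %d criteria (%s weights)\n",
              nrow(x$questions), nrow(x$criteria),
              if (is.null(x$weights)) "equal" else "custom"))
  cat("criteria:", paste(x$criteria$criterion_id, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a survey design as a YAML config
#'
#' The on-disk format is a small YAML document with a `questions` list
#' (each entry `id`, optional `text`, `theme`), a `criteria` list and an
#' optional `weights` vector.
#'
#' @param path File path.
#' @return `read_design()` returns a [survey_design]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_validation("design file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$questions) || is.null(cfg$criteria)) {
    stop_validation("design config needs 'questions' and 'criteria'")
  }
  qs <- tibble::tibble(
    question_id = vapply(cfg$questions, function(q) as.character(q$id), ""),
    text  = vapply(cfg$questions, function(q) as.character(q$text %||% q$id), ""),
    theme = vapply(cfg$questions, function(q) as.character(q$theme %||% NA_character_), "")
  )
  cs <- tibble::tibble(
    criterion_id = vapply(cfg$criteria, function(c) as.character(c$id), ""),
    text = vapply(cfg$criteria, function(c) as.character(c$text %||% c$id), "")
  )
  survey_design(qs, cs, weights = cfg$weights)
}

#' @rdname read_design
#' @param design A [survey_design].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "survey_design"))
  cfg <- list(
    questions = lapply(seq_len(nrow(design$questions)), function(i) {
      q <- design$questions[i, ]
      out <- list(id = q$question_id, text = q$text)
      if (!is.na(q$theme)) out$theme <- q$theme
      out
    }),
    criteria = lapply(seq_len(nrow(design$criteria)), function(i) {
      list(id = design$criteria$criterion_id[i], text = design$criteria$text[i])
    })
  )
  if (!is.null(design$weights)) cfg$weights <- as.numeric(design$weights)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Normalised weights over a subset of criteria (used wherever some
# criterion scores are undefined and the mean renormalises).
effective_weights <- function(design) {
  w <- design$weights
  if (is.null(w)) {
    w <- rep(1, nrow(design$criteria))
    names(w) <- design$criteria$criterion_id
  }
  w
}
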