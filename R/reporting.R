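#' Render the ranked priority table
#'
#' Produces the familiar "top ten ranked questions" table: question label,
#' rank, question number, per-criterion scores (one decimal), RPS (one
#' decimal) and AEA (two decimals), sorted by rank and truncated to
#' `top_k`.  Rounding happens here and only here; ranks were computed on
#' full-precision values.
#'
#' @param scores A ranked `score_table` (see [rank_questions()]); if the
#'   `rank` column is absent the table is ranked first.
#' @param agreement Optional `agreement_table` supplying the AEA column
#'   (and the tie-break if ranking is still needed).
#' @param top_k Number of rows to keep (default 10; values larger than the
#'   number of questions keep all).
#' @param design Optional [survey_design] used to attach question text.
#' @return A tibble ready for printing or CSV export.
#' @export
render_ranking <- function(scores, agreement = NULL, top_k = 10,
                           design = NULL) {
  if (top_k < 1) stop_validation("top_k must be >= 1")
  if (!"rank" %in% names(scores)) {
    scores <- rank_questions(scores, agreement)
  }
  cids <- attr(scores, "criterion_ids") %||%
    sub("^score_", "", grep("^score_", names(scores), value = TRUE))
  out <- tibble::tibble(question_id = scores$question_id,
                        rank = scores$rank)
  if (!is.null(design)) {
    out$question <- design$questions$text[
      match(out$question_id, design$questions$question_id)]
  }
  for (cid in cids) {
    out[[cid]] <- round_half_up(scores[[paste0("score_", cid)]], 1)
  }
  out$rps <- round_half_up(scores$rps, 1)
  if (!is.null(agreement)) {
    out$aea <- round_half_up(
      agreement$aea[match(out$question_id, agreement$question_id)], 2)
  }
  out <- out[order(out$rank, na.last = TRUE), ]
  utils::head(out, top_k)
}

#' Format a ranking as aligned plain text
#'
#' @param ranking Tibble from [render_ranking()].
#' @return Character vector of lines.
#' @export
format_ranking_text <- function(ranking) {
  df <- as.data.frame(ranking)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      digits <- if (nm == "aea") 2 else if (nm == "rank") 0 else 1
      df[[nm]] <- fmt_num(df[[nm]], digits)
    }
  }
  withr::with_options(list(width = 10000),
                      utils::capture.output(print(df, row.names = FALSE)))
}

#' Scatterplot of expert agreement against priority score
#'
#' AEA against RPS for every question, with the top-`top_k` questions by
#' RPS highlighted and the least-squares fit overlaid.
#'
#' @param scores A `score_table` (ranked or not).
#' @param agreement An `agreement_table`.
#' @param top_k Number of top-ranked questions to highlight (default 10).
#' @return A ggplot object.
#' @export
plot_aea_rps <- function(scores, agreement, top_k = 10) {
  if (!"rank" %in% names(scores)) scores <- rank_questions(scores, agreement)
  df <- data.frame(
    rps = scores$rps,
    aea = agreement$aea[match(scores$question_id, agreement$question_id)],
    top = !is.na(scores$rank) & scores$rank <= top_k
  )
  df <- df[!is.na(df$rps) & !is.na(df$aea), ]
  ggplot2::ggplot(df, ggplot2::aes(x = rps, y = aea, colour = top)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 labels = c("other", sprintf("top %d", top_k)),
                                 name = NULL) +
    ggplot2::labs(x = "Research priority score (RPS)",
                  y = "Average expert agreement (AEA)")
}

#' Run the full analysis pipeline
#'
#' Reads a design and a response CSV, validates, scores, ranks, computes
#' agreement and (optionally) the bootstrap stability and AEA-RPS
#' association, and writes every table to `out_dir`.  Any stage failure
#' aborts with a stage-named error.
#'
#' @param responses_path Long-format response CSV (see [read_responses()]).
#' @param design_path YAML design config (see [read_design()]).
#' @param out_dir Output directory, created if needed.
#' @param weights Optional per-criterion weights overriding the design's.
#' @param top_k Rows kept in the rendered ranking (default 10).
#' @param bootstrap_reps Bootstrap replicates; 0 skips the stability stage.
#' @param n_permutations Permutations for the association test; 0 skips it.
#' @param seed Seed for the randomised stages (default 20160509).
#' @param formats Output formats, subset of `c("csv", "txt", "json")`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `scores`, `agreement`, `ranking`, and
#'   optionally `stability` and `association`.
#' @export
run_pipeline <- function(responses_path, design_path, out_dir,
                         weights = NULL, top_k = 10, bootstrap_reps = 0,
                         n_permutations = 0, seed = 20160509L,
                         formats = c("csv", "txt"), quiet = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cls <- if (inherits(e, "chnri_validation_error")) {
        "chnri_validation_error"
      } else {
        "chnri_computation_error"
      }
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c(cls, "chnri_error")))
    })
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  design <- stage("read_design", read_design(design_path))
  responses <- stage("read_responses", read_responses(responses_path, design))
  say("read %d records from %d experts", nrow(responses$answers),
      length(responses$experts))
  scores <- stage("score", score_all(responses, weights = weights))
  agreement <- stage("agreement", agreement_all(responses))
  ranked <- stage("rank", rank_questions(scores, agreement))
  rng <- attr(scores, "rps_range"); arng <- attr(agreement, "aea_range")
  say("RPS range %.1f to %.1f; AEA range %.2f to %.2f",
      rng[1], rng[2], arng[1], arng[2])

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ranking <- render_ranking(ranked, agreement, top_k = top_k,
                            design = design)
  if ("csv" %in% formats) {
    utils::write.csv(as.data.frame(ranked),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(agreement),
                     file.path(out_dir, "agreement.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ranking),
                     file.path(out_dir, "ranking.csv"), row.names = FALSE)
  }
  if ("txt" %in% formats) {
    writeLines(format_ranking_text(ranking),
               file.path(out_dir, "ranking.txt"))
  }
  bundle <- list(scores = ranked, agreement = agreement, ranking = ranking)

  if (bootstrap_reps > 0) {
    stab <- stage("stability",
                  bootstrap_ranks(responses, weights = weights,
                                  n_replicates = bootstrap_reps,
                                  seed = seed, top_k = top_k))
    if ("csv" %in% formats) {
      utils::write.csv(as.data.frame(stab$summary),
                       file.path(out_dir, "stability.csv"),
                       row.names = FALSE)
    }
    bundle$stability <- stab
  }
  if (n_permutations > 0) {
    assoc <- stage("association",
                   aea_rps_association(scores, agreement,
                                       n_permutations = n_permutations,
                                       seed = seed))
    if (any(c("json", "csv") %in% formats)) {
      jsonlite::write_json(unclass(assoc),
                           file.path(out_dir, "association.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    bundle$association <- assoc
  }
  invisible(bundle)
}

#' Published top-ten criterion scores from a wasting-stunting CHNRI exercise
#'
#' The top ten rows of the published priority table from a CHNRI exercise
#' on the relationship between wasting and stunting: per-criterion scores
#' (answerability, usefulness, impact), the published RPS and AEA, and the
#' published rank.  The raw per-expert responses behind these summaries
#' were never deposited, so this table is the finest-grained real input
#' available; it is used in examples and to check that the scoring
#' arithmetic reproduces the published summary column.
#'
#' Note the published rank-9 row: its RPS was rounded from already-rounded
#' criterion scores (81.3, 90.6, 76.7 print as 82.8 although their mean is
#' 82.87), a reminder that ranking must be done on full-precision values.
#'
#' @return Tibble with columns `question_no`, `rank_published`, `question`,
#'   `answerability`, `usefulness`, `impact`, `rps_published`,
#'   `aea_published`.
#' @export
#' @examples
#' t10 <- wasting_stunting_top10()
#' research_priority_score(unlist(t10[1, c("answerability", "usefulness",
#'                                         "impact")]))
wasting_stunting_top10 <- function() {
  tibble::tibble(
    question_no = c(24L, 27L, 20L, 7L, 28L, 21L, 30L, 23L, 11L, 5L),
    rank_published = 1:10,
    question = c(
      "Can interventions outside of the 1000 days lead to catch-up in height and other developmental markers?",
      "What timely interventions work to mitigate seasonal peaks in undernutrition (both wasting and stunting)?",
      "What is the optimal formulation of RUTF to promote ponderal growth and support linear growth during and after SAM recovery?",
      "What is the role of pre-pregnancy nutritional status in determining risk of being born stunted and/or wasted?",
      "What are effective packages of interventions for both maternal nutrition and new-born outcomes?",
      "Can nutrition convalescent support prevent both wasting and stunting?",
      "What practical linkages between interventions to treat and prevent wasting and stunting will have the highest impact?",
      "What new interventions work in trial conditions for treating severe stunting in order to prevent associated mortality?",
      "What role does gut health/inflammation play in wasting?",
      "Does treatment of wasting support catch-up in linear growth?"
    ),
    answerability = c(93.8, 93.3, 84.4, 88.2, 93.3, 89.3, 78.1, 71.9, 81.3, 86.1),
    usefulness    = c(93.8, 86.7, 93.8, 86.7, 90.6, 90.6, 90.6, 87.5, 90.6, 78.1),
    impact        = c(85.7, 86.7, 83.3, 85.7, 75.0, 73.3, 83.3, 89.3, 76.7, 80.0),
    rps_published = c(91.1, 88.9, 87.2, 86.9, 86.3, 84.4, 84.0, 82.9, 82.8, 81.4),
    aea_published = c(0.84, 0.80, 0.85, 0.82, 0.79, 0.79, 0.74, 0.74, 0.72, 0.77)
  )
}
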