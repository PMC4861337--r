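#' Bootstrap stability of the priority ranking
#'
#' CHNRI panels are small (18 scorers in a typical exercise), so the
#' ranking can be sensitive to panel composition.  This resamples experts
#' with replacement, recomputes every score, AEA and rank per replicate,
#' and summarises how much each question's rank moves.  The resampling
#' unit is the expert, not the individual answer, because the uncertainty
#' of interest is "would a different panel of the same size rank these
#' questions differently?".
#'
#' Within a replicate, questions that lose every responder under a
#' criterion renormalise over the remaining criteria, and questions with
#' no defined RPS at all sink to the bottom of that replicate's ranking
#' (deterministically, in design order).
#'
#' @param matrix A [response_matrix] with at least 2 responding experts.
#' @param weights Optional per-criterion weights (see [score_all()]).
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; resampling is deterministic given the seed.
#' @param top_k Ranks `<= top_k` count as "top-k" in the retention
#'   probability (default 10).
#' @return A `stability_report`: list with `summary` (per question: median
#'   rank, central 95% rank interval, `p_top_k`), `kendall_w` (Kendall's W
#'   concordance of the replicate rank vectors), `mean_spearman` (mean
#'   pairwise Spearman correlation implied by W), `ranks` (the replicate x
#'   question rank matrix), `n_replicates`, `top_k` and `seed`.
#' @export
bootstrap_ranks <- function(matrix, weights = NULL, n_replicates = 2000,
                            seed, top_k = 10) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (n_replicates < 1) stop_validation("n_replicates must be >= 1")
  if (missing(seed)) stop_validation("bootstrap_ranks requires a seed")
  if (is.null(weights)) weights <- matrix$design$weights
  arr <- response_array(matrix)
  responders <- rowSums(arr != 0L) > 0
  arr <- arr[responders, , drop = FALSE]
  ne <- nrow(arr)
  if (ne < 2) {
    stop_validation("expert bootstrap needs at least 2 responding experts")
  }
  qids <- matrix$design$questions$question_id
  cids <- matrix$design$criteria$criterion_id
  nq <- length(qids); nc <- length(cids)
  w <- if (is.null(weights)) rep(1, nc) else as.numeric(weights)

  ranks <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_integer_, nrow = n_replicates, ncol = nq)
    for (b in seq_len(n_replicates)) {
      sub <- arr[sample.int(ne, ne, replace = TRUE), , drop = FALSE]
      out[b, ] <- replicate_ranks(sub, nq, nc, w)
    }
    out
  })
  colnames(ranks) <- qids

  qs <- apply(ranks, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 1)
  summary <- tibble::tibble(
    question_id = qids,
    median_rank = unname(qs[2, ]),
    rank_lo = unname(qs[1, ]),
    rank_hi = unname(qs[3, ]),
    p_top_k = unname(colMeans(ranks <= top_k))
  )
  # Kendall's W; ranks are full permutations per replicate (no ties), so
  # no tie correction is needed.
  col_tot <- colSums(ranks)
  s <- sum((col_tot - mean(col_tot))^2)
  kendall_w <- 12 * s / (n_replicates^2 * (nq^3 - nq))
  mean_spearman <- if (n_replicates > 1) {
    (n_replicates * kendall_w - 1) / (n_replicates - 1)
  } else {
    NA_real_
  }
  structure(list(summary = summary, kendall_w = kendall_w,
                 mean_spearman = mean_spearman, ranks = ranks,
                 n_replicates = n_replicates, top_k = top_k,
                 seed = as.integer(seed)),
            class = "stability_report")
}

# Full rank vector (1..Q) for one code matrix: descending RPS, ties broken
# by higher AEA then design order; undefined RPS sinks below everything.
replicate_ranks <- function(arr, nq, nc, w) {
  sc <- array_scores(arr)
  smat <- matrix(sc$score, nrow = nq, ncol = nc)
  wmat <- matrix(rep(w, each = nq), nrow = nq)
  wmat[is.na(smat)] <- 0
  wsum <- rowSums(wmat)
  rps <- ifelse(wsum > 0, rowSums(wmat * smat, na.rm = TRUE) / wsum, -Inf)

  fr <- matrix(NA_real_, nrow = nq, ncol = nc)
  for (j in seq_len(ncol(arr))) {
    fr[j] <- cell_modal(arr[, j])$fraction
  }
  aea <- rowMeans(fr, na.rm = TRUE)
  aea[is.nan(aea)] <- 0

  ord <- order(-rps, -aea, seq_len(nq))
  rk <- integer(nq)
  rk[ord] <- seq_len(nq)
  rk
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d replicates; Kendall's W = %.3f (mean pairwise Spearman %.3f)\n",
    x$n_replicates, x$kendall_w, x$mean_spearman))
  print(x$summary)
  invisible(x)
}

#' Association between expert agreement and priority score
#'
#' CHNRI exercises typically find that highly rated questions also attract
#' more agreement.  This fits an ordinary least-squares regression of AEA
#' on RPS and tests the slope with a two-sided permutation test (random
#' relabelling of the AEA values across questions), which avoids
#' distributional assumptions at the small number of questions involved; a
#' t-based p-value is reported alongside for reference.
#'
#' @param scores A `score_table` from [score_all()].
#' @param agreement An `agreement_table` from [agreement_all()].
#' @param n_permutations Number of permutations (default 9999).
#' @param seed Integer seed for the permutation draw.
#' @return An `association_report`: list with `slope`, `intercept`,
#'   `r_squared`, `p_permutation` (add-one estimator, never exactly 0),
#'   `p_t`, `n_questions`, `n_permutations` and `seed`.
#' @export
aea_rps_association <- function(scores, agreement, n_permutations = 9999,
                                seed) {
  if (missing(seed)) stop_validation("aea_rps_association requires a seed")
  m <- match(scores$question_id, agreement$question_id)
  rps <- scores$rps
  aea <- agreement$aea[m]
  ok <- !is.na(rps) & !is.na(aea)
  rps <- rps[ok]; aea <- aea[ok]
  n <- length(rps)
  if (n < 3) {
    stop_validation("association needs >= 3 questions with defined RPS and AEA")
  }
  if (stats::var(rps) == 0) {
    stop_computation("RPS has zero variance; slope undefined")
  }
  slope <- stats::cov(aea, rps) / stats::var(rps)
  intercept <- mean(aea) - slope * mean(rps)
  fit <- stats::lm(aea ~ rps)
  sfit <- suppressWarnings(summary(fit))  # warns on an exact affine fit
  p_t <- sfit$coefficients["rps", "Pr(>|t|)"]
  r2 <- sfit$r.squared

  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      a <- sample(aea)
      stats::cov(a, rps) / stats::var(rps)
    }, numeric(1))
  })
  p_perm <- (1 + sum(abs(perm) >= abs(slope))) / (1 + n_permutations)

  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_permutation = p_perm, p_t = p_t, n_questions = n,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf(
    "<association_report> AEA ~ RPS over %d questions\n  slope %.5f, intercept %.3f, R^2 %.3f\n  permutation p = %.4g (%d permutations), t-based p = %.4g\n",
    x$n_questions, x$slope, x$intercept, x$r_squared,
    x$p_permutation, x$n_permutations, x$p_t))
  invisible(x)
}
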