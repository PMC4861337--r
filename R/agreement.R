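#' Modal response fraction for one question x criterion cell
#'
#' The fraction of substantive responders (Yes / No / Undecided) who gave
#' the most frequent substantive answer.  With three categories the
#' fraction always lies in \[1/3, 1\]; a tie in the mode needs no
#' tie-break because only the maximal count enters the numerator.
#'
#' @param matrix A [response_matrix].
#' @param question_id,criterion_id Identifiers from the design.
#' @return List with `fraction`, `modal_count` and `responder_count`
#'   (`fraction` is `NA` and flagged when the cell has no responder).
#' @export
#' @examples
#' d <- survey_design("q1", "c1")
#' a <- data.frame(expert_id = paste0("e", 1:4), question_id = "q1",
#'                 criterion_id = "c1",
#'                 response = c("yes", "yes", "no", "undecided"))
#' modal_fraction(response_matrix(d, a), "q1", "c1")  # 2/4 = 0.5
modal_fraction <- function(matrix, question_id, criterion_id) {
  arr <- response_array(matrix)
  j <- cell_index(arr, question_id, criterion_id)
  cell_modal(arr[, j])
}

cell_modal <- function(codes) {
  counts <- tabulate(codes[codes %in% 1:3], nbins = 3L)
  n <- sum(counts)
  if (n == 0) {
    return(list(fraction = NA_real_, modal_count = NA_integer_,
                responder_count = 0L))
  }
  list(fraction = max(counts) / n, modal_count = as.integer(max(counts)),
       responder_count = as.integer(n))
}

#' Average Expert Agreement for one question
#'
#' The AEA summarises consensus versus controversy: for each of the
#' question's criterion queries it takes the fraction of responding
#' experts who gave the most frequent answer, and averages those fractions
#' over the criteria (three in the standard CHNRI design).  Values near 1
#' indicate consensus; the floor with three answer categories is 1/3.
#'
#' @param matrix A [response_matrix].
#' @param question_id Question identifier.
#' @return AEA in (1/3, 1\]; `NA` if no criterion cell has a responder.
#' @export
average_expert_agreement <- function(matrix, question_id) {
  arr <- response_array(matrix)
  cids <- attr(arr, "criterion_ids")
  fr <- vapply(cids, function(cid) {
    cell_modal(arr[, cell_index(arr, question_id, cid)])$fraction
  }, numeric(1))
  if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
}

# Per-cell modal summaries over a code matrix; criterion-major layout.
array_modals <- function(arr) {
  nqc <- ncol(arr)
  frac <- numeric(nqc); mcount <- integer(nqc); rcount <- integer(nqc)
  for (j in seq_len(nqc)) {
    m <- cell_modal(arr[, j])
    frac[j] <- m$fraction
    mcount[j] <- if (is.na(m$modal_count)) NA_integer_ else m$modal_count
    rcount[j] <- m$responder_count
  }
  list(fraction = frac, modal_count = mcount, responder_count = rcount)
}

build_agreement_table <- function(design, modals) {
  qids <- design$questions$question_id
  cids <- design$criteria$criterion_id
  nq <- length(qids); nc <- length(cids)
  fmat <- matrix(modals$fraction, nrow = nq, ncol = nc)
  aea <- rowMeans(fmat, na.rm = TRUE)
  aea[is.nan(aea)] <- NA_real_
  out <- tibble::tibble(question_id = qids, aea = aea)
  for (k in seq_len(nc)) {
    out[[paste0("modal_fraction_", cids[k])]] <- fmat[, k]
  }
  mmat <- matrix(modals$modal_count, nrow = nq)
  rmat <- matrix(modals$responder_count, nrow = nq)
  for (k in seq_len(nc)) {
    out[[paste0("modal_count_", cids[k])]] <- mmat[, k]
    out[[paste0("responder_count_", cids[k])]] <- rmat[, k]
  }
  structure(out, class = c("agreement_table", class(out)),
            criterion_ids = cids,
            aea_range = suppressWarnings(range(aea, na.rm = TRUE)))
}

#' Average Expert Agreement for every question
#'
#' @param matrix A [response_matrix].
#' @return An `agreement_table` tibble: `question_id`, `aea`, and
#'   per-criterion `modal_fraction_*`, `modal_count_*` and
#'   `responder_count_*` columns.  The AEA range is attached as attribute
#'   `aea_range`.
#' @export
agreement_all <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  arr <- response_array(matrix)
  build_agreement_table(matrix$design, array_modals(arr))
}

#' @export
print.agreement_table <- function(x, ...) {
  rng <- attr(x, "aea_range")
  cat(sprintf("<agreement_table> %d questions; AEA range %.2f to %.2f\n",
              nrow(x), rng[1], rng[2]))
  NextMethod()
}
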