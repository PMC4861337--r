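test_that("degenerate all-yes spec produces a unanimous panel", {
  d <- toy_design(2, 2)
  spec <- panel_spec(d, n_invited = 5, n_experts = 4,
                     base_probs = c(1, 0, 0, 0), seed = 3)
  panel <- generate_panel(spec)
  expect_equal(nrow(panel$answers), 4 * 2 * 2)
  expect_true(all(panel$answers$response == "yes"))
  expect_true(all(score_all(panel)$rps == 100))
  expect_true(all(agreement_all(panel)$aea == 1))
})

test_that("generation is deterministic given the seed", {
  spec <- default_panel_spec(seed = 42)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1$answers, p2$answers)
  spec2 <- default_panel_spec(seed = 43)
  expect_false(identical(generate_panel(spec2)$answers, p1$answers))
})

test_that("panel_spec validates its inputs", {
  d <- toy_design()
  expect_error(panel_spec(d, 5, 6), class = "chnri_validation_error")
  expect_error(panel_spec(d, 5, 4, base_probs = c(0.5, 0.5, 0.5, 0)),
               class = "chnri_validation_error")
  expect_error(panel_spec(d, 5, 4, consensus = 1.5),
               class = "chnri_validation_error")
  expect_error(panel_spec(d, 5, 4, partial_completion_rate = -0.1),
               class = "chnri_validation_error")
  expect_error(generate_panel(
    panel_spec(d, 5, 4,
               cell_probs = data.frame(question_id = "qX",
                                       criterion_id = "c1", p_yes = 1,
                                       p_no = 0, p_undecided = 0,
                                       p_missing = 0))),
    class = "chnri_validation_error")
})

test_that("large panels recover the closed-form expected score", {
  d <- survey_design("q1", "c1")
  spec <- panel_spec(d, n_invited = 500, n_experts = 500,
                     base_probs = c(0.5, 0.3, 0.2, 0), seed = 11)
  panel <- generate_panel(spec)
  cs <- criterion_score(panel, "q1", "c1")
  # expectation 100 * (0.5 + 0.5 * 0.2) = 60; per-expert point SD 0.436
  se <- 100 * sqrt(0.19) / sqrt(500)
  expect_lt(abs(cs$score - 60), 3 * se)
  expect_equal(expected_scores(spec)$erps, 60)
})

test_that("partial completion truncates the criterion-major query sequence", {
  d <- toy_design(3, 2)
  spec <- panel_spec(d, 10, 8, base_probs = c(0.6, 0.2, 0.2, 0),
                     partial_completion_rate = 1, seed = 21)
  panel <- generate_panel(spec)
  s <- completion_summary(panel, 10)
  expect_equal(s$n_complete, 0)   # every expert stopped early
  # each expert's answered cells form a prefix: all of criterion c1's
  # questions come before any of c2's
  arr_order <- as.vector(outer(d$questions$question_id,
                               d$criteria$criterion_id, paste, sep = "/"))
  for (e in unique(panel$answers$expert_id)) {
    rows <- panel$answers[panel$answers$expert_id == e, ]
    pos <- match(paste(rows$question_id, rows$criterion_id, sep = "/"),
                 arr_order)
    expect_equal(sort(pos), seq_len(nrow(rows)))
  }
})

test_that("theme and cell probability overrides cascade", {
  d <- survey_design(
    tibble::tibble(question_id = c("q1", "q2", "q3"),
                   text = c("a", "b", "c"),
                   theme = c("t1", "t1", "t2")),
    "c1")
  spec <- panel_spec(d, 30, 30,
                     base_probs = c(1, 0, 0, 0),
                     theme_probs = list(t2 = c(0, 1, 0, 0)),
                     cell_probs = data.frame(question_id = "q2",
                                             criterion_id = "c1",
                                             p_yes = 0, p_no = 0,
                                             p_undecided = 1, p_missing = 0),
                     seed = 2)
  panel <- generate_panel(spec)
  get_resp <- function(q) unique(panel$answers$response[
    panel$answers$question_id == q])
  expect_equal(get_resp("q1"), "yes")        # base
  expect_equal(get_resp("q2"), "undecided")  # cell override beats theme/base
  expect_equal(get_resp("q3"), "no")         # theme override
})

test_that("consensus parameter monotonically raises mean AEA", {
  base <- default_panel_spec(n_questions = 10, seed = 5)
  mean_aea <- vapply(c(0, 0.4, 0.8), function(g) {
    spec <- base
    spec$consensus <- if (g == 0) NULL else g
    vals <- vapply(1:5, function(i) {
      spec$seed <- 100L * i
      mean(agreement_all(generate_panel(spec))$aea, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_aea) > 0))
  # full consensus: every responder gives the modal answer
  full <- base
  full$consensus <- 1
  expect_true(all(agreement_all(generate_panel(full))$aea == 1))
})

test_that("recovery experiment reports zero bias for a degenerate spec", {
  d <- toy_design(2, 2)
  spec <- panel_spec(d, 6, 6, base_probs = c(1, 0, 0, 0), seed = 1)
  rec <- recovery_experiment(spec, n_replicates = 3, seed = 50,
                             n_reference = 1000)
  expect_equal(rec$summary$rps_bias, rep(0, 2))
  expect_equal(rec$summary$rps_sd, rep(0, 2))
  expect_equal(rec$summary$aea_mean, rep(1, 2))
  expect_equal(rec$summary$aea_expected, rep(1, 2))
})

test_that("RPS spread shrinks roughly as 1/sqrt(panel size)", {
  d <- default_survey_design(n_questions = 4)
  make_spec <- function(ne) panel_spec(d, ne, ne,
                                       base_probs = c(0.5, 0.2, 0.2, 0.1),
                                       seed = 1)
  r18 <- recovery_experiment(make_spec(18), n_replicates = 120, seed = 60,
                             n_reference = 2000)
  r180 <- recovery_experiment(make_spec(180), n_replicates = 120, seed = 61,
                              n_reference = 2000)
  ratio <- mean(r18$summary$rps_sd) / mean(r180$summary$rps_sd)
  # binomial scaling predicts sqrt(10) ~ 3.16
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 4.5)
})

test_that("panel spec YAML round-trips through read_panel_spec", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    design = list(
      questions = list(list(id = "q1"), list(id = "q2", theme = "t1")),
      criteria = list(list(id = "c1"))
    ),
    n_invited = 10, n_experts = 8,
    base_probs = c(0.6, 0.2, 0.1, 0.1),
    partial_completion_rate = 0.25,
    consensus = 0.5,
    seed = 9
  ), f)
  spec <- read_panel_spec(f)
  expect_s3_class(spec, "panel_spec")
  expect_equal(spec$n_experts, 8L)
  expect_equal(spec$base_probs, c(0.6, 0.2, 0.1, 0.1))
  expect_equal(spec$consensus, 0.5)
  panel <- generate_panel(spec)
  expect_s3_class(panel, "response_matrix")
})
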