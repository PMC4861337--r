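test_that("response encoding is total and injective over the four labels", {
  pts <- response_points()
  expect_named(pts, c("yes", "no", "undecided", "missing"))
  expect_equal(unname(pts[c("yes", "no", "undecided")]), c(1, 0, 0.5))
  expect_true(is.na(pts["missing"]))
  # distinct labels never collapse to the same substantive value
  expect_equal(anyDuplicated(pts[1:3]), 0)
  # survey wording and case variants normalise, unknown labels are rejected
  expect_equal(normalize_response(c("Yes", " NO ", "Undecided",
                                    "Insufficiently informed", "MISSING")),
               c("yes", "no", "undecided", "missing", "missing"))
  expect_error(normalize_response("maybe"), class = "chnri_validation_error")
})

test_that("survey_design validates ids and weights", {
  d <- survey_design(c("q1", "q2"), c("c1", "c2"), weights = c(2, 1))
  expect_s3_class(d, "survey_design")
  expect_equal(names(d$weights), c("c1", "c2"))
  expect_error(survey_design(c("q1", "q1"), "c1"),
               class = "chnri_validation_error")
  expect_error(survey_design(character(), "c1"),
               class = "chnri_validation_error")
  expect_error(survey_design("q1", "c1", weights = c(1, 2)),
               class = "chnri_validation_error")
  expect_error(survey_design("q1", c("c1", "c2"), weights = c(0, 0)),
               class = "chnri_validation_error")
})

test_that("read_responses maps labels, rejects duplicates and bad input", {
  d <- toy_design(1, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(expert_id = "e1", question_id = "q1",
                       criterion_id = c("c1", "c2", "c3"),
                       response = c("yes", "no", "undecided")),
            f, row.names = FALSE)
  m <- read_responses(f, d)
  expect_equal(nrow(m$answers), 3)
  expect_setequal(m$answers$response, c("yes", "no", "undecided"))

  # the survey's "Insufficiently informed" wording becomes the missing category
  write.csv(data.frame(expert_id = "e1", question_id = "q1",
                       criterion_id = "c1",
                       response = "Insufficiently informed"),
            f, row.names = FALSE)
  expect_equal(read_responses(f, d)$answers$response, "missing")

  # duplicated (expert, question, criterion) is an error
  write.csv(data.frame(expert_id = "e1", question_id = "q1",
                       criterion_id = c("c1", "c1"),
                       response = c("yes", "no")),
            f, row.names = FALSE)
  expect_error(read_responses(f, d), class = "chnri_validation_error")

  # unknown ids are named in the error
  write.csv(data.frame(expert_id = "e1", question_id = "qX",
                       criterion_id = "c1", response = "yes"),
            f, row.names = FALSE)
  expect_error(read_responses(f, d), "qX",
               class = "chnri_validation_error")

  # empty file is an error
  write.csv(data.frame(expert_id = character(), question_id = character(),
                       criterion_id = character(), response = character()),
            f, row.names = FALSE)
  expect_error(read_responses(f, d), class = "chnri_validation_error")
  expect_error(read_responses(file.path(tempdir(), "nope.csv"), d),
               class = "chnri_validation_error")
})

test_that("response CSV round-trips exactly, preserving explicit missing", {
  withr::local_seed(42)
  for (i in 1:5) {
    p <- random_small_panel(ne = 4, nq = 3, nc = 2)
    skip_rest <- nrow(p$matrix$answers) == 0
    if (skip_rest) next
    f <- withr::local_tempfile(fileext = ".csv")
    write_responses(p$matrix, f)
    back <- read_responses(f, p$design)
    expect_equal(back$answers, p$matrix$answers)
    # absent cells stay absent; explicit missing rows survive
    expect_equal(sum(back$answers$response == "missing"),
                 sum(p$matrix$answers$response == "missing"))
  }
  # an empty matrix cannot be written
  d <- toy_design()
  empty <- response_matrix(d, data.frame(expert_id = character(),
                                         question_id = character(),
                                         criterion_id = character(),
                                         response = character()),
                           experts = "e1")
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_responses(empty, f), class = "chnri_validation_error")
})

test_that("design YAML round-trips, including weights", {
  d <- survey_design(
    tibble::tibble(question_id = c("q1", "q2"),
                   text = c("first", "second"),
                   theme = c("burden", NA)),
    tibble::tibble(criterion_id = c("c1", "c2"),
                   text = c("answerable", "useful")),
    weights = c(2, 1))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_design(d, f)
  back <- read_design(f)
  expect_equal(back$questions$question_id, d$questions$question_id)
  expect_equal(back$questions$text, d$questions$text)
  expect_equal(back$criteria, d$criteria)
  expect_equal(unname(back$weights), c(2, 1))
})

test_that("validation rejects randomly corrupted answer tables", {
  withr::local_seed(99)
  d <- toy_design(2, 2)
  base <- make_answers(c("e1", "e2"), d$questions$question_id,
                       d$criteria$criterion_id, rep("yes", 8))
  for (i in 1:30) {
    a <- base
    mode <- sample(3, 1)
    row <- sample(nrow(a), 1)
    if (mode == 1) a$question_id[row] <- "bogus_q"
    if (mode == 2) a$criterion_id[row] <- "bogus_c"
    if (mode == 3) a$response[row] <- "perhaps"
    expect_error(response_matrix(d, a), class = "chnri_validation_error")
  }
  # duplicated key
  a <- rbind(base, base[1, ])
  expect_error(response_matrix(d, a), class = "chnri_validation_error")
})

test_that("completion summary counts participation and full completion", {
  d <- toy_design(2, 2)
  # 3 experts: one full, one partial, one explicit-missing-only
  a <- rbind(
    make_answers("full", d$questions$question_id, d$criteria$criterion_id,
                 rep("yes", 4)),
    data.frame(expert_id = "partial", question_id = "q1",
               criterion_id = "c1", response = "no"),
    data.frame(expert_id = "allmiss", question_id = "q1",
               criterion_id = "c1", response = "missing")
  )
  m <- response_matrix(d, a)
  s <- completion_summary(m, panel_size = 4)
  expect_equal(s$n_took_part, 3)     # explicit missing still counts as taking part
  expect_equal(s$n_complete, 1)
  expect_equal(s$participation_pct, 75)

  # all invited respond fully
  full <- unanimous_panel(ne = 4, nq = 2, nc = 2)
  s2 <- completion_summary(full, panel_size = 4)
  expect_equal(s2$n_complete, 4)
  expect_equal(s2$participation_pct, 100)

  # zero responders
  empty <- response_matrix(d, a[0, ], experts = "e1")
  expect_equal(completion_summary(empty, panel_size = 5)$participation_pct, 0)

  # panel smaller than responder count is impossible
  expect_error(completion_summary(m, panel_size = 2),
               class = "chnri_validation_error")
})
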