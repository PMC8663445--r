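test_that("log-odds to probability transform behaves as the logistic", {
  expect_equal(probability_from_log_odds(0), 0.5)
  expect_equal(probability_from_log_odds(log(3.9254)), 3.9254 / 4.9254,
               tolerance = 1e-12)
  expect_equal(probability_from_log_odds(log(0.345 / 0.655)), 0.345,
               tolerance = 1e-12)
  lo <- sort(stats::runif(50, -10, 10))
  expect_true(all(diff(probability_from_log_odds(lo)) > 0))
  expect_error(probability_from_log_odds(Inf), "finite")
  expect_error(probability_from_log_odds(NA_real_), "finite")
})

test_that("posttest log-odds match the hand odds-product worked examples", {
  kb <- default_kb
  # no answers: the pretest log-odds come straight back
  expect_equal(posttest_log_odds(0.345, answer_set(), kb, "vasovagal"),
               log(0.345 / 0.655), tolerance = 1e-12)
  # yes to the age question: (0.35/0.65) * 7.29 = 3.9254 -> p = 0.7970
  lo <- posttest_log_odds(0.35, answer_set(age_le_35 = "yes"), kb,
                          "vasovagal")
  expect_equal(probability_from_log_odds(lo), 0.7969702, tolerance = 1e-6)
  # no to the age question: (0.35/0.65) * 0.30 -> p = 0.1391
  lo <- posttest_log_odds(0.35, answer_set(age_le_35 = "no"), kb,
                          "vasovagal")
  expect_equal(probability_from_log_odds(lo), 0.1390728, tolerance = 1e-6)
})

test_that("invalid priors and unknown question ids are rejected", {
  expect_error(posttest_log_odds(0, answer_set(), default_kb, "vasovagal"),
               "open interval")
  expect_error(posttest_log_odds(1, answer_set(), default_kb, "vasovagal"),
               "open interval")
  expect_error(
    posttest_log_odds(0.5, answer_set(no_such_question = "yes"),
                      default_kb, "vasovagal"),
    "unknown question id")
})

test_that("log-sum aggregation equals the sequential odds-product oracle", {
  set.seed(101)
  for (trial in 1:250) {
    kb <- random_kb()
    answers <- random_answers(kb)
    for (et in syncope_etiologies()) {
      p_engine <- probability_from_log_odds(
        posttest_log_odds(kb$priors[[et]], answers, kb, et))
      p_oracle <- oracle_posttest_probability(kb$priors[[et]], answers,
                                              kb, et)
      expect_equal(p_engine, p_oracle, tolerance = 1e-10)
    }
  }
})

test_that("the two logistic parameterizations agree", {
  set.seed(202)
  for (trial in 1:100) {
    kb <- random_kb()
    answers <- random_answers(kb)
    for (et in syncope_etiologies()) {
      a <- posttest_log_odds(kb$priors[[et]], answers, kb, et)
      b <- syncopedx:::posttest_log_odds_beta(kb$priors[[et]], answers,
                                              kb, et)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("with all answers unknown every probability equals its prior", {
  kb <- default_kb
  unknowns <- stats::setNames(rep("unknown", 20), names(kb$questions))
  d <- compute_differential(as_answer_set(unknowns), kb)
  td <- tidy(d)
  for (et in syncope_etiologies()) {
    expect_equal(td$probability[td$etiology == et], kb$priors[[et]],
                 tolerance = 1e-12)
  }
  # ranking equals descending prior order
  expect_equal(td$etiology,
               names(sort(kb$priors[syncope_etiologies()],
                          decreasing = TRUE)))
})

test_that("flipping an answer moves the posterior in the direction of the cell", {
  set.seed(303)
  for (trial in 1:50) {
    kb <- random_kb()
    cells <- kb_lhr_cells(kb)
    if (nrow(cells) == 0) next
    i <- sample(nrow(cells), 1)
    qid <- cells$question_id[i]
    et <- cells$etiology[i]
    base <- random_answers(kb)
    ans_no <- base; ans_no$answers[qid] <- "no"
    ans_yes <- base; ans_yes$answers[qid] <- "yes"
    p_no <- probability_from_log_odds(
      posttest_log_odds(kb$priors[[et]], ans_no, kb, et))
    p_yes <- probability_from_log_odds(
      posttest_log_odds(kb$priors[[et]], ans_yes, kb, et))
    if (cells$lhr_pos[i] > cells$lhr_neg[i]) {
      expect_gt(p_yes, p_no)
    } else if (cells$lhr_pos[i] < cells$lhr_neg[i]) {
      expect_lt(p_yes, p_no)
    }
  }
})

test_that("a neutral cell (both ratios 1) leaves the posterior unchanged", {
  kb <- default_kb
  kb$questions[["chest_pain"]]$lhr$vasovagal <-
    list(lhr_pos = 1, lhr_neg = 1)
  base <- posttest_log_odds(0.3, answer_set(), kb, "vasovagal")
  for (a in c("yes", "no")) {
    lo <- posttest_log_odds(0.3, answer_set(chest_pain = a), kb,
                            "vasovagal")
    expect_equal(lo, base, tolerance = 1e-12)
  }
})

test_that("answer iteration order does not change results beyond roundoff", {
  set.seed(404)
  kb <- random_kb()
  answers <- random_answers(kb, p_unknown = 0.1)
  perm <- answers
  perm$answers <- perm$answers[sample(length(perm$answers))]
  for (et in syncope_etiologies()) {
    expect_equal(posttest_log_odds(0.3, answers, kb, et),
                 posttest_log_odds(0.3, perm, kb, et), tolerance = 1e-12)
  }
})

test_that("probabilities are never renormalized across etiologies", {
  # a strongly vasovagal picture: all four posteriors should keep their raw
  # per-model values, summing to something other than 1
  d <- compute_differential(
    answer_set(age_le_35 = "yes", trigger_context = "yes",
               nausea_vomiting_warmth = "yes"), default_kb)
  td <- tidy(d)
  expect_false(isTRUE(all.equal(sum(td$probability), 1)))
  # untouched etiologies keep exactly their priors
  expect_equal(td$probability[td$etiology == "orthostatic"], 0.10,
               tolerance = 1e-12)
  expect_equal(td$probability[td$etiology == "neurogenic_loc"], 0.05,
               tolerance = 1e-12)
})

test_that("a cardiac evidence chain ranks cardiogenic first", {
  # hand oracle: cardio odds (0.13/0.87)*2.93*4.25*4.36*1.43*1.38 = 16.01
  # -> p 0.9412; vasovagal odds (0.345/0.655)*0.072*0.498*0.552 -> p 0.0103
  a <- answer_set(heart_disease_history = "yes", chest_pain = "yes",
                  exertion = "yes", trigger_context = "no",
                  nausea_vomiting_warmth = "no")
  d <- compute_differential(a, default_kb)
  expect_equal(app_top(d), "cardiogenic")
  td <- tidy(d)
  expect_equal(td$probability[td$etiology == "cardiogenic"], 0.9412099,
               tolerance = 1e-6)
  expect_equal(td$probability[td$etiology == "vasovagal"], 0.0103175,
               tolerance = 1e-6)
})

test_that("override fires only when all flagged questions are yes", {
  kb <- default_kb
  # both orthostatic questions yes: ranked first despite a low probability
  d <- compute_differential(
    answer_set(orthostatic_vitals = "yes", orthostasis_suspected = "yes"),
    kb)
  expect_equal(app_top(d), "orthostatic")
  expect_true(tidy(d)$overridden[1])
  # probabilities are not numerically altered by the override
  expect_equal(tidy(d)$probability[1], kb$priors[["orthostatic"]],
               tolerance = 1e-12)

  # only one flagged question yes: no override, rank by probability alone
  d1 <- compute_differential(answer_set(orthostatic_vitals = "yes"), kb)
  expect_false(any(tidy(d1)$overridden))
  expect_equal(app_top(d1), "vasovagal")

  # neurogenic pair
  d2 <- compute_differential(
    answer_set(neuro_symptoms = "yes", new_focal_deficit = "yes"), kb)
  expect_equal(app_top(d2), "neurogenic_loc")
  expect_true(tidy(d2)$overridden[1])
})

test_that("among multiple overridden etiologies neurogenic LOC precedes orthostatic", {
  d <- compute_differential(
    answer_set(orthostatic_vitals = "yes", orthostasis_suspected = "yes",
               neuro_symptoms = "yes", new_focal_deficit = "yes"),
    default_kb)
  td <- tidy(d)
  expect_equal(td$etiology[1:2], c("neurogenic_loc", "orthostatic"))
  expect_true(all(td$overridden[1:2]))
})

test_that("with no flagged yes answers the ranking is pure probability order", {
  a <- answer_set(age_le_35 = "yes", heart_disease_history = "no")
  d <- compute_differential(a, default_kb)
  td <- tidy(d)
  expect_false(any(td$overridden))
  expect_equal(td$probability, sort(td$probability, decreasing = TRUE))
})

test_that("differential accessors are consistent", {
  d <- compute_differential(answer_set(trigger_context = "yes"), default_kb)
  expect_s3_class(d, "syncope_differential")
  expect_equal(app_top(d), tidy(d)$etiology[1])
  expect_equal(glance(d)$app_top, app_top(d))
  # probability/log-odds identity within 1e-12
  td <- tidy(d)
  expect_equal(td$probability, 1 / (1 + exp(-td$log_odds)),
               tolerance = 1e-12)
  p <- autoplot(d)
  expect_s3_class(p, "ggplot")
})
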