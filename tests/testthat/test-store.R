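test_that("append and read back yields an equal record, in append order", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  a <- answer_set(age_le_35 = "yes", trigger_context = "yes",
                  user_selected_ddx = "vasovagal")
  rec <- evaluation_record(assess(a, default_kb), record_id = "r1",
                           timestamp = "2024-01-01T00:00:00Z")
  append_record(store, rec, default_kb)
  b <- answer_set(troponin_elevated = "yes")
  rec2 <- evaluation_record(assess(b, default_kb), record_id = "r2",
                            timestamp = "2024-01-02T00:00:00Z")
  append_record(store, rec2, default_kb)

  back <- read_records(store)
  expect_length(back, 2)
  expect_equal(vapply(back, function(r) r$record_id, character(1)),
               c("r1", "r2"))
  expect_equal(unclass(back[[1]]), unclass(rec), tolerance = 0)
})

test_that("a tampered record fails the integrity check instead of persisting", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  a <- answer_set(age_le_35 = "yes", user_selected_ddx = "vasovagal")
  rec <- evaluation_record(assess(a, default_kb))
  rec$css_total <- rec$css_total + 1L
  expect_error(append_record(store, rec, default_kb), "integrity error")
  expect_false(file.exists(store) && length(readLines(store)) > 0)

  rec2 <- evaluation_record(assess(a, default_kb))
  rec2$app_top <- "cardiogenic"
  expect_error(append_record(store, rec2, default_kb), "integrity error")
})

test_that("an unwritable store path raises an I/O error", {
  rec <- evaluation_record(assess(answer_set(), default_kb))
  expect_error(
    append_record(file.path(tempdir(), "no_such_dir", "x.jsonl"), rec,
                  default_kb),
    "cannot open")
})

test_that("records carry no patient identifiers", {
  rec <- evaluation_record(assess(answer_set(), default_kb))
  expect_setequal(names(unclass(rec)),
                  c("record_id", "timestamp", "answers",
                    "user_selected_ddx", "app_top", "css_total",
                    "risk_class", "recommendation_keys", "hypothetical"))
})

test_that("congruence counts concordant records among user-selected ones", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store, n_concordant = 7, n_discordant = 3)
  rep <- congruence_report(read_records(store))
  expect_equal(rep$fraction, 0.7)
  expect_equal(rep$n_concordant, 7L)
  expect_equal(rep$n_eligible, 10L)

  # all concordant
  store2 <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store2, n_concordant = 5, n_discordant = 0)
  expect_equal(congruence_report(read_records(store2))$fraction, 1)
})

test_that("records without a user selection are excluded from the metric", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store, n_concordant = 3, n_discordant = 1)
  append_record(store,
                evaluation_record(assess(answer_set(), default_kb)),
                default_kb)
  rep <- congruence_report(read_records(store))
  expect_equal(rep$n_eligible, 4L)
  expect_equal(rep$n_records, 5L)
  expect_equal(rep$fraction, 0.75)
})

test_that("zero eligible records yields an explicit empty report", {
  rep <- congruence_report(list())
  expect_true(is.na(rep$fraction))
  expect_equal(rep$n_eligible, 0L)
  # restriction to an etiology absent from the store is also empty
  store <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store, n_concordant = 2, n_discordant = 0)
  rep2 <- congruence_report(read_records(store),
                            restrict_to = "neurogenic_loc")
  expect_true(is.na(rep2$fraction))
})

test_that("restriction filters on the user-selected etiology", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  # concordant records select vasovagal; discordant ones cardiogenic
  build_store(store, n_concordant = 6, n_discordant = 2)
  recs <- read_records(store)
  rep_vaso <- congruence_report(recs, restrict_to = "vasovagal")
  expect_equal(rep_vaso$n_eligible, 6L)
  expect_equal(rep_vaso$fraction, 1)
  rep_both <- congruence_report(recs,
                                restrict_to = c("cardiogenic",
                                                "vasovagal"))
  expect_equal(rep_both$n_eligible, 8L)
  expect_equal(rep_both$fraction, 0.75)
  # a superset restriction never decreases the eligible count
  expect_gte(rep_both$n_eligible, rep_vaso$n_eligible)
})

test_that("the report is permutation-invariant over records", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store, n_concordant = 4, n_discordant = 3)
  recs <- read_records(store)
  set.seed(9)
  shuffled <- recs[sample(length(recs))]
  expect_equal(as.data.frame(congruence_report(recs)),
               as.data.frame(congruence_report(shuffled)))
})

test_that("hypothetical records are excluded unless requested", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  build_store(store, n_concordant = 3, n_discordant = 0)
  a <- answer_set(heart_disease_history = "yes",
                  user_selected_ddx = "vasovagal")
  append_record(store,
                evaluation_record(assess(a, default_kb),
                                  hypothetical = TRUE),
                default_kb)
  recs <- read_records(store)
  expect_equal(congruence_report(recs)$n_eligible, 3L)
  expect_equal(congruence_report(recs,
                                 include_hypothetical = TRUE)$n_eligible,
               4L)
})
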