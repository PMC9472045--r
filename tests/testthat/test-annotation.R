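test_that("assignment partitions near-evenly and is seed-deterministic", {
  pats <- sprintf("p%02d", 1:10)
  a <- assign_patients(pats, c("ann1", "ann2"), "individual", seed = 4)
  expect_equal(as.integer(sort(table(a$annotator_id))), c(5L, 5L))
  expect_setequal(a$patient_id, pats)
  expect_equal(assign_patients(pats, c("ann1", "ann2"), "individual", seed = 4), a)
  b <- assign_patients(pats, c("ann1", "ann2"), "individual", seed = 5)
  expect_setequal(b$patient_id, pats)  # different seed: still a valid partition

  odd <- assign_patients(sprintf("p%02d", 1:11), c("a", "b", "c"), "individual", seed = 1)
  expect_true(max(table(odd$annotator_id)) - min(table(odd$annotator_id)) <= 1)

  sh <- assign_patients(sprintf("p%d", 1:5), c("a", "b"), "shared", seed = 1)
  expect_equal(nrow(sh), 10)
  expect_equal(sort(unique(sh$patient_id[sh$annotator_id == "a"])), sprintf("p%d", 1:5))

  expect_equal(nrow(assign_patients(character(0), "a", "individual", seed = 1)), 0)
  expect_error(assign_patients(pats, character(0), "individual", seed = 1),
               "at least one annotator")
})

test_that("suggest_label applies the adjudication rules in order", {
  m <- compile_lexicon(default_lexicon())
  run <- function(chart) {
    spans <- find_spans_all(segment_notes(chart), m)
    suggest_label(chart, spans)
  }

  # structured evidence dominates: donepezil with no text evidence
  med <- make_chart("p1", texts = "Routine visit today.", dates = "2017-06-01",
                    meds = "Donepezil 10 mg tablet")
  s <- run(med)
  expect_equal(s$label, "CI")
  expect_match(s$rationale, "dementia_medication")

  icd <- make_chart("p1", texts = "Routine visit today.", dates = "2017-06-01",
                    dx = list(code = "G30.9", system = "ICD10"))
  expect_equal(run(icd)$label, "CI")

  # empty chart: undetermined by sparsity
  expect_equal(run(make_chart("p1"))$label, "undetermined")

  # latest evidence decides conflicts: impaired in January, intact in June -> CN
  conflict <- make_chart("p1",
    texts = c("Concern for memory loss raised by family.",
              "Memory and cognition are fully intact today.",
              "Routine visit."),
    dates = c("2017-01-10", "2017-06-10", "2017-07-01"))
  s <- run(conflict)
  expect_equal(s$label, "CN")
  expect_match(s$rationale, "latest_evidence_intact")

  # reversed order: impaired latest -> CI
  rev_conflict <- make_chart("p1",
    texts = c("Memory and cognition are fully intact today.",
              "Concern for memory loss raised by family.",
              "Routine visit."),
    dates = c("2017-01-10", "2017-06-10", "2017-07-01"))
  expect_equal(run(rev_conflict)$label, "CI")

  # impaired only -> CI; intact only -> CN
  expect_equal(run(make_chart("p1", texts = c("Noted memory loss.", "f", "g"),
                              dates = c("2017-01-01", "2017-02-01", "2017-03-01")))$label, "CI")
  expect_equal(run(make_chart("p1", texts = c("Cognitively intact.", "f", "g"),
                              dates = c("2017-01-01", "2017-02-01", "2017-03-01")))$label, "CN")

  # no evidence: sparse -> undetermined, enough notes -> implicit CN
  sparse <- make_chart("p1", texts = c("Routine.", "Routine."),
                       dates = c("2017-01-01", "2017-02-01"))
  expect_equal(run(sparse)$label, "undetermined")
  full <- make_chart("p1", texts = rep("Routine visit.", 4),
                     dates = sprintf("2017-0%d-01", 1:4))
  s <- run(full)
  expect_equal(s$label, "CN")
  expect_equal(s$rationale, "implicit_evidence")
  # threshold is configurable
  expect_equal(suggest_label(sparse, natkit:::empty_spans(),
                             sparse_note_threshold = 1)$label, "CN")
})

test_that("suggest_label is deterministic and total over a random cohort", {
  cfg <- cohort_config(n_patients = 40, seed = 77)
  charts <- generate_cohort(cfg)$charts
  m <- compile_lexicon(default_lexicon())
  for (ch in charts) {
    spans <- find_spans_all(segment_notes(ch), m)
    s1 <- suggest_label(ch, spans)
    expect_true(s1$label %in% c("CN", "CI", "undetermined"))
    expect_identical(suggest_label(ch, spans), s1)
  }
})

test_that("annotation store is append-only with latest-record supersession", {
  asg <- assign_patients(c("p1", "p2"), c("a1", "a2"), "shared", seed = 1)
  store <- new_session(asg)
  record_annotation(store, "p1", "a1", "CI", duration_min = 3.5)
  expect_equal(nrow(store$records), 1)
  record_annotation(store, "p1", "a1", "CN", duration_min = 1.2,
                    confidence = "high")
  expect_equal(nrow(store$records), 2)  # both kept
  latest <- latest_annotations(store)
  expect_equal(latest$label[latest$patient_id == "p1" & latest$annotator_id == "a1"], "CN")

  expect_error(record_annotation(store, "p1", "a9", "CI", duration_min = 1),
               "not assigned")
  expect_error(record_annotation(store, "p1", "a1", "maybe", duration_min = 1),
               "unknown label")
  expect_error(record_annotation(store, "p1", "a1", "CI", duration_min = -1),
               "positive")
})

test_that("sessions round-trip through the JSONL file", {
  set.seed(41)
  store <- new_session()
  for (i in 1:100) {
    record_annotation(store, sprintf("p%03d", sample(50, 1)),
                      sample(c("a1", "a2", "a3"), 1),
                      sample(c("CN", "CI", "undetermined"), 1),
                      duration_min = round(runif(1, 0.5, 20), 2),
                      confidence = sample(c(NA, "low", "medium", "moderate", "high"), 1))
  }
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session(store, path)
  back <- read_session(path)
  expect_equal(back$records, store$records)
  expect_equal(latest_annotations(back), latest_annotations(store))
})

test_that("duration is derived from timestamps when not given", {
  store <- new_session()
  record_annotation(store, "p1", "a1", "CI",
                    started_at = "2021-01-01 10:00:00",
                    saved_at = "2021-01-01 10:04:30")
  expect_equal(store$records$duration_min, 4.5)
})

test_that("dashboard rows recompute from their inputs", {
  cfg <- cohort_config(n_patients = 8, seed = 55)
  charts <- generate_cohort(cfg)$charts
  m <- compile_lexicon(default_lexicon())
  clf <- baseline_lexicon_classifier(m)
  res <- lapply(charts, process_chart, matcher = m, model = clf)
  feats <- lapply(res, `[[`, "features")
  ranks <- lapply(res, `[[`, "ranking")
  asg <- assign_patients(names(charts), "ann1", "individual", seed = 2)
  store <- new_session(asg)
  record_annotation(store, names(charts)[1], "ann1", "CI", duration_min = 2)

  rows <- dashboard_summary(asg, charts, feats, ranks, store)
  expect_equal(rows$patient_id, sort(names(charts)))
  expect_equal(rows$label[rows$patient_id == names(charts)[1]], "CI")
  expect_true(all(rows$label[rows$patient_id != names(charts)[1]] == "unlabeled"))
  for (i in seq_len(nrow(rows))) {
    pid <- rows$patient_id[i]
    expect_equal(rows$n_notes[i], nrow(charts[[pid]]$notes))
    expect_equal(rows$cognition_seq_count[i], feats[[pid]]$cognition_seq_count)
    expect_equal(rows$n_notes_ci[i], sum(ranks[[pid]]$class == "CI"))
    age <- floor(as.numeric(charts[[pid]]$period_end -
                              charts[[pid]]$patient$birth_date) / 365.25)
    expect_equal(rows$age[i], age)
  }
})
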