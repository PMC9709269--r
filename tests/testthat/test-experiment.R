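test_that("the reference and compiled engines produce identical runs", {
  corp <- generate_corpus(corpus_config(n_items = 150, seed = 301))
  novel <- generate_novel_items(
    corpus_config(seed = 301), default_verb_table()$lemma,
    attr(corp, "names_used")
  )
  rr <- run_simulation(corp, engine_config(),
    run_seed = 302, novel_items = novel, backend = "r", log_fired = TRUE
  )
  rc <- run_simulation(corp, engine_config(),
    run_seed = 302, novel_items = novel, backend = "cpp", log_fired = TRUE
  )
  expect_identical(rr$trials, rc$trials)
  expect_identical(rr$novel_eval, rc$novel_eval)
  expect_identical(rr$final_store$strengths, rc$final_store$strengths)
})

test_that("runs are exactly reproducible under a seed", {
  corp <- generate_corpus(corpus_config(n_items = 500, seed = 303))
  a <- run_simulation(corp, engine_config(), run_seed = 304, log_fired = TRUE)
  b <- run_simulation(corp, engine_config(), run_seed = 304, log_fired = TRUE)
  expect_identical(a$trials, b$trials)
  expect_identical(a$final_store$strengths, b$final_store$strengths)

  c <- run_simulation(corp, engine_config(), run_seed = 305)
  expect_false(identical(a$trials$predicted_role, c$trials$predicted_role))

  expect_identical(nrow(a$trials), nrow(corp))
  # the presentation order is a permutation of the corpus
  expect_setequal(a$trials$item_id, corp$item_id)
})

test_that("the association store gains mass during early training", {
  corp <- generate_corpus(corpus_config(n_items = 400, seed = 306))
  short <- run_simulation(corp[1:50, ], engine_config(),
    run_seed = 307, permute = FALSE
  )
  long <- run_simulation(corp, engine_config(), run_seed = 307, permute = FALSE)
  m_short <- sum(short$final_store$strengths)
  m_long <- sum(long$final_store$strengths)
  expect_gt(m_short, 0)
  expect_gt(m_long, m_short)
})

test_that("cohorts use distinct derived seeds and pool runs correctly", {
  coh <- run_cohort(
    n_runs = 4, corpus_config(n_items = 300, seed = 308),
    engine_config(),
    master_seed = 309
  )
  expect_length(coh$runs, 4L)
  seeds <- vapply(coh$runs, `[[`, integer(1), "run_seed")
  expect_identical(length(unique(seeds)), 4L)

  trials <- tidy(coh)
  expect_identical(nrow(trials), 4L * 300L)
  expect_setequal(unique(trials$run_id), 1:4)

  g <- glance(coh)
  expect_identical(g$n_runs, 4L)
  expect_true(g$reward_rate > 0 && g$reward_rate < 1)
})

test_that("binned curves average within runs before averaging across runs", {
  coh <- run_cohort(
    n_runs = 3, corpus_config(n_items = 400, seed = 310),
    master_seed = 311
  )
  cv <- bin_proportions(coh, "category", "p_subject_prediction")
  expect_identical(max(cv$bin_index), 4L) # 400 items / bins of 100
  expect_true(all(cv$proportion >= 0 & cv$proportion <= 1, na.rm = TRUE))
  expect_true(all(!cv$empty))

  # oracle: recompute one cell by hand
  trials <- tidy(coh)
  cell <- trials[
    trials$trial_index <= 100 & trials$verb_category == "neutral",
  ]
  by_run <- tapply(cell$predicted_role == "subject", cell$run_id, mean)
  expect_equal(
    cv$proportion[cv$bin_index == 1 & cv$group == "neutral"],
    mean(by_run)
  )

  # per-verb grouping exposes one curve per verb
  cvv <- bin_proportions(coh, "verb", "p_subject_prediction")
  expect_setequal(unique(cvv$group), default_verb_table()$lemma)

  # empty cells are emitted flagged, not dropped
  cve <- bin_proportions(coh, "category", "p_pronoun_given_predicted_object")
  expect_true(all(c("n_trials", "empty") %in% names(cve)))
})

test_that("novel evaluation is frozen and leaves the store untouched", {
  corp <- generate_corpus(corpus_config(n_items = 2000, seed = 312))
  novel <- generate_novel_items(
    corpus_config(seed = 312), default_verb_table()$lemma,
    attr(corp, "names_used")
  )
  run <- run_simulation(corp, engine_config(),
    run_seed = 313, novel_items = novel, n_reps_novel = 20
  )
  expect_identical(nrow(run$novel_eval), 25L * 20L)

  # replaying the novel items against the final store changes nothing
  lex <- build_lexicon(
    c(default_verb_table()$lemma, unique(novel$verb[novel$condition != "novel_name"])),
    c(attr(corp, "names_used"),
      setdiff(c(novel$subject_name, novel$object_name), attr(corp, "names_used")))
  )
  m <- ref_model(lex, engine_config())
  m$store <- run$final_store
  before <- m$store$strengths
  ne <- evaluate_novel(m, novel, n_reps = 5)
  expect_identical(m$store$strengths, before)
  expect_true(m$config$learning_enabled) # restored afterwards
  expect_identical(nrow(ne), 125L)
})

test_that("grand-average curves are stable across master seeds", {
  rates <- vapply(c(314, 315), function(ms) {
    coh <- run_cohort(
      n_runs = 100, corpus_config(n_items = 10000, seed = 316),
      master_seed = ms
    )
    unlist(final_rates(coh, "p_subject_prediction"))
  }, numeric(3))
  expect_true(all(abs(rates[, 1] - rates[, 2]) < 0.02))
})

test_that("report writes curves, novel evaluation, summary and figures", {
  coh <- run_cohort(
    n_runs = 2, corpus_config(n_items = 300, seed = 317),
    master_seed = 318
  )
  out <- withr::local_tempdir()
  paths <- report(coh, out, final_window = 100L)
  expect_true(all(file.exists(paths)))

  curves <- readr::read_csv(
    file.path(out, "curves.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  # one row per (grouping, bin, group, measure)
  expect_identical(
    nrow(curves[curves$group_by == "category", ]),
    3L * 3L * 3L # 3 bins x 3 categories x 3 measures
  )
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(all(c(
    "final_p_subject_prediction",
    "final_p_pronoun_given_predicted_object", "novel"
  ) %in% names(summ)))
  expect_error(report(coh, file.path("/proc/none", "x")), "cannot create")
})
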