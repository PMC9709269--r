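test_that("the lexicon covers all words plus the single pronoun chunk", {
  verbs <- default_verb_table()$lemma
  set.seed(101)
  nms <- generate_names(40, avoid = verbs)
  lex <- build_lexicon(verbs, nms)
  expect_identical(nrow(lex), 51L) # 10 verbs + 40 names + "she"
  expect_identical(sum(lex$pos == "pronoun"), 1L)
  expect_identical(lex$meaning[lex$form == nms[1]], paste0("c-", nms[1]))
  expect_false(anyDuplicated(lex$form) > 0)
  expect_error(build_lexicon("fascinated", c("leah", "leah")), "duplicate")
})

test_that("the operator set matches the model definition", {
  ops <- build_operators()
  expect_identical(length(ops), 14L)
  expect_setequal(names(ops), c(
    "retrieve-V1", "store-V1", "retrieve-V2", "store-V2",
    "retrieve-V3", "store-V3",
    "predict-subj", "predict-obj",
    "predict-subj-name", "predict-obj-name", "predict-pro", "retrieve-pro",
    "correct-re", "correct-ref"
  ))

  ps <- ops[["predict-subj"]]
  expect_identical(
    vapply(ps$conditions, function(p) paste(p$kind, p$src), character(1)),
    c("not_nil WM3", "is_nil WM4", "is_nil WM5")
  )
  expect_identical(ps$actions[[1]]$kind, "copy")
  expect_identical(ps$actions[[1]]$src, "WM1")
  expect_identical(ps$actions[[1]]$dst, "WM5")

  # predict-pro requests a lexical-entry chunk whose third slot is 'pronoun'
  pp <- ops[["predict-pro"]]
  expect_identical(
    vapply(pp$actions, function(p) paste(p$src, "->", p$dst), character(1)),
    c("lexical-entry -> RT1", "pronoun -> RT3")
  )

  cr <- ops[["correct-ref"]]
  expect_identical(
    vapply(cr$conditions, function(p) paste(p$kind, p$src), character(1)),
    c("cmp_ne WM5", "is_nil V3")
  )
  expect_identical(cr$conditions[[1]]$dst, "V2")
  expect_identical(cr$actions[[1]]$src, "V2")
  expect_identical(cr$actions[[1]]$dst, "WM5")
})

test_that("sentence comprehension builds the event representation in order", {
  m <- ref_model(tiny_lexicon())
  set.seed(102)
  state <- comprehend_sentence(m, manual_item())
  expect_identical(
    state$buffers$WM, c("leah", "fascinated", "kathy", "nil", "nil")
  )
  expect_identical(
    state$fired,
    c("retrieve-V1", "store-V1", "retrieve-V2", "store-V2",
      "retrieve-V3", "store-V3")
  )
  # retrieval buffer released for the prediction stage
  expect_identical(state$buffers$RT, rep("nil", 4L))

  expect_error(
    comprehend_sentence(m, tibble::tibble(
      subject_name = "nil", verb = "nil", object_name = "nil",
      continuation_token = NA_character_
    )),
    "no operator eligible"
  )
})

test_that("prediction fills WM5 then WM4 and respects learned strengths", {
  # naive model: subject predictions at chance over many trials
  corp <- generate_corpus(corpus_config(n_items = 10000, seed = 103))
  frozen <- engine_config(learning_enabled = FALSE)
  run <- run_simulation(corp, frozen, run_seed = 104)
  expect_gt(mean(run$trials$predicted_role == "subject"), 0.47)
  expect_lt(mean(run$trials$predicted_role == "subject"), 0.53)
  expect_gt(mean(run$trials$predicted_form == "pronoun"), 0.47)
  expect_lt(mean(run$trials$predicted_form == "pronoun"), 0.53)

  # a strong context-operator association dominates at low noise
  m <- ref_model(tiny_lexicon(), engine_config(noise_sd = 0.05))
  m$store$strengths["fascinated", "predict-subj"] <- 1
  set.seed(105)
  roles <- vapply(seq_len(300), function(i) {
    st <- comprehend_sentence(m, manual_item())
    st <- predict_continuation(m, st, manual_item())
    st$predicted_role
  }, character(1))
  expect_gt(mean(roles == "subject"), 0.99)

  # after a subject prediction, exactly the pronoun and subject-name
  # operators compete for the form
  b <- slot_set(comprehended_buffers(), "WM5", "leah")
  eligible <- names(Filter(
    isTRUE, lapply(build_operators(), eval_conditions, b = b)
  ))
  expect_setequal(eligible, c("predict-subj-name", "predict-pro"))
})

test_that("observation rewards exact matches and otherwise revises WM", {
  # correct referent and form: reward, no revision
  m <- forced_model("subject", "pronoun")
  item <- manual_item(role = "subject", form = "pronoun")
  set.seed(106)
  st <- comprehend_sentence(m, item)
  st <- predict_continuation(m, st, item)
  expect_identical(st$predicted_role, "subject")
  expect_identical(st$predicted_form, "pronoun")
  st <- observe_continuation(m, st, item)
  expect_true(st$rewarded)
  expect_false(any(grepl("correct", st$fired)))

  # wrong form only: correct-re replaces WM4 with the observed token
  m2 <- forced_model("subject", "name")
  st2 <- comprehend_sentence(m2, item)
  st2 <- predict_continuation(m2, st2, item)
  st2 <- observe_continuation(m2, st2, item)
  expect_false(st2$rewarded)
  expect_true("correct-re" %in% st2$fired)
  expect_false("correct-ref" %in% st2$fired)
  expect_identical(st2$buffers$WM[[4]], "she")
  expect_identical(st2$buffers$WM[[5]], "leah")

  # wrong referent and form: both revision operators fire
  item3 <- manual_item(role = "object", form = "name")
  m3 <- forced_model("subject", "pronoun")
  st3 <- comprehend_sentence(m3, item3)
  st3 <- predict_continuation(m3, st3, item3)
  st3 <- observe_continuation(m3, st3, item3)
  expect_false(st3$rewarded)
  expect_true(all(c("correct-re", "correct-ref") %in% st3$fired))
  expect_identical(st3$buffers$WM[[4]], "kathy")
  expect_identical(st3$buffers$WM[[5]], "kathy")
})

test_that("a trial is rewarded iff both referent and form match", {
  corp <- generate_corpus(corpus_config(n_items = 2000, seed = 107))
  run <- run_simulation(corp, engine_config(), run_seed = 108)
  expect_identical(
    run$trials$rewarded,
    run$trials$predicted_role == run$trials$actual_role &
      run$trials$predicted_form == run$trials$actual_form
  )
  # exclusivity: every trial takes exactly one role and one form value
  expect_true(all(run$trials$predicted_role %in% c("subject", "object")))
  expect_true(all(run$trials$predicted_form %in% c("name", "pronoun")))
})

test_that("frozen learning leaves the store untouched across trials", {
  m <- ref_model(tiny_lexicon(), engine_config(learning_enabled = FALSE))
  m$store$strengths["fascinated", "predict-subj"] <- 0.33
  before <- m$store$strengths
  set.seed(109)
  for (i in 1:20) run_trial(m, manual_item())
  expect_identical(m$store$strengths, before)
})

test_that("WM revision leaves the observed continuation in WM4/WM5", {
  corp <- generate_corpus(corpus_config(n_items = 30, seed = 110))
  m <- ref_model(
    build_lexicon(default_verb_table()$lemma, attr(corp, "names_used"))
  )
  set.seed(111)
  for (i in seq_len(nrow(corp))) {
    item <- corp[i, ]
    st <- comprehend_sentence(m, item)
    st <- predict_continuation(m, st, item)
    st <- observe_continuation(m, st, item)
    expect_identical(st$buffers$WM[[4]], item$continuation_token)
    expect_identical(st$buffers$WM[[5]], item$continuation_referent)
  }
})
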