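test_that("condition prims evaluate against buffer contents without mutating them", {
  ops <- build_operators()
  b <- comprehended_buffers()

  expect_true(eval_conditions(ops[["predict-subj"]], b))

  b5 <- slot_set(b, "WM5", "leah")
  expect_false(eval_conditions(ops[["predict-subj"]], b5))

  # two-slot comparison: unequal contents fail
  b2 <- buffer_set()
  b2 <- slot_set(b2, "V1", "leah")
  b2 <- slot_set(b2, "RT2", "kathy")
  expect_false(eval_conditions(ops[["store-V1"]], b2))

  # content comparisons require content: empty slots are neither equal
  # nor unequal to anything
  expect_false(eval_prim(prim("cmp_eq", "WM4", "WM5"), buffer_set()))
  expect_false(eval_prim(prim("cmp_ne", "WM4", "WM5"), buffer_set()))
  b_half <- slot_set(buffer_set(), "WM4", "she")
  expect_false(eval_prim(prim("cmp_ne", "WM4", "WM5"), b_half))

  before <- b
  eval_conditions(ops[["predict-obj"]], b)
  expect_identical(b, before)

  expect_error(slot_get(b, "WM9"), "out of range")
  expect_error(slot_get(b, "XY1"), "malformed")
})

test_that("action prims move symbols, request retrievals and emit signals", {
  ops <- build_operators()
  b <- comprehended_buffers()

  expect_identical(
    execute_actions(ops[["predict-subj"]], b)$buffers$WM[[5]], "leah"
  )
  expect_identical(
    execute_actions(ops[["predict-obj"]], b)$buffers$WM[[5]], "kathy"
  )

  # retrieve-pro copies the pronoun form out of RT and asks for the next input
  b2 <- slot_set(b, "WM5", "leah")
  b2$RT <- c("lexical-entry", "she", "pronoun", "c-she")
  res <- execute_actions(ops[["retrieve-pro"]], b2)
  expect_identical(res$buffers$WM[[4]], "she")
  expect_identical(res$signals, "read-next")
  expect_true(res$consumed_rt)

  # a retrieval request is flagged when RT slots are written
  res2 <- execute_actions(ops[["predict-pro"]], slot_set(b, "WM5", "leah"))
  expect_true(res2$retrieval_request)
  expect_identical(res2$buffers$RT[[1]], "lexical-entry")
  expect_identical(res2$buffers$RT[[3]], "pronoun")

  # copying from an empty slot is an operator-design bug
  expect_error(
    execute_actions(operator("bad", list(), list(prim("copy", "WM4", "WM5"))), b),
    "empty slot"
  )
})

test_that("declarative retrieval is deterministic and must be unambiguous", {
  lex <- tiny_lexicon()

  hit <- retrieve_chunk(list(form = "leah"), lex)
  expect_identical(hit$pos, "noun")
  expect_identical(hit$meaning, "c-leah")

  expect_identical(retrieve_chunk(list(pos = "pronoun"), lex)$form, "she")

  expect_error(retrieve_chunk(list(form = "zzz"), lex), "retrieval failure")
  expect_error(retrieve_chunk(list(pos = "noun"), lex), "ambiguous")
  expect_error(retrieve_chunk(list(form = "nil"), lex), "constrains no field")
})

test_that("activation sums context-operator strengths over WM1-WM3 only", {
  st <- association_store(c("leah", "fascinated", "kathy"))
  expect_identical(
    operator_activation("predict-subj", c("leah", "fascinated", "kathy"), st), 0
  )

  st$strengths["fascinated", "predict-subj"] <- 0.4
  st$strengths["leah", "predict-subj"] <- 0.1
  expect_equal(
    operator_activation("predict-subj", c("leah", "fascinated", "kathy"), st), 0.5
  )

  # a value sitting in WM5 is not part of the context
  b <- comprehended_buffers()
  b <- slot_set(b, "WM5", "zuzu")
  st$strengths <- rbind(
    st$strengths,
    zuzu = stats::setNames(rep(0, ncol(st$strengths)), colnames(st$strengths))
  )
  st$strengths["zuzu", "predict-subj"] <- 0.9
  expect_false("zuzu" %in% wm_context(b))
  expect_equal(
    operator_activation("predict-subj", wm_context(b), st), 0.5
  )
})

test_that("selection is at chance between condition-equivalent competitors", {
  ops <- build_operators()[c("predict-subj", "predict-obj")]
  st <- association_store(c("leah", "fascinated", "kathy"))
  cfg <- engine_config()
  b <- comprehended_buffers()
  set.seed(401)
  picks <- vapply(
    seq_len(10000),
    function(i) select_operator(ops, b, st, cfg)$name,
    character(1)
  )
  expect_gt(mean(picks == "predict-subj"), 0.47)
  expect_lt(mean(picks == "predict-subj"), 0.53)
})

test_that("selection probability increases weakly with context strength", {
  ops <- build_operators()[c("predict-subj", "predict-obj")]
  cfg <- engine_config()
  b <- comprehended_buffers()
  rates <- vapply(c(0, 0.3, 0.6, 0.9), function(s) {
    st <- association_store(c("leah", "fascinated", "kathy"))
    st$strengths["fascinated", "predict-subj"] <- s
    set.seed(402)
    mean(vapply(
      seq_len(4000),
      function(i) select_operator(ops, b, st, cfg)$name,
      character(1)
    ) == "predict-subj")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_gt(rates[4], 0.85)
})

test_that("condition gating skips the highest-activation operator", {
  # predict-obj-name can carry the most activation yet lose to the
  # eligible competitor when the subject was predicted
  ops <- build_operators()[c("predict-obj-name", "predict-pro")]
  st <- association_store(c("leah", "fascinated", "kathy"))
  st$strengths["fascinated", "predict-obj-name"] <- 1
  cfg <- engine_config(noise_sd = 0.05)
  b <- slot_set(comprehended_buffers(), "WM5", "leah") # subject predicted
  set.seed(403)
  picks <- vapply(
    seq_len(200),
    function(i) select_operator(ops, b, st, cfg)$name,
    character(1)
  )
  expect_true(all(picks == "predict-pro"))

  # and selection fails cleanly when nothing is eligible
  expect_null(select_operator(build_operators(), buffer_set(), st, cfg))
})

test_that("learning updates only fired pairs and keeps strengths in [0, R]", {
  cfg <- engine_config(alpha = 0.2, reward = 1)
  st <- association_store("fascinated")

  apply_reward("predict-subj", "fascinated", st, cfg)
  expect_equal(assoc_strength(st, "fascinated", "predict-subj"), 0.2)

  # the reward magnitude is a fixed point
  st$strengths["fascinated", "predict-subj"] <- 1
  apply_reward("predict-subj", "fascinated", st, cfg)
  expect_equal(assoc_strength(st, "fascinated", "predict-subj"), 1)

  # operators that did not fire remain unchanged
  expect_equal(assoc_strength(st, "fascinated", "predict-obj"), 0)

  # extinction moves fired pairs toward zero and never below it
  apply_extinction("predict-subj", "fascinated", st, cfg)
  expect_equal(assoc_strength(st, "fascinated", "predict-subj"), 0.8)

  # boundedness under arbitrary reward/extinction sequences
  set.seed(404)
  st2 <- association_store(c("a", "b", "c"))
  ops <- names(build_operators())
  for (i in seq_len(500)) {
    fired <- sample(ops, sample(1:4, 1))
    ctx <- sample(c("a", "b", "c"), sample(1:3, 1))
    if (runif(1) < 0.5) {
      apply_reward(fired, ctx, st2, cfg)
    } else {
      apply_extinction(fired, ctx, st2, cfg)
    }
    expect_true(all(st2$strengths >= 0 & st2$strengths <= cfg$reward))
  }

  # frozen learning leaves the store bit-identical
  frozen <- engine_config(learning_enabled = FALSE)
  before <- st2$strengths
  apply_reward(ops, c("a", "b"), st2, frozen)
  apply_extinction(ops, c("a", "b"), st2, frozen)
  expect_identical(st2$strengths, before)
})

test_that("association stores serialize losslessly to JSON", {
  set.seed(405)
  st <- association_store(c("leah", "fascinated", "kathy"))
  st$strengths[] <- runif(length(st$strengths))
  path <- withr::local_tempfile(fileext = ".json")
  write_store(st, path)
  st2 <- read_store(path)
  expect_identical(st2$strengths, st$strengths)
})
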