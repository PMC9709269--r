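# Small fixtures shared across test files; everything is generated in code.

tiny_lexicon <- function() {
  build_lexicon("fascinated", c("leah", "kathy"))
}

# buffers holding the comprehended sentence "Leah fascinated Kathy"
comprehended_buffers <- function() {
  b <- buffer_set()
  b$WM <- c("leah", "fascinated", "kathy", "nil", "nil")
  b
}

# a one-row item without relying on the corpus generator
manual_item <- function(subject = "leah", verb = "fascinated",
                        object = "kathy", role = "subject",
                        form = "pronoun") {
  referent <- if (role == "subject") subject else object
  tibble::tibble(
    item_id = 1L,
    subject_name = subject, verb = verb, verb_category = "subject_biased",
    object_name = object,
    continuation_role = role, continuation_form = form,
    continuation_token = if (form == "pronoun") "she" else referent,
    continuation_referent = referent
  )
}

# a model whose predictions are forced through associations + zero noise
forced_model <- function(predict = c("subject", "object"),
                         form = c("pronoun", "name")) {
  predict <- match.arg(predict)
  form <- match.arg(form)
  m <- ref_model(tiny_lexicon(), engine_config(noise_sd = 0))
  ref_op <- if (predict == "subject") "predict-subj" else "predict-obj"
  form_op <- if (form == "pronoun") {
    "predict-pro"
  } else if (predict == "subject") {
    "predict-subj-name"
  } else {
    "predict-obj-name"
  }
  m$store$strengths["fascinated", ref_op] <- 1
  m$store$strengths["fascinated", form_op] <- 1
  m
}

# the default-condition cohort used by the acceptance checks, computed once
acceptance_env <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(acceptance_env$cohort)) {
    acceptance_env$cohort <- run_cohort(
      n_runs = 100,
      corpus_cfg = corpus_config(n_items = 10000, seed = 20260920),
      model_cfg = engine_config(),
      master_seed = 20260920
    )
  }
  acceptance_env$cohort
}

last_bin_rates <- function(cohort, measure) {
  cv <- bin_proportions(cohort, "category", measure)
  last <- cv[cv$bin_index == max(cv$bin_index), ]
  stats::setNames(last$proportion, last$group)
}

first_bin_rates <- function(cohort, measure) {
  cv <- bin_proportions(cohort, "category", measure)
  first <- cv[cv$bin_index == 1, ]
  stats::setNames(first$proportion, first$group)
}
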