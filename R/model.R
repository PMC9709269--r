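#' Create a reference learning model
#'
#' Bundles a lexicon, the fixed operator set, an engine configuration and
#' an (initially all-zero) association store into one model object. The
#' model starts without any prediction biases; everything it ever learns
#' is stored in the association store.
#'
#' @param lexicon A lexicon tibble from [build_lexicon()].
#' @param config An [engine_config()].
#' @return An environment of class `ref_model` with fields `lexicon`,
#'   `operators`, `config` and `store`.
#' @examples
#' m <- ref_model(build_lexicon("fascinated", c("leah", "kathy")))
#' m
#' @export
ref_model <- function(lexicon, config = engine_config()) {
  stopifnot(is.data.frame(lexicon), inherits(config, "engine_config"))
  if (sum(lexicon$pos == "pronoun") != 1) {
    stop("the lexicon must contain exactly one pronoun chunk", call. = FALSE)
  }
  m <- new.env(parent = emptyenv())
  m$lexicon <- lexicon
  m$operators <- build_operators()
  m$config <- config
  m$store <- association_store(
    symbols = lexicon$form[lexicon$pos != "pronoun"],
    operators = m$operators
  )
  class(m) <- "ref_model"
  m
}

#' @export
print.ref_model <- function(x, ...) {
  cat(sprintf(
    "ref_model: %d chunks, %d operators, %d non-zero associations\n",
    nrow(x$lexicon), length(x$operators), sum(x$store$strengths != 0)
  ))
  print(x$config)
  invisible(x)
}

#' @describeIn ref_model Learned associations as a tibble (via the store).
#' @param x A `ref_model`.
#' @param ... Unused.
#' @export
tidy.ref_model <- function(x, ...) {
  tidy(x$store)
}

#' @describeIn ref_model One-row model summary.
#' @export
glance.ref_model <- function(x, ...) {
  tibble(
    n_chunks = nrow(x$lexicon),
    n_operators = length(x$operators),
    n_associations = sum(x$store$strengths != 0),
    total_strength = sum(x$store$strengths),
    alpha = x$config$alpha,
    reward = x$config$reward,
    noise_sd = x$config$noise_sd,
    learning_enabled = x$config$learning_enabled
  )
}

new_trial_state <- function(item) {
  b <- buffer_set()
  b$V <- c(item$subject_name, item$verb, item$object_name)
  list(
    buffers = b,
    fired = character(),
    predicted_role = NA_character_,
    predicted_form = NA_character_,
    rewarded = NA,
    observed = FALSE,
    done = FALSE
  )
}

# One selection-fire-bookkeep step of the trial loop. Returns the state;
# state$done is set when no operator was eligible or when an
# evaluation-only item (no continuation) has been predicted.
step_trial <- function(model, state, item) {
  op <- select_operator(model$operators, state$buffers, model$store, model$config)
  if (is.null(op)) {
    state$done <- TRUE
    return(state)
  }
  res <- execute_actions(op, state$buffers)
  state$buffers <- res$buffers
  state$fired <- c(state$fired, op$name)

  if (res$retrieval_request) {
    b <- state$buffers
    chunk <- retrieve_chunk(
      list(
        chunk_type = b$RT[[1]], form = b$RT[[2]],
        pos = b$RT[[3]], meaning = b$RT[[4]]
      ),
      model$lexicon
    )
    state$buffers$RT <- c(chunk$chunk_type, chunk$form, chunk$pos, chunk$meaning)
  }
  if (res$consumed_rt) {
    state$buffers$RT <- rep("nil", 4L)
  }
  if ("read-next" %in% res$signals) {
    b <- state$buffers
    state$predicted_role <- if (identical(b$WM[[5]], b$WM[[1]])) "subject" else "object"
    pron <- model$lexicon$form[model$lexicon$pos == "pronoun"]
    state$predicted_form <- if (identical(b$WM[[4]], pron)) "pronoun" else "name"
    if (is.na(item$continuation_token)) {
      # evaluation-only item: prediction is the outcome; nothing to observe
      state$done <- TRUE
    } else {
      state$buffers$V <- c(item$continuation_token, item$continuation_referent, "nil")
      state$buffers$AC <- "nil"
      state$observed <- TRUE
      state$rewarded <- identical(state$buffers$WM[[4]], item$continuation_token) &&
        identical(state$buffers$WM[[5]], item$continuation_referent)
    }
  }
  state
}

#' Process the transitive sentence of one input item
#'
#' Runs the comprehension stage: the six retrieve/store operators fire in
#' alternation until the sentence occupies WM1-WM3 (subject, verb,
#' object).
#'
#' @param model A [ref_model()].
#' @param item One input item (a one-row data frame or list with at least
#'   `subject_name`, `verb`, `object_name`).
#' @return A trial state list; `$buffers` holds the resulting buffer set
#'   and `$fired` the operators fired so far.
#' @export
comprehend_sentence <- function(model, item) {
  state <- new_trial_state(item)
  while (!state$done && state$buffers$WM[[3]] == "nil") {
    state <- step_trial(model, state, item)
  }
  if (state$buffers$WM[[3]] == "nil") {
    stop("sentence comprehension stalled: no operator eligible", call. = FALSE)
  }
  state
}

#' Predict the next referent and its form
#'
#' Runs the prediction stage on a comprehended state: one referent operator
#' (`predict-subj` / `predict-obj`) fires and fills WM5, then one form
#' path (`predict-subj-name`, `predict-obj-name`, or `predict-pro` +
#' `retrieve-pro`) fills WM4 and emits `read-next`.
#'
#' @param model A [ref_model()].
#' @param state A trial state from [comprehend_sentence()].
#' @param item The input item being processed.
#' @return The updated state, with `$predicted_role` (`"subject"` /
#'   `"object"`) and `$predicted_form` (`"name"` / `"pronoun"`) set.
#' @export
predict_continuation <- function(model, state, item) {
  while (!state$done && is.na(state$predicted_role)) {
    state <- step_trial(model, state, item)
  }
  state
}

#' Observe the continuation: reward or revise
#'
#' After `read-next`, the actual continuation sits in the input buffer
#' (V1 = surface form, V2 = referent). If both predictions match, the
#' trial is rewarded and every (context symbol, fired operator) strength
#' moves toward the reward; otherwise no reward is issued, the same
#' strengths move toward zero, and the applicable revision operators fire,
#' leaving WM4/WM5 aligned with the observed continuation.
#'
#' @param model A [ref_model()].
#' @param state A trial state from [predict_continuation()].
#' @param item The input item being processed.
#' @return The completed state, with `$rewarded` set.
#' @export
observe_continuation <- function(model, state, item) {
  while (!state$done) {
    state <- step_trial(model, state, item)
  }
  if (isTRUE(state$observed)) {
    context <- wm_context(state$buffers)
    if (isTRUE(state$rewarded)) {
      apply_reward(state$fired, context, model$store, model$config)
    } else {
      apply_extinction(state$fired, context, model$store, model$config)
    }
  }
  state
}

#' Run one trial
#'
#' Full comprehend -> predict -> observe cycle for one input item. For
#' evaluation-only items (no continuation) the trial ends after the
#' prediction and no learning occurs.
#'
#' @param model A [ref_model()]; its store is updated in place when
#'   learning is enabled.
#' @param item One input item (a one-row tibble from [generate_corpus()]
#'   or [generate_novel_items()]).
#' @param trial_index Optional position of the trial within its run.
#' @return A one-row tibble: `item_id`, `trial_index`, `verb`,
#'   `verb_category`, `predicted_role`, `predicted_form`, `actual_role`,
#'   `actual_form`, `rewarded`, `fired_ops` (the fired operator names,
#'   `";"`-separated, in order).
#' @examples
#' corp <- generate_corpus(corpus_config(n_items = 5, seed = 1))
#' m <- ref_model(build_lexicon(default_verb_table()$lemma,
#'                              attr(corp, "names_used")))
#' set.seed(1)
#' run_trial(m, corp[1, ])
#' @export
run_trial <- function(model, item, trial_index = NA_integer_) {
  item <- as.list(item)
  if (is.null(item$continuation_token)) item$continuation_token <- NA_character_
  state <- comprehend_sentence(model, item)
  state <- predict_continuation(model, state, item)
  state <- observe_continuation(model, state, item)
  tibble(
    item_id = as.integer(item$item_id %||% NA_integer_),
    trial_index = as.integer(trial_index),
    verb = item$verb,
    verb_category = item$verb_category %||% NA_character_,
    predicted_role = state$predicted_role,
    predicted_form = state$predicted_form,
    actual_role = item$continuation_role %||% NA_character_,
    actual_form = item$continuation_form %||% NA_character_,
    rewarded = state$rewarded,
    fired_ops = paste(state$fired, collapse = ";")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
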