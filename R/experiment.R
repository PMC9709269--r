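# ---- backend bridge -------------------------------------------------------

SLOT_INDEX <- c(
  V1 = 0L, V2 = 1L, V3 = 2L,
  WM1 = 3L, WM2 = 4L, WM3 = 5L, WM4 = 6L, WM5 = 7L,
  RT1 = 8L, RT2 = 9L, RT3 = 10L, RT4 = 11L, AC1 = 12L
)

PRIM_CODE <- c(
  cmp_eq = 1L, cmp_ne = 2L, is_nil = 3L, not_nil = 4L,
  copy = 5L, set_const = 6L, ext_action = 7L
)

# integer encoding of the operator set for the compiled backend; symtab
# maps symbol -> id (nil = 0)
encode_operators <- function(operators, symtab) {
  sym_id <- function(s) {
    i <- match(s, symtab)
    if (is.na(i)) stop("symbol not in symbol table: ", s, call. = FALSE)
    i
  }
  enc_prim <- function(p) {
    kind <- PRIM_CODE[[p$kind]]
    a <- b <- 0L
    if (p$kind %in% c("cmp_eq", "cmp_ne")) {
      a <- SLOT_INDEX[[p$src]]
      b <- SLOT_INDEX[[p$dst]]
    } else if (p$kind %in% c("is_nil", "not_nil")) {
      a <- SLOT_INDEX[[p$src]]
    } else if (p$kind == "copy") {
      a <- SLOT_INDEX[[p$src]]
      b <- SLOT_INDEX[[p$dst]]
    } else if (p$kind == "set_const") {
      a <- sym_id(p$src)
      b <- SLOT_INDEX[[p$dst]]
    } else if (p$kind == "ext_action") {
      a <- sym_id(p$src)
    }
    c(kind, a, b)
  }
  enc_block <- function(prims) {
    m <- t(vapply(prims, enc_prim, integer(3)))
    storage.mode(m) <- "integer"
    m
  }
  list(
    cond = lapply(operators, function(o) enc_block(o$conditions)),
    act = lapply(operators, function(o) enc_block(o$actions))
  )
}

# symbol table: forms first (their ids index the strength-matrix rows),
# then the structural constants the operators mention
build_symtab <- function(lexicon) {
  c(
    lexicon$form,
    "lexical-entry", "noun", "verb", "pronoun", "read-next",
    lexicon$meaning
  )
}

encode_lexicon <- function(lexicon, symtab) {
  m <- cbind(
    match(lexicon$chunk_type, symtab),
    match(lexicon$form, symtab),
    match(lexicon$pos, symtab),
    match(lexicon$meaning, symtab)
  )
  storage.mode(m) <- "integer"
  m
}

encode_items <- function(items, symtab) {
  tok <- match(items$continuation_token, symtab)
  ref <- match(items$continuation_referent, symtab)
  tok[is.na(items$continuation_token)] <- 0L
  ref[is.na(items$continuation_referent)] <- 0L
  m <- cbind(
    match(items$subject_name, symtab),
    match(items$verb, symtab),
    match(items$object_name, symtab),
    tok, ref
  )
  if (anyNA(m)) stop("item token not covered by the lexicon", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

run_items_backend <- function(model, items, order, backend, log_fired = FALSE) {
  if (backend == "cpp") {
    symtab <- build_symtab(model$lexicon)
    enc <- encode_operators(model$operators, symtab)
    lex <- encode_lexicon(model$lexicon, symtab)
    # strength matrix over the full symbol table, seeded from the store
    S <- matrix(0, nrow = length(symtab), ncol = length(model$operators))
    have <- intersect(rownames(model$store$strengths), symtab)
    if (length(have)) {
      S[match(have, symtab), ] <- model$store$strengths[have, , drop = FALSE]
    }
    pron <- match(model$lexicon$form[model$lexicon$pos == "pronoun"], symtab)
    res <- run_items_cpp(
      encode_items(items, symtab), as.integer(order),
      enc$cond, enc$act, lex, pron, S,
      model$config$alpha, model$config$reward,
      logistic_scale(model$config$noise_sd),
      model$config$learning_enabled, log_fired
    )
    if (model$config$learning_enabled) {
      forms <- model$lexicon$form[model$lexicon$pos != "pronoun"]
      st <- association_store(forms, model$operators)
      st$strengths[] <- res$strengths[match(forms, symtab), ]
      model$store <- st
    }
    rec <- res$records
    fired_ops <- NA_character_
    if (log_fired) {
      op_names <- names(model$operators)
      ends <- cumsum(rec[, 5])
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      fired_ops <- vapply(
        seq_along(ends),
        function(i) paste(op_names[res$fired[starts[i]:ends[i]]], collapse = ";"),
        character(1)
      )
    }
    tibble(
      trial_index = seq_along(order),
      item_row = rec[, 1],
      predicted_role = c("subject", "object")[rec[, 2]],
      predicted_form = c("name", "pronoun")[rec[, 3]],
      rewarded = ifelse(rec[, 4] < 0, NA, rec[, 4] == 1),
      fired_ops = fired_ops
    )
  } else {
    recs <- vector("list", length(order))
    for (i in seq_along(order)) {
      row <- run_trial(model, items[order[[i]], ], trial_index = i)
      row$item_row <- order[[i]]
      recs[[i]] <- row
    }
    out <- dplyr::bind_rows(recs)
    out[, c(
      "trial_index", "item_row", "predicted_role", "predicted_form",
      "rewarded", "fired_ops"
    )]
  }
}

# ---- single run -----------------------------------------------------------

#' Run one simulated learner over a corpus
#'
#' A fresh model (all-zero association store) is trained on the corpus in
#' a randomized order, logging every trial; afterwards, if novel items are
#' supplied, learning is frozen and each novel item is presented
#' `n_reps_novel` times for prediction only.
#'
#' @param corpus A corpus tibble from [generate_corpus()].
#' @param model_cfg An [engine_config()] (its `learning_enabled` applies
#'   to the training phase).
#' @param run_seed Integer seed for this run (permutation, selection noise).
#' @param novel_items Optional tibble from [generate_novel_items()].
#' @param n_reps_novel Presentations of each novel item.
#' @param permute Randomize presentation order (`TRUE` for training).
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference engine);
#'   both produce identical results under the same seed.
#' @param log_fired Record the fired-operator sequence per trial.
#' @return A `ref_run` object: list with `run_seed`, `trials` (one row per
#'   training trial), `novel_eval` (one row per novel presentation),
#'   `final_store` (the trained [association_store()]) and `config`.
#' @examples
#' corp <- generate_corpus(corpus_config(n_items = 200, seed = 1))
#' run <- run_simulation(corp, engine_config(), run_seed = 42)
#' mean(run$trials$rewarded)
#' @export
run_simulation <- function(corpus, model_cfg = engine_config(), run_seed = 1L,
                           novel_items = NULL, n_reps_novel = 1L,
                           permute = TRUE, backend = c("cpp", "r"),
                           log_fired = FALSE) {
  backend <- match.arg(backend)
  vt <- attr(corpus, "verb_table")
  verbs <- if (is.null(vt)) unique(corpus$verb) else vt$lemma
  names_used <- attr(corpus, "names_used")
  if (is.null(names_used)) {
    names_used <- unique(c(corpus$subject_name, corpus$object_name))
  }
  novel_tokens <- character()
  if (!is.null(novel_items)) {
    novel_tokens <- setdiff(
      unique(c(novel_items$verb, novel_items$subject_name, novel_items$object_name)),
      c(verbs, names_used)
    )
    novel_verbs <- intersect(novel_tokens, unique(novel_items$verb))
  } else {
    novel_verbs <- character()
  }
  lex <- build_lexicon(
    c(verbs, novel_verbs),
    c(names_used, setdiff(novel_tokens, novel_verbs))
  )
  model <- ref_model(lex, model_cfg)

  set.seed(run_seed)
  order <- if (permute) sample.int(nrow(corpus)) else seq_len(nrow(corpus))
  trials <- run_items_backend(model, corpus, order, backend, log_fired)
  trials <- dplyr::mutate(
    trials,
    item_id = corpus$item_id[.data$item_row],
    verb = corpus$verb[.data$item_row],
    verb_category = corpus$verb_category[.data$item_row],
    actual_role = corpus$continuation_role[.data$item_row],
    actual_form = corpus$continuation_form[.data$item_row],
    item_row = NULL
  )

  novel_eval <- NULL
  if (!is.null(novel_items)) {
    frozen <- model$config
    frozen$learning_enabled <- FALSE
    model$config <- frozen
    ne_order <- rep(seq_len(nrow(novel_items)), times = n_reps_novel)
    ne <- run_items_backend(model, novel_items, ne_order, backend, log_fired)
    novel_eval <- dplyr::mutate(
      ne,
      item_id = novel_items$item_id[.data$item_row],
      condition = novel_items$condition[.data$item_row],
      verb = novel_items$verb[.data$item_row],
      verb_category = novel_items$verb_category[.data$item_row],
      item_row = NULL, rewarded = NULL
    )
  }

  structure(
    list(
      run_seed = run_seed, trials = trials, novel_eval = novel_eval,
      final_store = model$store, config = model_cfg
    ),
    class = "ref_run"
  )
}

#' @export
print.ref_run <- function(x, ...) {
  cat(sprintf(
    "ref_run: %d trials (%.1f%% rewarded), %s novel presentations, seed=%d\n",
    nrow(x$trials), 100 * mean(x$trials$rewarded, na.rm = TRUE),
    if (is.null(x$novel_eval)) "no" else nrow(x$novel_eval), x$run_seed
  ))
  invisible(x)
}

#' Evaluate novel items with frozen learning
#'
#' Presents each novel sentence to an already-trained model with the
#' learning mechanism switched off, so every item stays equally novel; the
#' model only predicts (there is no continuation, hence no reward and no
#' revision). The association store is untouched.
#'
#' @param model A trained [ref_model()].
#' @param novel_items A tibble from [generate_novel_items()].
#' @param n_reps Presentations of each item.
#' @param backend `"cpp"` or `"r"`.
#' @return A tibble with one row per presentation: `condition`, `verb`,
#'   `verb_category`, `predicted_role`, `predicted_form`.
#' @export
evaluate_novel <- function(model, novel_items, n_reps = 1L,
                           backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  saved <- model$config
  on.exit(model$config <- saved)
  frozen <- saved
  frozen$learning_enabled <- FALSE
  model$config <- frozen
  ord <- rep(seq_len(nrow(novel_items)), times = n_reps)
  out <- run_items_backend(model, novel_items, ord, backend)
  dplyr::mutate(
    out,
    condition = novel_items$condition[.data$item_row],
    verb = novel_items$verb[.data$item_row],
    verb_category = novel_items$verb_category[.data$item_row],
    item_row = NULL, rewarded = NULL, fired_ops = NULL
  )
}

# ---- cohort ---------------------------------------------------------------

#' Run a cohort of simulated learners
#'
#' Each run is an independent model ("one simulated participant") trained
#' on the same corpus in its own randomized order, then evaluated on the
#' shared novel items with learning frozen. Setting
#' `fresh_corpus_per_run = TRUE` regenerates the corpus for every run
#' instead.
#'
#' @param n_runs Number of independent runs.
#' @param corpus_cfg A [corpus_config()].
#' @param model_cfg An [engine_config()].
#' @param master_seed Integer seed from which all per-run seeds derive.
#' @param fresh_corpus_per_run Regenerate the corpus each run.
#' @param n_reps_novel Presentations of each novel item per run.
#' @param backend `"cpp"` or `"r"`.
#' @param progress Print per-run progress to stderr.
#' @return A `ref_cohort` object: list with `runs` (list of `ref_run`),
#'   `corpus`, `novel_items`, `corpus_cfg`, `model_cfg`, `master_seed`.
#' @examples
#' coh <- run_cohort(2, corpus_config(n_items = 200, seed = 1),
#'   engine_config(),
#'   master_seed = 7
#' )
#' glance(coh)
#' @export
run_cohort <- function(n_runs = 100L, corpus_cfg = corpus_config(),
                       model_cfg = engine_config(), master_seed = 1L,
                       fresh_corpus_per_run = FALSE, n_reps_novel = 1L,
                       backend = c("cpp", "r"), progress = FALSE) {
  stopifnot(n_runs >= 1)
  backend <- match.arg(backend)
  corpus <- generate_corpus(corpus_cfg)
  set.seed(master_seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  corpus_seeds <- sample.int(.Machine$integer.max, n_runs)
  novel_items <- generate_novel_items(
    corpus_cfg,
    trained_verbs = corpus_cfg$verb_table$lemma,
    trained_names = attr(corpus, "names_used")
  )
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    corp_i <- corpus
    if (fresh_corpus_per_run) {
      cfg_i <- corpus_cfg
      cfg_i$seed <- corpus_seeds[[i]]
      corp_i <- generate_corpus(cfg_i)
    }
    runs[[i]] <- run_simulation(
      corp_i, model_cfg,
      run_seed = run_seeds[[i]],
      novel_items = novel_items, n_reps_novel = n_reps_novel,
      backend = backend
    )
    runs[[i]]$run_id <- i
    if (progress) {
      message(sprintf("run %d/%d done", i, n_runs))
    }
  }
  structure(
    list(
      runs = runs, corpus = corpus, novel_items = novel_items,
      corpus_cfg = corpus_cfg, model_cfg = model_cfg,
      master_seed = master_seed
    ),
    class = "ref_cohort"
  )
}

#' @export
print.ref_cohort <- function(x, ...) {
  cat(sprintf(
    "ref_cohort: %d runs x %d trials, master_seed=%d\n",
    length(x$runs), nrow(x$runs[[1]]$trials), x$master_seed
  ))
  invisible(x)
}

#' @describeIn run_cohort All training trials of a cohort as one tibble
#'   (with `run_id`).
#' @param x A `ref_cohort`.
#' @param ... Unused.
#' @export
tidy.ref_cohort <- function(x, ...) {
  dplyr::bind_rows(lapply(x$runs, function(r) {
    dplyr::mutate(r$trials, run_id = r$run_id, .before = 1)
  }))
}

#' @describeIn run_cohort One-row cohort summary (reward rate, final-bin
#'   subject-prediction rates per verb category).
#' @export
glance.ref_cohort <- function(x, ...) {
  trials <- tidy(x)
  n_items <- nrow(x$runs[[1]]$trials)
  final <- dplyr::filter(trials, .data$trial_index > n_items - 2000L)
  fin <- final |>
    dplyr::group_by(.data$verb_category) |>
    dplyr::summarise(
      p = mean(.data$predicted_role == "subject"), .groups = "drop"
    )
  tibble(
    n_runs = length(x$runs),
    n_items = n_items,
    reward_rate = mean(trials$rewarded),
    final_p_subject_subject_biased =
      fin$p[fin$verb_category == "subject_biased"],
    final_p_subject_neutral = fin$p[fin$verb_category == "neutral"],
    final_p_subject_object_biased =
      fin$p[fin$verb_category == "object_biased"]
  )
}

# pooled novel-eval rows across runs
cohort_novel <- function(cohort) {
  dplyr::bind_rows(lapply(cohort$runs, function(r) {
    dplyr::mutate(r$novel_eval, run_id = r$run_id, .before = 1)
  }))
}

# ---- aggregation ----------------------------------------------------------

#' Binned grand-average learning curves
#'
#' Training trials are cut into consecutive bins of `bin_size`
#' presentations. Within each run the proportion is computed per bin and
#' group, then averaged over runs (each run simulates one participant).
#' Three measures are supported: the proportion of subject-referent
#' predictions, and the proportion of pronoun form predictions among
#' predicted-subject and among predicted-object trials.
#'
#' @param cohort A `ref_cohort` from [run_cohort()].
#' @param group_by Group curves by verb `"category"` or by `"verb"`.
#' @param measure One of `"p_subject_prediction"`,
#'   `"p_pronoun_given_predicted_subject"`,
#'   `"p_pronoun_given_predicted_object"`, or `"all"` (default) for all
#'   three.
#' @param bin_size Presentations per bin.
#' @return A tibble of class `refbias_curves`: `bin_index`, `group`,
#'   `measure`, `proportion` (grand average; `NaN` when no run has trials
#'   in the cell), `n_trials` (pooled count), `empty` flag.
#' @examples
#' coh <- run_cohort(2, corpus_config(n_items = 400, seed = 1), master_seed = 7)
#' bin_proportions(coh, bin_size = 100)
#' @export
bin_proportions <- function(cohort, group_by = c("category", "verb"),
                            measure = "all", bin_size = 100L) {
  group_by <- match.arg(group_by)
  measures <- c(
    "p_subject_prediction",
    "p_pronoun_given_predicted_subject",
    "p_pronoun_given_predicted_object"
  )
  measure <- if (identical(measure, "all")) measures else match.arg(measure, measures)
  trials <- tidy(cohort)
  trials$group <- if (group_by == "category") trials$verb_category else trials$verb
  trials$bin_index <- (trials$trial_index - 1L) %/% as.integer(bin_size) + 1L

  one_measure <- function(m) {
    sub <- switch(m,
      p_subject_prediction = trials,
      p_pronoun_given_predicted_subject =
        dplyr::filter(trials, .data$predicted_role == "subject"),
      p_pronoun_given_predicted_object =
        dplyr::filter(trials, .data$predicted_role == "object")
    )
    value <- if (m == "p_subject_prediction") {
      sub$predicted_role == "subject"
    } else {
      sub$predicted_form == "pronoun"
    }
    sub$value <- value
    per_run <- sub |>
      dplyr::group_by(.data$bin_index, .data$group, .data$run_id) |>
      dplyr::summarise(
        p = mean(.data$value), n = dplyr::n(), .groups = "drop"
      )
    per_run |>
      dplyr::group_by(.data$bin_index, .data$group) |>
      dplyr::summarise(
        proportion = mean(.data$p), n_trials = sum(.data$n),
        .groups = "drop"
      ) |>
      dplyr::mutate(measure = m, .before = "proportion")
  }
  out <- dplyr::bind_rows(lapply(measure, one_measure))
  # fill cells with no trials in any run
  grid <- tidyr::expand_grid(
    bin_index = sort(unique(trials$bin_index)),
    group = sort(unique(trials$group)),
    measure = measure
  )
  out <- dplyr::left_join(grid, out, by = c("bin_index", "group", "measure")) |>
    dplyr::mutate(
      n_trials = dplyr::coalesce(.data$n_trials, 0L),
      empty = .data$n_trials == 0L
    )
  class(out) <- c("refbias_curves", class(out))
  out
}

#' Novel-item prediction summary
#'
#' Pools the frozen-learning novel-item predictions of a cohort and
#' summarizes, per novelty condition (splitting the familiar-verb
#' condition by verb category), the proportion of subject-referent
#' predictions and the pronoun proportion among predicted-subject and
#' predicted-object presentations.
#'
#' @param cohort A `ref_cohort` from [run_cohort()].
#' @return A tibble of class `refbias_novel`: `condition`, `measure`,
#'   `proportion`, `n`.
#' @export
novel_summary <- function(cohort) {
  ne <- cohort_novel(cohort)
  ne$condition_full <- ifelse(
    ne$condition == "novel_name",
    paste0("novel_name:", ne$verb_category),
    ne$condition
  )
  p_subj <- ne |>
    dplyr::group_by(condition = .data$condition_full) |>
    dplyr::summarise(
      measure = "p_subject_prediction",
      proportion = mean(.data$predicted_role == "subject"),
      n = dplyr::n(), .groups = "drop"
    )
  p_form <- ne |>
    dplyr::group_by(
      condition = .data$condition_full, role = .data$predicted_role
    ) |>
    dplyr::summarise(
      proportion = mean(.data$predicted_form == "pronoun"),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      measure = ifelse(.data$role == "subject",
        "p_pronoun_given_predicted_subject",
        "p_pronoun_given_predicted_object"
      ),
      role = NULL
    )
  out <- dplyr::bind_rows(p_subj, p_form)
  out <- out[, c("condition", "measure", "proportion", "n")]
  class(out) <- c("refbias_novel", class(out))
  out
}

# ---- reporting ------------------------------------------------------------

#' Write the standard experiment report
#'
#' Writes, under `out_dir`: `curves.csv` (grand-average binned curves for
#' all three measures, grouped by category and by verb),
#' `novel_eval.csv` (pooled novel-item predictions), `summary.json`
#' (final-bin proportions per category, the final pronoun rates on
#' predicted-object trials, and the novel-item table) and
#' `figs/*.png` (learning-curve and novel-item figures).
#'
#' @param cohort A `ref_cohort` from [run_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param final_window Number of final presentations pooled for the
#'   asymptotic summaries.
#' @return Invisibly, the paths written.
#' @export
report <- function(cohort, out_dir, final_window = 2000L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  figs <- file.path(out_dir, "figs")
  dir.create(figs, recursive = TRUE, showWarnings = FALSE)

  curves_cat <- bin_proportions(cohort, "category")
  curves_verb <- bin_proportions(cohort, "verb")
  curves <- dplyr::bind_rows(
    dplyr::mutate(curves_cat, group_by = "category", .before = 1),
    dplyr::mutate(curves_verb, group_by = "verb", .before = 1)
  )
  f_curves <- file.path(out_dir, "curves.csv")
  readr::write_csv(curves, f_curves, progress = FALSE)

  ne <- cohort_novel(cohort)
  f_novel <- file.path(out_dir, "novel_eval.csv")
  readr::write_csv(ne, f_novel, progress = FALSE)

  summ <- list(
    n_runs = length(cohort$runs),
    n_items = nrow(cohort$runs[[1]]$trials),
    final_window = final_window,
    final_p_subject_prediction = final_rates(
      cohort, "p_subject_prediction", final_window
    ),
    final_p_pronoun_given_predicted_subject = final_rates(
      cohort, "p_pronoun_given_predicted_subject", final_window
    ),
    final_p_pronoun_given_predicted_object = final_rates(
      cohort, "p_pronoun_given_predicted_object", final_window
    ),
    novel = novel_summary(cohort)
  )
  f_summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, f_summary, digits = NA, auto_unbox = TRUE)

  paths <- c(f_curves, f_novel, f_summary)
  p1 <- autoplot(curves_cat)
  ggplot2::ggsave(file.path(figs, "curves_category.png"), p1,
    width = 9, height = 4, dpi = 150
  )
  p2 <- autoplot(curves_verb)
  ggplot2::ggsave(file.path(figs, "curves_verb.png"), p2,
    width = 9, height = 4, dpi = 150
  )
  p3 <- autoplot(novel_summary(cohort))
  ggplot2::ggsave(file.path(figs, "novel_items.png"), p3,
    width = 9, height = 4, dpi = 150
  )
  paths <- c(paths, file.path(figs, c(
    "curves_category.png", "curves_verb.png", "novel_items.png"
  )))
  invisible(paths)
}

#' Grand-average rate over the final presentations
#'
#' Pools, within each run, the last `final_window` presentations; computes
#' the per-run proportion per verb category; averages over runs.
#'
#' @param cohort A `ref_cohort`.
#' @param measure As in [bin_proportions()].
#' @param final_window Number of final presentations per run.
#' @return A named list of grand-average proportions, one per verb
#'   category.
#' @export
final_rates <- function(cohort, measure = "p_subject_prediction",
                        final_window = 2000L) {
  trials <- tidy(cohort)
  n_items <- nrow(cohort$runs[[1]]$trials)
  sub <- dplyr::filter(trials, .data$trial_index > n_items - final_window)
  sub <- switch(measure,
    p_subject_prediction = sub,
    p_pronoun_given_predicted_subject =
      dplyr::filter(sub, .data$predicted_role == "subject"),
    p_pronoun_given_predicted_object =
      dplyr::filter(sub, .data$predicted_role == "object"),
    stop("unknown measure: ", measure, call. = FALSE)
  )
  sub$value <- if (measure == "p_subject_prediction") {
    sub$predicted_role == "subject"
  } else {
    sub$predicted_form == "pronoun"
  }
  out <- sub |>
    dplyr::group_by(.data$verb_category, .data$run_id) |>
    dplyr::summarise(p = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$verb_category) |>
    dplyr::summarise(p = mean(.data$p), .groups = "drop")
  setNames(as.list(out$p), out$verb_category)
}
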