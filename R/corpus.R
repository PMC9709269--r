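#' Default verb table
#'
#' The ten implicit-causality verbs the training corpus samples from: five
#' subject-biased verbs, three object-biased verbs and two roughly neutral
#' verbs. `p_subject` is the probability that the discourse continuation
#' rementions the verb's subject. The value for "repulsed" (0.76) comes
#' from sentence-completion norms; the remaining values are package
#' defaults chosen to respect each verb's category, and can be overridden
#' through [corpus_config()].
#'
#' @return A tibble with columns `lemma`, `category`
#'   (`subject_biased` / `object_biased` / `neutral`) and `p_subject`.
#' @examples
#' default_verb_table()
#' @export
default_verb_table <- function() {
  tibble(
    lemma = c(
      "repulsed", "angered", "fascinated", "disappointed", "apologized",
      "comforted", "feared", "congratulated",
      "interrupted", "filmed"
    ),
    category = c(
      rep("subject_biased", 5), rep("object_biased", 3), rep("neutral", 2)
    ),
    p_subject = c(0.76, 0.80, 0.75, 0.78, 0.70, 0.25, 0.30, 0.20, 0.50, 0.52)
  )
}

validate_verb_table <- function(vt) {
  stopifnot(
    is.data.frame(vt),
    all(c("lemma", "category", "p_subject") %in% names(vt)),
    !anyDuplicated(vt$lemma),
    all(vt$category %in% c("subject_biased", "object_biased", "neutral")),
    all(vt$p_subject >= 0 & vt$p_subject <= 1)
  )
  bad <- (vt$category == "subject_biased" & vt$p_subject <= 0.5) |
    (vt$category == "object_biased" & vt$p_subject >= 0.5)
  if (any(bad)) {
    stop(
      "verb category inconsistent with p_subject for: ",
      paste(vt$lemma[bad], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(vt)
}

#' Corpus generator configuration
#'
#' Describes the synthetic training input: transitive sentences
#' "Name1 VERB Name2" followed by a continuation referent (the subject or
#' the object, with verb-dependent probability) realized as a proper name
#' or the pronoun "she" (with grammatical-role-dependent probability).
#'
#' @param n_items Number of items to generate.
#' @param verb_table Verb table as in [default_verb_table()].
#' @param n_names Number of distinct proper names (at least 2).
#' @param p_pronoun_given_subject Probability that a subject continuation
#'   is realized as a pronoun.
#' @param p_name_given_object Probability that an object continuation is
#'   realized as a proper name.
#' @param seed Integer seed; corpus generation is a pure function of the
#'   configuration including the seed.
#' @return A `corpus_config` object (a list).
#' @examples
#' corpus_config(n_items = 100, seed = 1)
#' @export
corpus_config <- function(n_items = 10000, verb_table = default_verb_table(),
                          n_names = 40, p_pronoun_given_subject = 0.75,
                          p_name_given_object = 0.75, seed = 1) {
  validate_verb_table(verb_table)
  stopifnot(
    n_items >= 1, n_names >= 2,
    p_pronoun_given_subject >= 0, p_pronoun_given_subject <= 1,
    p_name_given_object >= 0, p_name_given_object <= 1
  )
  structure(
    list(
      n_items = as.integer(n_items), verb_table = verb_table,
      n_names = as.integer(n_names),
      p_pronoun_given_subject = p_pronoun_given_subject,
      p_name_given_object = p_name_given_object,
      seed = as.integer(seed)
    ),
    class = "corpus_config"
  )
}

#' @export
print.corpus_config <- function(x, ...) {
  cat(sprintf(
    "corpus_config: %d items, %d verbs, %d names, P(pro|subj)=%g, P(name|obj)=%g, seed=%d\n",
    x$n_items, nrow(x$verb_table), x$n_names,
    x$p_pronoun_given_subject, x$p_name_given_object, x$seed
  ))
  invisible(x)
}

#' Generate distinct synthetic female names
#'
#' Names are synthetic pronounceable tokens (consonant-vowel syllables with
#' a feminine `-a` ending); only distinctness matters to the model. The
#' result is deterministic given the RNG state.
#'
#' @param n Number of names (at least 2).
#' @param avoid Character vector of tokens the names must not collide with
#'   (e.g. verb lemmas and `"she"`).
#' @return Character vector of `n` distinct name tokens.
#' @examples
#' set.seed(1)
#' generate_names(5)
#' @export
generate_names <- function(n, avoid = character()) {
  stopifnot(n >= 2)
  consonants <- c(
    "b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
    "p", "r", "s", "t", "v", "z"
  )
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(1:2, 1)
    body <- paste0(
      sample(consonants, k + 1, replace = TRUE),
      c(sample(vowels, k, replace = TRUE), "a"),
      collapse = ""
    )
    if (!(body %in% out) && !(body %in% avoid) && body != "she") {
      out <- c(out, body)
    }
  }
  out
}

#' Sample one input item
#'
#' One generation cycle: sample a verb (uniformly) and two distinct names
#' (uniformly, without replacement) to build the transitive sentence; then
#' sample the continuation referent (subject with the verb's `p_subject`)
#' and the continuation form (pronoun with `p_pronoun_given_subject` for
#' subject continuations, name with `p_name_given_object` for object
#' continuations).
#'
#' @param cfg A [corpus_config()].
#' @param names Character vector of available names.
#' @param item_id Item identifier.
#' @return A one-row tibble (see [generate_corpus()] for columns).
#' @export
sample_item <- function(cfg, names, item_id = 1L) {
  vt <- cfg$verb_table
  vi <- sample.int(nrow(vt), 1L)
  nm <- names[sample.int(length(names), 2L)]
  role <- if (runif(1) < vt$p_subject[[vi]]) "subject" else "object"
  p_pro <- if (role == "subject") {
    cfg$p_pronoun_given_subject
  } else {
    1 - cfg$p_name_given_object
  }
  form <- if (runif(1) < p_pro) "pronoun" else "name"
  referent <- if (role == "subject") nm[[1]] else nm[[2]]
  tibble(
    item_id = as.integer(item_id),
    subject_name = nm[[1]],
    verb = vt$lemma[[vi]],
    verb_category = vt$category[[vi]],
    object_name = nm[[2]],
    continuation_role = role,
    continuation_form = form,
    continuation_token = if (form == "pronoun") "she" else referent,
    continuation_referent = referent
  )
}

#' Generate a training corpus
#'
#' Draws `n_items` independent items from the configured distribution
#' (items are not deduplicated). The name inventory is generated first and
#' attached as attribute `"names_used"`; the verb table is attached as
#' `"verb_table"`.
#'
#' @param cfg A [corpus_config()].
#' @return A tibble with one row per item and columns `item_id`,
#'   `subject_name`, `verb`, `verb_category`, `object_name`,
#'   `continuation_role`, `continuation_form`, `continuation_token`,
#'   `continuation_referent`.
#' @examples
#' corp <- generate_corpus(corpus_config(n_items = 50, seed = 1))
#' head(corp)
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "corpus_config"))
  set.seed(cfg$seed)
  nms <- generate_names(cfg$n_names, avoid = cfg$verb_table$lemma)
  vt <- cfg$verb_table
  n <- cfg$n_items
  vi <- sample.int(nrow(vt), n, replace = TRUE)
  # two distinct names per item, uniform without replacement
  n1 <- sample.int(cfg$n_names, n, replace = TRUE)
  shift <- sample.int(cfg$n_names - 1L, n, replace = TRUE)
  n2 <- 1L + (n1 - 1L + shift) %% cfg$n_names
  role <- ifelse(runif(n) < vt$p_subject[vi], "subject", "object")
  p_pro <- ifelse(
    role == "subject", cfg$p_pronoun_given_subject, 1 - cfg$p_name_given_object
  )
  form <- ifelse(runif(n) < p_pro, "pronoun", "name")
  referent <- ifelse(role == "subject", nms[n1], nms[n2])
  out <- tibble(
    item_id = seq_len(n),
    subject_name = nms[n1],
    verb = vt$lemma[vi],
    verb_category = vt$category[vi],
    object_name = nms[n2],
    continuation_role = role,
    continuation_form = form,
    continuation_token = ifelse(form == "pronoun", "she", referent),
    continuation_referent = referent
  )
  attr(out, "names_used") <- nms
  attr(out, "verb_table") <- vt
  out
}

#' Generate the novel-item evaluation sentences
#'
#' Builds the 25 evaluation sentences used to probe generalization after
#' learning is frozen: 5 fully novel items (novel verb and novel names),
#' 5 novel-verb items (novel verb, familiar names) and 15 novel-name items
#' (familiar verb -- five per verb category -- with novel names).
#' Evaluation items carry no continuation: the model only predicts.
#'
#' @param cfg A [corpus_config()] (supplies the verb table).
#' @param trained_verbs Character vector of verbs seen in training.
#' @param trained_names Character vector of names seen in training.
#' @return A tibble like a corpus but with `condition`
#'   (`fully_novel` / `novel_verb` / `novel_name`) and `NA` continuation
#'   fields.
#' @examples
#' corp <- generate_corpus(corpus_config(n_items = 10, seed = 1))
#' set.seed(2)
#' novel <- generate_novel_items(corpus_config(seed = 1),
#'   trained_verbs = default_verb_table()$lemma,
#'   trained_names = attr(corp, "names_used")
#' )
#' table(novel$condition)
#' @export
generate_novel_items <- function(cfg, trained_verbs, trained_names) {
  avoid <- c(trained_verbs, trained_names)
  novel_verbs <- paste0("nverb", seq_len(10L))
  stopifnot(!any(novel_verbs %in% avoid))
  novel_names <- generate_names(40L, avoid = avoid)
  vt <- cfg$verb_table
  pick_cat <- function(cat) {
    lemmas <- vt$lemma[vt$category == cat]
    rep(lemmas, length.out = 5L)
  }
  fam_verbs <- c(
    pick_cat("subject_biased"), pick_cat("object_biased"), pick_cat("neutral")
  )
  fam_cats <- rep(c("subject_biased", "object_biased", "neutral"), each = 5L)
  verbs <- c(novel_verbs[1:5], novel_verbs[6:10], fam_verbs)
  cats <- c(rep(NA_character_, 10L), fam_cats)
  cond <- c(rep("fully_novel", 5L), rep("novel_verb", 5L), rep("novel_name", 15L))
  subj <- obj <- character(25L)
  # fully novel + novel-name items draw from the untrained name pool,
  # novel-verb items from the trained pool
  pool_idx <- 1L
  for (i in seq_len(25L)) {
    if (cond[i] == "novel_verb") {
      nm <- trained_names[sample.int(length(trained_names), 2L)]
    } else {
      nm <- novel_names[c(pool_idx, pool_idx + 1L)]
      pool_idx <- pool_idx + 2L
    }
    subj[i] <- nm[[1]]
    obj[i] <- nm[[2]]
  }
  tibble(
    item_id = seq_len(25L),
    condition = cond,
    subject_name = subj,
    verb = verbs,
    verb_category = cats,
    object_name = obj,
    continuation_role = NA_character_,
    continuation_form = NA_character_,
    continuation_token = NA_character_,
    continuation_referent = NA_character_
  )
}

#' Summarize the continuation distributions of a corpus
#'
#' Computes the empirical analogues of the configured sampling
#' probabilities: the per-verb subject-continuation proportion and the
#' pronoun proportion per verb category and continuation role. Each
#' proportion is paired with its cell count.
#'
#' @param items A corpus tibble from [generate_corpus()].
#' @return A tibble with columns `measure`
#'   (`p_subject_continuation` / `p_pronoun`), `group` (verb or
#'   category x role), `proportion` and `n`.
#' @examples
#' corp <- generate_corpus(corpus_config(n_items = 2000, seed = 1))
#' validate_corpus(corp)
#' @export
validate_corpus <- function(items) {
  stopifnot(nrow(items) > 0)
  by_verb <- items |>
    dplyr::group_by(.data$verb) |>
    dplyr::summarise(
      proportion = mean(.data$continuation_role == "subject"),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::transmute(
      measure = "p_subject_continuation",
      group = .data$verb, .data$proportion, .data$n
    )
  by_cell <- items |>
    dplyr::group_by(.data$verb_category, .data$continuation_role) |>
    dplyr::summarise(
      proportion = mean(.data$continuation_form == "pronoun"),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::transmute(
      measure = "p_pronoun",
      group = paste(.data$verb_category, .data$continuation_role, sep = ":"),
      .data$proportion, .data$n
    )
  dplyr::bind_rows(by_verb, by_cell)
}

#' Read and write corpora
#'
#' Corpora round-trip losslessly through JSON Lines (one item object per
#' line) or CSV; the format is chosen from the file extension
#' (`.jsonl` vs `.csv`).
#'
#' @param items A corpus tibble.
#' @param path Output/input path ending in `.jsonl` or `.csv`.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` the
#'   corpus tibble.
#' @export
write_corpus <- function(items, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(items, con, verbose = FALSE)
  } else if (grepl("\\.csv$", path)) {
    readr::write_csv(items, path, progress = FALSE)
  } else {
    stop("unsupported corpus format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "r")
    on.exit(close(con))
    as_tibble(jsonlite::stream_in(con, verbose = FALSE))
  } else if (grepl("\\.csv$", path)) {
    readr::read_csv(
      path,
      col_types = readr::cols(
        item_id = readr::col_integer(), .default = readr::col_character()
      ),
      progress = FALSE
    )
  } else {
    stop("unsupported corpus format: ", path, call. = FALSE)
  }
}

#' Read and write generator configurations
#'
#' Configurations serialize to YAML (or JSON) and round-trip losslessly.
#'
#' @param cfg A [corpus_config()].
#' @param path Path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_corpus_config` returns `path` invisibly;
#'   `read_corpus_config` a [corpus_config()].
#' @export
write_corpus_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$verb_table <- as.data.frame(cfg$verb_table)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, digits = NA, dataframe = "rows")
  } else {
    stop("unsupported config format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_corpus_config
#' @export
read_corpus_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", path, call. = FALSE)
  }
  vt <- as_tibble(as.data.frame(obj$verb_table))
  corpus_config(
    n_items = obj$n_items, verb_table = vt, n_names = obj$n_names,
    p_pronoun_given_subject = obj$p_pronoun_given_subject,
    p_name_given_object = obj$p_name_given_object, seed = obj$seed
  )
}
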