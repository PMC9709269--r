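#' Build the model's lexicon of declarative-memory chunks
#'
#' Each word the model can process is stored as a lexical-entry chunk with
#' four content slots: chunk type (always `"lexical-entry"`), surface form,
#' part of speech, and meaning. Meanings follow the one-concept-per-word
#' convention `"c-" + form`. Besides the verbs and proper names supplied,
#' the lexicon always contains the single pronoun chunk `"she"` (the input
#' only ever contains female referents).
#'
#' @param verbs Character vector of verb lemmas.
#' @param names Character vector of proper names.
#' @return A tibble with one row per chunk and columns `name`,
#'   `chunk_type`, `form`, `pos`, `meaning`.
#' @examples
#' lex <- build_lexicon(c("fascinated"), c("leah", "kathy"))
#' lex
#' @export
build_lexicon <- function(verbs, names) {
  stopifnot(length(verbs) > 0, length(names) > 0)
  verbs <- as.character(verbs)
  names <- as.character(names)
  forms <- c(names, verbs, "she")
  if (anyDuplicated(forms)) {
    stop(
      "duplicate forms in lexicon: ",
      paste(unique(forms[duplicated(forms)]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble(
    name = paste0("ch-", forms),
    chunk_type = "lexical-entry",
    form = forms,
    pos = c(rep("noun", length(names)), rep("verb", length(verbs)), "pronoun"),
    meaning = paste0("c-", forms)
  )
}

#' Retrieve a chunk from declarative memory
#'
#' Declarative retrieval matches a partial specification against the
#' lexicon. With base-level activation disabled, retrieval is
#' deterministic: exactly one chunk must match all constrained fields.
#'
#' @param request Named list of constrained chunk fields; any of
#'   `chunk_type`, `form`, `pos`, `meaning`. At least one field must be
#'   constrained (fields holding `"nil"` or `NULL` are unconstrained).
#' @param lexicon A lexicon tibble from [build_lexicon()].
#' @return The matching chunk as a one-row tibble.
#' @examples
#' lex <- build_lexicon("fascinated", c("leah", "kathy"))
#' retrieve_chunk(list(form = "leah"), lex)
#' retrieve_chunk(list(pos = "pronoun"), lex)
#' @export
retrieve_chunk <- function(request, lexicon) {
  fields <- c("chunk_type", "form", "pos", "meaning")
  request <- request[!vapply(request, is.null, logical(1))]
  request <- request[!vapply(request, identical, logical(1), "nil")]
  if (length(request) == 0) {
    stop("retrieval request constrains no field", call. = FALSE)
  }
  bad <- setdiff(names(request), fields)
  if (length(bad)) {
    stop("unknown chunk field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(lexicon))
  for (f in names(request)) {
    keep <- keep & lexicon[[f]] == request[[f]]
  }
  hits <- lexicon[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    stop(
      "retrieval failure: no chunk matches ",
      paste(names(request), unlist(request), sep = "=", collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(hits) > 1) {
    stop(
      "ambiguous retrieval: ", nrow(hits), " chunks match; ",
      "the lexicon must be unambiguous",
      call. = FALSE
    )
  }
  hits
}
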