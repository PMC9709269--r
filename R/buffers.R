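#' Create an empty buffer set
#'
#' The model exchanges symbols through four buffers with ordered, unlabeled
#' slots: the input buffer `V` (3 slots, holds the current sentence or the
#' discourse continuation), working memory `WM` (5 slots; during sentence
#' processing WM1 = subject, WM2 = verb, WM3 = object, WM4 = predicted form,
#' WM5 = predicted referent), the retrieval buffer `RT` (4 slots mirroring a
#' declarative chunk: type, form, part of speech, meaning) and the external
#' action buffer `AC` (1 slot). Empty slots hold the symbol `"nil"`.
#'
#' @return An object of class `buffer_set`: a named list of character
#'   vectors, one per buffer.
#' @examples
#' b <- buffer_set()
#' b <- slot_set(b, "V1", "leah")
#' slot_get(b, "V1")
#' @export
buffer_set <- function() {
  structure(
    list(
      V = rep("nil", 3L),
      WM = rep("nil", 5L),
      RT = rep("nil", 4L),
      AC = "nil"
    ),
    class = "buffer_set"
  )
}

#' @export
print.buffer_set <- function(x, ...) {
  for (buf in names(x)) {
    cat(sprintf("%-3s %s\n", buf, paste(x[[buf]], collapse = " | ")))
  }
  invisible(x)
}

parse_slot <- function(address) {
  m <- regmatches(address, regexec("^(V|WM|RT|AC)([0-9]+)$", address))[[1]]
  if (length(m) != 3L) {
    stop("malformed slot address: ", address, call. = FALSE)
  }
  list(buffer = m[2], index = as.integer(m[3]))
}

#' Read or write one buffer slot
#'
#' Slots are addressed by buffer name plus position, e.g. `"WM3"` or `"V1"`.
#' A malformed address or an out-of-range position is an error.
#'
#' @param b A [buffer_set()].
#' @param address Slot address such as `"WM1"`.
#' @param value Symbol to store (for `slot_set`).
#' @return `slot_get` returns the symbol held in the slot (`"nil"` if
#'   empty); `slot_set` returns the modified buffer set.
#' @export
slot_get <- function(b, address) {
  a <- parse_slot(address)
  slots <- b[[a$buffer]]
  if (a$index > length(slots)) {
    stop("slot out of range: ", address, call. = FALSE)
  }
  slots[[a$index]]
}

#' @rdname slot_get
#' @export
slot_set <- function(b, address, value) {
  a <- parse_slot(address)
  if (a$index > length(b[[a$buffer]])) {
    stop("slot out of range: ", address, call. = FALSE)
  }
  b[[a$buffer]][[a$index]] <- value
  b
}

#' Condition and action primitives
#'
#' Operators are assembled from primitive elements ("prims"). Condition
#' prims compare buffer slots and never change state:
#' * `cmp_eq` / `cmp_ne` -- two slots hold the same / a different symbol.
#'   Content comparisons require content: an empty slot is neither
#'   `cmp_eq` nor `cmp_ne` to anything (emptiness is tested with
#'   `is_nil` / `not_nil`),
#' * `is_nil` / `not_nil` -- a slot is empty / filled.
#'
#' Action prims each change exactly one slot (or emit one external signal):
#' * `copy` -- copy the symbol in slot `src` into slot `dst`,
#' * `set_const` -- write the constant symbol `src` into slot `dst`
#'   (writing into an `RT` slot states a retrieval constraint),
#' * `ext_action` -- emit the external signal named by `src` (e.g.
#'   `"read-next"`, which triggers presentation of the discourse
#'   continuation); the signal is transient, not a persistent slot value.
#'
#' @param kind One of `"cmp_eq"`, `"cmp_ne"`, `"is_nil"`, `"not_nil"`,
#'   `"copy"`, `"set_const"`, `"ext_action"`.
#' @param src Slot address, or a constant symbol for `set_const` /
#'   `ext_action`.
#' @param dst Slot address (unused for single-slot conditions and
#'   `ext_action`).
#' @return A `prim` object.
#' @export
prim <- function(kind, src = NULL, dst = NULL) {
  kind <- match.arg(kind, c(
    "cmp_eq", "cmp_ne", "is_nil", "not_nil",
    "copy", "set_const", "ext_action"
  ))
  structure(list(kind = kind, src = src, dst = dst), class = "prim")
}

prim_is_condition <- function(p) {
  p$kind %in% c("cmp_eq", "cmp_ne", "is_nil", "not_nil")
}

eval_prim <- function(p, b) {
  switch(p$kind,
    cmp_eq = {
      x <- slot_get(b, p$src)
      y <- slot_get(b, p$dst)
      # content comparisons require content: an empty slot is neither
      # equal nor unequal to anything (emptiness is tested with is_nil)
      x != "nil" && identical(x, y)
    },
    cmp_ne = {
      x <- slot_get(b, p$src)
      y <- slot_get(b, p$dst)
      x != "nil" && y != "nil" && !identical(x, y)
    },
    is_nil = identical(slot_get(b, p$src), "nil"),
    not_nil = !identical(slot_get(b, p$src), "nil"),
    stop("not a condition prim: ", p$kind, call. = FALSE)
  )
}

#' Define an operator
#'
#' An operator is a named list of condition prims and action prims. It can
#' fire only when every condition holds against the current buffers; firing
#' applies every action in order.
#'
#' @param name Operator name (a symbol such as `"predict-subj"`).
#' @param conditions List of condition [prim()]s.
#' @param actions List of action [prim()]s.
#' @return An `operator` object.
#' @export
operator <- function(name, conditions, actions) {
  stopifnot(
    all(vapply(conditions, prim_is_condition, logical(1))),
    !any(vapply(actions, prim_is_condition, logical(1)))
  )
  structure(
    list(name = name, conditions = conditions, actions = actions),
    class = "operator"
  )
}

#' @export
print.operator <- function(x, ...) {
  fmt <- function(p) {
    switch(p$kind,
      cmp_eq = paste0(p$src, " = ", p$dst),
      cmp_ne = paste0(p$src, " <> ", p$dst),
      is_nil = paste0(p$src, " = nil"),
      not_nil = paste0(p$src, " <> nil"),
      copy = paste0(p$src, " -> ", p$dst),
      set_const = paste0("'", p$src, "' -> ", p$dst),
      ext_action = paste0("signal '", p$src, "'")
    )
  }
  cat(x$name, "\n")
  for (p in x$conditions) cat("  ", fmt(p), "\n")
  cat("  ==>\n")
  for (p in x$actions) cat("  ", fmt(p), "\n")
  invisible(x)
}

#' Evaluate an operator's condition prims
#'
#' @param op An [operator()].
#' @param b A [buffer_set()].
#' @return `TRUE` iff every condition prim holds against `b`. The buffers
#'   are never modified.
#' @examples
#' ops <- build_operators()
#' b <- buffer_set()
#' b$WM <- c("leah", "fascinated", "kathy", "nil", "nil")
#' eval_conditions(ops[["predict-subj"]], b)
#' @export
eval_conditions <- function(op, b) {
  for (p in op$conditions) {
    if (!eval_prim(p, b)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Apply an operator's action prims
#'
#' Actions are applied in order. Writing into a retrieval-buffer (`RT`)
#' slot states a retrieval constraint: the caller (the trial loop) resolves
#' the pending request against declarative memory after the operator
#' completes. An `ext_action` prim emits a transient signal which is
#' returned, not stored.
#'
#' @inheritParams eval_conditions
#' @return A list with elements `buffers` (the updated buffer set),
#'   `signals` (character vector of emitted external signals),
#'   `retrieval_request` (`TRUE` if an RT slot was written) and
#'   `consumed_rt` (`TRUE` if a symbol was copied out of `RT` into `WM`,
#'   which releases the retrieval buffer).
#' @examples
#' ops <- build_operators()
#' b <- buffer_set()
#' b$WM <- c("leah", "fascinated", "kathy", "nil", "nil")
#' execute_actions(ops[["predict-subj"]], b)$buffers$WM
#' @export
execute_actions <- function(op, b) {
  signals <- character()
  retrieval_request <- FALSE
  consumed_rt <- FALSE
  for (p in op$actions) {
    switch(p$kind,
      copy = {
        v <- slot_get(b, p$src)
        if (identical(v, "nil")) {
          stop(
            "operator '", op$name, "' copies from empty slot ", p$src,
            " (operator-design bug)",
            call. = FALSE
          )
        }
        b <- slot_set(b, p$dst, v)
        if (startsWith(p$src, "RT") && startsWith(p$dst, "WM")) {
          consumed_rt <- TRUE
        }
        if (startsWith(p$dst, "RT")) retrieval_request <- TRUE
      },
      set_const = {
        b <- slot_set(b, p$dst, p$src)
        if (startsWith(p$dst, "RT")) retrieval_request <- TRUE
      },
      ext_action = {
        signals <- c(signals, p$src)
      },
      stop("not an action prim: ", p$kind, call. = FALSE)
    )
  }
  list(
    buffers = b, signals = signals,
    retrieval_request = retrieval_request, consumed_rt = consumed_rt
  )
}
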