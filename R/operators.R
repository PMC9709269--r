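#' The reference learning model's operator set
#'
#' Builds the fixed set of 14 operators the model uses:
#'
#' * **Sentence comprehension** (`retrieve-V1/2/3`, `store-V1/2/3`): each
#'   word of the transitive sentence is looked up in declarative memory and
#'   its form copied into working memory, so that WM1 = subject,
#'   WM2 = verb, WM3 = object. The retrieve/store pair for word *k*
#'   additionally requires the previous word to be stored already, which
#'   enforces left-to-right processing.
#' * **Referent prediction** (`predict-subj`, `predict-obj`): once the
#'   sentence is in WM1-WM3, copy the subject (WM1) or the object (WM3)
#'   into WM5, the slot for the predicted next referent. The two operators
#'   have identical conditions, so a naive model picks between them at
#'   chance.
#' * **Form prediction** (`predict-subj-name`, `predict-obj-name`,
#'   `predict-pro`, `retrieve-pro`): predict whether the next referent is
#'   realized as a proper name or as a pronoun, writing the predicted form
#'   into WM4. The name operators are gated on which referent was
#'   predicted (`predict-subj-name` requires WM1 = WM5,
#'   `predict-obj-name` requires WM3 = WM5) while `predict-pro` applies to
#'   either; this asymmetry in condition checking is what lets verb-specific
#'   associations surface only on predicted-object trials. `predict-pro`
#'   requests the pronoun chunk from declarative memory and `retrieve-pro`
#'   copies its form into WM4. The operators that complete a form
#'   prediction emit the `read-next` signal, which triggers presentation of
#'   the actual continuation.
#' * **Revision** (`correct-re`, `correct-ref`): after a mismatching
#'   continuation (presented as V1 = surface form, V2 = referent), replace
#'   the predicted form (WM4) and/or referent (WM5) with the observed ones.
#'
#' @return A named list of [operator()]s, in the fixed order used by
#'   operator selection.
#' @examples
#' ops <- build_operators()
#' names(ops)
#' ops[["predict-subj"]]
#' @export
build_operators <- function() {
  ops <- list(
    operator(
      "retrieve-V1",
      conditions = list(
        prim("not_nil", "V1"),
        prim("is_nil", "RT1"),
        prim("is_nil", "WM1")
      ),
      actions = list(
        prim("set_const", "lexical-entry", "RT1"),
        prim("copy", "V1", "RT2")
      )
    ),
    operator(
      "store-V1",
      conditions = list(
        prim("cmp_eq", "V1", "RT2"),
        prim("is_nil", "WM1")
      ),
      actions = list(prim("copy", "RT2", "WM1"))
    ),
    operator(
      "retrieve-V2",
      conditions = list(
        prim("not_nil", "V2"),
        prim("is_nil", "RT1"),
        prim("is_nil", "WM2"),
        prim("not_nil", "WM1")
      ),
      actions = list(
        prim("set_const", "lexical-entry", "RT1"),
        prim("copy", "V2", "RT2")
      )
    ),
    operator(
      "store-V2",
      conditions = list(
        prim("cmp_eq", "V2", "RT2"),
        prim("is_nil", "WM2")
      ),
      actions = list(prim("copy", "RT2", "WM2"))
    ),
    operator(
      "retrieve-V3",
      conditions = list(
        prim("not_nil", "V3"),
        prim("is_nil", "RT1"),
        prim("is_nil", "WM3"),
        prim("not_nil", "WM2")
      ),
      actions = list(
        prim("set_const", "lexical-entry", "RT1"),
        prim("copy", "V3", "RT2")
      )
    ),
    operator(
      "store-V3",
      conditions = list(
        prim("cmp_eq", "V3", "RT2"),
        prim("is_nil", "WM3")
      ),
      actions = list(prim("copy", "RT2", "WM3"))
    ),
    operator(
      "predict-subj",
      conditions = list(
        prim("not_nil", "WM3"),
        prim("is_nil", "WM4"),
        prim("is_nil", "WM5")
      ),
      actions = list(prim("copy", "WM1", "WM5"))
    ),
    operator(
      "predict-obj",
      conditions = list(
        prim("not_nil", "WM3"),
        prim("is_nil", "WM4"),
        prim("is_nil", "WM5")
      ),
      actions = list(prim("copy", "WM3", "WM5"))
    ),
    operator(
      "predict-subj-name",
      conditions = list(
        prim("is_nil", "WM4"),
        prim("cmp_eq", "WM1", "WM5"),
        prim("is_nil", "RT1")
      ),
      actions = list(
        prim("copy", "WM5", "WM4"),
        prim("ext_action", "read-next")
      )
    ),
    operator(
      "predict-obj-name",
      conditions = list(
        prim("is_nil", "WM4"),
        prim("cmp_eq", "WM3", "WM5"),
        prim("is_nil", "RT1")
      ),
      actions = list(
        prim("copy", "WM5", "WM4"),
        prim("ext_action", "read-next")
      )
    ),
    operator(
      "predict-pro",
      conditions = list(
        prim("is_nil", "WM4"),
        prim("not_nil", "WM5"),
        prim("is_nil", "RT1")
      ),
      actions = list(
        prim("set_const", "lexical-entry", "RT1"),
        prim("set_const", "pronoun", "RT3")
      )
    ),
    operator(
      "retrieve-pro",
      conditions = list(
        prim("is_nil", "WM4"),
        prim("not_nil", "WM5"),
        prim("not_nil", "RT1")
      ),
      actions = list(
        prim("copy", "RT2", "WM4"),
        prim("ext_action", "read-next")
      )
    ),
    operator(
      "correct-re",
      conditions = list(
        prim("cmp_ne", "WM4", "V1"),
        prim("is_nil", "V3")
      ),
      actions = list(prim("copy", "V1", "WM4"))
    ),
    operator(
      "correct-ref",
      conditions = list(
        prim("cmp_ne", "WM5", "V2"),
        prim("is_nil", "V3")
      ),
      actions = list(prim("copy", "V2", "WM5"))
    )
  )
  setNames(ops, vapply(ops, function(o) o$name, character(1)))
}
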