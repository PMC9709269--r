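#' Engine configuration
#'
#' Tunable parameters of operator selection and context-operator learning.
#'
#' @param alpha Associative learning rate in (0, 1]. Each learning event
#'   moves a strength a fraction `alpha` of the way toward its target (the
#'   reward magnitude after a rewarded trial, zero after an unrewarded
#'   one), so strengths are recency-weighted estimates of how often firing
#'   the operator in that context ends in reward.
#' @param reward Reward magnitude `R` (positive). Strengths live in
#'   `[0, R]`.
#' @param noise_sd Standard deviation of the zero-mean logistic noise added
#'   independently to each candidate operator's activation at selection
#'   time. `0` makes selection deterministic up to ties.
#' @param learning_enabled If `FALSE`, the association store is frozen: no
#'   trial changes any strength.
#' @param seed Optional integer seed recorded for reproducibility;
#'   [run_simulation()] and [run_cohort()] seed the RNG from it.
#' @return An `engine_config` object (a list).
#' @examples
#' engine_config()
#' engine_config(noise_sd = 0, learning_enabled = FALSE)
#' @export
engine_config <- function(alpha = 0.2, reward = 1, noise_sd = 0.3,
                          learning_enabled = TRUE, seed = NULL) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1,
    is.numeric(reward), length(reward) == 1, reward > 0,
    is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0,
    is.logical(learning_enabled), length(learning_enabled) == 1
  )
  structure(
    list(
      alpha = alpha, reward = reward, noise_sd = noise_sd,
      learning_enabled = learning_enabled, seed = seed
    ),
    class = "engine_config"
  )
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf(
    "engine_config: alpha=%g reward=%g noise_sd=%g learning=%s seed=%s\n",
    x$alpha, x$reward, x$noise_sd, x$learning_enabled,
    if (is.null(x$seed)) "NULL" else x$seed
  ))
  invisible(x)
}

# logistic scale parameter for a target standard deviation
logistic_scale <- function(noise_sd) noise_sd * sqrt(3) / pi

#' Create an association store
#'
#' The association store is the model's entire learned state: a bounded
#' strength in `[0, R]` for every (context symbol, operator) pair, read as
#' 0 where no pair has been stored. Context symbols are the surface forms
#' that can occupy working memory (names and verbs).
#'
#' @param symbols Character vector of context symbols (rows).
#' @param operators Character vector of operator names, or the list from
#'   [build_operators()] (columns).
#' @return An environment of class `association_store` holding the strength
#'   matrix.
#' @examples
#' st <- association_store(c("leah", "fascinated"), build_operators())
#' assoc_strength(st, "leah", "predict-subj")
#' @export
association_store <- function(symbols = character(), operators = build_operators()) {
  if (is.list(operators)) operators <- names(operators)
  st <- new.env(parent = emptyenv())
  st$strengths <- matrix(
    0, nrow = length(symbols), ncol = length(operators),
    dimnames = list(symbols, operators)
  )
  class(st) <- "association_store"
  st
}

#' @export
print.association_store <- function(x, ...) {
  nz <- sum(x$strengths != 0)
  cat(sprintf(
    "association_store: %d symbols x %d operators (%d non-zero)\n",
    nrow(x$strengths), ncol(x$strengths), nz
  ))
  invisible(x)
}

store_ensure_symbols <- function(store, symbols) {
  new <- setdiff(symbols, rownames(store$strengths))
  if (length(new)) {
    add <- matrix(
      0, nrow = length(new), ncol = ncol(store$strengths),
      dimnames = list(new, colnames(store$strengths))
    )
    store$strengths <- rbind(store$strengths, add)
  }
  invisible(store)
}

#' Read one associative strength
#'
#' @param store An [association_store()].
#' @param symbol Context symbol.
#' @param op_name Operator name.
#' @return The strength, 0 for any pair not present.
#' @export
assoc_strength <- function(store, symbol, op_name) {
  s <- store$strengths
  if (!(symbol %in% rownames(s)) || !(op_name %in% colnames(s))) {
    return(0)
  }
  s[symbol, op_name]
}

#' @describeIn assoc_strength All strengths as a tidy tibble (one row per
#'   non-zero pair).
#' @export
tidy.association_store <- function(x, ...) {
  s <- x$strengths
  out <- tibble(
    symbol = rep(rownames(s), times = ncol(s)),
    operator = rep(colnames(s), each = nrow(s)),
    strength = as.vector(s)
  )
  dplyr::filter(out, .data$strength != 0)
}

#' Working-memory context of a buffer set
#'
#' The context used for operator activation and credit assignment is
#' restricted to the sentence representation: the non-empty values of
#' WM1-WM3 (subject, verb, object). Predicted values in WM4/WM5 never
#' contribute.
#'
#' @param b A [buffer_set()].
#' @return Character vector of context symbols (possibly empty).
#' @export
wm_context <- function(b) {
  v <- b$WM[1:3]
  v[v != "nil"]
}

#' Operator activation
#'
#' An operator's activation is the sum of its associative strengths with
#' the current context symbols. There is no base-level term: a naive model
#' (all-zero store) gives every operator activation 0.
#'
#' @param op An [operator()] or an operator name.
#' @param context Character vector of context symbols (see [wm_context()]).
#' @param store An [association_store()].
#' @return The activation (a scalar).
#' @examples
#' st <- association_store(c("leah", "fascinated", "kathy"))
#' st$strengths["fascinated", "predict-subj"] <- 0.4
#' st$strengths["leah", "predict-subj"] <- 0.1
#' operator_activation("predict-subj", c("leah", "fascinated", "kathy"), st)
#' @export
operator_activation <- function(op, context, store) {
  name <- if (inherits(op, "operator")) op$name else op
  if (length(context) == 0) {
    return(0)
  }
  sum(vapply(context, assoc_strength, numeric(1), store = store, op_name = name))
}

#' Select an operator by noisy activation with condition gating
#'
#' Every candidate is scored as activation plus independent zero-mean
#' logistic noise, and candidates are considered in descending score
#' order; the first whose condition prims all hold is returned.
#' (Equivalently: the highest-scoring condition-eligible candidate, since
#' conditions do not depend on the scores.) Exact ties are broken
#' uniformly at random. If no candidate is eligible, selection fails and
#' `NULL` is returned -- a valid outcome that ends a trial.
#'
#' One noise value is always drawn per candidate, in candidate order, so
#' that selection consumes the RNG identically across backends.
#'
#' @param candidates Named list of [operator()]s (fixed order).
#' @param b A [buffer_set()].
#' @param store An [association_store()].
#' @param cfg An [engine_config()].
#' @return The selected operator, or `NULL` if none is eligible.
#' @export
select_operator <- function(candidates, b, store, cfg) {
  n <- length(candidates)
  noise <- rlogis(n, location = 0, scale = logistic_scale(cfg$noise_sd))
  context <- wm_context(b)
  scores <- vapply(
    candidates, operator_activation, numeric(1),
    context = context, store = store
  ) + noise
  eligible <- vapply(candidates, eval_conditions, logical(1), b = b)
  if (!any(eligible)) {
    return(NULL)
  }
  idx <- which(eligible)
  best <- idx[scores[idx] == max(scores[idx])]
  if (length(best) > 1) {
    best <- best[floor(runif(1) * length(best)) + 1]
  }
  candidates[[best]]
}

#' Update associative strengths after a trial
#'
#' Context-operator learning is driven by prediction outcome. After a
#' rewarded trial, the strength between every current context symbol and
#' every operator that fired on the trial moves toward the reward
#' magnitude: `s <- s + alpha * (R - s)`. After an unrewarded trial the
#' same pairs move toward zero: `s <- s + alpha * (0 - s)`. Strengths of
#' operators that did not fire are never touched, so each strength is a
#' recency-weighted estimate of the probability that firing the operator
#' in that context ends in reward, scaled by `R`, and stays in `[0, R]`.
#'
#' `apply_reward` performs the rewarded-trial update; `apply_extinction`
#' the unrewarded-trial one. Both are no-ops when `cfg$learning_enabled`
#' is `FALSE`.
#'
#' @param fired Character vector (or list of operators) that fired on the
#'   trial, in firing order.
#' @param context Character vector of context symbols (see [wm_context()]).
#' @param store An [association_store()]; updated in place.
#' @param cfg An [engine_config()].
#' @return The store, invisibly.
#' @examples
#' st <- association_store("fascinated")
#' apply_reward("predict-subj", "fascinated", st, engine_config(alpha = 0.2))
#' assoc_strength(st, "fascinated", "predict-subj") # 0.2
#' @export
apply_reward <- function(fired, context, store, cfg) {
  learn_update(fired, context, store, cfg, target = cfg$reward)
}

#' @rdname apply_reward
#' @export
apply_extinction <- function(fired, context, store, cfg) {
  learn_update(fired, context, store, cfg, target = 0)
}

learn_update <- function(fired, context, store, cfg, target) {
  if (!cfg$learning_enabled) {
    return(invisible(store))
  }
  if (is.list(fired)) {
    fired <- vapply(fired, function(o) o$name, character(1))
  }
  fired <- unique(fired)
  context <- unique(context)
  if (length(fired) == 0 || length(context) == 0) {
    return(invisible(store))
  }
  store_ensure_symbols(store, context)
  ops <- intersect(fired, colnames(store$strengths))
  s <- store$strengths[context, ops, drop = FALSE]
  store$strengths[context, ops] <- s + cfg$alpha * (target - s)
  invisible(store)
}

#' Serialize / restore an association store
#'
#' @param store An [association_store()].
#' @param path File path for JSON output/input.
#' @return `write_store` returns `path` invisibly; `read_store` returns an
#'   [association_store()].
#' @export
write_store <- function(store, path) {
  obj <- list(
    symbols = rownames(store$strengths),
    operators = colnames(store$strengths),
    strengths = unname(store$strengths)
  )
  # I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- association_store(obj$symbols, obj$operators)
  if (length(obj$symbols)) {
    st$strengths[] <- matrix(obj$strengths, nrow = length(obj$symbols))
  }
  st
}
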