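# Safe expression dialect for config-only programs.
#
# Program files may bind an internal-state updater or a conditional-
# transition condition to a small arithmetic expression instead of a
# registered function name.  The expression is parsed once, its AST is
# checked against a whitelist (arithmetic, comparisons, a few math
# primitives, `normrnd(mu, sigma)`, `pop("Species")`, `time()`, and the
# permitted identifiers), and anything else is rejected at validation
# time.  Arbitrary host code in program files is never evaluated.

.stg_allowed_calls <- c(
  "+", "-", "*", "/", "^", "(",
  "<", ">", "<=", ">=", "==", "!=", "&", "|", "!",
  "min", "max", "abs", "exp", "log", "sqrt",
  "floor", "ceiling", "round", "ifelse",
  "normrnd", "pop", "time"
)

.check_expr <- function(ex, vars, what = "expression") {
  if (is.atomic(ex)) return(invisible(TRUE))
  if (is.symbol(ex)) {
    nm <- as.character(ex)
    if (!nm %in% vars)
      stop_stg("validation", sprintf(
        "unknown identifier `%s` in %s (allowed: %s)",
        nm, what, paste(vars, collapse = ", ")))
    return(invisible(TRUE))
  }
  if (is.call(ex)) {
    head <- ex[[1L]]
    if (!is.symbol(head) || !as.character(head) %in% .stg_allowed_calls)
      stop_stg("validation", sprintf(
        "disallowed call `%s` in %s", deparse(ex[[1L]]), what))
    for (i in seq_along(ex)[-1L]) .check_expr(ex[[i]], vars, what)
    return(invisible(TRUE))
  }
  stop_stg("validation", sprintf("unsupported construct in %s", what))
}

.parse_expr <- function(text, what = "expression") {
  lang <- tryCatch(str2lang(text), error = function(e)
    stop_stg("validation", sprintf("cannot parse %s: %s", what, conditionMessage(e))))
  lang
}

# Compile an internal-state updater expression into fn(x, ctx).
# `x` is the current value vector (length = dup); normrnd() draws one
# value per element of x; pop()/time() read the live engine state.
compile_state_expr <- function(text) {
  lang <- .parse_expr(text, "state updater expression")
  .check_expr(lang, vars = "x", what = "state updater expression")
  function(x, ctx) {
    ev <- list(
      x = x,
      normrnd = function(mu, sigma) stats::rnorm(length(x), mu, sigma),
      pop = function(s) ctx$pop(s),
      time = function() ctx$time()
    )
    out <- eval(lang, ev, baseenv())
    if (length(out) == 1L && length(x) > 1L) out <- rep(out, length(x))
    out
  }
}

# Compile a conditional-transition condition into fn(values, ctx) where
# `values` is a named list of per-individual state-value vectors; the
# result is a logical vector over individuals.
compile_condition <- function(text, state_names) {
  lang <- .parse_expr(text, "condition")
  .check_expr(lang, vars = state_names, what = "condition")
  function(values, ctx) {
    ev <- c(values, list(
      pop = function(s) ctx$pop(s),
      time = function() ctx$time()
    ))
    out <- eval(lang, ev, baseenv())
    as.logical(out)
  }
}

# Variables referenced by a condition (to validate against state defs).
expr_vars <- function(text) {
  lang <- .parse_expr(text)
  vars <- character(0)
  walk <- function(ex) {
    if (is.symbol(ex)) vars <<- c(vars, as.character(ex))
    else if (is.call(ex)) for (i in seq_along(ex)[-1L]) walk(ex[[i]])
  }
  walk(lang)
  setdiff(unique(vars), .stg_allowed_calls)
}
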