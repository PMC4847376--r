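# Updater registry: named bindings for the updating functions a program
# file can reference.  Internal-state updaters map a current value vector
# to an updated one; global updaters map the system state (population
# sizes, elapsed time) to new per-rule rates and branch probabilities.

.stg <- new.env(parent = emptyenv())

.builtin_state <- function() list(
  ms_step            = list(fn = ms_step, builtin = TRUE),
  gen_increment      = list(fn = gen_increment, builtin = TRUE),
  stochastic_counter = list(fn = stochastic_counter_step, builtin = TRUE),
  identity           = list(fn = function(x) x, builtin = TRUE)
)

.builtin_global <- function() list(
  empty           = list(fn = NULL, builtin = TRUE, pass_time = FALSE),
  lotka_volterra  = list(fn = lotka_volterra_updater, builtin = TRUE,
                         pass_time = FALSE),
  clone_expansion = list(fn = clone_expansion_updater, builtin = TRUE,
                         pass_time = FALSE)
)

#' Create a fresh updater registry
#'
#' A registry resolves the updating-function names a program file refers
#' to.  Every registry contains the built-ins `ms_step`, `gen_increment`,
#' `stochastic_counter` and `identity` (internal-state updaters) and
#' `empty`, `lotka_volterra` and `clone_expansion` (global updaters);
#' built-ins cannot be overwritten.
#'
#' @return An object of class `stg_registry`.
#' @seealso [register_updater()], [validate_program()]
#' @export
new_registry <- function() {
  reg <- structure(
    list(state = new.env(parent = emptyenv()),
         global = new.env(parent = emptyenv())),
    class = "stg_registry"
  )
  for (nm in names(.builtin_state())) assign(nm, .builtin_state()[[nm]], reg$state)
  for (nm in names(.builtin_global())) assign(nm, .builtin_global()[[nm]], reg$global)
  reg
}

#' The session-wide default registry
#'
#' Returned registry is shared: updaters registered on it are visible to
#' every subsequent [validate_program()] call that does not pass its own
#' registry.
#'
#' @return The default `stg_registry`.
#' @export
default_registry <- function() {
  if (is.null(.stg$registry)) .stg$registry <- new_registry()
  .stg$registry
}

#' Register a user updating function
#'
#' @param registry An `stg_registry` (see [new_registry()]).
#' @param name Identifier the program file will use.
#' @param kind `"state"` for an internal-state updater (called as
#'   `fn(x)` or `fn(x, ctx)` where `x` is the current value vector and
#'   `ctx` exposes `ctx$pop(species)` and `ctx$time()`), or `"global"`
#'   for a global updater (called as `fn(populations, time, ...)`,
#'   returning a named list `species -> list(rate, probs)`).
#' @param fn The function to bind.
#' @return The registry, invisibly.
#' @examples
#' reg <- new_registry()
#' register_updater(reg, "my_decay", "state", function(x) x * 0.9)
#' @export
register_updater <- function(registry, name, kind = c("state", "global"), fn) {
  kind <- match.arg(kind)
  if (!inherits(registry, "stg_registry"))
    stop_stg("validation", "`registry` must be an stg_registry")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_stg("validation", "updater name must be a non-empty string")
  env <- registry[[kind]]
  existing <- if (exists(name, env, inherits = FALSE)) get(name, env) else NULL
  if (!is.null(existing) && isTRUE(existing$builtin))
    stop_stg("validation", "`%s` is a built-in updater and cannot be re-registered", name)
  if (!is.function(fn))
    stop_stg("validation", "`fn` must be a function")
  nf <- length(formals(fn))
  if (kind == "state" && nf < 1L)
    stop_stg("validation", "a state updater must accept at least (x)")
  if (kind == "global" && nf < 2L)
    stop_stg("validation", "a global updater must accept at least (populations, time)")
  assign(name, list(fn = fn, builtin = FALSE, pass_time = (kind == "global")), env)
  invisible(registry)
}

# --- binding resolution -----------------------------------------------------

# Parse "name" or "name(arg = 1, ...)" with literal arguments.  Returns
# list(name, args) or NULL when the text is not of that shape (in which
# case state bindings fall back to the expression dialect).
.parse_binding <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(list(name = "", args = list()))
  lang <- tryCatch(str2lang(text), error = function(e) NULL)
  if (is.null(lang)) return(NULL)
  if (is.symbol(lang)) return(list(name = as.character(lang), args = list()))
  if (is.call(lang) && is.symbol(lang[[1L]])) {
    args <- as.list(lang)[-1L]
    lit <- lapply(args, function(a) {
      if (is.atomic(a)) return(a)
      # allow negative literals, which parse as calls to unary `-`
      if (is.call(a) && identical(a[[1L]], as.name("-")) &&
          length(a) == 2L && is.atomic(a[[2L]])) return(-a[[2L]])
      NULL
    })
    if (any(vapply(lit, is.null, logical(1)))) return(NULL)
    return(list(name = as.character(lang[[1L]]), args = lit))
  }
  NULL
}

# Resolve an internal-state updater binding to fn(x, ctx).
resolve_state_updater <- function(registry, text) {
  b <- .parse_binding(text)
  if (!is.null(b)) {
    if (b$name == "" || b$name == "identity" && !length(b$args))
      return(function(x, ctx) x)
    if (exists(b$name, registry$state, inherits = FALSE)) {
      entry <- get(b$name, registry$state)
      fn <- entry$fn
      fml <- names(formals(fn))
      bad <- setdiff(names(b$args)[nzchar(names2(b$args))], fml)
      if (length(bad))
        stop_stg("validation", "updater `%s` has no argument `%s`", b$name, bad[1])
      args <- b$args
      if ("ctx" %in% fml)
        return(function(x, ctx) do.call(fn, c(list(x, ctx = ctx), args)))
      return(function(x, ctx) do.call(fn, c(list(x), args)))
    }
  }
  # not a registered name: treat as a safe expression over `x`
  compile_state_expr(text)
}

# Resolve a global updater binding to fn(populations, time) or NULL (no-op).
resolve_global_updater <- function(registry, text) {
  b <- .parse_binding(text)
  if (is.null(b))
    stop_stg("validation",
             "global updater binding `%s` is not a registered name", text)
  if (b$name == "" || b$name == "empty") return(NULL)
  if (!exists(b$name, registry$global, inherits = FALSE))
    stop_stg("validation", "unknown global updater `%s`", b$name)
  entry <- get(b$name, registry$global)
  fn <- entry$fn
  if (is.null(fn)) return(NULL)
  args <- b$args
  if (isTRUE(entry$pass_time))
    return(function(pops, t) do.call(fn, c(list(pops, t), args)))
  function(pops, t) do.call(fn, c(list(pops), args))
}

names2 <- function(x) { n <- names(x); if (is.null(n)) rep("", length(x)) else n }
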