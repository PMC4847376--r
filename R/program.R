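# XML dialect (see inst/extdata/program.xsd for the schema reference):
#   <Program>
#     <ExecParams><SimTime>..</SimTime><Seed>..</Seed></ExecParams>
#     <FunHandleName>global updater name, may be empty</FunHandleName>
#     <Rule>
#       <Name>A</Name> <InitPop>..</InitPop> <Rate>..</Rate>
#       <Prod><Products>A,B</Products><Prob>0.5 | ow</Prob></Prod> ...
#       <InternalState><Name>..</Name><InitVal>..</InitVal>
#                      <FuncName>..</FuncName><DupNum>..</DupNum></InternalState> ...
#       <ConditionalTransition><Condition>expr</Condition>
#                              <Transition>Species | {0}</Transition></ConditionalTransition> ...
#     </Rule> ...
#     <Sink>SpeciesWithNoRule</Sink> ...
#   </Program>

.xml_children_named <- function(node, allowed, where) {
  kids <- xml2::xml_children(node)
  nms <- xml2::xml_name(kids)
  bad <- setdiff(unique(nms), allowed)
  if (length(bad))
    stop_stg("schema", "unknown element <%s> inside <%s>", bad[1], where)
  kids
}

.xml_text1 <- function(node, name, where, required = TRUE, default = NULL) {
  found <- xml2::xml_find_all(node, name)
  if (length(found) == 0L) {
    if (required)
      stop_stg("schema", "missing required element <%s> in <%s>", name, where)
    return(default)
  }
  if (length(found) > 1L)
    stop_stg("schema", "element <%s> repeated in <%s>", name, where)
  trimws(xml2::xml_text(found))
}

.as_num <- function(txt, what) {
  x <- suppressWarnings(as.numeric(txt))
  if (is.na(x)) stop_stg("schema", "<%s> is not a number: '%s'", what, txt)
  x
}

#' Parse a stochastic-tree-grammar program document
#'
#' Reads the XML dialect describing a grammar program: per-species
#' transition rules (rate, probability-weighted outcome groups, initial
#' population), internal-state definitions with updater bindings,
#' conditional transitions, optional rule-less sink species, the global
#' updating-function name, and execution parameters (simulation time,
#' random seed).  Probabilities may use the sentinel `ow` ("otherwise",
#' one minus the sum of the other branch probabilities); `ow` is
#' preserved verbatim here and resolved by [validate_program()].
#'
#' @param x Path to an XML file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return An unvalidated object of class `stg_program`.
#' @seealso [validate_program()], [write_program()], [fixture_program()]
#' @examples
#' p <- parse_program(fixture_path("lotka_volterra"))
#' p
#' @export
parse_program <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else {
    tryCatch(xml2::read_xml(x), error = function(e)
      stop_stg("parse", "malformed XML: %s", conditionMessage(e)))
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Program")
    stop_stg("schema", "root element must be <Program>, found <%s>",
             xml2::xml_name(root))
  .xml_children_named(root, c("ExecParams", "FunHandleName", "Rule", "Sink"),
                      "Program")

  ep <- xml2::xml_find_all(root, "ExecParams")
  if (length(ep) != 1L)
    stop_stg("schema", "missing required element <ExecParams> in <Program>")
  .xml_children_named(ep, c("SimTime", "Seed"), "ExecParams")
  sim_time <- .as_num(.xml_text1(ep, "SimTime", "ExecParams"), "SimTime")
  seed_txt <- .xml_text1(ep, "Seed", "ExecParams", required = FALSE, default = "1")
  seed <- as.integer(.as_num(seed_txt, "Seed"))

  fh <- .xml_text1(root, "FunHandleName", "Program", required = FALSE, default = "")

  rules <- lapply(xml2::xml_find_all(root, "Rule"), function(rn) {
    .xml_children_named(rn, c("Name", "InitPop", "Rate", "Prod",
                              "InternalState", "ConditionalTransition"), "Rule")
    name <- .xml_text1(rn, "Name", "Rule")
    if (!nzchar(name)) stop_stg("schema", "empty species <Name> in <Rule>")
    rate <- .as_num(.xml_text1(rn, "Rate", "Rule"), "Rate")
    init_pop <- .as_num(
      .xml_text1(rn, "InitPop", "Rule", required = FALSE, default = "0"),
      "InitPop")
    prods <- xml2::xml_find_all(rn, "Prod")
    if (length(prods) == 0L)
      stop_stg("schema", "rule `%s` has no <Prod> outcome group", name)
    outcomes <- lapply(prods, function(pn) {
      .xml_children_named(pn, c("Products", "Prob"), "Prod")
      ptxt <- .xml_text1(pn, "Products", "Prod", required = FALSE, default = "")
      products <- trimws(strsplit(ptxt, ",", fixed = TRUE)[[1]])
      products <- products[nzchar(products)]
      prob_txt <- .xml_text1(pn, "Prob", "Prod")
      prob <- if (identical(prob_txt, "ow")) "ow" else .as_num(prob_txt, "Prob")
      list(products = products, prob = prob)
    })
    states <- lapply(xml2::xml_find_all(rn, "InternalState"), function(sn) {
      .xml_children_named(sn, c("Name", "InitVal", "FuncName", "DupNum"),
                          "InternalState")
      list(
        name = .xml_text1(sn, "Name", "InternalState"),
        init = .as_num(.xml_text1(sn, "InitVal", "InternalState"), "InitVal"),
        updater = .xml_text1(sn, "FuncName", "InternalState",
                             required = FALSE, default = ""),
        dup = as.integer(.as_num(
          .xml_text1(sn, "DupNum", "InternalState", required = FALSE,
                     default = "1"), "DupNum"))
      )
    })
    conds <- lapply(xml2::xml_find_all(rn, "ConditionalTransition"), function(cn) {
      .xml_children_named(cn, c("Condition", "Transition"), "ConditionalTransition")
      tgt <- .xml_text1(cn, "Transition", "ConditionalTransition")
      list(
        condition = .xml_text1(cn, "Condition", "ConditionalTransition"),
        target = if (identical(tgt, "{0}")) NA_character_ else tgt
      )
    })
    list(name = name, init_pop = init_pop, rate = rate,
         outcomes = outcomes, states = states, conditionals = conds)
  })
  if (length(rules) == 0L)
    stop_stg("schema", "program declares no <Rule>")

  sinks <- vapply(xml2::xml_find_all(root, "Sink"), function(s)
    trimws(xml2::xml_text(s)), character(1))

  structure(
    list(rules = rules, sinks = sinks, global_updater = fh,
         exec = list(sim_time = sim_time, seed = seed),
         validated = FALSE),
    class = "stg_program"
  )
}

#' Resolve the `ow` probability sentinel
#'
#' Replaces the sentinel `"ow"` ("otherwise") in a vector of branch
#' probabilities by one minus the sum of the numeric entries, so the
#' result is a full probability vector.
#'
#' @param probs A list or vector of numbers in `[0, 1]`, at most one of
#'   which is the string `"ow"`.
#' @return A numeric probability vector summing to 1.
#' @examples
#' resolve_ow(list(0.49, "ow"))   # 0.49 0.51
#' resolve_ow(list("ow"))         # 1
#' @export
resolve_ow <- function(probs) {
  raw <- as.list(probs)
  is_ow <- vapply(raw, function(p) identical(p, "ow"), logical(1))
  if (sum(is_ow) > 1L)
    stop_stg("validation", "at most one outcome group may use the `ow` sentinel")
  nums <- vapply(raw[!is_ow], function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 1L || is.na(v))
      stop_stg("validation", "probability is neither a number nor `ow`")
    v
  }, numeric(1))
  if (any(nums < 0 | nums > 1))
    stop_stg("validation", "probabilities must lie in [0, 1]")
  tol <- 1e-12
  s <- sum(nums)
  out <- numeric(length(raw))
  out[!is_ow] <- nums
  if (any(is_ow)) {
    if (s > 1 + tol)
      stop_stg("validation", "probabilities sum to %.15g > 1 with `ow` present", s)
    out[is_ow] <- 1 - s
  } else if (abs(s - 1) > tol) {
    stop_stg("validation", "probabilities sum to %.15g, expected 1", s)
  }
  out
}

#' Validate a parsed program
#'
#' Cross-checks a parsed program and compiles its bindings: resolves `ow`
#' sentinels into full probability vectors, verifies that each species has
#' at most one rule, that every species named in an outcome group or
#' conditional target is declared (as a rule or a `<Sink>`), that internal
#' states referenced by conditions exist with duplication 1, that a state
#' name carries the same duplication number wherever it appears, and that
#' every updater binding resolves against the registry (or compiles in the
#' safe expression dialect).  Idempotent.
#'
#' @param program An `stg_program` from [parse_program()].
#' @param registry An `stg_registry`; defaults to [default_registry()].
#' @return The validated program (class `stg_program`, `validated = TRUE`),
#'   with per-rule resolved `probs` and compiled updaters attached.
#' @export
validate_program <- function(program, registry = default_registry()) {
  if (!inherits(program, "stg_program"))
    stop_stg("validation", "`program` must be an stg_program")
  rules <- program$rules
  species <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(species)) {
    dup <- species[duplicated(species)][1]
    stop_stg("validation", paste0(
      "species `%s` is the left side of more than one rule; each species ",
      "may have at most one transition rule"), dup)
  }
  sinks <- unique(program$sinks)
  if (length(bad <- intersect(sinks, species)))
    stop_stg("validation", "`%s` is declared both as a <Rule> and a <Sink>", bad[1])
  declared <- c(species, sinks)

  if (program$exec$sim_time <= 0)
    stop_stg("validation", "simulation time must be positive")

  state_dup <- new.env(parent = emptyenv())  # state name -> dup, for consistency

  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    if (!is.finite(r$rate) || r$rate < 0)
      stop_stg("validation", "rule `%s` has a negative or non-finite rate", r$name)
    if (r$init_pop < 0 || r$init_pop != round(r$init_pop))
      stop_stg("validation", "rule `%s` has a non-integer or negative InitPop", r$name)
    for (o in r$outcomes) {
      if (length(o$products) > 2L)
        stop_stg("validation",
                 "rule `%s` has an outcome group with more than two products", r$name)
      for (sp in o$products)
        if (!sp %in% declared)
          stop_stg("validation",
                   "rule `%s` produces undeclared species `%s`", r$name, sp)
    }
    rules[[ri]]$probs <- resolve_ow(lapply(r$outcomes, `[[`, "prob"))

    st_names <- vapply(r$states, `[[`, character(1), "name")
    if (anyDuplicated(st_names))
      stop_stg("validation", "rule `%s` defines internal state `%s` twice",
               r$name, st_names[duplicated(st_names)][1])
    for (si in seq_along(r$states)) {
      s <- r$states[[si]]
      if (s$dup < 1L)
        stop_stg("validation", "internal state `%s` has DupNum < 1", s$name)
      if (exists(s$name, state_dup, inherits = FALSE) &&
          get(s$name, state_dup) != s$dup)
        stop_stg("validation",
                 "internal state `%s` has inconsistent DupNum across species", s$name)
      assign(s$name, s$dup, state_dup)
      rules[[ri]]$states[[si]]$fn <- resolve_state_updater(registry, s$updater)
    }
    for (ci in seq_along(r$conditionals)) {
      cn <- r$conditionals[[ci]]
      if (!is.na(cn$target) && !cn$target %in% declared)
        stop_stg("validation",
                 "conditional transition of `%s` targets undeclared species `%s`",
                 r$name, cn$target)
      vars <- expr_vars(cn$condition)
      unknown <- setdiff(vars, st_names)
      if (length(unknown))
        stop_stg("validation",
                 "condition of `%s` references `%s`, not an internal state of that species",
                 r$name, unknown[1])
      dups <- vapply(r$states[match(vars, st_names)], `[[`, integer(1), "dup")
      if (any(dups != 1L))
        stop_stg("validation",
                 "condition of `%s` references a state with DupNum > 1", r$name)
      rules[[ri]]$conditionals[[ci]]$vars <- vars
      rules[[ri]]$conditionals[[ci]]$fn <- compile_condition(cn$condition, st_names)
    }
  }

  program$rules <- rules
  program$global_fn <- resolve_global_updater(registry, program$global_updater)
  program$validated <- TRUE
  program
}

#' Serialize a program back to its XML dialect
#'
#' Writes a program as it was authored: `ow` sentinels and updater
#' binding texts are preserved, so `parse -> serialize -> parse` is the
#' identity on program structure.
#'
#' @param program An `stg_program` (validated or not).
#' @param path Optional file path; when `NULL` the XML text is returned.
#' @return The XML text (invisibly when written to `path`).
#' @export
write_program <- function(program, path = NULL) {
  num <- function(x) {
    if (x == round(x) && abs(x) < 1e15) sprintf("%d", as.integer(x))
    else format(x, digits = 17)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ln <- c("<Program>",
          "  <ExecParams>",
          sprintf("    <SimTime>%s</SimTime>", num(program$exec$sim_time)),
          sprintf("    <Seed>%d</Seed>", program$exec$seed),
          "  </ExecParams>",
          sprintf("  <FunHandleName>%s</FunHandleName>", esc(program$global_updater)))
  for (r in program$rules) {
    ln <- c(ln, "  <Rule>",
            sprintf("    <Name>%s</Name>", esc(r$name)),
            sprintf("    <InitPop>%s</InitPop>", num(r$init_pop)),
            sprintf("    <Rate>%s</Rate>", num(r$rate)))
    for (o in r$outcomes) {
      prob <- if (identical(o$prob, "ow")) "ow" else num(o$prob)
      ln <- c(ln, "    <Prod>",
              sprintf("      <Products>%s</Products>",
                      esc(paste(o$products, collapse = ","))),
              sprintf("      <Prob>%s</Prob>", prob),
              "    </Prod>")
    }
    for (s in r$states)
      ln <- c(ln, "    <InternalState>",
              sprintf("      <Name>%s</Name>", esc(s$name)),
              sprintf("      <InitVal>%s</InitVal>", num(s$init)),
              sprintf("      <FuncName>%s</FuncName>", esc(s$updater)),
              sprintf("      <DupNum>%d</DupNum>", s$dup),
              "    </InternalState>")
    for (cn in r$conditionals)
      ln <- c(ln, "    <ConditionalTransition>",
              sprintf("      <Condition>%s</Condition>", esc(cn$condition)),
              sprintf("      <Transition>%s</Transition>",
                      if (is.na(cn$target)) "{0}" else esc(cn$target)),
              "    </ConditionalTransition>")
    ln <- c(ln, "  </Rule>")
  }
  for (s in program$sinks)
    ln <- c(ln, sprintf("  <Sink>%s</Sink>", esc(s)))
  ln <- c(ln, "</Program>", "")
  txt <- paste(ln, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @export
print.stg_program <- function(x, ...) {
  cat(sprintf("Stochastic tree grammar program (%d rule%s%s)\n",
              length(x$rules), if (length(x$rules) == 1) "" else "s",
              if (length(x$sinks)) paste0(", ", length(x$sinks), " sink(s)") else ""))
  for (r in x$rules) {
    br <- vapply(r$outcomes, function(o) {
      prods <- if (length(o$products)) paste(o$products, collapse = ",") else "phi"
      p <- if (identical(o$prob, "ow")) "ow" else format(o$prob)
      sprintf("{%s}_%s", prods, p)
    }, character(1))
    cat(sprintf("  %s --(%g)--> %s   [init %d]\n", r$name, r$rate,
                paste(br, collapse = " | "), as.integer(r$init_pop)))
    for (s in r$states)
      cat(sprintf("    state %s = %g, updater '%s', dup %d\n",
                  s$name, s$init, s$updater, s$dup))
    for (cn in r$conditionals)
      cat(sprintf("    if (%s) -> %s\n", cn$condition,
                  if (is.na(cn$target)) "{0}" else cn$target))
  }
  cat(sprintf("  sim time %g, seed %d, global updater '%s'%s\n",
              x$exec$sim_time, x$exec$seed, x$global_updater,
              if (isTRUE(x$validated)) " (validated)" else ""))
  invisible(x)
}

# Drop compiled closures so structural equality can be tested.
strip_compiled <- function(program) {
  program$global_fn <- NULL
  program$validated <- NULL
  program$rules <- lapply(program$rules, function(r) {
    r$probs <- NULL
    r$states <- lapply(r$states, function(s) { s$fn <- NULL; s })
    r$conditionals <- lapply(r$conditionals, function(cn) { cn$fn <- NULL; cn })
    r
  })
  program
}
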