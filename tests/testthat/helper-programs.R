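# Programmatic program builders (XML text), used to assemble small
# grammars in code rather than shipping fixture files per test.

prod_xml <- function(products, prob) {
  sprintf("<Prod><Products>%s</Products><Prob>%s</Prob></Prod>",
          paste(products, collapse = ","), prob)
}

state_xml <- function(name, init, fun = "", dup = 1) {
  sprintf(paste0("<InternalState><Name>%s</Name><InitVal>%s</InitVal>",
                 "<FuncName>%s</FuncName><DupNum>%d</DupNum></InternalState>"),
          name, init, fun, dup)
}

cond_xml <- function(condition, target) {
  sprintf(paste0("<ConditionalTransition><Condition>%s</Condition>",
                 "<Transition>%s</Transition></ConditionalTransition>"),
          condition, target)
}

rule_xml <- function(name, init, rate, prods, states = "", conds = "") {
  sprintf("<Rule><Name>%s</Name><InitPop>%d</InitPop><Rate>%s</Rate>%s%s%s</Rule>",
          name, as.integer(init), rate, paste(prods, collapse = ""),
          paste(states, collapse = ""), paste(conds, collapse = ""))
}

program_xml <- function(rules, sim_time = 10, seed = 1, fun = "",
                        sinks = character(0)) {
  sprintf(paste0("<Program><ExecParams><SimTime>%s</SimTime><Seed>%d</Seed>",
                 "</ExecParams><FunHandleName>%s</FunHandleName>%s%s</Program>"),
          sim_time, as.integer(seed), fun, paste(rules, collapse = ""),
          paste(sprintf("<Sink>%s</Sink>", sinks), collapse = ""))
}

# A -> {A,A}_1 pure-birth (Yule) program.
yule_program <- function(n0 = 50, rate = 0.5, sim_time = 2) {
  validate_program(parse_program(program_xml(
    rule_xml("A", n0, rate, prod_xml(c("A", "A"), 1)),
    sim_time = sim_time)))
}

# Diff-only subcritical program: birth 0.49 / death 0.51 at rate 1.
diff_only_program <- function(n0 = 40, sim_time = 5) {
  validate_program(parse_program(program_xml(
    rule_xml("Diff", n0, 1, c(prod_xml(c("Diff", "Diff"), 0.49),
                              prod_xml(character(0), "ow"))),
    sim_time = sim_time)))
}

# SC-only critical program with inert Diff sink:
# SC -(0.1)-> {SC,SC}_0.5 | {Diff,Diff}_0.5, Diff has no rule.
sc_critical_program <- function(n0 = 20, sim_time = 20) {
  validate_program(parse_program(program_xml(
    rule_xml("SC", n0, 0.1, c(prod_xml(c("SC", "SC"), 0.5),
                              prod_xml(c("Diff", "Diff"), "ow"))),
    sim_time = sim_time, sinks = "Diff")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared expensive simulations, computed once per test session.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}
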