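test_that("rules translate into channels with c_i = r * p_i", {
  ch <- translate_rules(fixture_program("stem_cell_ms"))
  # SC: r = 0.1, p = (0.5, 0.5); Diff: r = 1, p = (0.49, 0.51)
  expect_equal(ch$rate_c, c(0.05, 0.05, 0.49, 0.51))
  expect_equal(ch$rule, c("SC", "SC", "Diff", "Diff"))
  # per-rule channel sum equals the rule rate
  expect_equal(as.numeric(tapply(ch$rate_c, ch$rule, sum)[c("SC", "Diff")]),
               c(0.1, 1))
  one <- translate_rules(validate_program(parse_program(
    program_xml(rule_xml("A", 1, 2, prod_xml(c("A", "A"), 1))))))
  expect_equal(one$rate_c, 2)
})

test_that("propensities are channel rate times left-hand population", {
  ch <- translate_rules(fixture_program("stem_cell_ms"))
  a <- compute_propensities(ch, c(SC = 0, Diff = 100))
  expect_equal(a, c(0, 0, 49, 51))
  expect_equal(compute_propensities(ch, c(SC = 0, Diff = 0)), rep(0, 4))
  expect_error(compute_propensities(ch, c(SC = -1, Diff = 0)),
               class = "stg_runtime_error")
})

test_that("the direct method samples tau and channel from two uniforms", {
  s <- sample_next_event(c(2), u = c(0.5, 0.5))
  expect_equal(s$tau, log(2) / 2)
  expect_equal(s$channel, 1L)
  expect_equal(sample_next_event(c(1, 3), u = c(0.5, 0.1))$channel, 1L)
  expect_equal(sample_next_event(c(1, 3), u = c(0.5, 0.9))$channel, 2L)
  # a zero-propensity channel is unreachable
  for (u2 in seq(0.05, 0.95, by = 0.1))
    expect_true(sample_next_event(c(5, 0, 5), u = c(0.5, u2))$channel != 2L)
  expect_null(sample_next_event(c(0, 0)))
})

test_that("firing closes the parent and spawns product children with updated states", {
  p <- fixture_program("stem_cell_ms")
  e <- engine_init(p, seed = 42, t_span = 10)
  e$t <- 1.5
  ev <- fire_event(e, 2L)  # SC differentiation channel
  expect_equal(ev$rule, "SC")
  expect_length(ev$children, 2L)
  f <- stgsim:::finalize_run(e)$forest
  expect_equal(f$cause[ev$parent], "division")
  expect_equal(f$end[ev$parent], 1.5)
  expect_equal(f$species[ev$children], c("Diff", "Diff"))
  expect_equal(f$birth[ev$children], c(1.5, 1.5))
  # Gen is new to Diff: initialised to 1 at differentiation
  expect_equal(f$states$Gen[ev$children, 1], c(1, 1))
  # MS inherited through ms_step: within one repeat of the parent
  expect_true(all(abs(f$states$MS[ev$children, ] - 30) <= 1))
})

test_that("a division then a daughter division increments Gen to 2", {
  p <- fixture_program("stem_cell_ms")
  e <- engine_init(p, seed = 7, t_span = 10)
  e$t <- 1
  ev1 <- fire_event(e, 2L)            # SC -> Diff, Diff (Gen = 1)
  e$t <- 2
  ev2 <- fire_event(e, 3L)            # Diff -> Diff, Diff (Gen = 2)
  f <- stgsim:::finalize_run(e)$forest
  expect_equal(f$states$Gen[ev1$children, 1], c(1, 1))
  expect_equal(f$states$Gen[ev2$children, 1], c(2, 2))
})

test_that("the empty outcome group kills the individual", {
  prog <- validate_program(parse_program(program_xml(
    rule_xml("A", 1, 1, prod_xml(character(0), 1)))))
  run <- run_program(prog, seed = 1, t_span = 100)
  expect_equal(nrow(run$events), 1L)
  expect_equal(run$end_reason, "extinction")
  expect_equal(run$forest$n, 1L)
  expect_equal(run$forest$cause, "death")
})

test_that("ms_step with p = 0 makes children inherit repeat counts exactly", {
  prog <- validate_program(parse_program(program_xml(
    rule_xml("A", 1, 1, prod_xml(c("A", "A"), 1),
             states = state_xml("MS", 30, "ms_step(p = 0)", dup = 2)))))
  run <- run_program(prog, seed = 5, t_span = 2)
  expect_true(all(run$forest$states$MS == 30))
})

test_that("the global updater rewrites rates and probabilities keeping sum c_i = r", {
  p <- fixture_program("lotka_volterra")
  e <- engine_init(p, seed = 1, t_span = 10)  # updated once at t = 0
  expect_equal(e$r_rate, c(19, 19))
  expect_equal(e$r_probs[[1]], c(10 / 19, 9 / 19), tolerance = 1e-12)
  expect_equal(e$r_probs[[2]], c(9 / 19, 10 / 19), tolerance = 1e-12)
  for (ri in 1:2)
    expect_equal(sum(e$ch_c[e$ch_rule == ri]), e$r_rate[ri], tolerance = 1e-12)

  # with the compatibility flag the first event is sampled under placeholders
  e2 <- engine_init(p, seed = 1, t_span = 10, legacy_first_update = TRUE)
  expect_equal(e2$r_rate, c(1, 1))

  # an empty updater leaves parameters untouched
  e3 <- engine_init(fixture_program("stem_cell_ms"), seed = 1)
  expect_null(e3$global_fn)
  expect_equal(e3$r_rate, c(0.1, 1))
})

test_that("an updater returning an invalid probability vector aborts the run", {
  reg <- new_registry()
  register_updater(reg, "broken", "global",
                   function(populations, time)
                     list(A = list(rate = 1, probs = c(0.7, 0.4))))
  prog <- validate_program(parse_program(program_xml(
    rule_xml("A", 3, 1, c(prod_xml(c("A", "A"), 0.5),
                          prod_xml(character(0), "ow"))),
    fun = "broken")), reg)
  expect_error(run_program(prog, seed = 1, t_span = 1),
               "probability", class = "stg_runtime_error")
})

test_that("conditional transitions transform or kill individuals past threshold", {
  prog <- validate_program(parse_program(program_xml(c(
    rule_xml("S", 2, 1, prod_xml(c("S", "S"), 1),
             states = state_xml("C", 0, "stochastic_counter(mu = 1, sigma = 0)"),
             conds = cond_xml("C &gt; 5", "D")),
    rule_xml("D", 0, 1, prod_xml(c("D", "D"), 1),
             states = c(state_xml("C", 0, "stochastic_counter(mu = 1, sigma = 0)"),
                        state_xml("G", 7, "gen_increment")),
             conds = cond_xml("C &gt; 10", "{0}"))))))
  e <- engine_init(prog, seed = 1, t_span = 100)
  # no individual satisfies any condition: sweep is a no-op
  expect_length(apply_conditional_transitions(e), 0L)

  # push one S counter over the transform threshold
  id <- e$living[[1]][1]  # first S individual
  e$set_state(id, "C", 5.7)
  e$t <- 3
  tr <- apply_conditional_transitions(e)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$species, "S")
  expect_equal(tr[[1]]$target, "D")
  f <- stgsim:::finalize_run(e)$forest
  expect_equal(f$cause[id], "transform")
  child <- tr[[1]]$child
  expect_equal(f$species[child], "D")
  expect_equal(f$states$C[child, 1], 5.7)   # shared state carried over
  expect_equal(f$states$G[child, 1], 7)     # state new to target: init value
})

test_that("conditional termination closes the node as a death", {
  prog <- validate_program(parse_program(program_xml(
    rule_xml("D", 1, 1, prod_xml(c("D", "D"), 1),
             states = state_xml("C", 0, "stochastic_counter(mu = 1, sigma = 0)"),
             conds = cond_xml("C &gt; 10", "{0}")))))
  e <- engine_init(prog, seed = 1, t_span = 100)
  e$set_state(1L, "C", 10.2)
  e$t <- 1
  tr <- apply_conditional_transitions(e)
  expect_length(tr, 1L)
  expect_true(is.na(tr[[1]]$target))
  f <- stgsim:::finalize_run(e)$forest
  expect_equal(f$cause[1], "death")
  expect_true(f$by_condition[1])
  expect_equal(sum(e$pop), 0)
})

test_that("runs are bit-identical under the same (program, seed, span)", {
  p <- fixture_program("conditional_toy")
  r1 <- run_program(p, seed = 11, t_span = 15)
  r2 <- run_program(p, seed = 11, t_span = 15)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$forest$end, r2$forest$end)
  expect_identical(r1$forest$states, r2$forest$states)
  r3 <- run_program(p, seed = 12, t_span = 15)
  expect_false(identical(r1$events, r3$events))
})

test_that("run_batch returns one independent run per seed, in order", {
  p <- yule_program(n0 = 5, rate = 0.5, sim_time = 1)
  runs <- run_batch(p, seeds = 1:10)
  expect_length(runs, 10L)
  expect_equal(vapply(runs, `[[`, integer(1), "seed"), 1:10)
  logs <- lapply(runs, `[[`, "events")
  expect_gt(length(unique(lapply(logs, function(x) x$time))), 1L)
  expect_warning(dup <- run_batch(p, seeds = c(7, 7)), "duplicate")
  expect_identical(dup[[1]]$events, dup[[2]]$events)
})

test_that("pure-birth growth matches the Yule mean N0 * exp(lambda t)", {
  p <- yule_program(n0 = 50, rate = 0.5, sim_time = 2)
  finals <- cached("yule_finals", vapply(
    run_batch(p, seeds = 1:200), function(r)
      sum(r$population$sizes[nrow(r$population$sizes), ]), numeric(1)))
  expected <- 50 * exp(0.5 * 2)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("the event whose time would exceed the span is discarded and clocks stop", {
  p <- yule_program(n0 = 20, rate = 1, sim_time = 0.5)
  run <- run_program(p, seed = 3)
  expect_equal(run$end_reason, "span-exhausted")
  expect_equal(run$end_time, 0.5)
  expect_true(all(run$events$time <= 0.5))
  expect_true(all(run$forest$end <= 0.5))
  cens <- run$forest$cause == "censored"
  expect_true(all(run$forest$end[cens] == 0.5))
})
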