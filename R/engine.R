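# Gillespie direct-method engine over a validated grammar program.
#
# The engine state lives in a closure environment (class `stg_engine`)
# holding flat, preallocated arrays for nodes, events and internal-state
# values; arrays double in capacity when exhausted.  The per-event step
# functions are closures over that environment and mutate it with `<<-`,
# which keeps element assignment into the large arrays free of
# copy-on-write.  One R random stream per run, seeded with the run seed;
# the draw order per event is fixed: u1 (waiting time), u2 (channel),
# u3 (which individual of the left-hand species fires), then updater
# draws in child order x state order x duplicate order.

.CAUSE_ALIVE <- 0L; .CAUSE_DIVISION <- 1L; .CAUSE_DEATH <- 2L
.CAUSE_TRANSFORM <- 3L; .CAUSE_CENSORED <- 4L
.CAUSE_LABELS <- c("alive", "division", "death", "transform", "censored")

#' Translate grammar rules into reaction channels
#'
#' Each rule `A -(r)-> {S1}_p1 | ... | {Sn}_pn` is expanded into `n`
#' chemical reaction channels `A -(c_i)-> S_i` with `c_i = r * p_i`.
#' Channel order is deterministic: rule order, then outcome order.
#'
#' @param program An `stg_program` (validated automatically if needed).
#' @return A data frame with one row per channel: `channel`, `rule`
#'   (left-hand species), `outcome` (index within the rule), `products`
#'   (comma-separated), `prob`, and `rate_c`.
#' @examples
#' translate_rules(fixture_program("stem_cell_ms"))
#' @export
translate_rules <- function(program) {
  if (!isTRUE(program$validated)) program <- validate_program(program)
  rows <- list()
  k <- 0L
  for (r in program$rules) {
    for (i in seq_along(r$outcomes)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        channel = k, rule = r$name, outcome = i,
        products = paste(r$outcomes[[i]]$products, collapse = ","),
        prob = r$probs[i], rate_c = r$rate * r$probs[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compute channel propensities
#'
#' The propensity of a channel is its rate `c_i` multiplied by the current
#' population of the rule's left-hand species.
#'
#' @param channels Data frame from [translate_rules()].
#' @param populations Named numeric vector of population sizes covering
#'   every left-hand species.
#' @return Numeric vector of propensities, one per channel.
#' @export
compute_propensities <- function(channels, populations) {
  pops <- as.numeric(populations[channels$rule])
  if (anyNA(pops))
    stop_stg("runtime", "populations missing for species `%s`",
             channels$rule[which(is.na(pops))[1]])
  if (any(pops < 0))
    stop_stg("runtime", "negative population encountered")
  channels$rate_c * pops
}

#' Sample the next reaction (direct method)
#'
#' Draws the waiting time `tau = ln(1/u1) / a0` and the channel identity
#' (the smallest `j` with cumulative propensity exceeding `u2 * a0`) from
#' two uniform deviates, as in Gillespie's direct method.
#'
#' @param propensities Numeric vector of channel propensities.
#' @param u Two uniform deviates in (0, 1); drawn from the session random
#'   stream by default, injectable for testing.
#' @return `list(tau, channel)`, or `NULL` when the total propensity is
#'   zero (extinction: the caller halts).
#' @examples
#' sample_next_event(c(2), u = c(0.5, 0.5))  # tau = log(2)/2, channel 1
#' @export
sample_next_event <- function(propensities, u = stats::runif(2)) {
  a0 <- sum(propensities)
  if (a0 <= 0) return(NULL)
  cs <- cumsum(propensities)
  list(tau = -log(u[1]) / a0,
       channel = findInterval(u[2] * a0, cs) + 1L)
}

# --- engine state -----------------------------------------------------------

#' Initialise an engine state for a program
#'
#' Creates the mutable simulation state: one lineage root per initial
#' individual (with internal states at their initial values), the channel
#' table, and the event log.  Unless `legacy_first_update` is set, the
#' global updater is invoked once at `t = 0` so that placeholder rates
#' and probabilities in the program file are corrected before the first
#' event is sampled; with the flag, the first event is sampled under the
#' placeholders and the update happens only after it fires.
#'
#' @param program An `stg_program` (validated automatically if needed).
#' @param seed Integer seed for the run's random stream.
#' @param t_span Simulation span; defaults to the program's `SimTime`.
#' @param legacy_first_update Defer the first global update until after
#'   the first fired event (default `FALSE`).
#' @return An environment of class `stg_engine`.
#' @seealso [run_program()] for the full event loop; [fire_event()],
#'   [apply_conditional_transitions()], [update_global_parameters()] for
#'   single steps.
#' @export
engine_init <- function(program, seed = program$exec$seed,
                        t_span = program$exec$sim_time,
                        legacy_first_update = FALSE) {
  if (!isTRUE(program$validated)) program <- validate_program(program)
  if (!is.numeric(t_span) || t_span <= 0)
    stop_stg("validation", "t_span must be positive")
  seed <- as.integer(seed)
  t_span <- as.numeric(t_span)

  rules <- program$rules
  species <- c(vapply(rules, `[[`, character(1), "name"), program$sinks)
  ns <- length(species)
  nr <- length(rules)
  rule_of_species <- c(seq_len(nr), rep(NA_integer_, length(program$sinks)))

  r_rate <- vapply(rules, `[[`, numeric(1), "rate")
  r_probs <- lapply(rules, `[[`, "probs")
  r_nout <- vapply(rules, function(r) length(r$outcomes), integer(1))
  r_out <- lapply(rules, function(r)
    lapply(r$outcomes, function(o) match(o$products, species)))

  ch_rule <- rep(seq_len(nr), r_nout)
  ch_out <- unlist(lapply(r_nout, seq_len))
  ch_lhs <- ch_rule
  ch_p <- unlist(r_probs)
  ch_c <- r_rate[ch_rule] * ch_p
  nch <- length(ch_rule)
  channel_counts <- numeric(nch)

  # internal states: one wide matrix, states side by side by column block
  state_dup <- integer(0)
  for (r in rules) for (s in r$states) state_dup[s$name] <- s$dup
  state_cols <- list()
  off <- 0L
  for (nm in names(state_dup)) {
    state_cols[[nm]] <- off + seq_len(state_dup[nm])
    off <- off + state_dup[nm]
  }
  n_scol <- off
  state_defs_by_sp <- c(lapply(rules, function(r) {
    lapply(r$states, function(s) {
      s$cols <- state_cols[[s$name]]
      s$init_vec <- rep(s$init, s$dup)
      s
    })
  }), rep(list(list()), length(program$sinks)))
  state_names_by_sp <- lapply(state_defs_by_sp, function(defs)
    vapply(defs, `[[`, character(1), "name"))
  names(state_names_by_sp) <- species

  conds_by_sp <- c(lapply(rules, function(r) {
    lapply(r$conditionals, function(cn) {
      list(fn = cn$fn, vars = cn$vars,
           cols1 = vapply(cn$vars, function(v) state_cols[[v]][1], integer(1)),
           target = if (is.na(cn$target)) 0L else match(cn$target, species))
    })
  }), rep(list(list()), length(program$sinks)))
  cond_sp <- which(vapply(conds_by_sp, length, integer(1)) > 0L)
  has_cond <- length(cond_sp) > 0L
  global_fn <- program$global_fn

  # mutable arrays (modified with <<- from the closures below)
  t <- 0
  end_reason <- NA_character_
  cap <- 1024L; n <- 0L
  nd_sp <- integer(cap); nd_parent <- integer(cap)
  nd_birth <- numeric(cap); nd_end <- numeric(cap)
  nd_cause <- integer(cap); nd_cond <- logical(cap)
  smat <- matrix(NA_real_, cap, n_scol)
  pop <- numeric(ns)
  living <- rep(list(integer(64L)), ns)
  lcount <- integer(ns)
  ecap <- 1024L; nev <- 0L
  ev_t <- numeric(ecap); ev_ch <- integer(ecap)
  ev_parent <- integer(ecap); ev_c1 <- integer(ecap); ev_c2 <- integer(ecap)
  pop_hist <- matrix(0, ecap, ns)
  tcap <- 256L; ntr <- 0L
  tr_t <- numeric(tcap); tr_ev <- integer(tcap)
  tr_node <- integer(tcap); tr_child <- integer(tcap); tr_tgt <- integer(tcap)

  ctx <- list(
    pop = function(s) {
      i <- match(s, species)
      if (is.na(i)) stop_stg("runtime", "pop() of unknown species `%s`", s)
      pop[i]
    },
    time = function() t
  )

  grow_nodes <- function() {
    new <- cap * 2L
    length(nd_sp) <<- new; length(nd_parent) <<- new
    length(nd_birth) <<- new; length(nd_end) <<- new
    length(nd_cause) <<- new; length(nd_cond) <<- new
    m <- matrix(NA_real_, new, n_scol)
    if (n > 0L && n_scol > 0L) m[seq_len(n), ] <- smat[seq_len(n), ]
    smat <<- m
    cap <<- new
  }

  new_node <- function(sp, parent, birth) {
    if (n + 1L > cap) grow_nodes()
    id <- n <<- n + 1L
    nd_sp[id] <<- sp; nd_parent[id] <<- parent
    nd_birth[id] <<- birth; nd_end[id] <<- NA_real_
    nd_cause[id] <<- .CAUSE_ALIVE; nd_cond[id] <<- FALSE
    lc <- lcount[sp] + 1L
    if (lc > length(living[[sp]]))
      living[[sp]] <<- c(living[[sp]], integer(length(living[[sp]])))
    living[[sp]][lc] <<- id
    lcount[sp] <<- lc
    pop[sp] <<- pop[sp] + 1
    id
  }

  remove_living <- function(sp, id) {
    lc <- lcount[sp]
    pos <- which(living[[sp]] == id)
    pos <- pos[pos <= lc][1L]
    living[[sp]][pos] <<- living[[sp]][lc]
    lcount[sp] <<- lc - 1L
    pop[sp] <<- pop[sp] - 1
  }

  # child creation: a state also on the parent's species is updated from
  # the parent's value; a state new to the child starts at its init value
  spawn_child <- function(csp, parent, psp, via_updater) {
    cid <- new_node(csp, parent, t)
    defs <- state_defs_by_sp[[csp]]
    if (length(defs)) {
      pnames <- state_names_by_sp[[psp]]
      for (d in defs) {
        if (d$name %in% pnames) {
          if (via_updater) {
            nv <- d$fn(smat[parent, d$cols], ctx)
            if (length(nv) != d$dup || !is.numeric(nv))
              stop_stg("runtime",
                       "updater for state `%s` returned %d value(s), expected %d",
                       d$name, length(nv), d$dup)
            smat[cid, d$cols] <<- nv
          } else {
            smat[cid, d$cols] <<- smat[parent, d$cols]
          }
        } else {
          smat[cid, d$cols] <<- d$init_vec
        }
      }
    }
    cid
  }

  grow_events <- function() {
    new <- ecap * 2L
    length(ev_t) <<- new; length(ev_ch) <<- new
    length(ev_parent) <<- new; length(ev_c1) <<- new; length(ev_c2) <<- new
    ph <- matrix(0, new, ns)
    ph[seq_len(nev), ] <- pop_hist[seq_len(nev), ]
    pop_hist <<- ph
    ecap <<- new
  }

  fire <- function(ch) {
    sp <- ch_lhs[ch]
    lc <- lcount[sp]
    if (lc < 1L)
      stop_stg("runtime",
               "no living individual of `%s` despite positive propensity",
               species[sp])
    pick <- min(lc, floor(stats::runif(1) * lc) + 1)
    node <- living[[sp]][pick]
    living[[sp]][pick] <<- living[[sp]][lc]
    lcount[sp] <<- lc - 1L
    pop[sp] <<- pop[sp] - 1
    products <- r_out[[ch_rule[ch]]][[ch_out[ch]]]
    np <- length(products)
    nd_end[node] <<- t
    nd_cause[node] <<- if (np) .CAUSE_DIVISION else .CAUSE_DEATH
    c1 <- 0L; c2 <- 0L
    if (np >= 1L) c1 <- spawn_child(products[1L], node, sp, TRUE)
    if (np >= 2L) c2 <- spawn_child(products[2L], node, sp, TRUE)
    channel_counts[ch] <<- channel_counts[ch] + 1
    if (nev + 1L > ecap) grow_events()
    k <- nev <<- nev + 1L
    ev_t[k] <<- t; ev_ch[k] <<- ch; ev_parent[k] <<- node
    ev_c1[k] <<- c1; ev_c2[k] <<- c2
    pop_hist[k, ] <<- pop
    list(time = t, channel = ch, rule = species[sp],
         outcome = ch_out[ch], parent = node,
         children = c(c1, c2)[c(c1, c2) > 0L])
  }

  # one conditional sweep: conditions are evaluated over a snapshot of the
  # living individuals, then the transforms are applied in node-id order;
  # transform children are not re-examined until the next event
  sweep_conditionals <- function() {
    if (!has_cond) return(list())
    m_node <- integer(0); m_tgt <- integer(0)
    for (sp in cond_sp) {
      lc <- lcount[sp]
      if (lc == 0L) next
      ids <- living[[sp]][seq_len(lc)]
      claimed <- logical(lc)
      for (cond in conds_by_sp[[sp]]) {
        values <- lapply(cond$cols1, function(cc) smat[ids, cc])
        names(values) <- cond$vars
        sel <- cond$fn(values, ctx)
        sel <- !is.na(sel) & sel & !claimed
        if (any(sel)) {
          claimed <- claimed | sel
          m_node <- c(m_node, ids[sel])
          m_tgt <- c(m_tgt, rep(cond$target, sum(sel)))
        }
      }
    }
    if (!length(m_node)) return(list())
    ord <- order(m_node)
    m_node <- m_node[ord]; m_tgt <- m_tgt[ord]
    out <- vector("list", length(m_node))
    for (i in seq_along(m_node)) {
      node <- m_node[i]; tgt <- m_tgt[i]
      sp <- nd_sp[node]
      remove_living(sp, node)
      nd_end[node] <<- t
      child <- 0L
      if (tgt == 0L) {
        nd_cause[node] <<- .CAUSE_DEATH
        nd_cond[node] <<- TRUE
      } else {
        nd_cause[node] <<- .CAUSE_TRANSFORM
        child <- spawn_child(tgt, node, sp, FALSE)
      }
      if (ntr + 1L > tcap) {
        new <- tcap * 2L
        length(tr_t) <<- new; length(tr_ev) <<- new
        length(tr_node) <<- new; length(tr_child) <<- new
        length(tr_tgt) <<- new
        tcap <<- new
      }
      k <- ntr <<- ntr + 1L
      tr_t[k] <<- t; tr_ev[k] <<- nev
      tr_node[k] <<- node; tr_child[k] <<- child; tr_tgt[k] <<- tgt
      out[[i]] <- list(node = node, species = species[sp],
                       target = if (tgt == 0L) NA_character_ else species[tgt],
                       child = child)
    }
    if (nev > 0L) pop_hist[nev, ] <<- pop
    out
  }

  update_global <- function() {
    names(pop) <- species
    res <- global_fn(pop, t)
    names(pop) <- NULL
    if (!is.list(res))
      stop_stg("runtime", "global updater must return a named list")
    for (nm in names(res)) {
      si <- match(nm, species)
      ri <- if (is.na(si)) NA_integer_ else rule_of_species[si]
      if (is.na(ri))
        stop_stg("runtime", "global updater names `%s`, which has no rule", nm)
      upd <- res[[nm]]
      if (!is.null(upd$rate)) {
        if (!is.finite(upd$rate) || upd$rate < 0)
          stop_stg("runtime",
                   "global updater returned invalid rate for rule `%s`", nm)
        r_rate[ri] <<- upd$rate
      }
      if (!is.null(upd$probs)) {
        p <- upd$probs
        if (length(p) != r_nout[ri] || any(p < 0) || abs(sum(p) - 1) > 1e-9)
          stop_stg("runtime",
                   "global updater returned an invalid probability vector (sum %.9g) for rule `%s`",
                   sum(p), nm)
        r_probs[[ri]] <<- p
        ch_p[ch_rule == ri] <<- p
      }
    }
    ch_c <<- r_rate[ch_rule] * ch_p
    invisible(NULL)
  }

  # the Gillespie event loop (run_program drives this)
  loop <- function() {
    repeat {
      a <- ch_c * pop[ch_lhs]
      a0 <- sum(a)
      if (a0 <= 0) {
        end_reason <<- "extinction"
        break
      }
      u <- stats::runif(2)
      tau <- -log(u[1]) / a0
      if (t + tau > t_span) {
        end_reason <<- "span-exhausted"
        t <<- t_span
        break
      }
      t <<- t + tau
      fire(findInterval(u[2] * a0, cumsum(a)) + 1L)
      if (has_cond) sweep_conditionals()
      if (!is.null(global_fn)) update_global()
    }
  }

  set_time <- function(new_t) t <<- new_t
  get_state <- function(node, name) smat[node, state_cols[[name]]]
  set_state <- function(node, name, values) smat[node, state_cols[[name]]] <<- values

  set.seed(seed)
  for (ri in seq_len(nr)) {
    np <- as.integer(rules[[ri]]$init_pop)
    if (np > 0L) for (k in seq_len(np)) {
      id <- new_node(ri, 0L, 0)
      for (d in state_defs_by_sp[[ri]]) smat[id, d$cols] <- d$init_vec
    }
  }
  if (!legacy_first_update && !is.null(global_fn)) update_global()

  e <- environment()
  class(e) <- "stg_engine"
  e
}

#' Fire one reaction channel
#'
#' Chooses a living individual of the channel's left-hand species
#' uniformly at random, closes its lineage node at the engine's current
#' time (end cause `division` when the outcome has products, `death` for
#' the empty group), and creates one node per product species with every
#' internal-state instance updated from the parent's value.
#'
#' @param state An `stg_engine` from [engine_init()].
#' @param channel Channel index (see [translate_rules()]).
#' @return The event record: `list(time, channel, rule, outcome, parent,
#'   children)`.
#' @export
fire_event <- function(state, channel) state$fire(channel)

#' Apply conditional transitions
#'
#' Examines every living individual of each species with conditional
#' transitions against a snapshot of the engine state; individuals whose
#' condition holds are transformed into the target species (internal
#' states carried over) or, for the termination target, die.  Transform
#' children are not re-examined within the same sweep.
#'
#' @param state An `stg_engine`.
#' @return List of applied transformations (possibly empty).
#' @export
apply_conditional_transitions <- function(state) state$sweep_conditionals()

#' Re-evaluate environment-dependent rates and probabilities
#'
#' Invokes the program's global updater with the current population sizes
#' and time, overwrites each named rule's rate and branch probabilities,
#' and rebuilds the channel rates so that the per-rule channel sum again
#' equals the rule rate.
#'
#' @param state An `stg_engine`.
#' @return The state, invisibly; no-op when the program has no updater.
#' @export
update_global_parameters <- function(state) {
  if (!is.null(state$global_fn)) state$update_global()
  invisible(state)
}

# --- run loop ---------------------------------------------------------------

#' Execute a program
#'
#' Runs the Gillespie direct-method event loop: sample (tau, channel),
#' halt when the tentative event time would exceed the span (the event is
#' discarded, the clock stops at the span, and living individuals are
#' censored there) or when the total propensity reaches zero (extinction);
#' otherwise fire the event, apply conditional transitions, and re-run
#' the global updater.  The result is bit-reproducible for identical
#' `(program, seed, t_span)`.
#'
#' @inheritParams engine_init
#' @return An object of class `stg_run`: `seed`, `end_time`, `end_reason`
#'   (`"span-exhausted"` or `"extinction"`), `events` (one row per fired
#'   event), `transforms` (conditional transformations), `channel_counts`,
#'   `population` (times and per-species sizes at every event), and
#'   `forest` (the complete lineage, class `stg_forest`).
#' @examples
#' run <- run_program(fixture_program("stem_cell_ms"), seed = 1, t_span = 2)
#' run
#' @export
run_program <- function(program, seed = program$exec$seed,
                        t_span = program$exec$sim_time,
                        legacy_first_update = FALSE) {
  e <- engine_init(program, seed, t_span, legacy_first_update)
  e$loop()
  finalize_run(e)
}

finalize_run <- function(e) {
  end_time <- e$t
  n <- e$n
  nd_cause <- e$nd_cause[seq_len(n)]
  nd_end <- e$nd_end[seq_len(n)]
  alive <- which(nd_cause == .CAUSE_ALIVE)
  nd_end[alive] <- end_time
  nd_cause[alive] <- .CAUSE_CENSORED

  parent <- e$nd_parent[seq_len(n)]
  children <- vector("list", n)
  has_par <- which(parent > 0L)
  if (length(has_par)) {
    spl <- split(has_par, parent[has_par])
    children[as.integer(names(spl))] <- spl
  }
  root_of <- seq_len(n)
  for (id in has_par) root_of[id] <- root_of[parent[id]]

  states <- lapply(e$state_cols, function(cols)
    e$smat[seq_len(n), cols, drop = FALSE])

  forest <- structure(list(
    n = n,
    species = e$species[e$nd_sp[seq_len(n)]],
    parent = parent,
    birth = e$nd_birth[seq_len(n)],
    end = nd_end,
    cause = .CAUSE_LABELS[nd_cause + 1L],
    by_condition = e$nd_cond[seq_len(n)],
    children = children,
    roots = which(parent == 0L),
    root_of = root_of,
    states = states,
    state_names = e$state_names_by_sp,
    state_dup = e$state_dup,
    all_species = e$species,
    t_end = end_time
  ), class = "stg_forest")

  nev <- e$nev
  events <- data.frame(
    time = e$ev_t[seq_len(nev)],
    rule = e$species[e$ch_lhs[e$ev_ch[seq_len(nev)]]],
    outcome = e$ch_out[e$ev_ch[seq_len(nev)]],
    channel = e$ev_ch[seq_len(nev)],
    parent = e$ev_parent[seq_len(nev)],
    child1 = e$ev_c1[seq_len(nev)],
    child2 = e$ev_c2[seq_len(nev)],
    stringsAsFactors = FALSE)

  ntr <- e$ntr
  transforms <- data.frame(
    time = e$tr_t[seq_len(ntr)],
    event = e$tr_ev[seq_len(ntr)],
    node = e$tr_node[seq_len(ntr)],
    species = forest$species[e$tr_node[seq_len(ntr)]],
    target = ifelse(e$tr_tgt[seq_len(ntr)] == 0L, "{0}",
                    e$species[pmax(e$tr_tgt[seq_len(ntr)], 1L)]),
    child = e$tr_child[seq_len(ntr)],
    stringsAsFactors = FALSE)

  channel_counts <- data.frame(
    channel = seq_len(e$nch),
    rule = e$species[e$ch_lhs],
    outcome = e$ch_out,
    count = e$channel_counts,
    stringsAsFactors = FALSE)

  init_row <- numeric(e$ns)
  for (ri in seq_along(e$rules))
    init_row[ri] <- e$rules[[ri]]$init_pop
  sizes <- rbind(init_row, e$pop_hist[seq_len(nev), , drop = FALSE])
  dimnames(sizes) <- list(NULL, e$species)

  structure(list(
    seed = e$seed,
    t_span = e$t_span,
    end_time = end_time,
    end_reason = e$end_reason,
    events = events,
    transforms = transforms,
    channel_counts = channel_counts,
    population = list(times = c(0, e$ev_t[seq_len(nev)]), sizes = sizes),
    forest = forest,
    species = e$species
  ), class = "stg_run")
}

#' @export
print.stg_run <- function(x, ...) {
  cat(sprintf(
    "Grammar simulation run (seed %d): %d events, %d nodes, end %s at t = %g\n",
    x$seed, nrow(x$events), x$forest$n, x$end_reason, x$end_time))
  final <- x$population$sizes[nrow(x$population$sizes), ]
  cat("  final populations:",
      paste(sprintf("%s = %g", names(final), final), collapse = ", "), "\n")
  invisible(x)
}

#' Execute a program under several seeds
#'
#' Performs independent replicate executions, one per seed; each run
#' depends only on `(program, seed, t_span)`, so replicates form a
#' stochastic sample from the space of possible outcomes.
#'
#' @inheritParams run_program
#' @param seeds Non-empty integer vector of seeds.  Duplicate seeds are
#'   allowed (they produce identical runs) but draw a warning.
#' @return A list of `stg_run`, in seed order.
#' @export
run_batch <- function(program, seeds, t_span = program$exec$sim_time,
                      legacy_first_update = FALSE) {
  if (!length(seeds)) stop_stg("validation", "`seeds` must be non-empty")
  if (anyDuplicated(seeds))
    warning("duplicate seeds produce identical runs", call. = FALSE)
  if (!isTRUE(program$validated)) program <- validate_program(program)
  lapply(seeds, function(s)
    run_program(program, seed = s, t_span = t_span,
                legacy_first_update = legacy_first_update))
}
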