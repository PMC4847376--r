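---
title: "Simulating population dynamics as stochastic tree grammars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating population dynamics as stochastic tree grammars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgsim)
```

## The model

`stgsim` simulates populations described by context-free stochastic
rewrite rules.  Each species `A` has at most one rule

```
A --(r)--> {S1}_p1 | {S2}_p2 | ... | {Sn}_pn
```

with per-capita rate `r` and branch probabilities summing to one; each
outcome group is empty (the individual dies), one species, or two
species.  The `ow` ("otherwise") sentinel in a program file stands for
one minus the sum of the other branch probabilities, so a 49 %/51 %
birth–death rule can be written `{A,A}_0.49 | {phi}_ow`.

Individuals of the same species are exchangeable, so the process is
simulated at population level: each rule is expanded into `n` reaction
channels `A --(c_i)--> S_i` with `c_i = r * p_i`, the propensity of a
channel is `c_i` times the current population of `A`, and events are
sampled exactly with the Gillespie direct method — waiting time
`tau = ln(1/u1)/a0` for total propensity `a0`, and the channel is the
first whose cumulative propensity exceeds `u2 * a0`.  When an event
fires, the firing individual is drawn uniformly among the living members
of the left-hand species; exchangeability under mass-action kinetics
makes this the unique consistent choice.

The formalism deliberately abstracts away direct interactions between
individuals.  Environment dependence enters only through the *global
updating function*, which after every event (and once at `t = 0`) may
rewrite each rule's rate and probabilities as a function of all
population sizes and the elapsed time.  The bundled predator–prey
program is the canonical example: with constants `c1, c2, c3` it sets

```
r1 = c1 + c2*|Predator|    p1 = c1/r1            (prey birth vs death)
r2 = c2*|Prey| + c3        p2 = c2*|Prey|/r2     (predator birth vs death)
```

so each rule's birth channel carries the familiar mass-action term and
its death channel the complementary one, and the stochastic system
oscillates around the deterministic predator–prey cycle.

## Lineage recording

Every individual ever alive becomes a node of a lineage forest: one root
per initial individual, `birth_time`, `end_time`, an end cause
(`division`, `death`, `transform`, or `censored` for individuals still
alive when the clock stops), parent and children links, and the values
of all internal states.  Products of a rule are always *new* nodes, even
when a species rewrites into itself: the rewrite semantics keeps the
forest a strict tree and makes extinct sub-lineages first-class data.
This is the package's reason to exist — population curves are derivable
from the forest, but the forest (including its dead branches) is not
derivable from population curves.

Trees export to Newick with labels `<species>_<node id>` (suffix `_dead`
on death-terminated leaves) and branch length equal to the node's life
span.  With `living_only = TRUE` dead subtrees are pruned and the
resulting unary chains collapsed, summing branch lengths — the view a
phylogeny of sampled extant individuals would show.  Several trees can
be joined under a zero-length pseudo-root (`merge_forest()`); the
pseudo-root is excluded from every statistic.

## Internal states and their updaters

A species may declare internal states with an initial value, an updater
binding and a duplication number `dup` (how many independent instances
each individual carries).  At every division, each child's state
instances are computed by applying the state's updater to the parent's
values — independently per child and per instance.  A state the parent's
species does not carry is initialised to its declared initial value on
the child; this is how "set the generation counter to 1 at
differentiation" is expressed without a special case.  Conditional
transformations copy shared states unchanged, drop states the target
species lacks, and initialise states new to the target.

Built-in updaters:

* `ms_step(p)` — symmetric stepwise microsatellite mutation: the repeat
  count changes by +1 or −1, each with probability `p/2`, per locus per
  division.  Default `p = 0.01` per locus per division, a plausible
  somatic microsatellite rate; repeat counts default to 30 and are
  stored as integer-valued reals for simple export.
* `gen_increment` — exact generation counter, `x + 1`.
* `stochastic_counter(mu, sigma)` — adds `N(mu, sigma)` per event;
  defaults `mu = 1`, `sigma = 0.1` make it a noisy event clock.
* `lotka_volterra(c1, c2, c3)` and `clone_expansion(species, cap, rate)`
  — global updaters described above and below.

User code can register additional updaters (`register_updater()`).
Program files themselves may bind a state updater to a small arithmetic
expression (e.g. `x + normrnd(1, 0.1)`), checked against a whitelist of
arithmetic, comparison and a few math primitives plus `pop("Species")`
and `time()`.  The same dialect powers conditional expressions.  The
whitelist is the design decision: it preserves the expressiveness of
configurable updaters without ever evaluating arbitrary host code found
in a configuration file.  Global updaters, whose contract returns a
rate and a probability vector per rule, must be registered functions
(built-in or user-supplied); a scalar expression cannot express that
contract, so the dialect does not apply to them.

## Conditional transitions

After every fired event, each living individual of a species with
conditional transitions is checked against a snapshot of the state; if
its condition holds (conditions may reference only that species' own
`dup = 1` states), the individual transforms into the target species or
— for the `{0}` target — dies.  The sweep is a single pass in node-id
order, and children created by a transformation are not re-examined
until the next event.  A single pass prevents unbounded transform
cascades within one instant and keeps execution deterministic; whether a
multi-pass semantics would ever differ in practice depends on programs
where a transform's carry-over immediately satisfies the target's own
condition, which the bundled programs avoid by construction (thresholds
5 and 10 on a shared monotone counter).

## Timing of global updates

Program files carry placeholder rates and probabilities for rules
governed by a global updater (the bundled predator–prey file uses 1 and
0.5).  By default the engine invokes the updater once at `t = 0`, so the
very first waiting time is already sampled under the environment-
dependent parameters; the placeholders then only seed the document.  The
alternative convention — sample the first event under the placeholders
and correct the parameters immediately after it fires — is available as
`legacy_first_update = TRUE` for compatibility with tools that behave
that way.  The default was chosen because a placeholder-driven first
event is an artefact of file encoding, not a modelling intent; with
per-capita rates near 19 the difference is confined to the first ~0.05
time units but is visible in a bit-exact event log.

The updater also runs after every event, including events whose
population change came only from conditional transformations.

## Numerical and determinism choices

* One random stream per run, seeded by the run seed.  Draw order per
  event is fixed: `u1` (waiting time), `u2` (channel), `u3` (which
  individual fires), then updater draws in child order × state order ×
  duplicate order.  Identical `(program, seed, span)` reproduce the run
  bit for bit across sessions.
* Channel choice uses the cumulative-sum rule via `findInterval`;
  zero-propensity channels are unreachable, and ties occur with
  probability zero.
* An event whose tentative time exceeds the span is discarded, the clock
  stops at the span, and living individuals are censored there (their
  Newick branch runs to the span).  A total propensity of zero ends the
  run as `extinction`.
* Branch probabilities must sum to 1 within `1e-12` at validation;
  global updaters must return probability vectors summing to 1 within
  `1e-9` (they typically involve division by a computed rate) and
  non-negative rates, otherwise the run aborts naming the rule.
* Newick branch lengths are written with 12 significant digits so that a
  round-trip through an external parser preserves them to `1e-9` even
  for spans of order 10–100.
* Node ids are assigned in creation order from 1 (the merged pseudo-root
  uses 0), so a child's id always exceeds its parent's; several
  algorithms (pruning, root lookup) rely on that monotonicity.
* Species whose probability placeholder `ow` resolves at validation keep
  their authored form when a program is serialized, so
  parse→validate→serialize→parse is the identity on program structure.

Programs may declare `<Sink>` species: species with no rule of their
own that only arise as products and never fire.  They keep
otherwise-identical programs valid when one species is deliberately
inert (the critical-branching test below uses an inert differentiated
compartment), while a typo in a product name is still rejected.

## Bundled programs and the conditions they encode

Four programs ship with the package and double as the test bed.  Where
the scenario fixes parameters (rates 0.1 and 1, branch probabilities
50/50 and 49/51, counter increments `N(1, 0.1)`, thresholds 5 and 10,
900/900 founders over 10 time units for the predator–prey program) the
files carry them verbatim.  Initial conditions the scenarios leave open
were chosen once for the package, balancing statistical information
against desk-scale runtimes:

* `stem_cell_ms` — 100 stem cells, span 10: about 100 stem-cell firings
  and 500 differentiated-cell firings per run, so replicate batches
  accumulate tens of thousands of observations in seconds.
* `conditional_toy` — 10 asymmetric founders, span 30: long enough for
  symmetric stem cells to cross the transform threshold and for
  differentiated cells to reach the death threshold.
* `lotka_volterra` — constants `c1 = c3 = 10`, `c2 = 0.01`, giving an
  oscillation period of about 0.63 time units around the 1000/1000
  equilibrium, clearly visible within the 10-unit span (~4×10⁵ events).
* `clone_expansion` — a founder seeds single cells at rate 0.5; each
  cell divides at rate 1 until the population reaches the 1000-cell cap,
  at which point the global updater zeroes the division rate.  This file
  is a synthetic analogue of repeated single-cell clonal-expansion
  experiments, not a reproduction of any specific published run.

## What the simulations do and do not show

The test suite validates the engine against closed forms: pure-birth
growth matches the Yule mean `N0·e^{λt}`; the critical stem-cell rule
(birth and loss each 50 % at rate 0.1) keeps a flat mean; the 49/51
rule at rate 1 decays like `e^{-0.02 t}`; waiting times pass a
Kolmogorov–Smirnov test against `Exponential(a0)`; and simulated firing
fractions and per-capita rate estimates recover the programmed
parameters within three standard errors.  Batch sizes in the suite
(200–500 replicates, 10⁴ observations for parameter recovery) were
chosen so each check resolves its own 3-standard-error band.

These checks certify the simulator, not any biological claim: the
programs assume exchangeable individuals, exponential waiting times,
at most two products per event, and no direct individual-to-individual
interaction — environment dependence is mediated entirely by global
population sizes and time.  Real lineages violate several of these
(cell-cycle refractoriness makes waiting times non-exponential; niches
impose spatial interactions).  Passing tests therefore demonstrate
correct execution of the formalism, and transfer to real data only as
far as the formalism itself does.

## Known limitations

* The event loop is interpreted R (~4×10³–10⁴ events/second with
  lineage recording); runs beyond ~10⁶ events or populations beyond
  ~10⁴ call for a compiled engine or tau-leaping, both out of scope —
  the engine is exact by design.
* Conditional transitions are checked after events, not in continuous
  time: a condition that becomes true between events is acted upon at
  the next event.  With event rates well above the conditions' time
  scale (as in the bundled programs) the discretisation is negligible.
* Memory holds the full forest; a 10⁶-event run occupies a few hundred
  MB across node arrays and state matrices.
* The archive format favours human-diffable TSV over compactness.
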