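# Build a forest by hand for exact-output checks.
make_forest <- function(species, parent, birth, end, cause, t_end,
                        states = list(), state_names = NULL) {
  n <- length(species)
  children <- vector("list", n)
  has_par <- which(parent > 0L)
  if (length(has_par)) {
    spl <- split(has_par, parent[has_par])
    children[as.integer(names(spl))] <- spl
  }
  root_of <- seq_len(n)
  for (id in has_par) root_of[id] <- root_of[parent[id]]
  all_sp <- unique(species)
  if (is.null(state_names))
    state_names <- stats::setNames(rep(list(character(0)), length(all_sp)), all_sp)
  structure(list(
    n = n, species = species, parent = as.integer(parent),
    birth = birth, end = end, cause = cause,
    by_condition = rep(FALSE, n), children = children,
    roots = which(parent == 0L), root_of = root_of,
    states = states, state_names = state_names,
    state_dup = vapply(states, ncol, integer(1)),
    all_species = all_sp, t_end = t_end), class = "stg_forest")
}

test_that("living counts follow birth <= t < end with censoring through the span", {
  f1 <- make_forest("A", 0L, 0, 5, "censored", 5)
  expect_equal(living_population(f1, 0)[["A"]], 1L)
  expect_equal(living_population(f1, 5)[["A"]], 1L)

  f2 <- make_forest(c("A", "A", "A"), c(0L, 1L, 1L), c(0, 2, 2),
                    c(2, 5, 5), c("division", "censored", "censored"), 5)
  expect_equal(living_population(f2, 1)[["A"]], 1L)
  expect_equal(living_population(f2, 3)[["A"]], 2L)
  expect_error(living_population(f2, 6), class = "stg_validation_error")
  expect_error(living_population(f2, -1), class = "stg_validation_error")
})

test_that("forest counts at the end of a run equal the engine's population series", {
  run <- cached("toy_run", run_program(fixture_program("conditional_toy"),
                                       seed = 2, t_span = 20))
  lp <- living_population(run$forest, run$end_time)
  final <- run$population$sizes[nrow(run$population$sizes), ]
  expect_equal(lp[names(final)], final[names(final)],
               ignore_attr = TRUE)
  # and at an interior time point the counts partition over roots
  mid <- run$end_time / 2
  total <- sum(living_population(run$forest, mid))
  per_root <- table(factor(run$forest$root_of[stgsim:::.alive_at(run$forest, mid)],
                           levels = run$forest$roots))
  expect_equal(sum(per_root), total)
})

test_that("Newick output matches hand-constructed trees", {
  f <- make_forest(c("A", "A", "A"), c(0L, 1L, 1L), c(0, 2, 2),
                   c(2, 5, 5), c("division", "censored", "censored"), 5)
  expect_equal(to_newick(f), "(A_2:3,A_3:3)A_1:2;")

  chain <- make_forest(c("SCSym", "Diff"), c(0L, 1L), c(0, 4), c(4, 10),
                       c("transform", "censored"), 10)
  expect_equal(to_newick(chain), "(Diff_2:6)SCSym_1:4;")

  dead <- make_forest(c("A", "A", "A"), c(0L, 1L, 1L), c(0, 2, 2),
                      c(2, 3, 5), c("division", "death", "censored"), 5)
  expect_equal(to_newick(dead), "(A_2_dead:1,A_3:3)A_1:2;")
  # living-only pruning collapses the unary chain left by the dead child
  expect_equal(to_newick(dead, living_only = TRUE), "A_3:5;")
})

test_that("living-only export errors on a fully extinct tree", {
  f <- make_forest("A", 0L, 0, 1, "death", 2)
  expect_error(to_newick(f, living_only = TRUE), "living",
               class = "stg_validation_error")
})

test_that("Newick round-trips through an independent parser", {
  p <- fixture_program("stem_cell_ms")
  trees_checked <- 0L
  for (seed in 1:30) {
    run <- run_program(p, seed = seed, t_span = 1.5)
    f <- run$forest
    branched <- f$roots[lengths(f$children[f$roots]) > 0L]
    for (root in branched[sample.int(length(branched), min(4, length(branched)))]) {
      nwk <- to_newick(f, root = root)
      tr <- ape::read.tree(text = nwk)
      labs <- c(tr$tip.label, tr$node.label)
      ids <- as.integer(sub("_dead$", "", sub("^[A-Za-z]+_", "", labs)))
      # topology: the parent of every edge's child node is preserved
      child_ids <- ids[tr$edge[, 2]]
      parent_ids <- ids[tr$edge[, 1]]
      expect_equal(f$parent[child_ids], parent_ids)
      # branch lengths: each edge is the child's life span, to 1e-9
      expect_equal(tr$edge.length, f$end[child_ids] - f$birth[child_ids],
                   tolerance = 1e-9)
      # the root's own life span is carried as the root edge
      expect_equal(tr$root.edge, f$end[root] - f$birth[root],
                   tolerance = 1e-9)
      trees_checked <- trees_checked + 1L
    }
  }
  expect_gte(trees_checked, 100L)
})

test_that("merging joins trees under a zero-length pseudo-root excluded from stats", {
  f <- make_forest(c("A", "B"), c(0L, 0L), c(0, 0), c(5, 5),
                   c("censored", "censored"), 5)
  m <- merge_forest(f, c(1L, 2L))
  expect_equal(to_newick(m), "(A_1:5,B_2:5)__merged___0:0;")
  expect_error(merge_forest(f, 1L), "two roots", class = "stg_validation_error")
  expect_error(merge_forest(f, c(1L, 99L)), class = "stg_validation_error")

  run <- cached("toy_run", run_program(fixture_program("conditional_toy"),
                                       seed = 2, t_span = 20))
  roots <- run$forest$roots
  m2 <- merge_forest(run$forest, roots)
  t <- run$end_time / 3
  merged_counts <- living_population(m2, t)
  expect_equal(sum(merged_counts), sum(living_population(run$forest, t)))
  expect_false("__merged__" %in% names(merged_counts))
})

test_that("internal-state tables expand duplicates and track generations", {
  p <- fixture_program("stem_cell_ms")
  e <- engine_init(p, seed = 3, t_span = 10)
  e$t <- 1; ev1 <- fire_event(e, 2L)   # differentiation: Gen = 1
  e$t <- 2; ev2 <- fire_event(e, 3L)   # Diff division: Gen = 2
  f <- stgsim:::finalize_run(e)$forest

  gen <- internal_state_table(f, "Gen")
  expect_equal(sort(unique(gen$value_at_birth)), c(1, 2))
  expect_equal(gen$value_at_birth[match(ev2$children, gen$node_id)], c(2, 2))
  expect_true(all(gen$species == "Diff"))  # SC does not carry Gen

  ms <- internal_state_table(f, "MS")
  expect_equal(sum(ms$node_id == 1), 3L)   # dup = 3: three rows per node
  expect_equal(ms$dup_index[ms$node_id == 1], 1:3)
  expect_error(internal_state_table(f, "NoSuchState"),
               class = "stg_validation_error")
})

test_that("a state whose carrier species never arises yields an empty table", {
  p <- fixture_program("stem_cell_ms")
  prog_run <- run_program(p, seed = 1, t_span = 1e-4)  # no differentiation yet
  gen <- internal_state_table(prog_run$forest, "Gen")
  expect_equal(nrow(gen), 0L)
  expect_true(all(c("node_id", "dup_index", "value_at_birth") %in% names(gen)))
})

test_that("edge times are consistent across every fixture run", {
  for (nm in c("stem_cell_ms", "conditional_toy")) {
    run <- run_program(fixture_program(nm), seed = 4, t_span = 5)
    f <- run$forest
    kids <- which(f$parent > 0L)
    expect_true(all(f$birth[kids] == f$end[f$parent[kids]]), info = nm)
    expect_true(all(f$birth <= f$end))
    internal <- f$cause %in% c("division", "transform")
    n_kids <- lengths(f$children)
    expect_true(all(n_kids[internal] >= 1L))
    expect_true(all(n_kids[!internal] == 0L))
    expect_true(all(n_kids[f$cause == "transform"] == 1L))
  }
})
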