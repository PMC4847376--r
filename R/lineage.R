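# Lineage forest queries and exports.  A forest (class `stg_forest`,
# built by the engine) stores every individual ever alive as flat,
# id-indexed arrays; node ids are assigned in creation order starting at
# 1, so a child's id is always larger than its parent's.

#' Count living individuals at a time point
#'
#' A node is alive at `t` when `birth <= t < end`; censored nodes (still
#' alive when the run halted) count as alive through the halt time.
#'
#' @param forest An `stg_forest` (from a run) or the result of
#'   [merge_forest()] (counts are then restricted to the merged trees).
#' @param t Time point in `[0, t_end]` of the run.
#' @param species Optional species name filter.
#' @param ... Passed between methods.
#' @return Named integer vector of counts per species (all species of the
#'   program, or just the requested one).
#' @export
living_population <- function(forest, t, species = NULL, ...) {
  UseMethod("living_population")
}

.alive_at <- function(forest, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > forest$t_end)
    stop_stg("validation", "`t` must lie in [0, %g]", forest$t_end)
  forest$birth <= t &
    (forest$end > t | (forest$cause == "censored" & forest$end >= t))
}

#' @export
living_population.stg_forest <- function(forest, t, species = NULL, ...) {
  alive <- .alive_at(forest, t)
  lv <- forest$all_species
  counts <- table(factor(forest$species[alive], levels = lv))
  out <- stats::setNames(as.integer(counts), lv)
  if (!is.null(species)) {
    if (!all(species %in% lv))
      stop_stg("validation", "unknown species `%s`",
               setdiff(species, lv)[1])
    out <- out[species]
  }
  out
}

#' @export
living_population.stg_merged <- function(forest, t, species = NULL, ...) {
  f <- forest$forest
  alive <- .alive_at(f, t) & f$root_of %in% forest$roots
  lv <- f$all_species
  counts <- table(factor(f$species[alive], levels = lv))
  out <- stats::setNames(as.integer(counts), lv)
  if (!is.null(species)) out <- out[species]
  out
}

#' Export a lineage tree in Newick format
#'
#' Node labels are `<species>_<node id>`, with the suffix `_dead` on
#' death-terminated leaves; the branch length of every node is its life
#' span `end - birth` (censored nodes: halt time minus birth).  Branch
#' lengths are written with 12 significant digits and internal node labels
#' are emitted, giving a plain-label dialect any standard parser accepts.
#' With `living_only = TRUE` dead subtrees are pruned and unary chains
#' are collapsed, summing branch lengths along the chain.
#'
#' @param forest An `stg_forest` or [merge_forest()] result.
#' @param root Root node id; may be omitted when the forest has a single
#'   root (merged forests always export from their pseudo-root).
#' @param living_only Prune lineages without living (censored) descendants.
#' @param ... Passed between methods.
#' @return A Newick string terminated by `";"`.
#' @examples
#' run <- run_program(fixture_program("stem_cell_ms"), seed = 1, t_span = 1)
#' nwk <- to_newick(run$forest, root = run$forest$roots[1])
#' @export
to_newick <- function(forest, ...) UseMethod("to_newick")

.nwk_label <- function(forest, id, leaf) {
  lab <- paste0(forest$species[id], "_", id)
  if (leaf && forest$cause[id] == "death") lab <- paste0(lab, "_dead")
  lab
}

.nwk_build <- function(forest, id) {
  kids <- forest$children[[id]]
  bl <- sprintf("%.12g", forest$end[id] - forest$birth[id])
  if (is.null(kids) || !length(kids))
    return(paste0(.nwk_label(forest, id, TRUE), ":", bl))
  inner <- vapply(kids, function(k) .nwk_build(forest, k), character(1))
  paste0("(", paste(inner, collapse = ","), ")",
         .nwk_label(forest, id, FALSE), ":", bl)
}

# keep[i]: node i is censored-living or has a living descendant
.living_keep <- function(forest) {
  keep <- forest$cause == "censored"
  for (id in rev(seq_len(forest$n))) {
    if (keep[id] && forest$parent[id] > 0L) keep[forest$parent[id]] <- TRUE
  }
  keep
}

.nwk_build_living <- function(forest, id, keep, acc = 0) {
  kids <- forest$children[[id]]
  kids <- kids[keep[kids]]
  len <- forest$end[id] - forest$birth[id] + acc
  if (!length(kids))
    return(paste0(.nwk_label(forest, id, TRUE), ":", sprintf("%.12g", len)))
  if (length(kids) == 1L)
    return(.nwk_build_living(forest, kids, keep, len))
  inner <- vapply(kids, function(k) .nwk_build_living(forest, k, keep, 0),
                  character(1))
  paste0("(", paste(inner, collapse = ","), ")",
         .nwk_label(forest, id, FALSE), ":", sprintf("%.12g", len))
}

#' @rdname to_newick
#' @export
to_newick.stg_forest <- function(forest, root = NULL, living_only = FALSE, ...) {
  if (is.null(root)) {
    if (length(forest$roots) != 1L)
      stop_stg("validation", "forest has %d roots; specify `root`",
               length(forest$roots))
    root <- forest$roots
  }
  if (!root %in% forest$roots)
    stop_stg("validation", "node %s is not a root of this forest", root)
  if (living_only) {
    keep <- .living_keep(forest)
    if (!keep[root])
      stop_stg("validation", "tree rooted at %d has no living descendants", root)
    return(paste0(.nwk_build_living(forest, root, keep), ";"))
  }
  paste0(.nwk_build(forest, root), ";")
}

#' @rdname to_newick
#' @export
to_newick.stg_merged <- function(forest, living_only = FALSE, ...) {
  f <- forest$forest
  sub <- vapply(forest$roots, function(r) {
    if (living_only) {
      keep <- .living_keep(f)
      if (!keep[r])
        stop_stg("validation", "tree rooted at %d has no living descendants", r)
      .nwk_build_living(f, r, keep)
    } else .nwk_build(f, r)
  }, character(1))
  paste0("(", paste(sub, collapse = ","), ")__merged___0:0;")
}

#' Merge several lineage trees under a synthetic root
#'
#' Joins the selected trees under a zero-length pseudo-root of species
#' `__merged__` (node id 0) for joint display and export.  The pseudo-root
#' is display plumbing: it is excluded from every statistic, and the
#' underlying forest is left unmodified.
#'
#' @param forest An `stg_forest`.
#' @param roots At least two root node ids (defaults to all roots).
#' @return An object of class `stg_merged`.
#' @export
merge_forest <- function(forest, roots = forest$roots) {
  if (!inherits(forest, "stg_forest"))
    stop_stg("validation", "`forest` must be an stg_forest")
  if (length(roots) < 2L)
    stop_stg("validation", "merging requires at least two roots")
  if (!all(roots %in% forest$roots))
    stop_stg("validation", "unknown root id(s): %s",
             paste(setdiff(roots, forest$roots), collapse = ", "))
  structure(list(forest = forest, roots = as.integer(roots)),
            class = "stg_merged")
}

#' Tabulate internal-state values across a forest
#'
#' One row per node per duplicate instance of the state, for every node
#' whose species defines the state: node id, species, birth and end time,
#' duplicate index, and the state value at birth and at end.  Values
#' change only when a transition creates a child, so a node's value is
#' constant over its life span and both value columns coincide; they are
#' emitted separately to keep the table self-describing.
#'
#' @param forest An `stg_forest`.
#' @param state_name Name of the internal state.
#' @param path Optional path; when given, the table is written as
#'   tab-separated text with a header row.
#' @return A data frame (invisibly when written to `path`).
#' @export
internal_state_table <- function(forest, state_name, path = NULL) {
  if (!state_name %in% names(forest$states))
    stop_stg("validation", "unknown internal state `%s`", state_name)
  carriers <- names(forest$state_names)[vapply(forest$state_names, function(x)
    state_name %in% x, logical(1))]
  ids <- which(forest$species %in% carriers)
  dup <- ncol(forest$states[[state_name]])
  tab <- data.frame(
    node_id = rep(ids, each = dup),
    species = rep(forest$species[ids], each = dup),
    birth_time = rep(forest$birth[ids], each = dup),
    end_time = rep(forest$end[ids], each = dup),
    dup_index = rep(seq_len(dup), times = length(ids)),
    value_at_birth = as.vector(t(forest$states[[state_name]][ids, , drop = FALSE])),
    stringsAsFactors = FALSE)
  tab$value_at_end <- tab$value_at_birth
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @export
print.stg_forest <- function(x, ...) {
  cat(sprintf("Lineage forest: %d nodes, %d roots, span [0, %g]\n",
              x$n, length(x$roots), x$t_end))
  cat("  end causes:", paste(sprintf("%s = %d", names(table(x$cause)),
                                     as.integer(table(x$cause))),
                             collapse = ", "), "\n")
  invisible(x)
}
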