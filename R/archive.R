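# Run archives: a structured directory holding the program snapshot, the
# per-run event logs, node tables (with internal-state values), population
# series, channel counts and Newick exports, plus a JSON manifest.  An
# archive reloads into `stg_run` objects that reproduce every statistic
# bit-identically without re-simulation (numbers are serialized with 17
# significant digits, enough to round-trip doubles).

.fmt <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else as.character(x)
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- .fmt(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.nodes_table <- function(forest) {
  tab <- data.frame(
    node_id = seq_len(forest$n),
    species = forest$species,
    parent = forest$parent,
    birth_time = forest$birth,
    end_time = forest$end,
    end_cause = forest$cause,
    by_condition = as.integer(forest$by_condition),
    stringsAsFactors = FALSE)
  for (nm in names(forest$states)) {
    m <- forest$states[[nm]]
    for (k in seq_len(ncol(m)))
      tab[[sprintf("%s.%d", nm, k)]] <- m[, k]
  }
  tab
}

#' Run a program file and archive the full history
#'
#' Parses and validates a program file, executes it once per seed, and
#' writes a self-contained archive directory: the program snapshot, a
#' JSON manifest (seeds, span, per-run end states, package version), and
#' per-run tab-separated event logs, transform logs, node tables with
#' internal-state values, population series, channel counts, plus Newick
#' exports of the lineage trees.
#'
#' @param program_path Path to a program XML file.
#' @param seeds Integer vector of run seeds.
#' @param out_dir Archive directory (created, may exist).
#' @param t_span Simulation span; default the program's `SimTime`.
#' @param merge Export one merged Newick tree per run instead of one
#'   tree line per root.
#' @param living_only Prune dead lineages from the Newick exports.
#' @param legacy_first_update See [engine_init()].
#' @param registry Updater registry for validation.
#' @return Invisibly, the list of `stg_run` objects.
#' @seealso [load_archive()], [cmd_stats()]
#' @export
cmd_run <- function(program_path, seeds, out_dir,
                    t_span = NULL, merge = FALSE, living_only = FALSE,
                    legacy_first_update = FALSE,
                    registry = default_registry()) {
  prog <- validate_program(parse_program(program_path), registry)
  if (is.null(t_span)) t_span <- prog$exec$sim_time
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(program_path, file.path(out_dir, "program.xml"), overwrite = TRUE)

  info <- vector("list", length(seeds))
  runs <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    run <- run_program(prog, seed = seeds[i], t_span = t_span,
                       legacy_first_update = legacy_first_update)
    rd <- file.path(out_dir, sprintf("run_%d", seeds[i]))
    dir.create(rd, showWarnings = FALSE)
    .write_tsv(run$events, file.path(rd, "events.tsv"))
    .write_tsv(run$transforms, file.path(rd, "transforms.tsv"))
    .write_tsv(.nodes_table(run$forest), file.path(rd, "nodes.tsv"))
    pop <- data.frame(time = run$population$times, run$population$sizes,
                      check.names = FALSE)
    .write_tsv(pop, file.path(rd, "population.tsv"))
    .write_tsv(run$channel_counts, file.path(rd, "channels.tsv"))
    nwk <- if (merge && length(run$forest$roots) > 1L) {
      to_newick(merge_forest(run$forest), living_only = living_only)
    } else {
      ok <- run$forest$roots
      if (living_only) {
        keep <- .living_keep(run$forest)
        ok <- ok[keep[ok]]
      }
      vapply(ok, function(r)
        to_newick(run$forest, root = r, living_only = living_only),
        character(1))
    }
    writeLines(nwk, file.path(rd, "forest.nwk"))
    for (nm in names(run$forest$states))
      internal_state_table(run$forest, nm,
                           file.path(rd, sprintf("state_%s.tsv", nm)))
    info[[i]] <- list(seed = seeds[i], end_time = run$end_time,
                      end_reason = run$end_reason,
                      n_events = nrow(run$events), n_nodes = run$forest$n)
    runs[[i]] <- run
  }
  manifest <- list(
    tool = "stgsim",
    version = as.character(utils::packageVersion("stgsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    program = "program.xml",
    t_span = t_span,
    legacy_first_update = legacy_first_update,
    seeds = as.integer(seeds),
    runs = info)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(runs)
}

#' Reload an archive written by [cmd_run()]
#'
#' @param dir Archive directory.
#' @param registry Updater registry used to re-validate the archived
#'   program snapshot.
#' @return List of `stg_run` objects equivalent to the originals.
#' @export
load_archive <- function(dir, registry = default_registry()) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  prog <- validate_program(parse_program(file.path(dir, mf$program)), registry)
  species <- c(vapply(prog$rules, `[[`, character(1), "name"), prog$sinks)
  state_names <- lapply(prog$rules, function(r)
    vapply(r$states, `[[`, character(1), "name"))
  state_names <- c(state_names, rep(list(character(0)), length(prog$sinks)))
  names(state_names) <- species
  state_dup <- integer(0)
  for (r in prog$rules) for (s in r$states) state_dup[s$name] <- s$dup

  lapply(seq_along(mf$seeds), function(i) {
    seed <- mf$seeds[i]
    rd <- file.path(dir, sprintf("run_%d", seed))
    rt <- function(f) utils::read.table(file.path(rd, f), sep = "\t",
                                        header = TRUE, check.names = FALSE,
                                        stringsAsFactors = FALSE)
    nodes <- rt("nodes.tsv")
    n <- nrow(nodes)
    parent <- nodes$parent
    children <- vector("list", n)
    has_par <- which(parent > 0L)
    if (length(has_par)) {
      spl <- split(has_par, parent[has_par])
      children[as.integer(names(spl))] <- spl
    }
    root_of <- seq_len(n)
    for (id in has_par) root_of[id] <- root_of[parent[id]]
    states <- lapply(names(state_dup), function(nm) {
      cols <- sprintf("%s.%d", nm, seq_len(state_dup[nm]))
      as.matrix(nodes[, cols, drop = FALSE])
    })
    names(states) <- names(state_dup)
    run_info <- mf$runs[i, , drop = FALSE]
    forest <- structure(list(
      n = n, species = nodes$species, parent = parent,
      birth = nodes$birth_time, end = nodes$end_time,
      cause = nodes$end_cause, by_condition = nodes$by_condition == 1L,
      children = children, roots = which(parent == 0L), root_of = root_of,
      states = states, state_names = state_names, state_dup = state_dup,
      all_species = species, t_end = run_info$end_time
    ), class = "stg_forest")
    pop <- rt("population.tsv")
    sizes <- as.matrix(pop[, -1, drop = FALSE])
    structure(list(
      seed = as.integer(seed), t_span = mf$t_span,
      end_time = run_info$end_time, end_reason = run_info$end_reason,
      events = rt("events.tsv"), transforms = rt("transforms.tsv"),
      channel_counts = rt("channels.tsv"),
      population = list(times = pop$time, sizes = sizes),
      forest = forest, species = species
    ), class = "stg_run")
  })
}

#' Compute and export summary statistics from an archive
#'
#' Delegates to the statistics layer: `"population"` averages the
#' per-species population size over runs, `"clones"` builds the
#' clone-size histogram, `"rules"` the rule-execution histogram and
#' `"states"` the internal-state histogram.
#'
#' @param archive Archive directory (or a list of `stg_run` objects).
#' @param which One of `"population"`, `"clones"`, `"rules"`, `"states"`.
#' @param species Species name (population averages; optional clone
#'   member filter).
#' @param t Time point for clone/state histograms; default end of span.
#' @param state Internal-state name for `"states"`.
#' @param founder_species Optional clone founder filter.
#' @param out_file Optional path for a tab-separated export.
#' @return The statistic object (data frame or `stg_histogram`).
#' @export
cmd_stats <- function(archive, which = c("population", "clones", "rules", "states"),
                      species = NULL, t = NULL, state = NULL,
                      founder_species = NULL, out_file = NULL) {
  which <- match.arg(which)
  runs <- if (is.character(archive)) load_archive(archive) else archive
  if (is.null(t)) t <- min(vapply(runs, `[[`, numeric(1), "end_time"))
  res <- switch(which,
    population = {
      if (is.null(species))
        stop_stg("validation", "`species` is required for population statistics")
      average_population(runs, species)
    },
    clones = clone_size_histogram(runs, t = t,
                                  founder_species = founder_species,
                                  member_species = species),
    rules = rule_execution_histogram(runs),
    states = {
      if (is.null(state))
        stop_stg("validation", "`state` is required for state statistics")
      internal_state_histogram(runs, state, t = t)
    })
  if (!is.null(out_file)) {
    df <- if (inherits(res, "stg_histogram"))
      data.frame(label = res$labels, count = res$counts, percent = res$percent)
    else res
    .write_tsv(df, out_file)
  }
  res
}
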