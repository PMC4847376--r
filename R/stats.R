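# Summary statistics over one or many runs: population step functions and
# their replicate averages, and the three histogram families (clone sizes,
# rule executions, internal-state values).

.step_at <- function(times, sizes, grid) {
  sizes[findInterval(grid, times)]
}

#' Per-species population step function of one run
#'
#' @param run An `stg_run`.
#' @param species Species name.
#' @return List with `times` and `sizes`: a right-continuous step
#'   function changing only at event times, starting at the initial
#'   population at `t = 0`.
#' @export
population_timeseries <- function(run, species) {
  i <- match(species, run$species)
  if (is.na(i)) stop_stg("validation", "unknown species `%s`", species)
  list(times = run$population$times,
       sizes = as.numeric(run$population$sizes[, i]))
}

#' Average population size over replicate runs
#'
#' Evaluates each run's population step function on a common time grid
#' (zero-order hold) and returns the pointwise mean and standard error
#' across runs.
#'
#' @param runs List of `stg_run`.
#' @param species Species name.
#' @param grid Time grid; defaults to 200 uniform points over the span.
#' @return Data frame with `time`, `mean`, `se`.
#' @export
average_population <- function(runs, species, grid = NULL) {
  if (!length(runs)) stop_stg("validation", "`runs` must be non-empty")
  if (is.null(grid)) {
    span <- max(vapply(runs, `[[`, numeric(1), "t_span"))
    grid <- seq(0, span, length.out = 200L)
  }
  if (!length(grid)) stop_stg("validation", "`grid` must be non-empty")
  m <- vapply(runs, function(run) {
    ts <- population_timeseries(run, species)
    .step_at(ts$times, ts$sizes, grid)
  }, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  mean_ <- rowMeans(m)
  se <- if (ncol(m) > 1L) apply(m, 1L, stats::sd) / sqrt(ncol(m)) else rep(0, length(grid))
  data.frame(time = grid, mean = mean_, se = se)
}

.new_histogram <- function(labels, counts, normalized = TRUE) {
  structure(list(
    labels = labels,
    counts = as.numeric(counts),
    percent = if (sum(counts) > 0) 100 * counts / sum(counts) else counts * 0,
    normalized = normalized
  ), class = "stg_histogram")
}

#' @export
print.stg_histogram <- function(x, ...) {
  df <- data.frame(label = x$labels, count = x$counts,
                   percent = round(x$percent, 3))
  cat(sprintf("Histogram (%d bins, %g observations)\n",
              length(x$labels), sum(x$counts)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Clone-size histogram over replicate runs
#'
#' A clone is the set of descendants of a single founder (root); its size
#' is the number of living clone members at `t`, the founder included
#' when it is itself alive.  Founders and members can be filtered by
#' species; clones whose founder is dead with no living descendants have
#' size 0 and are included by default, making extinction visible.
#'
#' @param runs List of `stg_run`.
#' @param t Time point within the simulation span.
#' @param founder_species Optional filter on the founder's species.
#' @param member_species Optional filter on counted members.
#' @param include_extinct Include size-0 clones (default `TRUE`).
#' @return An `stg_histogram` of clone sizes, as percentages of all
#'   clones pooled across runs.
#' @export
clone_size_histogram <- function(runs, t, founder_species = NULL,
                                 member_species = NULL,
                                 include_extinct = TRUE) {
  sizes <- unlist(lapply(runs, function(run) {
    f <- run$forest
    founders <- f$roots
    if (!is.null(founder_species))
      founders <- founders[f$species[founders] %in% founder_species]
    if (!length(founders)) return(numeric(0))
    alive <- .alive_at(f, t)
    if (!is.null(member_species)) alive <- alive & f$species %in% member_species
    as.integer(table(factor(f$root_of[alive], levels = founders)))
  }))
  if (!length(sizes)) return(.new_histogram(integer(0), integer(0)))
  if (!include_extinct) sizes <- sizes[sizes > 0]
  tab <- table(sizes)
  .new_histogram(as.integer(names(tab)), as.integer(tab))
}

#' Rule-execution histogram over replicate runs
#'
#' Total number of firings of each transition rule (its channels summed),
#' pooled across runs.
#'
#' @param runs List of `stg_run`.
#' @return An `stg_histogram` labelled by rule (left-hand species).
#' @export
rule_execution_histogram <- function(runs) {
  if (!length(runs)) stop_stg("validation", "`runs` must be non-empty")
  cc <- runs[[1]]$channel_counts
  totals <- stats::setNames(numeric(length(unique(cc$rule))), unique(cc$rule))
  for (run in runs) {
    agg <- tapply(run$channel_counts$count, run$channel_counts$rule, sum)
    totals[names(agg)] <- totals[names(agg)] + agg
  }
  .new_histogram(names(totals), as.numeric(totals))
}

#' Internal-state value histogram over replicate runs
#'
#' Pools the values of one internal state (all duplicate instances)
#' either across the individuals living at time `t`, or across every
#' recorded individual when `t = "all-events"`.
#'
#' @param runs List of `stg_run`.
#' @param state_name Internal state name.
#' @param t Time point, or `"all-events"` (default).
#' @param breaks Passed to [graphics::hist()] for non-integer values.
#' @return An `stg_histogram`; the pooled raw values are attached as
#'   element `values`.
#' @export
internal_state_histogram <- function(runs, state_name, t = "all-events",
                                     breaks = "Sturges") {
  values <- unlist(lapply(runs, function(run) {
    f <- run$forest
    if (!state_name %in% names(f$states))
      stop_stg("validation", "unknown internal state `%s`", state_name)
    carriers <- names(f$state_names)[vapply(f$state_names, function(x)
      state_name %in% x, logical(1))]
    sel <- f$species %in% carriers
    if (!identical(t, "all-events")) sel <- sel & .alive_at(f, t)
    as.vector(f$states[[state_name]][sel, , drop = FALSE])
  }))
  if (!length(values)) {
    h <- .new_histogram(numeric(0), numeric(0))
    h$values <- values
    return(h)
  }
  if (all(abs(values - round(values)) < 1e-9)) {
    tab <- table(round(values))
    h <- .new_histogram(as.numeric(names(tab)), as.integer(tab))
  } else {
    hh <- graphics::hist(values, breaks = breaks, plot = FALSE)
    h <- .new_histogram(hh$mids, hh$counts)
  }
  h$values <- values
  h
}
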