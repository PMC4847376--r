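# Bundled example programs.

.fixture_meta <- function() data.frame(
  name = c("lotka_volterra", "stem_cell_ms", "conditional_toy",
           "clone_expansion"),
  description = c(
    "Predator-prey grammar: 900 Prey + 900 Predator founders, environment-dependent rates/probabilities via the lotka_volterra global updater, span 10.",
    "Stem-cell differentiation: SC divides at rate 0.1 (self-renewal vs differentiation, 50/50); Diff proliferates (49%) or dies (51%) at rate 1; microsatellite vector (dup 3, stepwise mutation) and a generation counter.",
    "Conditional transitions: asymmetric and symmetric stem cells plus differentiated cells; a stochastic counter (increment N(1, 0.1) per event) transforms SCSym to Diff above 5 and kills Diff above 10.",
    "Synthetic clonal expansion analogue: a founder seeds single cells; cells divide at rate 1 until the population cap (1000) zeroes the division rate."),
  stringsAsFactors = FALSE)

#' List the bundled example programs
#'
#' @return Data frame with `name`, `description`, and `path`.
#' @export
list_fixtures <- function() {
  meta <- .fixture_meta()
  meta$path <- vapply(meta$name, fixture_path, character(1))
  meta
}

#' Path to a bundled example program
#'
#' @param name Fixture name (see [list_fixtures()]).
#' @return Path to the program's XML file.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", "programs", paste0(name, ".xml"),
                   package = "stgsim")
  if (!nzchar(p))
    stop_stg("validation", "no bundled program named `%s`", name)
  p
}

#' Parse and validate a bundled example program
#'
#' @inheritParams fixture_path
#' @param registry Registry for updater resolution.
#' @return A validated `stg_program`.
#' @examples
#' fixture_program("conditional_toy")
#' @export
fixture_program <- function(name, registry = default_registry()) {
  validate_program(parse_program(fixture_path(name)), registry)
}
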