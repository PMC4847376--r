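#' Symmetric single-step microsatellite mutation update
#'
#' Applies the stepwise mutation model to a vector of microsatellite (MS)
#' repeat counts: at each cell division every locus gains one repeat with
#' probability `p/2`, loses one with probability `p/2`, and is otherwise
#' left unchanged.  One uniform draw is consumed per locus.
#'
#' @param x Numeric vector of current repeat counts (one entry per locus).
#' @param p Per-locus, per-division probability of a repeat-count change,
#'   in `[0, 1]`.  Default 0.01, a small somatic mutation rate typical of
#'   MS loci; override from a program file with `ms_step(p = ...)`.
#' @return Numeric vector of updated repeat counts, same length as `x`.
#' @examples
#' ms_step(c(30, 30, 30), p = 0)    # identity when p = 0
#' set.seed(1); ms_step(rep(30, 5), p = 1)  # every locus steps +/-1
#' @export
ms_step <- function(x, p = 0.01) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  u <- stats::runif(length(x))
  x + (u < p / 2) - (u >= p / 2 & u < p)
}

#' Generation counter update
#'
#' Increments a per-individual generation counter by one at every division,
#' counting generations since the event (e.g. a differentiation) that
#' initialised the counter.
#'
#' @param x Numeric vector of current generation counts.
#' @return `x + 1`.
#' @examples
#' gen_increment(1)  # 2
#' @export
gen_increment <- function(x) x + 1

#' Stochastic counter update
#'
#' Adds a Gaussian increment `N(mu, sigma)` to a per-individual counter at
#' every transition event.  With the defaults the counter advances by about
#' one unit per division, so it behaves as a noisy event clock that can
#' drive threshold-conditioned transformations.
#'
#' @param x Numeric vector of current counter values.
#' @param mu Mean of the increment (default 1).
#' @param sigma Standard deviation of the increment (default 0.1); must be
#'   non-negative (`sigma = 0` gives the deterministic increment `x + mu`).
#' @return `x` plus one normal draw per element.
#' @examples
#' stochastic_counter_step(0, mu = 1, sigma = 0)  # exactly 1
#' @export
stochastic_counter_step <- function(x, mu = 1, sigma = 0.1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  x + stats::rnorm(length(x), mean = mu, sd = sigma)
}

#' Lotka-Volterra global rate/probability updater
#'
#' Environment-dependent update for the two-species predator-prey grammar
#'   `Prey -> {Prey,Prey}_p1 | {phi}_ow` and
#'   `Predator -> {Predator,Predator}_p2 | {phi}_ow`,
#' mapping the classical Lotka-Volterra constants onto per-capita rates and
#' branch probabilities:
#' \deqn{r_1 = c_1 + c_2 |Predator|, \quad p_1 = c_1 / r_1}
#' \deqn{r_2 = c_2 |Prey| + c_3, \quad p_2 = c_2 |Prey| / r_2}
#' so that the birth channel of the prey carries rate `c1`, its death
#' channel `c2 |Predator|`, and symmetrically for the predator.
#'
#' @param populations Named numeric vector/list of current population sizes;
#'   must contain `Prey` and `Predator`.
#' @param c1,c2,c3 Positive Lotka-Volterra constants (prey birth, coupling,
#'   predator death).  Defaults `c1 = c3 = 10`, `c2 = 0.01` oscillate
#'   visibly at the bundled fixture's 900/900 initial populations.
#' @return A named list with entries `Prey` and `Predator`, each a list
#'   with elements `rate` and `probs` (probabilities sum to 1).
#' @examples
#' lotka_volterra_updater(c(Prey = 900, Predator = 900))
#' @export
lotka_volterra_updater <- function(populations, c1 = 10, c2 = 0.01, c3 = 10) {
  if (!all(c(c1, c2, c3) > 0))
    stop("Lotka-Volterra constants must be positive", call. = FALSE)
  prey <- as.numeric(populations[["Prey"]])
  pred <- as.numeric(populations[["Predator"]])
  r1 <- c1 + c2 * pred
  r2 <- c2 * prey + c3
  p1 <- c1 / r1
  p2 <- c2 * prey / r2
  list(
    Prey     = list(rate = r1, probs = c(p1, 1 - p1)),
    Predator = list(rate = r2, probs = c(p2, 1 - p2))
  )
}

#' Capped clonal-expansion global updater
#'
#' Zeroes the division rate of one species once its population reaches a
#' cap, so that clones expand to a fixed size and then stop dividing while
#' other rules (e.g. a founder species seeding new single cells) keep
#' firing.  Used by the bundled synthetic `clone_expansion` fixture.
#'
#' @param populations Named numeric vector/list of current population sizes.
#' @param species Name of the capped species (default `"Cell"`).
#' @param cap Population size at which division stops (default 1000).
#' @param rate Division rate while below the cap (default 1).
#' @return A named list with one entry for `species` carrying the new rate
#'   (`probs = NULL` leaves branch probabilities untouched).
#' @export
clone_expansion_updater <- function(populations, species = "Cell",
                                    cap = 1000, rate = 1) {
  r <- if (as.numeric(populations[[species]]) >= cap) 0 else rate
  out <- list(list(rate = r, probs = NULL))
  names(out) <- species
  out
}
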