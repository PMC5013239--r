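#' Optimizer parameter sets
#'
#' Constructors for the tuning parameters of the three bitstring optimizers.
#' Defaults are the benchmark settings used throughout the package: swarms of
#' 20 particles run for 100 iterations; the BQPSO contraction-expansion
#' coefficient is 1; BPSO uses velocity clamp 6 with inertia 0.5 and
#' cognitive/social coefficients 2 and 2; the GA uses crossover probability
#' 0.9, per-bit mutation probability 0.04, roulette selection and elitism 1.
#'
#' @param swarm_size,population_size Number of particles / individuals.
#' @param iterations Fixed iteration (generation) budget; there is no
#'   convergence-based early stop.
#' @param ce_coefficient Positive scalar multiplying the Hamming distance to
#'   the mean best in the jump-length draw; constant over all iterations.
#' @param crossover_mode Crossover used to build the local attractor:
#'   `"one-point"` or `"multipoint"`.
#' @param v_max Velocity clamp: BPSO velocities are confined to
#'   `[-v_max, v_max]` componentwise.
#' @param inertia_w,c1,c2 BPSO inertia weight and cognitive/social
#'   acceleration coefficients.
#' @param p_crossover,p_mutation GA per-pair crossover and per-bit mutation
#'   probabilities.
#' @param selection GA parent selection: `"roulette"` (fitness-proportional)
#'   or `"tournament"` (size 2).
#' @param elitism Number of best individuals copied unchanged into the next
#'   GA generation.
#' @param seed Integer seed making the run fully reproducible.
#' @return A parameter list of class `bqpso_params`, `bpso_params`, or
#'   `ga_params`.
#' @name optimizer_params
NULL

#' @rdname optimizer_params
#' @export
bqpso_params <- function(swarm_size = 20L, iterations = 100L,
                         ce_coefficient = 1,
                         crossover_mode = c("one-point", "multipoint"),
                         seed = 1L) {
  crossover_mode <- match.arg(crossover_mode)
  stopifnot(swarm_size >= 1L, iterations >= 1L, ce_coefficient > 0)
  structure(
    list(
      swarm_size = as.integer(swarm_size),
      iterations = as.integer(iterations),
      ce_coefficient = ce_coefficient,
      crossover_mode = crossover_mode,
      seed = as.integer(seed)
    ),
    class = "bqpso_params"
  )
}

#' @rdname optimizer_params
#' @export
bpso_params <- function(swarm_size = 20L, iterations = 100L, v_max = 6,
                        inertia_w = 0.5, c1 = 2, c2 = 2, seed = 1L) {
  stopifnot(swarm_size >= 1L, iterations >= 1L, v_max > 0)
  structure(
    list(
      swarm_size = as.integer(swarm_size),
      iterations = as.integer(iterations),
      v_max = v_max,
      inertia_w = inertia_w,
      c1 = c1,
      c2 = c2,
      seed = as.integer(seed)
    ),
    class = "bpso_params"
  )
}

#' @rdname optimizer_params
#' @export
ga_params <- function(population_size = 20L, iterations = 100L,
                      p_crossover = 0.9, p_mutation = 0.04,
                      selection = c("roulette", "tournament"),
                      elitism = 1L, seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(
    population_size >= 2L, iterations >= 1L,
    p_crossover >= 0, p_crossover <= 1,
    p_mutation >= 0, p_mutation <= 1,
    elitism >= 0L, elitism < population_size
  )
  structure(
    list(
      population_size = as.integer(population_size),
      iterations = as.integer(iterations),
      p_crossover = p_crossover,
      p_mutation = p_mutation,
      selection = selection,
      elitism = as.integer(elitism),
      seed = as.integer(seed)
    ),
    class = "ga_params"
  )
}
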