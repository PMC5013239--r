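#' Binary quantum-behaved particle swarm optimization
#'
#' Maximizes a fitness function over fixed-length bitstrings with the binary
#' quantum-behaved particle swarm. Positions are initialized with each bit
#' Bernoulli(0.5). Every iteration the swarm (i) forms the mean best position
#' `mbest` by per-bit majority over all personal bests ([get_mbest()]),
#' then for each particle (ii) builds a local attractor by crossover of its
#' personal best with the global best ([get_local_attractor()]), (iii) draws
#' a Hamming jump length against `mbest` from the particle's current position
#' ([jump_length()]), (iv) mutates the attractor bitwise with the resulting
#' probability ([mutate_toward()]), and (v) re-evaluates, updating personal
#' and global bests under strict improvement. Multi-variable layouts apply
#' the crossover/jump/mutation per substring.
#'
#' @param fitness_fn Function mapping a 0/1 integer vector of length
#'   `layout$total_length` to a numeric score, or to a composite
#'   `fitness_value` (see [evaluate_particle()]); maximized.
#' @param layout A [particle_layout()].
#' @param params A [bqpso_params()] object.
#' @param trace When `TRUE`, emit a structured per-iteration log line
#'   (iteration, global-best fitness and accuracy, subset size).
#' @return A `run_result` with the best position and fitness, the best
#'   position's LOOCV accuracy when the fitness carries one, the 1-bit
#'   indices, the per-iteration global-best trajectory (monotone
#'   non-decreasing), the number of fitness evaluations, and the seed.
#' @examples
#' onemax <- function(bits) sum(bits)
#' res <- run_bqpso(onemax, particle_layout(10), bqpso_params(seed = 42))
#' res$best_fitness
#' @export
run_bqpso <- function(fitness_fn, layout = particle_layout(),
                      params = bqpso_params(), trace = FALSE) {
  stopifnot(inherits(layout, "particle_layout"), inherits(params, "bqpso_params"))
  evaluator <- make_evaluator(fitness_fn)
  l <- layout$total_length
  sub_end <- cumsum(layout$substring_lengths)
  sub_start <- c(1L, utils::head(sub_end, -1L) + 1L)

  with_local_seed(params$seed, {
    positions <- random_swarm(params$swarm_size, l)
    state <- init_state(positions, evaluator)
    trajectory <- numeric(params$iterations)

    for (iter in seq_len(params$iterations)) {
      mbest <- get_mbest(state$pbest)
      for (i in seq_len(params$swarm_size)) {
        new_bits <- integer(l)
        for (d in seq_len(layout$num_variables)) {
          idx <- sub_start[d]:sub_end[d]
          attractor <- get_local_attractor(
            state$pbest[i, idx], state$gbest[idx],
            mode = params$crossover_mode
          )
          draw <- jump_length(positions[i, idx], mbest[idx],
                              ce_coefficient = params$ce_coefficient)
          new_bits[idx] <- mutate_toward(attractor, draw)
        }
        positions[i, ] <- new_bits
        res <- evaluator$eval_one(new_bits)
        state <- update_bests(state, i, new_bits, res)
      }
      trajectory[iter] <- state$gbest_score
      if (trace) trace_iteration("bqpso", iter, state)
    }

    new_run_result("bqpso", state$gbest, state$gbest_score, state$gbest_acc,
                   trajectory, evaluator$n_evals(), params$seed)
  })
}
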