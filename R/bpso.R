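#' Sigmoid binary particle swarm optimization
#'
#' The canonical binary PSO baseline. Each particle carries a real-valued
#' velocity per bit, updated with inertia, cognitive, and social terms
#' (fresh uniform multipliers per bit) and clamped to `[-v_max, v_max]`;
#' the bit is then set to 1 when a uniform draw falls below the logistic
#' sigmoid of the velocity. Velocities are initialized uniformly in
#' `[-v_max, v_max]` and positions with each bit Bernoulli(0.5). Personal
#' and global bests follow the same strict-improvement bookkeeping as
#' [run_bqpso()].
#'
#' @inheritParams run_bqpso
#' @param params A [bpso_params()] object.
#' @return A `run_result`; see [run_bqpso()].
#' @export
run_bpso <- function(fitness_fn, layout = particle_layout(),
                     params = bpso_params(), trace = FALSE) {
  stopifnot(inherits(layout, "particle_layout"), inherits(params, "bpso_params"))
  evaluator <- make_evaluator(fitness_fn)
  l <- layout$total_length
  n <- params$swarm_size

  with_local_seed(params$seed, {
    positions <- random_swarm(n, l)
    velocities <- matrix(stats::runif(n * l, -params$v_max, params$v_max), n, l)
    state <- init_state(positions, evaluator)
    trajectory <- numeric(params$iterations)

    for (iter in seq_len(params$iterations)) {
      for (i in seq_len(n)) {
        r1 <- stats::runif(l)
        r2 <- stats::runif(l)
        v <- params$inertia_w * velocities[i, ] +
          params$c1 * r1 * (state$pbest[i, ] - positions[i, ]) +
          params$c2 * r2 * (state$gbest - positions[i, ])
        v <- pmin(pmax(v, -params$v_max), params$v_max)
        velocities[i, ] <- v
        bits <- as.integer(stats::runif(l) < 1 / (1 + exp(-v)))
        positions[i, ] <- bits
        res <- evaluator$eval_one(bits)
        state <- update_bests(state, i, bits, res)
      }
      trajectory[iter] <- state$gbest_score
      if (trace) trace_iteration("bpso", iter, state)
    }

    result <- new_run_result("bpso", state$gbest, state$gbest_score,
                             state$gbest_acc, trajectory,
                             evaluator$n_evals(), params$seed)
    result$max_abs_velocity <- max(abs(velocities))
    result
  })
}
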