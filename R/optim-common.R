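# Shared machinery for the three bitstring optimizers: seeded evaluation,
# run bookkeeping, and the RunResult container.

# Evaluate under a local RNG state so optimizer runs are reproducible from
# their seed without clobbering the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Wraps a user fitness function into an evaluator that counts calls and
# splits composite fitness values (score + LOOCV accuracy + subset size)
# from bare numeric scores. +Inf/NaN/NA are rejected; -Inf is the documented
# empty-subset sentinel and flows through ordinary max-comparisons.
make_evaluator <- function(fitness_fn) {
  count <- 0L
  eval_one <- function(bits) {
    count <<- count + 1L
    res <- fitness_fn(bits)
    if (inherits(res, "fitness_value")) {
      score <- res$score
      accuracy <- res$accuracy
    } else {
      score <- as.numeric(res)
      accuracy <- NA_real_
    }
    if (length(score) != 1L || is.na(score) || is.nan(score) ||
        (is.infinite(score) && score > 0)) {
      stop("fitness function returned a non-finite value", call. = FALSE)
    }
    list(score = score, accuracy = accuracy)
  }
  list(eval_one = eval_one, n_evals = function() count)
}

new_run_result <- function(algorithm, best_position, best_score, best_accuracy,
                           trajectory, evaluations, seed) {
  best_position <- as_bits(best_position)
  structure(
    list(
      algorithm = algorithm,
      best_position = best_position,
      best_fitness = best_score,
      best_accuracy = best_accuracy,
      selected_indices = which(best_position == 1L),
      fitness_trajectory = trajectory,
      evaluations = evaluations,
      seed = seed
    ),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(x$algorithm, " run (seed ", x$seed, ")\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness), "\n", sep = "")
  if (!is.na(x$best_accuracy)) {
    cat("  best LOOCV accuracy: ", format(x$best_accuracy), "%\n", sep = "")
  }
  cat("  subset size: ", length(x$selected_indices), "\n", sep = "")
  cat("  fitness evaluations: ", x$evaluations, "\n", sep = "")
  invisible(x)
}

random_swarm <- function(n, l) {
  matrix(as.integer(stats::runif(n * l) < 0.5), nrow = n, ncol = l)
}

# Strict-improvement pbest/gbest bookkeeping: incumbents are retained on
# ties, which keeps runs reproducible and trajectories monotone.
update_bests <- function(state, i, bits, res) {
  if (res$score > state$pbest_scores[i]) {
    state$pbest_scores[i] <- res$score
    state$pbest_acc[i] <- res$accuracy
    state$pbest[i, ] <- bits
    if (res$score > state$gbest_score) {
      state$gbest_score <- res$score
      state$gbest_acc <- res$accuracy
      state$gbest <- bits
    }
  }
  state
}

# Structured per-iteration log line: iteration, gbest fitness/accuracy and
# the gbest subset size.
trace_iteration <- function(algorithm, iter, state) {
  message(sprintf(
    "%s iter %d: gbest fitness %.4f, accuracy %s, subset size %d",
    algorithm, iter, state$gbest_score,
    if (is.na(state$gbest_acc)) "NA" else sprintf("%.2f%%", state$gbest_acc),
    sum(state$gbest)
  ))
}

init_state <- function(positions, evaluator) {
  n <- nrow(positions)
  scores <- numeric(n)
  accs <- numeric(n)
  for (i in seq_len(n)) {
    res <- evaluator$eval_one(positions[i, ])
    scores[i] <- res$score
    accs[i] <- res$accuracy
  }
  best <- which.max(scores)
  list(
    pbest = positions,
    pbest_scores = scores,
    pbest_acc = accs,
    gbest = positions[best, ],
    gbest_score = scores[best],
    gbest_acc = accs[best]
  )
}
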