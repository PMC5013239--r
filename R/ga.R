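#' Canonical genetic algorithm over bitstrings
#'
#' Generational GA baseline: fitness-proportional (roulette) parent
#' selection by default, one-point crossover applied to each parent pair
#' with probability `p_crossover`, independent per-bit mutation with
#' probability `p_mutation`, and elitism copying the best individual(s)
#' unchanged into the next generation. Because roulette weights must be
#' non-negative, scores are shifted by the population minimum; if every
#' individual has the same (or a non-finite sentinel) score, selection
#' falls back to uniform.
#'
#' @inheritParams run_bqpso
#' @param params A [ga_params()] object.
#' @return A `run_result`; see [run_bqpso()]. The trajectory tracks the
#'   best-so-far fitness, which elitism keeps monotone in the population
#'   as well.
#' @export
run_ga <- function(fitness_fn, layout = particle_layout(),
                   params = ga_params(), trace = FALSE) {
  stopifnot(inherits(layout, "particle_layout"), inherits(params, "ga_params"))
  evaluator <- make_evaluator(fitness_fn)
  l <- layout$total_length
  n <- params$population_size

  select_parent <- function(scores) {
    if (params$selection == "tournament") {
      cand <- sample.int(n, 2L, replace = TRUE)
      return(cand[which.max(scores[cand])])
    }
    w <- scores
    w[!is.finite(w)] <- NA_real_
    if (all(is.na(w)) || max(w, na.rm = TRUE) == min(w, na.rm = TRUE)) {
      return(sample.int(n, 1L))
    }
    w <- w - min(w, na.rm = TRUE)
    w[is.na(w)] <- 0
    if (sum(w) == 0) return(sample.int(n, 1L))
    sample.int(n, 1L, prob = w)
  }

  crossover <- function(a, b) {
    if (l < 2L || stats::runif(1) >= params$p_crossover) return(list(a, b))
    cut <- sample.int(l - 1L, 1L)
    head_a <- seq_len(cut)
    list(c(a[head_a], b[-head_a]), c(b[head_a], a[-head_a]))
  }

  mutate <- function(bits) {
    if (params$p_mutation == 0) return(bits)
    flip <- stats::runif(l) < params$p_mutation
    bits[flip] <- 1L - bits[flip]
    bits
  }

  with_local_seed(params$seed, {
    population <- random_swarm(n, l)
    scores <- numeric(n)
    accs <- numeric(n)
    for (i in seq_len(n)) {
      res <- evaluator$eval_one(population[i, ])
      scores[i] <- res$score
      accs[i] <- res$accuracy
    }
    best_i <- which.max(scores)
    best_bits <- population[best_i, ]
    best_score <- scores[best_i]
    best_acc <- accs[best_i]
    trajectory <- numeric(params$iterations)

    for (iter in seq_len(params$iterations)) {
      nextgen <- matrix(0L, n, l)
      filled <- 0L
      if (params$elitism > 0L) {
        elite <- order(scores, decreasing = TRUE)[seq_len(params$elitism)]
        for (e in elite) {
          filled <- filled + 1L
          nextgen[filled, ] <- population[e, ]
        }
      }
      while (filled < n) {
        p1 <- population[select_parent(scores), ]
        p2 <- population[select_parent(scores), ]
        kids <- crossover(p1, p2)
        for (kid in kids) {
          if (filled >= n) break
          filled <- filled + 1L
          nextgen[filled, ] <- mutate(kid)
        }
      }
      population <- nextgen
      for (i in seq_len(n)) {
        res <- evaluator$eval_one(population[i, ])
        scores[i] <- res$score
        accs[i] <- res$accuracy
        if (res$score > best_score) {
          best_score <- res$score
          best_acc <- res$accuracy
          best_bits <- population[i, ]
        }
      }
      trajectory[iter] <- best_score
      if (trace) {
        trace_iteration("ga", iter, list(gbest_score = best_score,
                                         gbest_acc = best_acc,
                                         gbest = best_bits))
      }
    }

    new_run_result("ga", best_bits, best_score, best_acc, trajectory,
                   evaluator$n_evals(), params$seed)
  })
}
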