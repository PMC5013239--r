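#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the selection pipeline: the search algorithm,
#' the prefilter width (which fixes the particle length), the optimizer
#' parameters, the composite-fitness weights, the SVM configuration, and
#' the repeated-run protocol (number of independent executions and base
#' seed).
#'
#' @param algorithm `"bqpso"`, `"bpso"`, or `"ga"`.
#' @param prefilter_k Number of top-ranked genes kept as the search space.
#' @param params Optimizer parameters matching `algorithm`; defaults to the
#'   standard settings of [bqpso_params()], [bpso_params()] or
#'   [ga_params()].
#' @param weights A [fitness_weights()].
#' @param svm An [svm_config()].
#' @param repeats Independent executions for [run_benchmark()] (default
#'   25).
#' @param base_seed First seed; repeat r uses `base_seed + r - 1`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(algorithm = c("bqpso", "bpso", "ga"),
                            prefilter_k = 50L, params = NULL,
                            weights = fitness_weights(),
                            svm = svm_config(), repeats = 25L,
                            base_seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(params)) {
    params <- switch(algorithm,
      bqpso = bqpso_params(),
      bpso = bpso_params(),
      ga = ga_params()
    )
  }
  expected <- paste0(algorithm, "_params")
  if (!inherits(params, expected)) {
    stop("params must be a ", expected, " object for algorithm '",
         algorithm, "'", call. = FALSE)
  }
  stopifnot(prefilter_k >= 1L, repeats >= 1L)
  structure(
    list(algorithm = algorithm, prefilter_k = as.integer(prefilter_k),
         params = params, weights = weights, svm = svm,
         repeats = as.integer(repeats), base_seed = as.integer(base_seed)),
    class = "pipeline_config"
  )
}

#' Run the full gene-selection pipeline once
#'
#' Normalizes the dataset gene-wise, ranks genes by the two-sample t-test,
#' keeps the `prefilter_k` top-ranked genes as the search space, and runs
#' the configured optimizer with the LOOCV-SVM composite fitness
#' ([evaluate_particle()]) over subsets of those genes. Fitness values are
#' memoized by position within the run, so revisited subsets do not refit
#' the SVM. Selected genes are reported by their original identifiers.
#'
#' @param data An [expression_dataset()].
#' @param config A [pipeline_config()].
#' @param seed Optional seed overriding `config$params$seed` for this run.
#' @return A `run_result` (see [run_bqpso()]) with two extra fields:
#'   `selected_genes` (identifiers of the best subset) and
#'   `search_space` (identifiers of the prefiltered genes, in rank order).
#' @export
run_pipeline <- function(data, config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(data, "expr_dataset"), inherits(config, "pipeline_config"))
  params <- config$params
  if (!is.null(seed)) params$seed <- as.integer(seed)

  norm <- normalize_expression(data)
  ranking <- t_test_rank(norm)
  top_ids <- select_top_k(ranking, config$prefilter_k)
  reduced <- expression_dataset(
    norm$matrix[top_ids, , drop = FALSE], top_ids, norm$labels,
    norm$sample_ids
  )

  cache <- new.env(parent = emptyenv())
  fitness_fn <- function(bits) {
    evaluate_particle(bits, reduced, config$weights, config$svm, cache)
  }
  layout <- particle_layout(length(top_ids))

  result <- switch(config$algorithm,
    bqpso = run_bqpso(fitness_fn, layout, params),
    bpso = run_bpso(fitness_fn, layout, params),
    ga = run_ga(fitness_fn, layout, params)
  )
  result$selected_genes <- top_ids[result$selected_indices]
  result$search_space <- top_ids
  result
}

#' Repeated-run benchmark of the selection algorithms
#'
#' Executes each requested algorithm `repeats` times on the dataset with
#' seeds `base_seed .. base_seed + repeats - 1` and aggregates, per
#' algorithm: the best and mean LOOCV accuracy of the per-run best subsets,
#' the population standard deviation (denominator `n`) of those accuracies,
#' the mean subset size over all runs, and per-gene selection counts over
#' the runs attaining the maximum accuracy.
#'
#' @param data An [expression_dataset()].
#' @param algorithms Character vector among `"bqpso"`, `"bpso"`, `"ga"`.
#' @param config A [pipeline_config()]; its `algorithm` field is overridden
#'   per benchmark arm. The swarm/population size and iteration budget of
#'   `config$params` are shared by every arm (the comparison is run under
#'   one common search budget); algorithm-specific tunables of an arm keep
#'   their defaults unless `config$params` is of that arm's own class.
#' @param repeats,base_seed Optional overrides of the config protocol.
#' @return A `benchmark_report`: list with `summary` (one row per
#'   algorithm: `algorithm`, `best`, `mean`, `std_dev`, `mean_subset_size`,
#'   `repeats`), `frequencies` (named list of per-gene selection counts
#'   among best-accuracy runs), `accuracies` and `subset_sizes` (per-run
#'   records), and `runs` (all `run_result`s).
#' @export
run_benchmark <- function(data, algorithms = c("bqpso", "bpso", "ga"),
                          config = pipeline_config(), repeats = NULL,
                          base_seed = NULL) {
  stopifnot(all(algorithms %in% c("bqpso", "bpso", "ga")))
  repeats <- if (is.null(repeats)) config$repeats else as.integer(repeats)
  base_seed <- if (is.null(base_seed)) config$base_seed else as.integer(base_seed)
  stopifnot(repeats >= 1L)

  summary_rows <- list()
  frequencies <- list()
  accuracies <- list()
  subset_sizes <- list()
  runs <- list()

  # the comparison protocol shares swarm size and iteration budget across
  # arms; algorithm-specific tunables keep their defaults unless config
  # carries params for that very algorithm
  n_pop <- config$params$swarm_size
  if (is.null(n_pop)) n_pop <- config$params$population_size
  n_iter <- config$params$iterations

  for (alg in algorithms) {
    arm_params <- if (inherits(config$params, paste0(alg, "_params"))) {
      config$params
    } else {
      switch(alg,
        bqpso = bqpso_params(n_pop, n_iter),
        bpso = bpso_params(n_pop, n_iter),
        ga = ga_params(n_pop, n_iter)
      )
    }
    arm_config <- pipeline_config(
      algorithm = alg, prefilter_k = config$prefilter_k, params = arm_params,
      weights = config$weights, svm = config$svm, repeats = repeats,
      base_seed = base_seed
    )
    arm_runs <- lapply(seq_len(repeats), function(r) {
      run_pipeline(data, arm_config, seed = base_seed + r - 1L)
    })
    acc <- vapply(arm_runs, function(r) r$best_accuracy, numeric(1))
    sizes <- vapply(arm_runs, function(r) length(r$selected_genes), numeric(1))
    best <- max(acc)
    best_runs <- arm_runs[acc == best]
    genes <- unlist(lapply(best_runs, function(r) r$selected_genes))
    freq <- sort(table(genes), decreasing = TRUE)

    summary_rows[[alg]] <- data.frame(
      algorithm = alg, best = best, mean = mean(acc),
      std_dev = stats::sd(acc) * sqrt((repeats - 1) / repeats),
      mean_subset_size = mean(sizes), repeats = repeats,
      stringsAsFactors = FALSE
    )
    frequencies[[alg]] <- stats::setNames(as.integer(freq), names(freq))
    accuracies[[alg]] <- acc
    subset_sizes[[alg]] <- sizes
    runs[[alg]] <- arm_runs
  }

  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  if (repeats == 1L) summary$std_dev <- 0
  structure(
    list(summary = summary, frequencies = frequencies,
         accuracies = accuracies, subset_sizes = subset_sizes,
         runs = runs, base_seed = base_seed),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark over", x$summary$repeats[1L], "repeats (base seed",
      x$base_seed, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Most frequently selected genes among the best runs
#'
#' Across the repeated runs that attained the maximum accuracy, counts how
#' often each gene appears in the best subset and returns the most frequent
#' ones, ties broken by gene identifier.
#'
#' @param report A `benchmark_report` from [run_benchmark()].
#' @param algorithm Which benchmark arm to summarize.
#' @param top_n Maximum number of genes to return (default 5).
#' @return A data frame with columns `gene_id` and `count`, sorted by
#'   descending count.
#' @export
selection_frequency_table <- function(report, algorithm = "bqpso",
                                      top_n = 5L) {
  stopifnot(inherits(report, "benchmark_report"), top_n >= 1L)
  freq <- report$frequencies[[algorithm]]
  if (is.null(freq) || length(freq) == 0L) {
    stop("no best-accuracy runs recorded for algorithm '", algorithm, "'",
         call. = FALSE)
  }
  ord <- order(-freq, names(freq))
  utils::head(
    data.frame(gene_id = names(freq)[ord], count = as.integer(freq[ord]),
               row.names = NULL, stringsAsFactors = FALSE),
    top_n
  )
}

#' Serialize a benchmark report
#'
#' `write_benchmark_report()` writes the report as a JSON file (summary,
#' per-run accuracies and subset sizes, selection frequencies, best
#' positions as 0/1 strings); `read_benchmark_report()` restores the
#' serialized numbers losslessly.
#'
#' @param report A `benchmark_report`.
#' @param path JSON output path.
#' @return The path (write) or the deserialized list (read).
#' @export
write_benchmark_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  payload <- list(
    base_seed = report$base_seed,
    summary = report$summary,
    accuracies = report$accuracies,
    subset_sizes = report$subset_sizes,
    frequencies = lapply(report$frequencies, as.list),
    best_positions = lapply(report$runs, function(arm) {
      vapply(arm, function(r) bits_to_string(r$best_position), character(1))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_benchmark_report
#' @export
read_benchmark_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
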