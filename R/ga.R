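#' Genetic-algorithm configuration
#'
#' Defaults follow the search's operating point: 50 individuals, uniform
#' crossover with probability 0.8, uniform random mutation with
#' per-individual probability 0.1, linear ranking selection at maximum
#' pressure, 10% elitism, at most 100 generations with a stall criterion of
#' five generations without significant improvement of the best MSE.
#'
#' @param population_size individuals per generation.
#' @param crossover_prob probability a selected pair is recombined.
#' @param mutation_prob mutation probability; with
#'   `mutation_mode = "per_individual"` (default) it triggers a mutation
#'   event in which each bit then flips with rate `1/length`, keeping the
#'   expected disruption low enough for elitist convergence; with
#'   `"per_bit"` every bit flips independently with this probability.
#' @param elitism_fraction fraction of the population copied unchanged into
#'   the next generation (elites remain eligible as parents).
#' @param selection_pressure linear-ranking pressure `SP` in `(1, 2]`.
#' @param max_generations generation budget.
#' @param stall_generations consecutive generations without significant
#'   improvement tolerated before stopping.
#' @param stall_epsilon minimum decrease of the best MSE that counts as a
#'   significant change.
#' @param max_evaluations hard cap on total fitness evaluations (cache
#'   misses); the loop ends gracefully with partial results when reached.
#' @param mutation_mode see `mutation_prob`.
#' @param seed master seed of the run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, crossover_prob = 0.8,
                      mutation_prob = 0.1, elitism_fraction = 0.10,
                      selection_pressure = 2, max_generations = 100,
                      stall_generations = 5, stall_epsilon = 1e-4,
                      max_evaluations = 20000,
                      mutation_mode = c("per_individual", "per_bit"),
                      seed = NULL) {
  mutation_mode <- match.arg(mutation_mode)
  for (p in c(crossover_prob, mutation_prob, elitism_fraction))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (selection_pressure <= 1 || selection_pressure > 2)
    stopf("selection_pressure must lie in (1, 2]")
  if (stall_generations < 1) stopf("stall_generations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_fraction = elitism_fraction,
                 selection_pressure = selection_pressure,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 stall_epsilon = stall_epsilon,
                 max_evaluations = as.integer(max_evaluations),
                 mutation_mode = mutation_mode, seed = seed),
            class = "ga_config")
}

#' Linear ranking selection
#'
#' Individuals are ranked by ascending fitness value (a minimised MSE: best
#' = rank `N`), and sampled with replacement with probability linear in
#' rank: `p(r) = (2 - SP)/N + 2 (r - 1) (SP - 1) / (N (N - 1))` for rank
#' `r` counted from 1 (worst) to `N` (best). At `SP = 2` the worst
#' individual has probability zero; at `N = 2` the best is chosen with
#' probability 1.
#'
#' @param fitnesses numeric vector of fitness values (lower is better).
#' @param n_parents how many parents to draw.
#' @param pressure selection pressure `SP`.
#' @return Integer vector of selected indices.
#' @export
linear_rank_select <- function(fitnesses, n_parents, pressure = 2) {
  N <- length(fitnesses)
  if (N == 0L) stopf("empty population")
  # best (lowest MSE) gets the highest rank; ties share their average rank so
  # that equal-fitness individuals are selected symmetrically
  rank_of <- rank(-fitnesses, ties.method = "average")
  prob <- (2 - pressure) / N +
    2 * (rank_of - 1) * (pressure - 1) / (N * (N - 1))
  sample.int(N, n_parents, replace = TRUE, prob = prob)
}

#' Uniform crossover
#'
#' With probability `prob` every position independently swaps or keeps the
#' parental alleles (each child inherits each locus from either parent with
#' equal chance, and the two children are complementary); otherwise the
#' children are clones of the parents.
#'
#' @param p1,p2 equal-length 0/1 genomes.
#' @param prob crossover probability.
#' @return A list with `child1` and `child2`.
#' @export
uniform_crossover <- function(p1, p2, prob = 0.8) {
  if (length(p1) != length(p2)) stopf("parent genomes differ in length")
  if (stats::runif(1) < prob) {
    swap <- stats::runif(length(p1)) < 0.5
    c1 <- ifelse(swap, p2, p1)
    c2 <- ifelse(swap, p1, p2)
    list(child1 = c1, child2 = c2)
  } else {
    list(child1 = p1, child2 = p2)
  }
}

#' Uniform random mutation
#'
#' @param bits 0/1 genome.
#' @param prob mutation probability (interpretation set by `mode`).
#' @param mode `"per_individual"`: with probability `prob` the individual
#'   mutates, each bit then flipping with rate `1/length` (expected one flip
#'   per mutated individual); `"per_bit"`: every bit flips independently
#'   with probability `prob`.
#' @return The mutated genome.
#' @export
mutate_genome <- function(bits, prob = 0.1,
                          mode = c("per_individual", "per_bit")) {
  mode <- match.arg(mode)
  if (mode == "per_individual") {
    if (stats::runif(1) >= prob) return(bits)
    flip <- stats::runif(length(bits)) < 1 / length(bits)
  } else {
    flip <- stats::runif(length(bits)) < prob
  }
  bits[flip] <- 1L - bits[flip]
  bits
}

#' Run the generational evolutionary loop
#'
#' The engine is agnostic about what the bits mean: it takes any fitness
#' function over genomes and minimises it. Each generation: evaluate (with
#' a cache keyed by the bit string, so re-scored duplicates cost nothing
#' and elites keep their fitness), log, copy elites, rank-select parents,
#' recombine, mutate, replace. The loop stops at the generation budget, at
#' the evaluation cap, or once the best fitness has failed to improve by at
#' least `stall_epsilon` for `stall_generations` consecutive generations.
#'
#' @param fitness_fn function taking a genome (integer 0/1 vector) and
#'   returning a single numeric fitness (lower is better). An error inside
#'   the fitness function demotes that individual to the worst-fitness
#'   sentinel rather than aborting the run.
#' @param n_bits genome length.
#' @param config a [ga_config()].
#' @param init_fn optional function returning one initial genome; defaults
#'   to i.i.d. fair bits.
#' @return An object of class `emdav_evolution`: list with `generations`
#'   (data frame of best/mean/worst fitness and the best genome string per
#'   generation), `best_bits`, `best_fitness`, `evaluations` (number of
#'   fitness calls), `termination` (`"max_generations"`, `"stall"` or
#'   `"evaluation_cap"`), and `config`.
#' @examples
#' res <- evolve(function(g) sum(g), n_bits = 12,
#'               config = ga_config(population_size = 20,
#'                                  max_generations = 30, seed = 1))
#' res$best_fitness   # 0: the all-zero genome
#' @export
evolve <- function(fitness_fn, n_bits, config = ga_config(), init_fn = NULL) {
  stopifnot(inherits(config, "ga_config"))
  N <- config$population_size
  with_seed(config$seed, {
    if (is.null(init_fn))
      init_fn <- function() as.integer(stats::runif(n_bits) < 0.5)
    pop <- t(vapply(seq_len(N), function(i) init_fn(), integer(n_bits)))
    cache <- new.env(parent = emptyenv())
    evaluations <- 0L
    eval_genome <- function(bits) {
      key <- bits_to_string(bits)
      if (!is.null(cache[[key]])) return(cache[[key]])
      if (evaluations >= config$max_evaluations) return(NA_real_)
      evaluations <<- evaluations + 1L
      f <- tryCatch(fitness_fn(bits), error = function(e) WORST_FITNESS)
      if (!is.finite(f)) f <- WORST_FITNESS
      cache[[key]] <- f
      f
    }
    n_elite <- max(0L, round(config$elitism_fraction * N))
    log <- vector("list", config$max_generations)
    best_bits <- NULL; best_fit <- Inf
    stall <- 0L; termination <- "max_generations"
    for (gen in seq_len(config$max_generations)) {
      fits <- apply(pop, 1L, eval_genome)
      if (anyNA(fits)) { termination <- "evaluation_cap"; break }
      ord <- order(fits)
      gen_best <- fits[ord[1L]]
      if (gen_best < best_fit - config$stall_epsilon) stall <- 0L
      else stall <- stall + 1L
      if (gen_best < best_fit) {
        best_fit <- gen_best
        best_bits <- pop[ord[1L], ]
      }
      log[[gen]] <- data.frame(generation = gen, best = best_fit,
                               gen_best = gen_best, mean = mean(fits),
                               worst = max(fits),
                               best_genome = bits_to_string(best_bits),
                               evaluations = evaluations,
                               stringsAsFactors = FALSE)
      if (stall >= config$stall_generations) { termination <- "stall"; break }
      if (gen == config$max_generations) break
      elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      n_children <- N - n_elite
      parents <- linear_rank_select(fits, 2L * ceiling(n_children / 2),
                                    config$selection_pressure)
      children <- matrix(0L, 0L, n_bits)
      for (i in seq_len(length(parents) / 2)) {
        pr <- uniform_crossover(pop[parents[2L * i - 1L], ],
                                pop[parents[2L * i], ], config$crossover_prob)
        children <- rbind(children, pr$child1, pr$child2)
      }
      children <- children[seq_len(n_children), , drop = FALSE]
      children <- t(apply(children, 1L, mutate_genome,
                          prob = config$mutation_prob,
                          mode = config$mutation_mode))
      if (n_children == 1L) children <- matrix(children, 1L, n_bits)
      pop <- rbind(elites, children)
    }
    structure(list(generations = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
                   best_bits = best_bits, best_fitness = best_fit,
                   evaluations = evaluations, termination = termination,
                   config = config),
              class = "emdav_evolution")
  })
}

#' @export
print.emdav_evolution <- function(x, ...) {
  ng <- nrow(x$generations)
  cat(sprintf("Evolutionary run: %d generations, %d evaluations (%s)\n",
              ng, x$evaluations, x$termination))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  invisible(x)
}
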