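test_that("linear ranking at N = 2, SP = 2 always picks the better parent", {
  set.seed(1)
  picks <- linear_rank_select(c(0.2, 0.9), 500, pressure = 2)
  expect_true(all(picks == 1))
})

test_that("equal fitnesses select uniformly; pressure favours the best", {
  set.seed(2)
  picks <- linear_rank_select(rep(1, 4), 10000, pressure = 2)
  freq <- tabulate(picks, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))

  fits <- c(0.5, 0.1, 0.9, 0.3)   # best is index 2, worst index 3
  picks2 <- linear_rank_select(fits, 10000, pressure = 1.5)
  freq2 <- tabulate(picks2, 4) / 10000
  expect_gt(freq2[2], freq2[3])
  expect_equal(order(freq2), order(-fits))
})

test_that("uniform crossover conserves alleles positionwise", {
  set.seed(3)
  p1 <- rep(1L, 40)
  p2 <- rep(0L, 40)
  ch <- uniform_crossover(p1, p2, prob = 1)
  expect_true(all(ch$child1 + ch$child2 == 1L))   # complementary parents
  same <- uniform_crossover(p1, p1, prob = 1)
  expect_identical(same$child1, p1)
  expect_identical(same$child2, p1)
  set.seed(4)
  g1 <- as.integer(runif(30) < 0.5); g2 <- as.integer(runif(30) < 0.5)
  for (i in 1:20) {
    ch <- uniform_crossover(g1, g2, prob = 1)
    expect_true(all((ch$child1 == g1 & ch$child2 == g2) |
                    (ch$child1 == g2 & ch$child2 == g1)))
  }
  expect_error(uniform_crossover(g1, g2[-1]), "length")
})

test_that("crossover inherits each locus 50/50 and respects its probability", {
  set.seed(5)
  p1 <- rep(1L, 8); p2 <- rep(0L, 8)
  kids <- replicate(10000, uniform_crossover(p1, p2, prob = 1)$child1)
  freq <- rowMeans(kids)
  expect_true(all(abs(freq - 0.5) < 5 * sqrt(0.25 / 10000)))
  clones <- replicate(2000, identical(uniform_crossover(p1, p2, 0)$child1, p1))
  expect_true(all(clones))
})

test_that("mutation honours its probability semantics", {
  g <- rep(0L, 50)
  set.seed(6)
  expect_identical(mutate_genome(g, prob = 0), g)
  expect_identical(mutate_genome(g, prob = 1, mode = "per_bit"), rep(1L, 50))
  flips <- replicate(10000, sum(mutate_genome(g, prob = 0.1)))
  # expected flips per call = 0.1 * 50 * (1/50) = 0.1
  se <- sd(flips) / sqrt(10000)
  expect_lt(abs(mean(flips) - 0.1), 3 * se + 1e-6)
})

test_that("the engine minimises a transparent surrogate and logs monotonically", {
  cfg <- ga_config(population_size = 12, max_generations = 15,
                   stall_generations = 100, seed = 7)
  res <- evolve(function(g) sum(g), n_bits = 10, config = cfg)
  expect_s3_class(res, "emdav_evolution")
  expect_true(all(diff(res$generations$best) <= 0))
  expect_equal(res$best_fitness, sum(res$best_bits))
  expect_lte(res$best_fitness, 2)
})

test_that("surrogate optimum matches exhaustive search on most seeds", {
  hits <- vapply(1:4, function(s) {
    res <- evolve(function(g) sum(g), n_bits = 8,
                  config = ga_config(population_size = 20,
                                     max_generations = 25,
                                     stall_generations = 100, seed = s))
    res$best_fitness == 0   # exhaustive optimum of sum(bits) is all-zeros
  }, TRUE)
  expect_gte(sum(hits), 3)
})

test_that("without variation the population collapses onto the elites", {
  cfg <- ga_config(population_size = 10, crossover_prob = 0, mutation_prob = 0,
                   max_generations = 12, stall_generations = 100,
                   elitism_fraction = 0.2, seed = 8)
  res <- evolve(function(g) sum(g) + 0, n_bits = 6, config = cfg)
  # best fitness can only improve by re-sampling elites: still monotone and
  # the final best equals the best initial individual's fitness
  expect_true(all(diff(res$generations$best) <= 0))
})

test_that("errors in the fitness function demote, not abort", {
  flaky <- function(g) if (g[1] == 1L) stop("boom") else sum(g)
  res <- evolve(flaky, n_bits = 5,
                config = ga_config(population_size = 8, max_generations = 6,
                                   stall_generations = 100, seed = 9))
  expect_s3_class(res, "emdav_evolution")
  expect_equal(res$best_bits[1], 0L)
})

test_that("the stall criterion and evaluation cap terminate the loop", {
  res <- evolve(function(g) 1, n_bits = 6,
                config = ga_config(population_size = 6, max_generations = 50,
                                   stall_generations = 3, seed = 10))
  expect_identical(res$termination, "stall")
  # constant fitness cannot improve: exactly stall_generations + 1 logged
  expect_lte(nrow(res$generations), 4)

  res2 <- evolve(function(g) sum(g), n_bits = 20,
                 config = ga_config(population_size = 10, max_generations = 50,
                                    stall_generations = 100,
                                    max_evaluations = 25, seed = 11))
  expect_identical(res2$termination, "evaluation_cap")
  expect_lte(res2$evaluations, 25)
})

test_that("identical master seeds reproduce an evolution exactly", {
  cfg <- ga_config(population_size = 10, max_generations = 8,
                   stall_generations = 100, seed = 12)
  a <- evolve(function(g) sum(g * seq_along(g)), n_bits = 15, config = cfg)
  b <- evolve(function(g) sum(g * seq_along(g)), n_bits = 15, config = cfg)
  expect_identical(a$generations, b$generations)
  expect_identical(a$best_bits, b$best_bits)
})

test_that("population size is maintained across generations", {
  counter <- new.env(); counter$n <- 0
  fit <- function(g) { counter$n <- counter$n + 1; sum(g) }
  cfg <- ga_config(population_size = 9, max_generations = 5,
                   stall_generations = 100, elitism_fraction = 0.1, seed = 13)
  res <- evolve(fit, n_bits = 12, config = cfg)
  # unique evaluations can be fewer than pop * generations (cache), never more
  expect_lte(res$evaluations, 9 * 5)
  expect_equal(nrow(res$generations), 5)
})
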