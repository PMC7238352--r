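toyFitness <- function(genes) length(intersect(genes, c(2, 5, 9))) / length(genes)

test_that("population initialization is seeded, sized and duplicate-free", {
  cfg <- gaConfig(5, populationBase = 6L, nFeatures = 30L, seed = 9L)
  p1 <- initPopulation(cfg)
  p2 <- initPopulation(cfg)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(24L, 5L))
  expect_equal(nrow(p1) %% 4, 0)
  expect_true(all(apply(p1, 1, anyDuplicated) == 0))
  expect_true(all(p1 >= 1 & p1 <= 30))

  # L = F: every chromosome is a permutation
  full <- initPopulation(gaConfig(10, populationBase = 2L, nFeatures = 10L))
  expect_true(all(apply(full, 1, function(g) identical(sort(g), 1:10))))
  expect_error(gaConfig(11, nFeatures = 10L), "L <= nFeatures")
})

test_that("roulette probabilities implement fitness-proportional selection", {
  expect_equal(rouletteProbabilities(c(1, 3)), c(0.25, 0.75))
  expect_equal(rouletteProbabilities(rep(2, 5)), rep(0.2, 5))
  expect_equal(rouletteProbabilities(7), 1)
  expect_message(u <- rouletteProbabilities(c(0, 0, 0)), "uniform")
  expect_equal(u, rep(1 / 3, 3))
  expect_equal(sum(rouletteProbabilities(runif(50))), 1, tolerance = 1e-12)
  expect_error(rouletteProbabilities(c(1, -1)), "non-negative")
})

test_that("(L-1)-point crossover alternates parental genes positionally", {
  # the canonical 5-gene alternation example: ABCDE x abcde -> AbCdE / aBcDe
  kids <- kpointCrossover(1:5, 11:15)
  expect_equal(kids[[1]], c(1, 12, 3, 14, 5))
  expect_equal(kids[[2]], c(11, 2, 13, 4, 15))

  kids3 <- kpointCrossover(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kids3[[1]], c(1, 5, 3))
  expect_equal(kids3[[2]], c(4, 2, 6))

  same <- kpointCrossover(c(7, 8, 9), c(7, 8, 9))
  expect_equal(same[[1]], c(7, 8, 9))
  expect_equal(same[[2]], c(7, 8, 9))

  expect_error(kpointCrossover(1:3, 1:4), "mismatch")
})

test_that("mutation repairs duplicates and never produces them", {
  cfg <- gaConfig(3, nFeatures = 10L, mutationProb = 0)
  set.seed(1)
  # duplicate 7 repaired, 9 and one 7 retained
  out <- mutateChromosome(c(7, 7, 9), cfg)
  expect_equal(anyDuplicated(out), 0)
  expect_true(all(c(7, 9) %in% out))

  # no duplicates and Pm = 0: unchanged
  expect_equal(mutateChromosome(c(1, 2, 3), cfg), c(1, 2, 3))

  # invariant sweep: 1000 mutated chromosomes, never a duplicate id
  cfgM <- gaConfig(6, nFeatures = 20L, mutationProb = 0.2)
  set.seed(5)
  for (i in 1:1000) {
    g <- sample.int(20, 6, replace = TRUE)
    m <- mutateChromosome(g, cfgM)
    expect_equal(anyDuplicated(m), 0)
    expect_true(all(m >= 1 & m <= 20))
  }
})

test_that("the GA converges on the toy landscape with monotone elitist progress", {
  cfg <- gaConfig(3, nFeatures = 10L, seed = 42L)
  res <- runGA(toyFitness, cfg)
  expect_equal(sort(res$genes), c(2, 5, 9))
  expect_equal(res$fitness, 1)
  # elitism: best-so-far non-decreasing every generation
  expect_true(all(diff(res$history) >= 0))
  # determinism
  expect_identical(res, runGA(toyFitness, cfg))
})

test_that("fitness is evaluated at most once per distinct subset", {
  calls <- new.env(); calls$keys <- character(0)
  counting <- function(genes) {
    calls$keys <- c(calls$keys, paste(sort(genes), collapse = ","))
    toyFitness(genes)
  }
  res <- runGA(counting, gaConfig(3, nFeatures = 10L, seed = 3L))
  expect_equal(anyDuplicated(calls$keys), 0)
  expect_equal(length(calls$keys), res$evaluations)
})

test_that("the sweep explores every size and reports a consistent global best", {
  sw <- gaSweep(toyFitness, nFeatures = 10, seed = 2L)
  expect_equal(nrow(sw$perL), 10)
  # L = 1 equals the exhaustive single-feature argmax
  singles <- vapply(1:10, toyFitness, numeric(1))
  expect_equal(sw$perL$fitness[1], max(singles))
  expect_equal(sw$genesPerL[[1]], which.max(singles))
  # global best is the max over sizes, ties towards smaller subsets
  expect_equal(sw$globalBest$fitness, max(sw$perL$fitness))
  expect_equal(sw$globalBest$L, sw$perL$L[which.max(sw$perL$fitness)])
  # fitness falls once uninformative features are forced in
  expect_lt(sw$perL$fitness[10], max(sw$perL$fitness))
  # ties (L = 1..3 all reach fitness 1) resolve to the most parsimonious size
  expect_equal(sw$globalBest$L, 1L)
  expect_true(sw$globalBest$genes %in% c(2, 5, 9))
  # the L = 3 winner is exactly the planted triple
  expect_equal(sort(sw$genesPerL[[3]]), c(2, 5, 9))
})
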