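# Modified genetic feature selection. Chromosomes are fixed-length sequences
# of DISTINCT integer feature ids (not bitmasks), so every chromosome encodes
# a subset of exactly L features. The GA combines elitism (best 2 copied
# unchanged), roulette-wheel selection, (L-1)-point crossover (genes
# alternate between the parents position by position) and a
# duplicate-repairing mutation; it stops when the best fitness has stagnated.
# A sweep runs the GA for every subset size L and returns the global best.

#' GA configuration
#'
#' @param L chromosome length (subset size).
#' @param populationBase population size is `4 * populationBase` (sizes are
#'   kept divisible by 4); defaults to the sweep schedule value.
#' @param elitismCount elite chromosomes copied unchanged each generation
#'   (fixed default 2).
#' @param crossoverProb crossover probability (default 1).
#' @param mutationProb per-gene random-resetting probability `Pm`
#'   (default 0.01).
#' @param stagnationX generations without best-fitness improvement before
#'   stopping (default 10).
#' @param maxGenerations hard generation cap.
#' @param nFeatures total number of selectable features `F` (default 130).
#' @param seed RNG seed for the run.
#' @return a list of class `GAConfig`.
#' @export
gaConfig <- function(L, populationBase = NULL, elitismCount = 2L,
                     crossoverProb = 1, mutationProb = 0.01,
                     stagnationX = 10L, maxGenerations = NULL,
                     nFeatures = 130L, seed = 1L) {
  L <- as.integer(L)
  nFeatures <- as.integer(nFeatures)
  if (L < 1L || L > nFeatures) stop("require 1 <= L <= nFeatures")
  if (is.null(populationBase))
    populationBase <- max(5L, as.integer(ceiling((nFeatures - L + 4L) / 4)))
  if (is.null(maxGenerations))
    maxGenerations <- max(15L, as.integer(60 - L / 3))
  popSize <- 4L * as.integer(populationBase)
  if (popSize < 4L) stop("population size must be >= 4")
  structure(list(L = L, popSize = popSize, elitismCount = as.integer(elitismCount),
                 crossoverProb = crossoverProb, mutationProb = mutationProb,
                 stagnationX = as.integer(stagnationX),
                 maxGenerations = as.integer(maxGenerations),
                 nFeatures = nFeatures, seed = as.integer(seed)),
            class = "GAConfig")
}

#' Initialize a random population of distinct-id chromosomes
#'
#' @param cfg a [gaConfig()].
#' @return integer matrix `popSize x L`; each row a uniform random subset of
#'   `1..nFeatures` without replacement, deterministic under `cfg$seed`.
#' @export
initPopulation <- function(cfg) {
  stopifnot(inherits(cfg, "GAConfig"))
  .withSeed(cfg$seed, t(vapply(seq_len(cfg$popSize), function(i)
    sample.int(cfg$nFeatures, cfg$L), integer(cfg$L))))
}

#' Roulette-wheel selection probabilities
#'
#' `P(c_i) = f(c_i) / sum_j f(c_j)`. All-zero fitness degenerates to the
#' uniform distribution (with a message), so selection never stalls.
#'
#' @param fitnesses non-negative fitness scores.
#' @return probability vector summing to 1.
#' @export
rouletteProbabilities <- function(fitnesses) {
  if (length(fitnesses) == 0L) stop("no fitnesses")
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  s <- sum(fitnesses)
  if (s <= 0) {
    message("all-zero fitness: uniform selection probabilities")
    return(rep(1 / length(fitnesses), length(fitnesses)))
  }
  fitnesses / s
}

#' (L-1)-point crossover
#'
#' With a crossover point between every adjacent gene pair (`K = L - 1`),
#' the exchanged segments are single genes, so the children alternate
#' parental genes position by position: child 1 takes parent 1's genes at
#' positions 1, 3, 5, ... and parent 2's at positions 2, 4, 6, ...; child 2
#' is the converse. Applied with probability 1 by default.
#'
#' @param p1,p2 integer gene vectors of equal length `L >= 2`.
#' @return list of two children (possibly containing duplicate ids, which
#'   [mutateChromosome()] repairs).
#' @export
kpointCrossover <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("parent length mismatch")
  L <- length(p1)
  if (L < 2L) stop("crossover requires L >= 2")
  odd <- seq(1L, L, by = 2L)
  c1 <- p2; c1[odd] <- p1[odd]
  c2 <- p1; c2[odd] <- p2[odd]
  list(c1, c2)
}

#' Duplicate-repairing mutation
#'
#' Every duplicated id beyond its first occurrence is replaced by a uniform
#' random id not currently present (the guided repair that keeps chromosomes
#' valid feature subsets after crossover); additionally each gene is reset
#' independently with probability `Pm` to a random absent id. The result
#' always has all-distinct ids.
#'
#' @param genes integer gene vector, possibly with duplicates.
#' @param cfg a [gaConfig()] (supplies `mutationProb` and `nFeatures`).
#' @return integer gene vector with distinct ids in `1..nFeatures`.
#' @export
mutateChromosome <- function(genes, cfg) {
  F <- cfg$nFeatures
  dup <- duplicated(genes)
  if (any(dup)) {
    pool <- setdiff(seq_len(F), genes)
    repl <- if (length(pool) == 1L) pool else sample(pool, sum(dup))
    genes[dup] <- repl
  }
  hit <- which(stats::runif(length(genes)) < cfg$mutationProb)
  for (i in hit) {
    pool <- setdiff(seq_len(F), genes)
    if (length(pool) == 0L) break
    genes[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  genes
}

# order-insensitive cache key for a feature subset
.subsetKey <- function(genes) paste(sort(genes), collapse = ",")

# fitness with per-subset memoisation; cache env maps key -> score
.evalFitness <- function(genes, fitnessFn, cache) {
  key <- .subsetKey(genes)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- fitnessFn(genes)
  if (!is.finite(val) || val < 0) stop("fitness must be a non-negative number")
  cache[[key]] <- val
  val
}

#' Run the genetic algorithm for one subset size
#'
#' Generational loop: evaluate all chromosomes (memoised per distinct
#' subset), copy the two elites unchanged, fill the remainder with
#' roulette-selected parents recombined by [kpointCrossover()] and repaired
#' by [mutateChromosome()]. Stops when the best fitness has not improved for
#' `stagnationX` generations or at `maxGenerations`. With elitism the
#' per-generation best is non-decreasing; the best-ever chromosome is
#' returned.
#'
#' @param fitnessFn function mapping an integer id subset to a non-negative
#'   score (deterministic for reproducibility).
#' @param cfg a [gaConfig()].
#' @return list with `genes`, `fitness`, `history` (best per generation),
#'   `evaluations` (distinct subsets evaluated) and `generations`.
#' @export
runGA <- function(fitnessFn, cfg) {
  stopifnot(inherits(cfg, "GAConfig"))
  cache <- new.env(parent = emptyenv())
  pop <- initPopulation(cfg)
  .withSeed(cfg$seed + 1L, {
    fit <- apply(pop, 1, .evalFitness, fitnessFn, cache)
    bestIdx <- which.max(fit)
    best <- list(genes = pop[bestIdx, ], fitness = fit[bestIdx])
    history <- best$fitness
    stagnation <- 0L
    gen <- 0L
    while (gen < cfg$maxGenerations && stagnation < cfg$stagnationX) {
      gen <- gen + 1L
      elite <- order(fit, decreasing = TRUE)[seq_len(cfg$elitismCount)]
      newPop <- pop[elite, , drop = FALSE]
      prob <- suppressMessages(rouletteProbabilities(fit))
      while (nrow(newPop) < cfg$popSize) {
        par <- sample.int(nrow(pop), 2L, replace = TRUE, prob = prob)
        if (cfg$L >= 2L && stats::runif(1) <= cfg$crossoverProb) {
          kids <- kpointCrossover(pop[par[1], ], pop[par[2], ])
        } else {
          kids <- list(pop[par[1], ], pop[par[2], ])
        }
        kids <- lapply(kids, mutateChromosome, cfg)
        newPop <- rbind(newPop, kids[[1]], kids[[2]])
      }
      pop <- newPop[seq_len(cfg$popSize), , drop = FALSE]
      fit <- apply(pop, 1, .evalFitness, fitnessFn, cache)
      genBest <- max(fit)
      if (genBest > best$fitness) {
        bestIdx <- which.max(fit)
        best <- list(genes = pop[bestIdx, ], fitness = genBest)
        stagnation <- 0L
      } else {
        stagnation <- stagnation + 1L
      }
      # elitism guarantees monotone best-so-far; record the running best
      history <- c(history, best$fitness)
    }
    list(genes = as.integer(best$genes), fitness = unname(best$fitness),
         history = unname(history), evaluations = length(ls(cache)),
         generations = gen)
  })
}

#' Sweep the GA over all subset sizes
#'
#' Explores every chromosome length on the schedule: `L = 1` by exhaustive
#' evaluation of all single features, `L = F` by evaluating the full set
#' once, and intermediate sizes by [runGA()] with a population/generation
#' schedule that shrinks slowly as `L` grows. Returns the per-size bests and
#' the global best (ties broken towards the smaller subset).
#'
#' @param fitnessFn subset fitness function (as in [runGA()]).
#' @param nFeatures total feature count `F`.
#' @param lValues subset sizes to explore (default `1:nFeatures`).
#' @param populationBase,maxGenerations,stagnationX,mutationProb optional
#'   schedule overrides applied to every GA run (defaults as in
#'   [gaConfig()]).
#' @param seed base seed; run `L` uses `seed + L`.
#' @return list of class `GASweep` with `perL` (data.frame of `L`, `fitness`,
#'   `genes` list-column) and `globalBest` (list with `L`, `genes`,
#'   `fitness`).
#' @export
gaSweep <- function(fitnessFn, nFeatures, lValues = seq_len(nFeatures),
                    populationBase = NULL, maxGenerations = NULL,
                    stagnationX = 10L, mutationProb = 0.01, seed = 1L) {
  lValues <- sort(unique(as.integer(lValues)))
  if (any(lValues < 1L | lValues > nFeatures)) stop("lValues outside 1..F")
  rows <- lapply(lValues, function(L) {
    if (L == 1L) {
      fits <- vapply(seq_len(nFeatures), function(i) fitnessFn(i), numeric(1))
      list(L = 1L, genes = which.max(fits), fitness = max(fits))
    } else if (L == nFeatures) {
      genes <- seq_len(nFeatures)
      list(L = L, genes = genes, fitness = fitnessFn(genes))
    } else {
      cfg <- gaConfig(L, populationBase = populationBase,
                      maxGenerations = maxGenerations,
                      stagnationX = stagnationX, mutationProb = mutationProb,
                      nFeatures = nFeatures, seed = seed + L)
      res <- runGA(fitnessFn, cfg)
      list(L = L, genes = res$genes, fitness = res$fitness)
    }
  })
  fits <- vapply(rows, `[[`, numeric(1), "fitness")
  bestIdx <- which.max(fits)  # which.max takes the first maximum: smallest L
  structure(list(
    perL = data.frame(L = vapply(rows, `[[`, integer(1), "L"), fitness = fits),
    genesPerL = lapply(rows, `[[`, "genes"),
    globalBest = rows[[bestIdx]]), class = "GASweep")
}

#' @export
print.GASweep <- function(x, ...) {
  cat(sprintf("GA sweep over %d subset sizes; global best: L = %d, fitness = %.4f\n",
              nrow(x$perL), x$globalBest$L, x$globalBest$fitness))
  cat("best subset ids:", paste(sort(x$globalBest$genes), collapse = " "), "\n")
  invisible(x)
}
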