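#' Genetic-algorithm configuration
#'
#' Integer-coded GA with tournament selection, uniform crossover, per-gene
#' mutation and single-individual elitism. The same configuration and seed
#' always reproduce the same trajectory.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param crossover_rate probability a child is produced by uniform crossover
#'   (otherwise it is a copy of the first parent).
#' @param mutation_rate per-gene mutation probability.
#' @param tournament_size individuals drawn per tournament.
#' @param seed integer RNG seed; every run with the same seed, config and
#'   inputs is bit-identical.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      tournament_size = 3, seed = 1) {
  stopifnot(
    population_size > 1, generations >= 1, tournament_size >= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1
  )
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         tournament_size = as.integer(tournament_size),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Minimize a fitness function over integer-coded chromosomes
#'
#' Generic engine behind the ring-diameter and shim-grid optimizers. Genes
#' take integer values `1..n_levels[g]`. `fitness` receives the whole
#' population as an integer matrix (individuals in rows) and must return one
#' fitness value per row; lower is better. Mutation replaces a gene by a
#' uniform draw from its levels. Elitism guarantees the best-so-far fitness
#' is non-increasing across generations.
#'
#' @param fitness function(matrix) -> numeric vector of length nrow(matrix).
#' @param n_levels integer vector: number of levels per gene.
#' @param config a [ga_config()].
#' @param init optional integer matrix of initial individuals (rows are
#'   recycled/truncated to the population size).
#' @return list with `best` (integer vector), `best_fitness`, `trace`
#'   (tibble generation/best/mean), `population`, `fitness`.
#' @export
ga_optimize <- function(fitness, n_levels, config = ga_config(), init = NULL) {
  stopifnot(inherits(config, "ga_config"), all(n_levels >= 1))
  ng <- length(n_levels)
  np <- config$population_size
  run <- function() {
    pop <- matrix(0L, np, ng)
    for (g in seq_len(ng)) pop[, g] <- sample.int(n_levels[g], np, replace = TRUE)
    if (!is.null(init)) {
      init <- matrix(as.integer(init), ncol = ng)
      take <- min(nrow(init), np)
      pop[seq_len(take), ] <- init[seq_len(take), , drop = FALSE]
    }
    fit <- fitness(pop)
    trace <- matrix(0, config$generations, 2)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      newpop <- matrix(0L, np, ng)
      newpop[1, ] <- pop[ord[1], ]           # elite
      for (i in 2:np) {
        p1 <- .tournament(fit, config$tournament_size)
        if (runif(1) < config$crossover_rate) {
          p2 <- .tournament(fit, config$tournament_size)
          pick <- runif(ng) < 0.5
          child <- ifelse(pick, pop[p1, ], pop[p2, ])
        } else {
          child <- pop[p1, ]
        }
        mut <- which(runif(ng) < config$mutation_rate)
        if (length(mut)) {
          child[mut] <- vapply(mut, function(g) sample.int(n_levels[g], 1L), 1L)
        }
        newpop[i, ] <- child
      }
      pop <- newpop
      fit <- fitness(pop)
      # elitism makes the best monotone; assert it as a run invariant
      if (gen > 1 && min(fit) > trace[gen - 1, 1] + 1e-12) {
        abort("internal error: elitism violated (best fitness increased).")
      }
      trace[gen, ] <- c(min(fit), mean(fit))
    }
    ib <- which.min(fit)
    list(best = pop[ib, ], best_fitness = fit[ib],
         trace = tibble(generation = seq_len(config$generations),
                        best = trace[, 1], mean = trace[, 2]),
         population = pop, fitness = fit)
  }
  .with_seed(config$seed, run())
}

.tournament <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.min(fit[cand])]
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
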