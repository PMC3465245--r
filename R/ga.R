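# Compact real-valued genetic algorithm used to train the tier weights and
# the combined-model genome: tournament selection, uniform crossover,
# per-gene Gaussian mutation, elitism.  Maximises the fitness function.

#' Genetic-algorithm control parameters
#'
#' @param pop_size population size (default 80).
#' @param generations number of generations (default 100).
#' @param p_crossover probability a pair of parents is recombined (uniform
#'   crossover, each gene swapped with probability 1/2; default 0.9).
#' @param p_mutation per-gene mutation probability (default 0.02).
#' @param mutation_sd standard deviation of the Gaussian mutation step
#'   (default 0.1).
#' @param elitism number of top genomes copied unchanged into the next
#'   generation (default 1; guarantees a non-decreasing best-fitness trace).
#' @param tournament tournament size for parent selection (default 2).
#' @return list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 80L, generations = 100L,
                       p_crossover = 0.9, p_mutation = 0.02,
                       mutation_sd = 0.1, elitism = 1L, tournament = 2L) {
  stopifnot(pop_size >= 2L, generations >= 1L, elitism >= 0L,
            elitism < pop_size, tournament >= 1L)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_sd = mutation_sd, elitism = as.integer(elitism),
                 tournament = as.integer(tournament)),
            class = "ga_control")
}

#' Maximise a fitness function over a bounded real genome
#'
#' @param fitness function mapping a numeric genome to a scalar fitness
#'   (larger is better).
#' @param n_genes genome length.
#' @param lower,upper bounds, recycled to `n_genes`.
#' @param control a [ga_control()].
#' @param seed optional integer; the run is fully reproducible given the seed.
#' @return list with `par` (best genome), `value` (its fitness) and `trace`
#'   (best fitness per generation, non-decreasing under elitism >= 1).
#' @export
ga_optimize <- function(fitness, n_genes, lower = 0, upper = 1,
                        control = ga_control(), seed = NULL) {
  stopifnot(inherits(control, "ga_control"), n_genes >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lower <- rep_len(lower, n_genes); upper <- rep_len(upper, n_genes)
  np <- control$pop_size
  pop <- matrix(stats::runif(np * n_genes, lower, upper),
                nrow = np, byrow = TRUE)
  fit <- apply(pop, 1L, fitness)
  trace <- numeric(control$generations)
  pick <- function() {
    cand <- sample.int(np, control$tournament, replace = TRUE)
    cand[which.max(fit[cand])]
  }
  for (g in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    nxt <- matrix(NA_real_, np, n_genes)
    if (control$elitism > 0L)
      nxt[seq_len(control$elitism), ] <- pop[ord[seq_len(control$elitism)], , drop = FALSE]
    i <- control$elitism
    while (i < np) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < control$p_crossover) {
        swap <- stats::runif(n_genes) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      for (child in list(p1, p2)) {
        if (i >= np) break
        mut <- stats::runif(n_genes) < control$p_mutation
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, control$mutation_sd)
        i <- i + 1L
        nxt[i, ] <- pmin(pmax(child, lower), upper)
      }
    }
    pop <- nxt
    fit <- apply(pop, 1L, fitness)
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], trace = trace)
}
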