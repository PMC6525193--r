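# Real-coded genetic algorithm with elitism, tournament selection, blend
# crossover and Gaussian mutation, used as the global stage of parameter
# estimation. Written for this package: candidates live in a box, an
# optional repair function enforces linear constraints (biomass sum), and
# the whole search is deterministic under a seed.

#' Genetic-algorithm minimization over a box
#'
#' Minimizes `fn` over `[lower, upper]` with a real-coded GA. Every
#' candidate ever evaluated satisfies the bounds and, if supplied, the
#' `repair` projection (used for linear constraints). The best-fitness
#' trace is non-increasing by elitism.
#'
#' @param fn Objective function of a numeric vector, returning a scalar.
#' @param lower,upper Numeric bound vectors (equal length).
#' @param pop_size Population size.
#' @param generations Maximum number of generations (0 returns the best
#'   member of the seeded initial population).
#' @param elite_frac Fraction of the population copied unchanged.
#' @param mutation_sd Mutation standard deviation as a fraction of the
#'   parameter range.
#' @param p_mutate Per-gene mutation probability.
#' @param repair Optional function mapping a candidate into the feasible
#'   set (applied after crossover/mutation and to the initial population).
#' @param seed Integer seed; the search is reproducible given it.
#' @param early_stop_tol,early_stop_gens Stop when the best fitness has
#'   improved by less than `early_stop_tol` over `early_stop_gens`
#'   generations.
#' @return List with `par`, `value`, `trace` (best fitness per generation,
#'   non-increasing), `n_generations`, `n_evals` and `seed`.
#' @export
ga_optimize <- function(fn, lower, upper, pop_size = 60, generations = 200,
                        elite_frac = 0.1, mutation_sd = 0.15,
                        p_mutate = 0.25, repair = NULL, seed = 1,
                        early_stop_tol = 1e-8, early_stop_gens = 20) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  npar <- length(lower)
  rng <- upper - lower
  n_elite <- max(1L, floor(elite_frac * pop_size))
  fix <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    if (!is.null(repair)) x <- pmin(pmax(repair(x), lower), upper)
    x
  }
  set.seed(seed)
  pop <- matrix(0, pop_size, npar)
  for (i in seq_len(pop_size)) {
    pop[i, ] <- fix(lower + stats::runif(npar) * rng)
  }
  fit <- vapply(seq_len(pop_size), function(i) fn(pop[i, ]), 0)
  n_evals <- pop_size
  trace <- min(fit)
  if (generations > 0) {
    for (gen in seq_len(generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(pop_size, 2)
        cand[which.min(fit[cand])]
      }
      children <- matrix(0, pop_size - n_elite, npar)
      n_imm <- max(1L, round(0.1 * pop_size))  # random immigrants keep
      for (k in seq_len(nrow(children))) {     # diversity up
        if (k > nrow(children) - n_imm) {
          children[k, ] <- fix(lower + stats::runif(npar) * rng)
          next
        }
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        a <- stats::runif(npar, -0.25, 1.25)   # blend (BLX) crossover
        child <- a * p1 + (1 - a) * p2
        mut <- stats::runif(npar) < p_mutate
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, mutation_sd * rng[mut])
        children[k, ] <- fix(child)
      }
      child_fit <- vapply(seq_len(nrow(children)),
                          function(k) fn(children[k, ]), 0)
      n_evals <- n_evals + nrow(children)
      pop <- rbind(elite, children)
      fit <- c(fit[ord[seq_len(n_elite)]], child_fit)
      trace <- c(trace, min(fit))
      if (gen > early_stop_gens) {
        if (trace[gen + 1 - early_stop_gens] - trace[gen + 1] <
            early_stop_tol) break
      }
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], trace = cummin(trace),
       n_generations = length(trace) - 1L, n_evals = n_evals, seed = seed)
}
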