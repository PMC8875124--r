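## Seeded differential evolution (rand/1/bin) for the global stages of the
## calibration workflow, plus a seed-scoping helper. Self-contained so runs
## are bit-reproducible given (seed, bounds, control).

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Differential-evolution minimizer
#'
#' Classic DE/rand/1/bin with box constraints (reflection at the bounds),
#' deterministic for a given seed. Used as the evolutionary global stage of
#' the calibration; a local polish (\code{\link[stats]{nlminb}}) typically
#' follows.
#'
#' @param fn Objective, vectorised over a single parameter vector.
#' @param lower,upper Numeric bounds.
#' @param seed Integer seed.
#' @param popSize Population size (default 50).
#' @param generations Number of generations (default 200).
#' @param F Differential weight (default 0.8).
#' @param CR Crossover probability (default 0.9).
#' @param init Optional matrix of initial members (rows), recycled into the
#'   population (e.g. a warm start).
#' @return List: `par`, `value`, `trace` (data.frame generation/best),
#'   `evals`.
#' @export
deOptim <- function(fn, lower, upper, seed = 1L, popSize = 50L,
                    generations = 200L, F = 0.8, CR = 0.9, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  .withSeed(seed, {
    pop <- matrix(runif(popSize * d, rep(lower, each = popSize),
                        rep(upper, each = popSize)), nrow = popSize)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), popSize)
      pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
    }
    fit <- apply(pop, 1, fn)
    evals <- popSize
    trace <- data.frame(generation = 0L, best = min(fit))
    for (g in seq_len(generations)) {
      for (i in seq_len(popSize)) {
        idx <- sample(setdiff(seq_len(popSize), i), 3)
        trial <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        ## reflect into the box
        below <- trial < lower; trial[below] <- pmin(upper, 2 * lower - trial)[below]
        above <- trial > upper; trial[above] <- pmax(lower, 2 * upper - trial)[above]
        trial <- pmin(pmax(trial, lower), upper)
        cross <- runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        trial[!cross] <- pop[i, !cross]
        fv <- fn(trial)
        evals <- evals + 1
        if (is.finite(fv) && fv <= fit[i]) { pop[i, ] <- trial; fit[i] <- fv }
      }
      trace <- rbind(trace, data.frame(generation = g, best = min(fit)))
    }
    b <- which.min(fit)
    list(par = pop[b, ], value = fit[b], trace = trace, evals = evals)
  })
}
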