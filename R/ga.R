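# Small real-coded genetic algorithm: tournament selection, BLX-alpha blend
# crossover, Gaussian mutation, one elite. Deterministic under its seed.
# Used by the window-adjustment step to search the drying-constant
# correction coefficients; kept generic so it can be tested on its own.

#' Control-performance objective
#'
#' Scalar cost combining accuracy, control effort and speed:
#' `KS = w1 * sum(|e(k)|) + w2 * sum(u(k)^2) + w3 * tr`, plus the overshoot
#' percentage when an overshoot exists (piecewise definition). The error sum
#' is taken as the integral of absolute error; `tr` is the rise time in
#' samples (first entry of the error into the target band).
#'
#' @param e Systematic error series.
#' @param u Controller output series.
#' @param tr Rise time, in samples.
#' @param weights Numeric length-3 vector `(w1, w2, w3)`.
#' @param sigma_pct Overshoot percentage, or `NULL`/`NA` when no overshoot
#'   exists.
#' @return The objective value (smaller is better).
#' @export
ga_objective <- function(e, u, tr, weights, sigma_pct = NULL) {
  stopifnot(length(weights) == 3)
  ks <- weights[1] * sum(abs(e)) + weights[2] * sum(u^2) + weights[3] * tr
  if (!is.null(sigma_pct) && is.finite(sigma_pct)) ks <- ks + sigma_pct
  ks
}

#' Real-coded genetic-algorithm minimiser
#'
#' @param fitness Function of a numeric vector returning a scalar cost.
#' @param lower,upper Bounds on the design vector.
#' @param pop Population size (>= 4).
#' @param generations Number of generations.
#' @param pc,pm Crossover and mutation probabilities.
#' @param seed Integer seed; the full trajectory is reproducible.
#' @param init Optional matrix (rows = individuals) seeded into the initial
#'   population, e.g. the incumbent solution.
#' @param blx Blend-crossover expansion factor.
#' @param mut_sd Mutation standard deviation as a fraction of each bound
#'   range.
#' @return A list with `par` (best vector), `value`, and `history` of the
#'   best cost per generation (non-increasing thanks to elitism).
#' @export
ga_optimize <- function(fitness, lower, upper, pop = 40, generations = 50,
                        pc = 0.9, pm = 0.1, seed = 1, init = NULL,
                        blx = 0.3, mut_sd = 0.1) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), pop >= 4)
  rng <- upper - lower
  with_local_seed(seed, {
    P <- matrix(stats::runif(pop * d, rep(lower, each = pop),
                             rep(upper, each = pop)), nrow = pop)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      n0 <- min(nrow(init), pop)
      P[seq_len(n0), ] <- sweep(sweep(init[seq_len(n0), , drop = FALSE],
                                      2, lower, pmax), 2, upper, pmin)
    }
    cost <- apply(P, 1, fitness)
    history <- numeric(generations)
    for (g in seq_len(generations)) {
      elite_i <- which.min(cost)
      elite <- P[elite_i, ]; elite_cost <- cost[elite_i]
      # Binary tournaments pick the parents.
      pick <- function() {
        ij <- sample.int(pop, 2)
        ij[which.min(cost[ij])]
      }
      Q <- matrix(NA_real_, pop, d)
      for (i in seq(1, pop, by = 2)) {
        p1 <- P[pick(), ]; p2 <- P[pick(), ]
        if (stats::runif(1) < pc) {
          lo <- pmin(p1, p2) - blx * abs(p1 - p2)
          hi <- pmax(p1, p2) + blx * abs(p1 - p2)
          c1 <- stats::runif(d, lo, hi); c2 <- stats::runif(d, lo, hi)
        } else {
          c1 <- p1; c2 <- p2
        }
        Q[i, ] <- c1
        if (i + 1 <= pop) Q[i + 1, ] <- c2
      }
      mut <- matrix(stats::runif(pop * d) < pm, pop, d)
      Q[mut] <- Q[mut] + stats::rnorm(sum(mut), 0, mut_sd) *
        rep(rng, each = pop)[mut]
      Q <- sweep(sweep(Q, 2, lower, pmax), 2, upper, pmin)
      cost_q <- apply(Q, 1, fitness)
      # Elitism: the incumbent best replaces the worst child.
      worst <- which.max(cost_q)
      Q[worst, ] <- elite; cost_q[worst] <- elite_cost
      P <- Q; cost <- cost_q
      history[g] <- min(cost)
    }
    best <- which.min(cost)
    list(par = P[best, ], value = cost[best], history = history)
  })
}
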