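# Monte Carlo lineage simulation: many independent single-cell lineages
# followed through successive divisions, keeping one daughter per division.
# Vectorised across lineages, so 1e5 replicates over 10 divisions cost a
# handful of rbinom/rhyper calls.  This is the stochastic counterpart of
# propagate_distribution() and the workhorse of the oracle-equivalence and
# segregational-variance checks.

#' Simulate single-cell lineages through successive divisions
#'
#' Each lineage starts from a cell with `m0` mutant of `total0` mitochondria
#' and is followed through `n` divisions, tracking one randomly chosen
#' daughter per division.  Divisions follow [divide_cell()] semantics:
#' background mutation every division; while the total exceeds `M` the pool
#' is partitioned without replication (oogamous early development); at the
#' baseline the division is replicative (copying-error mutation, duplication,
#' hypergeometric partition).
#'
#' @param m0 Initial mutant count per lineage.
#' @param M Baseline mitochondria per cell.
#' @param n Number of divisions to simulate.
#' @param rates A [mutation_rates()]; defaults to no mutation, isolating
#'   segregational drift.
#' @param reps Number of independent lineages.
#' @param total0 Initial total per cell (default `M`; use `2^Q * M` for an
#'   oogamous zygote).
#' @return An integer matrix of dim `reps x (n + 1)`: column `k + 1` holds
#'   each lineage's mutant count after `k` divisions, with attribute
#'   `totals` giving the (common) cell total after each division.
#' @examples
#' x <- simulate_lineages(12, 50, n = 10, reps = 1000)
#' colMeans(x)  # martingale: stays near 12
#' @export
simulate_lineages <- function(m0, M, n, rates = mutation_rates(0, 0),
                              reps = 1e4, total0 = M) {
  stopifnot(inherits(rates, "mutation_rates"), m0 >= 0, m0 <= total0,
            total0 >= M, n >= 0, reps >= 1)
  m <- rep.int(as.integer(m0), reps)
  total <- as.integer(total0)
  out <- matrix(0L, nrow = reps, ncol = n + 1L)
  out[, 1L] <- m
  totals <- integer(n + 1L)
  totals[1L] <- total
  for (k in seq_len(n)) {
    if (rates$mu_B > 0) m <- m + rbinom(reps, total - m, rates$mu_B)
    if (total > M) {
      if (total %% 2L != 0L) stop("odd total in partition-only division")
      half <- total %/% 2L
      m <- rhyper(reps, m, total - m, half)
      total <- half
    } else {
      if (rates$mu_S > 0) m <- m + rbinom(reps, total - m, rates$mu_S)
      m <- rhyper(reps, 2L * m, 2L * (total - m), total)
    }
    out[, k + 1L] <- m
    totals[k + 1L] <- total
  }
  attr(out, "totals") <- totals
  out
}

#' Empirical mutant-count distribution from simulated lineages
#'
#' @param counts Integer vector of mutant counts (one column of
#'   [simulate_lineages()] output).
#' @param M Support upper bound (cell total).
#' @return A [distribution_vector()] of empirical frequencies over `0..M`.
#' @export
empirical_distribution <- function(counts, M) {
  distribution_vector(tabulate(counts + 1L, nbins = M + 1L) / length(counts))
}

#' Total-variation distance between two distributions on 0..M
#'
#' @param p,q Probability vectors of equal length.
#' @return `sum(abs(p - q)) / 2`.
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(as.numeric(p) - as.numeric(q))) / 2
}
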