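# Exact distribution propagation for single-cell lineages.  The state of an
# infinite cell population is a probability vector over mutant counts 0..M;
# one cell cycle applies a mutation transition matrix J followed by a
# segregation (random sampling without replacement) matrix K, so after n
# divisions p^(n) = (KJ)^n p^(0).  Serves as the exact oracle for the
# stochastic engine and for the extended-lifecycle approximation, where
# adult and gamete mutant loads are drawn from p^(n) directly.

#' Probability vector over mutant counts
#'
#' @param probs Numeric vector of length `M + 1`; entry `i + 1` is the
#'   probability that a cell carries `i` mutant mitochondria.  Must be
#'   non-negative and sum to 1 (within `1e-12`).
#' @return An object of class `distribution_vector` with attribute `M`.
#' @export
distribution_vector <- function(probs) {
  if (any(probs < -1e-12)) stop("probabilities must be non-negative")
  probs <- pmax(probs, 0)
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("probabilities must sum to 1 within 1e-12")
  }
  structure(as.numeric(probs), M = length(probs) - 1L,
            class = "distribution_vector")
}

#' Point-mass distribution at a given mutant count
#'
#' @param m0 Initial mutant count.
#' @param M Mitochondria per cell.
#' @return A [distribution_vector()] with all mass at `m0`.
#' @export
delta_distribution <- function(m0, M) {
  p <- numeric(M + 1L)
  p[m0 + 1L] <- 1
  distribution_vector(p)
}

#' Mutation transition matrix J
#'
#' Column `m + 1` holds the distribution of the mutant count after one round
#' of mutation acting on the `M - m` wild-type copies: entry `(q, m)` is the
#' binomial probability of `q - m` new mutants,
#' `choose(M - m, q - m) mu^(q - m) (1 - mu)^(M - q)`, zero for `q < m`.
#' Columns sum to 1: the matrix is column-stochastic.
#'
#' @param M Mitochondria per cell.
#' @param mu Per-copy mutation probability.
#' @return An `(M + 1) x (M + 1)` column-stochastic matrix.
#' @export
mutation_matrix <- function(M, mu) {
  stopifnot(M >= 1)
  check_probability(mu, "mu")
  q <- 0:M
  J <- vapply(0:M, function(m) dbinom(q - m, M - m, mu), numeric(M + 1L))
  dimnames(J) <- list(q = q, m = q)
  J
}

#' Segregation transition matrix K
#'
#' Column `m + 1` holds the hypergeometric distribution of a daughter cell's
#' mutant count: of the `2M` copies present after duplication, `2m` are
#' mutant, and the daughter samples `M` of them without replacement.  Entry
#' `(q, m)` is `dhyper(q, 2m, 2M - 2m, M)`.  Column-stochastic.
#'
#' @param M Mitochondria per cell.
#' @return An `(M + 1) x (M + 1)` column-stochastic matrix.
#' @export
segregation_matrix <- function(M) {
  stopifnot(M >= 1)
  q <- 0:M
  K <- vapply(0:M, function(m) dhyper(q, 2L * m, 2L * (M - m), M),
              numeric(M + 1L))
  dimnames(K) <- list(q = q, m = q)
  K
}

#' Propagate a mutant-count distribution through n cell divisions
#'
#' Applies the one-division operator `K %*% J` (mutation, then duplication
#' and random segregation) `n` times to `p0`, returning the exact
#' distribution of a cell's mutant count after `n` divisions.  The matrix
#' power is taken by iterated multiplication; tiny negative entries from
#' floating point (above `-1e-12`) are clipped to zero and the vector
#' renormalised, preserving stochasticity.
#'
#' @param p0 A [distribution_vector()] (or bare probability vector).
#' @param mu Per-copy mutation probability per division.
#' @param n Number of cell divisions, `n >= 0`.
#' @return A [distribution_vector()] for the state after `n` divisions.
#' @examples
#' p10 <- propagate_distribution(delta_distribution(12, 50), mu = 0.01, n = 10)
#' distribution_moments(p10)
#' @export
propagate_distribution <- function(p0, mu, n) {
  if (!inherits(p0, "distribution_vector")) p0 <- distribution_vector(p0)
  stopifnot(n >= 0)
  M <- attr(p0, "M")
  if (n == 0) return(p0)
  step <- segregation_matrix(M) %*% mutation_matrix(M, mu)
  p <- as.numeric(p0)
  for (i in seq_len(n)) {
    p <- as.numeric(step %*% p)
    if (any(p < -1e-12)) stop("propagation produced a negative probability")
    p <- pmax(p, 0)
    p <- p / sum(p)
  }
  distribution_vector(p)
}

#' Mean and variance of a mutant-count distribution
#'
#' @param p A [distribution_vector()].
#' @return A list with `mean` and `variance` of the mutant count, and
#'   `mean_freq`, `var_freq` of the mutant frequency `m / M`.
#' @export
distribution_moments <- function(p) {
  if (!inherits(p, "distribution_vector")) p <- distribution_vector(p)
  M <- attr(p, "M")
  i <- 0:M
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  list(mean = mu, variance = v, mean_freq = mu / M, var_freq = v / M^2)
}

#' Conditional variance of a daughter's mutant count given its parent
#'
#' For sampling without replacement from the duplicated pool, a daughter of
#' a parent with `m` of `M` mutants has
#' `Var(X_n | x_{n-1} = m) = m (M - m) / (2M - 1)`.
#'
#' @param m Parent mutant count.
#' @param M Mitochondria per cell.
#' @return The conditional variance.
#' @export
conditional_segregation_variance <- function(m, M) {
  stopifnot(all(m >= 0), all(m <= M))
  m * (M - m) / (2 * M - 1)
}

#' Closed-form segregational variance of mutant frequency
#'
#' With no mutational input, the variance of the mutant frequency after `n`
#' divisions is `p0 (1 - p0) [1 - (1 - 1/(2M - 1))^n]`: zero at `n = 0`,
#' non-decreasing in `n`, and saturating at the binomial limit
#' `p0 (1 - p0)`.
#'
#' @param p0 Initial mutant frequency.
#' @param M Mitochondria per cell.
#' @param n Number of divisions (vectorised).
#' @return Variance of the mutant frequency after `n` divisions.
#' @export
variance_closed_form <- function(p0, M, n) {
  check_probability(p0, "p0")
  stopifnot(all(n >= 0))
  p0 * (1 - p0) * (1 - (1 - 1 / (2 * M - 1))^n)
}

#' Segregational variance under oogamy (partition-only early divisions)
#'
#' An oogamous zygote carries `2^Q * M` mitochondria and undergoes `Q`
#' divisions without replication; the variance of mutant frequency follows
#' the recurrence
#' `Var(P_n) = p0 (1 - p0) / (2^(1 + Q - n) M - 1) +
#'   Var(P_{n-1}) (1 - 1 / (2^(1 + Q - n) M - 1))`
#' from `Var(P_0) = 0`, for `1 <= n <= Q`.  The large pool suppresses drift
#' in the first divisions relative to [variance_closed_form()].
#'
#' @param p0 Initial mutant frequency in the zygote.
#' @param M Baseline mitochondria per cell.
#' @param Q Oogamy level: the zygote holds `2^Q * M` copies.
#' @param n Division number, `1 <= n <= Q`.
#' @return Variance of mutant frequency after division `n`.
#' @export
oogamy_variance_recurrence <- function(p0, M, Q, n) {
  check_probability(p0, "p0")
  if (n < 1 || n > Q) stop("n must satisfy 1 <= n <= Q")
  v <- 0
  for (k in seq_len(n)) {
    denom <- 2^(1 + Q - k) * M - 1
    v <- p0 * (1 - p0) / denom + v * (1 - 1 / denom)
  }
  v
}

#' Large-pool approximation to the oogamy variance recurrence
#'
#' For a large initial pool (`2^Q * M` big), the recurrence is approximated
#' by `Var(P_n) = p0 (1 - p0) (2^n - 1) / (2^Q M)`, `1 <= n <= Q`.
#'
#' @inheritParams oogamy_variance_recurrence
#' @return Approximate variance of mutant frequency after division `n`.
#' @export
oogamy_variance_approx <- function(p0, M, Q, n) {
  check_probability(p0, "p0")
  if (n < 1 || n > Q) stop("n must satisfy 1 <= n <= Q")
  p0 * (1 - p0) * (2^n - 1) / (2^Q * M)
}

#' Expected fitness under a mutant-count distribution
#'
#' Averages the cell fitness function over a distribution of mutant counts:
#' `sum_i p_i (1 - s (i/M)^xi)`.  Used by the extended-lifecycle
#' approximation, where an adult's fitness is taken from the propagated
#' distribution instead of explicit development.
#'
#' @param p A [distribution_vector()].
#' @param fp A [fitness_params()].
#' @return Expected fitness in \[0, 1\].
#' @export
expected_fitness_of_distribution <- function(p, fp = fitness_params()) {
  if (!inherits(p, "distribution_vector")) p <- distribution_vector(p)
  stopifnot(inherits(fp, "fitness_params"))
  M <- attr(p, "M")
  i <- 0:M
  sum(as.numeric(p) * (1 - fp$s * (i / M)^fp$xi))
}
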