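# Single-cell mitochondrial dynamics: mutation, replication, partition,
# fitness.  A cell is summarised by its mutant count and total count; all
# mutants are interchangeable (fixed-severity mutations), so the pair is a
# sufficient statistic.  Back-mutation never occurs: mutation acts only on
# wild-type copies.

#' Construct a mitochondrial cell state
#'
#' A cell is represented by the number of mutant mitochondria it carries and
#' the total number of mitochondria.  The baseline total is `M` (50 by
#' default throughout the package); cells early in oogamous development
#' transiently carry `2^Q * M`.
#'
#' @param mutants Integer count of mutant mitochondria, `0 <= mutants <= total`.
#' @param total Integer total mitochondria in the cell, at least 2.
#' @return An object of class `mito_cell`: a list with integer fields
#'   `mutants` and `total`.
#' @examples
#' mito_cell(12, 50)
#' @export
mito_cell <- function(mutants, total) {
  mutants <- as.integer(mutants)
  total <- as.integer(total)
  if (length(mutants) != 1L || length(total) != 1L || is.na(mutants) ||
      is.na(total)) {
    stop("mutants and total must be single non-missing integers")
  }
  if (total < 2L) stop("a cell must contain at least 2 mitochondria")
  if (mutants < 0L || mutants > total) {
    stop("mutant count must lie in [0, total]")
  }
  structure(list(mutants = mutants, total = total), class = "mito_cell")
}

#' @export
print.mito_cell <- function(x, ...) {
  cat(sprintf("<mito_cell> %d mutant / %d mitochondria (load %.3f)\n",
              x$mutants, x$total, x$mutants / x$total))
  invisible(x)
}

#' Mutation-rate parameters
#'
#' `mu_S` is the probability that a wild-type copy picks up a replication
#' (copying) error per cell division; `mu_B` is the probability of background
#' damage (e.g. oxidative or UV) per wild-type copy per time unit, applied
#' whether or not the cell divides.
#'
#' @param mu_S Copying-error probability per replication round, in \[0, 1\].
#' @param mu_B Background-damage probability per time unit, in \[0, 1\].
#' @return A list of class `mutation_rates`.
#' @export
mutation_rates <- function(mu_S = 0.01, mu_B = 0.005) {
  check_probability(mu_S, "mu_S")
  check_probability(mu_B, "mu_B")
  structure(list(mu_S = mu_S, mu_B = mu_B), class = "mutation_rates")
}

#' Fitness-function parameters
#'
#' Cell fitness declines with mutant load as
#' \eqn{\omega(m) = 1 - s (m/M)^\xi}.  The default concave shape
#' (`xi = 2`) encodes the threshold effect of mitochondrial disease: many
#' mutants must accumulate before function is impaired, and with `s = 1`
#' fitness reaches zero only when every mitochondrion is mutant.
#'
#' @param s Selection strength in \[0, 1\].
#' @param xi Positive exponent shaping the fitness function: concave
#'   (`xi = 2`), linear (`xi = 1`) or convex (`xi = 0.5`).
#' @return A list of class `fitness_params`.
#' @export
fitness_params <- function(s = 1, xi = 2) {
  check_probability(s, "s")
  if (!is.numeric(xi) || length(xi) != 1L || is.na(xi) || xi <= 0) {
    stop("xi must be a single positive number")
  }
  structure(list(s = s, xi = xi), class = "fitness_params")
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("%s must be a single probability in [0, 1]", name))
  }
  invisible(p)
}

#' Apply background mutation to a cell
#'
#' Each wild-type copy independently mutates with probability `mu_B`; the
#' number of new mutants is one draw from
#' `Binomial(total - mutants, mu_B)`.  The total is unchanged.
#'
#' @param cell A [mito_cell()].
#' @param mu_B Background mutation probability per copy per time unit.
#' @return The mutated `mito_cell`.
#' @export
apply_background_mutation <- function(cell, mu_B) {
  stopifnot(inherits(cell, "mito_cell"))
  check_probability(mu_B, "mu_B")
  new_mutants <- rbinom(1L, cell$total - cell$mutants, mu_B)
  mito_cell(cell$mutants + new_mutants, cell$total)
}

#' Apply copying-error mutation to a cell
#'
#' Replication-error mutation acting on wild-type copies: the number of new
#' mutants is one draw from `Binomial(total - mutants, mu_S)`.  Callers
#' invoke this only at replicative divisions (see [divide_cell()]).
#'
#' @inheritParams apply_background_mutation
#' @param mu_S Copying-error probability per copy per replication round.
#' @return The mutated `mito_cell`.
#' @export
apply_copy_error_mutation <- function(cell, mu_S) {
  stopifnot(inherits(cell, "mito_cell"))
  check_probability(mu_S, "mu_S")
  new_mutants <- rbinom(1L, cell$total - cell$mutants, mu_S)
  mito_cell(cell$mutants + new_mutants, cell$total)
}

#' Duplicate the mitochondrial population of a cell
#'
#' Every copy is replicated once, doubling both counts and preserving the
#' mutant frequency exactly.
#'
#' @param cell A [mito_cell()].
#' @return A `mito_cell` with both counts doubled.
#' @export
replicate_mitochondria <- function(cell) {
  stopifnot(inherits(cell, "mito_cell"))
  mito_cell(2L * cell$mutants, 2L * cell$total)
}

#' Partition a cell's mitochondria into two daughters
#'
#' Random segregation at cell division: the first daughter receives
#' `total / 2` copies sampled without replacement, so its mutant count is
#' hypergeometric; the second daughter receives the complement.  Mutant
#' counts are conserved exactly.
#'
#' @param cell A [mito_cell()] with an even total.
#' @return A list of two `mito_cell` daughters.
#' @export
partition <- function(cell) {
  stopifnot(inherits(cell, "mito_cell"))
  if (cell$total %% 2L != 0L) {
    stop("cannot partition a cell with an odd number of mitochondria")
  }
  half <- cell$total %/% 2L
  d1 <- rhyper(1L, cell$mutants, cell$total - cell$mutants, half)
  list(mito_cell(d1, half), mito_cell(cell$mutants - d1, half))
}

#' Divide a cell, applying mutation, replication and random segregation
#'
#' One cell-division cycle.  Background mutation is applied first.  If the
#' cell is at the baseline mitochondrial number `baseline_M`, the division is
#' replicative: copying-error mutation, duplication of the mitochondrial
#' population, then hypergeometric partition into two daughters of
#' `baseline_M` each.  If the cell carries more than `baseline_M` copies (the
#' early divisions of an oogamous zygote), the existing population is
#' partitioned without further replication and without copying errors,
#' halving the total.
#'
#' @param cell A [mito_cell()] with `total >= baseline_M`.
#' @param baseline_M Baseline mitochondria per somatic cell.
#' @param rates A [mutation_rates()].
#' @return A list of two daughter `mito_cell`s.
#' @export
divide_cell <- function(cell, baseline_M, rates) {
  stopifnot(inherits(cell, "mito_cell"), inherits(rates, "mutation_rates"))
  baseline_M <- as.integer(baseline_M)
  if (cell$total < baseline_M) {
    stop("cell has fewer mitochondria than the baseline; cannot divide")
  }
  cell <- apply_background_mutation(cell, rates$mu_B)
  if (cell$total == baseline_M) {
    cell <- apply_copy_error_mutation(cell, rates$mu_S)
    cell <- replicate_mitochondria(cell)
  }
  partition(cell)
}

#' Cell fitness under the threshold-shaped fitness function
#'
#' Evaluates \eqn{\omega(m) = 1 - s (m / M)^\xi} with the cell's own total as
#' `M`.  Equals 1 for a mutation-free cell and `1 - s` for a fully mutant
#' cell, for every `xi > 0`.
#'
#' @param cell A [mito_cell()].
#' @param fp A [fitness_params()].
#' @return Fitness in \[0, 1\].
#' @examples
#' cell_fitness(mito_cell(25, 50), fitness_params(s = 1, xi = 2))  # 0.75
#' @export
cell_fitness <- function(cell, fp = fitness_params()) {
  stopifnot(inherits(cell, "mito_cell"), inherits(fp, "fitness_params"))
  1 - fp$s * (cell$mutants / cell$total)^fp$xi
}
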