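# Single-cell operations: mutation draws, replication, hypergeometric
# partition and the threshold fitness function.

test_that("cell construction enforces count invariants", {
  expect_s3_class(mito_cell(0, 50), "mito_cell")
  expect_error(mito_cell(-1, 50), "0, total")
  expect_error(mito_cell(51, 50), "0, total")
  expect_error(mito_cell(0, 1), "at least 2")
  expect_error(mutation_rates(mu_S = 1.5), "probability")
  expect_error(fitness_params(xi = 0), "positive")
})

test_that("mutation acts only on wild-type copies and at the stated rate", {
  set.seed(1)
  # no wild types left: both mutation channels are inert
  expect_identical(apply_background_mutation(mito_cell(50, 50), 0.1)$mutants,
                   50L)
  expect_identical(apply_copy_error_mutation(mito_cell(50, 50), 0.5)$mutants,
                   50L)
  # zero rate leaves the cell untouched
  expect_identical(apply_background_mutation(mito_cell(0, 50), 0)$mutants, 0L)
  expect_identical(apply_copy_error_mutation(mito_cell(25, 50), 0)$mutants,
                   25L)

  # mean increments match the binomial expectations
  reps <- 2e4
  inc_b <- vapply(seq_len(reps), function(i)
    apply_background_mutation(mito_cell(10, 50), 0.1)$mutants - 10L,
    integer(1))
  se <- sqrt(40 * 0.1 * 0.9 / reps)
  expect_lt(abs(mean(inc_b) - 4.0), 3 * se)

  inc_s <- vapply(seq_len(reps), function(i)
    apply_copy_error_mutation(mito_cell(0, 50), 0.01)$mutants, integer(1))
  se <- sqrt(50 * 0.01 * 0.99 / reps)
  expect_lt(abs(mean(inc_s) - 0.5), 3 * se)
})

test_that("replication doubles counts and preserves mutant frequency", {
  expect_identical(unclass(replicate_mitochondria(mito_cell(25, 50)))[1:2],
                   list(mutants = 50L, total = 100L))
  expect_identical(replicate_mitochondria(mito_cell(0, 50))$mutants, 0L)
  for (m in c(0L, 7L, 50L)) {
    r <- replicate_mitochondria(mito_cell(m, 50))
    expect_equal(r$mutants / r$total, m / 50)
  }
})

test_that("partition conserves mutants and follows the hypergeometric law", {
  set.seed(2)
  # degenerate parents split deterministically
  d <- partition(mito_cell(0, 100))
  expect_identical(c(d[[1]]$mutants, d[[2]]$mutants), c(0L, 0L))
  d <- partition(mito_cell(100, 100))
  expect_identical(c(d[[1]]$mutants, d[[2]]$mutants), c(50L, 50L))
  expect_error(partition(mito_cell(1, 3)), "odd")

  # conservation on every call
  for (i in 1:200) {
    m <- sample(0:60, 1)
    d <- partition(mito_cell(m, 60))
    expect_identical(d[[1]]$mutants + d[[2]]$mutants, as.integer(m))
    expect_identical(d[[1]]$total, 30L)
  }

  # (2, 4): daughter mutant count has pmf {1/6, 2/3, 1/6} by enumeration of
  # the C(4,2) = 6 equally likely samples
  draws <- vapply(seq_len(2e4), function(i) partition(mito_cell(2, 4))[[1]]$mutants,
                  integer(1))
  counts <- tabulate(draws + 1L, nbins = 3L)
  expect_gt(gof_pvalue(counts, c(1, 4, 1) / 6), 0.001)
})

test_that("divide_cell switches between partition-only and replicative modes", {
  set.seed(3)
  rates0 <- mutation_rates(0, 0)
  # an oogamous cell above baseline is partitioned without replication
  d <- divide_cell(mito_cell(0, 800), 50, rates0)
  expect_identical(c(d[[1]]$total, d[[2]]$total), c(400L, 400L))
  expect_identical(c(d[[1]]$mutants, d[[2]]$mutants), c(0L, 0L))
  # at baseline the division is replicative: daughters return to baseline
  d <- divide_cell(mito_cell(0, 50), 50, rates0)
  expect_identical(c(d[[1]]$total, d[[2]]$total), c(50L, 50L))
  expect_error(divide_cell(mito_cell(0, 24), 50, rates0), "fewer")

  # conditional daughter variance m(M-m)/(2M-1) = 625/99
  draws <- vapply(seq_len(2e4), function(i)
    divide_cell(mito_cell(25, 50), 50, rates0)[[1]]$mutants, integer(1))
  target <- conditional_segregation_variance(25, 50)
  expect_equal(target, 625 / 99)
  expect_lt(abs(var(draws) - target), 3 * se_of_variance(draws))
})

test_that("mutant frequency is a martingale under pure segregation", {
  set.seed(4)
  x <- simulate_lineages(12, 50, n = 20, rates = mutation_rates(0, 0),
                         reps = 5e4)
  final <- x[, 21]
  se <- sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - 12), 3 * se)
})

test_that("cell fitness is 1 at zero load, 1 - s at full load, decreasing", {
  expect_equal(cell_fitness(mito_cell(0, 50), fitness_params(1, 2)), 1)
  expect_equal(cell_fitness(mito_cell(50, 50), fitness_params(1, 2)), 0)
  expect_equal(cell_fitness(mito_cell(25, 50), fitness_params(1, 2)), 0.75)
  for (xi in c(0.5, 1, 2, 5)) {
    fp <- fitness_params(s = 0.8, xi = xi)
    f <- vapply(0:50, function(m) cell_fitness(mito_cell(m, 50), fp),
                numeric(1))
    expect_true(all(diff(f) <= 0))
    expect_equal(f[1], 1)
    expect_equal(f[51], 0.2)
  }
})
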