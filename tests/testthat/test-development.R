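# Organism development: lineage expansion, oogamous partition-only early
# divisions, germline sequestration and proliferation, ageing exposure, and
# tissue/adult fitness.

test_that("development yields 2^L cells and respects zero-mutation limits", {
  set.seed(10)
  lc <- life_cycle_params(L = 3, T_diff = 0, S = 40, baseline_M = 50)
  org <- develop(mito_cell(0, 50), lc, mutation_rates(0, 0), N_G = 2)
  expect_length(org$cells, 8L)
  expect_true(all(org$cells == 0L))
  expect_identical(org$cell_total, 50L)
  expect_true(all(org$germ == 0L))
  expect_error(develop(mito_cell(0, 50), lc, mutation_rates(0, 0), N_G = 4),
               "1..L")
})

test_that("an oogamous zygote is partitioned back to baseline M without
           replication, conserving mutants exactly", {
  set.seed(11)
  lc <- life_cycle_params(L = 4, T_diff = 0, S = 40, baseline_M = 50)
  org <- develop(mito_cell(160, 800), lc, mutation_rates(0, 0), N_G = 4)
  expect_identical(org$cell_total, 50L)            # 800 / 2^4
  expect_length(org$cells, 16L)
  expect_identical(sum(org$cells), 160L)           # partition-only conserves
  # six divisions from an 800-copy zygote: 4 partition-only + 2 replicative
  lc6 <- life_cycle_params(L = 6, T_diff = 0, S = 40, baseline_M = 50)
  org6 <- develop(mito_cell(160, 800), lc6, mutation_rates(0, 0), N_G = 3)
  expect_identical(org6$cell_total, 50L)
  expect_identical(sum(org6$cells), 160L * 4L)     # replication doubles twice
  # germ cell sequestered mid-partition carries the transient total
  expect_identical(org6$germ_total, 100L)          # 800 / 2^3
})

test_that("ageing applies the correct cumulative background exposure", {
  set.seed(12)
  lc <- life_cycle_params(L = 10, T_diff = 0, S = 40, baseline_M = 50)
  rates <- mutation_rates(0, 0.005)
  org0 <- develop(mito_cell(0, 50), life_cycle_params(L = 4), mutation_rates(0, 0),
                  N_G = 2)
  expect_identical(age_organism(org0, mutation_rates(0, 0))$cells, org0$cells)

  # post-development ageing alone: 30 rounds at mu_B = 0.005 on clean cells
  org <- develop(mito_cell(0, 50), lc, mutation_rates(0, 0), N_G = 3)
  org <- age_organism(org, rates)
  expected <- 50 * (1 - (1 - 0.005)^30)
  se <- sd(org$cells) / sqrt(length(org$cells))
  expect_lt(abs(mean(org$cells) - expected), 3.5 * se)

  # total exposure is ~S rounds for soma and germ alike, independent of N_G:
  # germ cells inherit N_G rounds from their source cell and accumulate
  # S - N_G more after sequestration
  germ_loads <- soma_loads <- numeric(400)
  for (i in seq_len(400)) {
    o <- develop(mito_cell(0, 50), lc, rates, N_G = 3)
    o <- age_organism(o, rates)
    germ_loads[i] <- mean(o$germ) / o$germ_total
    soma_loads[i] <- mean(o$cells) / o$cell_total
  }
  expected_freq <- 1 - (1 - 0.005)^40
  expect_lt(abs(mean(germ_loads) - expected_freq),
            3 * sd(germ_loads) / 20)
  expect_lt(abs(mean(soma_loads) - expected_freq),
            3 * sd(soma_loads) / 20)
})

test_that("germline proliferation produces 2^A germ cells", {
  set.seed(13)
  lc <- life_cycle_params(L = 6, T_diff = 0, S = 40, baseline_M = 50)
  org <- develop(mito_cell(10, 50), lc, mutation_rates(0.01, 0.005),
                 N_G = 2, A = 3)
  expect_length(org$germ, 8L)
  expect_identical(org$germ_total, 50L)
  expect_error(develop(mito_cell(10, 50), lc, mutation_rates(0, 0),
                       N_G = 4, A = 3), "N_G \\+ A")
})

test_that("tissue and adult fitness follow the worst-tissue rule", {
  fp <- fitness_params(1, 2)
  org <- fake_organism(c(0, 50, 0, 25), 50, c(1, 1, 2, 2))
  expect_equal(tissue_fitness(org, 1, fp), 0.5)
  expect_equal(tissue_fitness(org, 2, fp), (1 + 0.75) / 2)
  expect_equal(adult_fitness(org, fp), 0.5)                 # min rule
  expect_equal(adult_fitness(org, fp, epistasis = 0), (0.5 + 0.875) / 2)
  expect_equal(adult_fitness(org, fp, epistasis = 0.5),
               0.5 * 0.5 + 0.5 * 0.6875)
  single <- fake_organism(c(0, 50), 50, c(1, 1))
  expect_equal(adult_fitness(single, fp), tissue_fitness(single, 1, fp))
  expect_error(tissue_fitness(org, 5, fp), "tissue")
})

test_that("the development engine matches the analytic distribution", {
  set.seed(14)
  # with mu_B = 0 each cell's marginal after n divisions is p^(n); sample
  # the sequestered germ cell across organisms and compare to (KJ)^n p0
  M <- 50; n <- 5; mu <- 0.01
  lc <- life_cycle_params(L = 5, T_diff = 0, S = 40, baseline_M = M)
  reps <- 5e4
  res <- mitogerm:::cpp_develop_batch(rep(12L, reps), M, M, 5L, 0L, 5L, 0L,
                                      5L, mu, 0, 1, 2, 1)
  emp <- tabulate(res$germ_m + 1L, nbins = M + 1L) / reps
  p_n <- propagate_distribution(delta_distribution(12, M), mu, n)
  expect_lt(total_variation(emp, p_n), 0.02)
})

test_that("multiple tissues depress adult fitness; more mitochondria damp
           between-tissue variance", {
  set.seed(15)
  rates <- mutation_rates(0.01, 0.005)
  nrep <- 1200
  batch <- function(zm, zt, M, T_diff) {
    mitogerm:::cpp_develop_batch(rep(as.integer(zm), nrep), as.integer(zt),
                                 as.integer(M), 6L, as.integer(T_diff), 6L,
                                 0L, 40L, rates$mu_S, rates$mu_B, 1, 2, 1)
  }
  one <- batch(10, 50, 50, 0)
  multi <- batch(10, 50, 50, 3)
  se <- sqrt(var(one$fitness) / nrep + var(multi$fitness) / nrep)
  expect_gt(mean(one$fitness) - mean(multi$fitness), 3 * se)

  # raising M from 50 to 200 at the same 20% zygote load shrinks the
  # between-tissue variance in fitness
  m50 <- batch(10, 50, 50, 2)
  m200 <- batch(40, 200, 200, 2)
  expect_lt(mean(m200$tissue_var), mean(m50$tissue_var))
})

test_that("organisms serialise to JSON", {
  org <- fake_organism(c(0, 50, 0, 25), 50, c(1, 1, 2, 2))
  js <- organism_to_json(org)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$cell_total, 50)
  expect_length(parsed$tissues, 2)
})
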