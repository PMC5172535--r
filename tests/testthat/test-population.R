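# Nuclear modifier genetics, gametogenesis, fertilisation and the
# discrete-generation loop.

test_that("phenotype expression follows dominance and W linkage", {
  res <- trait_set(N_G = 10, A = 0, Q = 0)
  inv <- trait_set(N_G = 3, A = 2, Q = 4)
  het_f <- nuclear_genotype("female", a1 = 1, a2 = 2, w = 1)
  expect_equal(phenotype_of(het_f, res, inv)$N_G, 3)          # invader dominant
  expect_equal(phenotype_of(het_f, res, inv, "resident")$N_G, 10)
  expect_equal(phenotype_of(het_f, res, inv)$Q, 0)            # Q from W allele
  hom <- nuclear_genotype("female", a1 = 1, a2 = 1, w = 2)
  expect_equal(phenotype_of(hom, res, inv)$N_G, 10)
  expect_equal(phenotype_of(hom, res, inv)$Q, 4)
  male <- nuclear_genotype("male", a1 = 2, a2 = 2)
  expect_equal(phenotype_of(male, res, inv)$N_G, 3)
  expect_true(is.na(phenotype_of(male, res, inv)$Q))
  expect_error(nuclear_genotype("male", w = 1), "no W")
})

test_that("parent selection is linearly weighted by fitness within sex", {
  set.seed(20)
  # fitness ratio 2:1 between the two males
  fitness <- c(1, 1, 2, 1)      # two females, two males
  female <- c(TRUE, TRUE, FALSE, FALSE)
  sel <- select_parents(fitness, female, n_draws = 1e5)
  expect_true(all(sel$mothers %in% 1:2))
  expect_true(all(sel$fathers %in% 3:4))
  p <- mean(sel$fathers == 3)
  se <- sqrt(2 / 3 * 1 / 3 / 1e5)
  expect_lt(abs(p - 2 / 3), 3 * se)
  # a zero-fitness parent is never drawn
  sel <- select_parents(c(1, 1, 1, 0), female, n_draws = 1e4)
  expect_false(any(sel$fathers == 4))
  # all-zero fitness in a sex falls back to uniform with a warning
  expect_warning(sel <- select_parents(c(1, 1, 0, 0), female, n_draws = 1e3),
                 "uniform")
  expect_true(all(3:4 %in% sel$fathers))
})

test_that("oogamy amplification reaches 2^Q M and preserves frequency when
           mutation-free", {
  set.seed(21)
  g <- mito_cell(25, 50)
  expect_identical(oogamy_amplification(g, 0, 0.01)$total, 50L)
  expect_identical(oogamy_amplification(g, 4, 0.01)$total, 800L)
  amp <- oogamy_amplification(g, 2, 0)
  expect_identical(c(amp$mutants, amp$total), c(100L, 200L))
  # a germ cell sequestered mid-partition (2^j M copies) is topped up
  amp <- oogamy_amplification(mito_cell(0, 100), 3, 0, baseline_M = 50)
  expect_identical(amp$total, 400L)
  expect_error(oogamy_amplification(mito_cell(0, 100), 0, 0, baseline_M = 50),
               "j <= Q")
})

test_that("meiosis halves the mitochondrial content through two samplings", {
  set.seed(22)
  expect_identical(meiosis(mito_cell(0, 50))$total, 25L)
  expect_identical(meiosis(mito_cell(0, 50))$mutants, 0L)
  expect_identical(meiosis(mito_cell(50, 50))$mutants, 25L)
  egg <- meiosis(mito_cell(100, 800))
  expect_identical(egg$total, 400L)     # 2^Q M / 2 for Q = 4, M = 50
})

test_that("fertilisation is strictly maternal with binomial resampling", {
  set.seed(23)
  mom <- nuclear_genotype("female", a1 = 1, a2 = 2, w = 1)
  dad <- nuclear_genotype("male", a1 = 1, a2 = 2)
  z <- fertilize(mito_cell(0, 400), mito_cell(25, 25), mom, dad,
                 Q = 4, baseline_M = 50)
  expect_identical(z$zygote$total, 800L)
  expect_identical(z$zygote$mutants, 0L)   # sperm mitochondria excluded

  reps <- 4000
  sexes <- character(reps)
  geno <- matrix(0L, reps, 2)
  for (i in seq_len(reps)) {
    f <- fertilize(mito_cell(40, 400), mito_cell(0, 25), mom, dad,
                   Q = 4, baseline_M = 50)
    sexes[i] <- f$sex
    geno[i, ] <- c(f$genotype$a1, f$genotype$a2)
    if (f$sex == "female") expect_identical(f$genotype$w, 1L)
    if (f$sex == "male") expect_true(is.na(f$genotype$w))
  }
  # ZW symmetry: sex ratio 1:1
  expect_lt(abs(mean(sexes == "female") - 0.5), 3 * sqrt(0.25 / reps))
  # Mendelian segregation at the autosomal locus: het x het offspring
  # genotype classes 11 : (12 + 21) : 22 in ratio 1:2:1
  class <- rowSums(geno == 2L)
  expect_gt(gof_pvalue(tabulate(class + 1L, 3), c(1, 2, 1) / 4), 0.001)
})

test_that("generations conserve population size, sex quota and W linkage", {
  set.seed(24)
  params <- profile_params("desk", N = 60)
  pop <- initialize_population(params, 0.2)
  expect_identical(sum(pop$sex == 1L), 30L)
  for (g in 1:5) {
    pop <- next_generation(pop, params)
    expect_length(pop$sex, 60L)
    expect_identical(sum(pop$sex == 1L), 30L)
    expect_true(all(pop$w[pop$sex == 1L] %in% 1:2))
    expect_true(all(pop$w[pop$sex == 0L] == 0L))
  }
  expect_identical(pop$generation, 5L)
})

test_that("a mutation-free population keeps fitness 1 under zero rates", {
  set.seed(25)
  params <- sim_params(N = 40, lc = life_cycle_params(L = 4, S = 10),
                       rates = mutation_rates(0, 0),
                       resident = trait_set(N_G = 4))
  pop <- initialize_population(params, 0)
  for (g in 1:3) {
    pop <- next_generation(pop, params)
    expect_equal(attr(pop, "summary")$parent_mean_fitness, 1)
    expect_true(all(pop$zm == 0L))
  }
})

test_that("burn-in reaches a stationary mutant-load band", {
  set.seed(42)
  params <- profile_params("desk")
  pop <- initialize_population(params, 0.2)
  pop <- burn_in(pop, params, 300)
  tr <- attr(pop, "trajectory")
  # Mann-Kendall style trend test on a thinned tail of the trajectory
  tail_idx <- seq(150, 300, by = 5)
  mk <- suppressWarnings(
    cor.test(tail_idx, tr$mean_zygote_load[tail_idx], method = "kendall"))
  expect_gt(mk$p.value, 0.01)
  expect_true(all(tr$mean_zygote_load[150:300] > 0.2))
  expect_true(all(tr$mean_zygote_load[150:300] < 1))
})

test_that("population snapshots serialise to JSON", {
  set.seed(26)
  params <- profile_params("desk", N = 20)
  pop <- initialize_population(params, 0.2)
  js <- jsonlite::fromJSON(population_to_json(pop))
  expect_equal(js$N, 20)
  expect_equal(js$females, 10)
  expect_equal(js$autosomal_invader_freq, 0)
})
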