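# Population layer: nuclear modifier genetics (ZW mating types, an autosomal
# germline-timing locus, W-linked oogamy and uniparental-inheritance loci),
# fitness-weighted selection, gametogenesis and fertilisation with strict
# maternal transmission of mitochondria, and the discrete-generation loop.
#
# Alleles are coded 1 (resident) and 2 (invader).  A population is stored
# column-wise: one integer vector per field across all N individuals, which
# is what the C++ generation engine consumes.

#' Modifier-trait set
#'
#' The phenotypes controlled by the nuclear loci: `N_G` (division after
#' which the germline is sequestered) and `A` (additional proliferative
#' germline divisions) sit at the autosomal germline locus, expressed in
#' both sexes; `Q` (oogamy level: eggs are amplified so zygotes carry
#' `2^Q * M` mitochondria) and `v` (degree of uniparental inheritance) are
#' W-linked and expressed in females only.  Only strict maternal inheritance
#' (`v = 1`) is modelled.
#'
#' @param N_G Germline sequestration division.
#' @param A Additional germline divisions (atresia picks one of the `2^A`
#'   germ cells at gametogenesis).
#' @param Q Oogamy level.
#' @param v Degree of uniparental inheritance; must be 1.
#' @return A list of class `trait_set`.
#' @export
trait_set <- function(N_G, A = 0, Q = 0, v = 1) {
  if (v != 1) stop("only strict uniparental inheritance (v = 1) is modelled")
  structure(list(N_G = as.integer(N_G), A = as.integer(A),
                 Q = as.integer(Q), v = 1), class = "trait_set")
}

#' Nuclear genotype of one individual
#'
#' @param sex `"female"` (ZW) or `"male"` (ZZ).
#' @param a1,a2 Autosomal germline-locus alleles (1 resident, 2 invader).
#' @param w W-linked allele (females only; `NA` for males).
#' @return A list of class `nuclear_genotype`.
#' @export
nuclear_genotype <- function(sex = c("female", "male"), a1 = 1, a2 = 1,
                             w = if (sex[1] == "female") 1 else NA) {
  sex <- match.arg(sex)
  if (sex == "male" && !is.na(w)) stop("males carry no W chromosome")
  if (sex == "female" && (is.na(w) || !w %in% 1:2)) {
    stop("females carry exactly one W allele (1 or 2)")
  }
  structure(list(sex = sex, a1 = as.integer(a1), a2 = as.integer(a2),
                 w = if (is.na(w)) NA_integer_ else as.integer(w)),
            class = "nuclear_genotype")
}

#' Expressed phenotype of a genotype
#'
#' Germline timing (`N_G`, `A`) comes from the autosomal pair: homozygotes
#' express their allele, heterozygotes the allele named by `dominance`
#' (the invading allele by default).  `Q` and `v` are read from the W allele
#' and are only meaningful in females.
#'
#' @param genotype A [nuclear_genotype()].
#' @param resident,invader [trait_set()]s for alleles 1 and 2.
#' @param dominance Which allele a heterozygote expresses at the autosomal
#'   locus: `"invader"` (default) or `"resident"`.
#' @return A list with `N_G`, `A`, `Q`, `v` (the last two `NA` for males).
#' @export
phenotype_of <- function(genotype, resident, invader,
                         dominance = c("invader", "resident")) {
  stopifnot(inherits(genotype, "nuclear_genotype"),
            inherits(resident, "trait_set"), inherits(invader, "trait_set"))
  dominance <- match.arg(dominance)
  traits <- list(resident, invader)
  auto <- if (genotype$a1 == genotype$a2) {
    traits[[genotype$a1]]
  } else {
    traits[[if (dominance == "invader") 2L else 1L]]
  }
  wtr <- if (is.na(genotype$w)) list(Q = NA_integer_, v = NA) else
    traits[[genotype$w]]
  list(N_G = auto$N_G, A = auto$A, Q = wtr$Q, v = wtr$v)
}

#' Fitness-weighted parent selection
#'
#' Samples `n_draws` mothers from the females and `n_draws` fathers from the
#' males, with replacement, with probability proportional to adult fitness
#' within each sex.  If every fitness in a sex is zero the draw falls back
#' to uniform sampling with a warning.
#'
#' @param fitness Numeric vector of adult fitnesses.
#' @param female Logical vector marking females.
#' @param n_draws Draws per sex (default `length(fitness) / 2`).
#' @return A list with integer index vectors `mothers` and `fathers`.
#' @export
select_parents <- function(fitness, female, n_draws = length(fitness) %/% 2L) {
  stopifnot(length(fitness) == length(female))
  draw <- function(idx) {
    wt <- fitness[idx]
    if (sum(wt) <= 0) {
      warning("all fitnesses zero in one sex; falling back to uniform sampling")
      wt <- rep(1, length(idx))
    }
    idx[sample.int(length(idx), n_draws, replace = TRUE, prob = wt)]
  }
  list(mothers = draw(which(female)), fathers = draw(which(!female)))
}

#' Oogamy amplification of a female germ cell
#'
#' `Q` rounds of copying-error mutation followed by duplication, raising the
#' egg precursor's mitochondrial content to `2^Q * baseline_M`.  A germ cell
#' sequestered before the oogamous zygote finished its partition-only
#' divisions already carries `2^j * baseline_M` copies; only the remaining
#' `Q - j` rounds are applied so the target size is always `2^Q * M`.
#'
#' @param germ A [mito_cell()] whose total is `2^j * baseline_M`.
#' @param Q Oogamy level.
#' @param mu_S Copying-error probability per round.
#' @param baseline_M Baseline mitochondria per cell.
#' @return A `mito_cell` with total `2^Q * baseline_M`.
#' @export
oogamy_amplification <- function(germ, Q, mu_S, baseline_M = germ$total) {
  stopifnot(inherits(germ, "mito_cell"))
  check_probability(mu_S, "mu_S")
  j <- log2(germ$total / baseline_M)
  if (j %% 1 != 0 || j > Q) {
    stop("germ total must be 2^j * baseline_M with j <= Q")
  }
  for (r in seq_len(Q - j)) {
    germ <- apply_copy_error_mutation(germ, mu_S)
    germ <- replicate_mitochondria(germ)
  }
  germ
}

#' Meiosis: produce one gamete from a germ cell
#'
#' Two meiotic divisions with mitochondrial sampling without replacement:
#' one duplication (no mutation) followed by two successive hypergeometric
#' halvings, so the gamete carries half the germ cell's mitochondria while
#' experiencing two rounds of segregational sampling.  Male gametes end at
#' `M / 2` copies and eggs at `2^Q * M / 2`.
#'
#' @param germ A [mito_cell()] with even total.
#' @return A `mito_cell` gamete with total `germ$total / 2`.
#' @export
meiosis <- function(germ) {
  stopifnot(inherits(germ, "mito_cell"))
  if (germ$total %% 2L != 0L) stop("germ total must be even for meiosis")
  doubled <- replicate_mitochondria(germ)
  d1 <- partition(doubled)[[1L]]
  partition(d1)[[1L]]
}

#' Fertilisation with strict maternal mitochondrial inheritance
#'
#' The sperm's mitochondria are excluded (`v = 1`); the zygote's
#' `2^Q * baseline_M` mitochondria are resampled with replacement from the
#' egg's pool, i.e. the zygote mutant count is
#' `Binomial(2^Q * baseline_M, egg mutant frequency)`.  Nuclear inheritance:
#' one random autosomal allele from each parent; the mother transmits W or Z
#' equiprobably (W makes a daughter), the father transmits Z.
#'
#' @param egg A [mito_cell()] of total `2^Q * baseline_M / 2`.
#' @param sperm A [mito_cell()]; contents discarded.
#' @param mother,father [nuclear_genotype()]s.
#' @param Q Maternal oogamy level.
#' @param baseline_M Baseline mitochondria per cell.
#' @param resample `"binomial"` (default; with-replacement resampling of the
#'   egg pool) or `"duplicate"` (deterministic doubling, for sensitivity
#'   analysis).
#' @return A list with `zygote` (a `mito_cell`), `genotype`
#'   (a `nuclear_genotype`) and `sex`.
#' @export
fertilize <- function(egg, sperm, mother, father, Q, baseline_M,
                      resample = c("binomial", "duplicate")) {
  stopifnot(inherits(egg, "mito_cell"), inherits(sperm, "mito_cell"),
            inherits(mother, "nuclear_genotype"),
            inherits(father, "nuclear_genotype"))
  resample <- match.arg(resample)
  target <- as.integer(2^Q * baseline_M)
  if (egg$total != target %/% 2L) {
    stop("egg total must equal 2^Q * baseline_M / 2")
  }
  zygote <- if (resample == "binomial") {
    mito_cell(rbinom(1L, target, egg$mutants / egg$total), target)
  } else {
    replicate_mitochondria(egg)
  }
  female <- runif(1L) < 0.5
  genotype <- nuclear_genotype(
    sex = if (female) "female" else "male",
    a1 = if (runif(1L) < 0.5) mother$a1 else mother$a2,
    a2 = if (runif(1L) < 0.5) father$a1 else father$a2,
    w = if (female) mother$w else NA)
  list(zygote = zygote, genotype = genotype, sex = genotype$sex)
}

#' Simulation parameter bundle
#'
#' Collects everything one generation needs: population size, life cycle,
#' mutation rates, fitness function, tissue epistasis, and the trait sets
#' mapped to the resident (1) and invader (2) alleles.
#'
#' @param N Population size (even; equal sexes enforced every generation).
#' @param lc A [life_cycle_params()].
#' @param rates A [mutation_rates()].
#' @param fp A [fitness_params()].
#' @param epistasis Worst-tissue interpolation weight (see
#'   [adult_fitness()]).
#' @param resident,invader [trait_set()]s for alleles 1 and 2.
#' @param dominance Autosomal heterozygote expression, `"invader"` or
#'   `"resident"`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(N = 500, lc = life_cycle_params(),
                       rates = mutation_rates(), fp = fitness_params(),
                       epistasis = 1, resident = trait_set(N_G = lc$L),
                       invader = resident,
                       dominance = c("invader", "resident")) {
  stopifnot(inherits(lc, "life_cycle_params"),
            inherits(rates, "mutation_rates"), inherits(fp, "fitness_params"),
            inherits(resident, "trait_set"), inherits(invader, "trait_set"))
  N <- as.integer(N)
  if (N < 2L || N %% 2L != 0L) stop("N must be an even integer >= 2")
  dominance <- match.arg(dominance)
  for (tr in list(resident, invader)) {
    if (tr$N_G < 1L || tr$N_G > lc$L) stop("N_G must lie in 1..L")
    if (tr$N_G + tr$A > lc$L) stop("N_G + A must not exceed L")
    if (tr$Q > lc$L) stop("Q must not exceed L")
  }
  structure(list(N = N, lc = lc, rates = rates, fp = fp,
                 epistasis = epistasis, resident = resident,
                 invader = invader, dominance = dominance),
            class = "sim_params")
}

#' Advance a population by one discrete generation
#'
#' Develops and ages every individual, computes adult fitness, samples `N/2`
#' mothers and `N/2` fathers with replacement weighted by fitness within
#' each sex, and produces exactly `N` offspring (`N/2` per sex, quota filled
#' by rejection on offspring sex) with a fresh meiotic draw per offspring.
#'
#' @param pop A population (see [initialize_population()]).
#' @param params A [sim_params()].
#' @return The next-generation population, with a `summary` attribute
#'   recording the parent generation's mean/min adult fitness and mean
#'   zygote load.
#' @export
next_generation <- function(pop, params) {
  stopifnot(inherits(pop, "mg_population"), inherits(params, "sim_params"))
  lc <- params$lc
  res <- cpp_next_generation(
    pop$sex, pop$a1, pop$a2, pop$w, pop$zm, pop$zt,
    lc$baseline_M, lc$L, lc$T_diff, lc$S,
    params$rates$mu_S, params$rates$mu_B,
    params$fp$s, params$fp$xi, params$epistasis,
    c(params$resident$N_G, params$invader$N_G),
    c(params$resident$A, params$invader$A),
    c(params$resident$Q, params$invader$Q),
    if (params$dominance == "invader") 2L else 1L)
  if (res$uniform_fallback) {
    warning("all fitnesses zero in one sex; uniform parent sampling used")
  }
  out <- structure(list(sex = res$sex, a1 = res$a1, a2 = res$a2, w = res$w,
                        zm = res$zm, zt = res$zt,
                        generation = pop$generation + 1L),
                   class = "mg_population")
  attr(out, "summary") <- list(
    parent_mean_fitness = res$parent_mean_fitness,
    parent_min_fitness = res$parent_min_fitness,
    parent_mean_zygote_load = res$parent_mean_zygote_load)
  out
}

#' Invader-allele frequency in a population
#'
#' @param pop A population.
#' @param locus `"autosomal"` (fraction of the `2N` autosomal copies) or
#'   `"W"` (fraction of the `N/2` W chromosomes).
#' @return Frequency in \[0, 1\].
#' @export
allele_frequency <- function(pop, locus = c("autosomal", "W")) {
  locus <- match.arg(locus)
  if (locus == "autosomal") {
    (sum(pop$a1 == 2L) + sum(pop$a2 == 2L)) / (2L * length(pop$a1))
  } else {
    wf <- pop$w[pop$sex == 1L]
    sum(wf == 2L) / length(wf)
  }
}

#' Population snapshot as JSON
#'
#' Genotype tallies and the zygote mutant-load histogram, for debugging and
#' provenance.
#'
#' @param pop A population.
#' @param path Optional output path.
#' @return JSON string (invisibly if written to a file).
#' @export
population_to_json <- function(pop, path = NULL) {
  stopifnot(inherits(pop, "mg_population"))
  obj <- list(
    generation = pop$generation,
    N = length(pop$sex),
    females = sum(pop$sex == 1L),
    autosomal_invader_freq = allele_frequency(pop, "autosomal"),
    w_invader_freq = allele_frequency(pop, "W"),
    zygote_load = list(mean = mean(pop$zm / pop$zt),
                       histogram = as.list(table(round(pop$zm / pop$zt, 2)))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.mg_population <- function(x, ...) {
  cat(sprintf("<population> N = %d (generation %d), mean zygote load %.4f\n",
              length(x$sex), x$generation, mean(x$zm / x$zt)))
  cat(sprintf("  invader frequency: autosomal %.3f, W-linked %.3f\n",
              allele_frequency(x, "autosomal"), allele_frequency(x, "W")))
  invisible(x)
}
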