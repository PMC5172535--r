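# Experiment drivers: burn-in to mutation-selection balance, introduction of
# a modifier allele at low frequency, tracking to fixation or loss, and
# aggregation of fixation probabilities with binomial confidence intervals,
# plus parameter sweeps.  Replicates run on deterministic per-replicate
# seeds (base seed + replicate index) so results are bit-reproducible and
# embarrassingly parallel.

#' Invasion experiment configuration
#'
#' @param params A [sim_params()] carrying resident and invader trait sets.
#' @param locus Locus of the invading allele: `"autosomal"` (germline
#'   timing) or `"W"` (oogamy).
#' @param f0 Introduction frequency (default 0.05, the neutral fixation
#'   benchmark).
#' @param n_reps Number of invasion replicates.
#' @param max_generations Censoring horizon per replicate.
#' @param burn_in_generations Resident-only generations run before the
#'   allele is introduced.
#' @param p_init Initial mutant load of the burn-in founders.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @return A list of class `invasion_config`.
#' @export
invasion_config <- function(params, locus = c("autosomal", "W"), f0 = 0.05,
                            n_reps = 1000, max_generations = 5000,
                            burn_in_generations = 200, p_init = 0.2,
                            seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  locus <- match.arg(locus)
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)")
  if (n_reps < 1) stop("n_reps must be at least 1")
  structure(list(params = params, locus = locus, f0 = f0,
                 n_reps = as.integer(n_reps),
                 max_generations = as.integer(max_generations),
                 burn_in_generations = as.integer(burn_in_generations),
                 p_init = p_init, seed = as.integer(seed)),
            class = "invasion_config")
}

#' Initialise a resident population of zygotes
#'
#' `N` zygotes with mutant counts drawn from
#' `Binomial(2^Q * M, p_init)`, all-resident genotypes, and exactly `N/2`
#' of each sex.  The zygotes are raw (undeveloped); development happens
#' inside [next_generation()].
#'
#' @param params A [sim_params()].
#' @param p_init Initial mutant frequency.
#' @return A population object (class `mg_population`).
#' @export
initialize_population <- function(params, p_init = 0.2) {
  stopifnot(inherits(params, "sim_params"))
  check_probability(p_init, "p_init")
  N <- params$N
  zt <- as.integer(2^params$resident$Q * params$lc$baseline_M)
  sex <- rep(c(1L, 0L), each = N %/% 2L)
  structure(list(sex = sex, a1 = rep(1L, N), a2 = rep(1L, N),
                 w = ifelse(sex == 1L, 1L, 0L),
                 zm = rbinom(N, zt, p_init), zt = rep(zt, N),
                 generation = 0L),
            class = "mg_population")
}

#' Run resident-only generations to reach mutation-selection balance
#'
#' @param pop A population.
#' @param params A [sim_params()].
#' @param generations Number of generations (default 200).
#' @return The evolved population, with attribute `trajectory`: a data frame
#'   of per-generation mean zygote load and mean adult fitness, for
#'   stationarity inspection.
#' @export
burn_in <- function(pop, params, generations = 200) {
  stopifnot(inherits(pop, "mg_population"))
  load <- fit <- numeric(generations)
  for (g in seq_len(generations)) {
    pop <- next_generation(pop, params)
    s <- attr(pop, "summary")
    load[g] <- s$parent_mean_zygote_load
    fit[g] <- s$parent_mean_fitness
  }
  attr(pop, "trajectory") <- data.frame(generation = seq_len(generations),
                                        mean_zygote_load = load,
                                        mean_fitness = fit)
  pop
}

#' Introduce the invading allele at frequency f0
#'
#' Autosomal locus: `round(2 N f0)` single allele copies are placed in
#' distinct randomly chosen individuals (heterozygotes).  W-linked locus:
#' `round(N/2 * f0)` randomly chosen females have their W allele replaced.
#'
#' @param pop A resident population.
#' @param locus `"autosomal"` or `"W"`.
#' @param f0 Introduction frequency.
#' @return The population with invader alleles placed.
#' @export
introduce_allele <- function(pop, locus = c("autosomal", "W"), f0 = 0.05) {
  stopifnot(inherits(pop, "mg_population"))
  locus <- match.arg(locus)
  N <- length(pop$sex)
  if (locus == "autosomal") {
    k <- round(2 * N * f0)
    if (k < 1) stop("f0 too small: no allele copies to introduce")
    if (k > N) stop("f0 too large for single-copy heterozygote placement")
    carriers <- sample.int(N, k)
    pop$a1[carriers] <- 2L
  } else {
    females <- which(pop$sex == 1L)
    k <- round(length(females) * f0)
    if (k < 1) stop("f0 too small: no W chromosomes to replace")
    pop$w[sample(females, k)] <- 2L
  }
  pop
}

#' Track an introduced allele until fixation or loss
#'
#' Iterates [next_generation()] until the invader frequency reaches 0 or 1,
#' or `max_generations` is exceeded (censored).
#'
#' @param pop A population carrying the invading allele.
#' @param cfg An [invasion_config()].
#' @return A list with `outcome` (`"fixed"`, `"lost"` or `"censored"`) and
#'   `generations` elapsed.
#' @export
run_to_fixation <- function(pop, cfg) {
  stopifnot(inherits(pop, "mg_population"), inherits(cfg, "invasion_config"))
  freq <- allele_frequency(pop, cfg$locus)
  gens <- 0L
  while (freq > 0 && freq < 1) {
    if (gens >= cfg$max_generations) {
      return(list(outcome = "censored", generations = gens))
    }
    pop <- next_generation(pop, cfg$params)
    freq <- allele_frequency(pop, cfg$locus)
    gens <- gens + 1L
  }
  list(outcome = if (freq >= 1) "fixed" else "lost", generations = gens)
}

#' Estimate the fixation probability of an invading allele
#'
#' Runs the full invasion experiment: one resident burn-in to
#' mutation-selection balance (seeded with the base seed), then `n_reps`
#' independent invasion replicates starting from the equilibrated
#' population, each on its own seed (`seed + replicate`).  The fixation
#' probability is `fixed / (fixed + lost)` with the Gaussian-approximation
#' 95% binomial confidence half-width `1.96 sqrt(p (1 - p) / n)`; censored
#' replicates are reported separately and never counted.
#'
#' An allele is deemed advantageous when its fixation probability exceeds
#' the neutral benchmark `f0` (the fixation probability of a neutral allele
#' equals its introduction frequency).
#'
#' @param cfg An [invasion_config()].
#' @return A list of class `fixation_record`: `p_hat`, `ci_halfwidth`,
#'   `fixed`, `lost`, `censored`, `n_effective`, `advantageous`,
#'   `mean_generations`, and the per-replicate `outcomes`.
#' @export
estimate_fixation_probability <- function(cfg) {
  stopifnot(inherits(cfg, "invasion_config"))
  set.seed(cfg$seed)
  base <- initialize_population(cfg$params, cfg$p_init)
  if (cfg$burn_in_generations > 0) {
    base <- burn_in(base, cfg$params, cfg$burn_in_generations)
  }
  outcomes <- character(cfg$n_reps)
  gens <- integer(cfg$n_reps)
  for (i in seq_len(cfg$n_reps)) {
    set.seed(cfg$seed + i)
    pop <- introduce_allele(base, cfg$locus, cfg$f0)
    res <- run_to_fixation(pop, cfg)
    outcomes[i] <- res$outcome
    gens[i] <- res$generations
  }
  fixed <- sum(outcomes == "fixed")
  lost <- sum(outcomes == "lost")
  censored <- sum(outcomes == "censored")
  n_eff <- fixed + lost
  if (n_eff == 0) stop("all replicates censored; raise max_generations")
  p_hat <- fixed / n_eff
  structure(list(p_hat = p_hat,
                 ci_halfwidth = 1.96 * sqrt(p_hat * (1 - p_hat) / n_eff),
                 fixed = fixed, lost = lost, censored = censored,
                 n_effective = n_eff,
                 advantageous = p_hat > cfg$f0,
                 mean_generations = mean(gens[outcomes != "censored"]),
                 outcomes = outcomes, seed = cfg$seed, f0 = cfg$f0),
            class = "fixation_record")
}

#' @export
print.fixation_record <- function(x, ...) {
  cat(sprintf("<fixation_record> p_hat = %.4f +/- %.4f (95%% CI)\n",
              x$p_hat, x$ci_halfwidth))
  cat(sprintf("  %d fixed / %d lost / %d censored; neutral benchmark %.3f%s\n",
              x$fixed, x$lost, x$censored, x$f0,
              if (x$advantageous) " -> advantageous" else ""))
  invisible(x)
}

#' Fixation-probability sweep over a parameter grid
#'
#' Runs [estimate_fixation_probability()] at every row of `grid`, a data
#' frame whose columns override fields of the template configuration.
#' Recognised columns: `mu_S`, `mu_B`, `T_diff`, `baseline_M`,
#' `resident_Q`, `invader_Q`, `resident_N_G`, `invader_N_G`, `resident_A`,
#' `invader_A`, `locus`, `n_reps`, `seed`.
#'
#' @param grid Data frame of parameter combinations.
#' @param cfg Template [invasion_config()].
#' @return A data frame: one row per grid point with all varied parameters,
#'   `p_hat`, `ci_halfwidth`, replicate tallies, `seed` and `n_reps`
#'   (full provenance).
#' @export
sweep_fixation <- function(grid, cfg) {
  stopifnot(is.data.frame(grid), inherits(cfg, "invasion_config"))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, , drop = FALSE]
    cfg_i <- amend_config(cfg, g)
    rec <- estimate_fixation_probability(cfg_i)
    prov <- data.frame(p_hat = rec$p_hat, ci_halfwidth = rec$ci_halfwidth,
                       fixed = rec$fixed, lost = rec$lost,
                       censored = rec$censored, n_reps = cfg_i$n_reps,
                       seed = cfg_i$seed, f0 = cfg_i$f0, row.names = NULL)
    cbind(g, prov[, setdiff(names(prov), names(g)), drop = FALSE])
  })
  do.call(rbind, rows)
}

# apply one grid row's overrides to a template invasion_config
amend_config <- function(cfg, g) {
  p <- cfg$params
  lc <- p$lc; rates <- p$rates
  res <- p$resident; inv <- p$invader
  pick <- function(col, default) if (col %in% names(g)) g[[col]] else default
  lc <- life_cycle_params(L = lc$L, T_diff = pick("T_diff", lc$T_diff),
                          S = lc$S,
                          baseline_M = pick("baseline_M", lc$baseline_M))
  rates <- mutation_rates(mu_S = pick("mu_S", rates$mu_S),
                          mu_B = pick("mu_B", rates$mu_B))
  res <- trait_set(N_G = pick("resident_N_G", res$N_G),
                   A = pick("resident_A", res$A),
                   Q = pick("resident_Q", res$Q))
  inv <- trait_set(N_G = pick("invader_N_G", inv$N_G),
                   A = pick("invader_A", inv$A),
                   Q = pick("invader_Q", inv$Q))
  params <- sim_params(N = p$N, lc = lc, rates = rates, fp = p$fp,
                       epistasis = p$epistasis, resident = res,
                       invader = inv, dominance = p$dominance)
  invasion_config(params,
                  locus = as.character(pick("locus", cfg$locus)),
                  f0 = cfg$f0,
                  n_reps = pick("n_reps", cfg$n_reps),
                  max_generations = cfg$max_generations,
                  burn_in_generations = cfg$burn_in_generations,
                  p_init = cfg$p_init, seed = pick("seed", cfg$seed))
}

#' Preset simulation profiles
#'
#' `"desk"` is a scaled-down profile (N = 100, L = 6, resident somatic
#' gametogenesis at N_G = 6) sized for interactive work on one CPU;
#' `"paper"` is the full-scale profile (N = 500, L = 10, N_G = 10).  Both
#' use M = 50, S = 40, mu_S = 0.01, mu_B = 0.005, s = 1, xi = 2 and a single
#' tissue unless overridden.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... Overrides passed to [sim_params()] components: `T_diff`,
#'   `mu_S`, `mu_B`, `resident`, `invader`, `N`, and friends.
#' @return A [sim_params()].
#' @export
profile_params <- function(profile = c("desk", "paper"), T_diff = 0,
                           mu_S = 0.01, mu_B = 0.005, s = 1, xi = 2,
                           N = NULL, resident = NULL, invader = NULL,
                           dominance = "invader") {
  profile <- match.arg(profile)
  L <- if (profile == "desk") 6L else 10L
  N <- if (is.null(N)) (if (profile == "desk") 100L else 500L) else N
  lc <- life_cycle_params(L = L, T_diff = T_diff, S = 40, baseline_M = 50)
  if (is.null(resident)) resident <- trait_set(N_G = L)
  if (is.null(invader)) invader <- resident
  sim_params(N = N, lc = lc, rates = mutation_rates(mu_S, mu_B),
             fp = fitness_params(s, xi), epistasis = 1,
             resident = resident, invader = invader, dominance = dominance)
}
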