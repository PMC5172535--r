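# Shared test utilities.

# standard error of a sample variance via the fourth central moment
se_of_variance <- function(x) {
  n <- length(x)
  m <- mean(x)
  m4 <- mean((x - m)^4)
  s2 <- var(x)
  sqrt((m4 - (n - 3) / (n - 1) * s2^2) / n)
}

# chi-square goodness-of-fit p-value of observed counts against probs
gof_pvalue <- function(counts, probs) {
  keep <- probs > 0
  suppressWarnings(chisq.test(counts[keep], p = probs[keep] / sum(probs[keep]))$p.value)
}

# build a bare organism object for fitness-function tests
fake_organism <- function(cells, total, tissue) {
  structure(list(cells = as.integer(cells), cell_total = as.integer(total),
                 tissue = as.integer(tissue),
                 germ = 0L, germ_total = as.integer(total),
                 N_G = 1L, A = 0L, age = 40L,
                 lc = life_cycle_params(L = 2, T_diff = 1, S = 40,
                                        baseline_M = max(2L, total))),
            class = "organism")
}
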