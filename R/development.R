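# Organism-level model: a zygote grows into an adult of 2^L cells over L
# divisions, tissues are assigned by ancestry from the 2^T cells present at
# division T, a primordial germ cell is sequestered after division N_G
# (copying a randomly chosen cell, without depleting the soma) and may
# proliferate for A further divisions, and background mutation continues to
# act on all cells until the lifespan S.  One division = one time unit.

#' Life-cycle parameters
#'
#' @param L Divisions from zygote to adult (cell count `2^L`); default 10.
#' @param T_diff Division at which tissues differentiate: the `2^T_diff`
#'   cells present then each found a tissue.  `T_diff = 0` means a single
#'   undifferentiated tissue.
#' @param S Lifespan in time units before gamete production; default 40.
#' @param baseline_M Mitochondria per somatic cell; even, default 50.
#' @return A list of class `life_cycle_params`.
#' @export
life_cycle_params <- function(L = 10, T_diff = 0, S = 40, baseline_M = 50) {
  L <- as.integer(L); T_diff <- as.integer(T_diff)
  S <- as.integer(S); baseline_M <- as.integer(baseline_M)
  if (T_diff < 0 || T_diff > L || L > S) {
    stop("life cycle requires 0 <= T_diff <= L <= S")
  }
  if (baseline_M < 2L || baseline_M %% 2L != 0L) {
    stop("baseline_M must be an even number >= 2")
  }
  structure(list(L = L, T_diff = T_diff, S = S, baseline_M = baseline_M),
            class = "life_cycle_params")
}

#' Develop a zygote into an adult organism
#'
#' Runs `L` rounds of cell division from the zygote.  While the cell total
#' exceeds `baseline_M` (oogamous early development from a `2^Q * M`
#' zygote), divisions partition the existing mitochondria without
#' replication; once the baseline is restored, divisions are replicative
#' with copying-error input.  Background mutation acts every time unit.
#' After division `N_G` a primordial germ cell is sequestered by copying a
#' randomly chosen cell; it undergoes `A` further proliferative divisions
#' (yielding `2^A` germ cells) and thereafter only background damage.
#'
#' The returned organism has `age = L`; use [age_organism()] to continue
#' background mutation to the lifespan `S`.
#'
#' @param zygote A [mito_cell()]; its total must be `2^Q * baseline_M` for
#'   some integer `Q <= L`.
#' @param lc A [life_cycle_params()].
#' @param rates A [mutation_rates()].
#' @param N_G Division after which the germline is sequestered, in `1..L`.
#' @param A Additional proliferative germline divisions (default 0);
#'   requires `N_G + A <= L`.
#' @return An object of class `organism`: list with `cells` (integer mutant
#'   counts of the `2^L` somatic cells in ancestry order), `cell_total`,
#'   `tissue` (tissue index per cell, `1..2^T_diff`), `germ` (mutant counts
#'   of the `2^A` germ cells), `germ_total`, `N_G`, `A`, `age`, `lc`.
#' @examples
#' org <- develop(mito_cell(10, 50), life_cycle_params(L = 4),
#'                mutation_rates(0.01, 0.005), N_G = 2)
#' length(org$cells)  # 16
#' @export
develop <- function(zygote, lc, rates, N_G = lc$L, A = 0) {
  stopifnot(inherits(zygote, "mito_cell"), inherits(lc, "life_cycle_params"),
            inherits(rates, "mutation_rates"))
  N_G <- as.integer(N_G); A <- as.integer(A)
  if (N_G < 1L || N_G > lc$L) stop("N_G must lie in 1..L")
  if (A < 0L || N_G + A > lc$L) {
    stop("germline proliferation requires N_G + A <= L")
  }
  ratio <- zygote$total / lc$baseline_M
  if (ratio < 1 || log2(ratio) %% 1 != 0) {
    stop("zygote total must be 2^Q * baseline_M for integer Q >= 0")
  }
  if (log2(ratio) > lc$L) stop("zygote too large to reach baseline_M in L divisions")
  res <- cpp_develop(zygote$mutants, zygote$total, lc$baseline_M, lc$L,
                     N_G, A, lc$L, rates$mu_S, rates$mu_B)
  structure(list(cells = res$cells, cell_total = res$cell_total,
                 tissue = rep(seq_len(2L^lc$T_diff),
                              each = 2L^(lc$L - lc$T_diff)),
                 germ = res$germ, germ_total = res$germ_total,
                 N_G = N_G, A = A, age = lc$L, lc = lc),
            class = "organism")
}

#' @export
print.organism <- function(x, ...) {
  cat(sprintf(paste0("<organism> %d cells of %d mitochondria in %d tissue(s),",
                     " %d germ cell(s), age %d\n"),
              length(x$cells), x$cell_total, max(x$tissue), length(x$germ),
              x$age))
  cat(sprintf("  mean somatic load %.4f, germ load %.4f\n",
              mean(x$cells) / x$cell_total, mean(x$germ) / x$germ_total))
  invisible(x)
}

#' Age an organism to the end of its lifespan
#'
#' Applies background mutation to every somatic and germ cell once per
#' remaining time unit up to `S`.  Because copies mutate independently and
#' never revert, the `k = S - age` rounds are collapsed into a single
#' binomial draw per cell with per-copy probability `1 - (1 - mu_B)^k`,
#' which has exactly the same distribution as `k` sequential rounds.
#'
#' @param org An [develop()]ed organism.
#' @param rates A [mutation_rates()].
#' @return The organism with `age = S`.
#' @export
age_organism <- function(org, rates) {
  stopifnot(inherits(org, "organism"), inherits(rates, "mutation_rates"))
  k <- org$lc$S - org$age
  if (k < 0) stop("organism is older than its lifespan")
  if (k > 0 && rates$mu_B > 0) {
    peff <- 1 - (1 - rates$mu_B)^k
    org$cells <- org$cells +
      rbinom(length(org$cells), org$cell_total - org$cells, peff)
    org$germ <- org$germ +
      rbinom(length(org$germ), org$germ_total - org$germ, peff)
  }
  org$age <- org$lc$S
  org
}

#' Mean fitness of one somatic tissue
#'
#' @param org An [organism][develop()].
#' @param tissue Tissue index in `1..2^T_diff`.
#' @param fp A [fitness_params()].
#' @return The arithmetic mean of cell fitness over the tissue's cells.
#' @export
tissue_fitness <- function(org, tissue, fp = fitness_params()) {
  stopifnot(inherits(org, "organism"))
  idx <- org$tissue == tissue
  if (!any(idx)) stop("empty or unknown tissue index")
  mean(1 - fp$s * (org$cells[idx] / org$cell_total)^fp$xi)
}

#' Adult fitness under worst-tissue epistasis
#'
#' By default adult fitness is the minimum of the tissue fitnesses: if one
#' tissue inherits a disproportionate share of mutant mitochondria the whole
#' organism suffers.  `epistasis` interpolates between the mean of tissue
#' fitnesses (`0`) and the minimum (`1`, the default).
#'
#' @param org An [organism][develop()].
#' @param fp A [fitness_params()].
#' @param epistasis Interpolation weight on the worst tissue, in \[0, 1\].
#' @return Adult fitness in \[0, 1\].
#' @export
adult_fitness <- function(org, fp = fitness_params(), epistasis = 1) {
  stopifnot(inherits(org, "organism"))
  check_probability(epistasis, "epistasis")
  tf <- vapply(seq_len(max(org$tissue)), function(t) tissue_fitness(org, t, fp),
               numeric(1))
  (1 - epistasis) * mean(tf) + epistasis * min(tf)
}

#' Serialise an organism to JSON
#'
#' Cells are written as count pairs grouped by tissue, for debugging and
#' fixtures.
#'
#' @param org An [organism][develop()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
organism_to_json <- function(org, path = NULL) {
  stopifnot(inherits(org, "organism"))
  obj <- list(
    age = org$age, cell_total = org$cell_total, germ_total = org$germ_total,
    N_G = org$N_G, A = org$A,
    tissues = lapply(split(org$cells, org$tissue), function(m) {
      lapply(m, function(x) c(x, org$cell_total))
    }),
    germ = lapply(org$germ, function(x) c(x, org$germ_total)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
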