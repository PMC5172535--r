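---
title: "Modelling germline evolution through selection for mitochondrial quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling germline evolution through selection for mitochondrial quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitogerm)
set.seed(1)
```

## The scientific question

Most bilaterian animals sequester a dedicated germline early in development,
while plants and basal metazoans form gametes late from somatic stem cells
(somatic gametogenesis).  `mitogerm` implements a multilevel evolutionary
model in which this difference is driven by selection for *mitochondrial*
quality.  Mitochondria accumulate two kinds of mutation — copying errors at
rate $\mu_S$ per genome per replication, and background damage at rate
$\mu_B$ per genome per time unit — and, unlike nuclear genes, they double
and segregate randomly at every cell division.  Segregational drift raises
the variance in mutant load between cells without changing its mean, which
is both a curse (tissues can inherit a biased share of mutants) and a
blessing (some gametes end up nearly mutation-free, giving selection
something to act on).  Whether early sequestration of a germline pays off
depends on the balance between limiting copying-error input and losing
segregational variance.

## Model structure

### Cells

A cell is a pair $(m, M)$: $m$ mutant mitochondria of $M$ total.  Mutation
severity is fixed, so counts are a sufficient statistic; back-mutation never
occurs.  One division cycle applies, in order: background mutation
($\mathrm{Binom}(M-m,\mu_B)$ new mutants), copying-error mutation
($\mathrm{Binom}(M-m,\mu_S)$), duplication $(m, M) \to (2m, 2M)$, and
hypergeometric partition (a daughter samples $M$ of the $2M$ copies without
replacement).  Cells above the baseline $M$ — the early divisions of an
oogamous zygote — are partitioned without replication and without
copying-error input until the baseline is restored.

Cell fitness follows the threshold-shaped function
$$\omega(m) = 1 - s\,(m/M)^{\xi},$$
with defaults $s = 1$ and $\xi = 2$ (concave: a large mutant load must
accumulate before function is impaired, as in mitochondrial disease).
$\xi = 1$ and $\xi = 0.5$ give linear and convex alternatives.

### The analytic oracle

For a single lineage the model is exactly solvable.  With state vector
$\mathbf p^{(n)}$ over mutant counts $0..M$, one division is the
column-stochastic operator $\mathbf K \mathbf J$, where
$J_{q,m} = \binom{M-m}{q-m}\mu^{q-m}(1-\mu)^{M-q}$ is the mutation kernel
and $K_{q,m}$ the hypergeometric sampling kernel
$\mathrm{Hypergeom}(2M, 2m, M)$ evaluated at $q$.  (In the printed form of
the sampling kernel the running index appears as $k$; it is the row index
$q$.)  `propagate_distribution()` computes
$\mathbf p^{(n)} = (\mathbf K \mathbf J)^n \mathbf p^{(0)}$ by iterated
multiplication — $n \le 60$ in every use here, so eigendecomposition buys
nothing — clipping floating-point negatives above $-10^{-12}$ and
renormalising to preserve stochasticity.  The pmfs come from `dbinom()` and
`dhyper()`, which work on log scale internally and are accurate at the
largest pools used ($2^Q M \le 1600$).

Without mutation the variance of mutant frequency has the closed form
$$\mathrm{Var}(P_n) = p_0(1-p_0)\left[1 - \left(1 -
\tfrac{1}{2M-1}\right)^n\right],$$
and for an oogamous zygote of $2^QM$ copies undergoing $Q$ partition-only
divisions the recurrence
$$\mathrm{Var}(P_n) = \frac{p_0(1-p_0)}{2^{1+Q-n}M-1} +
\mathrm{Var}(P_{n-1})\left(1 - \frac{1}{2^{1+Q-n}M-1}\right),
\qquad 1 \le n \le Q,$$
with large-pool approximation
$\mathrm{Var}(P_n) \approx p_0(1-p_0)(2^n-1)/(2^QM)$.  These formulas are
the package's primary correctness gate: the stochastic engine must
reproduce them to Monte Carlo accuracy (total-variation distance < 0.01 on
$10^5$ lineages; variances within three standard errors).

```{r oracle}
p <- propagate_distribution(delta_distribution(12, 50), mu = 0.01, n = 10)
distribution_moments(p)
variance_closed_form(0.5, 50, 10)
```

### Organisms

Development runs $L$ divisions from a zygote ($2^L$ cells).  The $2^T$
cells present at division $T$ each found a tissue, and descendants inherit
the label (ancestry assignment — cells are stored in lineage order so
tissues are contiguous blocks).  Tissue fitness is the mean of its cells'
$\omega$; adult fitness is the *minimum* over tissues (worst-tissue
epistasis).  The strength of tissue interdependence is set by the number of
tissues; an explicit interpolation `epistasis` $\in [0,1]$ between mean (0)
and minimum (1) is provided for sensitivity analysis, with the minimum as
default.

After division $N_G$ the germline is sequestered by *copying* a randomly
chosen cell (the soma is not depleted).  It undergoes $A$ further
replicative divisions — yielding $2^A$ germ cells, of which gametogenesis
picks one uniformly at random (random atresia) — and thereafter only
background damage.  Time accounting: one division = one time unit;
background mutation applies to every cell once per time unit until the
lifespan $S$.  A germ cell sequestered at $N_G$ therefore receives
$S - N_G$ post-sequestration exposures on top of the $N_G$ it inherited, so
total background exposure is $\approx S$ regardless of germline timing —
background damage cannot be escaped by sequestering early, copying errors
can.  We apply background mutation in the same time unit as a replicative
division (both steps are part of one cell cycle); the germline's extra
divisions are full replicative divisions and do accrue copying errors.

Post-developmental ageing is collapsed into a single draw per cell with
per-copy probability $1-(1-\mu_B)^k$ over the $k$ remaining time units.
Because copies mutate independently and never revert, this is exactly
distribution-equivalent to $k$ sequential rounds, not an approximation.

### Populations and nuclear genetics

A population holds $N$ individuals (default 500), half female (ZW) and half
male (ZZ), in discrete non-overlapping generations.  Germline timing
$(N_G, A)$ sits at an autosomal locus expressed in both sexes, with the
invading allele dominant by default (configurable); oogamy $Q$ and the
degree of uniparental inheritance $v$ are W-linked, so dominance never
arises for them.  Only strict maternal inheritance ($v = 1$) is modelled:
no mixing rule exists for paternal leakage, so the trait is carried but
fixed.

Each generation: develop and age all individuals; sample $N/2$ mothers and
$N/2$ fathers with replacement, weighted by adult fitness within each sex
(if every fitness in a sex is zero the draw falls back to uniform, with a
warning); produce exactly $N$ offspring, filling the $N/2$-per-sex quota by
rejection on offspring sex, with an independently drawn parent pair and a
fresh meiosis per offspring.  Female gametogenesis applies $Q$ rounds of
copying-error mutation plus duplication (oogamy amplification, reaching
$2^QM$), then meiosis.

Two modelling points deserve explanation because the verbal description
underdetermines them:

* **Meiosis arithmetic.**  "Two meiotic divisions with sampling without
  replacement" must end at half the germ cell's content (sperm $M/2$, eggs
  $2^QM/2$), which forces one net duplication.  We implement duplicate
  (without mutation, since mutational input is accounted in the $Q$
  amplification rounds) followed by two successive hypergeometric halvings:
  both stated gamete sizes come out exactly and the gamete experiences two
  rounds of segregational sampling.
* **Resampling after fusion.**  The zygote's $2^QM$ copies are resampled
  *with replacement* from the egg's pool, i.e. the zygote mutant count is
  $\mathrm{Binom}(2^QM, m_{\mathrm{egg}}/M_{\mathrm{egg}})$.  This is the
  simplest reading of restoring the zygote content from an egg of half that
  size; a deterministic duplicate-all alternative sits behind
  `fertilize(..., resample = "duplicate")` for sensitivity analysis.

A related edge case: a germ cell sequestered while the oogamous zygote was
still above baseline carries $2^jM$ copies; amplification then applies only
the remaining $Q-j$ rounds so the egg size is always $2^QM/2$.  Male germ
cells develop identically (the locus is expressed in both sexes), but their
gamete mitochondria are unobservable under $v=1$ and are not drawn.

## Invasion experiments

`estimate_fixation_probability()` runs the full experiment: a resident
population is initialised with zygote loads
$\mathrm{Binom}(2^QM, p_{\mathrm{init}})$ ($p_{\mathrm{init}} = 0.2$ by
default), burnt in to mutation–selection balance for a fixed, configurable
number of generations (default 200; the mean-load trajectory is recorded so
stationarity can be inspected rather than enforced), and the invading
allele is introduced at $f_0 = 0.05$ — single copies in distinct
heterozygotes at the autosomal locus, or replacement of
$\mathrm{round}(f_0 N/2)$ W chromosomes.  Each replicate then iterates
generations until the allele fixes or is lost (a censoring horizon guards
against pathological configurations; censored replicates are reported,
never counted).  The estimate is $\hat p = \mathrm{fixed}/(\mathrm{fixed} +
\mathrm{lost})$ with the Gaussian 95% binomial half-width
$1.96\sqrt{\hat p(1-\hat p)/n}$, and an allele is advantageous when
$\hat p$ exceeds the neutral benchmark $f_0$.

Replicates use seeds `base_seed + replicate`, so runs are bit-reproducible
and trivially parallelisable.  The burn-in is performed once per
configuration and the equilibrated population shared across replicates:
replicate trajectories remain independent given their seeds, and for the
calibration case of a phenotypically neutral allele the starting
mitochondrial state does not affect the fixation probability at all.

```{r neutral, eval = FALSE}
params <- profile_params("desk")         # N = 100, L = 6, single tissue
cfg <- invasion_config(params, "autosomal", n_reps = 2000, seed = 101)
estimate_fixation_probability(cfg)
#> <fixation_record> p_hat = 0.0500 +/- 0.0096 (95% CI)
#>   100 fixed / 1900 lost / 0 censored; neutral benchmark 0.050
```

## Problem sizes and the desk profile

Two preset profiles ship with the package.  The `paper` profile uses
$N = 500$, $L = 10$, $S = 40$, $M = 50$, $\mu_S = 0.01$, $\mu_B = 0.005$,
somatic gametogenesis at $N_G = 10$; fixation-probability surfaces at this
scale need $10^3$–$10^4$ replicates per point and are cluster-scale work.
The `desk` profile ($N = 100$, $L = 6$, resident $N_G = 6$, invading
germline allele at $N_G = 3$) preserves every qualitative contrast — the
$\mu_S$/$\mu_B$ gradient of germline fixation, oogamy's suppression of
early-germline invasion, its restoration by germline proliferation — at a
few CPU-minutes per estimate, and is what the test suite exercises.  The
desk lifecycle halves the copying-error differential between early
germline and somatic gametogenesis (3 of 6 divisions saved rather than 7
of 10), so absolute thresholds — notably the background-mutation rate above
which the early germline stops being advantageous — sit at different
parameter values than at full scale; only directions of effects transfer.

Test replicate counts (200 per grid point for trend tests over a 3×3
$\mu_S \times \mu_B$ grid centred on $(0.01, 0.005)$ and spanning a factor
of 25; 600 per point for pairwise oogamy/atresia contrasts; 2000 for
neutral calibration) were chosen for adequate power at these effect sizes.

One contrast cannot be run at $L = 6$ at all: whether additional germline
divisions rescue an early germline suppressed by resident oogamy.  With
$N_G = 3$ and $A = 3$ under a six-division lifecycle, the invader's germ
lineage performs the same three replicative divisions as the resident's
somatic stem cells, so the two phenotypes nearly coincide, both sit at the
neutral fixation level, and their difference measures noise.  That check
therefore uses an intermediate $L = 8$ lifecycle (resident $N_G = 8$,
invader $N_G = 3$, $A = 3$, $Q = 3$, eight tissues), which preserves a
five-division copying-error differential while remaining tractable.

## What the synthetic data does and does not emulate

All inputs are generated internally; the model is deliberately abstract.
It captures: two mutation channels with distinct exposure accounting,
segregational drift at every division, worst-tissue epistasis, ZW mating
types with W-linked maternal-effect loci, and the oogamy/atresia mechanics
of female gametogenesis.  It ignores: within-cell mitochondrial selection
(mitophagy, selfish replication — roughly equivalent to shifting the
mutation rates), variable mutation severity, spatial structure, cell death
during development, overlapping generations, mate choice, and paternal
mitochondrial leakage.  Mutation rates are orders of magnitude above
empirical estimates so that dynamics resolve in hundreds of generations;
conclusions should be read through relative, not absolute, parameter
values.  Passing tests therefore certify the model's internal consistency
and its qualitative selection patterns, not quantitative predictions for
any real species.

## Numerical and degenerate-input choices

* All stochastic functions consume R's global RNG; `set.seed()` fixes whole
  experiments.  The generation engine is C++ (via Rcpp) drawing from the
  same RNG stream.
* Transition matrices are validated column-stochastic to $10^{-12}$;
  propagation clips negatives above $-10^{-12}$ and renormalises.
* An all-mutant cell is inert under both mutation channels (empty
  binomial); partition of an odd total is a structural error, as is
  developing a zygote whose total is not $2^QM$.
* `round()` (banker's rounding) sets introduced allele copies; the realised
  frequency is within $1/(2N)$ of $f_0$.
* With $s = 1$ a fully mutant population has fitness exactly zero in every
  tissue; parent sampling then falls back to uniform with a warning rather
  than failing.

## Known limitations

* The evolutionary dynamics of partial uniparental inheritance ($v < 1$)
  are out of scope: the trait is represented but has no mixing rule.
* Germline proliferation must complete during development
  ($N_G + A \le L$).
* The extended-lifecycle approximation (adult fitness from
  $\mathbf p^{(60)}$, gamete loads from $\mathbf p^{(60)}$ and
  $\mathbf p^{(10)}$ via `expected_fitness_of_distribution()`) supplies the
  ingredients but not a packaged driver; how the two distributions combine
  per genotype is a modelling choice the user must make explicit.
* Even with one tissue, oogamy slightly raises mean adult fitness (the
  concave fitness function converts variance suppression into a mean
  effect, ~0.02 at $L = 10$); the multi-tissue benefit is about three times
  larger.  "No effect without tissue differentiation" is an approximation
  at figure resolution, and the tests assert the relative contrast.
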