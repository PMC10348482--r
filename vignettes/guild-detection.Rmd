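---
title: "Detecting metabolic functional guilds with the aspect Bernoulli model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metabolic functional guilds with the aspect Bernoulli model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildAB)
```

## The problem

A genome collection — MAGs, SAGs, isolates — annotated for pathway presence
yields a binary matrix *Y* with G genomes as rows and F functions as
columns. A *metabolic functional guild* is a set of functions that co-occur
within individual genomes because they jointly enable an ecological
strategy (e.g. the enzymes of DMSP degradation, or the photosystem
components). Hierarchical clustering and ordination struggle here: they
assign each function to at most one group, cannot express partial genome
membership, and treat every 0 as a true absence even though draft genomes
are incomplete.

## The model

The aspect Bernoulli model assumes each cell is an independent Bernoulli
realization of a latent probability,

$$Y_{gf} \sim \mathrm{Bernoulli}(V_{gf}), \qquad V = \Gamma\beta,$$

with $\Gamma \in [0,1]^{G \times K}$ row-stochastic (genome *g*'s weights
over K *aspects*) and $\beta \in [0,1]^{K \times F}$ (aspect *k*'s
probability of exhibiting function *f*). Equivalently, each cell carries a
latent indicator $Z_{gfk}$ naming the aspect that generated it, drawn from
$\Gamma_{g\cdot}$, after which $Y_{gf} \sim \mathrm{Bernoulli}(\beta_{kf})$.
Because observations are probabilities rather than hard assignments, a
false absence in a draft genome is absorbed as an unlikely draw instead of
distorting group structure, functions may participate in several aspects,
and genomes may spread weight over several aspects.

### Fitting

`fit_ab()` maximizes the Bernoulli log-likelihood
$\sum_{g,f} [Y_{gf}\log V_{gf} + (1-Y_{gf})\log(1-V_{gf})]$ by EM:

* **E step.** For each cell, the posterior over the generating aspect:
  $w_{gfk} = \Gamma_{gk}\beta_{kf}/V_{gf}$ if $Y_{gf}=1$, and
  $\Gamma_{gk}(1-\beta_{kf})/(1-V_{gf})$ if $Y_{gf}=0$.
* **M step.** $\Gamma_{gk} \leftarrow \frac1F \sum_f w_{gfk}$ (rows remain
  on the simplex because responsibilities sum to one) and
  $\beta_{kf} \leftarrow \sum_g w_{gfk} Y_{gf} / \sum_g w_{gfk}$.

The implementation (RcppArmadillo) never materializes the G × F × K
responsibility array: with $A = Y/V$ and $B = (1-Y)/(1-V)$, the M-step
sufficient statistics are four matrix products per iteration, so a
1,000 × 200 matrix at K = 8 fits in a couple of seconds.

Tunable parameters, defaults, and why:

* `K` — number of aspects, the one genuinely free parameter; default 10 in
  `run_pipeline()`, but it should be chosen with the simulation sweep below.
* `n_iter = 500` — on matrices of a few thousand genomes the likelihood
  plateaus by roughly this many iterations; a relative-change rule
  (`tol = 1e-10`) usually stops earlier.
* `n_restarts = 10` — EM only finds local maxima; the best of 10 random
  starts is returned, and each restart's seed (`seed + r - 1`) makes any
  single restart reproducible.
* Initialization: $\Gamma$ rows from a symmetric flat Dirichlet, $\beta$
  entries from Uniform(0.25, 0.75). Boundary starts (0 or 1) would freeze
  responsibilities; interior starts cannot.

Numerical choices: $V$ is clipped into $[10^{-12}, 1-10^{-12}]$ before
logs and divisions, because a perfectly fit block drives $V$ to the
boundary. Post-hoc scores normalize the Bayes numerators
$\Gamma_{gk}\beta_{kf}$ by their sum over aspects instead of dividing by
the clipped $V$ — the identical quantity, but exact even where $V$
underflows; a cell whose total presence probability is exactly zero falls
back to the prior $\Gamma$ row. Aspects are label-symmetric, so for stable
output they are reported sorted by descending total genome weight
$\sum_g \Gamma_{gk}$.

## From aspects to guilds

Aspects are defined over *all* functions; a guild is a small, co-occurring
subset. Within each aspect, functions are ranked by the score
$s_{fk} = r_{fk} \cdot q_{fk}$:

* $r_{fk} = \frac1G \sum_g P(Z_{gfk}=1 \mid Y_{gf}=1)$ — how much of
  function *f*'s presence the aspect explains. The average runs over
  **all** genomes, not only carriers of *f*; under this marginal reading
  $\sum_k r_{fk} = 1$ for every function,
  and `attribution_scores(..., conditional = TRUE)` exposes the
  carrier-restricted mean for comparison without endorsing it.
* $q_{fk}$ — function *f*'s abundance among aspect *k*'s *probabilistic
  representatives* $A_k$ (genomes with $\arg\max_j \Gamma_{gj} = k$ **and**
  $\Gamma_{gk} > 2/K$), divided by the mean function abundance in $A_k$.
  The 2/K cut drops genomes with nearly uniform weights. Note that at
  K = 2 the threshold equals 1 and excludes every genome: all $A_k$ are
  empty, $q \equiv 0$, and the aspect is reported "unrepresented" with a
  warning rather than an error. Use K ≥ 3 (and preferably the sweep below)
  when representative-based scores matter. Argmax ties go to the lowest
  aspect index, with a warning, so output is deterministic.

Ties in the score ranking are broken by ascending function ID.

Two guild definitions are provided, both prefixes of the score ranking:

* `define_guild_fixed()` — top *m* functions (default 5).
* `define_guild_min_mapback()` — the **largest** prefix whose *mapback
  genomes* (genomes carrying every prefix function) number at least
  `min_genomes` (default 100, applied as ≥). Mapback counts are
  non-increasing in prefix size — each added function is one more
  conjunct — so the largest qualifying prefix is well defined and maximally
  informative; `expansion_curve()` exposes the whole count-vs-size curve.
  If even the size-2 prefix lacks support the size-2 guild is returned
  flagged `below_threshold`.

Guilds from different aspects may share functions; that is a feature of the
decomposition (clustering methods forbid it) and duplicates are reported
as-is.

### Guild specificity

`guild_confidence_report()` computes the association-rule confidence
$\mathrm{Conf}(A \to B) = \sum_g Y_{gA}Y_{gB} / \sum_g Y_{gA}$ for every
ordered pair of guild functions, separately within the mapback genomes
(1 by construction), the outgroup, and the whole dataset. Low outgroup
confidence means the pair co-occurs essentially only inside the guild. A
zero-support antecedent makes the ratio undefined: it is reported missing —
never coerced to 0 or 1, which would bias the minimum summary — and
summaries (mean, minimum over off-diagonal pairs) count skipped cells.

## The synthetic-guild framework and choosing K

`generate_base_matrix()` draws a surrogate background with its own latent
aspect structure (Dirichlet genome weights; per-aspect presence
probabilities mixing 0.9 and 0.05, rescaled to a target density — default
0.25, a typical pathway-table fill rate). `insert_artificial_guilds()`
appends *perfect* planted guilds: brand-new columns that are 1 in exactly
`round(abundance × G)` member genomes and 0 elsewhere (nearest-integer
rounding, halves up, so a 2% guild in 3,840 genomes has exactly 77
members). The default design space — sizes 5/7/9, abundances 2/5/10%,
non-overlapping insertion, 100 replicates — spans weak to strong guilds;
the non-overlapping mode caps total membership at G, and the random mode
draws members independently per guild (the overlapping-variant assignment
scheme was left open; independent sampling is the simplest faithful
choice).

What the generator emulates: a sparse background with low-rank block-ish
structure plus exactly co-occurring planted modules. What it does not:
annotation error (planted guilds are perfect — `flip_noise()` can degrade
them), phylogenetic correlation between genomes, or the long-tailed
function-prevalence distribution of real pathway tables. Passing recovery
tests on these simulations therefore demonstrates that the estimator finds
planted co-occurrence structure at realistic sizes and abundances, not that
any particular real dataset has such structure.

`ksweep()` fits a range of K over replicate simulations and reports, per K:

* **hit rate** — fraction of planted guilds whose functions all appear in
  the top 15 (`top_window`) of exactly ≥1 aspect's ranking, averaged per
  dataset over replicates;
* **extra hits** — surplus appearances, $\sum_{\text{guilds}} \max(0,
  \#\text{matching aspects} - 1)$, the over-fitting signal.

`select_k()` applies the selection heuristic: among K values whose mean
extra hits are ≤ 0.05 (absorbing simulation noise around zero), return
those with maximal hit rate. Too-small K hides rare guilds (hit rate drops,
extra hits stay zero); too-large K splits guilds across aspects (extra
hits rise).

Problem sizes used in the shipped tests: the recovery suite runs a
1,000 × 200 background with five latent aspects and three planted
9-function guilds at 10% abundance, 20 replicates at the matched K = 8
(5 background aspects + 3 guilds), and 8 replicates each at the under-fit
(K = 4, with 2% guilds) and over-fit (K = 16) regimes, using 300 EM
iterations and 2 restarts per fit. These sizes reproduce all three regimes
cleanly; larger replicate counts (the generator's 100-replicate default)
sharpen the curves without changing them qualitatively.

## Degenerate inputs and edge behavior

* All-zero rows/columns are retained with a warning — they still inform
  $\beta$ — never silently dropped.
* Continuous completeness fractions are refused by `read_matrix()` unless
  an explicit `binarize_threshold` is given; re-thresholding silently would
  change every downstream guild. Transposed input requires an explicit
  `transpose = TRUE`; orientation is never guessed.
* An empty function set maps back to every genome (vacuous conjunction);
  an unknown function ID is an error naming it.
* `K = 1` collapses to the per-column Bernoulli MLE ($\beta_{1f}$ = column
  mean); an all-ones matrix reaches log-likelihood 0.

## Known limitations

* K must be supplied; the sweep narrows the range, but the final choice on
  real data needs inspection of the resulting guilds. Information-criterion
  selection is out of scope.
* EM finds local optima; pathological starts are mitigated, not eliminated,
  by restarts.
* Scores compare within an aspect; comparing raw $s$ values across datasets
  is not meaningful.
* The confidence summaries carry no significance testing; they are
  descriptive.
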