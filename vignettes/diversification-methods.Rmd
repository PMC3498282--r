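---
title: "Diversification-rate analysis on dated phylogenies: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversification-rate analysis on dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdltest)
```

## The problem

Given a dated, ultrametric phylogeny of extant species, how did the tempo of
lineage accumulation change through time?  `bdltest` implements the classic
birth--death likelihood (BDL) answer to that question: extract the branching
times of the reconstructed tree, fit a panel of five diversification models
by maximum likelihood, compare them by AIC, and calibrate the resulting
rate-constancy statistic against a simulated pure-birth null.  The package
grew out of the analysis style used for small freshwater clades -- a dwarf
crayfish subfamily with a Mexican highland clade and a Gulf coastal clade is
the running example in `analysis/` -- but nothing in the machinery is
taxon-specific.

All ages in the package are measured **backward from the present** (tips at
age 0), in the time units of the branch lengths (Myr throughout the
examples).  The branching times $x_2 \ge x_3 \ge \dots \ge x_n$ -- the ages
at which the reconstructed tree first has $2, 3, \dots, n$ lineages -- are
the sufficient statistic for every model here, so all model code consumes a
`branching_times` object, never a tree.

## The five models

Let $d_i$ be the duration during which exactly $i$ lineages exist ($d_n$
runs from $x_n$ to the present), and $\lambda_i$ the per-lineage speciation
rate during that interval.  The shared pure-birth kernel is

$$\ln L = \sum_{i=2}^{n-1} \ln(i\,\lambda_i) \;-\; \sum_{i=2}^{n} i\,\lambda_i\,d_i ,$$

each interval contributing an exponential waiting-time log-density, the last
interval censored at the present.

| model | $\lambda_i$ | free parameters |
|---|---|---|
| pureBirth | $r_1$ | 1 |
| BD | constant birth--death, extinction fraction $a = \mu/\lambda$ | 2 |
| DDL | $r_1\,(1 - i/k)$ | 2 |
| DDX | $r_1\, i^{-x}$ | 2 |
| yule2rate | $r_1$ for ages $> s_t$, $r_2$ after | 3 |

The constant-rate birth--death model uses the reconstructed-process
likelihood in the $(r, a)$ parameterisation

$$\ln L(r, a) = (n-2)\ln r + r \sum_{i=3}^{n} x_i + n \ln(1-a)
  - 2 \sum_{i=2}^{n} \ln\!\left(e^{r x_i} - a\right),$$

which at $a = 0$ reduces algebraically to the pure-birth likelihood up to
the orderings constant $\sum_{i=2}^{n-1} \ln i$.  We add that constant to
the BD expression so **all five models share one additive constant**;
absolute log-likelihoods may therefore differ from other implementations by
a constant, which cancels in every AIC difference.  This is why the
package's $\ln L$ values should only ever be compared within a run.

### Fitting

* **pureBirth** has the closed form $\hat\lambda = (n-2)/\sum_i i\,d_i$.
* **BD** is maximised by bounded quasi-Newton over $(\log r, a)$ from five
  deterministic starts spread over log-spaced $r$, with the $a = 0$ boundary
  evaluated explicitly (its profile optimum is exactly the pure-birth MLE).
  Boundary solutions are reported as such, with a note, because a fitted
  $a = 0$ with $\ln L$ identical to pure birth is a scientifically
  meaningful pattern, not an optimiser failure.
* **DDL** and **DDX** profile $r_1$ out in closed form, leaving smooth
  one-dimensional problems (in $u = 1/k$ and in $x \in [-5, 5]$) solved by a
  41-point grid scan plus golden-section refinement of the bracketing
  interval.  The DDL search admits $u = 0$, i.e. $k = \infty$: when the
  optimum sits there the fit is reported as *collapsed to pure birth*.  We
  prefer reporting $k = \infty$ over a huge finite cap because the supremum
  of the model family is exactly the pure-birth likelihood, which keeps the
  nesting identity $\ln L_\text{DDL} \ge \ln L_\text{pureBirth}$ exact; a
  finite cap (the published analyses print carrying capacities near $5
  \times 10^5$) undershoots it by a few parts in $10^6$.
  `loglik_ddl(r1, k, bt)` still evaluates any finite $k$ directly.
* **yule2rate**'s likelihood is piecewise in the shift time, so within each
  piece the optimum is attained at the closed-form segment MLEs
  $\hat r_1 = n_1/E_1$, $\hat r_2 = n_2/E_2$ (events and exposures on each
  side of the shift).  Candidate shifts are the internal branching times
  plus midpoints of adjacent branching intervals; candidates leaving no
  event on one side are skipped, ties break toward the older candidate.  An
  event falling exactly on the shift belongs to the older regime.

Zero-duration intervals (tied node ages) contribute nothing to exposure
sums while their event terms are retained, so polytomy-free trees with
simultaneous nodes are handled without special cases.

### AIC conventions

Two conventions are computed side by side.  `standard` is
$-2\ln L + 2k$.  `table5` is $-(2\ln L + 2k)$ -- the parameter penalty
enters with inverted sign -- because published model-comparison tables in
this analysis tradition print that quantity; reproducing their cells
requires it.  The two satisfy `aic_standard - aic_table5 = 4k` for every
fit, and the delta-AIC-versus-pureBirth column is available under either.
`standard` is the default everywhere; the compatibility convention has to
be requested explicitly and is recorded in all output metadata.

## The rate-constancy test

The statistic is $\Delta\mathrm{AIC}_{RC} = \mathrm{AIC}_{RC} -
\mathrm{AIC}_{RV}$: best constant-rate AIC (pureBirth, BD) minus best
variable-rate AIC (DDL, DDX, yule2rate), positive when a rate-variable
model approximates the data better.  Its null distribution is obtained by
simulating pure-birth trees conditioned on the observed tip count at the
observed pure-birth rate estimate (9000 replicates by default; the desk
analyses in `analysis/` use 1000), refitting all five models to each, and
recomputing the statistic.  The p-value is the one-sided upper tail with
the add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(R+1)$, so
it is never exactly zero at finite replicates.

Two design points deserve note.  The statistic is invariant to time
rescaling (all AICs shift equally), so the null conditions on tip count
only -- simulated crown ages vary -- and the p-value is exactly invariant
to rescaling the input tree.  Replicates whose fits fail are resampled and
counted; more than 1% failures aborts the run rather than silently
imputing.

At full spec'd scale (200 pure-birth datasets, 200-replicate nulls,
$n = 20$, $\lambda = 0.15$) the acceptance suite finds the p-values
uniform (Kolmogorov--Smirnov $p = 0.39$ at the frozen seed) with empirical
size 0.050 at nominal 0.05.

## Synthetic data: what it emulates, what it does not

The generators exist so every stage is testable without external data.

* `simulate_yule()` draws the inter-node durations $d_i \sim
  \mathrm{Exp}(i\lambda)$ directly -- the exact generative counterpart of
  the likelihood -- and assembles a topology by uniform splitting.
  Conditioning on $n$ appends a censored $\mathrm{Exp}(n\lambda)$ final
  interval.  One useful exact consequence: $\sum_i i\,d_i \sim
  \Gamma(n-1, \lambda)$, so $E[\hat\lambda] = \lambda$ exactly, which the
  tests exploit.  Another: for $n = 3$ the age ratio $x_3/x_2$ has CDF
  $3r/(2+r)$ (not uniform -- the censored final interval weights the
  younger age), and the test suite checks the simulator against that
  analytic law.
* `simulate_birth_death()` runs the process forward with extinction and
  prunes extinct lineages.  Conditioning on $n$ survivors uses simple
  rejection, stopping at the first up-crossing of $n$; this is adequate at
  desk scale but mildly biased for parameter regimes where the extant
  count re-crosses $n$ often (high $\mu/\lambda$) -- a documented caveat,
  not corrected.
* `simulate_rate_shift()` needs a fixed observation window: a shift "at
  age $s_t$" is only well defined relative to the present, so the crown
  age is a required argument and the tip count is met by rejection over
  that window.  The recovery scenario used in testing (rate drop
  $0.5 \to 0.05$ at age 10 of a 15-Myr crown, $n = 20$) was chosen so the
  conditioned tip count is consistent with the unconditioned expectation
  (about 40); conditioning much below the expected count distorts the very
  shift signal being tested.
* `simulate_alignment()` delegates to `phangorn::simSeq()` under HKY, with
  among-site rate variation approximated by the standard discrete
  four-category gamma.

What passing tests on these generators do **not** show: real dated trees
carry dating error and topological uncertainty, real alignments have
indels, missing data and non-stationary composition, and real clades
violate the homogeneous-rates assumption in richer ways than any of the
five models.  The package analyses a given dated tree; it does not
propagate uncertainty from the dating step.

## Distances and the clock test

Pairwise distances come in the matched pair the published tables use:
uncorrected $p$ below the diagonal, HKY85 maximum-likelihood distance
above.  The HKY distance maximises the pairwise likelihood over distance
and transition/transversion parameter jointly, with per-pair empirical
base frequencies; a per-pair gamma shape is not identifiable, so no
$+\Gamma$ correction is applied unless a shape is fixed explicitly
(`gamma_alpha`).  Transition probabilities are computed by
eigendecomposition of the scaled rate matrix rather than a hand-derived
closed form -- slower, but one fewer place for algebra to go wrong, and
the equal-frequency $\kappa = 1$ limit is verified against the
Jukes--Cantor closed form to $10^{-6}$ in the tests.  Saturated pairs
(optimum at the search bound) are returned as `NA` flagged `saturated`,
never as a fabricated large number.  Sites with a gap or ambiguity code in
either sequence are excluded pairwise, matching mixed-coverage matrices;
group means average unordered pairs, and singleton groups get `NA` within-
means rather than zeros.

The molecular-clock LRT consumes externally computed tree log-likelihoods
(clock-enforced versus free); the package does not refit tree likelihoods.
The degrees of freedom depend on the tree and model and must be supplied
-- no default is assumed.  The worked example in
`analysis/05_distances_clock.R` uses scores of $-13893$ and $-13767$,
giving $\chi^2 = 252$.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance: $10^{-6}$ relative to crown age, rejecting
  (with the max deviation cited) rather than averaging -- dated trees
  should be exactly ultrametric, so deviation signals user error.
* Polytomies are rejected explicitly; silent resolution would change the
  branching times.
* $\ln(e^{rx} - a)$ is computed as $rx + \log(1 - a e^{-rx})$ to avoid
  overflow at large $r x$.
* Optimiser failures raise errors carrying the best-so-far state; no
  silent best-effort values.
* The Newick writer emits 10 significant digits; round-tripping a tree
  through write/parse preserves branching times to about $10^{-9}$
  relative (path sums accumulate a few units of the per-branch rounding).
* Nesting is asserted after every five-model fit: a variable-rate optimum
  below the pure-birth log-likelihood (beyond $10^{-6}$) aborts with an
  optimiser-failure error instead of returning a wrong table.

## Problem sizes used in the shipped analyses

The `analysis/` scripts simulate a 26-tip, two-clade subfamily (14-tip
clade with an 11.1-Myr crown at rate 0.174; 12-tip clade with a 16.7-Myr
crown at rate 0.106; root at 21.9 Myr), a 501-bp HKY$+\Gamma$ 16S-like
alignment ($\kappa = 4$, shape 0.232, 0.5% substitutions per site per
Myr), and 1000-replicate nulls.  These sizes keep a complete desk rerun in
the low minutes while leaving every statistical property testable; a full
analysis would raise `n_reps` to the 9000 default.

## Known limitations

No incomplete-sampling corrections, no more-than-two-rate shift models, no
time-continuous density dependence, no fossilised birth--death -- the model
panel is deliberately the classic five.  The null simulation conditions on
tip count, not on crown age; for statistics that are not scale-invariant
that choice would matter, but $\Delta\mathrm{AIC}_{RC}$ is scale-invariant.
Clade membership is always explicit input: the Gulf/Mexican style split is
a biological decision, and the pipeline refuses to guess it from topology.
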