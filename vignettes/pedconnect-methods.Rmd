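---
title: "Pedigree-based diversity and connectedness: models and methods"
author: "pedconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based diversity and connectedness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedconnect)
```

# Scope

`pedconnect` supports two recurring questions in small, selected
livestock populations such as regional dairy sheep breeds:

1. **How fast is genetic variability being lost?** Answered through
   pedigree quality control, inbreeding and kinship coefficients, and
   the effective population size estimated from the mean rate of
   increase in coancestry, tracked over sliding birth-year windows.
2. **Can estimated breeding values be compared fairly across flocks?**
   Answered through four mixed-model connectedness statistics between
   management units.

Everything operates on a plain pedigree table (animal, sire, dam, sex,
birth year, flock), optionally joined with a records table assigning
phenotyped animals to management units.

# The pedigree data model

`pedigree()` (and `read_pedigree()` for delimited files) normalizes a
raw table into a canonical object: unknown values become `NA`, parents
referenced without a row of their own become founder placeholders (sex
inferred from the role, everything else unknown), and records are
placed in topological order so that every parent precedes its
offspring. All downstream recursions are single passes over that
ordering.

Two policies are worth making explicit:

* **Unknown parents are unrelated, non-inbred founders.** No
  unknown-parent groups are fitted. The mitigation for missing ancestry
  is instead *explicit gating*: reference populations can require
  minimum PCI, NEG, or NFG, which is where incomplete pedigrees
  actually bias rate estimates.
* **Birth-year inconsistencies are warnings, not errors.** Historic
  pedigrees contain year gaps; birth-year windows simply never include
  animals with unknown year. Structural impossibilities (cycles,
  selfing, an id used as both sire and dam, sex-inconsistent parents)
  are errors, and a pedigree with errors is rejected by the pipeline.

# Pedigree quality metrics

For ancestral generation $g$ an animal has $2^g$ ancestor slots; the
per-generation completeness $a_g$ is the fraction of those slots filled
by a known animal (an ancestor reached through several lines counts
once per slot — the metric measures information, not distinctness).

* **NEG** (equivalent complete generations):
  $\mathrm{NEG} = \sum_{g \ge 1} a_g = \sum_{\text{known slots}} (1/2)^g$,
  i.e. 1/2 per known parent, 1/4 per known grandparent, with no depth
  cap (the recursion
  $\mathrm{NEG}_i = \sum_{p \in \{s,d\}} \tfrac12 (1 + \mathrm{NEG}_p)$
  over known parents is exact).
* **NFG** — the largest $g$ with *every* slot known up to generation
  $g$; **NMG** — the longest known ancestral path.
* **PCI** — the harmonic mean $2 C_f C_m / (C_f + C_m)$ of the
  paternal- and maternal-side completeness, each
  $C = \frac1d \sum_{g=1}^{d} a_g$ computed over the side's own slots
  (the parent itself is generation 1 of its side). The harmonic mean
  weights the weaker side, so PCI is exactly 0 whenever a parent is
  unknown.

**Depth $d$ for PCI** is a genuine free parameter of this index family;
we default to $d = 5$ generations and expose it everywhere
(`pci_depth`). Five generations is deep enough that a fully recorded
modern cohort scores near 1 while animals above the recording horizon
are clearly penalized; sensitivity can be probed directly by changing
the argument rather than being hidden in the implementation.

# Relatedness

Kinship (coancestry) $C_{ij}$ is computed by the exact tabular
recursion on the numerator relationship matrix $A = 2C$, restricted to
the ancestor closure of the animals requested — exact, with memory
bounded by the closure size. Inbreeding uses the Meuwissen–Luo
algorithm (compiled), and the identity $F_i = C_{\text{sire}_i,
\text{dam}_i}$ is asserted pedigree-wide in the test suite. The sparse
$A^{-1}$ needed by the mixed-model equations is assembled directly from
the pedigree by the Henderson/Quaas rules with Mendelian-sampling
variances adjusted for parental inbreeding; the tests verify
$A A^{-1} = I$ to $10^{-8}$ against dense inversion.

The generation interval is the mean mid-parent age over offspring with
both parental birth years known (a pathway-based mean over the four
parent–offspring sex paths is reported alongside, since the two
conventions differ in unbalanced data).

# Effective population size from the coancestry rate

For a pair $(i, j)$ with kinship $C_{ij}$ and equivalent complete
generations $g_i, g_j$, the per-generation rate of increase in
coancestry is

$$\Delta C_{ij} = 1 - \left(1 - C_{ij}\right)^{\frac{2}{g_i + g_j}},$$

the geometric annualization of the accumulated coancestry over the mean
traced depth $(g_i + g_j)/2$. Averaging over all unordered distinct
pairs of a reference population gives
$N_e = 1 / (2 \overline{\Delta C})$.

Choices embedded here:

* $g$ is always NEG, even when the reference population is gated on
  NFG — the rate's denominator is the *traced depth*, which NEG
  measures, while NFG is a gate on reliability.
* Pairs are unordered and distinct; self-pairs are excluded. Members
  with $\mathrm{NEG} = 0$ carry no depth and are excluded from the pair
  set, while the reported mean $F$ averages all members of the window.
* If $\overline{\Delta C} = 0$ (all members unrelated) the estimate is
  reported as `Inf` rather than an error: disconnected founders carry
  no drift signal.

**Sliding windows and trends.** `sliding_windows()` produces birth-year
windows of a fixed span (default 4 years, one generation interval)
advanced by a step, labelled with a 1-based generation number.
`trend()` regresses a per-window quantity (window $N_e$, window mean
$F$) on that number by ordinary least squares, so the slope is a
per-generation rate; the regressor is the window index, not the
calendar year, which keeps slopes comparable across window layouts. A
numerical note: when the fit is exact or the series constant, the OLS
standard error is pure floating-point noise, so slope and SE below a
$10^{-10}$ relative tolerance are snapped to zero (then $p = 1$ for a
zero slope, $p = 0$ for an exact nonzero line).

# Connectedness between management units

The model is a single-trait animal model $y = Xb + Zu + e$ with one
fixed-effect level per unit (no separate intercept), a random effect
for *every* pedigree animal, and variance ratio
$\lambda = \sigma_e^2 / \sigma_u^2 = (1 - h^2)/h^2$. Henderson's
coefficient matrix

$$M = \begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda A^{-1}
\end{bmatrix}$$

is nonsingular under this parameterization (no intercept–unit
confounding), so the animal block $C^{22}$ of $M^{-1}$ is obtained by a
sparse Cholesky factorization solved only for the columns of the
recorded animals. PEV$(\hat u_i) = C^{22}_{ii}\sigma_e^2$ and
PEC$(\hat u_i,\hat u_j) = C^{22}_{ij}\sigma_e^2$. A test verifies that
the animal block is invariant to re-parameterizing with an intercept
plus a zero constraint on the first unit level.

Unit-level statistics, for units $i'$, $j'$ with $n_{i'}$, $n_{j'}$
recorded animals:

* **PEVD_ind** — mean over all cross-unit animal pairs of
  $\mathrm{PEV}_i + \mathrm{PEV}_j - 2\,\mathrm{PEC}_{ij}$.
* **PEVD_group** — prediction error variance of the *difference of
  unit-mean* EBVs: full-block means (within-unit covariances included)
  combined as $\overline{\mathrm{PEV}}_{i'i'} +
  \overline{\mathrm{PEV}}_{j'j'} - 2\overline{\mathrm{PEC}}_{i'j'}$,
  equivalently the quadratic form $w' C^{22} w\,\sigma_e^2$ with
  contrast weights $\pm 1/n$. The minus sign on the covariance term is
  required for the statistic to be a variance (identical units give
  exactly 0); a plus sign would violate nonnegativity.
* **CD** — the coefficient of determination of unit EBV differences:
  $1 - \sum \mathrm{PEVD}_{ij} / (\sigma_u^2 \sum (K_{ii} + K_{jj} -
  2K_{ij}))$ with $K = A$ entries over the same pair set; identically,
  the ratio-of-sums aggregation of the pairwise
  $CD_{ij} = 1 - \lambda (C^{22}_{ii} + C^{22}_{jj} - 2C^{22}_{ij}) /
  (K_{ii} + K_{jj} - 2K_{ij})$ (asserted to $10^{-10}$ in the tests).
* **r** — the flock-level prediction error correlation
  $\sum \mathrm{PEC}_{i'j'} / \sqrt{\sum \mathrm{PEV}_{i'i'} \sum
  \mathrm{PEV}_{j'j'}}$, with full-block sums so that a unit has
  correlation 1 with itself. Benchmarks: $\bar r \ge 0.05$ "good",
  $\ge 0.10$ "superior", otherwise insufficient for unbiased
  across-unit comparison.

Aggregation always runs over *recorded* animals per unit (the pedigree
still informs $A^{-1}$ in full, so unrecorded relatives contribute
their links); unit-level and overall summaries exclude the self-pair
diagonal. PEVD values are reported in units of $\sigma_e^2$: the
statistic has no intrinsic $[0, 1]$ bound, and any such appearance in
practice reflects a particular variance parameterization. Since
connectedness here characterizes the *design*, not a fitted model, the
variance parameters default to $h^2 = 0.3$ (typical for dairy traits)
and $\sigma_e^2 = 1$, both configurable and echoed in outputs. Repeated
records per animal are accepted as repeated incidence rows; no
permanent-environment effect is fitted — connectedness patterns depend
on the design and relationship structure, and that simplification is
deliberate and documented.

# The simulators

Two seeded generators provide known-truth inputs for every stage.

**`simulate_flock_population()`** emulates a multi-flock,
performance-recorded sheep population with overlapping generations.
Defaults (14 flocks × 30 ewes + 2 rams, 12 years, lambing rate 0.7)
are desk-scale: a few thousand animals in under a second. Mechanisms:

* **Ram exchange**: each mating's sire is drawn from a uniformly chosen
  other flock with probability `migration_rate` — the simplest
  mechanism mapping onto exchange of breeding animals, and the lever
  the connectedness statistics respond to. With `migration_rate = 0`
  flocks are disjoint pedigree components and cross-flock PEC and r are
  exactly zero.
* **Turnover**: breeders are culled at `replacement_rate` per year and
  replaced by the youngest eligible local youngstock, recruited as
  yearlings (first service at age 2). The default rate is derived from
  the target mean parent age of 3.8 years via the geometric service-age
  distribution, and the realized generation interval of the default
  configuration comes out near that target (the acceptance script
  recomputes it).
* **Historic incompleteness**: parent links are deleted with a per-year
  probability decaying linearly from 0.5 to 0 over the first 60% of the
  horizon, reproducing the characteristic pattern of completeness
  decaying with ancestral generation in older cohorts and of strong
  PCI–NEG correlation (> 0.9 on the default scenario).

What it does *not* emulate: selection (matings are random within
roster), phenotypes and genetic trend, seasonal structure, multi-breed
ancestry, or recording errors. Passing tests on these pedigrees
therefore validate the estimators' algebra and their response to
migration and missing-data structure — not robustness to selection
bias, which pedigree-based $N_e$ estimators are known to share.

**`simulate_idealized()`** is the ground-truth scenario for $N_e$:
constant census $N$, discrete generations, each offspring drawing its
sire uniformly from the previous generation's males and its dam from
its females. Its pedigree-derived $N_e$ is approximately $N$ at equal
sex ratio, and the coancestry-rate estimator recovers it within the
tested 0.8–1.25 band at $N \in \{20, 50, 100\}$.

One boundary effect matters when comparing with the textbook curve
$F_t = 1 - (1 - 1/2N)^t$: that closed form counts generations of
accumulated coancestry. Because the generator is dioecious (no
selfing) and founders are unrelated, the cohort born in generation $t$
is produced by parents whose coancestry accumulated over $t - 1$
completed rounds of random mating — generation 1 has $F = 0$ exactly.
The trajectory checks therefore evaluate the closed form at the number
of completed coancestry-accumulating generations; ignoring the lag
shifts the predicted curve by about $1/2N$ everywhere.

# Numerical choices and degenerate inputs

* Kinship subsets use the tabular method on the ancestor closure —
  exact; memory scales with the closure, not the full pedigree.
* The MME solve uses one sparse Cholesky factorization and solves only
  the recorded animals' columns; an oracle test matches a full dense
  inverse to $10^{-8}$ on systems up to ~200 equations.
* Degenerate cases are explicit: units of clones make the CD
  denominator vanish (error); single-animal units get `NA` on the CD
  diagonal; an empty reference population or an all-unrelated one gives
  an error and `Inf` respectively; cyclic pedigrees are carried through
  validation (which names the cycle) and refused by every algorithm.
* Ties in the simulator's youngest-first recruitment are broken by
  stable ordering, keeping a fixed seed byte-reproducible.

# Problem sizes

The test suite runs on pedigrees of tens to hundreds of animals
(oracle comparisons are exponential or dense, so they stay small by
design) and completes in well under a minute; the acceptance script
uses the default 14-flock simulator (~3000 animals) and idealized
populations up to $N = 100$ over 10 generations, a few seconds per
scenario. All statistics scale to pedigrees of a few tens of thousands
of animals on a laptop, the regime the estimators are designed for.

# Known limitations

* No unknown-parent groups or metafounders; severely incomplete
  pedigrees must be handled by gating, not modelling.
* The coancestry-rate $N_e$ inherits the usual sensitivity to pedigree
  depth: with shallow ancestry it overestimates $N_e$ (recent
  inbreeding is invisible), which is precisely why the gating
  constraints exist.
* Connectedness is pedigree-based only; genomic (marker-based)
  relationship variants are out of scope.
* The CD diagonal and any statistic on single-animal units are of
  limited meaning and are excluded from summaries.
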