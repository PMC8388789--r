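# pedconnect

Pedigree-based monitoring of genetic diversity and across-flock genetic
evaluation design for small livestock populations.

Breeding programs in small, selected populations — regional dairy sheep
breeds are the canonical case — face two coupled risks. First, the
overuse of a few superior (and mutually related) sires erodes genetic
variability: the quantity to watch is the effective population size
N<sub>e</sub> and its trend. Second, when flocks rarely exchange
breeding animals, genetic and flock effects cannot be disentangled, and
BLUP breeding values of animals in different flocks cannot be compared
fairly: the quantity to watch is the genetic *connectedness* between
management units. `pedconnect` computes both families of diagnostics
from a plain pedigree table, for geneticists running or auditing a
selection program.

## What it computes

**Pedigree quality** (to gate which animals are informative enough to
enter rate estimation):

- per-generation completeness a<sub>g</sub> (known ancestor slots /
  2<sup>g</sup>),
- PCI, the harmonic mean 2C<sub>f</sub>C<sub>m</sub> / (C<sub>f</sub> +
  C<sub>m</sub>) of sire- and dam-side completeness (0 whenever a
  parent is unknown),
- NEG = Σ (1/2)<sup>g</sup> over known ancestor slots (equivalent
  complete generations), NFG (fully traced generations), NMG (longest
  traced path).

**Relatedness**: inbreeding F (Meuwissen–Luo), kinship matrices
C<sub>ij</sub> (exact tabular recursion, C<sub>ii</sub> = ½(1 + F)),
the sparse A<sup>-1</sup> (Henderson/Quaas rules with inbreeding), and
the generation interval from mid-parent ages.

**Effective population size** from the mean rate of increase in
coancestry,

&nbsp;&nbsp;&nbsp;&nbsp;ΔC<sub>ij</sub> = 1 − (1 −
C<sub>ij</sub>)<sup>2/(g<sub>i</sub>+g<sub>j</sub>)</sup>,&nbsp;&nbsp;
N<sub>e</sub> = 1 / (2 ΔC̄),

over sliding birth-year windows, with ΔN<sub>e</sub> and ΔF estimated
by regressing the per-window values on the window generation number.

**Connectedness** between management units from an animal-model BLUP
system (one fixed-effect level per unit, λ = (1 − h²)/h²): the
prediction-error variance/covariance block of the inverted mixed-model
equations yields four statistics per unit pair — PEVD_ind (mean
pairwise PEV difference), PEVD_group (PEV of the unit-mean difference),
CD (the PEVD rescaled by the relationship contrast) and r (prediction
error correlation, with the 0.05 "good" / 0.10 "superior" benchmarks).

**Simulators** with known truth: a multi-flock overlapping-generation
sheep population with tunable ram migration and historic
missing-parent rates, and an idealized constant-size random-mating
population whose pedigree N<sub>e</sub> is its census size.

## Worked example

```r
library(pedconnect)

sim <- simulate_flock_population(sim_flock_config(seed = 42))
ped <- sim$pedigree
ped
#> <pedigree> 2841 animals (602 founders, 14 flocks)

quality_summary(ped)
#>   metric min       max median      mean
#> 1    NEG   0 3.8750000   1.25 1.3033538
#> 2    NFG   0 3.0000000   1.00 0.7895107
#> 3    NMG   0 6.0000000   2.00 2.0165435
#> 4    PCI   0 0.7504065   0.24 0.2276073

round(generation_interval(ped)$gi, 2)
#> [1] 3.88

nw <- ne_windows(ped, from = 5, to = 12, window_len = 4, min_neg = 2)
nw$table
#>   generation label    ne  nt ratio mean_f
#> 1          1   5-8  90.1 203 0.444 0.0729
#> 2          2   6-9 101.2 342 0.296 0.0733
#> 3          3  7-10 107.8 468 0.230 0.0786
#> 4          4  8-11 111.4 595 0.187 0.0778
#> 5          5  9-12 112.2 676 0.166 0.0842
nw$trend_ne
#> <trend> slope = 5.428 +/- 1.16 (p = 0.0184, n = 5)

connectedness(ped, sim$design, h2 = 0.3)
#> <connectedness> 14 units, h2 = 0.3
#>   overall: PEVD_ind = 0.5477, PEVD_group = 0.05144, CD = 0.3788,
#>   r = 0.01974 (insufficient)
```

Reading the output: each window row is a 4-year birth cohort treated as
one generation; `ne` is 1/(2ΔC̄) over all member pairs passing the
NEG ≥ 2 gate, `ratio` is N<sub>e</sub>/N<sub>t</sub> against the census
of the window, and the positive N<sub>e</sub> slope here simply
reflects this synthetic population's growing, increasingly
well-recorded cohorts. The overall prediction error correlation r̄ ≈
0.02 sits below the 0.05 benchmark: with the default 10% ram-migration
rate these 14 flocks are still too weakly linked for unbiased
across-flock ranking, which is exactly the situation the statistic is
designed to flag.

The full pipeline (quality tables, F distribution, windowed
N<sub>e</sub> with trends, connectedness matrices, JSON manifest) runs
as one call:

```r
run_full_pipeline(run_config(pedigree = ped, records = sim$design,
                             out_dir = "out", from = 5, to = 12,
                             min_neg = 2))
```

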