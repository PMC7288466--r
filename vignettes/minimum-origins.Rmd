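---
title: "Cell-cycle phase durations and minimum replication origins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle phase durations and minimum replication origins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orimin)
```

# The problem

Single-celled eukaryotes replicate their nuclear genomes from multiple
replication origins.  How many origins a chromosome *needs* — as opposed to
how many it *uses* — depends on only three quantities: the chromosome
length, the S-phase duration, and the mean speed of replication forks.
`orimin` implements the two halves of that calculation:

1. estimating the S phase (and the other cell-cycle phases) of an
   asynchronous exponentially growing population from microscopy
   observables, and
2. converting phase and fork-rate parameters into a per-chromosome lower
   bound on origin number, with replication-stress scenarios and
   comparisons against origin counts mapped by experimental methods.

# The phase-duration estimator

## The age structure of exponential growth

In an asynchronous population growing exponentially with doubling time $T$
hours, the specific growth rate is $\alpha = \ln 2 / T$ and the density of
cell ages $a \in [0, T]$ is $f(a) = 2\alpha e^{-\alpha a}$: newborn cells
are exactly twice as frequent as cells about to divide.  Integrating this
density gives the cumulative-time relation (Williams 1971) used throughout:

$$x = \frac{-\ln(1 - y/2)}{\alpha},$$

where $y$ is the cumulative proportion of cells up to a cycle position and
$x$ the time into the cycle needed to reach it.  The printed layout of this
equation in older sources collapses the fraction bar; the two limit
identities pin the intended reading: $y = 0 \Rightarrow x = 0$ and
$y = 1 \Rightarrow x = T$ (both asserted to $10^{-12}$ relative in the test
suite).

## The estimation pipeline

`estimate_phases()` runs five stages in a fixed order, each consuming the
previous results:

* **Cytokinesis** closes the cycle, so with a fraction $f_C$ of cells in
  cytokinesis, $C = T - x(1 - f_C)$.
* **Mitosis** comes from the combined window: $M = (T - x(1 - f_{MC})) - C$,
  where $f_{MC}$ is the fraction in mitosis *or* cytokinesis.
* **G2**: cells pulse-labeled with EdU in S need $G2 + M$ hours before the
  first cell with two labeled nuclei appears.  The package subtracts only
  $M$ from that chase time, taking the two-nuclei morphology to mark entry
  into cytokinesis rather than its completion; whether cells already in
  cytokinesis should also be excluded is ambiguous in the source
  literature, and the package implements the $G2 = t_{2N} - M$ reading
  verbatim.
* **S** uses the Stanners–Till (1960) relation for the EdU-labeled fraction
  $L$ after a pulse of $t$ hours:
  $$S = \frac{1}{\alpha}\ln\!\left(L + e^{\alpha Z}\right) - (Z + t),
  \qquad Z = G2 + M + C.$$
* **G1** is the remainder, $G1 = T - S - Z$.

Durations are reported in hours and in *cell-cycle units* (ccu), a phase's
fraction of one doubling time; a ccu breakdown always sums to 1.

## Error policy

Degenerate or contradictory observations are rejected with classed errors,
never clamped: a negative computed duration names the two observations
that conflict (e.g. an M+C window shorter than C alone), $f = 1$ fractions
are refused as degenerate, and a labeled fraction too small to support a
positive S phase raises a labeling error.  Silent clamping would hide
miscounted microscopy data, which is precisely the situation the errors
are meant to surface.  Hours are the canonical internal unit; the CLI
converts minutes and percentages at the interface only.  Displayed values
are rounded to 2 decimals (hours) and 3 decimals (ccu); full precision is
kept internally.

# The population simulator

`simulate_snapshot()` is the estimator's independent oracle: it draws
`n_cells` ages by inverse-CDF sampling from the exponential age
distribution ($a = -\ln(1 - u/2)/\alpha$), classifies them on the
half-open cumulative boundaries $[0, G1, G1{+}S, \dots, T)$, and emits the
empirical observables.

**Labeling window.**  The pulse is anchored at its start: a cell drawn
with age $a$ is labeled iff $a \in (G1 - t,\; G1 + S]$, i.e. iff its age
*at pulse end* lies in $(G1, G1 + S + t]$.  With this convention the
expected labeled fraction is exactly the Stanners–Till closed form
$e^{\alpha(S+Z+t)} - e^{\alpha Z}$, so estimator round-trips are sharp:
any discrepancy beyond Monte-Carlo noise is a bug, not a modelling gap.
The convention is only self-consistent when no labeled cell divides during
the pulse and no newborn inherits label from its mother, which requires
$t \le Z$ *and* $t \le G1$; the simulator rejects configurations outside
that envelope (as well as $S = 0$) rather than producing data its own
closed form cannot describe.  The two-nuclei chase time is emitted
noiselessly as exactly $G2 + M$, mirroring its treatment as a directly
measured scalar.

The simulator deliberately omits features of real data: phase durations do
not vary between cells, there is no cell death or quiescence, and EdU
detection is perfect by default (a `detection_prob < 1` option exists for
sensitivity checks).  Passing round-trip tests therefore demonstrates the
*estimator's* correctness under the model's own assumptions, not
robustness to biological heterogeneity.

**Round-trip study conditions.**  The acceptance suite crosses three
doubling times (8.5, 10.5 and 24 h, the range spanned by the bundled
organisms) with three $(G1, S, Z)$ splits echoing their measured
breakdowns, at $n = 10^5$ cells and a 0.25 h pulse; each recovered phase
must fall within 3 Monte-Carlo standard errors (estimated from 12
replicate simulations) of the truth.  These sizes keep the whole suite in
seconds while leaving binomial noise small relative to the durations.

# Minimum number of origins

Each fired origin sends out two forks in opposite directions for the whole
S phase, so one origin can replicate at most $2 v S$ base pairs.  The
minimum number of origins for a chromosome of $N$ bp is

$$MO = \left\lceil \frac{N}{2 v S} \right\rceil,$$

with $v$ in bp/min and $S$ in minutes.  An exact integer quotient is *not*
bumped: the ceiling raises only true fractions.

## Exact arithmetic

Several bundled chromosomes sit within 0.5% of a ceiling boundary, where
binary floating point could flip the result.  `minimum_origins()`
therefore scales $v$ to an integer in units of $10^{-5}$ kb/min and $S$ to
integer deciminutes, carries stress factors as exact rationals, and
computes the ceiling with integer division; all intermediates stay far
below $2^{53}$, so the result is bit-exact.  A guarded floating-point path
(used only for stress factors with no small rational form) agrees with the
exact path everywhere off the boundary, which is regression-tested on the
most rounding-sensitive bundled case (*L. major* XIV under harsh stress,
quotient 1.9936: both paths give 2; the published 3 arises only if the
stressed rate is rounded to 0.81 kb/min before use, which the package
never does).

## Stress scenarios

Replication stress is, in general, a slowing of fork progression, so the
scenarios multiply the *rate only* and hold $S$ fixed (the robustness
assumption): mild stress uses $2v/3$, harsh stress $v/3$.  The ordering
$MO^{HR} \ge MO^{MR} \ge MO$ and the ceiling-algebra bound
$MO(v/2) \in [MO(v),\, 2\,MO(v)]$ are property-tested.

## Combing-derived counts

DNA combing measures the mean inter-origin distance (IOD) on stretched
fibers; the average number of origins fired per chromosome is
$O_c = \lceil N / IOD \rceil$ (`combing_origins()`), with the same
exact-arithmetic and no-bump conventions (IOD at 0.01 kb resolution).

## Bundled karyotypes and published-value errata

Five reference karyotypes ship as plain-text fixtures (41, 36, 11, 16 and
3 chromosomes; 107 in total) together with their fork rates and S-phase
durations.  The *S. cerevisiae* sizes were published in kb with decimal
commas ("230,19" = 230.19 kb); fixtures store base-pair integers.  Some
published size orderings are non-monotone (e.g. *T. cruzi* XX smaller than
XIX); fixtures preserve the printed order and values verbatim.

Re-evaluating the ceiling formula at the stated parameters reproduces 101
of the 107 published base-table cells and all but eight stress-table
cells.  The disagreements are carried as a documented erratum list and the
tests assert the formula's output, not the printed value:

* *T. cruzi* XXV and XXVII: printed 2, formula 1 (the stress table and the
  all-single-origin statement for this genome both agree with 1);
* *T. brucei* V, IX, XI: printed 2/4/6, formula 3/5/7 (the mild and harsh
  columns for the same chromosomes match the formula, suggesting the base
  column predates a parameter update);
* *S. cerevisiae* V: printed 7/10/19 across scenarios, formula 6/9/18 from
  the printed 574.86 kb — the real chromosome V is ≈576.87 kb, which
  yields exactly 7/10/19, so the printed *size* is most likely the typo;
* *T. cruzi* XXXIX–XLI harsh: printed 2, formula 3;
* *L. major* XIV harsh: printed 3, formula 2 (intermediate-rounding
  artefact, above);
* *S. cerevisiae* XIII harsh: printed 30, formula 29.

## ccu cross-checks

The published hour values and their ccu conversions are mutually
consistent once two conventions are recognised: the ccu were computed from
*unrounded* hours, and the $G2{+}M{+}C$ entry completes each breakdown to
1 (so it inherits the rounding of the other two).  The acceptance test
therefore compares recomputed ccu at half an ulp of the printed ccu plus
the uncertainty propagated from the printed-hour precision — a tolerance
fixed by the printed formats, not fitted to the data.  The identity
$G1 = T - S - Z$ holds exactly for all three trypanosomatid breakdowns.

# Method comparison

`fit_trend()` fits unweighted ordinary least squares with a free
intercept, $y = a x + b$, of origin counts against chromosome length — the
same annotation used on published comparison figures.  Whether such
figures used bp, kb or Mb on the x-axis is immaterial for the headline
statistic, because `fold_over_minimum()` (the ratio of a mapping method's
slope to the MO slope) is invariant under rescaling $x$; absolute slopes
and intercepts are not, and are reported in origins per bp.  When every
chromosome needs the same minimum (as for *T. cruzi*, where the MO line is
$y = 1$), the MO slope is exactly zero and the fold is reported as an
explicit infinite marker, serialised as the string `"inf"` — never a
floating-point overflow.  The published fold ratios (4.91, 5.1, 2.12,
1.44) depend on per-chromosome combing counts that live in cited
references rather than in text reproduced here, so they are documentation
examples; the machinery is validated by planting known slope ratios in
synthetic profiles and recovering them to $10^{-9}$.

`sufficiency_report()` flags chromosomes whose mapped count falls below
MO; one deficit renders a method insufficient on its own to explain
complete replication — the expected verdict for low-resolution methods
(MFA-seq, microarray) that see mostly constitutive origins.  Adding
origins can never flip a verdict from sufficient to insufficient
(property-tested).

# Numerical and design choices

* Chromosome-name matching is exact-string, with an explicit alias map for
  deliberate renames; silent "chr"-prefix normalisation corrupts
  cross-method joins.
* BED input is 0-based half-open; only the chromosome field matters for
  counting origin sites.
* Phase classification uses half-open `[lo, hi)` age intervals; an age of
  exactly $T$ maps to the final phase.
* kb→bp conversion is exactly 1000 throughout.
* Seeds are mandatory for simulation; identical configuration and seed
  give bit-identical snapshots, and the global RNG stream is left
  untouched.
* `fit_trend()` delegates the OLS solve to `stats::lm()`; the test oracle
  is an independent normal-equations closed form.

# Limitations

The MO is a deterministic lower bound, not a model of origin licensing,
firing-time stochasticity or replication-timing profiles.  The estimator
assumes steady-state exponential growth and perfect EdU detection; the
simulator shares those assumptions, so agreement between the two does not
validate them against real populations.  Origin counts from mapping
methods are taken as inputs; the package does not re-derive them from
sequencing or fiber data, and does not classify origins as flexible
versus dormant.
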