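---
title: "The sigma-chromosome model of heritable terminus DNA loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sigma-chromosome model of heritable terminus DNA loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmachrom)
```

## The phenomenon and the model

*Escherichia coli* mutants that cannot repair DNA double-strand breaks
(recB, recA, and combinations) lose DNA from the chromosome terminus, and
they lose it *heritably*: time-lapse microscopy of parS/ParB-tagged
terminus loci shows that ~18% of recB divisions produce one daughter
without the dif-proximal focus (an **initial event**), and in ~75% of
those cases the focus-retaining daughter does it again at the next
division, generation after generation (**transmitted events**).

The mechanistic picture simulated here: spontaneous breakage of one
replication fork leaves a **sigma-replicating chromosome** — an intact
circle covalently joined, through the surviving fork, to a linear tail.
The circle and tail segregate to opposite cell halves; FtsK pumps
KOPS-oriented DNA so the septum closes exactly on the tail's *dif* site
and breaks it. One daughter inherits a doomed, truncated linear
chromosome (the focus-less cell); the other keeps the circle plus a short
tail stub — a **carrier**. The next replication round regenerates a
full-length tail, so the carrier can repeat the loss. Exonucleolytic
resection from the septum-made ends removes terminus DNA around *dif*,
which is what marker frequency analysis (MFA) sees as a coverage dip
centred on *dif*.

Genotypes differ in three places only:

* whether the broken fork is repaired (`repair_prob` = 1 for
  rec-proficient cells, intermediate when only the RecFOR pathway
  remains);
* whether Exo V (RecBCD's exonuclease) degrades the whole tail before
  division and aborts the event (`rescue_prob`, nonzero only in recA
  single-type mutants where RecBCD is present but recombination is not);
* how far resection reaches (`degradation_scale_kb`, the mean of an
  exponential per-end extent: ~207 kb in recB, far larger in recA recD
  where the helicase opens DNA without the nuclease).

## State machine and parameters

Each generation, every viable cell divides once:

| state | with probability | outcome |
|---|---|---|
| intact, non-carrier | `p_sigma (1-repair_prob) (1-rescue_prob)` | INITIAL event: one `TRUNCATED_LINEAR` focus-less daughter + one carrier |
| carrier | `continuation_prob` | TRANSMITTED event: one `FULL_LINEAR_WITH_ENDS` daughter + one carrier |
| carrier | `1 - continuation_prob` | reverts to a normal division |
| focus-less, `div_rem > 0` | 1 | two focus-less daughters with `div_rem - 1` |

Parameters, units and defaults (recB):

* `p_sigma` = 0.218 per cell per generation — calibrated, see below; the
  corresponding wild-type inference is ~0.18 per cell, i.e. 0.09 per fork.
* `continuation_prob` = 0.745 per generation — transmission is a
  geometric chain, taken directly from the measured "% transmitted".
* `degradation_scale_kb` = 207 kb — fitted from the snapshot loss
  gradient (32% loss 10 kb from *dif* vs 7.9% at 300 kb):
  `scale = 290 / log(32/7.9)`.
* `dimer_rate` = 0.15 — background chromosome-dimer frequency, used only
  by the division-blocked (cephalexin) observable.
* Division-count distributions of newborn focus-less cells: degenerate at
  zero for hipAB-intact genotypes (see below); `(0.30, 0.60, 0.10)` /
  `(0, 0.87, 0.13)` over 0/1/2 divisions for the hipA-deleted variant.

Time is discretized to one replication-division cycle per generation;
within-cycle kinetics (tail regrowth, fork pausing at *ter*) are not
modelled because no rates for them are measured. The tus effect on
transmission is therefore represented only as the separately measured
`recA_tus` parameter set, not as a tail-length race.

## Calibration: from observed rates to engine rates

The observed initial-event fraction is *not* the sigma-formation
probability, because carrier divisions sit in the denominator of the
time-lapse statistic but cannot produce initial events. Writing `i_eff`
for the per-non-carrier-division event probability and `t` for
continuation, the dividing population reaches a steady state with

* per-division loss probability `q` solving
  `q^2 - q(2 + i_obs - t) + 2 i_obs = 0`,
* carrier fraction `c = q/(2-q)`,
* viable growth factor `lambda = 2 - q`,
* `i_obs = i_eff (1 - c)`.

`default_params()` inverts these identities so that a simulation
reproduces the measured `i_obs` exactly (for recB, `i_eff = 0.218`;
reassuringly, the same calibration applied to the recA single mutant
against the Exo V-null baseline 0.21 yields `rescue_prob = 0.65`,
matching the observed three-fold reduction of initial events). The
initial-event denominator includes transmitted divisions, following the
schematic worked example for the time-lapse statistic (2 initial events
out of 9 generations with one heritable chain → 2/9).

The snapshot prediction follows from cohort accounting: focus-less cells
are born at rate `q` per division and their cohorts dilute by `lambda`
per generation while a lineage allowed `k` divisions doubles `k` times.
This gives the closed form implemented by `steady_state_fraction()`:

`fraction = loss_prob * q * mu / (1 - q + q * mu)`,

with `mu` the division-distribution-weighted lineage weight (`mu = 1`
for non-dividing focus-less cells, in which case the fraction is exactly
`q`, the fixed point of the recursion `d' = (d+q)/(2-q)`), and
`loss_prob = exp(-d/scale)` the probability that resection actually
crossed the scored locus at distance `d` from the cleavage point.

For recB this predicts `q = 0.318` and a dif-proximal focus-less
fraction of `0.953 x 0.318 = 30.3%` against the measured `32 +/- 1.5%`;
for recA, `8.7%` against `9 +/- 2.8%`. The test suite verifies that
direct simulation agrees with the closed form to better than 1.5%
absolute across a 5 x 5 grid of `(i, t)` values.

## Do focus-less cells divide?

A design fork with a visible quantitative consequence. The measured
0/1/2-division distributions of first and second focus-less cells were
obtained in a *hipA hipB deleted* background — deliberately, because the
hipAB toxin-antitoxin operon sits next to *dif*, its antitoxin is
degraded together with the dif-proximal DNA, and the long-lived HipA
toxin then blocks division of every dif-proximal focus-less cell in
hipAB-intact strains (in time-lapse movies of the standard strains,
focus-less cells essentially never divide). We therefore:

* give hipAB-intact genotypes (everything except `recB_hipA`) a
  degenerate division distribution at zero — the world in which the
  snapshot table was measured;
* attach the measured distributions to `recB_hipA`, and to
  linear-chromosome daughters that retain the hipAB end, where focus-less
  proliferation genuinely occurs.

Had we let focus-less cells divide per the measured distribution in the
hipAB-intact world, the closed form gives a snapshot fraction of ~43-48%
(`mu ~ 2`), far outside the measured 32 +/- 1.5 — which is the internal
evidence that the distributions belong to the deleted background only.

## Linear chromosomes

With the chromosome linearized 3 kb from *dif* by the phage N15 tos/TelN
system, fork breakage produces a head-to-head linear dimer that TelN
resolves at *tos*: one intact chromosome, one truncated chromosome
lacking everything between the random break site and the *tos* end on the
broken side (plus slow resection at the broken end; the *tos* hairpin end
is protected). No sigma-chromosome can form, so the surviving daughter is
never a carrier: the simulated "transmission" statistic collapses to the
independence baseline (the initial rate itself), reproducing the observed
circular-vs-linear contrast. Daughters losing the hipAB-containing (ydeV)
end are inert; daughters losing the other (yddW) end can divide.

Known limitation: the very high steady-state yddW/pspE focus-less
fractions measured on linear chromosomes (~56-60%) imply focus-less
lineages proliferating for more than the two divisions the measured
distribution allows; the package reproduces the qualitative asymmetry and
the transmission collapse, not those magnitudes.

## Observables

* `snapshot_stats()` — per-locus 0/1/2-focus fractions with Wilson
  intervals. The two-focus split is a free phenomenological Bernoulli
  (replication-timing excess `2^(g(1-tau)) - 1` times a segregation
  probability), since no printed values constrain it.
* `timelapse_stats()` — initial fraction, transmission, `h = t x i`,
  chain-length histogram. Transmission is measured on the monitored next
  division of each focus-retaining daughter, which keeps the estimate
  unbiased under population down-sampling (a carrier removed by the
  population cap never gets its Bernoulli trial).
* `simulate_mfa()` — expected per-bin coverage = replication-gradient
  copy number x cells retaining the bin, total-normalized, Poisson read
  noise (negative-binomial overdispersion available as an option), ratio
  mutant/reference. The dip is centred on *dif* for FtsK-proficient
  genotypes and spans the *ter* fork trap for `cleavage = "trap"`
  genotypes. The gradient is applied to all cells alike; since the ratio
  of two profiles cancels the gradient, this simplification does not
  affect the MFA observable.
* `cephalexin_stats()` — division blocked for a sampling window (default
  2 rounds): non-segregated dif-proximal foci = sigma-carriers plus the
  15% dimer background (independent-overlap combination); linear
  chromosomes make no dimers and present a focus deficit instead.

## Numerical and design choices

* Coordinates are continuous kb, 0-based, modulo 4,641 on circular maps.
  *oriC* at 3926 kb and the *ter* positions (terD 1280, terA 1340, terC
  1600, terB 1680) are config-overridable defaults; yoaC and ycdN are
  placed at exactly 300/500 kb from *dif* on their stated replichores.
* Resection extents are capped so a lost arc never exceeds the genome —
  necessary for the near-flat recA case, where the fitted exponential
  scale (12,900 kb) exceeds the genome length and effectively models
  whole-chromosome degradation of the anucleate focus-less cells.
* One RNG stream per simulation, seeded from the config; draws occur in a
  documented order (breakage, rescue, continuation, cleavage, degradation
  extents, division budgets), so runs are bit-reproducible.
* Population cap (default 1e5) applies uniform down-sampling after each
  generation; per-generation tallies are taken before sampling, and the
  transmission statistic conditions on daughter survival, so no reported
  fraction is biased by the cap.
* Degenerate inputs: `p_sigma = 0` populations double exactly;
  `n_generations = 0` returns the founders; equal loss fractions at two
  distances flag an infinite (non-identifiable) degradation scale rather
  than fitting one; observed `(i, t)` pairs with no steady state (initial
  fractions unreachable at the given continuation) raise an error rather
  than being truncated.
* The per-fork rate divides the per-cell rate by two (the published
  apportionment); the independent-forks alternative
  `1 - sqrt(1 - p)` is provided under an explicit option flag.
* The snapshot growth exponent defaults to 1.0 (one overlapping
  replication round in exponential M9 growth) — a documented guess, as
  the sampling window is stated only as "exponential".

## What a green test establishes

The synthetic-data generators emulate the *statistical structure* of the
measurements: division-synchronous focus loss in exactly one daughter,
geometric transmission chains, exponential resection gradients, Poisson
read noise on a replication gradient. They do not emulate microscopy
segmentation error, chromosome-dimer guillotining (ftsK snapshots carry a
~15% additive background the model does not subtract), variable
generation times, cell elongation, or real library/alignment biases. A
green acceptance run therefore establishes internal consistency of rates,
closed forms and simulated observables at the measured parameter values —
not a reanalysis of the underlying sequencing data, which is out of
scope.
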