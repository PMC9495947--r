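---
title: "Competition-driven resistance evolution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition-driven resistance evolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugeCA)
```

## The question

*Spodoptera frugiperda* (fall armyworm, Sf) and *Helicoverpa armigera*
(cotton bollworm, Ha) co-occur on cotton, corn and soybean and compete —
and cannibalize — as larvae. refugeCA asks whether that larval
competition, by itself, can act as a selective force on insecticide
resistance alleles in a refuge of non-Bt, insecticide-free host plants.
Because the refuge applies no toxin, the only forces in the model are
(i) strain-dependent survival of competitive encounters and (ii) a
fecundity cost of resistance. Any change in allele frequency is therefore
attributable to the ecology, not to insecticide mortality.

## Model structure

One generation on a toroidal lattice (default 100 × 100 cells, one plant
per cell, at most one larva per plant) consists of four phases:

1. **Competition** (synchronous). Each larva draws a single uniform
   number on (0.00001, 1); it meets a competitor if the draw does not
   exceed the occupancy of eligible competitors among its 8 Moore
   neighbors divided by 8. Eligibility is any larva in the
   intra+interspecific mode, same-species larvae only in the
   intraspecific mode. The opponent is sampled uniformly among eligible
   neighbors, and the focal larva survives with probability
   $\rho_s(\text{focal}, \text{opponent})$ from the payoff matrix. All
   cells are resolved against the pre-update state, so the update order
   cannot matter; a larva faces at most one encounter per generation.
2. **Adulthood and dispersal.** Every surviving larva becomes an adult
   in one of four lattice quadrants (2 × 2 layout). Each adult stays
   with probability 0.50 or moves to each of the two orthogonal
   neighbor quadrants with probability 0.25 (diagonal moves are not
   allowed); counts are conserved exactly.
3. **Mating.** Random mating within each quadrant pool, within species.
   Adults contribute gametes in proportion to their effective
   reproductive capacity $R_o(\text{species}, \text{crop}) \times (1 -
   \text{cost(genotype)})$, so the fecundity cost of resistance acts at
   this stage and only at this stage. Offspring genotypes are
   Hardy-Weinberg at the fecundity-weighted gamete frequency
   (infinite-gamete approximation; no explicit pair formation and no
   sexes, since no sex ratio is part of the design).
4. **Oviposition.** Each empty cell is tested once: for each species,
   $W = n_{\text{neighbors}} \times \bar R_o^{\text{pool}} / (8 \times
   R_o^{\max})$, where $n_{\text{neighbors}}$ counts that species'
   larvae in the Moore window, $\bar R_o^{\text{pool}}$ is the mean
   effective capacity of the species' quadrant pool and $R_o^{\max}$ is
   the largest effective capacity on the crop. One uniform draw against
   $W_{SF} + W_{HA}$ decides colonization, a fecundity-weighted lottery
   picks the species, and the genotype comes from that species' quadrant
   mating distribution. Occupied cells are never overwritten.

Genetics are biallelic (S = susceptibility, R = resistance), autosomal,
monogenic and generational. Runs start at Hardy-Weinberg equilibrium
with $p_R = 0.1$ — high enough that all genotypes actually meet on the
lattice — with each cell independently occupied with probability 0.5 and
a 50:50 species mix (the same balance as the 5 + 5 larvae per cage of
the bioassay design). There is no mutation and no immigration, so a lost
allele stays lost.

## Payoff matrices

The per-encounter survival probabilities $\rho_s$ come from five-day
greenhouse competition bioassays of homozygous susceptible (SS) and
resistant (RR) strains of both species on each crop, estimated by
Kaplan-Meier at day 5. The matrices are **ordered**: the entry (A, B) is
A's survival against B and (B, A) is B's, and the two need not agree
(on corn, susceptible Ha survives an encounter with resistant Sf with
probability 0.00 while the Sf side survives with 0.25). Intraspecific
and interspecific entries come from two separate experiments and are
kept as separate strata: same-species encounters always use the
intraspecific entry, cross-species encounters the interspecific one.

Only the values reported numerically in the bioassay write-up are
transcribed into the shipped fixtures, flagged `printed`. Cells the text
reports only qualitatively ("no difference between curves") are filled
with the mean of the focal species' printed values for the same crop and
stratum, flagged `default`; the two strata are never mixed because they
are separate experiments. Every simulation output carries provenance
counts so a reader can see how much of a run rests on gap-filled cells,
and `run_scenario()` can be made to refuse them
(`allow_default_payoffs = FALSE`).

Heterozygote (RS) competition behavior was not assayed and is a scenario
axis with three settings: `BH_00RR` substitutes the same-species SS
strain for every RS slot, `BH_100RR` substitutes RR, and `BH_50RR` takes
the midpoint of the two substituted values. The midpoint reading of
"intermediate behavior" is the median of the two homozygote values; for
RS-vs-RS both slots are substituted in tandem, so the value is the
midpoint of the SS-vs-SS and RR-vs-RR entries. Expansion never touches
printed entries and is idempotent.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| lattice | 100 × 100, toroidal | one plant per cell |
| generations × replicates | 100 × 50 | the headline run length |
| initial $p_R$ | 0.1 | Hardy-Weinberg start, both species |
| occupancy / species mix | 0.5 / 50:50 | initial densities (the design leaves them open; chosen to mirror the balanced bioassay cages) |
| `cost_RR` | 0.25 | fractional fecundity reduction of RR adults |
| `cost_RS` | 0 | heterozygotes pay nothing: the cost is attributed to resistant individuals and resistance is incompletely recessive |
| $R_o$ | Sf: corn 1.0, soybean 0.8, cotton 0.6; Ha: cotton 1.0, soybean 1.0, corn 0.5 | relative reproductive capacities encoding the host-plant rankings (corn is Sf's primary host; Ha does relatively better on cotton/soybean); configurable |
| dispersal | stay 0.50, 0.25 per orthogonal neighbor quadrant | quadrant scheme |

The $R_o$ values are relative and only their ratios matter in the
oviposition lottery; the source design defers the absolute values to
life-table references without printing them, so the table above encodes
the qualitative rankings and ships as an explicit, overridable default.

## Numerical and design choices

* **Encounter rule.** The occupation/vacancy rules are inherited from an
  earlier game-theoretic automaton that the design cites without
  reproducing. The engine makes them explicit: occupancy-proportional
  encounter probability, one uniformly drawn opponent, Bernoulli
  survival, at most one encounter per larva per generation. The focal
  cell is part of the 3 × 3 window but a larva is never its own
  competitor (hence the /8 denominator).
* **The 0.00001 lower bound** of the encounter draw is kept verbatim for
  fidelity even though it is practically equivalent to 0.
* **W normalization.** How "relative fitness" becomes a probability is
  not fully specified in the design; the normalization by
  $8 R_o^{\max}$ is this package's documented choice. It guarantees
  $W_{SF} + W_{HA} \le 1$, reaches 1 exactly when all 8 neighbors belong
  to the maximum-fitness strain, and makes colonization pressure local
  (Moore window) while genotype composition is quadrant-level — the two
  scales the design describes.
* **Single-species runs.** The intraspecific-only mode is run as two
  independent single-species simulations, matching the per-species
  panels of the intraspecific experiment.
* **RNG.** One deterministic stream per replicate, seeded by a fixed
  map from (master seed, replicate index). Replicates are independent
  and individually reproducible: deleting a replicate never perturbs
  another, and the same (seed, replicate) pair replays bit-identically.
* **Extinction.** A species whose lattice count reaches zero is extinct
  for good; its allele frequency is reported as missing, not 0.
  Trajectories record generation 0 before any update, so a 100-step run
  yields 101 states.
* **Degenerate inputs.** Empty mating pools signal a typed "no mating"
  condition rather than returning 0; occupancy-0 lattices run to
  completion flagged extinct; a `p_R = 0` start can never produce an R
  allele (no mutation), which is tested.

## The bioassay layer

`simulate_bioassay()` generates synthetic five-day records under a
constant daily hazard $h$ with $(1-h)^5 = \rho_s$ — the minimal
assumption compatible with the day-5 endpoint, which is all the printed
results constrain. Records carry the randomized-block structure (4 cages
× 5 larvae per arm) but the estimators ignore it, matching per-arm
Kaplan-Meier curves; `km_estimate()` and `log_rank()` delegate to the
survival package, and `estimate_payoff()` reads $\hat S(5)$ — without
censoring before day 5 this is exactly the raw surviving fraction, so
whether the printed values were KM estimates or raw proportions is
immaterial. Pairwise log-rank decisions are reported unadjusted, as in
the source analysis.

## What the synthetic data do and do not show

The generator emulates: balanced arms, five daily observation times,
censoring at the endpoint, and a survival level calibrated to the true
$\rho_s$. It does not emulate cage-level frailty acting on the estimates
(the block label is carried but not used), time-varying hazards (any
hazard shape matching the day-5 endpoint is admissible), or the
day-by-day shape of the empirical curves, whose raw data were never
deposited. Passing tests therefore validate the estimators and the
calibration, not the shape of real survival curves.

## Problem sizes used in the test suite

The full-scale conditions (100 × 100 lattice, 50 replicates × 100
generations) are used for the three headline scenario checks and the
acceptance script. The qualitative panel sweep runs 18 scenarios at
50 × 50 with 10 replicates × 60 generations — the qualitative
rise/no-rise outcomes are insensitive to lattice size in this range and
the sweep stays affordable. Neutrality (martingale) checks run at
30 × 30 with 50 replicates, where three standard errors of the replicate
mean give a tight band.

## Known limitations

* Only the numerically printed payoff cells are empirical; on cotton in
  particular, both interspecific cells of resistant Ha are gap-filled
  defaults (mean of that species' printed cotton values, 0.075). Under
  that fill plus the 25% fecundity cost, resistant Ha is disfavored and
  the model does **not** reproduce the reported rise of Ha resistance on
  cotton under the `BH_00RR`/`BH_50RR` scenarios (it does reproduce
  every reported no-rise outcome, and the Sf outcomes on all three
  crops). The complete empirical matrices would be needed to close this
  gap; the corresponding acceptance check is left failing rather than
  tuned.
* With interspecific competition on corn and soybean, Ha is not merely
  held at its initial allele frequency but competitively excluded
  outright (extinct in every replicate at the default settings) —
  consistent with the reported absence of Ha resistance evolution there,
  but a stronger outcome than the trajectories suggest.
* One encounter per larva per generation is an explicit reading of an
  under-specified rule; allowing sequential encounters would lower all
  survival and likely sharpen competitive exclusion.
* No within-generation larval movement, no multiple larvae per plant,
  no plant damage states, no landscape-level movement between crops,
  and no temperature dependence of the interactions.

## A worked example

```{r example, eval = FALSE}
library(refugeCA)
cfg <- simulation_config("corn", "intra_plus_inter", "BH_50RR", seed = 1)
res <- run_scenario(cfg)
res
plot(res)
summary(res)
```
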