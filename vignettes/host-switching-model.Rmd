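---
title: "An individual-based model of host switching by ecological fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of host switching by ecological fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecofitsim)
```

## The model

`ecofitsim` simulates a parasite lineage whose fit to a host is summarized
by a single quantitative phenotype $p_i$ per individual. The occupied host
("resource") imposes Gaussian stabilizing selection around its optimum
$p_r$: an individual survives a selection episode with probability

$$S(p_i, p_r) = \exp\!\left[-\frac{(p_i - p_r)^2}{2\sigma_r^2}\right],$$

so a perfectly matched phenotype always survives and survival at three
kernel widths is $e^{-4.5} \approx 1\%$. The same kernel is the
colonization filter on a novel host and the mortality filter on the
current one; there is no other source of death, and hosts themselves do
not evolve or die.

Each generation executes one cycle:

1. **Reproduction.** The population of size $N$ produces a number of
   offspring drawn at rate $b$ per individual (law below), truncated so
   $N$ never exceeds the carrying capacity $K$. Each offspring takes the
   arithmetic mean of two parents drawn uniformly with replacement (the
   first parent is returned before the second draw, so self-fertilization
   has probability $1/N$) plus a mutational deviate
   $\delta \sim \mathcal{N}(0, \sigma_v^2)$.
2. **Resource offer.** A single novel host is offered, with optimum
   $p_{r'}$ uniform on $[p_r - \delta_r,\; p_r + \delta_r]$. The lineage
   gets exactly one opportunity per offered host.
3. **Dispersal.** Each eligible individual independently attempts
   dispersal with probability $d$, so the number of colonization
   propagules scales with population size.
4. **Colonization trial.** Every disperser survives on the new host with
   probability $S(p_i, p_{r'})$.
5. **Establishment or return.** If at least one disperser survives, the
   survivors alone found the next generation on $p_{r'}$ and the
   ancestral population — residents and that generation's offspring — is
   dropped from the model (a colonization *event*). Otherwise the
   population stays put: failed dispersers rejoin the residents, everyone
   undergoes the mortality check $S(p_i, p_r)$, and survivors plus
   offspring form the next generation.

A run starts from $n_0$ individuals placed exactly at the initial optimum
$p_{r0}$ (a best-adapted founding population, which avoids immediate
extinction) and iterates until extinction or a generation cap.

The **Information Space** (IS) is the population's standardized phenotypic
amplitude, $(p_{\max} - p_{\min})/\sigma_r$: the operational measure of
how much of the surrounding resource axis the lineage's standing variation
covers. Colonization events are classified retrospectively: an event is a
*successful* host switch if the founded lineage persists until the next
establishment (or to the end of the observation window), and a *failed
attempt* if it goes extinct first, however many generations that takes.
Events still pending when a run hits the generation cap are counted as
successes, since the colonization did not lead to extinction within the
observed horizon.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `n0` | founding population size | 1 | individuals |
| `b` | birth rate | 0.5 | offspring / individual / generation |
| `K` | carrying capacity (hard cap at reproduction) | 500 | individuals |
| `d` | per-individual dispersal probability | 0.05 | — |
| `sigma_r` | survival-kernel width | 0.5 | phenotype units |
| `sigma_v` | mutational standard deviation | 0.2 | phenotype units |
| `delta_r` | maximum offset of an offered optimum | 5 | phenotype units |
| `p_r0` | initial resource optimum | 5 | phenotype units |
| `max_generations` | run cap | 1000 | generations |
| `burn_in` | generations excluded from pooled statistics | 50 | generations |

These defaults are the reference condition used by the test suite and the
acceptance script. All distance-like observables (IS, switch distances,
midpoint offsets) are reported in multiples of `sigma_r`, which makes them
invariant under translation of the phenotype axis and under joint
rescaling of all phenotype-unit parameters — both properties are asserted
in the test suite with coupled RNG streams.

## Design choices where the rules were genuinely open

**Offspring-count law.** A rate of $b = 0.5$ offspring per individual
needs a stochastic rounding rule. The default draws the total as
$\mathrm{Poisson}(bN)$ truncated at $K - N$, which handles fractional and
greater-than-one rates uniformly and lets a single founder leave
offspring. A lower-variance alternative (`offspring_law = "binomial"`)
gives each parent $\lfloor b \rfloor$ offspring plus a Bernoulli
$b - \lfloor b \rfloor$ extra; headline statistics are insensitive to the
choice.

**Fate of a failed disperser.** The model text underlying this package
admits two readings of what happens to an individual whose colonization
trial fails: it dies with the attempt, or it returns home and faces the
ordinary mortality check against the home optimum. The default is
`failed_disperser_fate = "return"`: dispersal is an attempt, not a
suicide mission, and mortality in a no-establishment generation is
computed against the occupied resource for everyone. The lethal variant
(`"die"`) is retained as an option; it mainly punishes small wandering
colonies, lowering colonization-success estimates in the small-IS cells
while leaving the size–IS correlation essentially unchanged.

**Newborn eligibility.** Offspring generated at time $n$ join the
population at $n+1$; by default they are exempt from generation $n$'s
dispersal and mortality (survivors *and their offspring* form the next
generation). Setting `newborns_subject_to_events = TRUE` places newborns
in both pools immediately. Both variants satisfy every structural
invariant; the default is used throughout.

**Bookkeeping conventions.** Generation 0 is the initial state and
records are emitted for generations $1..\mathrm{final}$. One resource is
offered per generation and evaluated once. All of a generation's
surviving dispersers pool as co-founders of a single event. Event
covariates (`pre_switch_size`, `pre_switch_IS`,
`time_since_last_switch`) are those of the source population at the start
of the generation of establishment — "just before" the switch. Time on a
host counts from establishment (from generation 0 for the initial host).

## The analysis layer

`success_curve()` and `phase_diagram()` bin resolved events by pre-switch
covariates and report per-bin attempts, successes, and the success
fraction. Bin widths are not dictated by the model; the defaults used in
the package's own analyses are 0.1 (in `sigma_r` units) for IS and
distance axes and 10 individuals for population size, which resolve the
structure of the success surfaces at the replication the package runs at.
Empty bins are omitted rather than zero-filled, and cells with very few
attempts should be read with binomial error in mind (a minimum of ~20
attempts per interpreted cell is a sensible filter). Totals are conserved:
summed attempts equal the number of post-burn-in resolved events, which
the tests assert by brute-force recount.

`spearman_partial()` implements the first-order partial rank correlation
$$\rho_{xy\cdot z} = \frac{\rho_{xy} - \rho_{xz}\rho_{yz}}
{\sqrt{(1-\rho_{xz}^2)(1-\rho_{yz}^2)}}$$
with average ranks for ties; it is verified against an independent
rank-residual regression route to $10^{-12}$. The headline use is the
correlation between per-generation population size and IS controlling for
time since the last switch, pooled over post-burn-in records.

The first 50 generations of every run are excluded from pooled statistics
to remove the transient of the artificial, perfectly adapted founding
condition; the cut applies per run, to records and events alike.

## Randomness and reproducibility

A run consumes a single seeded RNG stream in a fixed order per generation:
offspring count, parent pairs, mutational deviates, resource proposal,
dispersal flags, survival trials. Identical `(params, seed)` pairs
reproduce records and events bit-for-bit, and file outputs are
byte-identical across re-runs. Batches draw per-run seeds without
replacement from a master-seeded stream, so seeds never collide and any
batch is reproducible from `(params, n_runs, master_seed)`.

## What the simulations do and do not show

The generator *is* the study system here — there is no external data.
Runs at the reference condition capture: growth of IS from a single
founder; the colonization–bottleneck cycle in which every switch resets
IS and population size; co-accommodation (the phenotype midpoint drifting
toward the new optimum while IS recovers); persistence of small,
sub-optimally adapted populations for tens of generations; and
stepping-stone displacement of the occupied optimum far beyond any single
jump. These are asserted in the test suite as sign and ordering
properties, not as curve fits.

Problem sizes are chosen to keep Monte-Carlo error well below the
decision thresholds while remaining routine to run: the test suite pools
a 60,000-replicate batch (about 300,000 post-burn-in generation records)
and the acceptance script a 150,000-replicate batch, large enough that
the sparsest analyzed cell (pre-switch IS < 0.4 with standardized
distance in [1.4, 1.5]) holds on the order of 50 events.

Two caveats matter when comparing against published descriptions of this
class of model. First, the far tail of establishment distances is
governed by the product of an equilibrium-IS tail and a Gaussian trial,
both of which are extremely sensitive to the exact selection and
mutation rules; at the reference condition the mutation–selection
balance puts the equilibrium phenotypic spread near $0.46\sigma_r$
(so IS $\approx 3$ at $K = 500$), and edge phenotypes occasionally
establish on resources beyond $3\sigma_r$. Second, post-burn-in
populations with very small IS are almost always freshly founded, tiny,
and often still off-optimum, so their colonizations of even very close
resources carry a non-trivial failure risk from demographic
stochasticity; an expectation of near-certain success in that cell
presumes well-adapted sources that the bottleneck dynamics rarely
supply. Both caveats are visible directly in the acceptance report the
package computes.

## Limitations

One phenotype dimension; static host optima; no parasite-induced host
mortality; no gene flow back to the ancestral host (the ancestral
population is dropped at establishment); a single colonization
opportunity per generation. Phenotypic plasticity, phylogenetic
conservatism and exaptation — other contributors to a lineage's realized
fitness space — are deliberately outside the model, so IS here reflects
heritable standing variation only.

## A short session

```{r example, eval = FALSE}
p <- sim_params()
run <- run_simulation(p, seed = 1)
run
run$events <- classify_outcomes(run$events, run)

b <- run_batch(p, n_runs = 200, master_seed = 1)
batch_summary(b)
sc <- success_curve(b$events, "standardized_distance", bin_width = 0.5)
sc
```
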