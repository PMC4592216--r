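# ecofitsim

An individual-based simulator of parasite **host switching by ecological
fitting**, with the analysis layer needed to study it: Information Space
metrics, colonization-success curves and phase diagrams, partial rank
correlation, and a batch/robustness-sweep harness.

## The scientific problem

Parasites are ecological specialists, yet host switching — not
co-speciation — dominates the history of most host–parasite associations.
One proposed resolution is that lineages carry *sloppy fitness space*:
standing phenotypic variation that confers positive fitness on resources
they never evolved with, letting them colonize new hosts without prior
adaptive change. `ecofitsim` models the minimal version of this idea for
a lineage with a direct (one-host) life cycle, such as gyrodactylid
ectoparasites of fishes.

Each parasite carries one quantitative phenotype `p_i`. Its host imposes
Gaussian stabilizing selection around an optimum `p_r`: survival per
selection episode is

    S(p_i, p_r) = exp( -(p_i - p_r)^2 / (2 σ_r²) )

Every generation the population reproduces (midparent recombination plus
a `N(0, σ_v²)` mutational deviate, capped at carrying capacity `K`), is
offered a single novel host with optimum uniform within `± δ_r` of the
current one, and each individual attempts dispersal with probability `d`.
Dispersers face the colonization filter `S(p_i, p_r')`; if any survive,
the survivors found the population on the new host and the ancestral
population is dropped. A colonization is a *successful* host switch if
the founded lineage persists to the next establishment (or the end of the
run), a *failed attempt* if it goes extinct first.

The population's **Information Space**, `IS = (p_max − p_min)/σ_r`, is
the operational stand-in for fitness-space size; the analysis layer asks
how colonization success depends on IS, population size, time since the
last switch, and the standardized distance `|p_r − p_r'|/σ_r` between
resources.

## A worked example

```r
library(ecofitsim)

p <- sim_params()            # reference parameters: N0=1, b=0.5, K=500,
                             # d=0.05, sigma_r=0.5, sigma_v=0.2, delta_r=5
run <- run_simulation(p, seed = 1)
run
#> <ecofit_run> 40 generation(s), 3 colonization event(s), extinct (seed 1)
```

One lineage, started as a single perfectly adapted individual, switched
host three times and went extinct after 40 generations — a typical short
chain. Pooling replicates gives the headline statistics:

```r
b <- run_batch(p, n_runs = 200, master_seed = 1)
b
#> <ecofit_batch> 200 run(s), 7177 generation records (1486 post-burn-in), 529 event(s)

batch_summary(b)
#> $partial_rho        0.883
#> $n_records          1486
#> $n_events           133
#> $success_fraction   0.759
#> $max_switch_distance 4.4
```

`partial_rho` is the Spearman partial correlation between per-generation
population size and IS, controlling for time since the last switch, over
post-burn-in records (the first 50 generations of each run are excluded):
size and variation grow together after every colonization bottleneck.
`success_fraction` is the share of post-burn-in colonizations that became
established switches rather than dead ends. Success falls off with the
standardized distance to the offered resource:

```r
success_curve(b$events, "standardized_distance", bin_width = 0.5)
#>   bin_lower bin_upper attempts successes probability
#> 1       0.0       0.5       37        36   0.9729730
#> 2       0.5       1.0       33        30   0.9090909
#> 3       1.0       1.5       29        25   0.8620690
#> 4       1.5       2.0       14         8   0.5714286
#> 5       2.0       2.5       11         2   0.1818182
#> 6       2.5       3.0        5         0   0.0000000
#> 7       3.0       3.5        3         0   0.0000000
#> 8       4.0       4.5        1         0   0.0000000
```

`phase_diagram()` produces the two-dimensional analogue (e.g. IS ×
distance), `robustness_sweep()` re-runs reduced batches over a parameter
grid, and `write_tables()` serializes everything as TSV + JSON. A thin
command-line wrapper with `simulate`, `batch`, `sweep`, and `accept`
subcommands is installed at `inst/scripts/ecofitsim`.

## The methods vignette

`vignettes/host-switching-model.Rmd` documents the model and its
assumptions, the generation cycle, the open design choices (offspring
rounding law, fate of failed dispersers, newborn eligibility) and why
each default was chosen, the analysis conventions (burn-in, bin widths,
event covariates), and known limitations.
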