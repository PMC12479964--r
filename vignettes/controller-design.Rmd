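---
title: "Host-aware design of evolutionarily stable genetic controllers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-aware design of evolutionarily stable genetic controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evostab)
```

## The problem

An engineered gene circuit consumes its host's ribosomes and anabolites.
The resulting growth defect ("burden") puts circuit-carrying cells at a
selective disadvantage against spontaneously arising loss-of-function
mutants, so circuit output is eventually purged from any evolving
population. `evostab` models this process mechanistically and asks a
control-engineering question: which feedback architectures slow the decay,
and how should their parameters be chosen?

## The single-cell model

The host model is the mechanistic resource-allocation cell of Weiße et
al. (2015), the established base model for burden studies, with its
published *E. coli* calibration as the default `host_params()`. Per cell
(units: molecules per cell, minutes):

* **Nutrient flux.** Transporters import external substrate
  (`p_t · v_t · s_X/(K_t + s_X)`); metabolic enzymes convert internal
  substrate into an anabolite pool `e` with yield `n_s`.
* **Transcription.** Each gene class transcribes at
  `w_x · e/(θ_x + e)`, with a large threshold `θ_r` for ribosomal genes
  (making ribosome synthesis the growth-rate-sensitive class) and
  autoinhibition of the housekeeping class, which implements the host's
  negative feedback on free protein capacity.
* **Translation.** mRNAs reversibly bind free ribosomes (`k_b`, `k_u`)
  into translation complexes; each complex elongates at
  `γ(e) = γ_max · e/(K_γ + e)` aa/min, consuming one anabolite per amino
  acid, and releases ribosome, mRNA and one finished protein per `n_x`
  elongated residues.
* **Growth.** `λ = γ(e) · Σ c_x / M` with `M` the cell's protein mass.
  Everything dilutes at `λ`. Nothing about burden is assumed: expressing a
  circuit sequesters ribosomes and anabolites, ribosome synthesis falls,
  and `λ` drops.

Circuit genes enter the same machinery. Their transcription is the
product of the designed maximal rate `ω`, the mutation level of their
promoter, the controller's regulatory factor, and the same anabolite
saturation `e/(θ_nr + e)` as non-ribosomal host genes — so transcription
shuts down in stationary phase along with everything else. An optional
host flag adds a per-nucleotide anabolite cost of transcription
(`transcription_cost`, `xi_nt`); it is off by default, reflecting the
assumption that translational demand dominates bacterial burden.

The ancestral initial condition is the balanced-growth steady state under
a fresh substrate bolus, found by long stiff integration (to 10^5 min,
extended once if the residual exceeds 10^-9 min^-1). Circuit species are
seeded at zero, so a silent circuit stays exactly silent.

## Controllers

All regulation is quasi-steady-state Hill kinetics with coefficient 2 by
default (configurable). The sensing/actuation matrix:

| input | transcriptional actuation | sRNA actuation |
|---|---|---|
| per-cell output `p_A` | `CLpATX` (co-expressed repressor) | `CLpATL` (co-expressed activator -> sRNA) |
| growth rate `λ` | `CLlamTX` | `CLlamTL`, `CLlamPF` (protein-free) |
| population output `P` | `PHEN_POP` (phenomenological), `QS_POP` (quorum sensing) | — |

plus the phenomenological single-gene controllers (`PHEN_PA`,
`PHEN_LAMBDA`, `PHEN_DUAL`) and five multi-input mechanistic combinations
(`CLpATXlamTL`, `CLpATLlamTX`, `CLpATLlamTL`, `CLpATXlamTX`,
`CLpATLlamPF`).

Design choices worth knowing:

* **Growth sensing.** Burden sensors are promoters *up*-regulated under
  stress, so the growth-sensitive promoters transcribe at
  `ω_B · k_λ²/(k_λ² + λ²)`: more controller when growth is low. The
  phenomenological growth controller instead applies
  `Φ(λ) = λ²/(k_λ² + λ²)` directly to the process gene — production is
  inhibited at low growth. Both routes inhibit the circuit when burden is
  high; they differ in where the Hill function sits. Sensing uses the
  instantaneous model `λ` (no sensor delay).
* **Co-expression.** Where process and controller proteins share a
  promoter, the shared promoter produces two independently
  ribosome-binding mRNAs at the same effective rate, keeping the two
  binding strengths independently tunable.
* **sRNA sequestration** is irreversible bimolecular co-degradation
  (`k_seq · m · r` removes one mRNA and one sRNA) — the simplest
  mass-balanced reading of sRNA silencing. The sRNA targets every
  transcript from the process promoter.
* **Quorum sensing** (`QS_POP`) is a deliberately minimal synthetic
  construction: a co-expressed synthase feeds a single well-mixed
  autoinducer pool `H` (`dH/dt = Σ N_i k_syn p_B,i − d_H H`), which
  represses the process promoter. It stands in for a detailed
  AHL mechanism and is assessed qualitatively only.

## Mutation and selection

Each mutable promoter has functional levels {100, 67, 33, 0} % of its
designed `ω`; only function-reducing, single-promoter transitions are
allowed, with rate `base_rate · attenuation^(levels skipped − 1)`.
Mutation acts as continuous first-order transfer between strain
populations inside the ODE — the deterministic-continuum reading of
rare mutations in large populations. The defaults,
`base_rate = 5e-5 min^-1` and `attenuation = 0.1`, are effective
aggregate rates chosen so that an uncontrolled circuit loses function
over one to two weeks of serial passage, the timescale reported by the
serial-passage experiments this protocol mirrors; both are configuration
parameters, and the transition matrix is written out with every run for
audit.

Within the population ODE, every strain carries its own full
intracellular state, integrated jointly with the strain populations and
the shared substrate as one stacked stiff system (deSolve's `lsodes`,
absolute tolerance 10^-8 on intracellular species, looser on the
10^12-molecule substrate and on cell counts; the flux field is compiled,
with a line-for-line R reference implementation cross-checked in the test
suite). States are kept non-negative by formulation — every removal flux
vanishes smoothly at zero — and asserted non-negative after each day
rather than clipped during integration. Strains are never extinguished by
thresholding.

## Batch protocol and metrics

Days are 1440 min; at each day end a representative sample of 1000 cells
(deterministic proportional rescaling by default; seeded multinomial
sampling optionally) is carried into fresh medium with the substrate
reset to 10^12 molecules. Because cells that have passed through
stationary phase start the next day in a different physiological state
than freshly equilibrated ones, runs are initialised from an ancestral
population *conditioned* to the serial-passage cycle (batch cycles are
iterated until the day-endpoint output is periodic, like growing the
inoculum overnight). `P0` is then the endpoint of one mutation-free
ancestral day, and without mutation the daily-endpoint output is constant
to well under 0.1 %.

Within a day the population output `P(t) = Σ N_i p_A,i` swings several
fold (dilution, regrowth, stationary plateau), so the longevity metrics
are defined on the daily-endpoint envelope with `P0` prepended at time
zero and linear interpolation between points: `τ±10` (first exit from
`P0 ± 10 %`, either side — an early rise counts and is flagged), `τ90`,
`τ50`, `P_max`, and the cumulative output
`Q = Σ_i ∫ T_L_A,i N_i dt` (trapezoidal on the stored grid) up to the
time the endpoint series falls below 1 % of `P0`. Metrics whose threshold
is never crossed are reported as `Inf` with explicit flags, never as the
horizon.

Controllers are compared against an **equal-output open loop**: an `ω_A`
sweep is filtered to the branch before the `P0` maximum (overburdened
designs, where output and longevity fall together, are removed) and each
metric is interpolated linearly in `P0`; queries outside the swept range
refuse to extrapolate. With this host calibration the open-loop `P0`
maximum sits near `ω_A ≈ 10^3`, and in the deep overburden regime growth
becomes so slow that selection weakens and longevity can lengthen again —
the equal-output comparison is only meaningful on the retained branch.

## Design optimisation and robustness

`pareto_optimize()` maximises `(P0, τ±10, τ50)` with a standard
real-coded NSGA-II (fast non-dominated sort, crowding distance, binary
tournament, SBX crossover η=15, polynomial mutation η=20), written in the
package because no multi-objective GA is available among its
dependencies. Rate-like parameters are searched in log10 space since the
biologically feasible bounds span decades (`design_space()`). The
reference settings are population 250 with Pareto fraction 0.4; the
shipped desk preset (`ga_settings_desk()`: population 40, 30 generations)
is for exploratory runs. Failed evaluations get worst-case fitness;
"not reached" τ values enter the ranking capped at the simulation horizon
and are flagged in the returned table; evaluations are memoised by
parameter value; everything is deterministic given the seed.

`robustness_analysis()` re-evaluates each front design under `n`
uniform ±X % parameter perturbations (X = 10, 25 by default), clipped
exactly to the design-space bounds, and reports per-design and
front-wide standard deviations of the percentage change in
`(P0, τ50, τ±10, τ90, P_max)` against the *stored* baselines, plus the
fraction of replicates that lose the `τ±10 = τ90` property (the discrete
short-term failure mode of strongly controlled, low-output designs).
Baseline designs that already violate `τ±10 = τ90` are excluded;
replicates with non-finite metrics are excluded per metric and counted.

## What the test-scale system does and does not show

The test suite and examples run on a miniature configuration
(`fixture_toy_system()`): 8-hour days, 500-cell samples, a 2×10^11
bolus and a 10× faster mutation clock, so a full evolution run takes
seconds while preserving the qualitative phenomena — day-endpoint decay,
non-functional takeover, the output/longevity trade-off of control, the
overburden fold, and transient super-ancestral producers under
controller-promoter mutation. Quantitative values at toy scale (τ in
480-min days, smaller populations) do not transfer to the full protocol,
and none of the tests claim they do. The acceptance script runs the full
1440-min protocol; its open-loop sweep uses 12 designs where an
exhaustive study would use thousands, which coarsens the equal-output
interpolation but changes nothing structural.

Known limitations: the deterministic continuum treats 10^-6 cells as
meaningful mass rather than extinction events; mutation pressure is
constant in time rather than replication-coupled, which overweights long
stationary phases; per-strain intracellular states are not mixed by
mutation flux (a new mutant inherits its own strain's average state);
and the host parameterisation is a published *E. coli* calibration rather
than a refit, so absolute timescales carry that model's biases. Within
those bounds the framework reproduces the qualitative design rules the
architecture comparison rests on.
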