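---
title: "Modelling bistable transfer-competence regulation of ICEclc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bistable transfer-competence regulation of ICEclc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The system

The integrative and conjugative element ICEclc resides in the chromosome of
*Pseudomonas* and transfers by conjugation only from a small subpopulation
of *transfer-competent* (tc) cells — about 3–5% of a stationary-phase
population. The decision is bistable: a cell either keeps the element
silent or commits to an activation programme it does not leave. The
regulatory cascade behind the switch has three transcription-factor nodes:
TciR activates the promoter `P_bisR`; its product BisR transiently
activates `P_alpA`; and the `P_alpA` transcript encodes the heteromeric
activator BisDC, which activates `P_alpA` itself (an autoregulatory
positive feedback) as well as the downstream ("late") promoters of the
transfer-competence programme.

`icebistab` implements this cascade as a stochastic reaction network and
asks the questions a single-cell experiment would ask: what fraction of
cells ends in the *zero* state (regulator count exactly 0) versus the
*positive* state, how do those fractions respond to rates and inputs, and
what does the output look like through a fluorescence readout.

## The stochastic model

Each node contributes four elementary processes — production,
oligomerization/binding, unbinding, degradation — realised as reaction
channels of a continuous-time Markov jump process and simulated exactly
with the Gillespie direct method (compiled core in `src/ssa.cpp`):

* **Binding.** An oligomer of $n$ monomers of an activator $X$ occupies a
  free promoter with propensity $A_1 \binom{x}{n}$, where $x$ is the free
  monomer count: every distinct $n$-subset is a potential binding complex.
  The $n$ bound monomers are sequestered from the free pool.
* **Unbinding.** A bound configuration releases its oligomer with constant
  propensity $A_2$, restoring the $n$ monomers exactly.
* **Production.** While bound, the promoter produces its product protein
  (transcription and translation collapsed into one step) at a constant
  rate — $A_3$ at the feedback node, $C_5$ at cascade nodes.
* **Degradation.** Free monomers decay with first-order rate $A_4$
  (per-species). Bound oligomers are protected from degradation until
  release; this is a model assumption, configurable through the rate
  parameters rather than hard-wired biology.

Promoter occupancy is mutually exclusive: each promoter copy is free or
bound by exactly one oligomer of one configuration. `P_alpA` carries two
configurations (BisR-bound and BisDC-bound) competing for the same
operator; this single-operator exclusivity is the minimal reading of a
promoter drawn with two incoming activation arrows.

All rates are per arbitrary model time unit. "100 time steps" of the
study design is interpreted as continuous simulated time $t \in [0, 100]$
with observation at $t = 100$, not as 100 simulation events; the
alternative (discrete-time updates) would only rescale the rate constants.
Counts at event times are right-continuous (post-event values). The zero
state is absorbing in every shipped preset because no promoter has basal
activity: once all regulator counts and occupancies are zero, total
propensity is zero and the simulation stops.

## Shipped network presets

* `build_feedback_only()` — the bare BisDC loop: one species, one
  promoter, four channels. Default input: binomial(16, 0.5) BisDC copies
  (mean 8). The study description uses both "uniformly distributed" and
  "binomially distributed (mean = 8)" for this input; the binomial form is
  the shipped default and the uniform family is available through
  `input_spec()`.
* `build_kickstart()` — adds BisR as a pulse (initial copies only, no
  production channel): BisR can occupy `P_alpA` and prime BisDC
  production, after which only the feedback sustains the positive state.
  Default input: uniform-integer BisR on {0..16}.
* `build_full_cascade()` — adds the TciR node (`P_bisR`, production rate
  $C_5$) and optionally a BisDC-dependent late gene with a stable
  (degradation 0.02) or unstable (0.3) product. Default input:
  uniform-integer TciR on {0..16}; means are kept within the per-cell
  copy-number range typically measured for bacterial transcription
  factors.

## Parameter defaults and calibration

The exact parametrization of the original simulations is not public, so
the shipped defaults were fixed once by the documented procedure in
`scripts/calibrate.R` against the study's qualitative and quantitative
anchors, and are not tuned per analysis:

| parameter | default | role |
|---|---|---|
| `A1` | 0.02 | BisDC dimer binding to `P_alpA` |
| `A2` | 0.5 | BisDC unbinding |
| `A3` | 4 | BisDC production while self-bound |
| `A4` | 0.15 | BisDC degradation |
| `n` | 2 | oligomer order, all activators |
| `B1`, `B2`, `B3` | 0.1, 1, 3 | BisR binding / unbinding / BisDC production at `P_alpA` |
| `bisr_deg` | 0.15 | BisR degradation |
| `T1`, `T2` | 6e-4, 0 | TciR binding / unbinding at `P_bisR` |
| `C5` | 0.6 | BisR production while TciR-bound |
| `tcir_deg` | 0.3 | TciR degradation |
| `L1`, `L2`, `L3` | 0.005, 0.5, 3 | late-gene node |

Calibration anchors: (i) the bare loop started from binomial mean-8 input
must yield a clearly bimodal output with both states well populated;
(ii) the default full cascade must place 3–5% of cells in the positive
BisDC state at $t = 100$, the empirically reported tc-cell range; (iii)
the feedback-ablation contrast and the input-shape contrasts must be
resolvable at 10,000 cells.

Two defaults deserve comment because they were genuinely open:

* **Oligomer order $n = 2$** at every node. Oligomerization is part of the
  conceptual model but its order is not quantified; a dimer is the typical
  case for bacterial transcription factors and makes the binding
  propensity quadratic at low copy number, which is what generates the
  hard zero state (a single remaining monomer cannot rebind). It is
  configurable per activator.
* **Irreversible TciR occupancy (`T2 = 0`).** TciR decays quickly
  (`tcir_deg = 0.3`), so the TciR node acts as an early, rare gate: a cell
  either recruits TciR to `P_bisR` within the first ~15 time units or
  never does. Once bound, the occupancy persists on the 100-unit horizon
  and sustains BisR production. This makes the cascade's fate legible from
  the BisR activity window [10, 20] — a cell with a silent window can
  never show positive BisDC output — and concentrates the bistable
  decision where the data place it, at kickstart success. A small positive
  `T2` mainly reintroduces cells whose BisR production stops almost
  immediately; it is available as an override.

The production-rate labels follow the node layout: $C_5$ belongs to
production at the upstream cascade node (TciR-driven BisR synthesis), and
the BisR-driven BisDC production at `P_alpA` gets its own constant `B3`,
so each arrow in the network carries one named rate.

## Bistability readouts

`classify_states()` partitions per-cell values at exactly zero — the
operational definition used throughout: the zero histogram bar versus
everything else, with no threshold above zero. Positive-subpopulation
statistics (median, IQR) are computed over positive cells only and
reported as `NA` when that set is empty. Fractions carry
normal-approximation Monte-Carlo standard errors; medians get seeded
bootstrap intervals (1,000 resamples). Histograms use integer-aligned unit
bins so the zero bar is its own bin.

On top of this sit `parameter_sweep()` (rate dependence of the
non-activated fraction), `dose_response()` (the analog-to-digital curve:
positive fraction versus relative input level, with the positive median
expected flat), `bimodal_input_response()` (input-shape contrast at equal
mean), `cascade_bimodality()` (per-node summaries: BisR on its [10, 20]
integral, BisDC at $t = 100$) and `compare_feedback()` (late-protein
output with and without the feedback configuration, in activated cells).

Ensembles derive one seed per cell from the root seed, so results are
independent of execution order and a sub-ensemble is a prefix of a larger
one — which the determinism tests exploit.

## Synthetic fluorescence data and the qq estimator

The experimental readout the package emulates is a per-cell fluorescence
distribution: a right-skewed background population plus a minority
activated subpopulation whose median does not move with the input level.
`generate_cells()` draws that structure directly (two log-normal
components, stored ground-truth labels); `link_ensemble()` derives it from
a simulated ensemble as background + gain x molecule count. The generator
emulates the *statistical* shape of a segmented-microscopy dataset only:
no cell-size or illumination structure, no segmentation errors, no
autofluorescence correlations. Passing estimator tests therefore show
correct recovery under the stated mixture model, not robustness to every
imaging artefact.

`qq_subpopulation_estimate()` reconstructs the quantile-quantile
subpopulation method: fit the background family (log-normal by default —
fluorescence distributions are right-skewed, which is also why the
skew-robust 75th percentile, `percentile_summary()`, is the standard
per-culture statistic) as a straight line on the qq plot over the lowest
50% of ordered cells; draw an envelope at the fitted quantile plus
$k\sigma$; take the breakpoint as the first order statistic above which at
least 95% of higher-ranked cells exceed the envelope; and report the
fraction of envelope-exceeding cells above the breakpoint. Counting
exceeding cells rather than the raw suffix length removes the upward bias
the 5% persistence allowance would otherwise introduce (about $+0.05 f$).
The envelope width $k = 2$ and the 50% fit window are repository
calibrations (`scripts/calibrate.R`): across true fractions 0.01–0.2
(1,000 cells, 10-fold component separation, 100 seeded replicates) the
median absolute error stays below 0.01 with no systematic sign bias, and
a half-active sample is still recovered within 0.05.

## Numerical choices

* Exact direct method, no tau-leaping: molecule numbers are tens, not
  thousands, and exactness is cheap at these sizes.
* Binding propensities use `choose(x, n)` exactly (no large-x
  approximation); an all-zero propensity vector terminates the cell early
  and the state is held to `t_end`.
* Window integrals are accumulated during simulation from the exact
  piecewise-constant path, not from sampled time grids.
* Ensemble seeds are derived as `(root + 48271 * cell) mod (2^31 - 1)`,
  keeping every derived seed a valid 32-bit integer.
* Quantiles interpolate between order statistics (R type 7) everywhere.

## Problem sizes

The shipped analyses use 10,000 cells per condition over 100 time units —
a bare-loop ensemble takes on the order of a second, the richest cascade
a few seconds on one core. Unit tests run reduced ensembles
(1,500–5,000 cells) where only direction, not precision, is asserted;
the headline checks in `tests/testthat/test-acceptance.R` use the full
10,000 (or the 5,000-per-point sweep sizes) of the corresponding analyses.

## Known limitations

* No cell growth, division, or partitioning noise: a "cell" is one
  realization of the reaction network over a fixed horizon; the positive
  state is quasi-stable and would decay at infinite time.
* The AlpA repressive branch, InrR modulation and RpoS dependence of the
  native system are deliberately outside the simulated network; BisDC is
  one species, not an explicit BisD + BisC assembly.
* Rate constants are in arbitrary time units; mapping onto wall-clock
  hours would require calibration data the model does not claim.
* The qq estimator assumes the lower half of the sample is pure
  background; active fractions above ~50% violate the fit window and are
  outside its design range.
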