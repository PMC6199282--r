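---
title: "Cooperation on a heterogeneous lattice: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation on a heterogeneous lattice: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`heterogame` simulates the weak prisoner's dilemma on an `L × L` periodic
square lattice with two coupled mechanisms: a *heterogeneous environment*
that contributes to fitness, and *preference selection* of the imitation
target. This vignette is the package's account of the model, the
measurement protocol, the numerical choices, and what the shipped tests do
and do not demonstrate.

```{r setup}
library(heterogame)
```

## The model and its assumptions

Every site holds a strategy (cooperate/defect) and a **quenched**
heterogeneity value `h` drawn once, at initialization, uniformly from the 41
discrete levels `0.0, 0.1, …, 4.0` (both endpoints included — the natural
reading of a uniform grid with spacing 0.1 on `[0, 4]`). `h` is a fixed
personal trait: it never changes within a run, and each replicate draws a
fresh field. The *environment* of a site is the arithmetic mean of its four
von Neumann neighbours' `h`; the site's own `h` is excluded. Fitness is the
affine mixture

$$F_x = (1-u)\,P_x + u\,H_x,$$

where `P_x` is the accumulated weak-PD payoff against the four neighbours
(`R = 1`, `T = b`, `P = S = 0`), recomputed from the instantaneous
configuration at every elementary update — there is no payoff memory.

One elementary update: pick a focal player uniformly at random; draw an
imitation target among its four neighbours with softmax weights
$\Omega_y \propto \exp(\alpha h_y)$; adopt the target's strategy with the
Fermi probability $W = 1/(1+\exp((F_x-F_y)/K))$. One Monte Carlo step (MCS)
is `L²` such updates (random sequential order: each player updates once *on
average*). The candidate set is exactly the four neighbours; the focal
player is never its own candidate.

Assumptions worth making explicit:

* the lattice is degree-regular (`k = 4`, toroidal wrap) — heterogeneity
  enters through `h`, never through the graph;
* `h` is exogenous and static (no coevolution of traits and strategies);
* all-C and all-D are absorbing: imitation dynamics cannot create a
  strategy that is no longer present.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `L` | lattice side (sites) | 100 | `L² = 10⁴` players at reference scale |
| `b` | temptation `T` | 1.1 | `b ≥ 1`; the single dilemma-strength knob |
| `u` | environment weight | 0 | `u = 0` traditional game; `u = 1` purely environmental fitness |
| `alpha` | preference strength | 0 | `α = 0` uniform neighbour choice; effects saturate above ~12 |
| `K` | Fermi noise | 0.1 | the conventional low-noise setting; `1/K` is selection intensity |
| `total_mcs` | scheduled sweeps | 6×10⁴ | |
| `avg_window` | averaging window | 10⁴ | also the stationarity window |
| `stationarity_tol` | stationarity threshold | 10⁻² | strict `<` on the difference of two window means |
| `n_replicates` | independent runs | 40 | quenched disorder makes replicate averaging essential |

All quantities are dimensionless; payoffs, `h` and fitness share one scale
through `K`.

## Measurement protocol

A run executes `total_mcs` sweeps, recording `ρ_c` after each. The
equilibrium value is the mean over the final `avg_window` sweeps. The
stationarity rule compares the means of the last two non-overlapping windows
of length `avg_window`; if they differ by `stationarity_tol` or more, the
run is extended by `extension_block` sweeps and rechecked, up to ten times
(a run that still fails is *flagged*, not errored). Because two windows are
needed, `sim_params()` requires `total_mcs ≥ 2·avg_window`. When an
extension occurs, the equilibrium average is taken over the final window of
the extended trajectory — averaging restarts rather than accumulating, the
simplest rule consistent with "extend and recheck".

Absorbing states short-circuit: once the lattice is uniform the trajectory
is filled as a constant and no further random numbers are drawn.

Ensembles derive per-replicate seeds from the master seed by a deterministic
counter scheme, so results are independent of execution order; sweeps hash
the master seed with each grid point's parameter *values*, so refining a
grid never perturbs existing points.

## Randomness and reproducibility

All randomness — initialization in R and the update kernel in C++ — draws
from R's RNG stream, seeded once per run. The RNG consumption order inside
an elementary update is fixed (focal, target, adoption), and the adoption
draw happens even when focal and target already agree, so the stream
position never depends on the configuration. Consequently a full run is
bit-reproducible from its seed, and one `mcs_sweep()` consumes exactly the
same stream as `L²` single `elementary_step()` calls (a property the test
suite checks directly).

## The oracle

The stochastic kernel is validated against exact calculators
(`exact_flip_probability()`, `exact_one_step_distribution()`) that recompute
payoffs, environments, selection and adoption probabilities in separate
straight-line R code sharing nothing with the C++ kernel. Agreement between
simulated flip frequencies and the closed-form probabilities (within four
binomial standard deviations across hundreds of random small
configurations) is therefore evidence of correctness, not a tautology.

## What the generator emulates — and what it does not

All inputs are synthetic by construction: the model *is* its own data
generator (random half-half strategies, the discrete uniform `h` field).
The defaults encode the reference study conditions; the desk-scale settings
used by the shipped reproductions (`L = 50`, 7000 MCS averaging the last
2000, 5–20 replicates) keep every experiment in the minutes range while
leaving the equilibria at the examined parameter points essentially
unchanged — the test suite's passing therefore demonstrates internal
correctness and reproducibility of the *model*, not anything about
empirical social systems, degree-heterogeneous networks, or time-varying
environments, none of which are represented.

## Numerical choices

* **Softmax stability.** Selection weights are computed as
  `exp(α(h_y − max_z h_z))`; with `α·h` up to `4α` this avoids overflow for
  any admissible `α`.
* **Fermi tails.** `1/(1+exp(Δ/K))` is evaluated directly; IEEE overflow to
  `Inf` yields exactly 0, the correct limit, so no clamping is needed.
* **Ties.** `locate_optimum()` breaks ties toward the smaller parameter
  value; the first maximum wins.
* **Degenerate inputs.** Uniform lattices are recognised before any sweep
  is run; a trajectory shorter than two stationarity windows is a contract
  error rather than a silent `TRUE`.
* **Stationarity at the boundary.** The comparison is strict, so a
  difference exactly equal to the tolerance fails the check.
* **Coordinates.** The R surface is 1-based `(row, col)`; the kernel uses
  0-based column-major linear indices; serialized grids state rows/cols in
  their header.

## Design decisions

* **Environment = neighbours' mean `h`.** The defining verbal rule —
  the environment is the average level of the neighbours' characteristics —
  is adopted; the focal site's own `h` is excluded. The main alternative
  (environment = own `h`) was examined and rejected: it destroys the
  observed low-α structure (the `u`-resonance at `α = 0` overshoots to
  ~0.9 and the optimal-α window collapses to 0).
* **Selection on the neighbour's personal `h`.** Weights use `h_y`, not the
  neighbour's environment `H_y`; preference is for the *individual*, and
  this reading reproduces the optimal-α window.
* **Per-replicate `h` fields.** Quenched disorder is redrawn each replicate
  (switchable via `share_h = TRUE`), which is what makes replicate
  averaging informative.
* **Unconditional adoption draw.** Drawing the adoption uniform even when
  the strategies already agree costs one RNG call and buys stream
  stability.

## Known limitations

* At strong environmental weight (`u ≳ 0.7`) the quenched environment
  differences between neighbours (standard deviation ≈ 0.8 in fitness
  units, i.e. many multiples of `K`) dominate the `(1−u)`-scaled payoff
  differences. Strategy flow then follows the fixed environment gradients
  and the dynamics approach neutral drift: in this implementation the
  cooperation enhancement is maximal at *intermediate* `u` and relaxes
  toward `ρ_c ≈ 0.5` as `u → 1`, rather than increasing monotonically up to
  the `u = 1` boundary.
* The stationarity rule is the protocol's two-window mean comparison only;
  no autocorrelation-time or finite-size-scaling diagnostics are provided.
* Only the 4-neighbour torus is implemented; other graphs, synchronous
  updating, aspiration dynamics and coevolving `h` are out of scope.
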