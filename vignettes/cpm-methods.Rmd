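---
title: "Methods: the Cellular Potts tumor-growth model in cpmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Cellular Potts tumor-growth model in cpmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmsim)
```

## The model

`cpmsim` implements a two-dimensional Cellular Potts
(Glazier–Graner–Hogeweg) model of tumor growth. A lattice of `x * y`
sites carries integer spins; all sites with the same spin σ ≥ 1 form one
cell, and σ = 0 is the extracellular matrix (ECM). Spin parity encodes
the cell class: odd spins are dark (tumor/mutated) cells, even spins
light (normal/healthy) cells. The configuration energy is

$$H = \sum_{\langle i,j\rangle} \left(1 - \delta_{\sigma_i\sigma_j}\right)
      J(\tau_i, \tau_j)
    + \lambda \sum_{\sigma \ge 1} \left(a(\sigma) - A_t(\sigma)\right)^2 .$$

The first term is differential adhesion: every adjacent pair of sites
from *different* cells pays the coefficient of its class pair —
`j_ecm` for any cell–ECM contact, `j_dark` and `j_light` for same-class
cell–cell contacts, `j_mixed` for dark–light contacts; same-cell pairs
(Kronecker δ = 1) and ECM–ECM pairs cost nothing. The second term is
area elasticity: each cell is penalised quadratically for deviating
from its target area, symmetrically above and below. The ECM carries no
target area (its volume term is suppressed), so it acts as a passive
background that cells can invade or retreat into.

Dynamics are Metropolis spin copies. One attempt picks a uniformly
random target site and a uniformly random 4-neighbour (the source); the
target proposes to adopt the source's spin, and the proposal is accepted
with probability 1 if the energy change ΔH ≤ 0 and `exp(-ΔH/T)`
otherwise. One Monte Carlo step (MCS), the time unit, is a fixed number
of attempts (`substeps`).

### Assumptions and conventions the model leaves open

Several details are not fixed by the model's usual statement; the
package pins them down as follows.

* **Neighbourhood and boundaries.** The 4-neighbour (von Neumann) graph
  with non-periodic boundaries: edge sites simply have fewer pairs. This
  is the minimal standard for a square grid; boundary coefficients `J`
  are therefore used exactly as printed, with each unordered pair
  counted once.
* **Copy direction.** The target site adopts the source neighbour's
  spin — the standard GGH convention.
* **Same-spin proposals** are no-ops that still consume one attempt (so
  an MCS is always exactly `substeps` attempts) and draw no acceptance
  uniform.
* **Site sampling** is uniform with replacement rather than a systematic
  sweep, the standard Metropolis choice.
* **Zero and negative temperature.** The acceptance rule is kept exact:
  uphill moves are rejected outright at `T <= 0`, while energy-lowering
  and energy-neutral copies are still accepted. A reading under which
  subzero temperatures freeze *all* spin changes would contradict the
  unconditional ΔH ≤ 0 branch of the acceptance rule; the rule-consistent
  choice is taken and only uphill motion stops.
* **Cell death and fragmentation.** Cell connectivity is not enforced —
  cells may shed loose bricks — and a cell whose area reaches 0 stays
  registered with area 0 (nothing re-seeds it).
* **Growing targets.** `target_growth_rate` adds a fixed increment to
  every cell's target area after each MCS, modelling target volume that
  grows with the cell. No canonical rate exists, so the default is 0
  (static targets) and the knob is explicit.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `x`, `y` | 32, 32 | lattice size in sites |
| `mcs`, `substeps` | 32, 64 | time: MCS count and attempts per MCS |
| `max_sigma` | 2 | number of cells; odd = dark, even = light |
| `matrix_density` | 0.8 | fraction of sites initially cellular |
| `temperature` | 10 | motility factor T of the Metropolis rule |
| `j_ecm`, `j_light`, `j_dark`, `j_mixed` | 16, 15, 2, 11 | adhesion coefficients per class pair |
| `lam` | 0.05 | area elasticity λ (energy per squared brick) |
| `target_area_factor_light/dark` | 0.4, 0.4 | dimensionless target-area factors |
| `dark_light_ratio` | 1/4 | initial dark:light brick ratio r |
| `target_growth_rate` | 0 | per-MCS target-area increment |
| `seed` | 42 | RNG seed |

The defaults are the `"default"` preset, the normative setting of the
original tool. With them the first Hamiltonian term is small relative to
the volume term, `j_dark = 2` makes tumor–tumor contact cheap, and
`j_mixed`/`j_ecm` control how costly heterogeneous contact is — the
lever behind the tumor-suppression effect of raising them. The target
area divides the lattice equally among cells and scales it per class:
`A_t = factor * x * y / max_sigma`; the model only ties A_t to the
lattice size, and equal partition is the simplest rule with the right
scaling. If `mcs * substeps < x * y` the run warns once: with fewer
attempts than sites the dynamics are under-sampled.

Literature presets (`ggh1992`, `ggh1993`, `ouchi2003`,
`rubenstein2008`) are best-effort readings of published settings — the
available tabulation is typographically damaged — so every field a
source does not pin down is filled with the default and listed in the
returned object's `filled_defaults` attribute. Only `"default"` is
normative; raw published target areas are converted to the package's
dimensionless factors.

## Initialization: what the generator emulates

`initialize_lattice()` occupies each site independently with probability
`matrix_density`, classes each occupied site dark with probability
`r/(1+r)` (so the default ratio 1/4 gives 20 % dark among occupied
bricks), and assigns it uniformly to one of its class's spins. With
`max_sigma = 1` only the single dark cell exists. One seeded RNG stream
in a fixed, documented draw order (occupancy, class, dark spins, light
spins, then the dynamics' target/neighbour/acceptance draws) drives the
whole run, making it bit-reproducible.

This scattered initialization emulates mutated cells intermixed with
normal tissue, not a compact spheroid: cells start fragmented and only
acquire contiguous shape through the adhesion dynamics. Consequences
worth knowing:

* Occupancy and class counts are binomial draws, not exact quotas —
  tests and expectations use binomial tolerances (e.g. 819.2 ± 3 SD
  occupied sites at the defaults).
* At low `matrix_density` with the default energies, isolated bricks
  whose four neighbours are ECM dissolve (removing one costs
  `-4 * j_ecm` boundary energy against a small volume penalty), so a
  sparse lattice *shrinks* rather than grows. Simulating growth from a
  small tumor is therefore done by raising the dark target-area factor
  (below), not by lowering density.
* Real tumors have vasculature, nutrient gradients, cell division as a
  discrete event, and mechanics none of which is modelled; passing tests
  show the lattice model's internal consistency and qualitative
  parameter responses, not quantitative agreement with any tissue.

## Growth trajectories and the Gompertz law

Trajectories record per-spin and per-class brick counts after
initialization (step 0) and after every MCS. `fit_gompertz()` fits the
decelerating growth law in ratio form,

$$V_t/V_0 = \exp\!\left(\tfrac{a}{b}\left(1 - e^{-bt}\right)\right),$$

to a count series normalized by its first value: `a` (> 0, per MCS) is
the initial specific growth rate, `b` (> 0, per MCS) the deceleration
constant, and `exp(a/b)` the plateau. A commonly printed variant of
this law with the deceleration constant inside a reciprocal,
`exp(a / (b (1 - e^{-at})))`, diverges at t = 0 and does not decelerate;
the package deliberately uses the standard bounded form above.

Numerical choices: the fit is unweighted least squares on the ratio
scale via Levenberg–Marquardt (`minpack.lm::nlsLM`) with positivity
bounds at 1e-9, starting values from the initial log-slope and the
plateau `log(max(y))`; if that fails, a 25×25 log-spaced grid search
plus `L-BFGS-B` refinement takes over. R² is 1 − SS_res/SS_tot; for a
perfectly flat series both sums vanish and R² is reported as 1 (the
degenerate fit with a at its lower bound is flat and exact). Fit
failures and degenerate inputs (short series, zero first value) return a
flagged `converged = FALSE` object instead of an error, so sweeps never
abort mid-batch.

**The tumor-growth study condition.** The package's canonical growth
run is the defaults with `target_area_factor_dark = 1.2` and `mcs = 64`:
the dark cell starts around 164 bricks against a target of 614.4 — far
below target — and grows toward it with a decelerating, Gompertz-like
trajectory (median R² ≈ 0.99 over seeds 1–10; the suite asserts ≥ 0.9).
Sixty-four MCS suffices for the curve to visibly saturate on a 32×32
lattice. The R² threshold is a package-level choice of what "follows the
trend" means, not a universal constant.

## Directional parameter effects

Three qualitative behaviors are asserted over 20 seeds each at otherwise
default settings (20 chosen up front to stabilise the small T = 0 vs
T = 10 contrast):

* mean final cellular brick count is non-decreasing in
  T ∈ {0, 10, 20, 80} — temperature as motility;
* mean final |area − A_t| is smaller at λ = 1 than at λ = 0.01 —
  elasticity pins cells to their targets;
* raising `j_mixed` and `j_ecm` to 100 lowers the mean final dark/light
  ratio below the default-parameter value — costly heterogeneous
  contacts suppress the tumor class.

These are directions, not effect sizes: the underlying panel values were
never published numerically, and single unseeded runs (such as a
once-printed 39 → 465 brick growth of one cell) are one random draw, not
a reproducible target — the suite asserts exactly that seed-dependence.

## Problem sizes and runtime

All routine tests run on 32×32 lattices with 32–64 MCS of 64 substeps
(2 048–4 096 attempts per run, well above the x·y under-sampling
threshold); the oracle-equivalence check compares incremental against
fully recomputed energies on 8×8 lattices over 1 000 proposals. At these
sizes a full seeded run takes well under a second in pure R, and the
whole suite a few tens of seconds. The energy of a proposal is computed
incrementally (only the four pairs touching the target site and the two
affected cells' volume terms), which is what makes the Metropolis loop
linear in attempts rather than in lattice area.

## Exports

CSV trajectories carry step, per-spin counts, class totals, the
dark/light ratio (empty field where no light bricks exist), and
acceptance bookkeeping; re-parsing reproduces the counts exactly. The
graph-elements JSON document has one node per site with id `"x_y"`
(0-based column/row), fixed-pitch pixel positions, hex color, spin,
class and parent-cell key — the structure a grid-layout graph renderer
consumes; interactive-UI attributes (selection state, neighbour lists)
are deliberately omitted. PNG snapshots use the same versioned palette
(grey ECM; dark red / light blue for two cells; deterministic
red–purple and blue–green ramps for more), so identical states render
byte-identical files.

## Known limitations

2D only; no chemotaxis, haptotaxis, diffusing fields or explicit
division/migration operators; a single global J per class pair (no
per-cell or dark–ECM vs light–ECM split); cells are not kept connected;
the ECM cannot grow unless given a target area; and pure-R dynamics make
very large lattices (say 500×500 with substeps = x·y) slow — the
literature presets at that scale are provided for completeness, not
routine use.
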