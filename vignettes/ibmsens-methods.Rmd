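---
title: "Methods: sensitivity, stability and calibration analysis of individual-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitivity, stability and calibration analysis of individual-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmsens)
```

## The problem

A stochastic individual-based model (IbM) maps a vector of $k$ input factors
to one or more response variables, $y = f(x_1, \dots, x_k) + \varepsilon$,
where $\varepsilon$ is the run-to-run variability the model introduces by
design. Three practical questions recur for every such model:

1. **How many replications** are needed before an output's dispersion is
   estimated reliably? (stability analysis)
2. **Which factors matter** for a given output, and do they act linearly,
   nonmonotonically, or through interactions? (screening and
   variance-decomposition sensitivity analysis)
3. **Which parameter values** best reproduce a reference observation?
   (calibration)

`ibmsens` answers these with native implementations of Morris
elementary-effects screening, Sobol variance decomposition,
coefficient-of-variation convergence tracking, and sampling-based
calibration, plus the experimental-design and seeded-execution machinery
they need. Two bundled biological simulators — a wolf–sheep–grass
predator–prey model and a bacterial conjugation model in which a cheater
plasmid exploits a co-resident plasmid's type IV secretion system (T4SS) —
are first-class test subjects, and a set of analytic fixtures with known
variance decompositions serve as oracles.

## The model contract and seeded execution

A model is an `sa_model`: a declared parameter list (queryable before any
run), and a `setup(params)` closure returning an instance whose
`run(ticks)` yields a tick-indexed data frame of named numeric outputs. All
stochasticity must flow from R's RNG; the engine calls `set.seed()` with a
per-replication seed immediately before `setup()`, so identical
`(params, seed, ticks)` always reproduce the series exactly — across
processes and platforms.

Per-replication seeds derive from a single master seed through a 3-round
bijective 31-bit linear-congruential mix of `(master_seed, counter)`
(`derive_seeds()`). Bijectivity guarantees distinctness; the derivation is
frozen so results remain reproducible across releases. `run_experiment()`
executes design-major, replication-minor and returns the result triple:
`paramset` (one row per design point), `output` (one row per design point
× replication, holding the objective's named scalars), and `dataset` (all
tick-level series concatenated).

The objective function is evaluated **once per replication**, and the
sensitivity methods consume the per-design-point *mean* over replications.
This targets the expected response $\eta = E(y)$ while keeping replicate
dispersion available for the stability module. Evaluating on pooled series
instead would entangle within-run and between-run variability; the
per-replication choice is deliberate and documented here because either
convention is defensible.

## Experimental designs

Designs are generated on the unit cube and mapped affinely onto the
declared physical ranges; both images are kept, because sensitivity
measures are computed in unit-cube coordinates so that factors with
different physical units stay comparable.

* **Random**: i.i.d. uniform points.
* **Latin hypercube** (via the `lhs` package): exactly one point per
  equal-probability stratum per factor, placed uniformly within its
  stratum, with independent stratum-to-row permutations per factor.
* **Full factorial**: the Cartesian product of evenly spaced per-factor
  grids, endpoints included (declared ranges are inclusive bounds).

Only uniform marginals are supported: all bundled workflows declare plain
ranges, and non-uniform priors or correlated sampling would complicate the
sensitivity estimators' assumptions without serving the bundled models.
Parameters whose default is stored as an R integer (e.g. initial population
sizes) are swept on the continuous scale and rounded half-up only when the
parameter set is built, so the analysis operates on a continuous cube while
the emitted parameter table records exactly what the model received.

## Morris elementary-effects screening

The region of experimentation is a $p$-level grid on the unit cube. The
step is $\Delta = p/(2(p-1))$ (recommended with even $p$) or the
alternative $\Delta = 1/(p-1)$; the default mode (`"auto"`) picks the
standard step for even $p$ and the alternative step for odd $p$, since the
standard formula is defined only for even level counts. Each of $r$
trajectories visits $k+1$ points: per factor, a transition pair
$\{x, x+\Delta\}$ with $x$ uniform on the sub-grid where $x + \Delta \le
1$, traversed in a random direction, factors in random order. This weights
every feasible transition equally — an earlier construction that chose
directions by feasibility alone over-weighted grid-edge transitions and
biased $\mu$ on periodic responses, which is why the orientation scheme is
used.

For the transition where factor $i$ moved,
$ee_i = (y(\text{upper}) - y(\text{lower})) / \Delta$, "upper" being the
point with the larger $i$-th coordinate, making the estimate independent of
walk direction. The metrics per factor are $\mu$ (mean signed effect),
$\mu^*$ (mean absolute effect, robust to sign cancellation) and $\sigma$
(dispersion, **divisor $r$** — the population form; a `sigma_divisor`
option switches to $r-1$ for compatibility with toolkits that use the
sample form). Interpretation: large $\mu^*$ ranks importance; $\sigma$
flags interactions or nonlinearity; $\mu^* \gg |\mu|$ signals a
nonmonotone response. Note that the *standard* step can be structurally
blind to periodic nonmonotonicity — for $\sin(2\pi x)$ with $p = 8$ the
standard $\Delta = 4/7$ spans more than half the period and every
elementary effect shares one sign — which is precisely the situation the
alternative step exists for.

For affine responses the method is exact: $\mu = \mu^*$ equals the
unit-cube slope and $\sigma = 0$ to machine precision, for every $p$, $r$
and seed; the test suite asserts this.

## Sobol variance decomposition

First-order indices $S_i = V_i / V(Y)$ measure the output-variance fraction
attributable to factor $i$ alone; total-order indices $S_{Ti}$ include all
interactions involving $i$. Sampling uses the A/B/AB$_i$ scheme: two
independent $N \times k$ matrices and the $k$ hybrids, $N(k+2)$ evaluations
in total. Estimators:

* $V(Y)$: sample variance of the pooled $f_A \cup f_B$ (divisor $2N-1$) —
  all non-hybrid points, documented so cross-checks can match.
* $V_i = \frac{1}{N}\sum_j f_{B,j}(f_{AB_i,j} - f_{A,j})$ (Saltelli 2010).
* $V(Y) - V_{-i} = \frac{1}{2N}\sum_j (f_{A,j} - f_{AB_i,j})^2$ (Jansen).

This pairing is the standard low-variance choice for this sampling scheme.
Outputs are centred by the pooled mean before estimation — unbiased, and it
sharply reduces the first-order estimator's Monte Carlo variance when
$E[Y]$ is far from zero. Even so, the Saltelli first-order estimator
carries noticeable noise (for a single active uniform factor its standard
deviation is ≈ 0.027 at $N = 4096$), which is why the tests use absolute
bands of 0.03–0.05 at $N = 8192$.

At small $N$, index estimates can come out slightly negative. They are
**reported unclamped with a warning**: a negative estimate is a useful
diagnostic that the sample size is too small, and clamping would hide it.
Optional bootstrap confidence intervals (resampling the $N$ rows of
A/B/AB$_i$ jointly) support interpreting small-$N$ runs. Constant output is
a degenerate case and raises a classed error rather than returning 0/0.

The estimators are validated against closed forms: the Ishigami function
($V(Y) = a^2/8 + b\pi^4/5 + b^2\pi^8/18 + 1/2$, $V_1 = (1+b\pi^4/5)^2/2$,
$V_2 = a^2/8$, $V_3 = 0$, $V_{13} = b^2\pi^8(1/18 - 1/50)$ — confirmed
against brute-force Monte Carlo before the estimators were built), the
additive linear fixture ($S_i = c_i^2/\sum c_j^2$), and the interacting
product fixture ($f = x_1 x_2$: $V(Y) = 7/144$, $V_1 = V_2 = 1/48$,
$V_{12} = 1/144$).

## Stability: how many replications?

For each of $s$ Latin-hypercube-sampled parameter sets, `r_max` seeded
replications are simulated **once**, and the coefficient of variation
(sample sd, divisor $n-1$, over the absolute mean) of every monitored
output is computed over the first $n$ replications at each checkpoint
$n \in \{5, 10, \dots, r_{max}\}$. Prefix reuse makes the curves
self-consistent — the CV at checkpoint $n$ depends only on the first $n$
seeds — and avoids re-simulation. Outputs whose prefix mean is zero (e.g.
a co-infection count that never fires under a given parameter set) have no
defined CV and are recorded as `NA`.

Convergence is declared at the smallest checkpoint beginning a run of
`window` (default 2) consecutive transitions whose successive CV changes
are all within `tol` (default 0.01, absolute). The original eyeball
criterion ("the CV stops varying") is replaced by this explicit rule so
the recommended replication count is reproducible. Defaults
(`r_max = 100`, checkpoints every 5, per-replication objective scalars or
time-averaged raw outputs) fit the bundled models; `tol` should scale with
the CV magnitude of interest.

## Calibration

The objective-function contract: one or more named non-negative scalars,
zero for a perfect fit, smaller is better. Building blocks:

* `categorical_cost(y, range)`: 0 iff `lower <= y <= upper` (inclusive),
  else 1 — the classic acceptance-interval criterion (e.g. a net
  reproductive rate accepted in [0.8, 1.2]).
* `nrmsd(sim, ref)`: RMSE over the reference range `max(ref) - min(ref)`.
  The range normalizer (not the mean) stays well defined when the
  reference crosses zero.
* `distance_cost(..., metric)`: `nrmsd`, `rmse` or `sse`; all satisfy the
  distance axioms (zero iff equal, positive otherwise).

`easy_calibration()` is pure sampling, not iterative optimisation: an LHS
design of `n_samples` points, `replications` seeded runs each, mean cost
per point, ascending rank. Multiple cost scalars are combined by their
unweighted sum for ranking (per-scalar costs are retained in the table);
ties keep design order. With 200 LHS samples over a 1-D range, the best
point lands within 0.5% of the range of the optimum of a smooth objective
with high probability — the tests assert this on a linear fixture.

## The predator–prey simulator

Wolves and sheep on a 50 × 50 periodic continuous space; grass on the
underlying unit grid. Declared parameters (defaults in parentheses):
initial populations (50 wolves, 100 sheep), energy gains from food (wolf
20, sheep 4), reproduction percentages per tick (wolf 5, sheep 4), and the
grass regrowth time (30 ticks). Each tick: every animal turns to a uniform
random heading, advances one unit, wraps, and pays one energy unit; one
sheep per grown patch (random order) grazes (+gain; the patch restarts its
regrowth countdown); in each unit patch the first min(wolves, sheep)
wolves each eat one distinct random sheep (+gain); animals reproduce with
probability rate/100, splitting energy evenly with the offspring; energy
≤ 0 is death. Initial energies are uniform on [0, 2 × gain] and half the
patches start grown — the classic wolf–sheep-predation conventions, adopted
because the narrative description leaves movement cost, initial energy and
reproduction mechanics open.

Scheduling is phase-synchronous (all move, graze, predation, reproduction,
death, regrowth) with randomised within-phase order wherever animals
contend for a resource. A strictly per-agent interleaving would differ
only in which individual wins a contested patch within a tick — a
different sample from the same distribution — while the phase form
vectorises, which is what makes thousand-run screening studies practical
in pure R. The companion `lv_reference()` integrates the mean-field
Lotka–Volterra system $dx/dt = c_1 x - c_3 x y$, $dy/dt = c_2 y + c_4 x y$
(predator decay rate $c_2 < 0$) with fixed-step 4th-order Runge–Kutta via
`deSolve`; tests verify the decoupled exponential limit, the algebraic
equilibrium, and conservation of the first integral
$H = c_4 x + c_2 \ln x + c_3 y - c_1 \ln y$ over a full orbit.

## The T4SS common-pool simulator

Bacterial cells on a 100 × 100 μm periodic lattice (continuous positions,
overlap allowed, no death). Plasmid P1 carries the conjugation genes;
cheater P2 has lost them and can only move horizontally through a
co-resident P1's machinery. Biological parameters: `doublingTime` (min,
plasmid-free; default 40), `p1P` (probability a cell conjugates at least
once per cycle; 0.25), `p1Cost`, `p2Cost` (fractional growth penalties;
0.1, 0.05). Per tick (1 min): a cell takes up to `uptake` (1) nutrient
particles from its lattice site (shuffled order; counts only decrease);
grows as $m \leftarrow m \exp(\phi \ln 2 / G_\mathrm{eff})$ with $\phi$
the uptake fraction and $G_\mathrm{eff} = \texttt{doublingTime}(1 + p_1
c_1 + p_2 c_2)$, capped at its division mass; divides at its division mass
into two half-mass cells that inherit both plasmid states, redraw division
masses from a normal deviate (mean 1, sd 0.05, truncated at ±3 sd by
rejection), displace the daughter 0.5 μm, and reset conjugation flags.

Conjugation gates on carrying P1 **and** mass ≥ 70% of division mass
(inclusive). "Conjugates at least once per cycle with probability `p1P`"
is realised literally: a single Bernoulli draw at first eligibility per
cycle; while pending, the donor tries one random cell within 1.5 μm each
tick until a transfer lands or it divides. A donor carrying both plasmids
transfers P1 or P2 with equal probability (the `hijack` knob makes the
cheater's share of the shared apparatus configurable); the recipient gains
the transferred plasmid, the donor keeps its copy, and states never
revert.

Initialization places the founders (default 50; 10% P1-only, 10% P2-only)
in a central inoculum square (default 20 μm side). This matters: scattered
lattice-wide, microcolonies never touch and conjugation is structurally
impossible, silencing `p1P` entirely. The nutrient budget (100
particles/site) and uptake quantum were chosen once so a colony grows
roughly 4–10× over 100 min and sustains donor–recipient contact; all
initialization knobs are declared parameters, overridable from a config.

## What the bundled models do and do not show

The analytic fixtures validate the estimators against exact decompositions;
the simulators exercise the full pipeline under realistic stochasticity.
Passing tests demonstrate correctness of the designs, estimators and
plumbing — not that any particular biological conclusion transfers to real
organisms. The predator–prey model omits age structure, satiation and
directed movement; the conjugation model omits cell death, segregational
plasmid loss, repression, pili-count state and mechanical shoving. Both
are standard teaching-scale abstractions, bundled as honest, well-specified
test subjects for the analysis methods.

## Numerical choices and problem sizes

* Sensitivity mathematics operates on the unit cube; physical and unit
  images interconvert exactly under the affine map.
* Sobol oracle checks run at $N = 8192$ (40,960 evaluations, seconds for
  analytic fixtures); the T4SS workflow ships at $N = 64$ with 2
  replications of 100 ticks, a desk-scale setting where slightly negative
  indices are expected and reported as such.
* The screening workflow on the predator–prey model uses the worked
  settings $p = 5$, $r = 10$ (80 design points), 2 replications of 200
  ticks; the replication-stability demonstration uses 5 parameter sets ×
  50 replications × 100 ticks.
* Stability checkpoints default to every 5 replications with `tol` 0.01
  and `window` 2.
* Degenerate inputs raise classed errors (`ibmsens_*`) rather than
  propagating NaN: constant Sobol output, constant NRMSD reference,
  zero-mean CV (curve rows become `NA`), empty factor tables, duplicate
  factors, degenerate ranges.

## Known limitations

* Uniform marginals only; no correlated factors, non-uniform priors or
  quasi-random (low-discrepancy) Sobol sequences.
* No second-order index estimation beyond the total-order aggregate; no
  FAST or metamodel-based methods.
* No optimized trajectory selection (spread-maximizing subset search) or
  factor groups in the Morris module.
* Calibration is pure sampling; no gradient, evolutionary or Bayesian
  search.
* Execution is single-process; determinism is a contract, so any future
  parallelism must preserve the design-major, replication-minor seeding.
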