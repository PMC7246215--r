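---
title: "An eco-evolutionary model of plant, wild pollinator and managed honey bee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-evolutionary model of plant, wild pollinator and managed honey bee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beevolve)
```

## The model

`beevolve` simulates a minimal pollination network: one plant species, its
coevolved wild pollinator, and a managed honey bee introduced on top of the
resident mutualism. All three species are facultative mutualists — the
plant can self-pollinate and the pollinators have alternative resources —
so each grows logistically on its own and gains extra fitness through the
interaction. Time is discrete (think day-to-day foraging cycles), and the
state carries eight variables: plant abundance $P_t$, a standing pool of
pollination rewards $X_t$ (nectar/pollen), pollinator abundances $N_{1,t}$
(wild) and $N_{2,t}$ (honey bee), two plant attraction traits $u_{1,t},
u_{2,t}$ (one per pollinator), and two pollinator investment traits
$v_{1,t}, v_{2,t}$.

Visitation couples the species. Pollinator $i$ visits each plant at rate

$$a_i = \frac{\ln(v_{i,t} + d_i u_{i,t} + 1)}{a_{0i} + P_t},$$

increasing (with diminishing returns) in both partners' traits and
decreasing in plant density: with more plants, any individual plant is less
likely to receive a visit, with half-saturation constant $a_{0i}$.

The abundance maps are Ricker-type:

$$P_{t+1} = P_t \exp\!\Big[r_P - \tfrac{r_P}{b_P} P_t
  + \theta_{P1} a_1 N_{1,t} + \theta_{P2} a_2 N_{2,t}\Big],$$
$$X_{t+1} = r_X P_t + X_t e^{-(a_1 N_{1,t} + a_2 N_{2,t})},$$
$$N_{i,t+1} = N_{i,t} \exp\!\Big[r_i - \tfrac{r_i}{b_i}(N_{i,t} + c_i N_{j,t})
  + \theta_i a_i X_t\Big],$$

where $j$ is the other pollinator. Rewards are produced at rate $r_X$ per
plant and the fraction $e^{-\sum_i a_i N_{i,t}}$ escapes consumption.
The competition term $(N_i + c_i N_j)/b_i$ groups interspecific competition
inside the density-dependent bracket; this grouping is the one consistent
with the analytic selection gradients below.

Every trait is costly: carrying capacities decline linearly with
investment, $b_P = k_P - f_{P1}u_1 - f_{P2}u_2$ and $b_i = k_i - f_i v_i$.
Without this cost, plant--pollinator feedback produces runaway selection
and unbounded growth.

## Trait evolution

Traits follow a simplified quantitative-genetics recursion: per step, each
trait moves by its genetic variance times the selection gradient of
per-capita log fitness,

$$u_{i,t+1} = u_{i,t} + \sigma_{Pi}^2 \,
  \frac{\partial \log W_P}{\partial u_i}, \qquad
v_{i,t+1} = v_{i,t} + \sigma_i^2 \,
  \frac{\partial \log W_{Ni}}{\partial v_i},$$

with the gradients available in closed form:

$$\frac{\partial \log W_P}{\partial u_i} =
  -\frac{r_P P_t f_{Pi}}{b_P^2}
  + \frac{\theta_{Pi} N_{i,t} d_i}{(v_i + d_i u_i + 1)(a_{0i} + P_t)},$$
$$\frac{\partial \log W_{Ni}}{\partial v_i} =
  -\frac{r_i (N_{i,t} + c_i N_{j,t}) f_i}{b_i^2}
  + \frac{\theta_i X_t}{(v_i + d_i u_i + 1)(a_{0i} + P_t)}.$$

The benefit half of each plant gradient scales with the abundance of the
associated pollinator — this is the engine of the model's headline result:
as the honey bee becomes the more abundant partner, selection moves plant
investment from $u_1$ to $u_2$, which further disadvantages the wild
pollinator. The test suite verifies all four analytic gradients against
central finite differences of the log-fitness functions (relative error
below $10^{-5}$ over 1,000 random admissible states and parameter sets),
so the trait maps are exactly the derivative of the ecological maps they
accompany.

## Parameters and defaults

`bv_params()` carries the standard values used throughout (dimensionless
units; one step is the model's generation/foraging cycle):

```{r}
unlist(bv_params())
```

Notable defaults: the plant benefits twice as much per wild-pollinator
visit as per honey bee visit ($\theta_{P1} = 0.5 > \theta_{P2} = 0.25$,
honey bees being less effective per-visit pollinators), competition is
symmetric at $c_1 = c_2 = 0.75$, and the pollinators are otherwise
identical. Growth rates of $0.01$ make the ecological dynamics slow, which
is why the standard protocols run for $2\times10^5$ steps.

One tabulated ambiguity: the genetic-variability constants are labelled as
variances with value $0.05$, while the recursion uses $\sigma^2$. The
package feeds $0.05$ in directly as the variance; `bv_params(sigma_is =
"sd")` squares it instead for sensitivity checks.

## Simulation protocols

Two introduction protocols are built in:

* **Burn-in / invasion** (`bv_protocol()` + `bv_invasion()`): the plant
  and wild pollinator coevolve alone (default budget 200,000 steps; the
  equilibrium detector usually stops the phase much earlier), then the
  honey bee is introduced at the wild pollinator's equilibrium abundance
  with small trait values ($v_2 = u_2 = 0.001$) and the full system runs
  up to 800,000 further steps. Phase-1 traits start at double the
  introduction values. With `bv_flags(plant_evolves = FALSE)` the plant
  traits are frozen at their two-species equilibrium for phase 2, which
  isolates the contribution of plant evolution to displacement; the
  pollinators keep evolving in that mode.
* **Simultaneous introduction** (used by `bv_sweep()` presets): plant and
  wild pollinator start at abundance $0.05$ with traits $0.005$, the honey
  bee enters after 2,000 steps at the same abundance and trait value, and
  the run lasts 200,000 steps in total.

Terminal states are classified by an extinction threshold of $10^{-6}$:
the Ricker map never reaches zero exactly, so a species below threshold at
equilibrium counts as displaced. The threshold affects classification
only, never the dynamics. Labels are `coexistence`, `wild_only`,
`honeybee_only`, `plant_only`, `collapse` and `unbounded`.

`bv_sweep()` runs one independent simulation per grid value (41 points by
default) — each grid point restarts from the same protocol, so sweeps
measure the attractor reached from a fixed introduction, not hysteresis.
`bv_find_threshold()` refines a regime boundary by bisection on the regime
label and reports the midpoint of the final bracket.

### Scenario presets

The `fig4_*`/`fig5_*` presets encode three displacement mechanisms:
(1) a per-capita competitive advantage for the honey bee ($c_1 = 0.95$,
$c_2 = 0.75$; a variant with $c_1 = 1$ is kept as `fig4_s1_text` because
both values are in circulation for this scenario), (2) a carrying-capacity
advantage ($k_2 = 1.75$), and (3) a per-visit benefit advantage
($\theta_1 = 0.005$, $\theta_2 = 0.075$; this override applies inside the
scenario only). Swept against these are the honey bee's own trait cost
$f_2$ and the plant-side cost of attracting honey bees $f_{P2}$. The
default sweep ranges for the cost parameters — $f_2 \in [0.25, 4]\,f_1$
and $f_{P2} \in [0.25, 10]\,f_{P1}$ — are the package's own choice of a
wide multiplicative neighbourhood around the wild-side costs, chosen so
that both the cheap-honey-bee and expensive-honey-bee extremes are
covered; the remaining sweep ranges are the standard ones
($c_1 \in [0.25, 2]\,c_2$, $k_2 \in [0.5, 2]\,k_1$,
$\theta_2 \in [0.5, 4]\,\theta_1$).

## Numerical choices

* **Synchronous update.** All eight $t+1$ quantities are computed from
  time-$t$ values; in particular the trait updates use pre-step
  abundances. No update ordering is imposed beyond this.
* **Trait clamping.** After each trait update, traits are clamped to
  $[0, (k - \varepsilon)/f]$ with $\varepsilon = 10^{-6}$ so carrying
  capacities stay positive and the visitation logarithm's argument stays
  $\ge 1$. The two plant traits share one carrying capacity, so if their
  joint cost still exceeds $k_P - \varepsilon$ both are scaled back
  proportionally. Negative traits or capacities are biologically
  meaningless and would break the map.
* **Equilibrium detection.** A run stops early when the largest relative
  change of any state variable over a trailing 1,000-step window drops
  below $10^{-10}$, with the denominator floored at $10^{-9}$ so that a
  species decaying exponentially toward extinction can still register as
  converged. Otherwise the run ends at the step budget and is flagged not
  converged; summaries always use the exact terminal state, never a
  strided sample.
* **Runaway guard.** If any abundance exceeds $10^{9}$ the run aborts
  with regime `unbounded`. This regime is reachable, e.g. for large honey
  bee carrying capacities, where the plant--honey bee feedback loses
  density dependence.
* **Storage.** Long runs record every 100th state (every state for runs
  of $\le 10^5$ steps) to bound memory; the exact final state is always
  appended.
* **Determinism.** The model has no stochastic component; identical
  configurations produce byte-identical outputs. The compiled inner loop
  (C++) mirrors the exported R step function bit for bit, and a test
  holds them to $10^{-12}$ relative agreement over hundreds of steps.

## What the simulations do and do not show

The simulator reproduces the deterministic mean-field dynamics of an
isolated three-species module. It does not model stochastic demography or
genetic drift, phenotypic plasticity, genetic correlations between the two
plant traits, spatial structure, or networks larger than one plant and two
pollinators — all of which matter for real plant--pollinator communities.
Passing tests therefore establish that the maps, gradients and protocols
are implemented correctly and that the model's qualitative regimes
(displacement, coexistence, cost-mediated rescue, unbounded growth) arise
under the documented parameter sets; they do not validate the model
against field data.

Two structural caveats worth knowing. Without any pollinator the reward
pool has no sink and grows linearly — rewards only equilibrate when
something consumes them. And equilibrium rewards need not vary
monotonically with a swept parameter all the way to the range extremes;
the package asserts reward monotonicity strictly in its acceptance checks
and reports the outcome as measured rather than smoothing over it.

## Problem sizes

The standard runs used by the tests and the acceptance script are:
200,000-step sweeps at 41 grid points, a burn-in/invasion budget of
200,000 + 800,000 steps, $10^6$-step logistic-limit checks, and 1,000-case
gradient verification. With the compiled loop a 200,000-step run takes a
few milliseconds, so the full suite is cheap to re-run.
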