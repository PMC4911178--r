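---
title: "Modelling nuclear clustering in the syncytiotrophoblast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nuclear clustering in the syncytiotrophoblast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(syncytia)
```

## The biological question

The syncytiotrophoblast — the multinucleated epithelial surface of the
placental villus — accumulates dense groups of nuclei: syncytial nuclear
aggregates (SNAs) in tissue, and their in vitro counterparts, syncytial
nuclear clusters (SNCs). Whether these groups are built by active,
cytoskeleton-driven nuclear transport or can arise passively is the question
this package's model addresses. It implements a deliberately minimal physical
null model: nuclei are inert Brownian particles with short-range adhesion,
confined to a thin corrugated strip representing a cross-section of the
syncytial layer. If passive diffusion plus contact adhesion reproduces the
qualitative phenomenology of cluster formation, active transport is not
required to explain it.

The package also implements the measurement side: the morphometric rules
used to score SNCs, SNAs, large syncytia, internuclear distances,
cytoplasmic area per nucleus and shed-particle censuses on micron-unit
point patterns, together with ground-truthed synthetic generators so every
rule is testable without any imaging data.

## The model

All lengths are measured in nuclear diameters; nuclei are unit discs.

**Domain.** A strip of length $L = 250$ with a flat lower boundary $y = 0$
and corrugated upper boundary $y = T + A\,h(x)$, with mean thickness
$T = 1.5$. The roughness $h$ is a natural cubic spline through knots
sampled every 2.5 diameters from a stationary Ornstein–Uhlenbeck process,
using the exact Gaussian transition density, so stationarity is exact and
testable. The stationary SD is 0.25 diameters: by the three-sigma rule the
variation stays within $\pm 0.75$ diameters with 99.7% confidence, so the
channel never closes entirely at the default amplitude $A = 1$. The OU
reversion rate defaults to $0.2$ per diameter (correlation length 5
diameters — boundary ripples a few nuclei wide); this choice is not
prescribed by the biology and sweeps of $A$ are insensitive to it in
expectation.

**Interactions.** The pair potential in centre distance $x$ is
piecewise quadratic:

$$
V(x) = \begin{cases}
k_{\mathrm{rep}}(1-x)^2 - S, & x < 1\\[2pt]
-S\,\bigl(1 - (x-1)/R\bigr)^2, & 1 \le x < 1 + R\\[2pt]
0, & x \ge 1 + R
\end{cases}
$$

with shell width $R = 0.05$, stickiness $S$, and $k_{\mathrm{rep}} = 100$
so the core dominates adhesion (near-hard discs). $V$ is continuous; its
derivative has a kink at contact, which is immaterial because only the
three regimes — strong repulsion on overlap, weak adhesion in the shell,
nothing beyond $1+R$ — are meaningful. Membranes act on any nucleus whose
boundary clearance drops below the radius $0.5$, with the same harmonic
stiffness; clearance to the upper profile is measured vertically, a valid
approximation for a profile bounded by 0.75 diameters of variation over a
250-diameter domain.

**Dynamics.** Overdamped Brownian motion with unit mobility,
Euler–Maruyama integrated:
$\Delta x_i = F_i\,\Delta t + \sqrt{2D\,\Delta t}\,\xi_i$. Time units are
fixed by the unit mobility, so the diffusion constant $D$ is the only
kinetic scale. Nuclei either all start in place (non-overlapping rejection
placement) or are injected at uniformly spaced arrival times over the
first half of the run at "fusion sites" drawn from
$\mathcal N(L/2, \sigma^2)$ ($\sigma = 0$ or $\infty$ means uniform).

**Cluster census.** At the end point (and at snapshot times) two nuclei
are connected when their centres are within $1 + R$; clusters are the
connected components, found by an iterative depth-first search. The
headline metric is the mass-weighted mean cluster size
$\sum_c s_c^2 / N$ — the expected size of the cluster containing a
randomly chosen nucleus — with singletons included; the unweighted mean is
also exported.

## Parameter defaults and numerical resolution

The adhesive well relaxes at rate $\kappa = 2S/R^2$. An explicit integrator
resolves sticking only if $\kappa\,\Delta t < 1$; beyond
$\kappa\,\Delta t \approx 1$ a bound pair overshoots the 0.05-wide shell
each step and adhesion is effectively destroyed. The defaults were chosen
from this constraint *a priori*:

| parameter | default | rationale |
|---|---|---|
| $\Delta t$ | $5\times10^{-4}$ | $\kappa\,\Delta t = 0.8$ at the default $S$ |
| $S$ | 2 | deepest well still resolved at this $\Delta t$ |
| $D$ | 0.125 | $S/D = 16$: strong sticking; run-length diffusion $\sqrt{2Dt_{\mathrm{end}}} \approx 3.5$ diameters |
| $t_{\mathrm{end}}$ | 50 | long enough for multi-nucleus clusters to accrete |
| $n$ | 140 | 29.4% area fraction of the $250 \times 1.5$ strip |

With these defaults the number of clusters of more than six nuclei grows
steadily over a run, the behaviour the model is meant to exhibit.

## The four scenario sweeps

Each scenario varies one knob with 50 replicates per grid value (the
full-scale protocol uses 500; 50 keeps a complete four-scenario sweep
around ten minutes on one CPU, and the conclusions asserted by the test
suite are trends over aggregated means, not absolute values).

* **Adhesion** ($S \in \{0.25, 0.5, 1, 2\}$): mean cluster size increases
  monotonically with stickiness. The grid stays inside the resolved-well
  regime; at fixed $\Delta t$, larger $S$ values cross into the
  under-resolved regime where measured clustering would *drop* — a
  numerical artefact, not model behaviour, so it is excluded from the
  default grid.
* **Diffusion** ($D$ over two decades, $S$ co-varied as $S = S_0 D/D_0$ to
  hold the dimensionless well depth $S/D$ fixed): in continuous time this
  covariation is an exact time-rescaling — the run at $(cD_0, S_0 c)$
  equals the base run viewed at effective time $c\,t_{\mathrm{end}}$ — so
  the low-$D$ side of the curve rises simply because slow nuclei have not
  yet finished clustering. At the high-$D$ end the fixed step size takes
  over: the per-step RMS displacement $\sqrt{2D\Delta t}$ exceeds the
  shell width and pairs unstick. The net result is the interior maximum:
  movement first promotes collisions, then breaks contacts — the same
  mechanism described for the biological model.
* **Fusion sites** ($\sigma \in \{10, 25, 50, 100, \infty\}$, staged
  injection): focused fusion deposits nuclei near $L/2$, and clustering
  increases as $\sigma$ falls. Two grid choices matter. First, this
  scenario runs in staged-injection mode: with all-at-start placement a
  tight focus is geometrically infeasible (140 non-overlapping discs
  cannot fit near $L/2$), whereas fusion is an arrival process in time.
  Second, the grid starts at $\sigma = 10$: below that the entire
  population fuses into one cluster and the metric saturates at $N = 140$,
  so tighter foci carry no trend information.
* **Amplitude** ($A \in \{0, 0.5, 1, 2\}$): boundary roughness has no
  systematic effect on clustering; the trend across the aggregated means
  is null. One caveat is documented: at $A = 2$ the channel pinches below
  one nuclear diameter over roughly a sixth of the domain, and the
  resulting corrals nudge the mean cluster size slightly upward. The
  effect is small (about 6% of the metric) and does not produce a
  monotone trend across the grid, but it is a real feature of extreme
  corrugation in this model.

```{r sweep-example, eval = FALSE}
sw <- run_sweep(sweep_spec("adhesion", n_replicates = 50, master_seed = 1))
plot(sw)
```

## Morphometric rules

* **Internuclear distance** is edge-to-edge:
  $\min_j(\lVert c_i - c_j\rVert - r_i - r_j)$, floored at zero for
  overlapping profiles.
* **SNC**: at least six nuclei, all with nearest-neighbour edge distances
  $\le 3\,\mu m$. Formalised as connected components of the
  $\le 3\,\mu m$ edge graph — inside such a component every member's
  nearest neighbour is automatically within the threshold. A stricter
  variant (each member's *global* nearest neighbour must lie in the same
  component) is available via `strict_nn = TRUE`.
* **SNA**: same construction with a floor of ten nuclei. The histological
  criterion of slight protrusion from the villus edge is expert
  annotation, not geometry; the call object flags it as unevaluated.
* **Cluster area**: convex hull of the member nucleus discs (each disc
  polygonised at 128 vertices). The original areas were traced in an image
  tool without a stated rule; the hull convention is documented and easy
  to swap.
* **Thresholds are inclusive** ($\le 3\,\mu m$, $\ge 80\,\mu m^2$); ties
  are measure-zero for simulated input but the convention matters for
  tabulated data.
* **Apoptotic exclusion** is an input flag column honoured by every
  operation, not an image-analysis step.

## What the synthetic generators emulate — and what they do not

`generate_clustered_pattern()` plants hexagonally packed clusters with
exact edge gaps (default 0.8 µm, matching the median internuclear distance
within syncytia) on fields with a quiet, well-separated background, so the
planted partition is recovered *exactly* whenever inter-cluster clearance
exceeds twice the call threshold and intra-cluster gaps stay below half of
it. Deterministic placement is a design choice: recovery tests assert
equality, not approximation; a jittered mode exists for robustness checks.
`generate_cell_population()` builds square-polygon cells with analytic
areas; `generate_particle_areas()` draws lognormal areas spanning the
observed 80–900 µm² particle range with closed-form survival ground truth.

Passing these tests shows the measurement rules are implemented correctly;
it does not show they are robust to what real histology adds — segmentation
error, touching nuclei mis-split, section-plane effects, irregular cell
outlines, or annotation ambiguity in the protrusion criterion. Those are
outside this package's scope.

## Numerical choices and degenerate inputs

* Exact OU transition sampling (no Euler bias), so stationarity tests are
  sharp.
* Natural cubic splines for the boundary (a global polynomial through ~100
  knots would oscillate).
* The upper-boundary force uses vertical clearance and a height table at
  0.02–0.05 diameter resolution inside the compiled core.
* Simulation noise comes from a xoshiro256++ stream seeded from R's RNG:
  `set.seed()` fully determines a trajectory, and the integer stream is
  platform-independent.
* Equal-seed runs are bit-identical; sweep replicate seeds derive
  deterministically from the master seed.
* Degenerate inputs are first-class: zero adhesion, zero diffusion, zero
  amplitude, empty patterns, single-nucleus patterns and channels locally
  too narrow for a nucleus all have defined behaviour and tests.
* Placement failure (overpacked configurations) reports the achieved
  count; replicate failures inside sweeps are caught, counted and
  reported without aborting the sweep.

## Known limitations

* Two-dimensional cross-section only; no hydrodynamics, no nuclear
  deformation, no shedding or apoptosis dynamics.
* The exact published potential curve and parameter scales were not
  available; the piecewise-quadratic form preserves the three stated force
  regimes, and conclusions are therefore trend-level, not curve-level.
* The interior maximum of the diffusion sweep depends on the fixed
  integration step at its high-$D$ end (see above); the continuum limit of
  the constant-$S/D$ covariation is a pure time-rescaling.
* At extreme corrugation ($A = 2$) channel pinch-off corrals nuclei and
  slightly elevates clustering.
* The SNA protrusion criterion and any staining-based scoring are not
  evaluated computationally.
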