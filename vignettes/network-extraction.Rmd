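---
title: "Extracting weighted networks from routing optimization and images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting weighted networks from routing optimization and images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routenet)
```

## The problem

Routing optimization in continuous space — moving mass from sources to sinks
at minimal transport cost — can be solved efficiently by integrating a
dynamical system, the dynamical Monge–Kantorovich (DMK) equations, a
continuous generalization of the *Physarum polycephalum* slime-mould
dynamics. The long-time solution is a conductivity field $\mu^*(x)$ whose
support traces the optimal transport network. That field, however, lives on
a finite-element triangulation: it is a picture of a network, not a network.
`routenet` turns it (or any raster image with a network-like intensity
pattern) into an explicit weighted graph in three stages:

1. **Continuous solve** (`run_continuous_dmk`) — find $(\mu^*, u^*)$ on a
   triangulation of the unit square;
2. **Graph pre-extraction** (`pre_extract`) — threshold $\mu^*$ and connect
   triangle barycenters into a weighted spatial graph;
3. **Graph filtering** (`filter_graph`) — run the *discrete* DMK dynamics on
   that graph to remove redundant structure in a principled way, with an
   interpretation as minimizing an operating-plus-infrastructure cost.

Evaluation metrics (`local_weight_metric`, `total_length`,
`edge_length_distribution`, `fit_exponential`) quantify how faithful and how
parsimonious the compression is, and support vein-length distribution
analysis of venation-like biological networks.

## The model

On an open bounded domain $\Omega$ with balanced forcing
$f = f^+ - f^-$, $\int_\Omega f\,dx = 0$, the flux is of Fick–Poiseuille
type, $q = -\mu \nabla u$, and the dynamics is

$$-\nabla\cdot(\mu \nabla u) = f, \qquad
  \partial_t \mu = (\mu|\nabla u|)^\beta - \mu, \qquad \mu(0,x) = \mu_0(x) > 0,$$

with no-flow Neumann boundary conditions. The exponent $\beta$ selects the
routing mechanism: $\beta = 1$ is shortest-path-like (at equilibrium
$|\nabla u^*| = 1$ wherever $\mu^* > 0$), $\beta > 1$ consolidates flow into
branched, tree-like networks; $\beta < 1$ (congestion avoidance) spreads
mass and is out of scope, as it does not produce network-like supports. The
equilibrium minimizes the transport-cost functional

$$\mathcal{L}(\mu, u) = \frac12\int_\Omega \mu |\nabla u|^2\,dx
  + \int_\Omega \frac{\mu^{P(\beta)}}{P(\beta)}\,dx,
  \qquad P(\beta) = \frac{2-\beta}{\beta},$$

dissipated energy plus a sub-additive infrastructure cost. The discrete
filter replays the same structure on a graph $G = (V, E, W)$ with signed
incidence matrix $B$, edge lengths $\ell_e$ and per-node forcing $f_i$:
Kirchhoff's law $f = B\,\mathrm{diag}(\mu_e/\ell_e)\,B^T u$ together with
$\mu_e' = (\mu_e|\sum_j B_{ej}u_j|/\ell_e)^{\beta_d} - \mu_e$. For
$\beta_d = 1$ this computes the solution of the corresponding basis-pursuit
/ minimum-cost-flow problem (the cost is convex, so the equilibrium is the
global minimizer); for $\beta_d > 1$ it concentrates on tree-like subgraphs,
which is what makes it work as a filter. The discrete cost splits into an
operating and an infrastructure percentage, reported with every filter run.

## Numerical choices

* **Discretization.** $u$ is piecewise linear on vertices (P1 elements),
  $\mu$ piecewise constant per triangle, assigned to the barycenter. The
  pure-Neumann system is solved with one pinned vertex and the constant mode
  removed by shifting to zero mean; the discrete filter grounds the
  lowest-index node of each active component.
* **Time integration.** Explicit relaxation with an energy-guarded adaptive
  step: the default `dt = 0.1` is halved (up to 10 times) whenever a step
  would increase the cost functional. The implicit-Euler/Newton scheme used
  in the literature reaches the same equilibria; the contract here is on the
  equilibrium, not the trajectory, and the explicit scheme keeps the
  Lyapunov property testable (`energy_trace` is checked to be
  non-increasing to `1e-8` of the initial energy).
* **Floors.** $\mu$ is floored at `delta_floor = 1e-10` (continuous) and
  `1e-12` (discrete) during iteration so the linear systems stay invertible
  while abandoned triangles/edges decay.
* **Convergence.** The iteration stops when the relative rate of change
  $\max_T |\Delta\mu_T| / (dt\,\mu_T)$ drops below `tol = 1e-4`. This is a
  strict, per-element criterion: for $\beta$ close to 1 the conductivity on
  near-critical triangles decays slowly ($\mu$ shrinks by a factor
  $1 - dt\,(1 - |\nabla u|)$ per step), so reaching a fully settled
  equilibrium can take several thousand iterations. The default cap
  `max_iter = 2000` flags `converged = FALSE` rather than erroring; study
  runs that feed the extraction (and the shipped acceptance analysis) raise
  the cap to 12000 so the extraction operates on the actual equilibrium.
* **Ties.** For $\beta_d > 1$ the filter concentrates on trees only under
  *generic* edge lengths: exactly tied parallel routes (e.g. symmetric
  forcings on the symmetric lattice mesh) are a valid tied equilibrium of
  the dynamics and both branches survive. A small length jitter restores
  genericity when acyclic output matters.
* **Meshes.** `build_structured_mesh(ndiv, nref)` triangulates
  $[0,1]^2$ with `ndiv`×`ndiv` cells split along the lower-left→upper-right
  diagonal; `nref` uniform quadrisections are mathematically identical to
  doubling `ndiv`, which is how they are implemented (the vertex sets nest
  across levels). Any conforming triangulation would do; the structured one
  is deterministic and symmetric.

## Pre-extraction rules and weights

Triangles with $\mu^*(b_i) \ge \delta$ are kept (`delta = 0` keeps the whole
grid; selections are nested in $\delta$). Nodes and edges follow one of
three rules — (I) barycenters joined when triangles share an edge *or* a
vertex, (II) only when they share an edge (degree $\le 3$), (III) the grid
vertices and edges of the selected triangles themselves — and weights follow
AVG, $w_{ij} = (\mu_i + \mu_j)/2$, or ER,
$w_{ij} = \mu_i/d_i + \mu_j/d_j$, which conserves the total selected density
exactly, $\sum_e w_e = \sum_{d_i > 0}\mu_i$ (rule III admits only AVG, with
boundary grid edges taking the one available triangle's $\mu$). Degrees
$d_i$ are those of the extracted graph itself, after thresholding.

## Terminals and the filter

Nodes whose positions lie in the support of $f^+$ ($f^-$) are *eligible*
sources (sinks). Among them the filter uses those that are vertices of the
convex hull of the eligible positions (outer shape of the terminal regions)
or whose normalized unweighted betweenness centrality is below
$\tau_{BC} = 0.1$ (end-points of the network; leaves always qualify).
Betweenness is computed globally on the pre-extracted graph: the default
threshold is meaningful on the normalized scale, and per-component
computation would change nothing for the dominant component while being
ill-defined for tiny ones. Degenerate collinear hulls keep the two extreme
points; nodes eligible for both signs are dropped with a warning. Fluxes are
uniform per connected component, $f_i = \pm 1/|S^\pm \cap V(C_m)|$, so each
active component is closed; components with no terminals are skipped by the
dynamics and dropped by default (`drop_inactive = FALSE` passes them through
untouched). The filter prunes edges with $\mu^*_e < \delta_d = 10^{-3}$
(absolute, with a `relative = TRUE` option, since the reference threshold
scale is not otherwise fixed) and reweights survivors with the equilibrium
conductivities (BPW) or their pre-extraction weights (IBP). The initial
condition is $\mu_e(0) = w(e)$.

## The synthetic study conditions

The shipped fixtures emulate the study conditions the pipeline is meant
for: a left/right two-rectangle source–sink pair, four corner sources
around a central sink, a family of rectangle placements, three initial
conductivity families (uniform $\mu_0 = 1$; a parabola-like bump
$0.05 + \max(0, 1 - 8r^2)$; a delta-like Gaussian peak of width $0.05$,
floored at $0.05$ — the floors keep $\mu_0 > 0$ as the dynamics requires),
and the venation layout: a central disk source
$(x-0.5)^2 + (y-0.5)^2 \le 0.01$ with an annular sink
$0.01 < (x-0.5)^2 + (y-0.5)^2 \le 0.45$. Defaults for the end-to-end runs
are `ndiv = 32`, $\beta = 1.1$, rule I + ER at $\delta = 0.01$,
$\tau_{BC} = 0.1$, $\beta_d = 1.1$, $\delta_d = 10^{-3}$, metric exponent
$q = 2$ on an $N = 11$ partition (100 cells). These sizes keep a full
pipeline run in the minutes range on one core while leaving the extracted
networks rich enough (hundreds of veins) for distribution fits.

What the synthetic problems do *not* emulate: imaging noise, non-uniform
illumination, anisotropic media, or the pixel-level resolution of real
venation photographs. Passing tests demonstrate the correctness of the
dynamics, extraction rules, conservation identities and fits — not that any
particular biological network follows these optimality principles.

## Metrics and the vein-length analysis

`local_weight_metric` partitions the domain into $P = (N-1)^2$ rectangles
$C_\alpha$ (half-open, upper/right boundary closed, so the partition is
exact) and compares, cell by cell, the graph's edge weights against the raw
thresholded field:

$$\hat w_q(G) = \frac1P\Big[\sum_\alpha \big|\sum_e \mathbb{I}_\alpha(e)
  w_e - w_\alpha\big|^q\Big]^{1/q},$$

with $\mathbb{I}_\alpha(e) = 1, \tfrac12, 0$ for edges with both, one or
neither endpoint in the cell. Zero means no mass was relocated.
`total_length` ($L(G) = \sum_e \ell_e$, unit or Euclidean) measures
parsimony; ensemble normalizations $L/L_{\max}$ are left to the caller.

For venation analysis, `edge_length_distribution` contracts every maximal
chain of degree-2 nodes into one junction-to-junction vein (pure degree-2
cycles become a single closed vein), and `fit_exponential` fits
$P(\ell) = P_0 e^{-\gamma\ell}$ to a 30-bin count histogram by nonlinear
least squares (Levenberg–Marquardt, log-linear start values). Counts rather
than densities are fitted, so $P_0$ depends on sample size and binning while
$\gamma$ — the decay rate per unit domain length — is the comparable
parameter. The decay rate recovered from the disk/annulus study is
mesh-dependent: the shortest representable vein is the barycenter spacing,
so finer meshes shift the histogram left and steepen the fit. At the default
`ndiv = 32` the fitted $\gamma$ lands in the tens per unit length, the same
order as reported for image-processed fungal networks.

## Images instead of solvers

`image_to_density` reads PNG/TIFF (or a matrix), block-mean downsamples,
maps colour to Rec. 709 luminance (or a named channel) and thresholds; the
surviving intensities act as an artificial $\mu^*$ on the pixel grid.
`grid_to_pregraph` is the pixel analogue of pre-extraction (4-connectivity ↔
edge sharing, 8-connectivity ↔ edge-or-node sharing, same AVG/ER identities)
and the filter applies unchanged. Because $\beta_d \ge 1$ filtering can only
produce trees, loop recovery is a two-part reconstruction:
`max_weight_forest` extracts the tree-like structure closest to the loopy
pregraph to feed the filter, and `recover_loops` re-inserts the shortest
pregraph path between terminal/leaf pairs that are within `radius` hops
(default 2) in the pregraph but further apart in the filtered graph. The
exact reconnection procedure is a design choice of this package (distance
notion: unweighted hops; candidates: terminals plus filtered-graph leaves);
`radius = 0` disables it.

## A small worked run

```{r example, eval = FALSE}
cfg <- generate_fixture("two-rectangles")
cfg$mesh$ndiv <- 16L
run <- run_pipeline(cfg, out_dir = "tworect-out")
run$solution                    # continuous equilibrium summary
run$filter_result               # filter iterations + energy split
igraph::ecount(run$filtered)    # the extracted network
run$metrics$w_hat$w_hat         # local-weight discrepancy
```

## Known limitations

* 2D domains only; the structured unit-square mesh is the only built-in
  geometry (arbitrary conforming meshes can be supplied in its format).
* The explicit relaxation needs many cheap iterations near $\beta = 1$;
  stiff problems would benefit from the implicit scheme the literature uses.
* $\hat w_q$ compares against the thresholded field of the same $\delta$
  used for extraction; comparing across different $\delta$ values conflates
  threshold and compression effects.
* The loop-recovery step is a stated reconstruction, not a canonical
  algorithm, and its `radius` is a user-facing knob.
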