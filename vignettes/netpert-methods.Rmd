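---
title: "Perturbation-theory ranking of network intermediates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-theory ranking of network intermediates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpertr)
```

## The model

A gene and its protein product are one vertex. Protein–protein
interactions are undirected edges; gene-regulatory interactions are
directed regulator→target edges. With unit activation rates the
activation matrix has $a_{ij} = 1$ when $j$ activates $i$ (both
orientations for an undirected edge), and each vertex decays at its
out-degree $d_j = \sum_i a_{ij}$. The linear dynamics

$$\frac{d\mathbf{x}}{dt} = (\mathbf{A} - \mathbf{D})\,\mathbf{x} \equiv \mathbf{H}\,\mathbf{x}$$

conserve total density (columns of $\mathbf{H}$ sum to zero), so
$x_i(t)$ is the occupation probability of a continuous-time random
walker and the Green's function $\mathbf{G}(t) = e^{\mathbf{H}t}$ has
nonnegative entries and unit column sums. $g_{ij}(t)$ is both the
density at $i$ at time $t$ given a unit at $j$ at time $0$ and the
linear response of $x_i(t)$ to a change in $x_j(0)$.

We use the *unnormalized* operator by default. Reaction rates are more
plausibly a property of the reaction than of the number of targets (a
kinase does not slow down because it has many substrates), and the
unnormalized stationary state on a connected undirected graph is
uniform, whereas the normalized operator
$\mathbf{A}\mathbf{D}^{-1} - \mathbf{I}$ concentrates stationary
density on hubs — a serious bias on long-tailed biological degree
distributions. The normalized form is available behind
`time_evolution_operator(..., normalized = TRUE)` for comparison only.
Vertices with out-degree zero are left decay-free in both forms so that
density is conserved.

## Sensitivities and vertex weights

A perturbation (knockdown, small-molecule inhibition, over-expression)
is modeled as a diagonal change of the operator,
$\mathbf{H} \to \mathbf{H} + \lambda_k \mathbf{1}_{kk}$. The first
derivative of the propagator with respect to $\lambda_k$ is the
convolution of two Green's functions,

$$s_{k;ij}(t) = \int_0^t dt'\, g_{ik}(t - t')\, g_{kj}(t'),$$

a three-vertex response function: signal flows from $j$ to $k$ for time
$t'$, is modulated at $k$, and flows on to $i$ for the remaining
$t - t'$. Because $\mathbf{H}$ and the perturbation do not commute, the
perturbed propagator is *not* $e^{\mathbf{H}t} e^{\Lambda t}$; the
package therefore ships a finite-difference oracle
(`finite_difference_sensitivity()`) that differentiates the exact
perturbed exponential and is used throughout the tests to certify the
convolution route.

The weight of vertex $k$ for a driver set $D$ and response set $R$ at
response time $t$ is

$$w_k(t) = \sum_{i \in R,\, i \neq k}\ \sum_{j \in D,\, j \neq k} s_{k;ij}(t).$$

Excluding the self-terms $i = k$ and $j = k$ matters: those terms are
dominated by $g_{kk}$, are large for every driver and response gene,
and would push the endpoints to the top of every ranking regardless of
topology. The endpoints variant (`include_endpoints = TRUE`) retains
them and is kept for comparison. For any vertex that is neither a
driver nor a response the two variants coincide exactly.

### Quadrature

The convolution is evaluated by the composite trapezoid rule on
$n_t + 1$ equally spaced nodes, with the propagator grid built from a
single matrix exponential of the base step $\mathbf{G}(t/n_t)$ followed
by repeated multiplication. The trapezoid rule is the natural choice
here: with endpoint exclusion the integrand vanishes at $t' = 0$ and
$t' = t$ (the identity propagator contributes only excluded diagonal
terms), so $n_t = 2$ collapses to a single midpoint evaluation — which
is also why the tied-diffusion baseline, an impulse at $t/2$, is the
$n_t = 2$ skeleton of the full convolution. Quadrature error decreases
as $O(n_t^{-2})$; the tests verify the ratio-4 error drop per doubling
against the chain closed form
$s_{k;RD}(t) = 1 - e^{-t}(1 + t + t^2/2)$.

Defaults are $n_t = 2$ and $r = 1/2$ (below). Rankings at $n_t = 2$ and
$n_t = 16$ agree to Spearman $\rho > 0.99$ on the synthetic networks
used in the tests, so the cheap default is not a practical compromise.

## Choosing the response time

The only free parameter is the response time $t$. It is parameterized
by the fraction $r$ of density that has escaped the driver(s): the
relaxation time $\tau_r$ is the first time at which
$\tfrac{1}{|D|}\sum_{i,j \in D} g_{ij}(t) = 1 - r$. For a single driver
with out-degree $d_i$, the non-returning approximation
$g_{ii}(t) \approx e^{-d_i t}$ gives the closed form

$$\tau_r \approx -\frac{1}{d_i}\ln(1 - r), \qquad
  \tau_{1/2} \approx \frac{\ln 2}{d_i}.$$

The approximation neglects walks that return to the driver; it is exact
whenever the driver has no incoming edges and accurate on large sparse
networks where escaped density randomizes. `escaped_density()` reports
the exact escaped fraction so the realized value can always be checked
against the requested $r$ (the run header records both), and
`relaxation_time()` falls back to numeric inversion of the exact
density for multiple drivers. `density_profile()` additionally tracks
the total density at the response genes, which rises and then falls as
density randomizes; its maximum is a plausible alternative criterion
for choosing $t$ that we expose as a diagnostic but do not adopt.

$r$ defaults to $1/2$. Requesting $r = 0$ is rejected rather than
silently returning the zero ranking ($t = 0$ gives $w_k \equiv 0$).
Rankings at $r = 0.4$ and $r = 0.6$ agree to $\rho > 0.99$ on the test
networks, so results are not delicately tuned to this choice.

## Comparison methods

**Subset betweenness centrality.**
$b_k = \sum_{i \in R, i \neq k} \sum_{j \in D, j \neq k}
\sigma(j,i|k)/\sigma(j,i)$, with $\sigma$ counting shortest directed
paths. We implement Brandes-style BFS accumulation restricted to the
driver sources and response targets, rather than delegating, so that
the endpoint conventions ($i \neq k$, $j \neq k$: endpoints get no
credit for paths they terminate) are controlled by us and tested
against exhaustive path enumeration on every small fixture. Genes on no
shortest path all score zero and share average tied ranks at the end of
the list; the tie rule is average (rather than maximum) so that tied
ranks interact correctly with Spearman correlation downstream.

**Tied diffusion.** The linking score is
$z = \min(v[\mathbf{x}(t_0), \mathbf{A}],\ v[\mathbf{y}(t_0),
\mathbf{A}^\intercal])$ with the heat-kernel relevance function
$v = e^{(\mathbf{A}-\mathbf{D})t'}\mathbf{x}(t_0)$: a forward diffusion
from the driver (initial score 1) and a backward diffusion from the
responses (initial scores $1/|R|$) under the reversed operator
$\mathbf{A}^\intercal - \mathbf{U}$, $u_i = \sum_j a_{ij}$. The total
diffusion time $2t'$ is identified with the response time $t$, so both
methods see the same diffusion kernel and total time. No score
threshold or edge filter is applied: neither affects the linking
scores, which are all we rank. The baseline supports a single driver;
driver sets can be collapsed first with `add_super_source()`, which
attaches a fast source vertex (default rate $10^3 \times \max_j d_j$)
so the injection delay is negligible.

**Short-time limits.** Expanding $\mathbf{G}(t)$ for small $t$ turns
the weight into
$w_k(t) = (t^3/6) \sum_{i \in R, i\neq k} \sum_{j \in D, j\neq k}
a_{ik} a_{kj} + O(t^4)$ — the coefficient counts endpoint-excluding
length-2 driver→response paths through $k$, which are necessarily
shortest paths. A vertex whose shortest driver→$k$→response route has
length $n$ receives weight of order $t^{n+1}$: unlike betweenness, the
weight never truncates to shortest paths, it only discounts longer
ones. `short_time_weights()` exposes the path-count coefficients. In
the same limit the tied-diffusion score of a DIR intermediate is
directly proportional to the same count, so the three views must rank
DIR intermediates with distinct counts identically at small $t$; ties
in the count may be broken either way by higher-order path terms, and
the tests assert exactly this (strict pairs, not ties).

## Vertex categories

Vertices are labeled `D`, `R`, `DIR` (on a length-2 driver→response
path), `DIIR` (on a length-3 but no length-2 path), `DI`, `IR`, or `I`
by directed-respecting adjacency; driver/response labels take
precedence (a response gene sitting on a length-2 path keeps label
`R`). Length-3 membership is enumerated over *simple* paths (no
repeated vertices); allowing repeats would only ever add degenerate
back-and-forth routes over undirected edges, which do not represent a
distinct signaling route. Labels are verified against exhaustive
simple-path enumeration on small random networks.

## Evaluation against drug assays

Assay scores are percentages of vehicle control (0 = complete
inhibition). Compounds listing more than five targets are excluded
outright — their activity cannot be attributed — and each remaining
target receives the most potent (numerically smallest) score among the
compounds listing it. Rankings are then compared with per-target scores
by Spearman correlation within three gene groups (driver+response,
intermediates, entire network). The orientation is fixed so that
positive $\rho$ means higher-ranked targets (rank 1 = top prediction)
show stronger inhibition (lower % of control); since both rank 1 and
score 0 are "best", this is the plain correlation of rank with score.
The two-sided p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; an exact permutation option exists
for $n < 10$. Groups with fewer than three tested proteins are skipped.
Single-test p-values are reported; multiple-testing accounting across
methods and groups is left to the user, with the test count visible in
the report.

## Synthetic data and what the tests do (and do not) show

`random_network()` emulates the *shape* of real inputs: an undirected
protein-interaction backbone with a long-tailed degree distribution
(static power-law model, exponent 2.5) plus uniformly random directed
regulatory edges, with disjoint driver and response sets and a driver
guaranteed an outgoing edge. `synthetic_assay()` emulates a screen with
a planted ground truth: pathway members are vertices on a directed
driver→$k$→response route of total length ≤ 4 — deliberately including
genes on longer-than-shortest routes, the regime in which shortest-path
methods tie everything at the end of the list — and member targets
score 20 versus 100 for the rest (endpoints 36), with Gaussian noise
(sd 10) and 1–3 targets per compound, the most potent target setting
the compound score.

These generators reproduce the structural features the method exploits
(directionality, degree heterogeneity, off-shortest-path signal
routes). They do not emulate curation biases of interaction databases,
correlated assay noise, compound promiscuity beyond three targets, or
any real transcriptional program; passing tests certify the
mathematics and the qualitative method ordering on these conditions,
not performance on any particular organism or screen.

Problem sizes used by the test-suite and the acceptance script — motifs
of ≤ 10 vertices with closed forms, random fixtures of 30 vertices for
the finite-difference oracle (quadrature $n_t = 256$,
$\varepsilon = 10^{-6}$), one 200-vertex network for robustness, and
twenty 60-vertex replicates for planted-signal recovery — were chosen
as the smallest sizes at which every property under test is
well-resolved.

## Numerical choices and degenerate inputs

- Propagators: one dense matrix exponential per base step
  (`Matrix::expm`), then matrix powers; drift versus a direct
  exponential is bounded at $10^{-8}$ in tests, conservation and
  nonnegativity at $10^{-9}$.
- Finite-difference oracle: central differences,
  $\varepsilon = 10^{-6}$ on unit-rate networks, balancing $O(\varepsilon^2)$
  truncation against round-off amplified by $1/\varepsilon$.
- Ranks: descending scores, average ranks on ties, everywhere.
- Duplicate interaction records are deduplicated silently; self-interactions
  removed; unknown response symbols dropped with a warning (incomplete
  interactomes routinely disconnect some differentially expressed genes);
  an absent driver is an error.
- Degenerate requests fail loudly: negative times, $r \notin [0,1)$,
  $r > 0$ with a zero-out-degree driver, multiple drivers passed to the
  tied-diffusion baseline.

## Known limitations

First-order theory only: combination perturbations and higher-order
responses are out of scope, as are perturbations modeled as component
removal. Unit rates are a modeling idealization; the response time is
the single tunable and results should be (and in tests are) checked for
robustness around it. Dense matrix exponentials bound practical network
size to a few thousand vertices on a laptop; the real-scale networks
the method targets (~16k vertices) call for sparse/Krylov exponentials,
which the module contract permits as an internal change.
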