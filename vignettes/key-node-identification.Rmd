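---
title: "Identifying key nodes with an entropy-fused spring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying key nodes with an entropy-fused spring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snefldsm)
```

## The problem

In an undirected, unweighted contact network — a dolphin social network, an
airline map, an e-mail graph, a proximity network of infected individuals —
some nodes matter far more than others: seeding an epidemic at them infects
the population faster, and deleting them shatters connectivity sooner. Purely
local scores (degree, neighborhood degree mass) miss a node's global position;
purely global scores (betweenness, closeness) miss local density. SNEFLD-SM
fuses both views and then converts them into a single "force" a node exerts on
the rest of the network.

The pipeline is: preprocess to the largest connected component → compute a
local/global entropy fusion (SNB) and a fractal descriptor (FLD) → mix them
into a composite node value $L_i$ → aggregate pairwise spring forces within a
per-node influence range (ISM) → rank greedily while attenuating each chosen
node's neighborhood.

## The two feature channels

**Second-order neighborhood betweenness entropy (SNB).** With $DC(i)$ the raw
degree, $CSN(i) = \sum_{u \in \Gamma(i)} DC(u)$ the degree mass of the
neighborhood, and $BC(i)$ raw (unnormalized, endpoint-excluded) betweenness,

$$SNB(i) = -\,BC(i) \sum_{j \in \Gamma(i)} CSN(j).$$

`snb_entropy()` returns this signed, non-positive value exactly as defined;
$SNB(i) = 0$ precisely when $BC(i) = 0$ (pendant and leaf-like nodes). The
related entropy measures $LE(i) = -\sum_{j \in \Gamma(i)} DC(j)\log DC(j)$ and
$ME(i) = -DC(i)\sum_{j\in\Gamma(i)} DC(j)$ are provided for comparison. The
defining formulas use the raw degree values, not probability-normalized ones;
we implement them as written and note that any positive rescaling of $BC$ or
$CSN$ leaves every downstream ranking unchanged, because the composite step
min–max normalizes.

**Fuzzy local dimension (FLD).** For each node $i$, boxes of growing radius
$r_t \in \{1, \dots, d_i^{\max}\}$ (up to the node's eccentricity) are centered
on it, and each box counts its members fuzzily: a node at hop distance
$d_{ij}$ belongs to the box of size $\varepsilon$ with Gaussian membership
$A_{ij}(\varepsilon) = \exp(-d_{ij}^2/\varepsilon^2)$. The fuzzy box count is

$$N_i(r_t) = \sum_{j:\,d_{ij}\le r_t} \exp(-d_{ij}^2/r_t^2),$$

and $FLD(i)$ is the ordinary-least-squares slope of $\log N_i(r_t)$ against
$\log r_t$. Three conventions needed fixing where the defining description is
ambiguous, and all three are deliberate package choices:

* **Box size–radius coupling**: $\varepsilon = r_t$ for each radius. This is
  the only reading that makes the count a one-parameter family per node; it is
  also the reading under which the all-crisp limit ($A_{ij} \to 1$) recovers
  the plain ball size $B_i(r)$ used by the crisp local dimension
  (`local_dimension()`).
* **Summation algebra**: the count is the membership-weighted number of nodes
  inside the radius. The literal "product" reading (crisp count times total
  fuzzy mass) double-counts and, in our measurements, orders nodes essentially
  identically, so nothing hinges on it.
* **Center inclusion**: the center belongs to its own box with $A_{ii} = 1$.
  Excluding it shifts all counts by a constant and visibly degrades log–log
  linearity on fixtures such as long cycles.

Nodes adjacent to the entire network have a single admissible radius, no
slope, and receive $FLD = 0$ with a warning; their importance is carried by
the SNB channel.

On a cycle $C_{101}$ the ball grows linearly ($B_i(r) = 2r + 1$) and both
fitted dimensions sit near 1 (LD $\approx 0.94$, FLD $\approx 0.97$), which
the test suite asserts within $|slope - 1| \le 0.15$; on vertex-transitive
graphs all per-node values agree to $10^{-9}$.

## Composite value and channel orientation

The composite node value mixes min–max-normalized channels with weight
$\lambda$ (default $0.5$, equal weight):

$$L_i = \lambda\,\widehat{SNB}_i + (1-\lambda)\,\widehat{FLD}_i, \qquad
\widehat{x} = \frac{x - x_{\min}}{x_{\max} - x_{\min}}.$$

Orientation matters and is explicit in `composite_value()`:

* `orientation = "magnitude"` (default) uses $|SNB| = BC \cdot \sum CSN$, so
  structurally central nodes get large values. Normalizing the signed
  (non-positive) values directly would rank high-betweenness hubs *lowest*;
  `"signed"` retains that literal reading for sensitivity analysis, and since
  $SNB \le 0$ the signed channel is exactly the mirror $1 - \widehat{|SNB|}$.
* `fld_orientation = "locality"` (default) uses $1 - \widehat{FLD}$. A hub's
  ball saturates within a couple of hops, so its growth exponent is *small*;
  peripheral nodes carry the steepest slopes. Low local dimension therefore
  marks central, densely embedded nodes — the ordering convention
  local-dimension rankings use — and on hub-dominated networks the top of the
  FLD ranking should coincide with the hubs, which only the complemented
  channel delivers. `"dimension"` feeds the raw exponent in unchanged for
  sensitivity analysis.

A degenerate channel (constant across nodes) contributes zero to every node
under either orientation: a feature with no spread carries no ranking
information, and flipping it to a constant one would inject a spurious offset.

## Spring model, influence range, attenuation

With $d$ the network diameter and $d_{ij}$ hop distances, the improved spring
model treats each pair as a spring with deformation $d - d_{ij}$ and scalar
force $L_i L_j (d - d_{ij})$ (magnitudes only; no vector dynamics). The
influence range balances node $i$'s force against the farthest node $v_l$ (at
distance $d_l$, ties broken toward the smaller label):

$$R_i = \frac{(L_i - L_l)\,d + L_l d_l}{L_l + L_i},$$

clamped to $[1, d]$: the raw formula goes negative when $L_i \ll L_l$, and a
range below one hop would unphysically zero the node's force; with
$L_i + L_l = 0$ there is no force to balance, and the range defaults to 1 with
a warning. The working score is then the range-restricted sum

$$ISM(v_i) = \sum_{j \ne i,\; d_{ij} \le R_i} L_i L_j (d - d_{ij}),$$

which reduces to the full sum exactly when every $R_i \ge d$ (asserted to
$10^{-9}$ in the tests).

Top spreaders tend to cluster (the rich-club effect), so a plain sort on
$ISM$ yields redundant seed sets. The ranking is instead greedy: select the
highest-valued unselected node, freeze its score, and multiply each
*unselected* neighbor's current value by

$$1 - \frac{ISM(v_i)}{ISM(v_i) + \sum_{u \in \Gamma(i)} ISM(v_u)} \in (0, 1],$$

with all terms evaluated on current (possibly already attenuated) values; the
factor is 1 exactly when the selected value is 0. Two contracts here were
genuinely open — whether the factor uses initial or current values, and
whether selected nodes keep their frozen score — and the package fixes both as
stated, matching the "select, weaken, repeat" loop structure: updates
propagate, already-ranked nodes are immutable. All ties, everywhere, break
toward the smaller node label (numeric-aware, so node "9" precedes "10"),
which makes every run byte-reproducible.

```{r}
g <- fixture_graph("two_blobs", a = 5, b = 5)
head(snefld_sm(g), 4)
```

## Validation harness

* `si_simulate()` — discrete-time synchronous SI: each infected node infects
  each susceptible neighbor independently with probability $\beta$ per step.
  The mean-field description is realized with per-edge Bernoulli trials, the
  standard network version; $S(t) + I(t) = N$ is asserted inside the loop,
  and infected sets are nested over time. $\beta = 0$ freezes the epidemic,
  $\beta = 1$ advances exactly one BFS layer per step.
* `si_ode()` — the closed-form logistic solution of the uniform-mixing SI
  equations, for reference curves. Note that at the default network scales the
  synchronous discrete-time chain is *not* approximated by the continuous
  logistic at the matching rate; the exact mean of the chain on a complete
  graph is a binomial Markov chain on the infected count, and that is the
  oracle our tests compare simulations against.
* `node_infectivity()` — each node in turn as sole seed; mean infected count
  at $t_{obs} = 10$ over 100 replicates is the realized spreading power
  (defaults as in the evaluation design: $\beta \in [0.01, 0.1]$ grid,
  $t_{obs} = 10$, 100 runs, seed sets of size 10).
* `kendall_tau()` — tau-a, $(C - D)/(0.5\,n(n-1))$: tied pairs count for
  neither $C$ nor $D$ while the denominator keeps all pairs. Empirical
  infectivities are integer-valued and tie often, which tau-a handles
  transparently; tau-b (tie-corrected, via `stats::cor`) is available and
  labeled distinctly.
* `jaccard_topk()` and `robustness_curve()` — top-$k$ set overlap, and
  normalized giant-component size (plus raw component count) under removal of
  the leading fraction of a ranking. Connectivity values like "0.95" only make
  sense normalized, so the giant-component ratio is the primary column.

Replicate $r$ of any stochastic routine uses a seed derived from
`(rng_seed, r)`, so replicates are mutually independent yet individually
reproducible, and every simulation is bit-reproducible given `rng_seed`.

## The synthetic generator and what it does (not) show

`er_graph(n, p, rng_seed)` emulates the reference artificial condition — an
Erdős–Rényi network with $n = 650$, $p = 0.01$, reduced to its largest
component (typically ~645 nodes, ~2100 edges, diameter ~7, mean path ~3.7).
`fixture_graph()` supplies the deterministic micro-worlds used throughout the
tests: stars, paths, cycles (the $C_{101}$ scaling fixture), complete graphs,
and a two-clique graph with a planted bridge whose betweenness is the strict
maximum when the cliques are equal-sized. A specific published ER instance is
one stochastic draw (its edge count sits well within four binomial standard
deviations of $\binom{n}{2}p \approx 2109$, which the suite checks across 20
seeds), so instance-level numbers are compared statistically, never exactly.

ER graphs are degree-homogeneous and unclustered. Passing tests on them shows
the machinery is correct and the ranking enriches for genuinely influential
nodes; it does not show how the method behaves under heavy-tailed degree
distributions, strong community structure, or core–periphery layouts typical
of real contact networks — for those, feed real edge lists through
`run_pipeline()` or `reproduce_tables()`.

On the ER condition the FLD channel is a far weaker, noisier predictor of
spreading power than the SNB channel: ER graphs are locally tree-like, so
per-node growth exponents vary little and mostly reflect eccentricity noise.
The default $\lambda = 0.5$ therefore trades some rank correlation for the
fractal channel's sensitivity to local structure. `scripts/acceptance.R`
computes the Kendall tau afresh at every run, both at the default mix and at
$\lambda = 1$ (SNB channel alone), rather than quoting figures.

## Numerical choices and limitations

* Natural logarithms everywhere; OLS fits need $\ge 2$ radii.
* Betweenness via Brandes' accumulation; unordered pairs, endpoints excluded,
  unnormalized.
* Average path length averages over unordered distinct pairs of the
  preprocessed component.
* Node labels are opaque strings, never reinterpreted: "007" round-trips as
  "007".
* Weighted, directed, temporal and multigraph inputs are out of scope; edges
  are deduplicated and self-loops dropped at ingestion.
* The method needs the full distance matrix, so memory is $O(n^2)$; the
  intended regime is networks up to a few thousand nodes.
* Problem sizes in the test suite (ER $n = 650$, $K_{50}$ with 500 SI
  replicates, $C_{101}$, 200 random oracle graphs $\le 10$ nodes) were chosen
  as the smallest scales at which each property is sharply testable.
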