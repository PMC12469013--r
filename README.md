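# snefldsm

Key-node identification in undirected, unweighted complex networks with
**SNEFLD-SM** — the Second-order Neighborhood Entropy Fuzzy Local Dimension
Spring Model — plus the full evaluation harness used to validate such
rankings (SI epidemic spreading, Kendall τ against realized infectivity,
top-k Jaccard overlap, robustness under targeted removal).

It is aimed at network scientists and epidemiologically minded analysts who
need to find influential spreaders in contact-like networks (social,
airline, e-mail, proximity graphs) of up to a few thousand nodes.

## The method

For a connected graph with diameter $d$ and hop distances $d_{ij}$:

1. **Entropy channel.** $SNB(i) = -BC(i)\sum_{j\in\Gamma(i)} CSN(j)$ fuses
   raw betweenness $BC$ (global path position) with the two-hop degree mass
   $CSN(j) = \sum_{u\in\Gamma(j)} DC(u)$ (local density).
2. **Fractal channel.** $FLD(i)$ is the log–log slope of the fuzzy ball size
   $N_i(r_t) = \sum_{d_{ij}\le r_t} e^{-d_{ij}^2/r_t^2}$ over radii
   $r_t = 1..d_i^{\max}$ — a per-node fractal dimension with Gaussian box
   membership.
3. **Composite value.** $L_i = \lambda\,\widehat{SNB}_i +
   (1-\lambda)\,\widehat{FLD}_i$ with min–max normalized, importance-oriented
   channels ($\lambda = 0.5$ by default).
4. **Spring forces with influence range.** Each pair acts as a spring of
   deformation $d - d_{ij}$: $ISM(v_i) = \sum_{j \ne i,\, d_{ij}\le R_i}
   L_i L_j (d - d_{ij})$, where the range
   $R_i = ((L_i - L_l)d + L_l d_l)/(L_l + L_i)$ balances node $i$ against its
   farthest node $v_l$ (clamped to $[1, d]$).
5. **Greedy ranking with attenuation.** Repeatedly select the highest-valued
   node and shrink each unselected neighbor by
   $1 - ISM(v_i)/(ISM(v_i) + \sum_{u\in\Gamma(i)} ISM(v_u))$, suppressing
   rich-club redundancy among top spreaders.

See `vignette("key-node-identification")` for the assumptions, parameter
semantics, and every convention adopted where the defining formulas are
ambiguous.

## Worked example

```r
library(snefldsm)

g <- largest_component(er_graph(650, 0.01, rng_seed = 7))
network_summary(g)
#>   n_nodes n_edges avg_degree max_degree avg_path diameter
#> 1     649    2120   6.533128         18 3.659695        7

rk <- snefld_sm(g)          # lambda = 0.5, oriented channels
head(rk, 5)
#>   rank node score      L     R   ism
#> 1    1  176 651.1 1.0000 6.405 651.1
#> 2    2  633 431.0 0.6796 6.214 431.0
#> 3    3  252 423.5 0.6692 6.036 423.5
#> 4    4   49 384.5 0.6197 6.103 384.5
#> 5    5  554 380.2 0.5895 5.921 380.2
```

Node 176 exerts the largest attenuated spring force: its composite value
tops both channels (`L = 1`), its influence range (6.4 of a diameter-7
network) lets it pull force from nearly everyone, and `score` is its
SNEFLD-SM value at selection time. Validation against realized spreading
power:

```r
inf <- node_infectivity(g, beta = 0.1, t_obs = 10, runs = 100, rng_seed = 7)
kendall_tau(setNames(rk$score, rk$node), inf)
#> Kendall tau-a = 0.3704  (C = 144071, D = 66188, n = 649)

jaccard_topk(rk, degree_centrality(g), 10)
#> [1] 0.5384615
```

The ranking is positively rank-correlated with the mean infected count each
node achieves as a sole SI seed after 10 steps, and its top-10 shares 7
nodes with the degree top-10 (Jaccard 7/13 ≈ 0.54).

A thin command-line front end ships in `inst/cli/snefldsm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "snefldsm.R", package = "snefldsm"))')" \
    generate --family er --n 650 --p 0.01 --seed 7 --out er.edgelist
```

with subcommands `generate`, `stats`, `centrality`, `rank`, `si`,
`infectivity`, `tau`, `jaccard`, `robustness`, `pipeline`, `reproduce`.

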