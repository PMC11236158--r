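# netpertr

Ranks the intermediate genes that carry a signaling response from a
driver gene (for example an induced transcription factor) to its
differentially expressed response genes, so that the top-ranked
intermediates can be prioritized as drug targets. It is aimed at
systems-biology and functional-genomics analysts who have a
protein–protein interaction network, a gene-regulatory edge list, a
driver, and a response-gene list — and, optionally, a compound screen
to validate against.

## The method

The network is a linear dynamical system
`dx/dt = (A − D) x`, with unit activation rates `a_ij = 1` when `j`
activates `i` (both directions for a protein–protein interaction, one
direction for a regulatory edge) and decay equal to out-degree
`d_j = Σ_i a_ij`, so total density is conserved and the propagator
`G(t) = exp[(A − D) t]` is the Green's function of a continuous-time
random walk. The effect of perturbing vertex `k` on signaling from
driver `j` to response `i` is the first-order sensitivity

    s_k;ij(t) = ∫₀ᵗ g_ik(t − t′) g_kj(t′) dt′

and the vertex weight sums these over all driver–response pairs,
excluding self-terms (`i ≠ k`, `j ≠ k`) so endpoints do not dominate:

    w_k(t) = Σ_{i∈R, i≠k} Σ_{j∈D, j≠k} s_k;ij(t)

The response time defaults to the relaxation time
`τ_r = −(1/d_i) ln(1 − r)` with `r = 1/2` (half the driver density has
escaped), and the convolution uses a trapezoid rule with `n_t = 2`
intervals. Two comparison methods are built in: subset betweenness
centrality (drivers as sources, responses as targets) and tied
diffusion linking scores `z = min(forward, backward)`; both analytic
short-time limits (`t³/6` path-count law) and a drug-assay evaluation
by Spearman rank correlation within gene groups complete the toolkit.

## Worked example

```r
library(netpertr)

res <- random_network(n_vertices = 60, n_ppi = 110, n_regulatory = 40,
                      n_drivers = 1, n_responses = 8, seed = 7)
net <- res$network
net
#> <netpert_network> 59 vertices, 259 directed activation entries
#>   drivers:  G0013
#>   responses: 8 connected

ranking <- netpert_run(net, methods = c("netpert", "bc", "tiedie"))
glance(ranking)
#> # A tibble: 1 × 5
#>   n_vertices     t   n_t realized_escape methods
#>        <int> <dbl> <dbl>           <dbl> <chr>
#> 1         59 0.347     2           0.458 netpert,bc,tiedie

head(as.data.frame(ranking[, 1:6]), 8)
#>    gene category netpert_score netpert_rank bc_score bc_rank
#> 1 G0015      DIR      0.002071            1      3.0     2.0
#> 2 G0050        R      0.001215            2      4.0     1.0
#> 3 G0016     DIIR      0.000245            3      0.0    34.5
#> 4 G0040     DIIR      0.000240            4      1.0     5.0
#> 5 G0032        R      0.000204            5      1.5     3.0
#> 6 G0053        R      0.000157            6      1.0     5.0
#> 7 G0047       IR      0.000128            7      0.5     8.0
#> 8 G0055     DIIR      0.000109            8      1.0     5.0
```

The driver's one direct driver→response bridge (`G0015`, category DIR:
adjacent to the driver and to a response) ranks first. `G0016` shows
the characteristic difference between the methods: it sits on a
length-3 path but on no shortest path, so betweenness ties it at the
end of the list (`bc_score = 0`, rank 34.5) while the perturbation
weight still resolves it (rank 3). The `glance()` header records the
response time `t = τ_1/2` and the realized escaped density (0.458
against the requested 0.5; the closed form is a non-returning
approximation, and the exact value is reported so the gap is visible).

Evaluating against a (here synthetic) compound screen:

```r
assay <- synthetic_assay(net, seed = 7)
netpert_evaluate(ranking, assay)
#>             group  method n_proteins n_drugs    rho p_value
#> 4   intermediates netpert         24      38  0.215   0.312
#> 5   intermediates      bc         24      38 -0.139   0.517
#> 6   intermediates  tiedie         24      38  0.253   0.234
#> ...
```

A positive `rho` means higher-ranked targets showed stronger inhibition
(lower % of vehicle control). On this single small replicate the
perturbation ranking correlates positively with the planted signal
while betweenness does not; the acceptance script (below) averages this
comparison over twenty replicates.

File-based workflows use the same functions
(`read_interactions()`, `build_network()`, `write_ranking()`), or the
thin CLI at `inst/scripts/netpert` with `run`, `evaluate`, and
`simulate` subcommands.

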