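# supplynet

Trade-network characterization and external supply-risk scoring for
agricultural imports.

Food-security analysts studying how shocks (epidemics, export bans,
contractions) propagate through bilateral agricultural trade need two
things from the same data: a picture of the *network* — who supplies whom
above a meaningful volume, how concentrated and modular that web is — and a
per-country *risk score* that says where external supply is fragile and
why. `supplynet` provides both halves as one pipeline, plus a synthetic
gravity-model world generator so every stage can be exercised and tested
without downloading trade statistics.

## The model

**Network.** Bilateral flows (exporter *i* → importer *j*, USD, per year)
form a directed weighted matrix `W`. Binarizing at a threshold τ (default
100 million USD) gives the adjacency `A`, `a_ij = 1` iff `w_ij ≥ τ` and
`w_ij > 0`. On `A` the package computes directed density `E / n(n−1)`,
in/out/total degrees, country trade shares with top-*k* cumulative
concentration, and a least-squares exponential fit `p(k) ≈ a·e^{−bk}` to the
empirical degree distribution (scale-free-like networks show a decreasing
long-tailed `p(k)`). Community structure is found by an in-package Louvain
optimizer of Newman modularity

    Q = 1/(2m) Σ_ij [A_ij − k_i k_j / 2m] δ(c_i, c_j)

on the symmetrized graph, with seeded deterministic restarts; an
exhaustive-search oracle (`brute_force_modularity`) is included for small
graphs. "Absolute dependence" pairs flag importers drawing ≥ θ (default
0.5) of their imports from a single supplier.

**Risk.** For each importing country and year, three components:

* `EDI = imports/GDP + 1` — external dependence (floored at 1);
* `HHI = Σ_k s_k²` — Herfindahl–Hirschman concentration over supplier
  shares `s_k` of the country's imports (1 = sole supplier);
* `RICI = Σ_k s_k·CRI_k` — epidemic exposure, the import-share-weighted
  epidemic-risk index (CRI) of the suppliers; in a pre-epidemic year with
  CRI ≡ 1 it is exactly 1.

Their sum is the composite `AECSI = R_EDI + R_HHI + R_RICI`. All indices
are graded 1–5 within the year's cross-section — components by
Fisher–Jenks natural breaks (exact dynamic program), the composite by equal
intervals — and the component contributing > 50% of AECSI names the
dominant risk type, otherwise "Compound risks".

## Worked example

```r
library(supplynet)

world <- generate_world(world_config(n_countries = 88, seed = 42))
net <- binarize(build_network(world$flows, 2019), threshold = 1e8)
net
#> <trade_network> year 2019: 88 countries, 548 binary edges (threshold 1e+08 USD)
network_density(net)
#> [1] 0.07157785

sh <- trade_shares(world$flows, 2019, "export")
sprintf("top-10 exporters hold %.2f%% of trade", 100 * attr(sh, "cumulative_top_k"))
#> "top-10 exporters hold 57.58% of trade"

louvain(net, weighted = TRUE, seed = 42, rescale = TRUE)
#> <community_partition> 4 communities (sizes 22/37/25/4), Q = 0.1622

rk <- risk_pipeline(world$flows, world$indicators, 2019)
head(rk[order(-rk$aecsi),
        c("country", "r_edi", "r_hhi", "r_rici", "aecsi", "grade_aecsi", "dominant")], 3)
#>    country    r_edi     r_hhi r_rici    aecsi grade_aecsi       dominant
#> 42     XBP 1.232249 0.5393267      1 2.771576           5 Compound risks
#> 9      XAI 1.087121 0.3362656      1 2.423386           3 Compound risks
#> 16     XAP 1.078369 0.3331960      1 2.411565           3 Compound risks
```

A synthetic 88-country world built from the package defaults lands near the
empirical regime the method was designed for: density ≈ 0.07 at the 100M
USD cutoff, a decreasing exponential degree law, EDI values a few percent
above 1. In this pre-epidemic year every RICI is exactly 1, so no country
can be RICI-dominated and most are compound-risk — switch
`cri_regime = "epidemic"` in `world_config()` and the mean AECSI jumps by
more than an order of magnitude with RICI dominating, the qualitative
signature the risk model exists to detect.

The same run end-to-end, from the command line:

```sh
Rscript -e 'supplynet::cli_main()' all --synthetic --years 2019,2021 --seed 42 --out runs/demo
```

writes per-year network/degree/share/partition/risk/breaks files, a
two-year change report (density and edge deltas, AECSI grade migrations)
and a manifest with a config hash — identical configs reproduce
bit-identical outputs.

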