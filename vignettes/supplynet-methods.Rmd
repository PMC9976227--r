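---
title: "Methods: trade networks and external supply-risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trade networks and external supply-risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supplynet)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what a green test does and does not
establish.

## 1. From flows to a network

The raw object is a long-format table of bilateral flows: year, exporter,
importer, value in USD. Validation drops negative values and self-flows
(both logged), sums duplicates of the same (year, exporter, importer)
triple, and flags country codes outside an optional whitelist without
dropping them.

`build_network()` lays one year out as an n×n matrix with **rows =
exporters, columns = importers**, so an edge i→j reads "i supplies j": a
country's in-degree counts its above-threshold suppliers and its out-degree
its customers. The source data never fixes this convention; we chose it
because it makes degree rankings directly readable as import/export partner
counts.

`binarize()` keeps an edge when the one-directional flow is **at least**
the threshold (default 1e8 USD, the conventional "100 million dollars"
cutoff for a meaningful trade relation). Three deliberate details:

* the comparison is inclusive (`≥`), fixed so tests are bit-exact;
* at `threshold = 0` an edge requires a *positive* flow — otherwise every
  empty cell would count as an edge;
* whether the cutoff should apply to the pair total rather than each
  direction is unstated in the source method; we binarize one-directionally
  and leave pair-total aggregation to the caller (sum the two directed
  flows upstream if desired).

Density is directed, without self-loops: `E / n(n−1)`. With n = 88, E = 556
gives 0.0726 and E = 505 gives 0.0660, reproducing the published 0.073 and
0.066 at 3-decimal rounding — that identity is what pins the convention.

## 2. Degree distributions

The empirical probability `p(k)` is the fraction of countries with exact
integer degree k over the observed support (no binning — the reference
figures plot per-degree points). The exponential model `a·e^{−bk}` is fitted
by least squares **on the raw probabilities**, not on `log p`: the
log-transform blows up the sampling noise of near-empty tail bins and
cannot use empty ones at all. A `method = "loglinear"` option exists and is
also used internally to seed the optimizer. With exactly two distinct
degrees the two-parameter model is saturated and solved in closed form
(rmse 0); with one distinct degree there is nothing to fit and the call
errors. (The build contract's precondition said "≥ 3 distinct" while its
own examples require the saturated 2-point fit; we follow the examples.)

## 3. Communities

Modularity is computed on the symmetrized matrix `A + Aᵀ` — the standard
treatment when a directed trade graph is fed to Louvain-style tooling; a
directed-modularity variant is out of scope. Weighted mode uses raw USD
(with an optional ÷1e6 rescale for numeric comfort; Q and partitions are
scale-invariant, and a test asserts it).

The Louvain optimizer is written in-package: seeded local moves that accept
only Q-improving relocations (ties broken by first encounter in the seeded
scan order), then aggregation of communities into super-nodes, repeated
until a pass stops improving. Additions a user should know about:

* **Deterministic restarts** (default 10). Greedy local moves are
  order-sensitive, and on small graphs some optima are unreachable from a
  singleton start under *any* visit order. Restart 1 is the classic
  singleton start; later restarts begin from a seeded random coarse
  partition. The best-Q run wins. Everything remains a pure function of
  `seed`. The acceptance bar — ≥ 0.9 × brute-force optimal Q on random
  ≤ 8-node graphs — is met with the optimum actually attained on all 100
  test graphs.
* `q_trace` records Q after each pass of the winning run; a test asserts it
  is non-decreasing, and the reported `q` is always *recomputed* from the
  returned assignment on the input graph (to 1e−12), never trusted from the
  optimizer's bookkeeping.

"Absolute dependence" — an importer drawing at least θ of its imports from
one supplier — has no published definition of θ; the package defaults to
0.5 (above which the dominant supplier is unique, a property that is
tested), makes it configurable, and stamps θ on every output.

## 4. Grading

`jenks_breaks()` is the exact Fisher–Jenks dynamic program on sorted
values: minimal total within-class sum of squared deviations, O(kn²) with
prefix sums. It matches exhaustive enumeration on 100 random instances in
the acceptance suite. Conventions that needed fixing:

* interior edge j sits midway between the last value of class j and the
  first value of class j+1 — strictly ascending even when an extreme class
  is a single value;
* classes are half-open `[low, high)` with the last class closed, so a
  value exactly on an interior edge belongs to the upper class;
* a DP boundary that would split a run of tied values is pushed to the next
  distinct value (stable order);
* out-of-range values clamp to the end classes with one warning per call.

Equal-interval breaks are arithmetic: `min + j(max−min)/k`. The published
grade table is titled "natural breaks" yet its composite row widths are
unequal *and* the accompanying text prescribes equal intervals for the
composite — the two cannot be reconciled from the printed numbers alone, so
the pipeline defaults to natural breaks for the three components and equal
intervals for the composite, records which classifier produced every break
set in its output, and lets the caller override either.

## 5. The risk composite

Per importer and year: `EDI = imports/GDP + 1` (the published rule assigns
1 when the ratio is negative; with positive GDP that cannot occur, so the
rule degenerates to a floor at 1 and is kept verbatim), `HHI = Σ s_k²` over
supplier shares, and RICI. The literal published RICI formula multiplies
the importer's own epidemic-risk index by shares that sum to one — it
collapses to the importer's own CRI and cannot produce cross-country
variation from trade structure. The default here is therefore
**partner-weighted**: `Σ_k s_k·CRI_k` over suppliers, which is what the
formula's own share terms suggest; the literal reading survives as
`mode = "own_cri"`. When every supplier shares one CRI value c the result
is exactly c (special-cased so the pre-epidemic identity `RICI = 1` holds
to the bit).

`AECSI` is the raw sum of the three (additive, a tested invariant);
`mode = "graded"` sums the 1–5 equal-interval scores instead (the
"standard risk factor values" reading). Contribution rates are component
over total; the dominant type needs a *strict* majority (> 0.5), an exact
half is "Compound risks". Grades are fitted within each year's
cross-section, never pooled across years, because the published break
tables are year-specific.

Known irreconcilables, documented rather than patched: the published
R_HHI break range (1.0140–3.5616) exceeds raw HHI's mathematical maximum
of 1, the published 2019 R_RICI range spans 0–8.455 although CRI ≡ 1 in
2019, and the reported 2021 mean composite (117.23) is incompatible with
the same table's composite maximum (10.51). The raw formulas are
implemented as printed; whatever rescaling produced those tables is not
recoverable from the text.

`risk_pipeline()` isolates failures per country (zero imports, unusable
GDP): the country is flagged in a `failures` attribute and the rest of the
cross-section is scored. A degenerate grading cross-section (e.g. RICI
constant pre-epidemic) cannot support five classes; everyone gets class 1
and the condition is flagged in a `degenerate` attribute.

## 6. The synthetic world

`generate_world()` draws country masses `S ~ Pareto(α_tail)`, places
countries uniformly in the unit square, and sets
`flow_ij ∝ S_i^α S_j^β / d_ij^γ · e^ε`, rescaled to a configured grand
total. Defaults, chosen once for realism and not revisited:

| parameter | default | why |
|---|---|---|
| `n_countries` | 88 | the empirical sample size of the reference network |
| `size_exponent` | 1.5 | heavy tail ⇒ hubs and a scale-free-like thresholded network |
| `gravity` | (1, 1, 1) | canonical gravity elasticities |
| `noise_sd` | 0.3 | log-scale noise under which the elasticities stay recoverable to ±0.1 |
| `total_trade` | 3e11 USD | the scale of the observed yearly grand totals |
| `gdp_ratio` | 20 | total GDP = 20 × total trade ⇒ imports/GDP ≈ 5%, i.e. EDI+1 in the observed ~1.005–1.15 band |
| epidemic CRI | lognormal(log 60, 0.5) | supplier CRIs mostly in 20–150, so the raw composite shifts >10× pre→post, echoing the reported magnitude change |

At these defaults an 88-country world thresholds to density ≈ 0.07 —
the empirical regime — without any per-run tuning; `calibrate_threshold()`
can binary-search a threshold for any attainable target density and
diagnoses unattainable ones with the feasible range.

What the generator does **not** emulate: real geography (distances are
planar Euclidean), the actual country membership, reporting gaps and
mirror-flow asymmetries of real trade statistics, and zero flows (gravity
gives every pair a positive value; sparsity comes from the threshold). A
green test on this world therefore certifies the *machinery* — formulas,
classifiers, optimizer, determinism — and the declared qualitative
responses (density falls under a trade contraction, mean composite rises
>10× under the epidemic CRI regime), not any specific published
per-country figure. The published figures that depend on the proprietary
extractions (exact edge lists, community memberships, break values, the
4.711/117.23 means) are correspondingly covered by property-based checks,
as the build contract prescribes.

## 7. Determinism and numerics

* Every stochastic routine takes a seed; seeded helpers save and restore
  the caller's RNG state, so library calls never perturb user code.
* Pipeline outputs are a pure function of (config, seed): reruns are
  bit-identical and the manifest stores a config hash plus per-file MD5s.
* Tolerances: recomputed modularity must match stored Q to 1e−12; share
  vectors sum to 1 within 1e−12; the Jenks DP is compared to enumeration
  with a scale-aware absolute bound (~1e−8) because prefix-sum and centered
  summation differ in the last bits; reported roundings follow the printed
  precision of the reference tables (densities 3 decimals, percentages 2).
* The one genuine print-vs-ratio conflict — a published cumulative share of
  60.49% whose exact ratio prints 60.48% — is resolved by asserting the
  column-sum-of-rounded-rows reading exactly and the exact ratio to
  reporting precision.
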