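---
title: "Signed social networks from nearest-neighbor scan sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed social networks from nearest-neighbor scan sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxnet)
```

## The problem

Groups of human-managed animals — horses on pasture, bears in a large
enclosure, laying hens in a pen, veal calves in a stable — carry social
structure that matters for their welfare: preferred companions provide
social support, avoided conspecifics generate stress, and the removal of a
structurally central individual can break a group apart. Direct behavioral
observation of interactions is expensive; spatial proximity is cheap,
especially with automatic location sensors. proxnet turns scan-sampled
proximity data (who is whose nearest neighbor, scan by scan) into signed
social networks and the node-, subgroup- and group-level summaries a welfare
manager can act on.

## The model

### From scans to counts

At each scan every visible individual has exactly one nearest neighbor (NN):
the conspecific at minimum 2-D Euclidean distance. The relation is directed
and not symmetric. Accumulated over scans this gives a directed count matrix
$o_{ij}$, the number of scans in which $j$ was $i$'s nearest neighbor; the
diagonal is structurally zero. Where neighbors are recorded directly (video
scans) the counts are tallied as recorded and no distances exist.

When fixed home ranges or territories dominate movement, nearest neighbors
reflect geography rather than preference. A distance ceiling on the
nearest-neighbor distance (NND) limits the analysis to animals in actual
proximity; both the inclusive ("at most 5 m") and the strict ("less than
1 m") reading of a ceiling are supported, because both conventions are in
use for different species.

### Significance of a dyad

The null hypothesis is that NN choice is independent of identity. Expected
counts use the contingency-table margins product over the off-diagonal
cells, $e_{ij} = r_i c_j / n$, and each cell is scored by its standardized
residual

$$\mathrm{SR}_{ij} = \frac{o_{ij} - e_{ij}}{\sqrt{e_{ij}}},$$

which is approximately standard normal under the null. Cells with
$\mathrm{SR} > 1.96$ mark attraction, cells with $\mathrm{SR} < -1.96$
avoidance (two-sided $p < 0.05$); equality at the boundary is treated as
non-significant. The positive network keeps the significant positive cells
as edge weights; the negative network keeps the significant negative cells
with their sign flipped so that both networks carry non-negative weights.

Two numerical caveats are deliberate design choices:

* **Structural zero diagonal.** The plain margins product does not exactly
  conserve the grand total on a table whose diagonal is forced to zero
  ($\sum e = n - \sum_i r_i c_i / n$). The classic chi-square convention is
  nevertheless the default because it is what the field's tooling computes;
  `expected_counts(method = "ipf")` provides iterative proportional fitting
  with the diagonal as a structural zero, which reproduces both margins
  (and hence the total) exactly.
* **Directed table, undirected graph.** SR is computed on the directed
  focal-by-neighbor table. An undirected dyad is significant if either
  direction passes; the edge weight is the larger directed SR and the edge
  records whether one or both directions passed (one-way vs two-way). This
  matches sociograms drawn with single and double arrows.

A 2-mode variant applies the same machinery to an individuals-by-facilities
table (nearest feeder, perch, cubicle, ...), where no structural diagonal
exists.

The simple ratio index is provided for incomplete visibility:
$\mathrm{SRI}_{ij} = (o_{ij} + o_{ji}) / (m_i + m_j)$ with $m_i$ the number
of scans in which $i$ was observed. It is 1 for a dyad mutually nearest in
every scan, 0 for a dyad never associated, and when every animal is visible
in every scan it ranks dyads exactly as the symmetrized counts do — the
justification for working with count matrices under complete visibility.

### Node and group metrics

Metrics are computed on the unweighted undirected graph (published tables
are integer-consistent with unweighted computation; SR weights are carried
for display and export):

* **degree**, **betweenness** (unnormalized Freeman, fractional credit for
  tied geodesics), **farness** (sum of geodesic distances; closeness is its
  reciprocal), **cutpoints** (articulation nodes), **blocks** (biconnected
  components, which overlap exactly in cutpoints), and **density**
  (significant dyads over possible dyads).
* **Unreachable pairs** need a finite distance for farness. The default
  charges the node count $n$ per unreachable pair — the convention under
  which a fully isolated animal in a 15-node network scores
  $14 \times 15 = 210$ and the endpoint of a 4-path component scores
  $1+2+3+11\times 15 = 171$, matching the published enclosure table this
  package uses as its worked anchor. A flag selects the alternative $n-1$
  convention. Other published tables for the same method family are *not*
  reproducible under either convention (nor under directed variants we
  tried); we implement the documented convention rather than guess at
  undocumented tool internals.

### Day-to-day stability

Stability of a network is the degree to which today's NN matrix correlates
with tomorrow's. The Mantel test computes the Pearson correlation over
corresponding off-diagonal cells and assesses it by jointly permuting rows
and columns of one matrix. Defaults: 10,000 permutations, one-tailed upper
test (stability is directional: positive correlation means a persistent
structure), add-one p-value $p = (1 + k)/(1 + N)$, and a mandatory seed for
reproducibility. For matrices up to $8 \times 8$ exact enumeration over all
$n!$ joint permutations is available and is tested against an independent
enumeration oracle. Daily matrices are symmetrized before correlating
(configurable); the summary statistic is the mean of the consecutive-day
correlations, excluding the first-vs-last comparison — the convention
validated by reproducing the published cross-species stability column from
the published day-pair tables.

## The synthetic herd

Real scan data for the published groups were never deposited, so the
package ships a generator whose defaults are the stated validation world:

* **Arena** 50 m × 50 m, a small pasture or large enclosure; 20
  individuals; 5 days × 100 scans (scan intervals of ~10 minutes justify
  treating snapshots as nearly independent, hence a static position model
  rather than a random walk).
* **Movement**: position = home center + isotropic Gaussian noise with
  per-individual scale `home_sd`, reflected at the fence. Small `home_sd`
  gives territorial animals; `home_sd = Inf` (the default) is the fully
  roaming limit with uniform positions. Reflection rather than truncation
  matters: clamping to the fence piles probability onto edges and corners
  and manufactures spurious spatial associations.
* **Affinity** pairs co-locate: with probability `strength` the
  lower-indexed member is moved next to its partner (1 m Gaussian offset).
  This reproduces the signature that matters — inflated mutual-NN
  frequency — without simulating locomotion.
* **Avoidance** pairs are resampled (up to 20 sweeps over the whole
  constraint set, so that satisfying one pair cannot silently break
  another) until at least `min_distance` apart. In the validation world
  `min_distance` is 25 m — half the arena. An avoidance distance comparable
  to the typical nearest-neighbor spacing (~5–6 m at these densities) is
  not avoidance at all: animals forced merely "not adjacent" still end up
  each other's nearest neighbor above expectation.
* **Facilities** are fixed named points; each individual's nearest facility
  is recorded. **Missingness** is i.i.d. per (scan, individual). Identical
  seeds give byte-identical datasets.

What the generator does *not* emulate: autocorrelated trajectories,
dominance hierarchies, diurnal activity rhythms, demographic turnover, and
observation error in identity. A green recovery test therefore establishes
that the pipeline detects planted co-location preferences in near-ideal
data; it does not establish robustness to tracking noise or non-stationary
behavior.

### What a null world shows

With no planted structure and fully roaming animals, NN counts are
exchangeable across dyads and the fraction of cells flagged at
$|\mathrm{SR}| > 1.96$ sits near the nominal 5% two-sided tail (NN data are
dependent — one animal's choice constrains another's — so calibration is
checked against a generous band, not an exact rate).

### The precision ceiling: a real property of the method

The validation world plants 8 affinity pairs among 20 animals, leaving 4
animals without partners. Two structural effects then act on the dyads
among those unpaired animals:

1. Their mutual-NN probability is *genuinely* elevated: eight cohesive
   pairs occupy effectively one location each, so an unpaired animal
   chooses its nearest neighbor among ~11 sites rather than 19 animals, and
   another unpaired animal is a full site of its own (roughly $2/19$
   instead of $1/19$).
2. The margins null simultaneously *deflates* the expected count for those
   cells, because the cohesive partners inflate each other's column totals
   and soak up expectation.

Both effects push the same way: unpaired-animal dyads flag positive with
very large residuals in essentially every replicate. Planting avoidance on
four of the six such dyads leaves two, capping positive-network precision
at $8/10 = 0.80$ exactly, with ordinary multiple-testing noise (~380 cells
tested) occasionally adding a borderline eleventh edge. The acceptance
suite documents this honestly: recall of planted affinity is 1.0
throughout, while the precision pass fraction hovers at its required
boundary and differs between seed batches. The bias is not an
implementation artifact — it persists under the IPF null and even under a
true uniform-choice null — and it is the quantitative face of a caveat the
source literature itself raises: nearest-neighbor networks confound spatial
arrangement with social preference. Negative networks are hit harder still:
in a heterogeneously gregarious group, every cross-pair dyad of cohesive
animals is flagged avoidant. Interpret negative-network densities with
corresponding care.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| SR threshold | 1.96 | – | two-sided normal 5%; strict inequality at the boundary |
| NND ceiling | `Inf` | m | no filtering unless territories are suspected; 5 m (inclusive) and 1 m (strict) are the published species conventions |
| expected-count null | `margins` | – | classic chi-square convention; `ipf` conserves margins under the structural-zero diagonal |
| Mantel permutations | 10,000 | – | p resolution ~1e-4; exact enumeration for n ≤ 8 |
| Mantel tail | upper | – | stability is a directional hypothesis |
| unreachable distance | `n` | hops | reproduces the published worked component (210/171/169) |
| sd convention (NND) | population | – | divide by N; switchable to sample |
| `home_sd` | `Inf` | m | fully roaming null; finite values model territories |
| `p_invisible` | 0 | – | published groups kept all animals visible in most scans |

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_individuals = 10, days = 3, scans_per_day = 60,
  affinity_pairs = data.frame(i = c(1, 3), j = c(2, 4), strength = 0.9),
  seed = 11)
sim <- generate_scans(cfg)

pairs <- nearest_neighbor_pairs(sim$scans)
nnd_statistics(pairs)

assoc <- pairs |> build_nn_matrix() |> signed_association()
tidy(assoc) |> dplyr::filter(signif != "ns")

pos <- build_graph(assoc, "positive")
node_table(pos)
autoplot(pos)

stab <- daily_series(sim$scans, permutations = 999, seed = 11)
glance(stab)

compare_networks(list(demo = list(association = assoc, stability = stab)))

recovery_score(sim$truth, assoc)
```

## Known limitations

* The margins null mis-calibrates when gregariousness varies across
  individuals (see above); treat negative networks and loner dyads as
  indicative, not confirmatory. No multiple-testing correction is applied
  by default, matching field practice; a Bonferroni-style tightening is a
  one-line threshold change.
* Small expected counts ($e \lesssim 5$) break the normal approximation of
  SR, exactly as in any chi-square analysis; territorial worlds produce
  such cells. Pool days or scans before testing.
* Metrics are computed on the unweighted graph; SR weights are
  display-only. Weighted centralities would need a different convention
  set.
* Coordinates are planar meters; no geodesy, no 3-D.
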