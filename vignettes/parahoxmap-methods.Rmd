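---
title: "Methods: similarity-map classification of Hox and ParaHox proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-map classification of Hox and ParaHox proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `parahoxmap`, the
default parameters and why they were chosen, the synthetic data generator's
realism and limitations, and the numerical design decisions. Code chunks are
shown but not evaluated at build time; every command runs in seconds to
minutes and is exercised verbatim by the test suite.

## 1. Why similarity maps

Hox and ParaHox proteins share one alignable region, the ~60-residue
homeodomain; their flanks are effectively unalignable across paralog groups.
Tree methods therefore work from a 60-column alignment in which
fast-evolving groups are mutationally saturated, and distance-based
inference then exhibits long-branch attraction (LBA): the two fastest
lineages are joined regardless of their true relationship.

The similarity-map approach replaces the single family-wide alignment with
all-against-all *pairwise* local alignments of full-length sequences. Each
pairwise comparison uses whatever similarity the pair actually shares;
saturation in one group degrades only that group's edges, not a shared
coordinate system. Classification then reads group membership off the
thresholded similarity graph rather than off tree topology.

## 2. Alignment scores and E-values

`smith_waterman()` computes the exact maximal local alignment score under
affine gap costs (Gotoh recursion, `gap_open = 11`, `gap_extend = 1`, a gap
of length $k$ costing $11 + k$), over BLOSUM62 with the `X` row and column
set to 0. These are the familiar BLASTP defaults, so E-values land on a
scale practitioners can interpret. Raw scores map to E-values by the
Karlin–Altschul formula

$$E = K\,m\,n\,e^{-\lambda S},\qquad \lambda = 0.267,\; K = 0.041,$$

with $m, n$ the full sequence lengths. The constants are the standard gapped
BLOSUM62/11/1 values and are treated as fixed per scoring scheme rather than
estimated per query: all E-values in a map share one scheme, and the method
only ever uses them *comparatively* (thresholding and `-log10` weighting),
so a global constant is the right trade-off. E-values are computed in log
space and floored at `1e-300` so that `-log10(E)` edge weights remain finite
for near-identical sequences.

An unordered pair becomes an edge when at least one direction's E-value is
at or below the cutoff (the comparison is inclusive); the edge weight is the
mean of `-log10(E)` over the directions present. Since $E$ is symmetric in
$m\,n$, both directions agree, and the weight is simply the pair's
significance on a log scale.

### Cutoffs

Two analysis cutoffs are used by default, `1e-33` and a more stringent
`1e-40`. At the permissive end the map shows the family's global structure;
tightening dissolves the weakest inter-group connections first, so the
connections that *persist* at `1e-40` carry the classification signal. All
hits are computed once at a permissive report cutoff (`1e-2`);
`apply_cutoff()` can then tighten without re-alignment, and refuses to
loosen (which would need a new search). Edge sets are nested by
construction — tightening never adds an edge — and the test suite checks
this property explicitly.

## 3. Domain model

`build_profile()` turns a seed homeodomain alignment into a
position-specific log-odds profile: columns with more than 50% gaps are
dropped, and each remaining column scores residue $a$ as

$$\log\frac{(c_{a} + \pi_a)/(n + 1)}{\pi_a},$$

with $c_a$ the column count, $n$ the non-gap count, and $\pi$ a
Robinson–Robinson background (pseudocount mass 1). `X` scores 0 everywhere.

The hit threshold is not a free parameter: `calibrate_threshold()` draws
1000 i.i.d. background sequences of length 500, records each one's best
sliding-window score, and takes the $1 - \text{fpr}$ quantile (default
`fpr = 1e-3`). This gives a per-sequence false-positive rate with a direct
operational meaning at database scale. Overlapping windows above threshold
are resolved best-first. `filter_multidomain()` removes sequences with two
or more accepted windows — in a real retrieval these are concatenated gene
models or multi-homeodomain proteins that would bridge unrelated clusters.

## 4. Redundancy clustering and re-inflation

Near-identical sequences (database duplicates, strains) inflate cluster mass
and distort both layout and connectivity statistics. `cluster_redundant()`
greedily clusters at 95% global identity (matches / alignment columns of a
match-1/mismatch-0/gap-1 global alignment), longest sequence first — the
CD-HIT strategy. Cluster *selection* (which connected components belong to
the family, via the seed sequences) happens on representatives;
`reinflate()` then restores all members so that per-group statistics count
real sequences.

## 5. Layout

`layout_graph()` is a deterministic spring embedder: each edge attracts its
endpoints with force proportional to `weight / max(weight) * distance`, all
node pairs repel with `repulsion_scale / distance^2`, positions move by
`step_size * net force` with a multiplicative cooling of 0.97 per iteration,
stopping when mean displacement drops below `1e-4` (or after 500
iterations). Defaults (`attraction_scale = 1`, `repulsion_scale = 0.05`,
`step_size = 0.05`) were chosen so that a few dozen to a few hundred nodes
settle well inside the iteration cap; weight normalisation by the map's
maximum makes the behaviour stable across cutoffs. Coincident points are
separated by a deterministic jitter from the same seeded RNG stream, so a
rerun with the same seed is bitwise identical — a property the manifest
checksums rely on.

The layout is *illustrative*; every decision statistic (connectivity,
ranking, tie sets) is computed on the graph, not on coordinates. The only
coordinate-derived statistic, the per-group mean distance from the map
centre (`center_distance()`, a divergence proxy), is invariant under rigid
motions of the embedding.

## 6. Group assignment and the tie criterion

For each (ParaHox, Hox) group pair at a cutoff, `connectivity()` reports
edge count, possible pairs $|A||B|$, density, mean weight, and the primary
statistic

$$\text{score} = \frac{\sum \text{weights}}{|A|\,|B|},$$

i.e. significance mass per possible pair — the quantitative analogue of
"number and darkness of connecting lines" on a printed map. `rank_hox()`
sorts groups by score and chains tie sets: a group joins the preceding tie
set when its score is within a relative margin (default 0.10) of the score
above it. The tie criterion is this package's formalisation of "similarly
strong connections"; the margin is reported in every output so downstream
users can judge borderline calls.

## 7. Synthetic data generator

`simulate_family()` evolves one ancestral protein (random flanks around a
60-residue homeodomain-like consensus) down a guide topology over paralog
groups, then radiates `n_species` terminal draws per group. The model is
deliberately minimal but captures the three properties the method depends
on:

- **two-tier site rates** — domain sites evolve at 0.3x, flank sites at
  1.25x the branch length (F81-style proportional substitutions from a
  Robinson–Robinson stationary distribution), reproducing the
  conserved-domain/divergent-flank architecture;
- **flank-only indels** (Poisson, short geometric lengths), so domain
  coordinates drift and must be *found*, not assumed;
- **per-group rate multipliers**, which scale every branch in a group's
  subtree and create genuine long branches for the LBA study.

Limitations, stated plainly: sites are i.i.d. within a tier (no covarion or
profile-specific domain constraint beyond the consensus start point), there
is no domain gain/loss, no compositional drift, and groups radiate as stars
below the guide tips. None of these omissions favours the method under
test; they mostly make the problem *harder* for it (e.g. i.i.d. flanks carry
less lineage signal than real linker motifs would).

The `paper_supported` preset (8 groups x 6 species, ~480–540 aa sequences)
encodes the generating truth Pdx-sister-to-PG3, Gsx equidistant from PG2 and
PG3, Cdx sister to the central groups. Branch lengths were derived
analytically, not fitted: groups whose comparison should tie (PG2/PG3 seen
from Gsx) share almost their entire path to the observer, because group stem
branches are single stochastic realisations whose noise does not average out
across species pairs — short independent terminal segments are the only way
to make a tie statistically stable. Flank lengths of 180–240 per side keep
relative score noise small for the same reason. The `lba` preset reuses this
truth with `severity`-fold rates on Cdx and the posterior group; at severity
8 the domain p-distances saturate (~0.78 observed) and neighbor joining
unites the two fast groups, while the full-length similarity graph holds
zero Cdx–posterior edges at `1e-40`.

Problem sizes throughout (48 sequences, 6 species per group, 20 replicates)
are this package's choice, set so the full study runs on one CPU in minutes
while keeping the recovery statistics far from their decision boundaries.

## 8. Trees and the LBA check

`domain_distance()` takes each sequence's best-scoring profile window — a
fixed 60-column frame, so extraction is an implicit alignment — and computes
uncorrected p-distances. `neighbor_joining()` is a textbook Q-criterion NJ
with two determinism guarantees: ties in the Q minimisation are broken by
the lexicographically smallest label pair, and negative branch lengths are
clamped to zero with the clamp recorded. Using *uncorrected* distances is
intentional: saturation-induced underestimation of long distances is
precisely the mechanism of LBA, and the package's point is to demonstrate
it, not to mitigate it. `attraction_check()` reports whether two groups form
an exclusive neighborhood in the unrooted tree (smallest bipartition side
containing both groups contains nothing else).

## 9. Numerical and I/O decisions

- All floating-point numbers in map files, hit tables and reports are
  printed with `%.17g`, enough digits to round-trip IEEE doubles exactly;
  the write→read→write cycle is byte-identical and tested.
- Coordinates in map files are 0-based half-open internally, 1-based closed
  in TSVs (the bioinformatics convention for human-readable tables), with
  the conversion tested in both directions.
- Every stochastic entry point (calibration, layout, simulation) takes an
  explicit seed and restores the caller's RNG state, so library use never
  perturbs a user's random stream.
- The pipeline manifest records per-stage counts, the full configuration
  and md5 checksums of all text artifacts; a rerun with the same
  configuration reproduces identical checksums, which is the package's
  operational definition of determinism. Figures (SVG) are excluded from
  checksumming because vector encoders do not guarantee byte stability.

## 10. Running the study

```{r}
library(parahoxmap)
cfg <- pipeline_config("out", preset = "paper_supported", sim_seed = 1,
                       nj_contrast = TRUE)
res <- run_pipeline(cfg)
res$report
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` reproduces the
headline numbers (assignment recovery rates, LBA contrast, determinism) from
a single seed.
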