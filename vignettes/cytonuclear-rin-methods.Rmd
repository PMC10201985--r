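---
title: "Methods: residue interaction networks for cytonuclear hybrid models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue interaction networks for cytonuclear hybrid models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cybrin)
```

## The model

Plastid ribosomes are assembled from plastid-encoded and nuclear-encoded
(plastid-targeted) proteins. In an interlineage hybrid the maternal parent
donates the plastid genome and the paternal parent half the nuclear
genome, so a cross between diverged lineages pairs plastid-encoded
variants of one lineage with nuclear-encoded variants of another. If the
two sides carry co-adapted substitutions at a protein–protein interface,
some combinations may destabilize it — a structural reading of
plastid–nuclear incompatibility.

`cybrin` operationalizes that reading as a deterministic pipeline:

1. **Variants.** From pre-aligned per-gene amino-acid alignments, a column
   is a *differentially fixed* substitution when it is monomorphic within
   every lineage but not identical across lineages. Columns with an
   alignment gap in any sample sequence are skipped, as are columns
   polymorphic within a lineage; the reference sequence takes no part in
   the fixation test. Columns are mapped to 1-based ungapped reference
   numbering (plus an optional per-gene offset to reach the structure's
   author numbering); a column over a reference gap is flagged unmappable
   rather than dropped.
2. **Combination models.** For lineages `L`, all `L²` ordered combinations
   are built: label `P_N` applies lineage `P`'s substitutions to
   plastid-compartment chains and lineage `N`'s to nuclear-compartment
   chains. Nuclear heterozygosity is deliberately ignored — the nuclear
   side carries only the paternal lineage's alleles, which is what the
   combination definition encodes.
3. **Networks.** Each model becomes a residue interaction network: an edge
   joins residues whose minimal any-atom distance lies in `[2.5, 5.0]` Å,
   both bounds inclusive. Pairs closer than 2.5 Å get no edge (they are
   presumed covalent or clashing); covalently adjacent residues are not
   special-cased. Waters and ligands are excluded at parse time; RNA
   chains survive parsing but are not part of the default protein
   selection.
4. **Centralities.** Betweenness, closeness, degree and eigenvector
   centralities are computed per network on the unweighted graph (edge
   distances are annotations, not weights) and standardized per network:
   `Z = (c − mean(c)) / sd(c)` with the population standard deviation;
   `sd = 0` maps to all-zero Z. Residues with `Z ≥ 2` are flagged central.
5. **PCA.** The combinations × residues Z-matrix is decomposed by singular
   values after column centering and (by default) unit-variance scaling.
   Variance shares, combination scores, and per-residue contributions
   (squared loading as a percent of the component) summarize how cross
   type and direction separate.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| interaction window | 2.5 – 5.0 | Å | the any-atom contact rule; both bounds inclusive |
| salt-bridge cutoff | 4.0 | Å | charged N (Arg/Lys/His) to carboxylate O (Asp/Glu) |
| hydrogen-bond cutoff | 3.5 | Å | heavy-atom N/O–N/O; no angle term (cryo-EM models carry no hydrogens) |
| hydrophobic cutoff | 4.5 | Å | side-chain C–C between apolar partners |
| clash distance | 2.5 | Å | heavy-atom pairs below this count as clashes, matching the window's lower edge |
| chi grid step | 15 | degrees | relaxation granularity |
| central-residue flag | Z ≥ 2 | – | standardized centrality threshold |
| PCA flags | center on, scale on | – | see "Resolving the scaling flag" |

Interaction-typing thresholds are exposed via `typing_thresholds()`. They
are this package's deterministic rendering of calls that were originally
made by visual inspection; no numeric criteria exist to copy, so agreement
with historical type labels is something to *report*, not to assert. The
packaged record table indeed contains calls (e.g. a 4.57 Å contact labelled
polar) that sit at the edge of any simple rule set.

## Mutagenesis without a force field

Side-chain replacement superposes an idealized internal-coordinate
template (standard bond lengths and angles; chi torsions free) onto the
residue's own N/CA/C backbone, which is never moved — backbone RMSD
between any combination model and its template is exactly 0. Rotamers come
from a small built-in backbone-independent library (gauche−/gauche+/trans
per sp3 chi with priors 0.35/0.20/0.45; planar orientations for terminal
sp2 groups; puckered values for proline). The selected candidate minimizes
a clash score — the count of heavy-atom pairs under 2.5 Å between the new
side chain and all other residues — with ties broken by higher library
prior, then lexicographically smallest chi vector, so the choice is fully
reproducible.

Relaxation is cyclic coordinate descent on a 15° chi grid: one chi at a
time is set to its clash-minimizing value (ties keep the incumbent),
sweeping until stable. A full cartesian grid over four chi angles would
cost 24⁴ evaluations per residue for no benefit at contact resolution,
so the descent form was chosen; the clash score is non-increasing by
construction and tested as such. Energy minimization of the kind performed
interactively in the original modelling workflow is intentionally not
reproduced: its settings are not recoverable, and a documented,
deterministic geometric stand-in keeps every downstream number exactly
reproducible. This is the main source of divergence from historical
"after mutation" contact calls, and the package treats the published
centrality tables as data, not as a regeneration target.

Multi-residue substitution strips every target side chain first, then
rebuilds in (chain, residue) order. Stripping first makes the operation
idempotent — re-applying a substitution set reproduces identical
intermediate environments, hence identical rotamer choices.

## Numerical choices

* **Eigenvector centrality** is computed by power iteration on the largest
  connected component with the shifted matrix `A + I`: the shift leaves
  eigenvectors unchanged but makes the leading eigenvalue strictly
  dominant on bipartite graphs, where plain iteration oscillates.
  Convergence is relative sup-norm `1e-10`, at most 1000 iterations
  (non-convergence is an error, not a silent result); the vector is
  non-negative and L2-normalized, nodes outside the component get 0.
* **Closeness on disconnected graphs** is computed within each node's
  component as the reciprocal shortest-path sum, then scaled by
  `(component size − 1)/(n − 1)` so values are comparable across
  components (singletons get 0). The unscaled per-component variant is a
  config switch.
* **Betweenness** is pair-normalized (divide by `(n−1)(n−2)/2`). Z-scores
  are invariant to this normalization, so the choice cannot affect any
  standardized result.
* **RIN construction** bins atoms on a grid at `d_max` resolution, so
  every atom pair within the window shares neighboring cells and the
  result is identical to the all-pairs scan the tests compare against.
* **PCA sign convention:** each component's largest-magnitude loading is
  made positive, so scores and loadings are stable across linear-algebra
  backends.
* **Degenerate inputs:** an all-constant matrix is an error; a constant
  column under scaling is an error naming the column.

## Resolving the scaling flag

Whether the combinations × residues matrix should be scaled to unit column
variance was genuinely open. Both settings were run on the packaged
16 × 17 Z-score tables:

```{r scale-choice}
run_pca(table3_fixture("BCA"), scale = TRUE)$variance_pct[1:2]
run_pca(table3_fixture("BCA"), scale = FALSE)$variance_pct[1:2]
```

Centered-unscaled PCA concentrates ~69% on PC1 for the betweenness table;
the scaled form gives ~33.6%/29.2% (betweenness) and ~39.4%/22.7%
(closeness), the configuration consistent with the reported variance
structure of these data. Scaling is therefore the shipped default.

A caveat that matters when comparing against historical figures: the
packaged tables are printed to two decimals, and several columns are
nearly constant (column standard deviations down to 0.004 — smaller than
the print resolution). Correlation-based PCA normalizes every column to
unit variance, so for those columns it amplifies rounding noise to full
weight. Perturbing the table within its rounding envelope (±0.005 per
cell) moves PC1's share over roughly 30–37% and individual contribution
percentages by several points:

```{r rounding-envelope, eval = FALSE}
x <- as.matrix(table3_fixture("BCA")[, -1])
spread <- replicate(500, {
  noisy <- x + matrix(runif(length(x), -0.005, 0.005), nrow(x))
  prcomp(noisy, center = TRUE, scale. = TRUE)$sdev[1]^2 /
    sum(prcomp(noisy, center = TRUE, scale. = TRUE)$sdev^2) * 100
})
range(spread)
```

Percentages recomputed from the printed tables are therefore exact for
*these* tables but only accurate to a few points relative to values
computed from unrounded source data. The package reports what it computes
and does not adjust toward historical figures.

## What the synthetic data does and does not emulate

`make_toy_dimer()` plants inter-chain contacts at exact target distances
(to 0.01 Å) while keeping every unplanned inter-chain pair beyond 6 Å, so
the expected edge set is known by construction; residues are glycine
backbones with pseudo side-chain carbons. `make_lineage_alignment()`
plants differentially fixed columns among four lineages (default
E1/W1/W2/W3, three sequences each) with optional within-lineage
polymorphism, sample-gap and reference-gap decoys, and returns its own
truth table. `make_graph_fixture()` provides path/star/complete/two-clique
families with closed-form centralities.

These generators exercise contracts — exact edge recovery, perfect variant
precision/recall, oracle-identical centralities, byte-identical pipeline
reruns — not realism. They contain no indels, no alignment uncertainty, no
B-factor/occupancy noise, no realistic packing, and toy side chains do not
reach across the planted interface. Green tests therefore demonstrate that
the machinery is correct, not that the geometric typing rules or the
rotamer stand-in reproduce any particular curated call on real structures;
for real data the reference-structure check
(`check_reference_interface()`) and manual inspection of the typed
interface report remain part of the workflow.

Test problem sizes are the package's own choices, kept deliberately small
because the oracles are exhaustive: toy dimers of 2 × 6 residues (100
seeded replicates), random graphs up to 12 nodes (200 replicates per
centrality oracle), alignments of 60 columns (100 replicates), and the
full 16-model pipeline on the toy dimer.

## Known limitations

* Four centrality measures are implemented; mentions of a fifth measure in
  the source literature are not accompanied by a definition, so there is
  nothing well-posed to implement.
* The published per-model centrality values cannot be regenerated without
  the original minimized models; they are shipped as data and analyzed
  as-is.
* The default analysis network is the two-protein interface selection;
  whether surrounding ribosomal chains should contribute nodes is exposed
  via chain selection but not decided by the package.
* Interaction typing is heavy-atom geometry only: no hydrogen placement,
  no angle terms, no π-stacking, cation-π or water-mediated contacts, and
  no RNA–protein edges.
* Proline's ring closure is approximated by its chi-angle template; exact
  ring geometry is irrelevant at contact resolution but would matter for
  anything finer.
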