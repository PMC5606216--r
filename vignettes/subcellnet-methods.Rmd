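---
title: "Compartment-constrained force-directed layout: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-constrained force-directed layout: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcellnet)
```

## The problem

A biomolecular interaction network carries more information than its
topology: most nodes are annotated with the subcellular compartment where
the molecule predominantly acts. Drawing the network *inside* a cell
diagram lets the eye read both at once — where interactions concentrate,
which compartments exchange many edges, and where a queried pathway lives.
`subcellnet` does this headlessly: XGMML in, laid-out XGMML / coordinate
tables / SVG / CSV out.

## Input contract and compartment vocabulary

Nodes must carry a single-valued compartment attribute named `Selected CC`
(IIS convention) or `Localization` (InnateDB convention); `Selected CC`
wins when both are present, since IIS-style exports are the native input.
The canonical vocabulary holds 21 labels (extracellular, cell wall, plasma
membrane, cytoplasm, cytosol, nucleus, and 15 further organelles from
mitochondrion to plastid); the 5-label InnateDB vocabulary folds into it by
aliases, with "cell surface" read as the plasma membrane. Matching is
case-insensitive. Any unrecognized or empty annotation falls back to the
cytosol, making compartment assignment a total function — a deliberate
choice: a layout tool should never refuse a network over annotation gaps.
An optional multivalued `Cellular Component` attribute (list att or
comma-separated string) is carried along so that selecting a node can
highlight *every* compartment the molecule is known to occupy, not only the
one used for placement.

Duplicate node ids and duplicate unordered edges are collapsed on load,
keeping the first occurrence. First-wins is a choice the input format does
not dictate; it is deterministic and order-stable, which matters more here
than any merge heuristic. Self-loops are kept (they are real data) but
flagged: they exert no link force and do not count toward degree.

## The cell diagram

Everything is a circle. With `R = min(canvas)/2 − margin`:

| region | geometry | default |
|---|---|---|
| cell wall | annulus | outer `R`, thickness `0.05 R` |
| plasma membrane | annulus | thickness `0.05 R` |
| cytoplasm | disc | radius = membrane inner radius |
| nucleus | central disc | radius `0.22 R` |
| organelles | discs on a ring | ring `0.55 R`, radius `0.12 R` |
| extracellular | canvas minus outer ring | — |

Circle-only geometry is a cost decision: both the membership test and the
constraint projection reduce to one distance computation per circle, which
is what keeps the per-tick constraint pass cheap at thousands of nodes.
Compartments nobody is annotated to are pruned: no cell wall ring when no
node lives there (the membrane becomes the outermost ring), no unused
organelle circles. The diagram proportions are this package's own choices
— no reference layout prescribes them — and are overridable through the
style configuration. When many organelles are present the default radius
is automatically shrunk to the largest value at which all circles fit on
the placement ring without overlap (at most `a·sin(π/n)` for `n` circles
on a ring of radius `a`, taken at 98% for a visible gap); construction
fails only when the geometry is truly infeasible. The alternative — erroring
whenever the default radius does not fit — would make fully annotated
networks unloadable, which is the wrong default for a viewer.

Organelles can be moved anywhere, carrying their member nodes rigidly —
even into the extracellular space. No consistency check is applied on
purpose: rearranging the diagram is an exploration gesture, and control
over cell-structure consistency is left to the user.

## The simulation

Mechanics follow the D3 v3 force layout: per tick, (1) link springs toward
rest length `link_distance`, (2) Barnes–Hut many-body charge with opening
angle `theta`, (3) weak gravity, (4) position-Verlet integration
(`velocity = (pos − prev) × friction`, forces scaled by the temperature
`alpha`), then (5) the constraint projection, then (6) the collision pass,
and finally `alpha ← alpha × alpha_decay`. Defaults (charge −30, link
distance 20 px, friction 0.9, theta 0.8, alpha 0.1 → ×0.99 per tick, stop
below 0.005, gravity 0.1) are the D3 v3 ones; the original parameterization
of this layout family is user-configurable rather than published, so the
upstream library defaults are the honest reference point. The 0.1/0.99/0.005
schedule cools in ~300 ticks, which is the tick budget used throughout the
tests. Only visible nodes participate, so filtering then restarting the
layout computes a layout of the visible subgraph alone.

Gravity pulls each node toward its *region's* centroid (an organelle's
center, else the cell center) rather than the canvas center. With
canvas-center gravity, cytosolic nodes pile against the nucleus border;
with region centroids the annulus and cytosol populations stay spread.

### Constraint projection

A node at distance `R` from its compartment circle's center, outside the
circle, moves to `center + (r_eff/R)·(p − center)` with
`r_eff = r − node_r`: the *node disc*, not just its center, respects the
region. The cytosol applies the same projection outward from the nucleus
and each organelle (`r_eff = r + node_r`) and inward from the cytoplasm
border; wall and membrane clamp the radial distance into
`[r_inner + node_r, r_outer − node_r]`; the extracellular region clamps
outside the outermost ring and inside the canvas. The projection is
applied only when violated, is idempotent, and preserves the polar angle
around the governing circle. Degenerate input — a node exactly at an
excluding circle's center, where the radial direction is undefined — is
displaced along +x before projecting, making the operation total and
deterministic. For the cytosol, expulsion from one circle can push a point
into another; the pass loops (at most 25 rounds, in practice 2–3) until
membership holds.

### Collision resolution

After each tick a quad-tree (bucketed leaves, depth-capped so coincident
points terminate) enumerates overlapping disc pairs; each pair is pushed
apart along its center line by `repulsive × overlap/2` per node, pinned
nodes absorbing nothing (their partner takes the full share), and displaced
nodes are re-projected into their compartments. `repulsive` trades
stability for separation speed; at 0 the pass is the identity, and it is
auto-disabled above `large_network_threshold = 1000` nodes, where overlap
is better read as edge density anyway. The symmetric-push rule is this
package's choice; only the parameter's direction of effect is prescribed
by the layout family. Pairs are processed in deterministic sorted order
with immediate position updates, so one pass resolves each detected
overlap exactly (two radius-5 discs at distance 6 end at distance 10 with
`repulsive = 1`).

The same quad-tree code drives the Barnes–Hut charge force (cells opened
when `s/d ≥ theta`); at `theta = 0.5` the approximation stays within a few
percent of exact summation, and `theta = 0` degenerates to the exact sum.

## Edge bundling

Force-directed edge bundling subdivides each edge into control points that
attract corresponding points of *compatible* edges while internal springs
keep each polyline smooth. Compatibility is the product of the standard
four measures (angle, scale, position, visibility), each in [0, 1] and
symmetric; only pairs at or above the threshold interact. The published
FDEB parameterization is used as the default (`K = 0.1`, 6 cycles starting
at 90 iterations decaying by 2/3, subdivisions doubling from 1, step 0.1
halving per cycle, threshold 0.6). The attraction term uses the raw
coordinate difference between corresponding points — the behavior of the
widely used JavaScript implementation — which decays as points merge and so
converges without the oscillation that unit-vector attraction exhibits.
Endpoints never move. Bundling operates on visible edges only, consistent
with the filter semantics.

## Measures, selection, export

Degree, betweenness and local clustering coefficient are computed over the
visible subgraph: degree ignores self-loops; betweenness is unnormalized,
unweighted, over unordered distinct pairs via Brandes' accumulation (the
canonical default where no variant is specified); clustering is
`2·e_nbr/(k(k−1))` with 0 for degree < 2. Search is exact-label and
case-insensitive — gene-symbol query lists would over-select under
substring matching. Filtering only flips visibility flags (edges visible
iff both endpoints are) and is fully reversible.

SVG output is assembled as text with fixed number formats, so identical
inputs give byte-identical documents, and node coordinates in the SVG are
printed with the same six-decimal format as the coordinates table. The
donut chart of per-compartment counts sits in the bottom-left corner; its
CSV lists label, count, percentage. Compartment fills come from a fixed
"BrBG" diverging assignment over the canonical label order, so a
compartment keeps its color across networks; cell contours are light,
organelle contours low-contrast, node contours dark, and unselected nodes
turn translucent when a selection exists. Numeric node coloring ramps
light-to-dark so the darkest node carries the highest value; categorical
coloring assigns a qualitative palette by first appearance. PNG export
redraws the same scene model on R's `png` device at a configurable DPI —
the SVG remains the source of truth for exact geometry.

## The synthetic generator

`gen_spec()`/`generate_network()` emulate the *shape* of IIS/InnateDB
exports: a compartment distribution spanning all four region kinds
(defaults: nucleus 0.25, cytosol 0.25, mitochondrion 0.12, plasma membrane
0.12, extracellular 0.10, ER 0.08, endosome 0.05, cell wall 0.03), a 5%
rate of unknown/empty labels to exercise the cytosol fallback, a 20% rate
of multivalued `Cellular Component` lists, and either Erdős–Rényi or
preferential-attachment topology (the latter reproduces the hubs that make
degree coloring informative). Generation is fully deterministic given the
spec. What it does **not** emulate: real interactome degree mixing,
compartment-correlated connectivity, or biologically meaningful labels —
so green tests demonstrate the geometric and algorithmic contract, not
biological fidelity of any particular layout.

## Problem sizes and numerical choices

The test suite runs simulations at 50–2000 nodes for 300 ticks (the
natural length of the default cooling schedule) and one synthetic
interactome-scale instance of 1942 nodes / 17498 edges; membership is
audited after every tick at tolerance 10⁻⁶ px against closed boundary
comparisons. Betweenness is verified exhaustively against an
all-shortest-paths enumeration on every labelled graph with 4 nodes and on
seeded 5–7-node samples, and against an independent graph library on 100
random networks. All randomness flows through explicit integer seeds;
reruns are byte-identical.

## Known limitations

- One placement compartment per node: multi-localized molecules are placed
  by their single `Selected CC`; other annotations are only highlighted.
- Constraining dense networks into small organelle discs necessarily
  yields node overlap; the collision pass mitigates but cannot guarantee
  separation (nor should it at interactome scale, where overlap encodes
  density).
- Bundling is O(E²) in the compatibility stage; at tens of thousands of
  edges it is a batch operation, not interactive.
- The renderer draws the diagram and network; it is not a general SVG
  scene graph (no zoom, tooltips, or incremental updates — this is a
  headless tool).
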