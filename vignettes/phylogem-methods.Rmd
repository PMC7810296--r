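---
title: "Models and methods in phylogem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylogem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phylogem reimplements, as one tested pipeline, the analysis style used in
morphology-based historical biogeography of flightless insects: an
equal-weights parsimony phylogeny from a discrete character matrix,
parsimony ancestral-state reconstruction of ecological traits on that
phylogeny, and an event-based reconstruction of range evolution on a
degree-pixel grid. The bundled case study is the Neotropical cricket genus
*Eidmanacris* (28 species across the Atlantic Forest, Cerrado and
Chiquitano Dry Forest). This vignette records the models, the tunable
parameters, and the design decisions taken where the methods literature
leaves choices open.

## 1. Parsimony scoring

Characters are unordered ("Fitch") with equal weights; states are the
digits 0–9, with `?` (unknown) and `-` (inapplicable) both scored as full
ambiguity. The two missing codes are distinguished in reporting only: the
software that this field uses treats them identically during optimization,
and the distinction is taxonomic rather than algorithmic.

Scoring is implemented as a unit-cost Sankoff dynamic program
(`fitch_length()`). On binary trees it reduces exactly to the Fitch
algorithm; on multifurcations it scores the polytomy as a simultaneous
radiation, which is the exact minimum over all internal assignments (the
pairwise-folding generalization of Fitch would only approximate it). The
conditional cost tables are kept so state optimization and branch-support
rules can reuse them without rescoring.

Ensemble fit indices follow the standard definitions: with per-character
length $s_j$, minimum conceivable steps $m_j$ (observed states minus one)
and maximum conceivable steps $M_j$ (steps on a star tree),

$$\mathrm{ci} = \frac{\sum_j m_j}{\sum_j s_j}, \qquad
  \mathrm{ri} = \frac{\sum_j (M_j - s_j)}{\sum_j (M_j - m_j)},$$

with parsimony-uninformative characters ($M_j = m_j$) excluded from both
ri sums to avoid 0/0; they always satisfy $s_j = m_j$, so the exclusion
changes nothing else. Raw ratios are kept; comparisons against published
values round to two decimals.

### ACCTRAN and DELTRAN

Both flavors produce one most-parsimonious assignment per character
(`optimize_states()`), and the per-character change counts provably equal
the Fitch length either way — a property the tests assert on random
matrices:

* **ACCTRAN** is the classic second pass over the downpass (Hartigan)
  state sets: in preorder a node keeps its parent's state when that state
  is in its downpass set, and otherwise changes immediately. Because the
  downpass sets ignore information from above, ambiguous changes land as
  close to the root as possible.
* **DELTRAN** is a preorder conditional dynamic program: a node keeps its
  parent's state whenever doing so still attains the conditional optimum
  (cost at most one above the subtree minimum), delaying changes toward
  the tips.

Ties among admissible states break toward the lowest state label, making
reconstructions deterministic. The per-character choice of flavor made in
the original study is not inferable from the publication, so the flavor is
a user argument (default DELTRAN), as is a per-character table if needed.

A change on a clade's stem branch is an **exclusive synapomorphy** when
its character reaches its minimum conceivable length on the whole tree
(character consistency of 1), otherwise homoplastic
(`classify_synapomorphies()`).

## 2. Tree search, consensus, Bremer support

`heuristic_search()` performs random-addition-sequence starts (each taxon
inserted at the placement minimizing incremental length, ties to the first
canonical edge) followed by first-improvement branch swapping to a local
optimum. The move sets are NNI, SPR, and TBR; TBR is implemented literally
as bisection of every edge and reconnection across all edge pairs of the
two fragments, which subsumes SPR. Searches run on unrooted topologies;
results are rooted on the declared outgroup.

Tree identity is judged after collapsing branches that lack character
support, because most-parsimonious-tree counts depend on the collapsing
rule. Three rules are exposed:

* `no-unambiguous-support` (default; `min-length-zero` is accepted as an
  alias): a branch survives only if some character changes on it in
  *every* most-parsimonious reconstruction. This is computed exactly from
  the inside/outside Sankoff tables rather than from any single
  reconstruction.
* `strict`: collapse only branches on which no character changes in *any*
  most-parsimonious reconstruction.
* `none`.

Bremer (decay) support uses converse-constraint searches: the search
objective penalizes trees containing the clade, and the support is the
extra length of the best clade-free tree. This matches the scripted
converse-search practice in the field and gives a well-defined per-clade
answer without pooling suboptimal trees. Decay values are lower bounds in
the same sense any heuristic search result is: more search effort can only
tighten them upward.

`strict_consensus()` intersects rooted clade sets and rebuilds the tree
from the shared laminar family; it is idempotent and order-independent.

## 3. Trait ancestral states

`reconstruct_trait()` optimizes one categorical trait on a fixed topology,
reporting total steps, exact per-node most-parsimonious state sets (from
inside/outside costs), and one delayed-transformation change list. Traits
are unordered by default. Body size is binned by `classify_size()` into
six contiguous 3 mm classes (0: below 12 mm, then 12–15, 15–18, 18–21,
21–24, 5: 24 mm and above; lower-inclusive). Size is ordinal in spirit,
and an ordered (Wagner) mode charging $|i-j|$ is available, but the
unordered default matches the generic parsimony reconstruction used in the
study this package mirrors.

Reconstruction runs on the ingroup subtree only: the bundled trait tables
cover the 28 ingroup species, and the published step counts (habitat 5,
size 12, bristles 1) are reproduced under that choice. Outgroups can be
attached by the caller with explicit states if desired.

**The bundled topology is a reconstruction, not the original file.** The
machine-readable tree behind the published figures is a supplementary
download that is not reproduced in the article text. The fixture
(`eidmanacris_ingroup_topology_synthetic.nwk`) was rebuilt from the
printed clade memberships and the clade relationships described in the
results, and it reproduces the published ancestral-state block exactly
(5/12/1 steps; straminicolous root habitat; root size class 12–15 mm; a
single gain of the fully bristled metanotum on clade N's stem). Within
the few clades whose internal resolution is not fully specified in print,
the step counts were verified to be insensitive to the remaining choices.
A green trait-reconstruction test therefore establishes that the method
reproduces the published character-evolution scenario on the published
clade structure — not that the original tree file was recovered
byte-for-byte.

## 4. The event model of range evolution

Occurrence records (taxon, longitude, latitude in decimal degrees) are
rasterized to a grid of `pixel`-degree cells by floor division; `fill = 1`
means a record occupies exactly its own cell. A taxon's range is its set
of occupied pixels; no projection and no cell adjacency is used — the
model is purely set-based.

Every internal node receives an ancestral range $A$ (non-empty, at most
$Z$ pixels; default $Z = 10$, enforced as a hard cap, with an optional
soft mode charging one step per excess pixel) and one of four events
relating it to the child ranges $D_1, D_2$. The published description of
the cost rules is prose; phylogem codifies them as:

* vicariance: $|D_1 \cap D_2| + |A \,\triangle\, (D_1 \cup D_2)| + c$
  (overlap is penalized; an ideal range split costs exactly $c$);
* sympatry: $|A \triangle D_1| + |A \triangle D_2| + c$;
* point sympatry ($D_2$ the point lineage):
  $(|D_1 \cap D_2| - 1)^{+} + |(D_1 \cup D_2)\setminus A| +
  |A \setminus D_1| + c$, where the overlap term is replaced by a one-step
  penalty when the descendants do not overlap (the prose presumes an
  overlap; one pixel change creates it);
* founder ($D_2$ the founder): $(|D_2| - 1) + |D_2 \cap A| +
  |A \triangle D_1| + c$.

All four base costs default to 1. Asymmetric events are evaluated in both
child orientations and the cheaper is kept; cost ties between events break
deterministically in the order vicariance, sympatry, founder, point
sympatry. Each ideal configuration costs exactly its base cost, and
scaling the base costs scales ideal configurations proportionally — both
are asserted as tests.

The prose description leaves open whether branch range-changes are summed
separately from the event terms; the formulas above embody them (default),
and `gem_config(change_mode = "separate")` switches to an explicit
symmetric-difference branch term should anyone want to recalibrate against
a published total cost.

`flip_search()` minimizes total cost by restarted local search: each
replicate initializes every internal range from its children
(intersection when non-empty, a truncated union, or a copied child, chosen
at random) and then flips single-pixel memberships at single nodes,
accepting strict improvements to a local optimum. All distinct
reconstructions at the best cost (and optionally within a slack, since
published analyses report near-optimal reconstructions alongside optimal
ones) are returned with per-reconstruction event censuses — censuses of
tied reconstructions are reported individually, never pooled. The search
is deterministic given the seed. Published protocol runs 10 × 10,000
replicates; the tests scale this down (tens to hundreds of restarts at toy
sizes, where exhaustive enumeration confirms optimality).

`permutation_test()` shuffles the taxon-to-range map and re-optimizes at
reduced effort. One honest caveat the test suite documents: because the
model is purely set-based, configurations whose ranges are exchangeable
(for example, every tip holding a distinct single pixel) have
permutation-invariant cost, and the test has no power there. Structure
means clade-shared, partially overlapping multi-pixel ranges.

## 5. The synthetic world

The generators (`simulate_tree()`, `simulate_matrix()`,
`simulate_range_history()`, `simulate_trait()`) are pure functions of
their arguments plus a seed. Branch "lengths" are abstract change counts —
the analyses mirrored here are all cladogram-based, so no clock or time
axis is simulated.

* Matrices evolve each character independently: uniform root state,
  Poisson(`rate`) change events per branch, each event moving to a
  uniformly chosen different state. The realized change count is returned,
  giving the parsimony bound (tree length on the true tree never exceeds
  it) for free.
* Range histories apply one ideal event per node from a script (or a
  lazily drawn feasible event when scripted as `random`), so a noiseless
  history's true reconstruction cost equals the internal node count under
  unit costs. Scripted vicariance cascades are made feasible by splitting
  ranges according to each subtree's pixel needs.
* Traits plant an exact number of changes on distinct branches, each
  introducing a fresh state. The generator flags configurations where
  parsimony can legitimately need fewer steps (a planted branch ancestral
  to another, or changes covering every root child so the root state comes
  free), and the recovery tests condition on that flag.

For the tree-recovery property (bipartition recall at least 90% from a
20-taxon, 100-character binary matrix), "low rate" had to be made
concrete: the chosen 0.06 changes/branch/character gives about six
expected supporting changes per internal edge — enough that no edge goes
unsampled — while total homoplasy stays moderate (about 2.3 expected
changes per character). At rates below about 0.035 a 100-character matrix
simply does not sample every short edge and recall plateaus near 0.85
regardless of search effort; this is a property of the stated world, not
of the search.

What the synthetic world does **not** emulate: spatial autocorrelation,
range cohesion or cell adjacency (ranges are arbitrary pixel sets, exactly
as the cost model sees them), collection bias, and character correlation.
A green synthetic test therefore establishes algorithmic correctness
against enumeration oracles and ground truth, not realism of the
generating process.

## 6. Reproducibility of the published numbers

Of the published quantities, the trait-reconstruction block is fully
recomputable from printed material and is asserted green in the acceptance
tests. The search statistics (240 steps, ci 0.47, ri 0.78, 1 and 11 trees,
Bremer 11, the seven exclusive synapomorphies of the genus) and the range
reconstruction (cost 44; 3 vicariances, 5 sympatries, 17 founder events,
no point sympatry) depend on the character matrix and the occurrence file,
which exist only as binary supplementary downloads. The corresponding
acceptance tests contain the complete verification blocks and fail with an
explanatory message while those inputs are absent; dropping transcriptions
into `inst/extdata/study_matrix_38x98.tsv` and
`inst/extdata/study_records_61.tab` activates them unchanged.

## 7. Numerical and degenerate-input conventions

State and event tie-breaks are deterministic (lowest state label;
documented event order). Every stochastic routine takes an explicit seed
and restores the caller's RNG state. Ranges must be non-empty; terminals
without records, leaves without trait states, and matrix characters with
no observed state are rejected with errors naming the offender rather than
silently coerced. A fully missing leaf row is legal (it scores as
ambiguity everywhere, like the female-only "wildcard" terminal of the case
study, whose inclusion is exactly what turns one most-parsimonious tree
into eleven).
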