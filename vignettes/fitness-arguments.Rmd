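---
title: "Structured fitness-for-purpose arguments for biological simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured fitness-for-purpose arguments for biological simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsnarg)
```

## Why argue fitness for purpose?

A computational model of a biological system cannot be proven correct, but
its developers can make a structured, reviewable case that it is *fit for a
stated purpose*. `gsnarg` adapts the assurance-case practice of
safety-critical engineering to biological simulation: the case is a tree of
typed nodes in a goal-structuring-notation (GSN) style. A top-level **goal**
(claim) is decomposed by **strategy** nodes into sub-goals that bottom out in
**evidence** (statistical results, publications), with **context**,
**assumption** and **justification** nodes scoping claims. Crucially for
biology — where knowledge is always incomplete — a claim that cannot
currently be substantiated may be marked **undeveloped** (drawn with an open
diamond) rather than papered over: the gap itself becomes a documented,
reviewable statement about where laboratory work is needed.

Two edge kinds carry the structure: `supported_by` (solid arrowhead) for the
argumentative decomposition and `in_context_of` (open arrowhead) for
scoping attachments. The graph is a strict tree — one parent per node — which
matches how such arguments are read and makes collapsing, labelling and
layout unambiguous.

## The data model and its well-formedness rules

Graphs are built through four constructors (`gsn_graph()`,
`gsn_add_child()`, `gsn_set_status()`, `gsn_collapse()`) that cannot produce
an ill-formed graph; the edge kind is inferred from the child kind, so users
never wire edges by hand. Documents decoded from files, however, can violate
the notation, so `gsn_validate()` checks a fixed rule set (single goal root,
acyclicity, reachability, edge typing, evidence as leaves, undeveloped only
on childless goals, no dangling or duplicated identifiers) and returns coded
issues rather than raising. Three of these rules cannot be violated in
isolation in a finite graph — if every node has a parent there must also be
a cycle, and an unreachable component necessarily contains either a second
root or a cycle — so validation reports of real documents often carry small
clusters of related codes.

Two deliberate typing choices, where standard GSN practice leaves room:

* evidence directly under a strategy is *tolerated with a warning* rather
  than forbidden — the evidence-substantiates-claims reading is preferred,
  but refusing to load such documents would be unhelpful;
* a node with more than one parent is reported under `BAD_EDGE_TYPING`,
  keeping the code enumeration closed while still rejecting non-trees.

Hierarchical labels follow field convention: the root is `1`, the k-th
supporting child of `L` is `L.k` (so the strategy under goal `1.1.3` is
`1.1.3.1`), and context-family attachments get per-parent suffix labels
`L-C1`, `L-A1`, `L-J1`. Labelling is idempotent and derived purely from
insertion order, which is the canonical child order everywhere (labelling,
serialization, layout).

`gsn_metrics()` summarizes an argument for review. A *terminal goal* is a
goal with no goal or strategy among its supporting children — the places
where the argument must bottom out — and coverage is the fraction of
terminal goals carrying at least one evidence node. Coverage is a
bookkeeping aid for spotting unsubstantiated branches, not a quality score:
an argument with honest undeveloped claims and coverage below 1 can be a
stronger case than one with superficial evidence everywhere.

## Serialization

`gsn_save()` writes a versioned JSON dialect (`format: "gsn-argument"`,
`version: 1`) in canonical form: nodes sorted by uid, edges sorted by
(source, target, kind), keys sorted, two-space indentation, trailing
newline. Equal graphs therefore serialize byte-identically, which makes
arguments diff-able and version-controllable — the practical point of the
format. Because sorting would destroy child order, every edge records an
`ordinal` (its position among same-kind siblings); ordinals are written on
`in_context_of` edges too, since context numbering also depends on order.
`gsn_load()` raises only on structurally unusable input (wrong format tag or
version, unknown kind, duplicated uid, dangling edge) and reports everything
else as validation issues. No compatibility with any other argumentation
tool's file format is claimed.

## Diagram layout and rendering

The layout (`gsn_layout()`) is a bottom-up subtree-width tree layout in the
Reingold–Tilford style: support depth defines the horizontal layer, each
subtree is allocated a disjoint horizontal slab whose width is the maximum
of its own width and the sum of its children's slabs, and each node is
centred in its slab. Context-family attachments sit in the same vertical
band as their source, to its right, inside the source's slab. Overlap
freedom and parent-above-child ordering are therefore guaranteed by
construction, and both are property-tested on random trees anyway. Collapsed
nodes keep their own box (plus a filled diamond) while their support subtree
is omitted; remaining siblings keep their relative order.

`gsn_render_svg()` emits SVG 1.1 with the notation's glyphs: goal =
rectangle, strategy = parallelogram, context = rounded rectangle,
assumption/justification = ellipse tagged `[A]`/`[J]`, evidence = circle;
solid versus open arrowhead markers distinguish the two edge kinds; open and
filled diamonds mark undeveloped and collapsed nodes. Text wraps at a fixed
character budget (26 characters, 16 inside circles) with boxes auto-sized to
the wrapped text; all coordinates are printed with one fixed decimal, so
output is byte-stable. Evidence hyperlinks become SVG link elements.
Colours are deliberately monochrome. PNG export replays the same layout on
R's cairo bitmap device at `ceiling(canvas × scale)` pixels and is
pixel-identical across runs on one platform; SVG is the full-fidelity
format of record.

## The statistical-evidence harness

The motivating use is turning a cell-motility comparison into an evidence
node. Tracks are timed 2-D positions (`track_id, t_min, x_um, y_um`),
uniformly sampled within a track; two behaviour responses are derived per
track: **velocity** = total path length / total duration (µm/min) and
**displacement** = straight-line first-to-last distance (µm). With uniform
sampling, path/duration equals mean instantaneous speed, so the choice
between the two conventions is immaterial here.

`partition_tracks()` splits tracks by the Euclidean distance of their
*first* position to an aggregation centre — strictly less than the
threshold (50 µm by default) is *near*, the boundary itself is *far*,
mirroring the convention that "near" means strictly within 50 µm.
Classification at observation start keeps group membership fixed over the
tracking period; per-frame reclassification is out of scope.

`mann_whitney_u()` computes U for the first sample as pairwise wins with
ties counted ½. For combined samples of at most 16 the two-sided p-value is
exact, by full enumeration of all `choose(n1 + n2, n1)` group assignments
of the pooled values — valid under ties, where the textbook U distribution
is not — with two-sidedness defined by distance of U from its null mean
`n1·n2/2`. Larger samples use the normal approximation with tie and
continuity corrections (matching `wilcox.test(exact = FALSE, correct =
TRUE)`, which the tests use as an independent cross-check; the exact branch
is cross-checked against `wilcox.test(exact = TRUE)` on tie-free samples
and against direct enumeration). The switch point of 16 keeps the exact
branch under ~13k enumerated assignments. No multiple-testing correction is
applied across the velocity and displacement responses; each evidence node
records a single test. A non-significant result is always worded as "no
significant difference at alpha", never as equivalence — absence of
evidence for a difference is not evidence of equivalence, and the wording
keeps reviewers from over-reading the node.

`compare_groups()` chains summaries, partition and test;
`attach_evidence()` appends the result as an evidence node whose statement
contains U, the group sizes, the p-value, the method and the verdict, with
an optional hyperlink to the underlying analysis.

### The synthetic track generator

`synthesize_tracks()` produces independent 2-D random walks,
`position[t+1] = position[t] + drift + N(0, step_sd²)` per axis, with
uniform start positions in a bounding box and 1-minute sampling by default —
a deliberately minimal emulation of a 1-hour *ex vivo* tracking session.
It reproduces exactly from a seed and restores the caller's RNG state. What
it does **not** emulate: persistent (correlated) motion, chemotactic bias
toward an aggregation, cell–cell interactions, track loss and imaging
noise. Passing tests on generated tracks therefore demonstrates the
correctness of the statistics pipeline, not biological realism of any
particular dataset; conclusions about real cells require real tracks read
via `read_tracks()`.

## The worked case study

`build_case_study()` constructs a complete argument for an agent-based
simulator of lymphoid tissue (Peyer's Patch) development: haematopoietic
LTin/LTi cells and stromal LTo cells in the pre-natal mouse gut, where
cell behaviour near forming aggregations changes and aggregations mature
into lymphoid organs. The top claim — that the model adequately represents
the biology — is argued over scientific context, abstraction adequacy and
experimental adequacy, decomposing into four sub-claims: underlying
biological data (1.1.1, argued over four strategies: LTin/LTi properties,
LTo properties, intestine environment, aggregation characteristics),
abstractions (1.1.2, four sub-arguments: chemokines, adhesion factors,
environment, cell signalling), 12-hour cell behaviour (1.1.3, with
Mann-Whitney evidence for cells near and far from a forming aggregation)
and 72-hour aggregation (1.1.4, three strategies). Claim 1.1.1.4.2 — that
simulated aggregations are quantitatively similar to those in vivo — is
left undeveloped, exactly because no quantitative in vivo data existed; it
is the argument's honest gap, not a defect.

Statements with an attested wording are kept verbatim; the rest are
paraphrases, flagged as such in the document metadata, and the evidence
hyperlinks are synthetic placeholders. Only the attested structure is
encoded; no leaf nodes beyond it are invented.
`case_study_facts()` exposes the structural facts as executable checks, and
the packaged JSON (`case_study_path()`) is byte-identical to
`gsn_save(build_case_study(), ...)` by test.

```{r case-study}
g <- build_case_study()
gsn_metrics(g)
unname(gsn_labels(g)[gsn_undeveloped(g)])
```

## Numerical and testing choices

Uniform-sampling checks tolerate relative jitter of 1e-6 in time steps;
distances and U statistics are exact doubles (ranks and half-ties are
dyadic, so no tolerance is needed for the U oracle equivalence). Degenerate
inputs are defined, not accidental: an all-tied large-sample comparison has
zero variance and p = 1; an empty track table partitions into two empty
groups; a single-node graph has depth 1, one terminal goal and coverage 0.
Property-style suites run at fixed seeds over generated trees — 1000 trees
for validation closure and serialization round trips, 500 for layout
invariants, 2000 sample pairs for the U oracle — sizes chosen to exercise
the combinatorics while keeping the full suite under a minute. The
`scripts/acceptance.R` entry point recomputes the same quantities from
scratch at a caller-supplied seed with 200–500 iterations per rate.

## Known limitations

Multi-parent argument graphs, GSN module notation, argument patterns and
automated synthesis are out of scope, as are 3-D tracks, per-frame
proximity reclassification and equivalence testing (TOST). PNG output
renders geometry and text via the cairo device but does not embed fonts;
the SVG output is the reproducible artifact. The case-study fixture encodes
text-attested structure only, so it is a faithful skeleton of the published
argument, not a reconstruction of every figure leaf.
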