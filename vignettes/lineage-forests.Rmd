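---
title: "Lineage forests from static label images: model, formats, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage forests from static label images: model, formats, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageforest)
```

## The problem

In tissues that must be fixed before imaging — early plant embryos are the
canonical case — cell divisions cannot be followed by time-lapse. Because
plant cells do not migrate and their walls persist, the division history is
still legible in a single segmented 3D image: an expert recursively pairs
sister cells, walking the pattern backwards one division at a time. This
package implements the bookkeeping that workflow needs: a forest data
structure whose leaves are the observed cells and whose internal nodes are
reconstructed mothers, serialization formats to save and exchange such
reconstructions, and image operations that project the forest back onto the
voxels.

## The forest model and its conventions

A forest is a set of disjoint, strictly binary rooted trees over positive
integer labels; label 0 is reserved for the image background and for "no
mother" in the file format. The modelling conventions, each of which was a
genuine design choice:

* **Mother labels.** A new mother is always `label_max + 1`, where
  `label_max` is the highest label ever assigned. This makes reconstructed
  labels disjoint from image labels by construction and makes a sequence of
  pairings fully reproducible from the order of its operations.
* **No label reuse.** Undoing a pairing retires its label forever and
  `label_max` never decreases. Reused labels would make a saved lineage
  ambiguous across editing sessions; stable provenance costs only unused
  array slots in the treeV file.
* **Unlink cascades.** The format is strictly binary, so a node cannot
  survive the loss of one daughter. Dissolving a mother therefore dissolves
  all its ancestors, the sibling branch at each level becoming a root. The
  alternative — re-parenting the surviving daughter upward — would silently
  rewrite divisions the user never asserted.
* **Only roots can be paired.** Pairing is the progressive bottom-up
  merging gesture of interactive reconstruction; allowing links into the
  middle of an existing tree would create nodes with two mothers or require
  implicit unlinks. Editing mid-tree is done by unlinking first.
* **Depth is per tree, root = 0.** A forest may have many roots (e.g. each
  progenitor of a 16-cell stage), and the absolute number of divisions
  since the zygote is unknowable from a static image, so generations are
  counted from each root downward. The generation-`g` cut maps each leaf to
  its ancestor at depth `g`, clamping shallow leaves to themselves — this
  is what keeps a stopped (undivided) cell visible and unmerged in rewound
  views, reproducing the generational gap of unbalanced lineages.
* **Tags are free text minus tab/newline** (the treeV field delimiters).
  A tag marks a node, and by extension the cells of its sub-tree; the same
  tag on several nodes delimits a whole anatomical domain.

## File formats

**treeV.** Two parallel arrays indexed by cell label from 1 to
`label_max`: mother-of-label (0 = root or never-instantiated label) and
tag-of-label. The on-disk dialect is a two-line UTF-8 file — mothers as
space-separated integers, tags as tab-separated fields, one trailing
newline, CRLF tolerated on read. The layout of the original interactive
tool's files is not publicly specified, so this dialect is defined (and
documented) here; it is deterministic and byte-stable, which the tests
exploit.

Membership on load is resolved against the companion image: the node set is
the image labels, every tagged index, and every index recording a mother,
closed upward under the mother array. Bare gaps — mother 0, no tag, never
referenced — are non-nodes: a discontinuous labeling and a retired label
are indistinguishable in the file, and the image is the authority on which
cells exist. When no image is at hand (e.g. CLI edits on the lineage
alone), every index is taken as a cell; this is lossless for editing
because unreferenced indices round-trip as zeros either way.

**Newick.** One statement per root in ascending root order, integer names
on every node (internal nodes included), no branch lengths, daughter order
preserved as given to `link_cells()`. Tags are not exported: Newick has no
standardized annotation slot and downstream consumers disagree on comment
conventions, so annotations travel in treeV only. The bundled reader
accepts exactly this dialect (it exists to round-trip exports); the test
suite additionally checks every exported clade against `ape`'s independent
parser.

## Image operations

Rewinding and extraction are implemented as a single vectorized relabeling
through a lookup table, so a 64^3 volume rewinds in milliseconds. Outputs
are always independent copies carrying the input's voxel spacing;
foreground never changes, only labels. Merged tag extraction resolves
nested tagged nodes by the **deepest tagged ancestor**: finer annotations
refine coarser ones. This case never arises in disjoint-domain tagging and
other resolutions (e.g. shallowest wins) are defensible; the choice is
documented rather than configurable.

TIFF I/O writes at the smallest of 8/16/32-bit precision that holds the
largest label. The 8- and 16-bit paths store integer samples and are exact;
the 32-bit path stores scaled floats and is exact for labels below 2^23.
The TIFF writer used here cannot embed resolution tags, so voxel spacing —
which only scales volumes, never topology — travels in memory, via the
`--spacing` flag, or from resolution tags of files produced by other tools;
a spacing argument always takes precedence over file metadata. 2D images
are simply one-slice volumes; every operation is dimension-agnostic.

## The division simulator

`simulate_divisions()` emulates the one property of a walled tissue that
the package's correctness rests on: **growth by recursive binary
subdivision of a fixed volume**. Starting from one inset box, each round
every active region splits into two non-empty halves by a random plane
through its centroid (falling back to an axis-aligned median split whenever
a drawn plane would empty a half — inevitable for very small regions);
with probability `stop_prob` a region permanently stops, producing
unbalanced trees; after the last round `dropout_frac` of the labels are
renumbered upward with gaps, emulating discontinuous labelings. The output
is the complete per-generation image stack plus the true forest, giving
every other module an exact oracle: rewinding the final image to
generation `g` must equal the stored generation-`g` image voxel for voxel.

Default rates in the test suite (`stop_prob` 0.2, `dropout_frac` 0.1,
3–5 generations) produce tissues of a few to a few dozen cells with both
balanced and stopped branches — the regime of early embryo reconstructions.
Internal labels are assigned deepest-first from `max(leaf label) + 1`, so
replaying them in ascending order through `link_cells()` reproduces the
ground truth exactly; this is itself a tested property, the desk-scale
analogue of an expert rebuilding a lineage from the image.

What the simulator deliberately does **not** model: curved or rule-driven
division walls, cell growth between divisions, segmentation errors, or any
mechanics. Passing its oracles therefore shows that the bookkeeping —
forest editing, serialization, relabeling, volumetry — is exact; it says
nothing about whether a human (or model) pairs the right sisters in real
images, which is outside the package's scope.

## Numerical and degenerate-input choices

* Volume standard deviations use the sample (n − 1) denominator; a
  single-cell group reports `NA`, never 0 — one cell carries no spread
  information.
* `group_summary()` counts only cells present in the volume table: a
  forest may legitimately cover more cells than one image (crops, multiple
  stacks).
* An all-background image yields an empty volume table, not an error;
  an empty label set refuses to build a forest ("no cells").
* A region of one voxel cannot split; the simulator refuses shapes too
  small for the requested generations rather than silently under-dividing.
* File errors are classified: structural violations of an otherwise
  readable file (cycles, non-binary records, array length mismatches) are
  parse errors (CLI exit 2), misuse of a valid state (self-pairing,
  re-linking, unknown labels or tags) are user errors (exit 1).

## Problem sizes used by the test suite

Round-trip properties run on 200 random forests of up to 256 leaves;
editing-algebra properties on 1000 random edit sessions; rewind oracles on
twelve 64^3 five-generation stacks spanning stop/dropout combinations;
smaller 2D stacks cover subdivision consistency and summaries. These sizes
exercise every code path (gaps, unbalanced branches, cascade unlinks,
multi-page TIFFs) while keeping the default check fast on one CPU.

## Known limitations

* treeV files from the original interactive tool are not guaranteed
  byte-compatible: that format's delimiters were never published.
* Only strictly binary divisions are representable; polytomies must be
  expressed as nested binary splits.
* Labels at or above 2^23 lose exactness on the 32-bit TIFF path.
* The apical/basal geometric decompositions used in embryo studies are
  external to this package; it provides the domain images and volume
  tables such analyses start from.
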