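---
title: "Constraint-based 3D structural motif search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based 3D structural motif search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motif3d)
```

## The problem and the model

A *structural motif* here is a small (typically 3–6, at most 32 residue)
arrangement of amino acids in three dimensions that need not be contiguous in
sequence: a serine-protease catalytic triad, an EF-hand calcium-binding loop,
or a buried cluster of side chains that stabilizes a fold.  Two families of
similarity measures exist for such configurations: the least-squares rmsd
after optimal superposition,

$$\mathrm{rmsd}(A,B) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}\lVert a_i-b_i\rVert^2},$$

and measures on the internal distance matrices $D^A$, $D^B$ of the two atom
sets (implemented as the sum of absolute entry differences; a distance matrix
determines a configuration up to mirror image).  Both yield a single number
whose meaning varies with the number and kind of atoms involved, which makes
thresholding unintuitive.  motif3d therefore defines motifs the third way: as
explicit *constraint sets*.  A configuration of residues is an instance of a
motif if and only if

* each residue's type is in its group's allowed set (a disjunction of
  one-letter codes, e.g. `DN` = Asp or Asn),
* each residue's secondary-structure state is in its group's allowed subset of
  {helix, strand, coil},
* every constrained inter-atomic distance $d$ satisfies
  $d^L \le d \le d^U$ (inclusive at both bounds), and
* every constrained signed sequence separation lies within its bounds.

Searching an $m$-residue structure for a $k$-residue motif naively ranges over
$\binom{m}{k}$ subsets (times $k!$ orderings); `count_candidate_subsets()`
reports this number.  The search is nonetheless fast in practice because the
constraint set is small and a candidate combination can be rejected at the
first violated constraint.

## The motif text format

A specification is plain text with three blocks.  `GROUP <label> <types>
<ss>` declares a motif residue; `DIST <label> <atom> <label> <atom> <min>
<measured> <max>` holds the least, measured and greatest admissible distance
in Å between two named atoms; `DELTA <label> <label> <min> <max>` bounds the
sequence separation between two groups and is optional.  Limits: 32 groups,
150 distance constraints, 31 per group pair.  Unrecognized lines are kept as
provenance comments; keywords are case-insensitive; `*` means no
secondary-structure restriction.  Because specifications are text, a user can
relax a constraint with an editor — changing a group's types from `D` to `DN`
tolerates an asparagine — and `widen_spec()` does the same for all distance
bounds programmatically.

## Generating motifs from structures

`build_motif()` derives a specification from an ordered residue selection of
an existing structure, so at least one satisfying structure is guaranteed to
exist.  Parameters that matter:

* **Atom pairs** — default `ca_only` emits one CA–CA constraint per unordered
  residue pair ($\binom{k}{2}$ constraints).  This is the scalable default:
  all-atom pairing would exceed the 150-constraint limit for $k \ge 4$ and
  side-chain atoms vary across the types a group may allow.  Explicit pairs
  are available for hand-crafted motifs (e.g. His NE2 – Ser OG in a triad).
* **Tolerance** — bounds are set at the measured distance ±x Å (default
  1.0 Å, the scale of backbone variation between crystal structures of
  related proteins) or ±x %.  Lower bounds are floored at 0.
* **Secondary structure** — `observed` records the assigned label;
  `wildcard` leaves it unrestricted.  Wildcard is the robust choice when
  searching structures whose assignment may differ from the source.
* **Separation (`delta`)** — `strict` emits, for each *consecutive* pair of
  groups in the order supplied, the observed signed separation as both
  bounds; a numeric slack `k` widens them by ±k; `none` omits the block.
  Chained (rather than all-pairs) constraints keep the block small while
  still fixing the overall sequence arrangement.

## Separation semantics

DELTA constraints apply to the *within-chain ordinal* position (the residue's
rank in its chain after parsing), not the author-assigned residue number, so
numbering gaps and insertion codes do not corrupt separations.  The
separation is *signed*, `ordinal(b) − ordinal(a)`, preserving the N→C
directionality of the source motif; negative lower bounds are legal and arise
naturally when a strict separation of 11 is loosened by ±25 (bounds −14, 36).
A finite DELTA between residues on different chains fails by definition.
`abs_delta = TRUE` gives magnitude-only semantics when direction should not
matter.  Permuted assignments of symmetric specifications count as distinct
matches by default (a search reports combinations of *atom coordinates*);
`dedupe_sets = TRUE` collapses them to one per residue set.

## The search algorithm

`find_matches()` is a backtracking constraint search: per-group candidate
lists are prefiltered by residue type and secondary structure; groups are
expanded most-constrained-first (smallest candidate list, ties by descending
incident-constraint count); each partial assignment is checked against every
constraint whose endpoints are both assigned and rejected at the first
violation; assignments are injective.  No spatial index is used: at desk
scale (hundreds of residues, ≤ 150 constraints) pairwise checks with early
exit dominate file I/O, not CPU.  Matches are reported in a deterministic
order (sorted by assigned residue keys), so repeated runs produce identical
report bytes.  `brute_force_search()` recomputes the same result by
exhaustively enumerating all injective assignments of type/ss-compatible
residues and filtering with the public predicate `match_satisfies()` — no
ordering heuristics, no early pruning — and is the oracle the engine is
tested against (guarded at 10^7 enumerated assignments).

## Structure input and normalization

PDB parsing is delegated to bio3d and then normalized for searching: first
MODEL only (motif search targets crystal structures; NMR ensembles would
multiply hits ambiguously), alternate locations resolved to the
highest-occupancy conformer (ties to first in file), MSE retained as Met,
waters/hydrogens/other HETATM dropped.  Residue identity is
`(chain, resno, insertion code)` verbatim from the file.

Secondary structure is assigned from backbone φ/ψ torsion windows: helix
φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] in runs of ≥ 4; strand φ ∈ [−180°, −40°],
ψ ∈ [90°, 180°] ∪ [−180°, −170°] in runs of ≥ 3; else coil; residues lacking
the atoms for a torsion (chain termini, breaks — detected as C–N > 2.0 Å)
degrade to coil.  This is deterministic and dependency-free; the windows are
arguments (`ss_windows()`) so a different backend can be swapped in.  Any
torsion-window scheme disagrees with DSSP-style assignments near element
boundaries, which is why `wildcard` is the recommended search policy and the
worked examples in the field use `*`.

## Superposition and scoring

`superpose()` is the standard SVD (Kabsch) least-squares fit with centroid
pre-centering and determinant sign correction, so only proper rotations are
returned and a mirror image cannot reach rmsd 0.  `rmsd()` itself never fits —
keeping measurement and fitting separate makes the optimality property
testable (the fitted rmsd must beat any sampled rigid transform).
`backbone_rmsd()` scores matched motifs over atoms {N, CA, C, O} per residue
(configurable; conventions differ on including O, so comparisons carry a few
hundredths of an Å of atom-set ambiguity), dropping pairs where either side
lacks the atom and recording how many were dropped.

## The synthetic test bed

`make_chain()` builds single-chain structures from idealized internal
coordinates (bond lengths/angles from standard peptide geometry, φ/ψ per
secondary-structure state, trans peptide bonds; full backbone plus CB except
glycine).  Motifs are *planted* by forcing residue types at chosen positions
and, for additional copies, transplanting a random rigid-motion image of the
template's atoms (recentred on the copy positions), optionally with isotropic
Gaussian coordinate noise of known σ per copy.  Rigid copies preserve every
internal distance exactly, so ground truth is constructive: a motif built
from the template with tolerance x must recover every copy whose noisy
distances stay within bounds — a condition tests check analytically per
constraint rather than assuming.

What the generator does **not** emulate: real side-chain rotamers (only CB
stubs, so test specs constrain backbone/CB atoms), crystallographic disorder,
multiple chains per file, or realistic residue-type composition (uniform by
default).  Passing tests therefore demonstrate the correctness of the
constraint machinery, not retrieval performance on real databases; the
worked-example tier against deposited PDB entries covers that and requires
the coordinate files to be supplied locally.

## Numerical choices and degenerate inputs

Distance-bound comparisons are inclusive at both ends.  Distances are exact
Euclidean values on coordinates carrying the PDB format's 3-decimal
precision.  A named atom missing from a candidate residue fails that
candidate (it never raises), and unreadable files in a batch are skipped
with a warning.  Empty structures yield empty match lists; an atom-free file
is an error.  `superpose()` requires ≥ 3 point pairs; `backbone_rmsd()`
requires ≥ 3 usable atom pairs.  Fixture generation rounds coordinates to
3 decimals *before* building the model, so written and in-memory fixtures are
bit-identical.

## Problem sizes used in the shipped checks

The randomized verification runs at desk scale, chosen to keep the exhaustive
oracle exact and the whole suite quick: 100 structure/motif pairs with chains
of 50–200 residues and motifs of 3–5 groups (chain length coupled to motif
size so the oracle enumerates ≤ ~10^5 assignments), 30 self-recovery builds,
20 widening cases, 1000-transform superposition optimality sampling, and one
500-residue / 5-group / 10-constraint timing case.  These sizes match the
scale at which the constraint representation is intended to be used
(motifs ≲ 10 residues).

## Known limitations

* Secondary-structure labels come from torsion windows, not hydrogen-bond
  topology; searches that restrict ss should expect boundary disagreements
  with other assigners.
* No symmetry-mate expansion, nucleic-acid support, or mmCIF input.
* Sequence separation across chains is undefined rather than infinite; motifs
  spanning chains must use `delta = "none"`.
* The search engine is exact, not heuristic: pathological specifications
  (all-wildcard groups with loose bounds in large structures) enumerate many
  candidates; the 10^7 oracle guard does not apply to `find_matches()`, which
  relies on pruning instead.
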