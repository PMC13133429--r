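---
title: "Detecting circular permutations and internal symmetry from SSE strings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular permutations and internal symmetry from SSE strings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssesym)
```

## The representation

`ssesym` treats a protein chain as a string of secondary-structure
elements. Per-residue 3-state assignments (H/E/C) are segmented into
maximal helix and strand runs; coil is discarded; each run becomes one
character. Case carries the element type (uppercase strand, lowercase
helix) and the letter carries a length bin with resolution that decays
with length:

* lengths 2–10: one letter each (2 → `A`, 3 → `B`, …, 10 → `I`);
* lengths 11–30: bins of width 2 (`J` … `S`), with length 11 assigned to
  the first bin so the map is gap-free;
* lengths 31–48: bins of width 3 (`T` … `Y`), then a single overflow token
  `Z`.

The 48-residue cap is the default because it makes the alphabet exactly
the 26 case-paired letters; the case encoding is part of the data model
(gap penalties and mismatch scores are keyed on it), so we do not extend
the alphabet with case-less symbols. The cap, the minimum kept run length
(default 2, where the token map starts), and the 8-to-3-state reduction
table ({H,G,I} → H, {E,B} → E, rest → C) are all configuration keys.

Assignments can come from a DSSP output file, from a plain sidecar string
produced by any assigner, or from a built-in C-alpha-only geometric
fallback (distance criteria on i→i+2/3/4 separations, in the style of
P-SEA). The fallback exists so synthetic fixtures need no external tool;
it is not a hydrogen-bond assigner and disagrees with DSSP near element
edges.

## Detection logic

**Circular permutations.** The query token string is doubled and aligned
locally against the target with Smith–Waterman under element-specific
affine gaps: the penalty charged for a gap column is that of the token
being skipped (helix and strand classes each carry their own open/extend
penalties, default −4/−1). A hit whose query range spans the duplication
seam is a CP candidate when each side of the seam holds at least 3 SSEs.
Candidates pass a cheap similarity surrogate (a monotone blend of
normalised alignment score, token identity and coverage, calibrated to 1
for self-alignments) before the expensive verification; the surrogate
only affects which candidates are verified, never the correctness of an
accepted call. Verification maps the seam to residues, rebuilds the query
with its C-terminal segment in front, and computes exact TM-scores in
both orders. The decision rule is `tm_rearranged >= 0.5` and
`delta_tm >= 0.1`.

Each unordered pair is evaluated in both role assignments and the record
with the better rearranged TM-score is kept. One subtlety: the residue
gap between the two segment images is measured on the *target*, so an
insertion is only visible in the role where the inserted material sits in
the target. The kept record therefore carries the larger gap seen across
the two roles, and the indel rule (gap ≥ 40 residues, or ≥ 60% of the
smaller segment) is applied to that value. Without this, the indel flag
of a pair would depend on which role happened to win a TM tie.

**Split symmetry.** Hits whose ΔTM stays below 0.1 often indicate
two-fold internal symmetry rather than permutation; the chain is split at
the duplication boundary and the halves are aligned (normalised on the
shorter); TM ≥ 0.5 classifies the chain as symmetric.

**Self-scanning.** For repeats that no cross-boundary alignment reveals,
a window starting at 3 SSEs (the smallest topological unit) grows one SSE
at a time and is aligned against the remainder of the chain, for every
start position, until fewer than 3 SSEs remain. For a 19-SSE chain the
N-terminal start contributes 14 window alignments. Retained hits (both
sides ≥ 3 SSEs, verified TM strictly above 0.5) are consolidated by
sequential maximisation: candidates sorted by start position; among
overlapping candidates (more than half of either hit's covered SSEs
shared) the higher TM wins when the difference is at least 0.05,
otherwise the longer residue span. Units are then summarised per
connected component of the range-overlap graph, split at gaps of 3 or
more SSEs, with `repeat_count = floor(coverage / minimal unit length)`.

Perfect k-fold tandem arrays with k ≥ 4 consolidate into double-size
units — the window extends across a unit boundary with an equally perfect
score and the longer span wins — so a 4-fold array is reported as 2
repeats of a doubled unit. This coarsening is inherent to the
scan-and-consolidate design; the planted-repeat tests accept
{k, ⌈k/2⌉} and the count never exceeds k.

**Networks.** Detected pairs form an undirected graph (one edge per pair,
max rearranged TM, flags cp/indel/both). Clustering uses igraph's Leiden
implementation (modularity objective, resolution 1.0, seeded, unweighted
edges by default — the TM weights are kept for reporting because there is
no principled reason they should steer community structure) or a
dependency-free union-find components method that is invariant to edge
order.

## The TM-score engine

TM-score for a fixed correspondence is the maximum over superpositions of
`(1/Lt) * sum_i 1/(1 + (d_i/d0)^2)` with
`d0 = max(1.24 (Lt-15)^(1/3) - 1.8, 0.5)`; the 0.5 Å floor keeps d0
positive for normalisation lengths up to 21. `Lt` is the length of the
normalisation chain (`shorter` by default for unit-vs-unit comparisons,
configurable because the score depends on the relative size of the
compared segments). The maximisation seeds Kabsch fits from contiguous
fragments of the full, half and quarter correspondence length at sliding
start positions (stride 1 up to 60 pairs, coarser beyond to bound cost)
and refines each by refitting on the pairs within d0, growing the cutoff
by 0.5 Å whenever fewer than 3 pairs survive, until the included set is
stable (at most 20 rounds). Reflections are excluded by the determinant
correction in the SVD.

Sequence-order alignment (`tm_align_sequential`) alternates that
superposition step with re-estimation of the correspondence by dynamic
programming on the superposed distance score matrix (free end gaps,
linear internal gap penalty −0.6), starting from the best gapless
threading offsets. This deliberately lightweight engine is sufficient
here because every use is seeded by an SSE correspondence or by
near-identical fixtures; it is not a general remote-homology aligner. An
adapter can delegate to an external TM-align executable (config key
`tmalign_bin`) for bit-faithful replication with reference tooling; both
paths return the same result shape with provenance recorded.

Degenerate inputs: superposition requires ≥ 3 non-collinear points and
raises an error otherwise; all tie-breaks in both DP kernels are fixed
(diagonal, then up, then left; traceback from the highest cell at the
smallest row/column), so outputs are byte-stable across runs.

## The synthetic generator

`make_chain()` builds elements with ideal geometry — helices with 1.5 Å
rise and 100° twist per residue (consecutive C-alpha spacing ≈ 3.8 Å),
strands as extended zigzags — joined by seeded self-avoiding coil walks
(3.8 Å steps, 2.5 Å clash tolerance, up to 100 direction resamples per
step). Ground-truth ss3 comes from the construction, so encoding tests do
not depend on the geometric assigner's fidelity. Operators plant the
rearrangements the pipeline must invert:

* `circular_permute` reorders residues without moving coordinates;
* `apply_indel(insert)` threads a constant-step coil arc between the
  flanking residues so both structured blocks stay fixed — exactly the
  geometry the gap rule presumes; deletions re-join with a minimally
  translated C-terminal block;
* `tandem_repeat` appends rigid copies, so units are exactly superposable.

An optional terminal coil tail keeps the first and last elements from
fusing into one SSE under circular permutation (real chains have termini;
an idealised chain that starts and ends mid-element would not).

Fixtures are reproducible bit-for-bit from (spec, seed). What they do
not emulate: side chains, realistic loop conformations, bent or frayed
elements, strand pairing geometry, and assignment noise. Passing tests
therefore establish the correctness of the algorithms and decision rules,
not field performance on experimental structures, where boundary
precision degrades with short or irregular SSEs.

## Problem sizes and defaults

The shipped tests run chains of roughly 30–200 residues (6–19 SSEs), 50
seeded circular-permutation fixtures for boundary recovery, tandem arrays
with k = 2–4, and an exhaustive Smith–Waterman cross-check against
brute-force enumeration for all token pairs up to length 3 over a 4-token
alphabet plus a seeded sample of longer pairs. These sizes exercise every
code path while keeping the whole suite in the low minutes on one core;
the method itself has no intrinsic size limit beyond the O(nm) dynamic
programming and the TM-score refinement.

Every printed threshold is a named configuration key with its default:
`cp_tm` 0.5, `cp_delta_tm` 0.1, `indel_min_gap` 40, `indel_frac` 0.6,
`sym_tm` 0.5, `scan_tm` 0.5 (strict), `consolidate_delta` 0.05, `min_sse`
5, `min_unit_sse` 3. Configuration files are YAML with unknown keys
rejected, so a typo cannot silently revert a threshold.

## Known limitations

Only two-fold rearrangements are modelled: one seam per pair, no
multi-boundary permutations, and no open-versus-closed symmetry
classification. Chains with fewer than 5 SSEs are excluded by design, and
sparse or short-element regions weaken the token alignment signal. The
substitution matrix shipped as default is a transparent bin-distance
scheme, not an optimised matrix; it is a loadable asset precisely so a
better-calibrated one can be dropped in without code changes.
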