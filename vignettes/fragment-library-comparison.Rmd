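---
title: "Comparing fragment libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing fragment libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the curation and fragmentation procedure, the statistics
computed on the resulting libraries, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## The problem

Fragment-based drug design works with libraries of very small organic
molecules. Such libraries come from two very different sources:
*deconstruction* of existing compound collections — in particular
natural products (NPs), which are oxygen-rich, stereocentre-rich and
built on fused, bridged and spiro ring systems — and *synthesis*, as in
commercial vendor catalogs, which tend to be nitrogen-rich, flat and
aromatic. A principled comparison asks, for each library: how many
structures survive curation; what fragments does retrosynthetic
decomposition yield; how many fragments satisfy the rule of three; what
is the elemental/ring/complexity composition; how synthetically
accessible are the fragments; how internally diverse is each library;
how much do libraries overlap; and where does each library sit in
chemical space. `fragcompare` implements each of those stages behind
explicit, tested contracts.

## Curation protocol

`standardize_molecule()` applies, in order: (1) a 13-element whitelist
(H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I), checked on the molecule
*as read*, before component splitting, so a disallowed counterion
rejects the whole input — the alternative order is available as
`element_stage = "post_split"` but is not the default; (2) splitting of
multi-component inputs, keeping the component with the most heavy atoms
(ties: higher molecular weight, then lexicographically smallest
canonical SMILES — the underlying protocol says only "largest");
(3) reionization; (4) neutralization, with quaternary nitrogens keeping
their charge; (5) a canonical tautomer from a deterministic scored
enumeration capped at 1000 tautomers (enumeration failure falls back to
the pre-tautomer form, flagged, rather than rejecting the record);
(6) the stereochemistry-aware canonical SMILES. Stereochemistry
deliberately participates in the canonical key: the fraction of chiral
carbons is one of the measured descriptors, and collapsing enantiomers
would distort it. `overlap()` offers a stereo-insensitive mode, always
reported separately.

Deduplication keys on the canonical string; the pre-deduplication
multiplicity is retained on each surviving record, so record counts
remain sum-consistent (tested).

## RECAP decomposition

The engine matches eleven bond-environment patterns — amine, amide,
ester, urea, olefin, ether, aromatic N–aliphatic C, lactam N–aliphatic
C, aromatic C–aromatic C, quaternary N, sulfonamide — against acyclic
bonds only; ring bonds are never cleaved. Decomposition is
hierarchical: all matching bonds of a fragment are broken
*simultaneously*, broken ends are capped with hydrogen, and the pieces
are decomposed further until no rule applies. Only leaves are returned,
and an undecomposable parent contributes no fragment at all (counting
intact parents as fragments would contaminate the rule-of-three
census).

Two design choices deserve comment.

*Atom conservation vs. the reaction-based tradition.* Reaction-based
RECAP implementations delete atoms for some rules (the ether oxygen,
the urea carbonyl) and mark cut points with dummy atoms. Here leaves
are ordinary molecules (the most frequent fragments of real libraries
are benzene, phenol, toluene — not asterisk-bearing synthons), and the
heavy atoms of the leaves always partition the parent's heavy atoms, a
property the test suite checks molecule by molecule. The cost is that
symmetric double cleavage produces *mini fragments*: a dialkyl ether
yields two alkanes and water, a urea yields two amines and
formaldehyde. This is deterministic, order-independent and chemically
transparent; mini fragments are in any case excluded by the 70–300 Da
window used for frequency tables.

*Order independence.* Breaking one bond at a time makes the leaf set
depend on cleavage order (breaking a methyl ether's C–O on one side
first leaves a phenol, on the other a methanol). Simultaneous per-round
breaking removes that ambiguity; the test suite permutes the internal
bond-breaking order and asserts identical leaf multisets. One
consequence is codified in the rule set itself: the ether pattern
excludes ester alkyl oxygens, so esters cleave only at the acyl C–O
bond (acyl fragment + alcohol) instead of additionally emitting water.

Parents with molecular weight ≥ 1000 Da are skipped (strict less-than
is fragmented; the boundary case is ambiguous in the source protocol
and the stricter reading is implemented). Occurrence counts each parent
once per unique fragment by default; `count_sites = TRUE` counts
per-site multiplicity, since the frequency denominators of the
published tables are not fully specified. Frequency tables are computed
under both denominators (`"occurrences"` and `"unique_fragments"`).

## Properties and the rule of three

The six rule-of-three properties use the community-standard
definitions: molecular weight from average atomic masses with implicit
hydrogens; rotatable bonds as acyclic single bonds between non-terminal
heavy atoms with amide C–N excluded; topological polar surface area in
the classic parametrization without S/P contributions; Crippen
atomic-contribution logP; acceptors as the N + O count and donors as
the N–H/O–H hydrogen count (Lipinski-style). All six thresholds are
inclusive (≤). The boundary tests construct, for each property, a
molecule at the threshold and a one-unit exceedance that violates *only
that property*.

The 18-descriptor panel counts C/N/O atoms and their heavy-atom
fractions, sp³ carbon fraction, chiral carbon fraction (assigned *and*
unassigned tetrahedral stereocentres — NP collections often omit stereo
annotations, and counting only assigned centres would understate
them), molecular weight, heavy atoms, SSSR ring counts (a ring is
aromatic when every bond is aromatic; aliphatic otherwise; a
heterocycle contains a non-carbon ring atom) and spiro/bridgehead atom
counts. The source tables print "aromatic heterocycles" identical to
"aromatic rings", which is impossible under the literal definition
(e.g. for a benzene library); the literal definition is implemented and
the discrepancy simply noted. Library summaries are plain arithmetic
means over unique structures, not occurrence-weighted.

## Synthetic accessibility

The SA score is `fragment_score − complexity_penalty`, mapped to
[1, 10] (1 = easy). The fragment score is the occurrence-weighted mean
of log-frequency contributions of radius-2 circular substructures,
looked up in the reference frequency table; substructures absent from
the table contribute the published default (−4). The penalty sums a
size term (`n^1.005 − n` over all atoms), log-scale terms for
stereocentres, spiro atoms and bridgehead atoms, a macrocycle term
(any ring > 8 atoms), minus a symmetry correction for molecules with
fewer distinct environments than atoms. The mapping to [1, 10] uses the
published linear rescaling with logarithmic smoothing above 8.

The frequency table is not shipped in this repository (it is a
multi-megabyte binary); it is read at runtime from the reference
distribution installed alongside the chemistry backend. The acceptance
suite runs the *actual published reference script* from that same
distribution as an independent oracle and requires agreement within
1e-6 over a 50-molecule battery spanning acyclic, macrocyclic, spiro,
bridged and stereocentre-rich structures. The "easy to synthesize"
boundary (score ≤ 6) is a named constant (`SA_EASY_THRESHOLD`), not a
hard-coded magic number.

## Diversity

Fingerprints: MACCS keys reported as 166 bits (the customary 167-bit
vector's unused bit 0 is dropped) and Morgan radius-2/3 hashed to 1024
bits. Tanimoto similarity is `|A∩B|/|A∪B|`, defined as 1 for two empty
fingerprints (two featureless objects are indistinguishable). Libraries
up to `trigger_size` (default 20,000 — desk scale; the study's
effective trigger of ~65,000 is reproducible via configuration) are
processed exhaustively, `n(n−1)/2` pairs; larger libraries use ten
independent subsets of 5000 drawn without replacement, pairwise
similarities computed *within* each subset, values pooled for the CDF
and median with per-subset medians retained for dispersion. Subset *i*
uses seed `seed + i`. The CDF is evaluated on a fixed 201-point grid on
[0, 1] — a plotting convenience, not a statistical choice.

## Overlap and scaffolds

Overlap intersects the stereo-aware canonical keys of two deduplicated
libraries; percentages are always quoted against the owning library's
size. Bemis–Murcko scaffolds (ring systems plus connecting linkers,
side chains removed; acyclic molecules contribute none) are classified
as non-heterocyclic (no ring heteroatom), nitrogen-containing (any N in
the scaffold, ring or linker — the source census does not say which,
and the inclusive reading is flagged), and fused. "Fused" includes
bridged and spiro unions, since the relevant contrast is with
monocyclic scaffolds; a stricter ortho-fused count (two SSSR rings
sharing exactly one bond — bridged systems share two or more, spiro
none) is reported alongside.

## Chemical-space embeddings

The tree-map embedding is implemented as exact-or-approximate kNN
search under Tanimoto distance (1 − similarity), a minimum spanning
tree per connected component (own Kruskal/union-find, checked against
an independent graph-library oracle), and a deterministic radial tree
layout: each tree is rooted at its topological centre and every
subtree receives an angular wedge proportional to its size, with
radius equal to depth. Defaults k = 50, kc = 10; kc only matters in
the approximate (MinHash LSH) mode, where it multiplies the candidate
pool rescored exactly per query. Exact search is used below 50,000
molecules. The layout contains no randomness, so reproducibility is
structural rather than seeded.

t-SNE runs with perplexity 40 and 300 iterations by default — the
iteration count is low by modern standards but is kept as the stated
analysis parameter, overridable in configuration. For small inputs the
perplexity is reduced to `(n−1)/3` with a warning; fewer than 5
molecules is an error. PCA initialization plus a fixed seed make
repeat runs identical.

## The synthetic-data generator

The generator is a block-and-linker grammar: ring/chain building
blocks (aromatic carbocycles, aromatic N-heterocycles, saturated
O-heterocycles, fused/bridged/spiro bicycles, short chains) joined by
linkers that are exactly the RECAP-cleavable bond environments (amide,
ester, ether, amine, sulfonamide, urea, olefin, biaryl). By
construction every molecule is valid, element-whitelisted,
charge-neutral and tautomer-stable (the curation protocol leaves it
unchanged — tested), and every multi-block molecule is decomposable
into at least two leaves.

The stated populations: `np_like` targets heavy-atom fractions
O = 0.21, N = 0.01 and an sp³ carbon fraction of 0.65, drawing mostly
saturated O-heterocycles, fused/bridged/spiro systems and ester/ether/
olefin links; `synthetic_like` targets O = 0.10, N = 0.14, sp³ = 0.30,
drawing aromatic rings and amide/amine/sulfonamide/urea links. These
values sit inside the composition ranges reported for real NP-derived
vs. vendor fragment collections and were fixed once, before any
acceptance measurement. Targets are reached by reweighting each
block/linker draw by the *projected library mean of per-molecule
fractions* — a negative-feedback loop at the sampling level (not
post-hoc filtering of whole libraries), annealed over the first ten
molecules. The controller makes the 500-molecule library means land
within a few thousandths of the targets; the acceptance criterion
requires ±0.03 over 20 seeds.

What a green test does *not* establish: generated molecules are
linear block chains — no branched linker topologies, no macrocycles
spanning blocks, no glycosides, no charged natural products, and no
attempt to match absolute molecular-weight distributions of real NP
collections. The generator exercises the pipeline's statistics, not
the chemistry of any real database.

The benchmark suite adds planted duplicate structures across library
pairs and deterministically resamples any *organic* (unplanted)
cross-library collision, so pairwise overlaps equal the planted counts
exactly; its ground-truth sheet also carries a ten-molecule RECAP audit
battery whose leaf sets were derived by manual rule application.

## Pipeline and reproducibility

`run_pipeline()` executes standardize → fragment → RO3 → descriptors →
SA → diversity → overlap → scaffolds → embeddings from a registry and
writes the report bundle (CSVs mirroring the attrition, overlap and
descriptor-mean tables, SA and diversity summaries, scaffold census,
embedding coordinates) plus a JSON manifest recording versions,
parameters and all derived seeds. One master seed fans out by fixed
offsets (+100 diversity, +200 embeddings). Reruns with the same
configuration are byte-identical except for the manifest timestamp;
counts are printed unrounded, percentages to one decimal. A stage
failure aborts with the stage and library name and leaves a `FAILED`
marker in the bundle.

## Known limitations

- Chemistry primitives run in a separate Python process; throughput is
  batched per operation, so per-molecule interactive calls are slow by
  design.
- The tautomer cap (1000) makes canonicalization deterministic but can
  fall back (flagged) on pathological inputs.
- The approximate kNN mode is a straightforward MinHash LSH; it meets
  its ≥95% edge-agreement contract at desk scale but is not tuned for
  millions of molecules.
- Scaled-down defaults (`trigger_size`, suite sizes) keep the test
  suite within minutes; the study-scale parameters are plain
  configuration values.
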