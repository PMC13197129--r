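---
title: "Quantifying the completeness of RNA fragment structural space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the completeness of RNA fragment structural space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafrag)
library(dplyr)
```

## The question and the model

RNA backbone conformation is locally repetitive: most short stretches of
most structures re-use a modest vocabulary of shapes. `rnafrag` makes that
statement quantitative. It treats every window of *k* consecutive
nucleotides (k = 2..5) of every RNA chain as a fragment, measures
structural similarity as the Kabsch superposition RMSD over a reduced atom
set, and asks — year of deposition by year of deposition — how many
fragments were *new*, i.e. farther than a fixed novelty radius from every
conformation already seen. If the cumulative curve plateaus, the local
structural space is essentially complete at that radius and that
representation; if it keeps climbing, new depositions still discover new
local geometry.

Two ideas do the real work:

1. **Reduced reference frames.** A nucleotide is represented by an ordered
   atom subset (`rna_frames()`): the six backbone atoms (M6S0B0), three
   base atoms (M0S0B3), three sugar atoms (M0S3B0), three mixed triads
   (M2S0B1, M1S1B1, M0S2B1), or all fifteen heavy atoms common to
   A/C/G/U (FULL15). Purine and pyrimidine base atoms are matched by
   positional role (N9↔N1, C8↔C6, C4↔C2), which is what makes fragments
   of different sequences comparable at all — the library is a library of
   *shapes*, with per-sequence tallies kept separately
   (`sequence_counts()`).
2. **A fixed correspondence metric.** RMSD is always computed under the
   canonical frame atom order; there is no correspondence search and no
   flexible alignment. Reflections are excluded by the SVD determinant
   correction in `kabsch()`, because allowing improper rotations would
   merge mirror-image backbones that chemistry distinguishes.

The backbone is additionally summarised by the pseudo-torsion pair
η = C4′(i−1)–P(i)–C4′(i)–P(i+1), θ = P(i)–C4′(i)–P(i+1)–C4′(i+1)
(`pseudo_torsions()`; defined only at interior positions, so a
tri-nucleotide is characterised at its centre). Distances in torsion space
use the wrapped root-mean-square `angle_distance()`. The package's
`angle_distance_vs_rmsd()` measures how often η/θ-similar fragment pairs
are structurally dissimilar — the known failure mode of two-angle
descriptions, which a χ rotation plus sugar repucker demonstrates exactly
(backbone P/C4′ untouched, full-atom RMSD large).

## Dataset rules

`read_structure()` parses PDB and mmCIF files (via bio3d) into one record
per residue of each RNA chain. Conventional choices, applied uniformly:

* first model only; for alternate locations the highest-occupancy
  conformer, ties to altloc `A`;
* a chain counts as RNA when at least half its residues carry a C1′ atom
  and at least one carries an O2′; protein and DNA chains are skipped,
  solvent/ligand groups are dropped;
* entry filters (`filter_entries()`): X-ray or cryo-EM, resolution
  strictly better than 3 Å ("better than" read strictly, so 3.00 Å is
  out), release year within the cutoff. Entries without a reported
  resolution are excluded.

`extract_fragments()` emits every stride-1 window in which all residues
are standard A/C/G/U (anything else — PSU, 1MA, DNA residues — is
"modified" and breaks windows; no modification dictionary is attempted),
author numbering is strictly consecutive with no insertion codes
(an insertion-coded residue conservatively breaks its windows), covalent
continuity holds (O3′(i)–P(i+1) < 2.0 Å, a standard bond-length
tolerance — numbering alone is unreliable in real files), and every atom
demanded by the chosen frame is present in every nucleotide. A fragment
carries its entry, chain, start index, sequence and the entry's initial
release year. Fragments are pooled per entry with chain provenance
recorded; chains are not treated as separate redundancy units.

## The three-stage clustering protocol

`build_yearly_library()` removes redundancy hierarchically:

1. within each entry, average-linkage (UPGMA) clustering of the fragment
   RMSD matrix cut at the **fine threshold** (default 0.5 Å), keeping one
   representative per cluster;
2. within each release year, the entry-level representatives are
   clustered again at the fine threshold;
3. in year order, each year-representative is compared against all
   previously accepted representatives; it is **new** iff its minimum
   RMSD exceeds the **novelty threshold** (default 1.0 Å), and accepted
   representatives join the reference set immediately.

Design points that were genuinely open and how they were settled:

* **Cut rule.** The linkage is fixed (average), the cut rule is not; flat
  clusters are taken from the dendrogram at linkage height ≤ threshold
  (`stats::cutree(h = ...)`), the standard reading.
* **Representative.** "Representative fragment" is implemented as the
  medoid — the member minimising mean RMSD to its co-members — because it
  is deterministic and always a real, member-realisable conformation.
  Ties go to the lowest (entry, chain, start index).
* **Same-year novelty.** Two medoids of the same year can sit 0.6–1.0 Å
  apart (fine clustering only guarantees 0.5 Å granularity). Candidates
  are therefore processed in the deterministic (entry, chain, start)
  order and earlier same-year acceptances count as "previous", which
  prevents double-counting near-duplicates within a year.
* **Memory contract.** Stage 3 compares one candidate at a time against
  the accumulated reference coordinates; no all-years matrix is ever
  formed, and the result is identical to the naive full-matrix
  computation (the pipeline is deterministic throughout — no seeds).

Downstream, `rmsd_correlation()` samples unordered fragment pairs
uniformly without replacement under a caller-supplied seed (sampling
details are otherwise unconstrained) and reports the Pearson correlation
between two frames' RMSDs; a zero-variance side yields `NA`, never a
silent 0. `grid_coverage()` bins (η, θ) into half-open 5° cells
(−180 + j·5 edges, +180 folded into the last cell): 72² = 5184 cells.
`classify_regions()` labels a fragment helix / loop / mixed-HL according
to whether all / none / some of its nucleotides appear in a base-pair
table. Base pairs are an *input* (TSV: entry, chain1, seq1, chain2, seq2),
in practice produced by an annotation tool such as DSSR; the package does
not re-derive them, and synthetic tests construct the table directly. The
discordant fraction reported by `angle_distance_vs_rmsd()` is conditional:
among pairs with angle distance below the cutoff, the share with RMSD
above the cutoff.

## The synthetic generator

`build_ideal_chain()` constructs all-heavy-atom chains from internal
coordinates: bond lengths and angles fixed at standard values (one
hard-coded table in the source), backbone torsions α–ζ and glycosidic χ
free, sugar ring shapes from two pseudo-rotation templates (C3′-endo,
C2′-endo). Branch-atom torsion offsets were fixed once so that the ribose
ring closes (C2′–C3′ ≈ 1.5 Å) with the correct D-ribose handedness. The
A-form defaults produce a translationally symmetric helix whose η/θ
(≈ 170°, ≈ −147°) sit in the canonical helical region, and the builder's
input torsions round-trip exactly through `backbone_torsions()` — that
self-consistency, not physical realism, is what tests rely on.

On top of the builder:

* `plant_fragment_clusters()` draws random-torsion conformers until all
  pairwise frame RMSDs exceed a requested separation, then adds members
  as Gaussian coordinate perturbations (σ in Å). Conformer diversity is
  generated in torsion space (α/γ/ζ/χ resampling) rather than Cartesian
  noise, so backbone-frame vs base-frame RMSD divergences resemble those
  of real conformational changes.
* `make_yearly_corpus()` writes a deposition history to disk: scheduled
  novel conformers per year (mutually separated by 1.5 Å by default,
  comfortably above the 1 Å novelty radius) plus rigid-copy redundant
  entries, each a small PDB/mmCIF file with sidecar metadata. The ground
  truth growth series equals the schedule by construction.

What the generator does *not* emulate: base pairing and tertiary context,
realistic B-factors/occupancy patterns, crystallographic disorder beyond
the injected test cases, sequence-dependent conformational propensities,
or physically relaxed geometry. Passing tests therefore demonstrate the
correctness of the bookkeeping and the geometry/clustering machinery, not
that any particular biological conclusion holds; conclusions about the
real PDB require running the pipeline on the real archive.

## Numerical choices and degenerate inputs

* Angles are degrees in (−180, 180] externally, radians internally;
  dihedrals use the IUPAC sign convention, and degenerate geometry
  (coincident or collinear consecutive points) raises an error rather
  than returning an arbitrary value.
* Kabsch RMSD computes explicit residuals after rotation; the
  singular-value shortcut loses ~7 significant digits to cancellation
  near zero, which would blur exact-copy detection.
* Superposition needs ≥ 3 points; size mismatches error. RMSD matrices
  require equal fragment lengths.
* PDB coordinates are fixed-width with 10⁻³ Å precision, mmCIF is written
  at 10⁻⁶ Å; round-trip tests assert exactly those tolerances, and the
  corpus generator keeps planted separations at margins (≥ 0.3 Å) far
  above either.
* Medoid and candidate-order tie-breaks are lexicographic on
  (entry, chain, start index), making every clustering result invariant
  under input permutation (tested).

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
planted populations of 5 clusters × 8 members (10 seeds), three-year
corpora of ~12 entries, correlation pools of 20 conformers (190 exhaustive
pairs), 100 random 9-point sets against the rotation-search oracle, 10⁴
random angle pairs. These sizes were chosen to exercise every code path
with exact ground truth; the pipeline itself is O(n²) per clustering
stage and has no intrinsic size limits beyond that.

## Known limitations

* Non-sequential and partial alignments are out of scope: the metric is
  the fixed-correspondence Kabsch RMSD only.
* Base-pair annotation quality is inherited from the input table; the
  package takes it on faith.
* The mmCIF metadata reader targets the standard categories
  (`_exptl.method`, `_refine.ls_d_res_high`,
  `_em_3d_reconstruction.resolution`, first
  `_pdbx_audit_revision_history` date); unusual archives may need a
  sidecar TSV instead.
* Growth counts depend on the processing order convention for same-year
  candidates (documented above); alternative conventions can differ by a
  fragment or two per year when medoids sit between 0.5 Å and 1 Å apart.
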