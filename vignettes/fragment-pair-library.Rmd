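---
title: "Interface fragment pair libraries: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface fragment pair libraries: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglib)
```

## The model

`fraglib` treats a protein–protein interface not as a single object but
as a bag of local packings. The atomic unit is the *interface fragment
pair*: two 9-residue stretches of backbone, one per binding partner,
whose central residues make at least one side-chain contact across the
interface. Nine residues is long enough to fix the local geometry of a
helix turn, a strand segment or a tight coil, and short enough that the
same packing recurs across unrelated complexes. Each record stores only
the two 9×3 blocks of Cα coordinates plus the 3-state secondary-structure
type of the two center residues.

Three operations are built on this unit.

**Extraction.** A residue pair (i ∈ domain I, j ∈ domain J) is an
interface pair when the minimum distance over the two residues'
side-chain heavy atoms is below 5 Å. "Side chain" means Cβ and beyond;
glycine contributes its Cα as a surrogate (dropping glycine would delete
genuine interface centers). Each interface pair becomes one fragment-pair
record, so a center in contact with two partner residues is recorded
twice, with the partner window shifted by one residue. Windows that would
cross a chain terminus, an author-numbering gap, a missing Cα or a
Cα–Cα step ≥ 4.5 Å are skipped and logged, so records plus skips always
equal the number of contacts.

**Clustering.** Similarity between two records p, q is the RMSD of a
joint 18-point Kabsch superposition of p's concatenated blocks onto q's,
taken as the minimum over the two block pairings (a→a/b→b and a→b/b→a) —
so the arbitrary labelling of the two sides cannot split a cluster, which
matters for homodimers. Fragment N→C direction is never reversed: that
would align chains backwards. Clustering is a single greedy pass in a
seed-shuffled order: each record joins the cluster of its nearest
already-visited record if that RMSD is under the cutoff (default 4 Å),
otherwise it founds a new cluster. The representative of a cluster is the
member with the most co-members within the cutoff (ties: lowest mean RMSD
to co-members, then lowest id). Clusters with **more than**
`min_members = 20` members (strict inequality) enter the library, sorted
by abundance. The greedy pass is order-dependent by construction; the
`stability_runs()` operation quantifies this by re-clustering under
several visiting orders, and `cutoff_scan()` traces cluster counts
across cutoffs. On well-separated data the partition is provably
order-independent, which is what the planted-data tests exercise.

**Assembly.** Given two monomers, every 9-residue window pair — there are
(N_I − 8)(N_J − 8) of them — is compared against every library entry in
both block orientations. A window pair is considered only if both window
*centers* are surface residues — the surface test deliberately applies
to the centers only, not to the whole window, since the centers are what
defines the contact. If both 9-atom fits beat the 2 Å alignment
cutoff, the two whole domains are carried rigidly by their window
transforms into the entry's frame, giving one candidate model per
orientation. Models with any inter-domain Cα pair closer than 3.5 Å are
discarded as clashes. The surviving ensemble is the package's answer to
"which quaternary arrangements are compatible with the library?"; it is
deliberately unscored — ranking and native-pose identification are out of
scope.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `contact_cutoff` | 5.0 | Å | side-chain contact defining interface residue pairs |
| `window` | 9 | residues | fragment length (odd) |
| `cluster_cutoff` | 4.0 | Å | greedy clustering RMSD threshold |
| `min_members` | 20 | — | abundance filter, strict ">" |
| `align_cutoff` | 2.0 | Å | per-window 9-atom fit threshold in assembly |
| `surface_threshold` | 10.0 | Å² | SASA above which a residue is "surface" (strict) |
| `probe` | 1.4 | Å | solvent probe radius |
| `sasa_points` | 960 | — | Shrake–Rupley lattice points per atom |
| `clash_cutoff` | 3.5 | Å | inter-domain Cα clash distance |
| `dedup` | off | — | optional greedy pose deduplication |

The first seven are the standard values of the procedure the package
implements; they are exposed (`default_params()`) but changing them
changes the science. The clash definition is this package's own design
choice — "clash" has no single standard definition — and a Cα-level
criterion at 3.5 Å is the natural companion of a Cα-only library (a
heavy-atom mode at 2.5 Å is available via `clash_mode = "heavy"`). Deduplication is off by default
because raw enumeration is the defined output; the flag exists because
neighbouring windows produce near-duplicate poses.

SASA is computed on the **isolated monomer**, not the complex: at filter
time the partner is unknown by assumption, and the monomer surface is
what a prediction setting would see.

## Numerical choices

* Superposition uses the SVD form of the Kabsch solution with the sign
  of the smallest singular value corrected so det(R) = +1 — mirror
  images are never produced, preserving chirality even for degenerate
  (collinear) point sets. RMSD is evaluated from explicit residuals, not
  the singular-value closed form, which cancels catastrophically for
  near-identical point sets. The all-against-all RMSD matrix uses the
  closed form for speed and falls back to the residual form below 1e-4 Å.
  Tests verify both paths against an independently written quaternion
  (Davenport eigenvalue) oracle at 1e-9 Å.
* Secondary structure comes from an internal Kabsch–Sander assigner:
  backbone H-bond energy E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH −
  1/r_CN) kcal/mol with the amide H placed 1.01 Å anti-parallel to the
  preceding carbonyl, bond when E < −0.5 kcal/mol; 4/3/5-turn patterns
  give helices, bridge patterns give strands, helices take precedence,
  and the 8→3-state collapse is H,G,I→H; E,B→S; rest→L. Exact parity
  with an external DSSP binary is not promised; the package's fixtures
  use geometries where the assignment is unambiguous (they were verified
  against an independent DSSP implementation during development), and a
  classic-format DSSP file can be supplied to `assign_ss3()` when
  bit-compatibility matters.
* SASA uses a deterministic Fibonacci point lattice (no RNG); areas at
  960 points sit within 2 % of a 4000-point run, which is far inside the
  10 Å² surface threshold's margin for realistic residues.
* Residues are indexed 1-based and sequentially within a domain, the
  idiomatic choice in R; author numbering (plus insertion codes) is kept
  alongside for reporting and for the window-continuity check.

## The synthetic generators

The package ships deterministic generators rather than fixture files.
`ideal_helix()` and `ideal_strand()` build backbones (N, Cα, C, O and a
tetrahedral pseudo-Cβ) from standard internal coordinates via natural
extension; `random_loop()` samples torsions from a broad non-helical
region under a 4 Å Cα self-avoidance constraint. Two-strand β-sheet
domains place the second strand by a deterministic grid search over sheet
offsets that maximizes the number of inter-strand Kabsch–Sander H-bonds,
subject to all inter-strand Cα pairs staying above 4.3 Å — i.e. the sheet
registration is *derived* from the same H-bond energy the assigner uses,
not hard-coded.

`make_toy_dimer()` packs two such domains into a complex with a planted
interface. Helix/loop/mixed interfaces pack the two elements' central
residues Cβ-to-Cβ at a 6.5 Å Cα separation (backed off in 0.5 Å steps if
any Cα pair would come under 4 Å) with a 150° inter-element crossing
angle — 90° for helix-on-sheet, where near-perpendicular packing is the
sterically reasonable choice. SS interfaces continue the sheet across
the interface with parallel or antiparallel strand sense. The generator
fails loudly if the requested geometry produces no 5 Å contact.
`toy_benchmark_specs(20)` fixes a 20-dimer roster cycling all seven
motifs with domain lengths 21–25.

`make_planted_pair_dataset()` plants K random fragment-pair geometries
(rejection-sampled to mutual RMSD above twice the clustering cutoff, so
cluster recovery is guaranteed by construction) and emits noisy copies
with known labels; σ = 0.3 Å noise and 30 members per geometry are the
package's standard clustering conditions, with σ = 0.5 Å perturbed
libraries standing in for "similar but not identical" library entries in
the assembly benchmark.

What the generators deliberately do **not** emulate: real side chains
beyond Cβ (so contact counts are sparser than in real interfaces),
crystallographic noise and disorder, sequence diversity, and the long
disordered loops that defeat fragment libraries in practice. Passing the
planted-data tests therefore demonstrates correctness of the machinery,
not database-scale performance on real complexes; database-scale
statistics (total pair counts, cluster censuses, or benchmark success
rates on real dimers) are outside the package's reproducible scope.

## The motif preference score

The score of motif XY is ln(P(XY) / (P(X)·P(Y))), with P(XY) the
fraction of pair records carrying the unordered motif (the six motif
probabilities sum to 1) and P(X) the fraction of individual fragments
(two per record) of type X. The formula is implemented exactly in this
form, including homogeneous motifs, ln(P(XX)/P(X)²). Note the
consequence: an unordered heterogeneous motif arises in two ways, so
under independent random pairing P(XY) → 2·P(X)·P(Y) and the score of
HL, HS and SL converges to ln 2 ≈ 0.693, not 0, while homogeneous motif
scores converge to 0. A combinatorial null of 2·P(X)P(Y) would center
all six at zero, but the package keeps the conventional form of the
score and documents the offset rather than "correcting" it; comparisons
between
heterogeneous motifs are unaffected since the offset is common to them.
Zero-count motifs are reported as −Inf; a zero fragment-type probability
is an error naming the type.

## Known limitations

* Greedy nearest-neighbor clustering is order-dependent on data with
  borderline separations; only well-separated planted data yields
  provably stable partitions. Single-linkage or hierarchical clustering
  would remove the order dependence at O(N²) memory.
* The O(N²) RMSD loop targets desk-scale inputs (up to tens of
  thousands of records); there is no approximate-nearest-neighbor index.
* Assembly transforms come from the 9-atom window fits alone; there is
  no post-placement refinement, scoring or ranking of poses.
* The internal secondary-structure assigner covers the helix and bridge
  patterns that decide H/S/L at fragment centers; π-bulges, ladders and
  kinks at the edge of DSSP's definitions may differ from an external
  DSSP run — which is why external DSSP ingestion takes precedence when
  supplied.
* Problem sizes in the shipped tests and the acceptance script (300-pair
  planted sets, 20 toy dimers of 21–25 residues per domain) were chosen
  so the full suite exercises every code path at interactive speed; all
  scale linearly upward with the same code.
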