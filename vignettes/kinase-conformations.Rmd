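---
title: "Gauging kinase conformations and interaction fingerprints with kinconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gauging kinase conformations and interaction fingerprints with kinconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconf)
```

## The problem

Protein kinases switch between an active conformation and several inactive
ones. Three structural motifs carry most of that switch in Aurora kinase
(AK): the **DFG motif** (Asp274-Phe275-Gly276) at the start of the activation
loop, which can sit "in" (active, Phe in the back pocket), "out" (swapped
toward the C-lobe, Asp and Phe on opposite sides) or "out-up" (lifted
parallel to the alphaC helix, with Phe275 between the two salt-bridge
formers and adjacent to Glu181); the **alphaC helix**, whose rotation makes
or breaks the conserved Lys162-Glu181 salt bridge; and the glycine-rich
**G-loop**, which is usually an extended beta hairpin but can fold its
aromatic Phe144 into the ATP site. Which conformation a structure is in
decides which binding-site sub-pockets exist and therefore which inhibitor
chemistry can engage it. `kinconf` implements a geometric gauge for these
three calls, a detector suite for the non-covalent interactions that
stabilise them, a 14-bit structure interaction fingerprint (SIFt), and a
mapping from fingerprint bits to binding-site sub-pockets and specificity
hot-spots.

## The conformational metric

Every quantity is computed from **side-chain centres of mass** (mass-weighted
means over side-chain heavy atoms; glycine falls back to its alpha carbon).
Author residue numbers are first mapped to canonical Aurora-A positions by
pairwise sequence alignment, so the same anchors can be addressed in any
kinase chain.

The **inter-motif metric** spans the catalytic lysine (K162), the alphaC
glutamate (E181), the gatekeeper (GK, canonical 210) and the DFG
phenylalanine (F275): distances r2(GK-E181), r3(GK-F275), r4(K162-F275),
r6(K162-E181), the diagnostic r5(E181-F275), and angles K-(GK+2)-E,
K-(GK+2)-F, E-(GK)-F. The **intra-motif metric** measures the spread of the
DFG motif and the adjoining activation loop: r1(A273-D274) through
r6(F275-T288) plus the DFG, FWH and FWT angles (vertices at F275 and W277).

Classification uses the discriminative subsets — inter {r2, r3, r4, r6,
E-(GK)-F} and intra {r5, r6, DFG, FWH} — as a joint nine-dimensional space.
Each parameter is z-scored with constants fixed at calibration time, and a
structure receives the label of the **nearest class centroid**; the margin
is the distance gap to the runner-up, and exact ties resolve to "in" (the
most populous class) with margin zero. The original analysis fitted
unpublished regression models; nearest centroids on the same discriminative
parameters are reproducible from published information alone, and
`calibrate_conformations()` accepts any labelled reference set, so a user
with the real crystal structures can calibrate exactly as the original
workflow did.

The **alphaC call** is deliberately simpler: "out" whenever r6(K162-E181)
exceeds the salt-bridge boundary (default 6.0 Angstrom between side-chain
centres of mass; a broken bridge cannot hold the helix in). Helix i/i+4
geometry around E181 (the Q177/Q185 alpha-carbon spacings) is reported as a
diagnostic but is not decisive.

The **G-loop call** combines two gauges: the mean circular deviation of the
loop's (phi, psi) over canonical 139-147 from the antiparallel beta-sheet
reference (-140, +135) degrees, and the distance of the F144 side-chain
centre of mass from the ATP-site centroid (the mean of the GK, GK+3, K162
and D274 side-chain centres). A loop is "folded" only when the backbone has
left the beta basin *and* F144 has moved into the pocket; both thresholds
are midpoints between a labelled folded and extended reference. Requiring
both prevents a merely disordered loop from being called folded.

## Interaction detection

All detectors work from heavy atoms, because most crystal structures carry
no hydrogens. Where a donor hydrogen is needed, it is inferred as the
direction opposite the resultant of the donor's covalent neighbours; when no
neighbour geometry is available the check degrades to distance-only and the
record carries a "no-angle" flag in its subtype. Default criteria (all
user-overridable through `interaction_criteria()`, and echoed in every
serialized table header so results are reproducible bit-for-bit):

| kind | geometry |
|---|---|
| strong H-bond | N/O donor to N/O acceptor <= 3.5 A, D-H...A >= 120 deg |
| weak H-bond | aromatic C-H donor to N/O acceptor <= 3.8 A |
| salt bridge | opposite formal charges, minimum heavy-atom distance <= 4.0 A |
| cation-pi | cation to ring centroid <= 6.0 A, within 30 deg of the ring normal |
| pi-pi face | centroids <= 5.5 A, interplanar angle <= 30 deg |
| pi-pi edge | centroids 4.5-6.5 A, interplanar angle 60-90 deg |
| CH-pi | carbon to centroid <= 4.5 A, elevation >= 30 deg above the plane |
| van der Waals | sum of vdW radii + 0.5 A (reported, never fingerprinted) |

The source analysis cites Rognan-style criteria without printing cutoffs;
the values above follow common SIFt practice. Histidine is treated as both
donor and acceptor and as an aromatic system. Protein-protein scanning is
restricted to the conserved pairs that the conformational story turns on:
the K162-E181 and E181-R255 ion pairs and the K162-F275 cation-pi contact.

## The 14-bit fingerprint

Each bit is a (residue, interaction kind, ligand pharmacophore role)
triplet: hinge H-bonds at L210, E211, Y212, A213, G216; H-bonds at A273,
E181, D274, H280; the K162 cation-pi with a ligand aromatic; and pi-pi
contacts at F275, W277, H280 and F144. HD/HA denote the *ligand* role. Two
bits required a decision: the printed table labels the A213 hinge bit "HD",
but the hinge amide of A213 donates to the *inhibitor's acceptor* — the bit
is therefore matched on the ligand-acceptor role; and the DFG-phenylalanine
bit is printed with a p38-family residue number from a cited example — it is
implemented as canonical F275. Only strong H-bonds set H-bond bits; weak
C-H bonds are detected and reported but fingerprinting them would make the
hinge bits fire on almost any planar heterocycle. Duplicated records cannot
change a fingerprint, and loosening a criterion can only add bits.

Fingerprints compare with `tanimoto()`; a set of fingerprints summarises
into a per-bit `frequency_profile()` with an `autoplot()` method.

## Sub-pockets, hot-spots and inhibitor classes

The active site is partitioned into six sub-pockets — adenine (AP), back
(BP, also called HPI), ribose (RP), phosphate (PP), solvent (SP) and
hydrophobic allosteric (HPII). Seven hot-spots group the fingerprint bits by
sub-pocket and chemistry, and four inhibitor-class profiles (type I, I1/2,
II, III) each require a conformation and cover a characteristic hot-spot
set (I: {2,3}; I1/2: {1,2,6}; II: {2,3,4,5,6,7}; III: {5,6,7}).
`suggest_class()` scores each class by the fraction of its required
hot-spots covered, zeroing classes whose conformational requirement
conflicts with the structure's call; scores are monotone under added bits.
The hot-spot membership is published only pictorially, so the shipped
mapping is **reconstructed** from the class-table consistency and shipped as
an editable TSV (`hotspot_table(path = ...)` overrides it).

## The synthetic world

Real Aurora crystal structures cannot be redistributed with the package, so
all closed-loop testing runs on a deterministic toy kinase
(`make_toy_kinase()`): the six motif segments (G-loop 136-148, beta3
158-166, alphaC 173-189, hinge 205-222, catalytic loop 250-260,
DFG/activation segment 268-292), author-numbered canonically, with the
bundled profile's sequence. The G-loop backbone is grown from ideal internal
coordinates with prescribed (phi, psi) — all (-140, 135) when extended,
(-60, -40) over 140-145 when folded. Anchor side chains are compact clusters
(true planar rings for aromatics) centred on designed points chosen to
realize each class's geometry at realistic magnitudes (salt bridge ~3.5 A,
broken bridge ~7 A, DFG-in r3 ~6 A versus ~14-18 A otherwise). Filler
residues are sequence carriers parked outside the interaction shell.
`make_toy_complex()` adds ligand fragments at mid-window geometry for any
requested bit subset, with a clearance search guaranteeing no unintended
bit-relevant geometry, and returns an audit list of intended records.

What the toy world is **not**: physically realistic. Bond topology between
backbone and the collapsed side-chain clusters is wrong, segments are
disconnected, and packing is absent. A green closed-loop test therefore
establishes that the geometry pipeline, classifier and detectors implement
their definitions exactly and robustly (labels survive 0.3 Angstrom
coordinate noise at >= 95% over 200 seeds per class) — it does not establish
performance on real crystal structures, which requires the
network-fetched reproduction set (`scripts/fetch_reproduction_data.R`).

Likewise, the bundled reference profile is a **synthetic stand-in**: anchor
positions and identities follow the published Aurora-A roster, but filler
positions between anchors are pseudo-random, because the real UniProt
sequence cannot be shipped. Mapping real kinase chains needs a real
reference sequence (pass it via `reference_profile(path = ...)`).

## Numerical choices and edge cases

* Alignment: ends-free Needleman-Wunsch (BLOSUM62, gap open 11 / extension
  1) for residue maps — chains are routinely fragments or supersets of the
  reference domain, so free end gaps are the right global variant; strict
  Smith-Waterman local alignment with the same scoring for percent identity,
  with identity = matches / alignment length (the blast-p convention),
  rounded to integer. Chains covering < 30% of the reference are rejected.
* Alternate locations keep the highest occupancy; ties prefer altloc "A".
  Multi-model files default to the first model.
* Modified residues TPO/PTR (phosphate groups dropped), MSE (SE relabelled
  SD) and CME (adduct atoms dropped) are renamed to their parents with the
  original code retained per atom; unknown codes pass through with a
  warning; the operation is idempotent.
* Anchors that do not align are *absent*, never guessed; operations that
  need a missing anchor fail naming it.
* Rigid-motion invariance of every metric, label and fingerprint is tested
  to 1e-6 against random rotations and translations.
* Degenerate geometry (zero-length angle arms, empty atom selections,
  G-loop spans more than half missing) raises explicit errors.

## Known limitations

* The published 42/9/5 (DFG), 42/14 (alphaC) and 53/3 (G-loop) bin counts
  depend on unpublished decision boundaries; with the real structure set the
  nearest-centroid calibration reproduces labels for the representative
  structures, but whole-set counts are calibration-dependent.
* Ligand feature typing is rule-based on heavy-atom geometry (rings by
  planar 5/6-cycles, charges by carboxylate/amine/guanidinium patterns); it
  is not a cheminformatics perception engine and can mistype exotic
  chemistry.
* Water-mediated bridges, halogen bonds and energetic scoring are out of
  scope.

## A short session

```{r example}
cal <- default_calibration()
toy <- make_toy_kinase("out_up", g_loop = "extended")
call <- classify_structure(toy, cal = cal)
call[, c("chain", "dfg", "dfg_margin", "alpha_c", "g_loop")]

cx <- make_toy_complex(c(4, 10, 12), dfg = "out_up")
fp <- compute_sift(interaction_table(cx$atoms, cx$pose, cx$map))
fp
suggest_class(classify_structure(cx$atoms, map = cx$map, cal = cal), fp)
```
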