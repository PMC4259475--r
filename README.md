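# kinconf

Kinase structures flip between an active DFG-in state and several inactive
ones (DFG-out, DFG-out-up), rotate their alphaC helix in and out, and can
fold the glycine-rich loop over the ATP site. Which of these conformations a
structure is in decides which binding-site sub-pockets exist and which class
of inhibitor (type I, I1/2, II, III) can engage it. `kinconf` is an R
package for structural bioinformaticians and kinase medicinal chemists that

* reads PDB structures (with modified-residue normalization: TPO, MSE, PTR,
  CME) and maps any kinase chain onto canonical Aurora-A numbering by
  pairwise sequence alignment (BLOSUM62, gap 11/1), so motif residues such
  as the gatekeeper Leu210, Lys162, Glu181 or the DFG triad 274-276 can be
  addressed uniformly;
* computes centre-of-mass distance/angle metrics over those residues — the
  inter-motif vector r2(GK-E181), r3(GK-F275), r4(K162-F275), r5(E181-F275),
  r6(K162-E181) and angles K-(GK+2)-E, K-(GK+2)-F, E-(GK)-F, plus an
  intra-motif vector over the DFG/activation segment — and classifies the
  DFG-loop (in / out / out-up, nearest centroid in the z-scored
  discriminative subspace {r2, r3, r4, r6, E-(GK)-F} x {r5, r6, DFG, FWH}),
  the alphaC helix (in/out by the Lys162-Glu181 salt-bridge distance) and
  the G-loop (extended/folded by circular phi/psi deviation from the beta
  reference (-140, 135) plus F144 displacement toward the ATP-site
  centroid);
* detects strong and weak hydrogen bonds, salt bridges, cation-pi, pi-pi,
  CH-pi and van der Waals contacts between protein and ligand from heavy
  atoms, encodes them into the 14-bit structure interaction fingerprint
  (hinge bits L210-G216, H-bond bits A273/E181/D274/H280, K162 cation-pi,
  pi-pi bits F275/W277/H280/F144), and maps set bits onto six binding-site
  sub-pockets (AP, BP, RP, PP, SP, HPII) and seven specificity hot-spots to
  rank compatible inhibitor classes;
* ships a deterministic synthetic toy-kinase generator that realizes any
  conformation label combination and any fingerprint bit subset, so the
  whole pipeline is testable offline with no downloads.

All user-facing functions take a data frame of atoms first and return
tibbles, so analyses chain with the pipe; fitted calibrations have
`tidy()`/`glance()` methods and frequency profiles have `autoplot()`.

## Worked example

```r
library(kinconf)

cal <- default_calibration()
toy <- make_toy_kinase("out_up", g_loop = "extended")
classify_structure(toy, cal = cal)[, c("chain", "dfg", "dfg_margin", "alpha_c", "g_loop")]
#>   chain    dfg dfg_margin alpha_c   g_loop
#> 1     A out_up       4.12     out extended
```

The structure is called DFG-out-up with a margin of 4.12 z-score units to
the nearest competing centroid; the broken Lys162-Glu181 salt bridge puts
the alphaC helix "out", and the G-loop backbone sits in the beta basin
("extended"). A complex engineered to make the A213 hinge H-bond, the K162
cation-pi and the W277 stacking contact:

```r
cx <- make_toy_complex(c(4, 10, 12), dfg = "out_up")
fp <- compute_sift(interaction_table(cx$atoms, cx$pose, cx$map))
fp
#> SIFt: 00010000010100
#>   bit  4  GK+3 A213 hinge H-bond (ligand acceptor)
#>   bit 10  K162 cation-pi (ligand aromatic)
#>   bit 12  A-loop W277 pi-pi
suggest_class(classify_structure(cx$atoms, map = cx$map, cal = cal), fp)[, 1:3]
#>   class score conformation_ok
#> 1   III 0.667            TRUE
#> 2    II 0.500            TRUE
#> 3     I 0.000           FALSE
#> 4  I1/2 0.000           FALSE
```

The fingerprint covers two of type III's three required hot-spots (the
K162/E181 polar hot-spot via bit 10 and the activation-loop hot-spot via bit
12) and half of type II's six; type I and I1/2 are zeroed because they
require a DFG-in, alphaC-in conformation.

A command-line front end wraps the same functions:

```sh
KINCONF=$(Rscript -e 'cat(system.file("cli/kinconf.R", package="kinconf"))')
Rscript "$KINCONF" fixtures --out /tmp/fixtures --seed 1
Rscript "$KINCONF" classify /tmp/fixtures/toy_out_up_folded.pdb
Rscript "$KINCONF" report   /tmp/fixtures/toy_complex_allbits.pdb
```

## Acceptance script

`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
re-runs the full pipeline from scratch — generating toy structures for every
conformation label combination, classifying them against the default
calibration, building complexes for random fingerprint bit subsets,
detecting their interactions, recomputing the fingerprints and the
frequency profile, and ranking inhibitor classes — then writes the
acceptance-target JSON to `--out`.

## Layout

* `R/` — parsing (`read_pdb`), numbering (`align_to_reference`), geometry
  (`residue_com`, `backbone_dihedrals`), metrics (`inter_motif_metric`,
  `intra_motif_metric`), classification (`classify_structure`,
  `calibrate_conformations`), detectors (`detect_*`, `interaction_table`),
  fingerprints (`compute_sift`, `tanimoto`, `frequency_profile`), hot-spots
  (`assign_subpockets`, `suggest_class`), fixtures (`make_toy_kinase`,
  `make_toy_complex`).
* `inst/extdata/` — synthetic reference profile (labelled synthetic),
  reconstructed hot-spot and class-profile tables (editable TSVs).
* `vignettes/kinase-conformations.Rmd` — the model, its assumptions,
  defaults and limitations.
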