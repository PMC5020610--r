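---
title: "Dissecting peptide-dimer conformational ensembles with dimerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting peptide-dimer conformational ensembles with dimerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Small soluble oligomers formed early in the aggregation of amyloidogenic
peptides — the 37-residue human islet amyloid polypeptide (hIAPP, amylin)
being the canonical type-II-diabetes example — are transient, heterogeneous
and hard to characterize experimentally. Atomistic simulation (typically
replica-exchange molecular dynamics, REMD) produces conformational
ensembles of the smallest oligomer, the dimer, with and without candidate
aggregation inhibitors such as the green-tea polyphenol EGCG. Turning those
raw coordinate ensembles into the quantities a structural paper reports —
secondary-structure populations, representative cluster structures, contact
maps, free-energy surfaces, stacking geometries, collision cross sections —
is the job of this package.

dimerscope implements that analysis stack and, because published
trajectories of this kind are rarely deposited, ships a synthetic-ensemble
generator that builds peptide backbones, beta-hairpins, dimers and ligand
placements with *known* ground truth. Every analysis is validated against
that ground truth or an independent oracle rather than against irreproducible
trajectory-specific numbers.

## The models and their assumptions

### Secondary structure (Kabsch–Sander)

`assign_ss()` reimplements the hydrogen-bond pattern rules: the
electrostatic bond energy

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

with distances in ångström and a bond whenever $E < -0.5$ kcal/mol;
3/4/5-turns and the consecutive-turn rule give G/H/I helices; parallel and
antiparallel bridge patterns give B, with ladders of consecutive bridges
extended to E; isolated turns give T; a C$_\alpha$ pseudo-angle
$\kappa > 70^\circ$ gives bend S; otherwise C. Per residue the final class
follows the priority H > E > B > G > I > T > S > C.

Choices worth knowing:

* **Inter-chain bridges are allowed**, so a three-stranded sheet spanning a
  dimer interface is assigned E across chains.
* **Amide H reconstruction**: when the topology declares no amide
  hydrogen, H is placed 1.0 Å from N anti to the preceding carbonyl C→O
  direction (the original DSSP convention). Chain starts and prolines are
  never donors.
* **Bond exclusions**: a residue cannot bond itself or its covalent
  same-chain neighbor ($|i-j| \le 1$). Separation 2 stays allowed because
  parallel bridges at the minimum strand separation use it.
* **Bulge-linked ladders are not merged**; on idealized geometry this
  only affects rare edge residues.
* **Class collapse for reporting** (`ss_profile()`): helix = {H, G, I},
  sheet = {E}, bridge = {B}, turn = {T}, bend = {S}, coil = {C}. Which
  helix subtypes to pool into a single "helix" bar is a reporting
  convention, not part of the assignment; the 8-state matrix stays
  available.
* **Strand-length normalization** (`strand_length_pdf()`): counts of
  maximal E runs divided by (frames × chains). Under this convention the
  values do not sum to 1 — a conformation with no strand contributes
  nothing — which is the convention under which published strand-length
  distributions with few-percent values are stated.

### Chain-independent clustering (Daura)

`daura_cluster()` implements the greedy neighbor rule: the frame with the
most neighbors within the RMSD cutoff (ties to the lowest frame index)
seeds a cluster, the cluster is removed, and the process repeats. The
pairwise metric for a homodimer is the **chain-independent** main-chain
RMSD — the minimum over the two chain-label assignments (A→A,B→B vs
A→B,B→A) of the Kabsch-superposed RMSD — because topologically identical
chains make the labeling arbitrary. Defaults: main chain = {N, CA, C, O},
cutoff 0.35 nm (the value stated for peptide-dimer clustering; a "3.5 nm"
variant that appears in some texts is treated as a typo for 0.35 nm).
Ligand atoms are never part of the clustering selection.

`rmsd_matrix()` computes the full $O(n^2)$ matrix with the fast
singular-value trace formula; the two-frame `chain_independent_rmsd()`
recomputes from rotated residuals instead, which is what makes the exact
chain-swap identity (RMSD $< 10^{-10}$ nm) testable — the trace formula
loses ~$10^{-8}$ nm to cancellation.

### Contacts, hydrogen bonds, stacking, cation–π

* **Contact maps**: a residue pair is in contact when the minimum distance
  between selected heavy atoms (MC–MC or SC–SC) is ≤ 0.5 nm. The source
  study does not state its cutoff; 0.5 nm is the common single-tier
  convention and is configurable everywhere it is used.
* **Hydrogen-bond counting** (`hbond_count()`): donor–acceptor distance
  ≤ 0.35 nm and H–donor–acceptor angle ≤ 30°, the standard geometric
  criterion of simulation analysis tools (also unstated in the source
  study).
* **Stacking classification** (`stacking_classify()`): plane angle
  $\theta = \arccos|n_1\cdot n_2| \in [0^\circ, 90^\circ]$; *parallel* if
  centroid distance ≤ 0.55 nm and $\theta \le 30^\circ$; *perpendicular*
  (T-shaped) if distance ≤ 0.75 nm and $\theta \ge 60^\circ$; otherwise
  none. The thresholds bracket the reported basin centers for
  peptide–polyphenol stacking, (0.4 nm, 15°) and (0.6 nm, 85°), and are
  exposed as arguments.
* **Intra-ligand ring torsions** (`ring_pair_torsion_pdf()`) use
  *oriented* ring normals — the right-hand rule over the declared ring-atom
  ordering — giving angles in [0°, 180°], so a flipped ring is
  distinguished from a coplanar one. The stacking angle, by contrast, is
  folded to [0°, 90°] because ring faces are physically equivalent there.
* **Cation–π** (`cation_pi_pdf()`): the cationic center is the mean
  position of the declared charged-group atoms. Chemically an arginine
  carries a guanidinium; in the minimal synthetic side chains the group is
  a single pseudo-nitrogen beyond CB, so the mean degenerates to that atom.

### Free-energy surfaces and diagnostics

`fes2d()` bins weighted samples of two reaction coordinates and returns
$G = -RT\ln P$ (R = 1.987×10⁻³ kcal/(mol·K)), shifted to zero at the
deepest bin, with empty bins masked. The pipeline's default coordinates are
the mass-weighted peptide radius of gyration (bin width 0.02 nm) and the
backbone H-bond count (integer bins of width 1); bin *edges* are fixed in
the configuration rather than data-driven so that two conditions remain
comparable bin by bin. `find_basins()` finds 8-neighborhood local minima
and filters them by topographic prominence (persistence merging): a minimum
survives only if the lowest saddle to any deeper minimum lies at least the
depth threshold above it.

`split_half_convergence()` compares each metric's distribution in the two
contiguous halves of an ensemble by the Jensen–Shannon distance (base 2, in
[0, 1]). `temperature_ladder()` generates the geometric ladder
$T_i = T_{\min}(T_{\max}/T_{\min})^{i/(n-1)}$ — the published ladder
generator is cited without equations in this literature, and the
constant-ratio ladder is the standard stand-in for systems with roughly
temperature-independent heat capacity. `replica_traversal()` counts
bottom→top→bottom round trips.

### Collision cross section

`ccs_projection()` uses the **projection approximation** (PA): for each
seeded uniform random orientation, atoms are projected as hard disks
(H 2.2 Å; C/N/O 2.7 Å) and the union area is estimated by Monte Carlo
sampling; the CCS is the orientation-averaged area. PA replaces the
trajectory method used with buffer-gas physics in dedicated CCS codes — it
is desk-scale and deterministic given a seed, but systematically low for
proteins (typically 10–15%); a calibration scale factor is exposed and
defaults to 1. The standard error is the spread of per-orientation area
estimates, which includes the Monte Carlo sampling noise.

## The synthetic world

`generate_mixture()` draws frames by seeded categorical sampling over rigid
component conformers (ideal α-helix (−57°, −47°); ideal β-strand
(−139°, 135°); β-hairpins; seeded random coils; dimer variants) plus
isotropic Gaussian jitter (default 0.002 nm — large enough to make frames
distinct, an order of magnitude below the 0.35 nm clustering cutoff). The
built-in presets emulate the reported architecture of the hIAPP dimer: a
hairpin with strands 8–16 and 25–33 and loop 17–24, a three-stranded-sheet
dimer (hairpin + paired strand), and a three-ring ligand placed at planted
parallel/perpendicular/unstacked geometries against the C-terminal tyrosine
ring.

Construction details that matter:

* Backbones are built by sequential internal-to-Cartesian placement with
  fixed ideal bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å;
  angles 111.2°, 116.2°, 121.7°), so requested dihedrals are reproduced
  exactly (round-trip tested to 10⁻³ degrees).
* `build_hairpin()` closes its loop by cyclic coordinate descent against
  an ideal antiparallel pairing target (N···O 0.29 nm with explicit
  amide-H alignment terms, both H-bond registers tried). A pure
  dihedral-template hairpin does not reliably hydrogen-bond for loops
  longer than two residues; the closure is what makes built hairpins
  assign as E ladders.
* The third strand of the sheet dimer is rigidly placed by the same
  pairing optimizer; its H-bond register is derived from the hairpin's own
  backbone H-bond pattern (chain B can only bond the face strand 1 does
  not use), followed by a heavy-atom-aware rigid refinement so aromatic
  side chains clear the partner chain (clash floor 0.15 nm, chosen so
  DSSP hydrogen-bond geometry stays computable).
* Side chains are minimal by design: CB for non-glycine residues, ideal
  planar 6-rings (C–C 1.39 Å) for PHE/TYR along the CA→CB axis, one
  pseudo-nitrogen for the ARG/LYS cationic centers. The ligand is a rigid
  three-ring template with two controllable inter-ring torsions — enough
  to exercise every contact/stacking/torsion analysis, with no claim to
  real EGCG chemistry or conformer energetics.
* The coil generator samples (φ, ψ) from three broad Ramachandran boxes
  (β/PPII, α_R, α_L with weights 0.5/0.35/0.15); no force field is implied.

**What a green test does and does not establish.** The generator produces
idealized, rigid, low-noise conformers. Green tests establish that the
*analyses* are correct — assignments match a reference implementation,
clustering matches its definition, planted compositions and geometries are
recovered, closed forms hold. They do not establish anything about real
hIAPP thermodynamics, real EGCG binding, or force-field quality, and the
synthetic ensembles make no attempt to reproduce published population
percentages.

## Numerical choices and degenerate inputs

* Internal unit is nm; PDB I/O converts Å↔nm at the boundary and
  round-trips to the format's 10⁻³ Å precision.
* Kabsch superposition disallows reflections (SVD sign correction);
  fewer than 3 atoms or zero total weight is an error.
* Daura ties (equal neighbor counts) go to the lowest frame index;
  clusters order by size then center index; `cutoff ≤ 0` is an error.
* `fes2d()` requires a nonzero-width range; all-masked surfaces make
  `find_basins()` error; a single populated bin yields G = 0 there and
  masks elsewhere.
* Ensembles require ≥ 1 frame, finite coordinates, nonnegative weights
  normalized to 1; `split_half_convergence()` requires ≥ 4 frames and
  skips metrics undefined for the topology with a warning.
* Ligand placement errors when any ring-atom pair would come closer than
  0.1 nm; the seeded azimuth can be retried to find a clash-free
  placement without changing the requested geometry.
* All randomness is explicit: generators and CCS take a `seed`; the
  pipeline (`run_full_analysis()`) is byte-deterministic for a fixed
  configuration, verified by MD5 manifests.

## Known limitations

* The DSSP reimplementation omits β-bulge ladder merging and later
  π-helix refinements; solvent accessibility is not computed.
* PA CCS is not the trajectory method: absolute values are systematically
  low and no buffer-gas dependence is modeled.
* The synthetic ligand cannot probe chemistry-dependent effects
  (H-bonding substituents, charge transfer).
* Clustering is exact $O(n^2)$; for very large ensembles use the
  `stride` option of `rmsd_matrix()`.
* No reweighting across replica temperatures (WHAM/MBAR) — analyses treat
  a single-temperature ensemble, which is how such data are analyzed at
  310 K.

## A worked tour

```{r, eval = FALSE}
library(dimerscope)

# a three-stranded-sheet dimer with known architecture
dimer <- build_sheet_dimer(hiapp_sequence(),
                           strand1 = 8:16, turn = 17:24, strand2 = 25:33)
assign_ss(dimer)

# a labeled synthetic ensemble and the full analysis
cfg <- analysis_config(out_dir = "dimer_run", preset_frames = 40, seed = 1)
run_full_analysis(cfg)
compare_conditions("dimer_run/without_ligand", "dimer_run/with_ligand")
```
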