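---
title: "Monte Carlo minimization modelling of cationic blockers in P-loop channel pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo minimization modelling of cationic blockers in P-loop channel pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremcm)
```

## The problem

Small cationic blockers such as mexiletine inhibit voltage-gated sodium
channels by binding in the inner pore, with the ammonium group reaching the
cation-attractive ring of backbone carbonyls at the outer-pore bottom and
the aromatic moiety extending either along the inner pore (the
use-dependent-block orientation) or laterally into the III/IV fenestration
(the tonic-block orientation).  Because the fenestrations connect the pore
to the lipid bilayer, their width — which changes with the conformational
state of the voltage-sensing domains (VSDs) — controls both how well the
fenestration-bound pose is accommodated and how easily a drug can pass
through on its way in or out of a closed channel.

`poremcm` implements, at desk scale, the computational machinery used to
study this system: Monte-Carlo-minimization (MCM) sampling over internal
coordinates, random-start ligand docking with pose-stack clustering,
in-silico deactivation of a voltage sensor by plane-constrained S4 pulling,
ligand egress energy profiling through a fenestration, and geometric
analyses of fenestration widths and lipid-facing residues.  A synthetic
four-repeat toy channel generator stands in for cryo-EM inputs so that
every protocol is exercised end to end by fast, reproducible tests.

## Residue nomenclature

Pore-domain residues are named with the universal P-loop channel labels:
repeat number (1–4), a segment letter — `k` for the S4–S5 linker helix,
`o` for the outer helix S5, `p` for the P-loop, `i` for the inner helix
S6 — and a position within the segment.  P-loop positions are relative to
`p50`, the selectivity-filter position (the DEKA ring in Nav1.x channels).
The packaged hNav1.5 anchor table maps labels to UniProt (Q14524) residue
numbers:

```{r}
anc <- hnav15_anchors()
resolve_label("4i15", anc)   # the S6_IV phenylalanine, F1760
resolve_label("4o1", anc)    # the S5_IV N-terminal methionine, M1652
format(label_of(1760, anc, hnav15_segment_ranges()))
```

Resolution is affine from one anchor per (repeat, segment).  Residues
outside the pore-domain segments (e.g. VSD residues) carry no label and
keep their sequential numbers; `label_of()` returns `NULL` for them.  Note
that a small number of published residue/label pairings differ by 1–2 from
pure affine arithmetic (alignment gaps between channel isoforms); the
packaged table follows the anchor definitions, and such residues are best
handled by explicit residue numbers.

## The energy model

The package uses a reduced united-atom model that preserves the structural
contracts of MCM channel modelling rather than the absolute energetics of
any published force field:

* **van der Waals**: 12-6 Lennard-Jones over a ~10-entry united-atom type
  table, multiplied by the shifting function $S(r) = (1-(r/c)^2)^2$ so that
  the energy *and its first derivative* are exactly zero at the cutoff
  $c = 9$ Å and beyond.
* **Electrostatics**: Coulomb term with a distance-dependent dielectric
  $\varepsilon(r) = \varepsilon_0 r$ (default $\varepsilon_0 = 4$), i.e.
  $E = 332.06\,q_iq_j/(\varepsilon_0 r^2)$ kcal/mol.  Pairs involving an
  ionized group (e.g. the ligand ammonium) are exempt from the cutoff; all
  other pairs are shifted to zero at the cutoff by the same $S(r)$.
* **Exclusions**: 1-2 and 1-3 bonded pairs are excluded, 1-4 pairs scaled
  by 0.5 (conventional).
* **Torsions**: a small threefold barrier on ligand rotatable bonds.
* Harmonic springs declared by a structure (the toy channel's S4-to-pore
  couplings) are added as a bonded term.

Because the type table, charges and dielectric are deliberately simple,
quantitative energies in kcal/mol are *model energies*: the package's
claims are orderings, contracts and geometric responses, which is also how
its tests are written.

## Restraints

Three restraint families drive all protocols:

* **Pins** — flat-bottom parabolic positional restraints on backbone
  beads: penalty-free within 1 Å of the template, $k(d-1)^2$ beyond with
  $k = 10$ kcal·mol⁻¹·Å⁻², so `pin_energy(2.0)` is exactly 10 kcal/mol.
  Pins keep the fold near the template while allowing local drift.
* **Planes** — an atom is free to move within a plane normal to the pore
  axis but not to leave it.  Implemented as exact projection of the axial
  coordinate after every perturbation plus a stiff harmonic
  (1000 kcal·mol⁻¹·Å⁻²) during minimization; the enforcement contract is a
  residual violation below 0.05 Å.
* **Axial distance** — the ligand para-carbon is held at a fixed
  cylindrical radius from the pore axis; azimuth and axial position remain
  completely free (equivalently: the atom moves on a sphere whose centre
  slides along the axis).  Enforced by rigid radial translation of the
  whole ligand plus the same stiff harmonic.

## The MCM engine

Each MCM step randomly perturbs a subset of the degrees of freedom —
ligand rigid-body pose (quaternion orientation + translation), ligand
rotatable torsions, channel side-chain torsions, optional per-repeat
rigid-body moves, and Cartesian beads — then locally minimizes the
objective (bounded quasi-Newton with a compiled objective/gradient), and
accepts or rejects by the Metropolis criterion at $kT = 0.6$ kcal/mol
(configurable; conventional MCM practice, since no temperature is implied
by the protocols themselves).  A run terminates when a configured number
of consecutive minimizations (`patience`) fails to improve the apparent
global minimum, or after a fixed step count in the coarse docking stage.

Design choices worth noting:

* The per-minimization parameter bounds (±2.5 Å ligand translation, ±π
  torsions, smaller rigid-body steps) act as a trust region: a clashing
  candidate relaxes locally instead of being ejected to infinity, and
  large motions are composed across MC steps.
* Channel backbones are rigid except for explicit rigid-body and
  Cartesian degrees of freedom; ligand bond angles are fixed.  This is a
  deliberate desk-scale simplification of fully flexible internal
  coordinates.
* Flexible side chains default to the rule "any residue with an atom
  within 10 Å of the ligand or of a moving restrained atom".
* Minimized candidates are clustered into a **pose stack**: records
  within 1.5 Å ligand heavy-atom RMSD (no superposition — poses share a
  frame) merge, keeping the lower-energy representative; the stack keeps
  at most 100 records within 7 kcal/mol of the best.

## Docking

`dock()` reproduces the random-start protocol: ligand mass centres are
drawn uniformly in a sphere of radius 8 Å centred at the focus of the P1
helices, orientations uniformly over rotation space, torsions uniformly;
each start is optimized by a fixed number of MC-minimizations (default
100) without ligand–channel restraints; the energetically best complexes
(default 100) are refined by patience-terminated MCM; all refined records
merge into one stack.  `report_poses()` filters by ligand–channel
*interaction* energy (matching how binding poses are reported), lists
4-Å contact residues with universal labels, and classifies poses
geometrically: aromatic-ring centroid beyond a radial boundary (default
8 Å) = fenestration/tonic-block-like, otherwise inner-pore/
use-dependent-block-like.

A worked parameter-recovery example:

```{r, eval = FALSE}
ch <- make_toy_channel()
lig <- make_toy_ligand()
# place the ligand in the inner pore, ammonium up toward the carbonyls
pose <- ligand_coords(lig)
pk <- plant_pocket(ch, set_ligand_coords(lig, pose), strength = 1)
res <- dock(pk$channel, lig,
            docking_config(n_starts = 20, coarse_steps = 10, n_refine = 3,
                           refine_patience = 40, seed = 1))
ligand_rmsd(res$stack$records[[1]]$coords, pk$optimum, lig)  # ~0.4 A
```

`plant_pocket()` adds an ionized bead opposite the ammonium, a second
anchor bead near the charged linker carbon (placed at least 5.5 Å from the
first so a cation cannot chelate both), and a six-bead aromatic clamp
sandwiching the ring plane.  The returned optimum is the planted pose
after a short deterministic MCM relaxation — the basin floor of the
constructed pocket — which is what docking from random starts should
recover.

## Voltage-sensor deactivation

`deactivate_vsd()` pulls the five S4 gating-charge beads of one repeat
down the pore axis through sets of planes (default 21 steps of 0.5 Å,
10.5 Å total), each bead free within its plane, with the four pore-domain
bodies pinned (flat-bottom, 1 Å) and movable as rigid bodies.  Each step's
MCM (default patience 200) starts from the previous step's minimized
structure.  In the toy channel, springs couple the S4 stub to the C-beta
columns flanking its interface window; pulling the stub below the window
stretches them and draws the flanking repeats together, so deactivating
repeat III narrows the planted III/IV pair distance — the direction
observed when comparing experimental structures with activated versus
resting sensors.  `build_state_models()` chains the protocol over any set
of repeats to emulate resting-sensor combinations.

## Egress profiling

`egress_profile()` increases the distance between the ligand para-carbon
and the pore axis stepwise (default 80 steps of 0.4 Å, 32 Å total).  At
each step a first MCM runs with the backbone fixed and the radius
constrained; optionally a second, unconstrained MCM follows, and the
ligand–channel interaction energy, achieved radius and 4-Å contacts are
recorded; the next step starts from the achieved state.  Two practical
notes from the toy system:

* Under the unconstrained second stage the ligand may slide back toward
  the pore near the barrier top; the profile records achieved radii
  honestly, and an `early_exit` flag marks runaway ligands.  For
  *measuring* barriers the single-stage (constrained) scan is the cleaner
  radial profile, and `egress_barrier()` — site-basin minimum to
  smoothed outward peak — is the robust statistic.
* `analyze_profile()` defines interior minima as steps strictly below
  both neighbours (plateaus count once, at their first step) and barriers
  as the maximum energy on the path between two points minus the energy
  at the origin point.

## The synthetic toy channel

`make_toy_channel()` builds a four-repeat pseudo-channel at united-atom
bead resolution: S5/P1/S6 helix rods per repeat at 90° spacing, a ring of
four carbonyl-oxygen beads (charge −0.4 e by default) at the outer-pore
bottom forming the cation-attractive site, a DEKA-like selectivity ring, a
framed fenestration window per interface whose flanking C-beta pair is
planted at exactly the requested width (default 12 Å; narrower values
emulate resting-sensor geometry), lipid-facing aromatic (F) and polar
(S/T/Q) decor residues on each interface wall — most numerous on III/IV,
where they provide the interim attraction site outside the window — and a
five-bead S4 stub per repeat with coupling springs (k = 6 kcal·mol⁻¹·Å⁻²,
chosen so pulling produces a clear mechanical response while the unpulled
springs rest at zero extension).  After assembly the structure is
equilibrated by one deterministic bounded rigid-body minimization under
pins and the width pair is re-planted exactly, so the as-built channel
carries no residual inter-repeat strain and protocol-induced changes are
attributable to the protocol.

What the toy does *not* emulate: sequence realism, side-chain rotamer
detail, explicit water or lipids, entropy, or the absolute energy scale of
a molecular-mechanics force field.  Tests passing on the toy demonstrate
that the protocols implement their contracts and reproduce the *response
directions* (width narrowing on deactivation, higher egress barriers and a
worse-accommodated fenestration pose at narrow widths, an interim minimum
midway to the lipids); they do not validate quantitative predictions for a
real channel.

## Numerical choices and problem sizes

Defaults follow the published protocol scales (docking patience 1000,
deactivation 21 × 0.5 Å with patience 200, egress 80 × 0.4 Å with patience
100, stack window 7 kcal/mol and capacity 100, report window 10 kcal/mol).
The test suite runs the same code at reduced sizes chosen for fast
reproducibility: 15–20 docking starts with patience ≈ 40, deactivation as
7 × 1.5 Å (the same 10.5 Å total) with patience 8, and egress scans of
16–17 × 0.5 Å with patience 8–12 on toy channels of ~300 beads.  Seeds are
fixed; every stochastic assertion is a majority vote over ≥ 5 seeds.
Stochastic-ordering checks use widths 7.5 Å (resting-like) and 12 Å
(activated-like): at bead resolution the steric response to width spans a
narrower dynamic range than in atomic structures, so the emulated
activated/resting difference is exaggerated relative to the ~1–2 Å seen
experimentally.

## Known limitations

* The minimizer is a bounded L-BFGS with finite-difference gradients — a
  contract-compatible substitute for derivative-based internal-coordinate
  minimizers; only descent and convergence-in-practice are guaranteed.
* The dielectric model implements the distance-dependent part only; the
  environment-dependent part of published screened-Coulomb models is out
  of scope and $\varepsilon_0$ is exposed as configuration.
* The lipid-facing census depends on explicit thresholds (facing angle,
  exposure radius, interface sector); defaults are calibrated on the toy
  geometry and should be re-calibrated before use on experimental
  structures.
* Real-structure workflows (PDB/mmCIF input, P1-helix superposition,
  fenestration comparisons across deposited structures) are implemented
  and unit-tested on synthetic geometry; no experimental structure is
  bundled.
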