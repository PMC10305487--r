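---
title: "Modeling IgM- and complement-mediated adenovirus neutralization and its inhibition by factor X"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling IgM- and complement-mediated adenovirus neutralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Human adenovirus C5 (HAdv-C5) injected into the bloodstream meets three
classes of host protein whose interplay decides whether the virion survives:
natural IgM, the complement system, and coagulation factor X (FX). Natural
IgM binds the hexon HVR1 loops multivalently, flips from its planar solution
conformation into a bent, dome-shaped ("staple") conformation, and thereby
exposes the Fc DLPSP motifs that recruit the C1 complex. C1 proteases
generate C4b, whose reactive thioester attaches covalently to the capsid;
the classical convertase then deposits C3b copies that amplify across the
facet. C3b that ends up near an icosahedral vertex can entangle the penton
base RGD loops and the fiber, "sealing" the vertex and blocking the release
of the membrane-lytic protein VI — neutralizing the virus. FX, by contrast,
coats every hexon trimer (its GLA domain docks in the trimer's central
depression, anchored at hexon residue T425) and this coat sterically
interferes with the IgM/complement pathway.

`adcomplement` rebuilds this entire chain of structural arguments as a
deterministic, testable pipeline over coarse-grained synthetic structures:
facet assembly, IgM pose enumeration, template-driven C1/C4b placement,
convertase-guided C3b propagation, FX competition, and nonbonded
interaction-energy analysis of C3b at the vertex.

## The synthetic structures

Everything runs on generated bead models (one pseudo-C-alpha bead per
residue, 3.8 Å consecutive spacing exact by construction), dimensioned to
the modeled system:

* **Hexon trimer** — three chains wound as interleaved helices; a dense top
  annulus annotated `hvr1` (the Fab-binding loops); a central depression
  ≥ 8 Å deep whose floor carries the `fx_site` marker at residue 425. The
  T425A FX-binding-ablated mutant is emulated by generating the hexon
  without the `fx_site` annotation (`fx_binding_enabled = FALSE`).
* **Penton base** — five chains spanning residues 38–571 with the fixed body
  (38–296, 377–571) and the flexible RGD loop (297–376) as an extended
  corkscrew arm; the loop apex (acidic beads around residues 335–337, the
  RGD motif) rises > 15 Å above the base top.
* **Fiber** — a template of N-terminal tail (residues 1–6), four exact shaft
  repeats, and knob; `build_fiber()` propagates repeats at 13 Å rise and
  51.4° twist per repeat to 21 repeats, giving a ~350 Å fiber. The repeats
  lie exactly on the shaft screw axis, so every repeat is a rigid copy and
  all junction bonds stay at bead spacing.
* **IgM** — five Fc units on a contiguous platform ring (bridged, with one
  angular gap at the pentamer's missing sixth position) and ten Fab arms.
  Bent form: all tips in one plane 55 Å below the platform. Planar form:
  arms extended radially, the designated pair (counterclockwise from the
  gap) drooping slightly so only it can reach a hexon top.
* **C1** — C1q hexamer (one subunit flagged `bent_upward`, hovering over the
  facet) plus the C1r2s2 tetramer, built directly in the bent-IgM frame so
  the stored IgM-to-C1 template transform is the identity.
* **C4b/C3b** — isomorphic two-chain models (α 650–1450, β 1–450 — the α
  chain longer, as in the real proteins) whose thioester domain (990–1290)
  hangs below the body with the reactive thioester (residues 1010/1013,
  charged bead pattern) at the underside, and a `substrate_interface`
  strand on the local +y face.
* **FX** — compact GLA chain sized to the hexon depression plus a protease
  chain protruding > 20 Å above the hexon top when docked.

Real sequence content is not modeled; the marker residue *indices* (425,
297–376, 335–337, 990–1290, 1010/1013, 1–6, 38–296/377–571) are honored so
residue-level statements stay addressable. What the fixtures do **not**
emulate: real side-chain chemistry and force-field parameters, icosahedral
curvature (the facet is flat; see below), glycans, the J chain, and
crystallographic detail of the template complexes (stored as fixed rigid
transforms instead).

## The facet

Eighteen hexon trimers occupy a triangular close-packed lattice (edge length
300 Å, lattice spacing 60 Å): twelve canonical slots labeled by
asymmetric-unit position 1–4 under the facet three-fold, plus six
edge-extension slots that complete the triangular array but belong to the
neighbouring facets of the capsid. Penton base pentamers sit at the three
vertices with fibers along the outward normal. The facet is modeled flat:
true icosahedral curvature within one facet is small, and the analysis is of
a facet-local arrangement. Because a flat model cannot satisfy both the
300 Å edge and the full-capsid diameter, edge length governs and the
diameter is never asserted.

## Placement rules and their parameters

**IgM poses.** The designated Fab pair is centred over the anchor hexon
(asymmetric-unit label 1–4) at rotation 0; rotations of 90/180/270° are
applied about the Fc-platform axis with the centre fixed, giving 16 bent
poses. The molecule descends along −z to its deepest clash-free height
(coarse-to-fine steps of 4/1/0.25 Å); a Fab tip is "in contact" within 5 Å
of an HVR1 marker bead. The *bent-conformation gate* — C1 is recruited only
when ≥ 8 of 10 tips are in contact — operationalizes the mechanism that the
dome forms only under multivalent attachment; the threshold is configurable.
For counting how many IgM fit a facet we additionally require ≥ 5 of the
contacts on the facet's own (canonical) hexons: an IgM anchored on an
edge-extension trimer would straddle the capsid fold in reality, which the
flat model cannot represent, and such a straddling dome does not form.

**C4b.** Two template sites flank the Fc gap adjacent to the C1s chains
(site radius 95 Å from the IgM centre, ±35° about the gap azimuth). A site
is feasible iff the thioester marker can reach a facet surface bead
(≤ 8 Å), its in-plane projection lies over the facet (edge-extension hexons
count as surface; beyond them does not), and the pose is clash-free.
Infeasible sites are recorded with their reason — in the enumeration the
single-C4b poses arise from the thioester projecting past the facet edge.

**C3b propagation.** For each bound convertase (first the C4b copies, then
each newly bound C3b), an incoming substrate is placed side-by-side at the
convertase's substrate interface (55 Å centroid offset), raised to
diffusion height above the hexon tops, and translated in 5 Å steps. The
default translation direction is the straight ray continuing away from the
convertase along its interface direction; when the path would leave the
facet it deflects off the boundary of the deposition surface (billiard
reflection off the dilated facet triangle) and continues, up to 300 Å of
path length — the distance the short-lived reactive C3b can diffuse — or a
molecular obstruction (fiber, Fab arm, penton, another complement
molecule). An anchor-to-facet-centroid ray variant is available
(`direction = "centroid_ray"`); it was not adopted as the default because
the facet-centred IgM–C1 complex then intercepts essentially every walk at
its rim, which contradicts the across-the-facet translations the model is
meant to reproduce. At the stopping point the substrate settles toward the
surface and a discrete orientation grid (30° steps about the facet normal
and the two in-plane axes, identity first, lexicographic order) searches
for a pose that is clash-free, has the thioester within 8 Å of the surface,
has its substrate interface unobstructed (no placed-molecule bead within a
forward cylinder of radius 15 Å over 60 Å), and leaves the interface an
on-facet runway so the next C3 can actually be recruited (long-runway
orientations preferred). If no such pose exists at the stopping point, the
substrate backs up step by step (up to 20 steps): it binds covalently at
the farthest reachable position where binding is feasible, recording the
nearest surface bead as its anchor. Propagation stops at three C3b per
facet — the stand-in for negative regulation of the amplification loop by
factor H.

**Vertex occupancy.** A vertex counts as occupied when a bound C3b's
thioester-domain centroid lies within 60 Å of the penton centroid, measured
in the facet plane (occupancy is about position on the facet; height above
the surface does not discount it). The 60 Å default is this package's
operationalization of "at a vertex" and the occupancy distribution is
sensitive to it.

**FX competition.** One FX per hexon slot: the three slots nearest the
facet three-fold get the canonical docking frame; the other fifteen a
seeded jitter (uniform spin, tilt ≤ 15°). An arriving IgM is placed with FX
clash-checking deferred — the multivalent binder displaces locally — and
every FX clashing with the final IgM is then removed, reproducing the
modeled order of operations. DLPSP accessibility uses a probe sphere
(radius 15 Å) centred above each marker; the IgM is overall accessible with
≥ 5 free sites (hexavalent C1q engagement). Residual deposition space scans
a 20 Å grid of candidate anchor points with the same orientation search as
propagation.

## Energetics

Nonbonded energies are Coulomb (332.0636 kcal·Å/mol/e², dielectric 1 — the
solvated treatment of the source calculations is unknown, so vacuum is the
default and the dielectric is exposed) plus 12-6 Lennard-Jones with
geometric-mean epsilon and arithmetic-mean Rmin, under a CHARMM-style C1
switching function from 10 to 12 Å; pairs beyond the cutoff are exactly
zero, and bonded neighbours within two bonds are excluded. Bead charges
come from the fixture sidecar: the acidic RGD apex carries −1 beads and the
thioester face a +1/−1 pattern, enough to reproduce electrostatics-dominated
vertex interactions at bead resolution.

The relaxation is a deliberate desk-scale stand-in for solvated
molecular dynamics, which is out of scope: steepest descent with a halving
line search on nonbonded energy plus harmonic bonds (k = 10 kcal/mol/Å²,
rest length 3.8 Å) between consecutive residues, with the penton-base body
(residues 38–296 and 377–571) and all hexon atoms held fixed and the RGD
loops, fiber and C3b mobile. Energy is non-increasing by construction;
fixed atoms move exactly zero; fixed–fixed pairs are excluded from the
reported energy (they are constant). The vertex survey relaxes 11 starting
models (deterministic azimuths and orientations of one C3b around the
penton+fiber vertex) and reports a pose × chain (P1–P5, F1–F3) table with
exact zeros for chains beyond the cutoff, flagging poses with ≥ 2 chains
below −40 kcal/mol as showing extensive interactions. The absolute
magnitudes of all-atom force-field energies are not reproducible at bead
resolution and are not targets.

## Calibration of the fixture constants

The constants that are not stated dimensions of the system (IgM Fab reach
and platform radius, the anchor-offset azimuth that positions the IgM
centre, C4b site radius/separation/height, the convertase-substrate offset)
were calibrated once, by a two-stage procedure: a fast 2-D geometric
surrogate to triage the parameter space, then full-pipeline enumeration on
the shortlist. Guiding constraints, in order: every one of the 16 poses
must pass the bent-conformation gate; exactly four poses should lose their
second C4b to the facet edge; the vertex-occupancy distribution should
approach the documented {two:11, one:4, none:1}. The IgM tip ring (75 Å)
is the largest radius for which all 16 poses keep ≥ 8 tips over the hexon
array — the pose envelope (anchor spread plus ring) just fits the facet —
and it places the ten tips across 4–6 distinct hexon trimers.

A structural limitation emerged from this calibration and is worth stating
plainly: under any deterministic, pose-independent translation rule, the two
C4b sites rotate with the IgM in 90° steps while the facet's vertices are
120° apart, so for a given anchor at most one of the four rotations can aim
a given site's walk at a vertex; reaching two vertices then depends on
multi-hop chains turning at bindings and riding the facet boundary into two
corners within the three-C3b cap. In this package's frozen calibration that
happens in a minority of poses, so the two-vertex count falls short of the
documented 11 while the single-C4b count (4) and one-vertex count are
reproduced. The vertex radius was deliberately not widened to force
agreement; the sensitivity is exposed through `vertex_radius` and the
`direction` rule.

## Numerical choices and degenerate inputs

Rigid transforms keep rotations orthonormal (SVD cleanup per composition
chain, tolerance 1e-8). Superposition is Kabsch with the determinant
correction, refusing < 3 points or collinear sets. Clash detection uses
`distance < r_i + r_j − 0.6 Å` on a spatial grid (near-linear cost; the
0.6 Å tolerance mirrors interactive viewers' default and is configurable);
empty models yield empty results. PDB output writes hybrid-36 serials past
99,999 atoms and keeps bead parameters in a JSON sidecar keyed by bead
type; chain ids longer than four characters round-trip through generated
segment ids recorded in the sidecar. Orientation searches and greedy loops
are fully deterministic (fixed grids, lexicographic tie-breaks); the only
randomness in the package is the seeded FX jitter.

## Problem sizes

Default problem sizes were chosen so the full suite and the analysis
scripts run comfortably on a single CPU: the assembled facet carries
~34,000 beads; enumeration over 16 poses performs a few thousand
grid-accelerated clash queries per pose; the vertex survey relaxes 11
~4,700-bead systems for up to 150 steepest-descent steps. All stages
complete in minutes.

## Known limitations

* The two-vertex occupancy count falls short of the documented value (see
  the calibration section); the package reports what its deterministic
  rules produce.
* Bead-resolution excluded volume is porous at scales below ~4 Å; clash
  detection is meaningful for domain-scale steric questions only.
* The flat facet cannot express capsid curvature; the straddling-IgM
  exclusion encodes its main consequence as a rule rather than geometry.
* Energies are qualitative: decompositions, zeros, percent splits and
  favorable-contact identification are meaningful; absolute kcal/mol values
  are not comparable to all-atom force fields.
* No kinetics: FX competition and complement deposition are order-of-
  operations rules, not binding simulations; no C5/MAC downstream steps; no
  whole-virion bookkeeping across facets.
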