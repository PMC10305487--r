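# adcomplement

Structural modeling of IgM- and complement-mediated adenovirus
neutralization and its inhibition by coagulation factor X, as a
deterministic, tested R pipeline over coarse-grained synthetic structures.

## The problem

Bloodborne human adenovirus C5 is attacked by natural IgM and the classical
complement pathway, and protected by coagulation factor X (FX):

* A planar IgM lands on a capsid facet, engages hexon HVR1 loops
  multivalently with its ten Fab arms, and flips into a bent dome that
  exposes the C1q-binding DLPSP motifs.
* The C1 complex generates C4b, whose reactive thioester binds the facet
  covalently; the convertase then deposits up to several C3b copies that
  translate across the facet before attaching.
* C3b that ends up near an icosahedral vertex can entangle the penton-base
  RGD loops and the fiber, "sealing" the vertex against release of the
  membrane-lytic protein VI — neutralization.
* FX docks its GLA domain into the central depression of every hexon
  trimer (anchored at hexon residue T425); the resulting FX layer lets a
  planar IgM touch down with only one Fab pair, blocks the rest, and
  crowds out complement deposition.

This package rebuilds that chain of structural arguments as code: synthetic
bead models of every molecule, facet assembly with helically built fibers,
enumeration of the 16 bent-IgM poses (4 asymmetric-unit anchors x 4
rotations) with template-driven C1/C4b placement and a convertase-guided
C3b walk, FX steric competition, and a nonbonded interaction-energy
calculator (Coulomb + Lennard-Jones with a C1 switching function,
chain/domain/residue-pair decomposition, fixed-base steepest-descent
relaxation). The methods vignette (`vignettes/methods.Rmd`) documents every
model, rule and parameter.

## Worked example

```r
library(adcomplement)

spec  <- fixture_spec()                 # 300 A facet, 3.8 A beads
kit   <- make_fixture_kit(spec)         # all molecules + template transforms
facet <- assemble_facet(kit$hexon, kit$penton, kit$fiber_template, spec)

measure_edge_length(facet)$mean         # 300      (facet edge, A)
measure_fiber_length(facet, 1)          # 348.73   (tail + 21 repeats + knob)

en <- enumerate_poses(facet, kit)       # 16 bent-IgM pose models
table(en$summary$n_vertices_occupied)   # vertex occupancy across poses
sum(en$summary$n_c4b == 1)              # 4 poses keep only a single C4b

fx  <- place_fx_all(facet, kit$fx, spec)          # 18 FX, one per hexon
pl  <- compete(facet, fx, kit$igm_planar, igm_pose(1, 0, "planar"))
pl$contacts                             # 2  (exactly one Fab pair down)
length(pl$retained_fx)                  # 15 (the FX layer stays)
bt  <- compete(facet, fx, kit$igm_bent, igm_pose(1, 0, "bent"))
bt$dlpsp_accessible                     # TRUE (C1 could still engage)
```

The numbers printed above mean: the assembled facet reproduces the ~300 A
edge and ~350 A fiber of the modeled system; four of the sixteen IgM poses
lose their second C4b because its thioester would hang past the facet edge;
on the FX-loaded facet a planar IgM reaches the capsid with exactly one Fab
pair while the FX layer stays essentially intact, whereas a bent IgM keeps
its DLPSP motifs free — yet the space left for C4b/C3b deposition shrinks
(see `residual_deposition_space()`).

## Analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
tables under `results/`:

```sh
Rscript analysis/01_build_facet.R        # facet + measurements
Rscript analysis/02_enumerate_poses.R    # 16-pose enumeration + summary TSV
Rscript analysis/03_fx_competition.R     # FX layer vs planar/bent IgM
Rscript analysis/04_vertex_energetics.R  # 11-pose vertex energy survey
```

`run_all(run_config(...))` performs the same stages from R with a manifest.

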