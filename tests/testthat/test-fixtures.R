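# Synthetic-structure generators: determinism, connectivity, symmetry,
# marker annotations, dimensioning.

test_that("generators are deterministic and exactly bead-connected", {
  spec <- tspec()
  for (gen in list(make_hexon_trimer, make_penton_base, make_fiber_template,
                   function(s) make_igm(s, "bent"), make_c1, make_c3b,
                   make_fx)) {
    m1 <- gen(spec); m2 <- gen(spec)
    expect_identical(coords(m1), coords(m2))
    expect_lt(max_spacing_error(m1), 1e-6)
  }
})

test_that("hexon trimer has exact 3-fold symmetry, HVR1 top and depression", {
  hx <- tkit()$hexon
  r120 <- transform_model(hx, rt_axis_angle(c(0, 0, 1), 120))
  iA <- which(hx$atoms$chain_id == "A"); iB <- which(hx$atoms$chain_id == "B")
  expect_lt(rmsd(coords(r120, iA), coords(hx, iB)), 1e-6)
  expect_equal(length(hx$chains), 3)
  expect_true(all(vapply(hx$chains, function(ch) ch$role == "hexon",
                         logical(1))))
  # hvr1 markers on the top face
  hv <- select_atoms(hx, domain = "hvr1")
  expect_gt(min(hx$atoms$z[hv]), 0.9 * max(hx$atoms$z))
  # central depression: recessed >= 8 A below the top, open in the centre
  top <- max(hx$atoms$z)
  r <- sqrt(hx$atoms$x^2 + hx$atoms$y^2)
  expect_gt(top - max(hx$atoms$z[r < 6]), 8)
  # fx_site at residue 425, present iff FX binding enabled
  expect_equal(unique(hx$atoms$residue_index[select_atoms(hx, domain = "fx_site")]),
               425)
  hx_mut <- make_hexon_trimer(fixture_spec(fx_binding_enabled = FALSE))
  expect_length(select_atoms(hx_mut, domain = "fx_site"), 0)
  expect_identical(coords(hx_mut), coords(hx))   # geometry unchanged
})

test_that("penton base has 5-fold symmetry and a reaching RGD loop", {
  pn <- tkit()$penton
  i1 <- which(pn$atoms$chain_id == "P1"); i2 <- which(pn$atoms$chain_id == "P2")
  expect_lt(rmsd(rt_apply(rt_axis_angle(c(0, 0, 1), 72), coords(pn, i1)),
                 coords(pn, i2)), 1e-6)
  expect_setequal(names(pn$chains), paste0("P", 1:5))
  loop <- select_atoms(pn, chain = "P1", domain = "rgd_loop")
  expect_equal(range(pn$atoms$residue_index[loop]), c(297, 376))
  expect_length(loop, 80)
  base <- select_atoms(pn, chain = "P1", domain = "base_n")
  expect_gt(max(pn$atoms$z[loop]) - max(pn$atoms$z[base]), 15)
  # acidic apex beads around the RGD motif
  motif <- select_atoms(pn, chain = "P1", domain = "rgd_motif")
  expect_true(all(pn$atoms$charge[motif] == -1))
})

test_that("fiber template carries tail, 4 exact repeats and 3-fold symmetry", {
  ft <- tkit()$fiber_template
  md <- ft$metadata
  expect_equal(md$n_template_repeats, 4)
  # repeat axial extent = rise
  a1 <- ft$atoms[ft$atoms$chain_id == "F1", ]
  rs <- md$repeat_start_residue
  z_rep1 <- a1$z[a1$residue_index == rs]
  z_rep2 <- a1$z[a1$residue_index == rs + md$beads_per_repeat]
  expect_equal(z_rep2 - z_rep1, 13, tolerance = 1e-6)
  # 3 chains related by 120 degrees
  i1 <- which(ft$atoms$chain_id == "F1"); i2 <- which(ft$atoms$chain_id == "F2")
  expect_lt(rmsd(rt_apply(rt_axis_angle(c(0, 0, 1), 120), coords(ft, i1)),
                 coords(ft, i2)), 1e-6)
  # annotated tail residues 1-6 on every chain
  for (cid in names(ft$chains)) {
    expect_equal(as.numeric(ft$chains[[cid]]$domains$tail), c(1, 6))
  }
})

test_that("IgM forms: 10 Fab arms, gap, dome depth, planar flatness", {
  kit <- tkit()
  bent <- kit$igm_bent
  fabs <- names(bent$chains)[vapply(bent$chains, function(ch)
    ch$role == "igm_fab", logical(1))]
  expect_length(fabs, 10)
  # dlpsp markers: 2 per Fc unit, on the convex (upper) face
  dl <- select_atoms(bent, domain = "dlpsp")
  expect_length(dl, 10)
  expect_gt(min(bent$atoms$z[dl]), kit$spec$calib$igm$platform_z)
  # bent: tips in a common plane >= 30 A below the platform
  tips <- select_atoms(bent, domain = "fab_tip")
  expect_lt(diff(range(bent$atoms$z[tips])), 5)
  expect_gt(kit$spec$calib$igm$platform_z - max(bent$atoms$z[tips]), 30)
  # bent footprint fits on one facet
  expect_lt(2 * max(sqrt(bent$atoms$x[tips]^2 + bent$atoms$y[tips]^2)),
            kit$spec$facet_edge_length)
  # planar: tips within 10 A of the platform plane
  pl <- kit$igm_planar
  tp <- select_atoms(pl, domain = "fab_tip")
  expect_lt(max(abs(pl$atoms$z[tp] - pl$metadata$platform_z)), 10)
  expect_error(make_igm(tspec(), "folded"))
})

test_that("C1 has the C1q hexamer + C1r2s2 composition with one bent head", {
  c1 <- tkit()$c1
  roles <- vapply(c1$chains, function(ch) ch$role, character(1))
  expect_equal(sum(roles == "c1q"), 6)
  expect_equal(sum(roles == "c1r"), 2)
  expect_equal(sum(roles == "c1s"), 2)
  bent_up <- vapply(c1$chains, function(ch)
    "bent_upward" %in% ch$flags, logical(1))
  expect_equal(sum(bent_up), 1)
})

test_that("C3b/C4b anatomy: chain lengths, thioester domain and markers", {
  c3 <- tkit()$c3b
  nA <- sum(c3$atoms$chain_id == "A"); nB <- sum(c3$atoms$chain_id == "B")
  expect_gt(nA, nB)   # alpha longer than beta
  expect_equal(as.numeric(c3$chains$A$domains$thioester_domain), c(990, 1290))
  m <- select_atoms(c3, chain = "A", residues = c(1010, 1013))
  d <- sqrt(sum((coords(c3)[m[1], ] - coords(c3)[m[2], ])^2))
  expect_lt(d, 2 * 3.8)      # thioester pair within two bead spacings
  # reactive face at the model underside
  expect_lt(max(c3$atoms$z[m]), min(c3$atoms$z) + 8)
  # substrate interface patch centred on the +y face
  ifc <- select_atoms(c3, domain = "substrate_interface")
  expect_gt(mean(c3$atoms$y[ifc]), 8)
  c4 <- tkit()$c4b
  expect_equal(c4$chains$A$role, "c4b_alpha")
  expect_equal(as.numeric(c4$chains$A$domains$thioester_domain), c(990, 1290))
})

test_that("FX: compact GLA fits the hexon depression, protease protrudes", {
  kit <- tkit()
  fx <- kit$fx
  gla <- which(fx$atoms$chain_id == "G")
  expect_lt(max(sqrt(fx$atoms$x[gla]^2 + fx$atoms$y[gla]^2)), 8)
  # docked: protease extends > 20 A above the hexon top
  dock_z <- fx$metadata$dock_z
  prot <- which(fx$atoms$chain_id == "S")
  top <- kit$hexon$metadata$top_z
  expect_gt(max(fx$atoms$z[prot]) + dock_z - top, 20)
  # jitter deterministic in the seed
  j1 <- fx_jitter(tspec(), 7); j2 <- fx_jitter(tspec(), 7)
  expect_identical(j1, j2)
  j3 <- fx_jitter(fixture_spec(rng_seed = 2), 7)
  expect_false(identical(j1, j3))
  expect_lte(j1$tilt_deg, tspec()$calib$fx$tilt_max)
})

test_that("template set is internally consistent", {
  kit <- tkit()
  tpl <- kit$templates
  # C1 placed on the bent IgM by the template clashes with nothing
  c1m <- transform_model(kit$c1, tpl$igm_to_c1)
  expect_equal(nrow(detect_clashes(c1m, kit$igm_bent)), 0)
  # convertase-substrate offset: side-by-side, 40-120 A centroid shift
  off <- sqrt(sum(tpl$convertase_to_substrate$t^2))
  expect_gt(off, 40); expect_lt(off, 120)
  expect_gt(off, 0)
})

test_that("fixture kit writes and re-reads as a complete directory", {
  dir <- tempfile("kit")
  write_fixture_kit(dir, tspec())
  files <- list.files(dir)
  expect_true(all(c("hexon.pdb", "penton.pdb", "igm_bent.pdb", "c3b.pdb",
                    "fx.pdb", "manifest.json") %in% files))
  hx <- read_structure(file.path(dir, "hexon.pdb"))
  expect_equal(n_atoms(hx), n_atoms(tkit()$hexon))
})
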