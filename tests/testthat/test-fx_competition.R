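# FX occupancy of the facet and steric competition with IgM.

test_that("FX loads every hexon slot: 3 canonical, 15 jittered, clash-free", {
  facet <- tfacet()
  kit <- tkit()
  fx <- place_fx_all(facet, kit$fx, tspec())
  expect_length(fx, 18)
  expect_equal(sum(vapply(fx, function(p) p$canonical, logical(1))), 3)
  expect_equal(sum(vapply(fx, function(p) p$jittered, logical(1))), 15)
  # canonical copies sit on the three slots nearest the 3-fold axis
  can <- Filter(function(p) p$canonical, fx)
  lat <- facet$lattice
  r <- sqrt(lat$x^2 + lat$y^2)
  inner3 <- lat$slot_index[order(r)][1:3]
  expect_setequal(vapply(can, function(p) p$slot_index, numeric(1)), inner3)
  # determinism in the seed
  fx2 <- place_fx_all(facet, kit$fx, tspec())
  expect_identical(coords(fx[[7]]$model), coords(fx2[[7]]$model))
  fx3 <- place_fx_all(facet, kit$fx, fixture_spec(rng_seed = 9))
  expect_false(identical(coords(fx[[7]]$model), coords(fx3[[7]]$model)))
})

test_that("the FX-ablated facet refuses FX placement", {
  spec_mut <- fixture_spec(fx_binding_enabled = FALSE)
  kit <- tkit()
  facet_mut <- assemble_facet(make_hexon_trimer(spec_mut), kit$penton,
                              kit$fiber_template, spec_mut)
  expect_error(place_fx_all(facet_mut, kit$fx, spec_mut), "fx_ablated")
})

test_that("planar IgM on the FX-loaded facet: one pair down, FX layer intact", {
  facet <- tfacet()
  kit <- tkit()
  fx <- place_fx_all(facet, kit$fx, tspec())
  res <- compete(facet, fx, kit$igm_planar, igm_pose(1, 0, "planar"))
  expect_equal(res$contacts, 2)     # exactly one Fab pair in HVR1 contact
  expect_gte(length(res$retained_fx), 15)
  # partition: initial = removed + retained, disjoint
  ids <- function(l) vapply(l, function(p) p$slot_index, numeric(1))
  expect_setequal(c(ids(res$removed_fx), ids(res$retained_fx)),
                  ids(res$initial_fx))
  # every removed copy clashed; no retained copy does
  for (p in res$removed_fx) {
    expect_gt(nrow(detect_clashes(p$model, res$igm$model)), 0)
  }
  for (p in res$retained_fx) {
    expect_equal(nrow(detect_clashes(p$model, res$igm$model)), 0)
  }
})

test_that("bent IgM on the FX-loaded facet keeps DLPSP accessible", {
  facet <- tfacet()
  kit <- tkit()
  fx <- place_fx_all(facet, kit$fx, tspec())
  res <- compete(facet, fx, kit$igm_bent, igm_pose(1, 0))
  expect_gte(res$contacts, 8)
  expect_true(res$dlpsp_accessible)
  for (p in res$retained_fx) {
    expect_equal(nrow(detect_clashes(p$model, res$igm$model)), 0)
  }
  # on the bare facet, competition reduces to plain placement
  res0 <- compete(facet, list(), kit$igm_bent, igm_pose(1, 0))
  expect_length(res0$removed_fx, 0)
  plain <- place_igm(facet, kit$igm_bent, igm_pose(1, 0))
  expect_equal(coords(res0$igm$model), coords(plain$model))
})

test_that("a synthetic blocker over every DLPSP site kills accessibility", {
  facet <- tfacet()
  kit <- tkit()
  rec <- place_igm(facet, kit$igm_bent, igm_pose(1, 0))
  acc0 <- dlpsp_accessibility(facet, rec)
  expect_true(acc0$overall)
  expect_true(all(acc0$per_site))
  sites <- coords(rec$model, select_atoms(rec$model, domain = "dlpsp"))
  blockers <- molecular_model("blockers", data.frame(
    x = sites[, 1], y = sites[, 2], z = sites[, 3] + 15,
    vdw_radius = 10, residue_index = seq_len(nrow(sites)), chain_id = "Z"))
  acc1 <- dlpsp_accessibility(facet, rec, others = list(blockers))
  expect_false(acc1$overall)
})

test_that("deposition space shrinks under FX and vanishes under full cover", {
  facet <- tfacet()
  kit <- tkit()
  rec <- place_igm(facet, kit$igm_bent, igm_pose(1, 0))
  params <- propagation_params()
  free <- residual_deposition_space(facet, list(rec), kit$c3b, params,
                                    grid_spacing = 40)
  expect_gte(free, 3)   # at least room for the three C3b copies
  fx <- place_fx_all(facet, kit$fx, tspec())
  withfx <- residual_deposition_space(facet, c(list(rec), fx), kit$c3b,
                                      params, grid_spacing = 40)
  expect_lt(withfx, free)
  # blanket of giant blockers: no room at all
  ext <- max(abs(facet$vertices))
  gx <- as.matrix(expand.grid(x = seq(-ext, ext, by = 50),
                              y = seq(-ext, ext, by = 50)))
  blanket <- molecular_model("blanket", data.frame(
    x = gx[, 1], y = gx[, 2], z = facet$hexon_top_z + 25,
    vdw_radius = 40, residue_index = seq_len(nrow(gx)), chain_id = "Z"))
  none <- residual_deposition_space(facet, list(rec, blanket), kit$c3b,
                                    params, grid_spacing = 40)
  expect_equal(none, 0)
})
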