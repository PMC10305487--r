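# IgM pose placement, C1 gating, C4b feasibility, C3b propagation.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("bent IgM placement engages the Fab arms on HVR1 markers", {
  facet <- tfacet()
  kit <- tkit()
  rec <- place_igm(facet, kit$igm_bent, igm_pose(1, 0))
  expect_true(rec$placed)
  expect_gte(rec$contacts, 8)
  # tips rest just above the hexon tops
  tips_z <- coords(rec$model)[rec$tips_idx, 3]
  expect_lt(max(tips_z) - facet$hexon_top_z, 8)
  # no clash with the facet at rest
  expect_false(has_clash(facet$coords, coords(rec$model),
                         facet$radii, rec$model$atoms$vdw_radius))
  # rotating the pose by 360 degrees reproduces the 0-degree transform
  rec360 <- place_igm(facet, kit$igm_bent, igm_pose(1, 360))
  expect_equal(rec$transform$R, rec360$transform$R, tolerance = 1e-6)
  expect_equal(rec$transform$t, rec360$transform$t, tolerance = 1e-6)
})

test_that("all 16 bent poses pass the bent-conformation gate", {
  facet <- tfacet()
  kit <- tkit()
  for (p in all_igm_poses()) {
    rec <- place_igm(facet, kit$igm_bent, p)
    expect_gte(rec$contacts, 8)
  }
})

test_that("planar IgM contacts with exactly one Fab pair", {
  facet <- tfacet()
  kit <- tkit()
  rec <- place_igm(facet, kit$igm_planar, igm_pose(1, 0, "planar"))
  expect_equal(rec$contacts, 2)   # the designated pair only
  expect_true(all(which(rec$tip_dists <= 5) %in% 1:2))
})

test_that("C1 placement is gated by the bent conformation", {
  facet <- tfacet()
  kit <- tkit()
  bent <- place_igm(facet, kit$igm_bent, igm_pose(1, 0))
  c1 <- place_c1(bent, kit$c1, kit$templates)
  expect_true(c1$placed)
  expect_false(has_clash(coords(bent$model), coords(c1$model),
                         bent$model$atoms$vdw_radius,
                         c1$model$atoms$vdw_radius))
  planar <- place_igm(facet, kit$igm_planar, igm_pose(1, 0, "planar"))
  c1p <- place_c1(planar, kit$c1, kit$templates)
  expect_false(c1p$placed)
  expect_equal(c1p$reason, "dlpsp_unexposed")
})

test_that("C4b sites are evaluated for thioester feasibility", {
  facet <- tfacet()
  kit <- tkit()
  found_feasible <- FALSE
  found_infeasible <- FALSE
  for (p in all_igm_poses()) {
    rec <- place_igm(facet, kit$igm_bent, p)
    c1 <- place_c1(rec, kit$c1, kit$templates)
    c4 <- place_c4b(facet, c1, kit$c4b, kit$templates, rec)
    expect_length(c4, 2)
    for (r in c4) {
      if (r$feasible) {
        found_feasible <- TRUE
        th <- adcomplement:::.thioester_idx(r$model)
        d <- min(nearest_dist(coords(r$model, th), facet$coords, 20))
        expect_lte(d, propagation_params()$thioester_contact_max)
        expect_true(on_facet(facet,
          colMeans(coords(r$model, th))[1:2]))
      } else {
        found_infeasible <- TRUE
        expect_true(nzchar(r$reason))
      }
    }
  }
  expect_true(found_feasible)
  expect_true(found_infeasible)
  expect_error(place_c4b(facet, list(placed = FALSE), kit$c4b,
                         kit$templates, NULL), "C1")
})

test_that("C3b propagation respects caps, anchoring and clash freedom", {
  facet <- tfacet()
  kit <- tkit()
  params <- propagation_params()
  rec <- place_igm(facet, kit$igm_bent, igm_pose(2, 270))
  c1 <- place_c1(rec, kit$c1, kit$templates)
  c4 <- place_c4b(facet, c1, kit$c4b, kit$templates, rec)
  inv <- propagate_c3b(facet, list(pose = rec$pose, igm = rec, c1 = c1,
                                   c4b = c4), kit$c3b, kit$templates, params)
  expect_lte(length(inv$c3b), params$max_c3b_per_facet)
  placed_models <- c(list(rec$model, c1$model),
                     lapply(Filter(function(r) r$feasible, inv$c4b),
                            function(r) r$model),
                     lapply(inv$c3b, function(r) r$model))
  # no two placed molecules clash in the final configuration
  for (i in seq_along(placed_models)) for (j in seq_len(i - 1)) {
    expect_false(has_clash(coords(placed_models[[i]]),
                           coords(placed_models[[j]]),
                           placed_models[[i]]$atoms$vdw_radius,
                           placed_models[[j]]$atoms$vdw_radius))
  }
  for (r in inv$c3b) {
    # covalent anchoring: thioester in surface contact at binding
    expect_lte(r$thioester_dist, params$thioester_contact_max)
    expect_true(is.numeric(r$anchor_atom))
    # translation bounded
    expect_lte(r$translation_used, params$max_translation + params$step)
  }
  for (tr in inv$traces) {
    expect_true(tr$verdict %in% c("bound", "obstructed_infeasible",
                                  "off_facet", "max_copies"))
  }
  # no feasible C4b -> inventory unchanged, empty trace
  inv0 <- propagate_c3b(facet, list(pose = rec$pose, igm = rec, c1 = c1,
                                    c4b = list()), kit$c3b, kit$templates)
  expect_length(inv0$c3b, 0)
})

test_that("vertex occupancy counting is monotone in the radius", {
  facet <- tfacet()
  kit <- tkit()
  rec <- place_igm(facet, kit$igm_bent, igm_pose(2, 270))
  c1 <- place_c1(rec, kit$c1, kit$templates)
  c4 <- place_c4b(facet, c1, kit$c4b, kit$templates, rec)
  inv <- propagate_c3b(facet, list(pose = rec$pose, igm = rec, c1 = c1,
                                   c4b = c4), kit$c3b, kit$templates)
  expect_equal(count_vertex_c3b(list(c3b = list()), facet)$n_occupied, 0)
  radii <- c(30, 60, 120, 250)
  counts <- vapply(radii, function(vr) {
    count_vertex_c3b(inv, facet, propagation_params(vertex_radius = vr))$n_occupied
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("removing the fiber never shortens a propagation walk", {
  kit <- tkit()
  spec <- tspec()
  facet <- tfacet()
  # rebuild the facet without fibers
  lat <- facet$lattice
  keep <- !startsWith(facet$model$atoms$chain_id, "FB")
  nofib <- facet
  nofib$model <- model_subset(facet$model, which(keep))
  nofib$coords <- coords(nofib$model)
  nofib$radii <- nofib$model$atoms$vdw_radius
  nofib$hvr1_idx <- select_atoms(nofib$model, domain = "hvr1")
  walks <- function(fc) {
    rec <- place_igm(fc, kit$igm_bent, igm_pose(1, 270))
    c1 <- place_c1(rec, kit$c1, kit$templates)
    c4 <- place_c4b(fc, c1, kit$c4b, kit$templates, rec)
    inv <- propagate_c3b(fc, list(pose = rec$pose, igm = rec, c1 = c1,
                                  c4b = c4), kit$c3b, kit$templates)
    vapply(inv$traces, function(t) as.numeric(t$t_reach %||% t$translation_used), numeric(1))
  }
  w_with <- walks(facet)
  w_without <- walks(nofib)
  n <- min(length(w_with), length(w_without))
  if (n >= 1) {
    expect_true(all(w_without[seq_len(n)] >= w_with[seq_len(n)] - 1e-9))
  }
})

test_that("pose enumeration yields 16 deterministic rows", {
  facet <- tfacet()
  kit <- tkit()
  en <- enumerate_poses(facet, kit)
  expect_equal(nrow(en$summary), 16)
  expect_equal(en$summary$pose_hexon, rep(1:4, each = 4))
  expect_equal(en$summary$pose_rot, rep(c(0, 90, 180, 270), 4))
  en2 <- enumerate_poses(facet, kit)
  expect_identical(en$summary, en2$summary)
})

test_that("only one stable bent IgM fits the facet; a relatively larger facet fits two", {
  kit <- tkit()
  expect_equal(max_igm_per_facet(tfacet(), kit$igm_bent), 1)
  # doubling the facet-to-IgM size ratio (half-size IgM on the same facet)
  # makes room for at least two stable bent placements
  sp_small <- fixture_spec()
  sp_small$calib$igm$tip_r <- sp_small$calib$igm$tip_r / 2
  sp_small$calib$igm$platform_r <- sp_small$calib$igm$platform_r / 2
  igm_small <- make_igm(sp_small, "bent")
  expect_gte(max_igm_per_facet(tfacet(), igm_small), 2)
})
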