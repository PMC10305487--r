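# Factor X occupancy of the facet and steric competition with IgM. FX "wins"
# binding kinetics (picomolar hexon affinity), so the facet is loaded first;
# an arriving IgM is then placed with FX clash-checking deferred, and every
# FX copy clashing with the final IgM position is removed — reproducing the
# modeled order of operations.

#' Place one FX on every hexon trimer of the facet
#'
#' The three hexon slots adjacent to the central three-fold axis receive the
#' canonical (unjittered) docking frame, matching the well-resolved density
#' there; the remaining fifteen receive a seeded orientation jitter (uniform
#' spin about the hexon axis plus a bounded tilt) standing in for FX domain
#' flexibility. Placements are verified clash-free against the capsid and
#' each other.
#'
#' @param facet a `FacetModel`.
#' @param fx FX model from [make_fx()].
#' @param spec a `FixtureSpec` (jitter seed and tilt bound).
#' @param seed optional seed overriding `spec$rng_seed`.
#' @return list of placements: `slot_index`, `transform`, `model`,
#'   `jittered`, `canonical`.
#' @export
place_fx_all <- function(facet, fx, spec = facet$spec, seed = NULL) {
  lat <- facet$lattice
  hexons <- lat[lat$kind == "hexon", , drop = FALSE]
  proto <- facet$prototype$hexon
  if (length(select_atoms(proto, domain = "fx_site")) == 0) {
    stop("fx_ablated: facet hexons carry no FX-binding site (T425A stand-in)")
  }
  if (!is.null(seed)) spec$rng_seed <- as.integer(seed)
  r <- sqrt(hexons$x^2 + hexons$y^2)
  canonical <- rank(r, ties.method = "first") <= 3   # nearest the 3-fold axis
  dock_z <- fx$metadata$dock_z
  out <- list()
  for (i in seq_len(nrow(hexons))) {
    tf <- rt_translation(c(hexons$x[i], hexons$y[i], dock_z))
    if (!canonical[i]) {
      j <- fx_jitter(spec, hexons$slot_index[i])
      tilt_ax <- c(cos(j$tilt_az_deg * pi / 180),
                   sin(j$tilt_az_deg * pi / 180), 0)
      jit <- rt_compose(rt_axis_angle(tilt_ax, j$tilt_deg),
                        rt_axis_angle(c(0, 0, 1), j$spin_deg))
      tf <- rt_compose(tf, jit)
    }
    m <- transform_model(fx, tf)
    m$name <- sprintf("FX%02d", hexons$slot_index[i])
    out[[length(out) + 1]] <- list(slot_index = hexons$slot_index[i],
                                   transform = tf, model = m,
                                   jittered = !canonical[i],
                                   canonical = canonical[i])
  }
  # verify: no FX-capsid or FX-FX clashes
  for (i in seq_along(out)) {
    xi <- coords(out[[i]]$model)
    ri <- out[[i]]$model$atoms$vdw_radius
    env_idx <- .facet_near(facet, colMeans(xi)[1:2], 60)
    if (has_clash(facet$coords[env_idx, , drop = FALSE], xi,
                  facet$radii[env_idx], ri)) {
      stop("FX placement clashes with capsid at slot ", out[[i]]$slot_index)
    }
    for (j in seq_len(i - 1)) {
      if (sqrt(sum((colMeans(xi) - colMeans(coords(out[[j]]$model)))^2)) > 90) next
      if (has_clash(coords(out[[j]]$model), xi,
                    out[[j]]$model$atoms$vdw_radius, ri)) {
        stop("FX-FX clash between slots ", out[[j]]$slot_index, " and ",
             out[[i]]$slot_index)
      }
    }
  }
  out
}

#' Compete an incoming IgM against a FX-loaded facet
#'
#' The IgM is placed exactly as on a bare facet (FX clash checking deferred:
#' the multivalent IgM displaces locally), then every FX copy clashing with
#' the final IgM position is removed and listed. For the planar conformation
#' only the designated (slightly reaching) Fab pair contacts the anchor
#' hexon; the platform stays parallel to the facet. The contact report and
#' DLPSP accessibility are computed on the final configuration.
#'
#' @param facet a `FacetModel`.
#' @param fx_placements result of [place_fx_all()] (may be empty list for
#'   the FX-ablated facet).
#' @param igm IgM model matching `pose$conformation`.
#' @param pose an `IgMPose`.
#' @return `CompetitionResult`: `igm` placement, `initial_fx`, `removed_fx`,
#'   `retained_fx`, `contacts`, `dlpsp_accessible`.
#' @export
compete <- function(facet, fx_placements, igm, pose) {
  rec <- place_igm(facet, igm, pose)
  xi <- coords(rec$model)
  ri <- rec$model$atoms$vdw_radius
  removed <- list(); retained <- list()
  for (p in fx_placements) {
    cl <- detect_clashes(p$model, rec$model)
    if (nrow(cl) > 0) {
      p$clash_partner <- rec$model$name
      removed[[length(removed) + 1]] <- p
    } else {
      retained[[length(retained) + 1]] <- p
    }
  }
  acc <- dlpsp_accessibility(facet, rec, retained)
  res <- list(igm = rec, pose = pose,
              initial_fx = fx_placements, removed_fx = removed,
              retained_fx = retained, contacts = rec$contacts,
              dlpsp_sites = acc$per_site, dlpsp_accessible = acc$overall)
  class(res) <- "CompetitionResult"
  res
}

#' DLPSP accessibility of a placed IgM
#'
#' A DLPSP site (C1q-binding motif on the Fc convex face) is accessible when
#' a probe sphere centred `probe_radius` above the site along the outward
#' normal contains no non-IgM atom. The IgM is overall accessible when at
#' least `min_sites` of its marker sites are free — enough for engagement of
#' the hexavalent C1q head arrangement.
#'
#' @param facet a `FacetModel`.
#' @param igm_placement record from [place_igm()].
#' @param others other placed molecules to test against (e.g. retained FX
#'   placements or blocker models); facet atoms are always included.
#' @param probe_radius probe sphere radius, Angstrom.
#' @param min_sites sites required for overall accessibility.
#' @return list with `per_site` (logical) and `overall`.
#' @export
dlpsp_accessibility <- function(facet, igm_placement, others = list(),
                                probe_radius = 15, min_sites = 5) {
  m <- igm_placement$model
  idx <- select_atoms(m, domain = "dlpsp")
  sites <- coords(m, idx)
  centres <- sites
  centres[, 3] <- centres[, 3] + probe_radius
  obst <- facet$coords
  for (o in others) {
    om <- if (!is.null(o$model)) o$model else o
    obst <- rbind(obst, coords(om))
  }
  dmin <- nearest_dist(centres, obst, probe_radius + 5)
  per_site <- dmin > probe_radius
  list(per_site = per_site, overall = sum(per_site) >= min_sites)
}

#' Residual deposition space on the facet
#'
#' Scans a deterministic grid of candidate anchor points (spacing
#' `grid_spacing`) over the facet, counting points where the given molecule
#' (C4b or C3b) can be oriented clash-free with its thioester in surface
#' contact — the same orientation search as the propagation step. The count
#' measures how much room remains for complement deposition in a given
#' configuration.
#'
#' @param facet a `FacetModel`.
#' @param placed list of placed molecules (IgM, FX, blockers...); each item
#'   a placement record with `$model` or a bare model.
#' @param mol the molecule to test (C4b or C3b model).
#' @param params a `PropagationParams`.
#' @param grid_spacing candidate grid spacing, Angstrom.
#' @return integer count of feasible deposition sites.
#' @export
residual_deposition_space <- function(facet, placed, mol,
                                      params = propagation_params(),
                                      grid_spacing = 20) {
  ext <- max(abs(facet$vertices)) + 20
  xs <- seq(-ext, ext, by = grid_spacing)
  env_extra <- do.call(rbind, lapply(placed, function(o) {
    om <- if (!is.null(o$model)) o$model else o
    coords(om)
  }))
  env_radii <- unlist(lapply(placed, function(o) {
    om <- if (!is.null(o$model)) o$model else o
    om$atoms$vdw_radius
  }))
  grid <- .orientation_grid(params$orientation_grid)
  th_loc <- .thioester_idx(mol)
  base <- coords(mol)
  rb <- mol$atoms$vdw_radius
  top_z <- facet$hexon_top_z
  count <- 0
  for (x in xs) for (y in xs) {
    if (!on_facet(facet, c(x, y))) next
    # drop the molecule at this grid point, thioester face down
    shift <- c(x, y, top_z + 2) - c(colMeans(base[th_loc, , drop = FALSE])[1:2],
                                    min(base[, 3]))
    cand0 <- sweep(base, 2, shift, "+")
    env_idx <- .facet_near(facet, c(x, y), 70)
    env <- list(coords = rbind(facet$coords[env_idx, , drop = FALSE],
                               env_extra),
                radii = c(facet$radii[env_idx], env_radii))
    ok <- FALSE
    for (g in seq_len(min(nrow(grid), 18))) {
      cand <- .rotate_about_centroid(cand0, grid$tx[g], grid$ty[g],
                                     grid$rz[g])
      thd <- min(nearest_dist(cand[th_loc, , drop = FALSE], facet$coords,
                              params$thioester_contact_max + 6))
      if (thd > params$thioester_contact_max) next
      if (!is.null(.env_clash(env, cand, rb))) next
      ok <- TRUE
      break
    }
    if (ok) count <- count + 1
  }
  count
}
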