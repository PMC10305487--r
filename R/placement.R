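# IgM pose enumeration and complement placement. All placements live in the
# facet frame (z = 0 plane, +z outward). The bent IgM is lowered along -z to
# its deepest clash-free position; C1 and C4b follow stored template
# transforms gated by the bent-conformation contact rule; C3b propagates by
# the convertase-substrate walk (template placement, in-plane translation
# toward/past the facet centroid, discrete orientation search, covalent
# thioester anchoring).

#' IgM pose descriptor
#'
#' @param anchor_hexon asymmetric-unit hexon label, 1-4.
#' @param rotation_deg rotation about the Fc-platform axis: 0, 90, 180, 270.
#' @param conformation `"bent"` or `"planar"`.
#' @return object of class `IgMPose`.
#' @export
igm_pose <- function(anchor_hexon, rotation_deg = 0,
                     conformation = c("bent", "planar")) {
  conformation <- match.arg(conformation)
  stopifnot(anchor_hexon %in% 1:4, rotation_deg %% 90 == 0)
  structure(list(anchor_hexon = as.integer(anchor_hexon),
                 rotation_deg = rotation_deg %% 360,
                 conformation = conformation), class = "IgMPose")
}

#' All 16 bent IgM poses
#' @return list of `IgMPose` (hexon-major, rotation-minor order).
#' @export
all_igm_poses <- function() {
  out <- list()
  for (h in 1:4) for (r in c(0, 90, 180, 270)) {
    out[[length(out) + 1]] <- igm_pose(h, r, "bent")
  }
  out
}

#' C3b propagation parameters
#'
#' @param max_translation maximum substrate translation from its activation
#'   site, Angstrom (the reactive C3b lifetime of ~60 microseconds limits
#'   diffusion to roughly this range).
#' @param max_c3b_per_facet cap on bound C3b per facet (stands in for
#'   negative regulation of the amplification loop).
#' @param step translation step, Angstrom.
#' @param orientation_grid orientation search step, degrees.
#' @param thioester_contact_max maximum thioester-to-surface distance for a
#'   feasible covalent binding pose, Angstrom.
#' @param vertex_radius distance from a penton centroid within which a bound
#'   C3b counts as occupying that vertex, Angstrom.
#' @return object of class `PropagationParams`.
#' @export
#' @param direction translation-direction rule: `"interface_ray"` (default)
#'   translates the substrate straight on, away from its convertase along
#'   the in-plane component of the convertase-to-substrate direction;
#'   `"centroid_ray"` translates along the anchor-to-facet-centroid ray,
#'   continuing across the centroid.
propagation_params <- function(max_translation = 300, max_c3b_per_facet = 3,
                               step = 5, orientation_grid = 30,
                               thioester_contact_max = 8, vertex_radius = 60,
                               direction = c("interface_ray", "centroid_ray")) {
  direction <- match.arg(direction)
  stopifnot(max_translation > 0, max_c3b_per_facet >= 1, step > 0,
            orientation_grid > 0, thioester_contact_max > 0, vertex_radius > 0)
  structure(list(max_translation = max_translation,
                 max_c3b_per_facet = max_c3b_per_facet, step = step,
                 orientation_grid = orientation_grid,
                 thioester_contact_max = thioester_contact_max,
                 vertex_radius = vertex_radius,
                 direction = direction), class = "PropagationParams")
}

# ---- internal helpers --------------------------------------------------------

# facet atoms near an xy disc (cheap pre-filter for clash queries)
.facet_near <- function(facet, xy, radius) {
  d2 <- (facet$coords[, 1] - xy[1])^2 + (facet$coords[, 2] - xy[2])^2
  which(d2 <= radius^2)
}

.placed_env <- function(placed) {
  if (length(placed) == 0) {
    return(list(coords = matrix(0, 0, 3), radii = numeric(),
                labels = character()))
  }
  list(coords = do.call(rbind, lapply(placed, function(p) p$coords)),
       radii = unlist(lapply(placed, function(p) p$radii)),
       labels = unlist(lapply(placed, function(p)
         rep(p$name, nrow(p$coords)))))
}

.as_placed <- function(name, model) {
  list(name = name, model = model, coords = coords(model),
       radii = model$atoms$vdw_radius)
}

# clash of coords xb (with radii rb) against an environment; returns first
# clashing environment label or NULL
.env_clash <- function(env, xb, rb, params = clash_params()) {
  if (nrow(env$coords) == 0 || nrow(xb) == 0) return(NULL)
  res <- .cpp_clash_pairs(env$coords, env$radii, xb, rb,
                          params$overlap_tolerance, params$hard_cutoff,
                          params$use_vdw_radii, TRUE)
  if (length(res$i) == 0) return(NULL)
  if (is.null(env$labels)) "env" else env$labels[res$i[1]]
}

# ---- IgM placement -----------------------------------------------------------

#' Place an IgM on the facet
#'
#' The designated Fab-arm pair (the pair counterclockwise from the Fc gap)
#' is centred over the anchor hexon's HVR1 markers at rotation 0; the pose
#' rotation is applied about the Fc-platform central axis (IgM centre fixed,
#' normal to the facet). The molecule is lowered along -z to its deepest
#' clash-free position and must make at least one Fab-tip/HVR1 contact
#' (tip within 5 A of a marker bead); the returned record reports how many
#' of the ten tips are in contact.
#'
#' @param facet a `FacetModel`.
#' @param igm IgM model from [make_igm()] matching `pose$conformation`.
#' @param pose an `IgMPose`.
#' @param extra_env optional additional placed molecules to avoid (list of
#'   placed records) — used when stacking placements.
#' @param anchor_xy optional explicit anchor point (overrides the pose's
#'   asymmetric-unit slot; used for edge-extension anchors).
#' @return placement record: `transform`, `model` (placed), `contacts`,
#'   `tip_dists`, `centre`, `placed = TRUE`.
#' @export
place_igm <- function(facet, igm, pose, extra_env = list(), anchor_xy = NULL) {
  spec <- facet$spec
  if (!identical(igm$metadata$conformation, pose$conformation)) {
    stop("IgM model conformation does not match the pose")
  }
  if (is.null(anchor_xy)) {
    lat <- facet$lattice
    slot <- lat[lat$label == as.character(pose$anchor_hexon) &
                lat$sector == 0, , drop = FALSE]
    if (nrow(slot) != 1) stop("anchor hexon label not found: ", pose$anchor_hexon)
    anchor_xy <- c(slot$x, slot$y)
  }
  a0 <- spec$calib$anchor_offset_az * pi / 180

  # designated pair midpoint in the IgM local frame
  tips_idx <- vapply(paste0("FAB", 1:10), function(cid) {
    max(select_atoms(igm, chain = cid, domain = "fab_tip"))
  }, integer(1))
  pair_mid <- colMeans(coords(igm, tips_idx[1:2]))
  r_pair <- sqrt(sum(pair_mid[1:2]^2))
  az_pair <- atan2(pair_mid[2], pair_mid[1])

  centre <- c(anchor_xy - r_pair * c(cos(a0), sin(a0)), 0)
  rot <- rt_axis_angle(c(0, 0, 1),
                       (a0 - az_pair) * 180 / pi + pose$rotation_deg)
  # place at a provisional height, then descend
  env_idx <- .facet_near(facet, centre[1:2],
                         igm$metadata$tip_r + spec$calib$igm$platform_r + 60)
  env <- list(coords = facet$coords[env_idx, , drop = FALSE],
              radii = facet$radii[env_idx],
              labels = facet$model$atoms$chain_id[env_idx])
  if (length(extra_env)) {
    ex <- .placed_env(extra_env)
    env$coords <- rbind(env$coords, ex$coords)
    env$radii <- c(env$radii, ex$radii)
    env$labels <- c(env$labels, ex$labels)
  }
  base_tf <- rt_compose(rt_translation(centre), rot)
  xyz0 <- rt_apply(base_tf, coords(igm))
  rb <- igm$atoms$vdw_radius
  # only environment beads vertically in the descent path can block it
  if (nrow(env$coords) > 0) {
    xy_env <- cbind(env$coords[, 1:2], 0)
    xy_igm <- cbind(xyz0[, 1:2], 0)
    keep <- .cpp_nearest_dist(xy_env, xy_igm, 4.0) <= 4.0
    env <- list(coords = env$coords[keep, , drop = FALSE],
                radii = env$radii[keep], labels = env$labels[keep])
  }
  top_z <- if (nrow(env$coords)) max(env$coords[, 3]) else 0
  z_start <- top_z + 6 - min(xyz0[, 3])
  # descend coarse-to-fine to the deepest clash-free height
  drop <- 0
  for (stp in c(4, 1, 0.25)) {
    repeat {
      cand <- xyz0
      cand[, 3] <- cand[, 3] + z_start - (drop + stp)
      if (!is.null(.env_clash(env, cand, rb))) break
      drop <- drop + stp
      if (drop > z_start + 80) break
    }
  }
  tf <- rt_compose(rt_translation(c(0, 0, z_start - drop)), base_tf)
  placed_xyz <- rt_apply(tf, coords(igm))
  hvr1 <- facet$coords[facet$hvr1_idx, , drop = FALSE]
  tip_dists <- nearest_dist(placed_xyz[tips_idx, , drop = FALSE], hvr1, 30)
  contacts <- sum(tip_dists <= 5)
  # contacts on this facet's own (canonical) hexons: the edge-extension
  # trimers belong to the neighbouring facets across the capsid fold
  hvr1_can <- facet$coords[facet$hvr1_idx_canonical, , drop = FALSE]
  contacts_facet <- sum(nearest_dist(placed_xyz[tips_idx, , drop = FALSE],
                                     hvr1_can, 30) <= 5)
  if (contacts < 1) {
    stop("IgM pose unreachable: no Fab-tip/HVR1 contact at the resting ",
         "height (min tip distance ", round(min(tip_dists), 1), " A)")
  }
  model <- set_coords(igm, placed_xyz)
  model$name <- sprintf("igm_%s_h%d_r%d", pose$conformation,
                        pose$anchor_hexon, pose$rotation_deg)
  list(molecule = "igm", pose = pose, transform = tf, model = model,
       centre = rt_apply(tf, c(0, 0, 0)), contacts = contacts,
       contacts_facet = contacts_facet,
       tip_dists = tip_dists, tips_idx = tips_idx, placed = TRUE)
}

#' Maximum number of stable bent IgM placements on a facet
#'
#' Greedily adds bent IgM placements over the 16 asymmetric-unit poses plus
#' the six edge-extension anchors. A placement counts only when it is
#' clash-free against everything already placed *and* achieves the
#' bent-conformation contact gate: at least `min_contacts` of the 10 Fab
#' tips on HVR1 markers (a bent IgM that cannot engage most of its arms
#' would not hold the dome conformation) with at least `min_facet_contacts`
#' of them on this facet's own hexons (an IgM straddling the capsid fold
#' onto the neighbouring facets' trimers cannot form the flat-footed dome).
#'
#' @param facet a `FacetModel`.
#' @param igm bent IgM model.
#' @param min_contacts total contact gate (default 8 of 10).
#' @param min_facet_contacts contacts required on canonical facet hexons
#'   (default 5: most of the multivalent attachment from the bound facet).
#' @return integer: maximum bent IgM count achieved.
#' @export
max_igm_per_facet <- function(facet, igm, min_contacts = 8,
                              min_facet_contacts = 5) {
  lat <- facet$lattice
  cands <- list()
  for (h in 1:4) for (r in c(0, 90, 180, 270)) {
    cands[[length(cands) + 1]] <- list(pose = igm_pose(h, r, "bent"),
                                       anchor_xy = NULL)
  }
  edges <- lat[lat$label == "edge", , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    cands[[length(cands) + 1]] <- list(pose = igm_pose(1, 0, "bent"),
                                       anchor_xy = c(edges$x[i], edges$y[i]))
  }
  placed <- list()
  for (cd in cands) {
    rec <- tryCatch(
      place_igm(facet, igm, cd$pose, extra_env = placed,
                anchor_xy = cd$anchor_xy),
      error = function(e) NULL)
    if (is.null(rec) || rec$contacts < min_contacts ||
        rec$contacts_facet < min_facet_contacts) next
    placed[[length(placed) + 1]] <- .as_placed(rec$model$name, rec$model)
  }
  length(placed)
}

# ---- C1 ----------------------------------------------------------------------

#' Place the C1 complex on a bound IgM
#'
#' C1 binds only when the DLPSP motifs are exposed: the IgM must be in the
#' bent conformation with at least `min_contacts` Fab tips engaged (the
#' dome forms only under multivalent attachment). A planar IgM, or a bent
#' pose short of the gate, returns a refusal with reason `dlpsp_unexposed`.
#'
#' @param igm_placement record from [place_igm()].
#' @param c1 C1 model from [make_c1()].
#' @param templates a `ComplexTemplateSet`.
#' @param min_contacts bent-conformation gate (default 8).
#' @return placement record (`placed`, `reason`, `transform`, `model`).
#' @export
place_c1 <- function(igm_placement, c1, templates, min_contacts = 8) {
  pose <- igm_placement$pose
  if (pose$conformation != "bent" || igm_placement$contacts < min_contacts) {
    return(list(molecule = "c1", placed = FALSE, reason = "dlpsp_unexposed"))
  }
  tf <- rt_compose(igm_placement$transform, templates$igm_to_c1)
  model <- transform_model(c1, tf)
  model$name <- "c1"
  list(molecule = "c1", placed = TRUE, transform = tf, model = model)
}

# ---- C4b ---------------------------------------------------------------------

.thioester_idx <- function(model) select_atoms(model, chain = "A",
                                               residues = c(1010, 1013))
.ted_idx <- function(model) select_atoms(model, chain = "A",
                                         domain = "thioester_domain")
.iface_idx <- function(model) select_atoms(model, chain = "A",
                                           domain = "substrate_interface")

#' Place C4b at the two template sites flanking the bound IgM
#'
#' Each site is evaluated for thioester feasibility: the reactive thioester
#' must be able to contact the facet surface (marker within
#' `thioester_contact_max` of a surface bead), its in-plane projection must
#' lie over the facet (edge-extension hexons count as surface; beyond them
#' does not), and the pose must be clash-free. Infeasible sites are recorded
#' with a reason, not dropped.
#'
#' @param facet a `FacetModel`.
#' @param c1_placement record from [place_c1()] (C1 must be placed).
#' @param c4b C4b model.
#' @param templates a `ComplexTemplateSet`.
#' @param igm_placement the IgM placement the templates are relative to.
#' @param params a `PropagationParams`.
#' @return list of two site records: `site`, `transform`, `model`,
#'   `feasible`, `reason`.
#' @export
place_c4b <- function(facet, c1_placement, c4b, templates, igm_placement,
                      params = propagation_params()) {
  if (!isTRUE(c1_placement$placed)) stop("C1 must be placed before C4b")
  placed_env <- list(.as_placed("igm", igm_placement$model),
                     .as_placed("c1", c1_placement$model))
  out <- list()
  for (s in 1:2) {
    site_tf <- templates[[paste0("igm_to_c4b_site", s)]]
    tf <- rt_compose(igm_placement$transform, site_tf)
    model <- transform_model(c4b, tf)
    model$name <- paste0("c4b_", s)
    th <- .thioester_idx(model)
    thxy <- colMeans(coords(model, th))[1:2]
    rec <- list(molecule = "c4b", site = s, transform = tf, model = model,
                feasible = FALSE, reason = "")
    if (!on_facet(facet, thxy)) {
      rec$reason <- "off_facet"
    } else {
      dmin <- min(nearest_dist(coords(model, th), facet$coords,
                               params$thioester_contact_max + 10))
      if (dmin > params$thioester_contact_max) {
        rec$reason <- "thioester_far"
      } else {
        env_idx <- .facet_near(facet, colMeans(coords(model))[1:2], 80)
        env <- list(coords = rbind(facet$coords[env_idx, , drop = FALSE],
                                   .placed_env(placed_env)$coords),
                    radii = c(facet$radii[env_idx],
                              .placed_env(placed_env)$radii))
        blk <- .env_clash(env, coords(model), model$atoms$vdw_radius)
        if (!is.null(blk)) {
          rec$reason <- "clash"
        } else {
          rec$feasible <- TRUE
          rec$reason <- "bound"
        }
      }
    }
    out[[s]] <- rec
  }
  out
}

# ---- C3b propagation ---------------------------------------------------------

# orientation grid (degrees): identity-first deterministic order
.orientation_grid <- function(step = 30, tilt_max = 30) {
  tilts <- unique(c(0, seq(step, tilt_max, by = step)))
  tilts <- unlist(lapply(tilts, function(t) if (t == 0) 0 else c(t, -t)))
  grid <- expand.grid(rz = seq(0, 359, by = step), ty = tilts, tx = tilts)
  grid[order(abs(grid$tx), abs(grid$ty), grid$rz), c("tx", "ty", "rz")]
}

# rotate a model about its own centroid
.rotate_about_centroid <- function(xyz, tx, ty, rz) {
  cen <- colMeans(xyz)
  tf <- rt_compose(rt_axis_angle(c(1, 0, 0), tx, cen),
        rt_compose(rt_axis_angle(c(0, 1, 0), ty, cen),
                   rt_axis_angle(c(0, 0, 1), rz, cen)))
  rt_apply(tf, xyz)
}

#' Propagate C3b onto the facet by the convertase-substrate walk
#'
#' For each feasible convertase anchor (first the bound C4b copies, then
#' each newly bound C3b), an incoming substrate is placed by the stored
#' convertase-to-substrate template. If the template start position projects
#' beyond the facet, or clashes in every orientation of the discrete grid,
#' the anchor recruits nothing. Otherwise the substrate is translated in the
#' facet plane along the anchor-to-centroid ray (continuing across the
#' centroid) in `step` increments until a clash, the facet boundary, or
#' `max_translation`; at the stopping point a discrete orientation search
#' looks for a clash-free pose with the thioester within reach of the
#' surface and the substrate interface unobstructed. Success binds the C3b
#' covalently (anchor bead recorded); every walk is traced.
#'
#' @param facet a `FacetModel`.
#' @param inventory inventory list carrying `igm`, `c1`, `c4b` entries (see
#'   [enumerate_poses()]).
#' @param c3b C3b model.
#' @param templates a `ComplexTemplateSet`.
#' @param params a `PropagationParams`.
#' @return the inventory with `c3b` placements and `traces` appended.
#' @export
propagate_c3b <- function(facet, inventory, c3b, templates,
                          params = propagation_params()) {
  inventory$c3b <- list()
  inventory$traces <- list()
  feas <- Filter(function(r) isTRUE(r$feasible), inventory$c4b)
  if (length(feas) == 0) return(inventory)

  placed <- list(.as_placed("igm", inventory$igm$model))
  if (isTRUE(inventory$c1$placed)) {
    placed <- c(placed, list(.as_placed("c1", inventory$c1$model)))
  }
  for (r in inventory$c4b) {
    if (isTRUE(r$feasible)) {
      placed <- c(placed, list(.as_placed(r$model$name, r$model)))
    }
  }

  queue <- lapply(feas, function(r) list(model = r$model,
                                         name = r$model$name,
                                         rot = r$transform$R))
  qi <- 1
  while (qi <= length(queue) &&
         length(inventory$c3b) < params$max_c3b_per_facet) {
    anchor <- queue[[qi]]
    qi <- qi + 1
    res <- .recruit_one(facet, anchor, placed, c3b, templates, params)
    inventory$traces[[length(inventory$traces) + 1]] <- res$trace
    if (!is.null(res$record)) {
      inventory$c3b[[length(inventory$c3b) + 1]] <- res$record
      placed <- c(placed, list(.as_placed(res$record$model$name,
                                          res$record$model)))
      queue[[length(queue) + 1]] <- list(model = res$record$model,
                                         name = res$record$model$name,
                                         rot = res$record$rotation)
    }
  }
  if (length(inventory$c3b) >= params$max_c3b_per_facet && qi <= length(queue)) {
    inventory$traces[[length(inventory$traces) + 1]] <-
      list(anchor = queue[[qi]]$name, verdict = "max_copies", steps = 0,
           translation_used = 0)
  }
  inventory
}

# attempt one recruitment from a bound convertase anchor
.recruit_one <- function(facet, anchor, placed, c3b, templates, params) {
  anchor_cen <- model_centroid(anchor$model)
  # the substrate-interface direction is the anchor's local +y (the face
  # where the incoming C3 binds), carried by the bound orientation
  iface_dir <- as.numeric(anchor$rot %*% c(0, 1, 0))
  iface_dir <- c(iface_dir[1:2] / max(sqrt(sum(iface_dir[1:2]^2)), 1e-9), 0)
  # template start: translate along the anchor's substrate-interface,
  # in the facet plane (the substrate diffuses above the surface)
  offset <- templates$convertase_to_substrate$t
  start_cen_shift <- sqrt(sum(offset^2)) * iface_dir
  # substrate initially in the anchor's orientation
  anchor_rot <- anchor$rot
  tf0 <- rigid_transform(anchor_rot,
                         anchor_cen + start_cen_shift -
                           as.numeric(anchor_rot %*% model_centroid(c3b)))
  xyz0 <- rt_apply(tf0, coords(c3b))
  rb <- c3b$atoms$vdw_radius
  trace <- list(anchor = anchor$name, steps = 0, translation_used = 0)

  start_xy <- colMeans(xyz0)[1:2]
  if (!on_facet(facet, start_xy)) {
    trace$verdict <- "off_facet"
    return(list(record = NULL, trace = trace))
  }
  # initial walk direction: either straight on away from the convertase
  # (the in-plane component of the convertase-to-substrate direction) or
  # along the anchor-to-facet-centroid ray continued across the centroid
  dxy <- if (identical(params$direction, "centroid_ray")) {
    c(-anchor_cen[1], -anchor_cen[2])
  } else {
    iface_dir[1:2]
  }
  ndl <- sqrt(sum(dxy^2))
  dxy <- if (ndl < 1e-6) c(1, 0) else dxy / ndl
  penv <- .placed_env(placed)
  env <- list(coords = rbind(facet$coords, penv$coords),
              radii = c(facet$radii, penv$radii),
              labels = c(facet$model$atoms$chain_id, penv$labels))
  grid <- .orientation_grid(params$orientation_grid)
  # the substrate diffuses above the capsid surface: raise it to clearance
  # height for the walk (thioester re-approaches the surface at binding)
  top_z <- facet$hexon_top_z
  lift <- max(0, top_z + 3.5 - min(xyz0[, 3]))
  xyz0[, 3] <- xyz0[, 3] + lift
  xyz_start <- NULL
  for (g in seq_len(nrow(grid))) {
    cand <- if (g == 1 && all(grid[1, ] == 0)) xyz0 else
      .rotate_about_centroid(xyz0, grid$tx[g], grid$ty[g], grid$rz[g])
    if (is.null(.env_clash(env, cand, rb))) { xyz_start <- cand; break }
  }
  if (is.null(xyz_start)) {
    trace$verdict <- "obstructed_infeasible"
    return(list(record = NULL, trace = trace))
  }

  # The reactive C3b stays over the facet while it diffuses: when the path
  # would leave the deposition surface it deflects off the facet boundary
  # (billiard reflection off the dilated triangle) and continues, up to
  # max_translation of total path length or a molecular obstruction.
  t_ok <- 0
  blocker <- NULL
  steps <- 0
  path <- list(matrix(0, 1, 3))        # cumulative displacements
  disp <- c(0, 0, 0)
  d2d <- dxy
  n_steps_max <- floor(params$max_translation / params$step)
  for (k in seq_len(n_steps_max)) {
    stp <- c(d2d * params$step, 0)
    cand_disp <- disp + stp
    cen_xy <- colMeans(xyz_start)[1:2] + cand_disp[1:2]
    if (!on_facet(facet, cen_xy)) {
      # reflect off the violated boundary edge(s)
      refl <- .reflect_direction(facet, colMeans(xyz_start)[1:2] + disp[1:2],
                                 d2d, params$step)
      if (is.null(refl)) { blocker <- "facet_boundary"; break }
      d2d <- refl
      stp <- c(d2d * params$step, 0)
      cand_disp <- disp + stp
      cen_xy <- colMeans(xyz_start)[1:2] + cand_disp[1:2]
      if (!on_facet(facet, cen_xy)) { blocker <- "facet_boundary"; break }
    }
    cand <- sweep(xyz_start, 2, cand_disp, "+")
    steps <- steps + 1
    blk <- .env_clash(env, cand, rb)
    if (!is.null(blk)) { blocker <- blk; break }
    disp <- cand_disp
    t_ok <- k * params$step
    path[[k + 1]] <- matrix(disp, 1, 3)
  }
  trace$steps <- steps
  trace$blocker <- blocker
  trace$t_reach <- t_ok          # raw obstruction distance, before the
                                 # bind-position backtracking

  # settle toward the surface and search the orientation grid for a
  # feasible covalent-binding pose; if none exists at the stopping point,
  # back the substrate up step by step (it binds at the farthest position
  # where its thioester can reach the surface)
  th_loc <- .thioester_idx(c3b)
  if_loc <- .iface_idx(c3b)
  found <- NULL
  n_path <- length(path)
  k_try <- n_path
  while (is.null(found) && k_try >= 2 && k_try >= n_path - 20) {
    t_try <- (k_try - 1) * params$step
    xyz_stop <- sweep(xyz_start, 2, path[[k_try]], "+")
    down <- 0
    for (stp in c(2, 0.5)) {
      repeat {
        cand <- xyz_stop
        cand[, 3] <- cand[, 3] - (down + stp)
        if (!is.null(.env_clash(env, cand, rb))) break
        down <- down + stp
        if (down > lift + 20) break
      }
    }
    xyz_stop[, 3] <- xyz_stop[, 3] - down
    # two-pass grid: prefer orientations whose binding interface leaves a
    # long on-facet runway for the next incoming C3 (tested with the same
    # geometry the next recruitment will use); fall back to a short runway
    conv_len <- sqrt(sum(templates$convertase_to_substrate$t^2))
    for (lookahead in c(conv_len + 90, conv_len + 5)) {
      for (g in seq_len(nrow(grid))) {
        cand <- .rotate_about_centroid(xyz_stop, grid$tx[g], grid$ty[g],
                                       grid$rz[g])
        thd <- min(nearest_dist(cand[th_loc, , drop = FALSE], facet$coords,
                                params$thioester_contact_max + 6))
        if (thd > params$thioester_contact_max) next
        if (!is.null(.env_clash(env, cand, rb))) next
        if (!.iface_clear(cand, if_loc, penv)) next
        # the binding interface must be exposed toward free facet surface
        # so the next incoming C3 can be recruited onto the facet
        R_g <- rt_compose(rt_axis_angle(c(1, 0, 0), grid$tx[g]),
                rt_compose(rt_axis_angle(c(0, 1, 0), grid$ty[g]),
                           rt_axis_angle(c(0, 0, 1), grid$rz[g])))$R
        ifd <- as.numeric((R_g %*% anchor_rot) %*% c(0, 1, 0))
        nif <- sqrt(sum(ifd[1:2]^2))
        if (nif < 1e-6) next
        ifd_xy <- ifd[1:2] / nif
        cen_xy <- colMeans(cand)[1:2]
        if (!on_facet(facet, cen_xy + lookahead * ifd_xy)) next
        found <- list(xyz = cand, g = g, thd = thd)
        break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) k_try <- k_try - 1
  }
  trace$translation_used <- if (is.null(found)) t_ok else (k_try - 1) * params$step
  t_ok <- trace$translation_used
  if (is.null(found)) {
    trace$verdict <- "obstructed_infeasible"
    return(list(record = NULL, trace = trace))
  }
  trace$verdict <- "bound"
  model <- set_coords(c3b, found$xyz)
  model$name <- paste0("c3b_", substr(anchor$name, 1, 12), "_",
                       format(round(t_ok)))
  g <- found$g
  R_grid <- rt_compose(rt_axis_angle(c(1, 0, 0), grid$tx[g]),
             rt_compose(rt_axis_angle(c(0, 1, 0), grid$ty[g]),
                        rt_axis_angle(c(0, 0, 1), grid$rz[g])))$R
  thg <- found$xyz[th_loc, , drop = FALSE]
  d2 <- rowSums(sweep(facet$coords, 2, colMeans(thg))^2)
  record <- list(molecule = "c3b", model = model, anchor = anchor$name,
                 translation_used = t_ok,
                 termination_reason = if (is.null(blocker)) "max_translation"
                                      else blocker,
                 thioester_dist = found$thd,
                 rotation = R_grid %*% anchor_rot,
                 anchor_atom = which.min(d2))
  list(record = record, trace = trace)
}

# billiard reflection of an in-plane direction off the dilated facet
# boundary; NULL when no reflection resolves the exit (pathological corner)
.reflect_direction <- function(facet, pos_xy, d2d, step) {
  V <- facet$vertices
  d_new <- d2d
  for (pass in 1:2) {
    adv <- pos_xy + step * d_new
    fixed <- FALSE
    for (e in 1:3) {
      a <- V[e, ]; b <- V[e %% 3 + 1, ]
      edge <- b - a
      nrm <- c(edge[2], -edge[1]); nrm <- nrm / sqrt(sum(nrm^2))
      if (sum((c(0, 0) - a) * nrm) > 0) nrm <- -nrm   # outward normal
      if (sum((adv - a) * nrm) > 28 && sum(d_new * nrm) > 0) {
        d_new <- d_new - 2 * sum(d_new * nrm) * nrm
        fixed <- TRUE
      }
    }
    if (!fixed) break
  }
  if (on_facet(facet, pos_xy + step * d_new)) d_new else NULL
}

# interface clearance: no placed-molecule bead inside a forward cylinder
.iface_clear <- function(xyz, iface_idx, penv, length_ahead = 60, radius = 15) {
  if (nrow(penv$coords) == 0) return(TRUE)
  icen <- colMeans(xyz[iface_idx, , drop = FALSE])
  dirv <- icen - colMeans(xyz)
  dirv <- dirv / sqrt(sum(dirv^2))
  rel <- sweep(penv$coords, 2, icen)
  proj <- as.numeric(rel %*% dirv)
  sel <- proj > 0 & proj < length_ahead
  if (!any(sel)) return(TRUE)
  perp2 <- rowSums(rel[sel, , drop = FALSE]^2) - proj[sel]^2
  all(perp2 > radius^2)
}

# interface direction of a placed C3b/C4b model (unit vector)
.model_iface_dir <- function(model) {
  icen <- colMeans(coords(model, .iface_idx(model)))
  cen <- model_centroid(model)
  v <- icen - cen
  v / sqrt(sum(v^2))
}

# ---- vertex occupancy --------------------------------------------------------

#' Count facet vertices occupied by bound C3b
#'
#' A vertex is occupied when some bound C3b's thioester-domain centroid lies
#' within `vertex_radius` of that vertex's penton centroid, measured in the
#' facet plane (occupancy is about position *on* the facet, so the height of
#' the domain above the surface does not discount it).
#'
#' @param inventory inventory with `c3b` placements.
#' @param facet a `FacetModel`.
#' @param params a `PropagationParams`.
#' @return list with `per_vertex` (logical, length 3) and `n_occupied`.
#' @export
count_vertex_c3b <- function(inventory, facet,
                             params = propagation_params()) {
  occ <- rep(FALSE, 3)
  for (rec in inventory$c3b) {
    ted <- model_centroid(rec$model, .ted_idx(rec$model))
    for (v in 1:3) {
      if (sqrt(sum((ted[1:2] - facet$vertices[v, ])^2)) <=
          params$vertex_radius) {
        occ[v] <- TRUE
      }
    }
  }
  list(per_vertex = occ, n_occupied = sum(occ))
}

# ---- enumeration -------------------------------------------------------------

#' Run the full 16-pose enumeration
#'
#' For every bent IgM pose (anchor hexon 1-4, rotations 0/90/180/270):
#' place IgM, gate and place C1, evaluate both C4b sites, propagate C3b, and
#' count occupied vertices. Stage errors abort the affected pose with a
#' failure row, not the run.
#'
#' @param facet a `FacetModel`.
#' @param kit fixture kit from [make_fixture_kit()].
#' @param params a `PropagationParams`.
#' @return list with `inventories` (16) and `summary` (data frame: pose,
#'   contacts, c1, n_c4b_feasible, n_c3b_bound, n_vertices_occupied,
#'   termination reasons).
#' @export
enumerate_poses <- function(facet, kit, params = propagation_params()) {
  poses <- all_igm_poses()
  inventories <- list()
  rows <- list()
  for (p in poses) {
    key <- sprintf("h%d_r%d", p$anchor_hexon, p$rotation_deg)
    inv <- tryCatch({
      igm <- place_igm(facet, kit$igm_bent, p)
      c1 <- place_c1(igm, kit$c1, kit$templates)
      inv <- list(pose = p, igm = igm, c1 = c1)
      if (isTRUE(c1$placed)) {
        inv$c4b <- place_c4b(facet, c1, kit$c4b, kit$templates, igm, params)
      } else {
        inv$c4b <- list()
      }
      inv <- propagate_c3b(facet, inv, kit$c3b, kit$templates, params)
      occ <- count_vertex_c3b(inv, facet, params)
      inv$vertex_occupancy <- occ
      inv
    }, error = function(e) list(pose = p, failed = conditionMessage(e)))
    inventories[[key]] <- inv
    if (!is.null(inv$failed)) {
      rows[[key]] <- data.frame(
        pose_hexon = p$anchor_hexon, pose_rot = p$rotation_deg,
        conformation = p$conformation, contacts = NA, c1_placed = FALSE,
        n_c4b = 0, n_c3b = 0, n_vertices_occupied = NA,
        termination_reasons = paste("error:", inv$failed),
        stringsAsFactors = FALSE)
    } else {
      term <- vapply(inv$traces, function(t) t$verdict, character(1))
      rows[[key]] <- data.frame(
        pose_hexon = p$anchor_hexon, pose_rot = p$rotation_deg,
        conformation = p$conformation, contacts = inv$igm$contacts,
        c1_placed = isTRUE(inv$c1$placed),
        n_c4b = sum(vapply(inv$c4b, function(r) isTRUE(r$feasible),
                           logical(1))),
        n_c3b = length(inv$c3b),
        n_vertices_occupied = inv$vertex_occupancy$n_occupied,
        termination_reasons = paste(term, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(inventories = inventories, summary = summary)
}
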