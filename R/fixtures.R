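# Coarse-grained synthetic structure generators. One bead per residue
# (pseudo-C-alpha, 3.8 A spacing, exact by construction), with bulky domains
# as bead shells. Marker residue indices follow the biology they stand in
# for: hexon FX-binding site at residue 425 (T425), HVR1 loops on the hexon
# top; penton-base RGD loop 297-376 with the RGD motif near the apex;
# C3b/C4b thioester domain 990-1290 with the reactive thioester at residues
# 1010/1013; fiber N-terminal tail residues 1-6.

#' Fixture specification
#'
#' Dimensions of the synthetic capsid and ligand models. Defaults follow the
#' modeled system: ~300 A facet edge, fiber built at 13 A rise and 51.4 deg
#' twist per shaft repeat to 21 repeats (~350 A total), pseudo-C-alpha beads
#' at 3.8 A. `fx_binding_enabled = FALSE` emulates the T425A mutant
#' (Ad5-FX*): the hexon is generated without its `fx_site` annotation.
#'
#' @param bead_spacing bead spacing, Angstrom.
#' @param facet_edge_length penton-to-penton facet edge, Angstrom.
#' @param fiber_total_length_target full fiber length target, Angstrom.
#' @param shaft_rise_per_repeat fiber shaft rise per repeat, Angstrom.
#' @param shaft_twist_per_repeat fiber shaft twist per repeat, degrees.
#' @param n_shaft_repeats total shaft repeats in the full fiber.
#' @param fx_binding_enabled annotate the hexon FX site (wild type) or not
#'   (T425A stand-in).
#' @param rng_seed seed for the only stochastic element (FX jitter).
#' @param calib calibration constants of the fixture family (see
#'   [default_calib()]); exposed for sensitivity analyses, fixed defaults.
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(bead_spacing = 3.8, facet_edge_length = 300,
                         fiber_total_length_target = 350,
                         shaft_rise_per_repeat = 13,
                         shaft_twist_per_repeat = 51.4,
                         n_shaft_repeats = 21, fx_binding_enabled = TRUE,
                         rng_seed = 1L, calib = default_calib()) {
  stopifnot(bead_spacing > 0, facet_edge_length > 0,
            fiber_total_length_target > 0, shaft_rise_per_repeat > 0,
            n_shaft_repeats >= 1)
  structure(list(
    bead_spacing = bead_spacing,
    facet_edge_length = facet_edge_length,
    fiber_total_length_target = fiber_total_length_target,
    shaft_rise_per_repeat = shaft_rise_per_repeat,
    shaft_twist_per_repeat = shaft_twist_per_repeat,
    n_shaft_repeats = n_shaft_repeats,
    fx_binding_enabled = fx_binding_enabled,
    rng_seed = as.integer(rng_seed),
    calib = calib
  ), class = "FixtureSpec")
}

#' Fixture calibration constants
#'
#' Geometric constants of the synthetic molecules that are not stated
#' dimensions of the modeled system but fixture design choices, calibrated
#' once so the assembled pipeline reproduces the documented facet
#' combinatorics (IgM Fab reach vs. hexon lattice, C4b site geometry,
#' convertase-substrate offset). See the methods vignette for how each was
#' chosen.
#'
#' @return named list of constants.
#' @export
default_calib <- function() {
  list(
    hexon = list(height = 49, wall_r = 26, fan_out = 28.5, fan_in = 7.5,
                 floor_z = 36, dep_r = 6.5),
    penton = list(height = 45, wall_r = 24, inner_r = 16, loop_rise = 28,
                  loop_r = 3.5),
    fiber = list(tail_r = 2, shaft_r_auto = TRUE, knob_a = 15, knob_c = 42,
                 knob_gap = 45),
    igm = list(tip_r = 75, platform_r = 55, platform_z = 55,
               pair_half_deg = 7.25, planar_tip_r = 130, droop = 8,
               gap_az = 300, unit_az = c(0, 60, 120, 180, 240)),
    c4b_site = list(radius = 95, half_sep_deg = 35, z = 2.4,
                    interface_gamma = -35),
    conv_offset = 55,
    anchor_offset_az = 113,
    fx = list(tilt_max = 15)
  )
}

# ------------------------------------------------------------------ hexon ----

#' Generate a hexon trimer
#'
#' Three chains wound as interleaved helices about the trimer axis (exact
#' three-fold symmetry), carrying a dense top annulus annotated `hvr1` (the
#' Fab-binding hypervariable loops), and a recessed central depression
#' (>= 8 A deep) whose floor carries the `fx_site` marker at residue 425 when
#' FX binding is enabled.
#'
#' @param spec a `FixtureSpec`.
#' @return `MolecularModel` with 3 chains of role `hexon` (ids A, B, C).
#' @export
make_hexon_trimer <- function(spec = fixture_spec()) {
  hx <- spec$calib$hexon
  sp <- spec$bead_spacing
  ax <- c(0, 0, 0)
  build_chain <- function(phase_deg) {
    phi <- phase_deg * pi / 180
    p0 <- c(hx$wall_r * cos(phi), hx$wall_r * sin(phi), 1)
    pts <- path_start(p0)
    pts <- path_helix(pts, ax, 175, dz = 0.25, spacing = sp)        # 1..176 wall
    # rim: spiral slightly up and out to the fan start
    for (k in 1:12) {                                               # 177..188
      last <- pts[nrow(pts), ]
      rel <- last[1:2]; rho <- sqrt(sum(rel^2))
      target_rho <- min(hx$fan_out, rho + 0.2)
      zt <- min(hx$height, last[3] + 0.9)
      azt <- atan2(rel[2], rel[1]) + 0.12
      pts <- path_jump(pts, c(target_rho * cos(azt), target_rho * sin(azt), zt), sp)
    }
    pts <- path_flat_spiral(pts, ax, 48, dr = (hx$fan_in - hx$fan_out) / 48,
                            spacing = sp)                           # 189..236 fan
    pts <- path_helix(pts, ax, 178, dz = -0.26, spacing = sp)       # 237..414 interior
    # riser to depression floor level
    last <- pts[nrow(pts), ]
    for (k in 1:10) {                                               # 415..424
      last <- pts[nrow(pts), ]
      rel <- last[1:2]; rho <- sqrt(sum(rel^2))
      target_rho <- max(hx$dep_r, rho - 2.2)
      azt <- atan2(rel[2], rel[1]) + 0.25
      zt <- last[3] + (hx$floor_z - 2 - last[3]) / (11 - k)
      pts <- path_jump(pts, c(target_rho * cos(azt), target_rho * sin(azt), zt), sp)
    }
    # depression floor spiral (425..436), fx_site = residue 425
    pts <- path_jump(pts, c(3 * cos(phi), 3 * sin(phi), hx$floor_z), sp)
    pts <- path_flat_spiral(pts, ax, 11, dr = 0.27, spacing = sp)
    # depression wall (437..460)
    pts <- path_helix(pts, ax, 24, dz = 0.46, spacing = sp)
    pts
  }
  chains <- list()
  atoms <- list()
  ids <- c("A", "B", "C")
  base <- build_chain(0)
  for (k in 1:3) {
    rot <- rt_axis_angle(c(0, 0, 1), 120 * (k - 1))
    pts <- rt_apply(rot, base)
    atoms[[k]] <- beads_to_atoms(pts, ids[k])
    dom <- list(hvr1 = c(177, 236), depression = c(425, 460))
    if (spec$fx_binding_enabled) dom$fx_site <- c(425, 425)
    chains[[ids[k]]] <- list(role = "hexon", domains = dom)
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  molecular_model("hexon", a, chains,
                  metadata = list(kind = "hexon_trimer",
                                  top_z = hx$height,
                                  footprint_r = hx$fan_out + 1.7))
}

# ----------------------------------------------------------------- penton ----

#' Generate a penton base pentamer
#'
#' Five chains P1-P5 related by exact 72 degree rotations. Each spans
#' residues 38-571: the fixed base (`base_n` 38-296, `base_c` 377-571) as
#' wall helices, and the flexible `rgd_loop` (297-376) as an extended
#' corkscrew arm rising well above the base top, with the acidic RGD motif
#' (residues 335-337, negatively charged beads around the apex) annotated.
#'
#' @param spec a `FixtureSpec`.
#' @return `MolecularModel` with 5 chains of role `penton_base`.
#' @export
make_penton_base <- function(spec = fixture_spec()) {
  pn <- spec$calib$penton
  sp <- spec$bead_spacing
  ax <- c(0, 0, 0)
  build_chain <- function(phase_deg) {
    phi <- phase_deg * pi / 180
    pts <- path_start(c(pn$wall_r * cos(phi), pn$wall_r * sin(phi), 1))
    pts <- path_helix(pts, ax, 258, dz = 0.17, spacing = sp)  # 38..296 base_n
    # rgd loop: corkscrew up and back around a local sub-axis; the down leg
    # runs on a wider radius so the two legs stay apart
    last <- pts[nrow(pts), ]
    sub_az <- atan2(last[2], last[1])
    sub_ax <- c(22 * cos(sub_az), 22 * sin(sub_az), 0)
    pts <- path_jump(pts, c(sub_ax[1] + pn$loop_r, sub_ax[2], last[3] + 2), sp)
    pts <- path_helix(pts, sub_ax, 39, dz = 0.72, spacing = sp)   # up
    last <- pts[nrow(pts), ]
    outward <- last[1:2] - sub_ax[1:2]
    outward <- outward / sqrt(sum(outward^2))
    pts <- path_jump(pts, c(last[1:2] + 3.2 * outward, last[3] - 1), sp)
    pts <- path_helix(pts, sub_ax, 39, dz = -0.72, sign = -1, spacing = sp)  # down
    # base_c: descend inside
    last <- pts[nrow(pts), ]
    pts <- path_jump(pts, c(pn$inner_r * cos(sub_az + 0.4),
                            pn$inner_r * sin(sub_az + 0.4), last[3] - 2), sp)
    n_so_far <- nrow(pts)
    pts <- path_helix(pts, ax, 534 - n_so_far, dz = -0.22, spacing = sp)
    pts
  }
  base <- build_chain(90)
  chains <- list(); atoms <- list()
  for (k in 1:5) {
    rot <- rt_axis_angle(c(0, 0, 1), 72 * (k - 1))
    pts <- rt_apply(rot, base)
    id <- paste0("P", k)
    types <- rep("CA", nrow(pts))
    resid <- seq.int(38, length.out = nrow(pts))
    types[resid >= 333 & resid <= 339] <- "NEG"   # acidic RGD apex
    atoms[[k]] <- beads_to_atoms(pts, id, residue_start = 38, types = types)
    chains[[id]] <- list(role = "penton_base",
                         domains = list(base_n = c(38, 296),
                                        rgd_loop = c(297, 376),
                                        rgd_motif = c(335, 337),
                                        base_c = c(377, 571)))
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  molecular_model("penton", a, chains,
                  metadata = list(kind = "penton_base", top_z = pn$height,
                                  footprint_r = pn$wall_r + pn$loop_r + 2))
}

# ------------------------------------------------------------------ fiber ----

# exact-chord shaft helix radius for a 4-bead repeat at the given rise/twist
.shaft_radius <- function(rise, twist_deg, spacing, beads_per_repeat = 4) {
  dz <- rise / beads_per_repeat
  dth <- (twist_deg / beads_per_repeat) * pi / 180
  lat <- sqrt(spacing^2 - dz^2)
  lat / (2 * sin(dth / 2))
}

#' Generate the fiber template
#'
#' Three chains F1-F3 related by 120 degree rotations about the fiber axis.
#' The template carries the N-terminal tail (annotated residues 1-6, acidic
#' beads), a short neck, exactly four shaft repeats (4 beads each, lying on
#' the exact-chord shaft helix for the given rise/twist), and the knob cap.
#' Knob and tail extents are the calibration constants that make the
#' 21-repeat fiber reach the total length target; they are recorded in the
#' model metadata.
#'
#' @param spec a `FixtureSpec`.
#' @return `MolecularModel` with 3 chains of role `fiber`; metadata carries
#'   the repeat frame (`repeat_start_residue`, `beads_per_repeat`, rise,
#'   twist, axis).
#' @export
make_fiber_template <- function(spec = fixture_spec()) {
  fb <- spec$calib$fiber
  sp <- spec$bead_spacing
  rise <- spec$shaft_rise_per_repeat
  twist <- spec$shaft_twist_per_repeat
  r_shaft <- .shaft_radius(rise, twist, sp)
  dz <- rise / 4
  dth <- (twist / 4) * pi / 180
  n_rep <- 4
  build_chain <- function(phase_deg) {
    phi <- phase_deg * pi / 180
    # tail: 6 beads straight up at small radius
    pts <- path_start(c(fb$tail_r * cos(phi), fb$tail_r * sin(phi), 0))
    pts <- path_line(pts, c(0, 0, 1), 5, sp)                       # 1..6
    # neck: bridge out to the shaft helix start keeping exact chords;
    # shaft start height solved so the last neck bead is one chord away
    shaft_phi0 <- phi
    start_xy <- c(r_shaft * cos(shaft_phi0), r_shaft * sin(shaft_phi0))
    repeat {
      lastb <- pts[nrow(pts), ]
      horiz <- sqrt(sum((start_xy - lastb[1:2])^2))
      if (horiz <= sp - 0.5) break
      pts <- path_jump(pts, c(start_xy, lastb[3] + 1.6), sp)
    }
    lastb <- pts[nrow(pts), ]
    horiz <- sqrt(sum((start_xy - lastb[1:2])^2))
    dz0 <- sqrt(sp^2 - horiz^2)
    z0 <- lastb[3] + dz0
    n_pre <- nrow(pts)
    # shaft: beads exactly on the helix (rigid-copy property across repeats)
    jj <- 0:(4 * n_rep - 1)
    shaft <- cbind(r_shaft * cos(shaft_phi0 + jj * dth),
                   r_shaft * sin(shaft_phi0 + jj * dth),
                   z0 + jj * dz)
    pts <- rbind(pts, shaft)
    # knob: prolate shell sector
    z_top <- z0 + (4 * n_rep - 1) * dz
    knob_center <- c(0, 0, z_top + fb$knob_gap)
    pts <- path_shell(pts, knob_center, fb$knob_a, fb$knob_c, 60,
                      z_from = -0.95, z_to = 0.97, n_levels = 9,
                      phi0 = phi, phi_span = 2 * pi / 3, spacing = sp)
    list(pts = pts, z0 = z0, n_pre = n_pre)
  }
  b1 <- build_chain(90)
  rep_start <- b1$n_pre + 1
  chains <- list(); atoms <- list()
  for (k in 1:3) {
    rot <- rt_axis_angle(c(0, 0, 1), 120 * (k - 1))
    pts <- rt_apply(rot, b1$pts)
    id <- paste0("F", k)
    types <- rep("CA", nrow(pts))
    types[1:6] <- "NEG"                      # acidic N-terminal tail
    # one acidic surface bead per shaft repeat (charged beta-spiral surface)
    shaft_res <- rep_start:(rep_start + 4 * n_rep - 1)
    types[shaft_res[(shaft_res - rep_start) %% 4 == 0]] <- "NEG"
    atoms[[k]] <- beads_to_atoms(pts, id, types = types)
    chains[[id]] <- list(role = "fiber",
                         domains = list(tail = c(1, 6),
                                        shaft = c(rep_start,
                                                  rep_start + 4 * n_rep - 1),
                                        knob = c(rep_start + 4 * n_rep,
                                                 nrow(pts))))
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  molecular_model("fiber_template", a, chains,
                  metadata = list(kind = "fiber_template",
                                  repeat_start_residue = rep_start,
                                  beads_per_repeat = 4,
                                  n_template_repeats = n_rep,
                                  rise = rise, twist = twist,
                                  shaft_radius = r_shaft,
                                  shaft_z0 = b1$z0,
                                  knob_gap = fb$knob_gap,
                                  knob_c = fb$knob_c,
                                  axis = c(0, 0, 1)))
}

# -------------------------------------------------------------------- igm ----

#' Generate a pentameric IgM
#'
#' Five Fc units on a platform ring with one angular gap (the pentamer's
#' missing sixth position) and ten Fab arms in five pairs. In the bent
#' (dome) conformation the Fab tips lie exactly in a common plane 55 A below
#' the Fc platform; in the planar conformation arms extend radially with all
#' tips within 8 A of the platform plane, the designated pair (the pair
#' counterclockwise from the Fc gap) drooping slightly so that it alone can
#' reach a hexon top. DLPSP markers (C1q-binding motifs) sit on the convex
#' (upper) face of each Fc unit.
#'
#' @param spec a `FixtureSpec`.
#' @param conformation `"bent"` or `"planar"`.
#' @return `MolecularModel`: 5 chains role `igm_fc` (FC1..FC5), 10 chains
#'   role `igm_fab` (FAB1..FAB10). FAB1/FAB2 are the designated pair.
#' @export
make_igm <- function(spec = fixture_spec(), conformation = c("bent", "planar")) {
  conformation <- match.arg(conformation)
  ig <- spec$calib$igm
  sp <- spec$bead_spacing
  chains <- list(); atoms <- list()
  plat_z <- if (conformation == "bent") ig$platform_z else 0
  tip_r <- if (conformation == "bent") ig$tip_r else ig$planar_tip_r

  for (u in seq_along(ig$unit_az)) {
    az <- ig$unit_az[u] * pi / 180
    ctr <- c(ig$platform_r * cos(az), ig$platform_r * sin(az), plat_z)
    pts <- path_start(ctr + c(0, 0, -5))
    pts <- path_shell(pts, ctr, 11, 5.5, 66, z_from = -0.9, z_to = 0.9,
                      n_levels = 6, phi0 = az, spacing = sp)
    # dlpsp markers: two beads on the top (convex) face
    pts <- path_jump(pts, ctr + c(0, 0, 9), sp)
    pts <- path_jump(pts, ctr + c(2 * cos(az), 2 * sin(az), 9), sp)
    n_dlpsp <- nrow(pts)
    # pentamer ring bridge to the next Fc unit (the platform is contiguous
    # except across the missing-sixth gap)
    if (u < length(ig$unit_az)) {
      b0 <- c(ig$platform_r * cos(az + 0.22), ig$platform_r * sin(az + 0.22),
              plat_z)
      nb <- max(2, floor(sqrt(sum((b0 - pts[nrow(pts), ])^2)) / sp))
      pts <- path_toward(pts, b0 + 2 * (b0 - pts[nrow(pts), ]), nb, sp)
      pts <- path_helix(pts, c(0, 0, 0), 8, dz = 0, spacing = sp)
    }
    id <- paste0("FC", u)
    atoms[[length(atoms) + 1]] <- beads_to_atoms(pts, id)
    chains[[id]] <- list(role = "igm_fc",
                         domains = list(dlpsp = c(n_dlpsp - 1, n_dlpsp)))
  }

  fab_i <- 0
  for (u in seq_along(ig$unit_az)) {
    for (s in c(-1, 1)) {
      fab_i <- fab_i + 1
      az_tip <- (ig$unit_az[u] + s * ig$pair_half_deg) * pi / 180
      az_u <- ig$unit_az[u] * pi / 180
      droop <- if (conformation == "planar" && u == 1) -ig$droop else 0
      tip <- c(tip_r * cos(az_tip), tip_r * sin(az_tip),
               if (conformation == "bent") 0 else droop)
      root <- c((ig$platform_r - 3) * cos(az_u) + s * 4 * -sin(az_u),
                (ig$platform_r - 3) * sin(az_u) + s * 4 * cos(az_u),
                plat_z - 2)
      elbow <- 0.45 * root + 0.55 * tip +
        if (conformation == "bent") c(0, 0, 6) else c(0, 0, 2)
      # two-segment rod root -> elbow -> tip; the last bead is the Fab tip
      pts <- path_start(root)
      n1 <- max(2, floor(sqrt(sum((elbow - root)^2)) / sp))
      far1 <- elbow + 3 * (elbow - root)
      pts <- path_toward(pts, far1, n1, sp)
      d2 <- sqrt(sum((tip - pts[nrow(pts), ])^2))
      n2 <- max(2, round(d2 / sp))
      far2 <- tip + 3 * (tip - pts[nrow(pts), ])
      pts <- path_toward(pts, far2, n2, sp)
      id <- paste0("FAB", fab_i)
      atoms[[length(atoms) + 1]] <- beads_to_atoms(pts, id)
      n <- nrow(pts)
      chains[[id]] <- list(role = "igm_fab",
                           domains = list(fab_tip = c(n, n)))
    }
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  molecular_model(paste0("igm_", conformation), a, chains,
                  metadata = list(kind = "igm", conformation = conformation,
                                  gap_az = ig$gap_az, tip_r = tip_r,
                                  platform_z = plat_z))
}

# --------------------------------------------------------------------- c1 ----

#' Generate the C1 complex
#'
#' C1q hexamer (six stalk+globular-head chains, one flagged `bent_upward`
#' positioned over the IgM Fc gap with its head hovering outward over the
#' facet) plus the C1r2s2 tetrameric protease (2 c1r + 2 c1s chains). Built
#' directly in the bent-IgM local frame so the stored IgM-to-C1 template
#' transform is the identity: heads land on the DLPSP ring by construction.
#'
#' @param spec a `FixtureSpec`.
#' @return `MolecularModel` with 10 chains.
#' @export
make_c1 <- function(spec = fixture_spec()) {
  ig <- spec$calib$igm
  sp <- spec$bead_spacing
  hub <- c(0, 0, 150)
  chains <- list(); atoms <- list()
  az6 <- c(ig$unit_az, ig$gap_az)
  for (k in 1:6) {
    az <- az6[k] * pi / 180
    bent_up <- (k == 6)
    head <- if (bent_up) {
      c(70 * cos(az), 70 * sin(az), 80)
    } else {
      c(ig$platform_r * cos(az), ig$platform_r * sin(az), ig$platform_z + 14)
    }
    pts <- path_start(hub)
    nst <- max(2, floor(sqrt(sum((head - hub)^2)) / sp))
    pts <- path_toward(pts, head + 2 * (head - hub), nst, sp)
    pts <- path_shell(pts, head + c(0, 0, 3), 6, 5, 14, n_levels = 4,
                      spacing = sp)
    id <- paste0("C1Q", k)
    atoms[[length(atoms) + 1]] <- beads_to_atoms(pts, id)
    chains[[id]] <- list(role = "c1q", domains = list(),
                         flags = if (bent_up) "bent_upward" else character())
  }
  prot <- list(C1R1 = c(30, 60, 100), C1R2 = c(-30, 60, 100),
               C1S1 = c(45 * cos(270 * pi / 180), 45 * sin(270 * pi / 180), 95),
               C1S2 = c(45 * cos(330 * pi / 180), 45 * sin(330 * pi / 180), 95))
  for (id in names(prot)) {
    pts <- path_start(prot[[id]] + c(0, 0, -6))
    pts <- path_shell(pts, prot[[id]], 8, 7, 40, n_levels = 5, spacing = sp)
    atoms[[length(atoms) + 1]] <- beads_to_atoms(pts, id)
    chains[[id]] <- list(role = if (grepl("C1R", id)) "c1r" else "c1s",
                         domains = list())
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  molecular_model("c1", a, chains, metadata = list(kind = "c1"))
}

# -------------------------------------------------------------- c3b / c4b ----

#' Generate complement C3b (or C4b)
#'
#' Two chains built from concentric helical barrels. The longer alpha chain
#' (residues 650-1450) carries the thioester domain (990-1290) whose
#' reactive thioester foot (residues 1010/1013 in a tight marker spiral,
#' charged +1/-1 pattern) points along local -z (the surface-reactive
#' face), and a `substrate_interface` strand (residues 1291-1320) on the
#' local +y face where the next incoming C3 binds. The shorter beta chain
#' (residues 1-450) forms the lower body. In the bound pose local z = 0
#' rests on the capsid surface.
#'
#' @param spec a `FixtureSpec`.
#' @param kind `"c3b"` or `"c4b"` (isomorphic geometry, distinct roles).
#' @return `MolecularModel` with chains `A` (alpha) and `B` (beta).
#' @export
make_c3b <- function(spec = fixture_spec(), kind = c("c3b", "c4b")) {
  kind <- match.arg(kind)
  sp <- spec$bead_spacing
  # beta: lower body, two concentric helical barrels (r 11 up, r 7 down)
  ptsB <- path_start(c(11, 0, 8))
  ptsB <- path_helix(ptsB, c(0, 0, 0), 281, dz = 0.159, spacing = sp)
  lastB <- ptsB[nrow(ptsB), ]
  ptsB <- path_jump(ptsB, c(7 * lastB[1:2] / sqrt(sum(lastB[1:2]^2)),
                            lastB[3] - 1), sp)
  ptsB <- path_helix(ptsB, c(0, 0, 0), 167, dz = -0.252, spacing = sp)

  # alpha body: wide barrel descending from the top (650..949)
  ptsA <- path_start(c(13, 0, 96))
  ptsA <- path_helix(ptsA, c(0, 0, 0), 299, dz = -0.135, spacing = sp)
  # connector strand (950..989): a zigzag column descending outside the
  # body toward the thioester-domain region (CUB-like linker); absolute
  # height schedule so the path never revisits itself
  ted_xy <- c(24, 0)
  n_need <- 990 - 650 - nrow(ptsA)
  col_xy <- c(40, -8)
  z_sched <- seq(ptsA[nrow(ptsA), 3] - 2.5, 2.2, length.out = n_need)
  for (k in seq_len(n_need)) {
    ptsA <- path_jump(ptsA, c(col_xy + c(2.8 * (-1)^k, 0.15 * k), z_sched[k]), sp)
  }
  # thioester domain underside: a flat disc spiral (990..1007) at z ~ 1,
  # then the reactive foot (1008..1016; residues 1010 and 1013 end close
  # together at the lowest face)
  ptsA <- path_jump(ptsA, c(ted_xy + c(11, -2), 0.8), sp)
  r_disc0 <- sqrt(sum((ptsA[nrow(ptsA), 1:2] - ted_xy)^2))
  ptsA <- path_flat_spiral(ptsA, c(ted_xy, 0), 17, dr = (4.5 - r_disc0) / 17,
                           spacing = sp)
  last <- ptsA[nrow(ptsA), ]
  relxy <- last[1:2] - ted_xy
  az <- atan2(relxy[2], relxy[1])
  d_xy <- abs(sqrt(sum(relxy^2)) - 2.6)
  dz_f <- sqrt(max(sp^2 - d_xy^2, 0.04))
  ptsA <- rbind(ptsA, c(ted_xy + 2.6 * c(cos(az), sin(az)), last[3] - dz_f))
  ptsA <- path_helix(ptsA, c(ted_xy, 0), 8, dz = 0.25, spacing = sp)
  # domain body: concentric barrels rising over the disc (1017..1290)
  ptsA <- path_jump(ptsA, c(ted_xy + c(9, 1.5), 2.2), sp)
  ptsA <- path_helix(ptsA, c(ted_xy, 0), 172, dz = 0.195, spacing = sp)  # r~9 up
  lastA <- ptsA[nrow(ptsA), ]
  rel <- lastA[1:2] - ted_xy
  ptsA <- path_jump(ptsA, c(ted_xy + 5 * rel / sqrt(sum(rel^2)),
                            lastA[3] - 1), sp)
  ptsA <- path_helix(ptsA, c(ted_xy, 0), 85, dz = -0.35, spacing = sp)   # r~5 down
  while (sqrt(sum((ptsA[nrow(ptsA), 1:2] - ted_xy)^2)) > 4.0) {
    lastA <- ptsA[nrow(ptsA), ]
    ptsA <- path_jump(ptsA, c(ted_xy, lastA[3] + 1.4), sp)
  }
  lastA <- ptsA[nrow(ptsA), ]
  rel <- lastA[1:2] - ted_xy
  az <- atan2(rel[2], rel[1])
  d_xy <- abs(sqrt(sum(rel^2)) - 2.2)
  ptsA <- rbind(ptsA, c(ted_xy + 2.2 * c(cos(az), sin(az)),
                        lastA[3] + sqrt(max(sp^2 - d_xy^2, 0.04))))
  n_ted_left <- (1290 - 650 + 1) - nrow(ptsA)
  ptsA <- path_helix(ptsA, c(ted_xy, 0), n_ted_left, dz = 0.9, spacing = sp)
  # substrate interface strand on the +y face (1291..1320)
  iface0 <- c(0, 16.5, 52)
  d_if <- sqrt(sum((ptsA[nrow(ptsA), ] - iface0)^2))
  n_route <- min(18, max(2, round(d_if / sp)))
  ptsA <- path_toward(ptsA, iface0 + 2 * (iface0 - ptsA[nrow(ptsA), ]),
                      n_route, sp)
  while (nrow(ptsA) < 1320 - 650 + 1) {
    last <- ptsA[nrow(ptsA), ]
    ptsA <- path_jump(ptsA, c(6 * sin(nrow(ptsA) / 3), 16.5, last[3] + 2.6), sp)
  }
  # alpha tail: inner barrels rising inside the body (1321..1450)
  ptsA <- path_jump(ptsA, c(6, 2, 60), sp)
  ptsA <- path_helix(ptsA, c(0, 0, 0), 101, dz = 0.29, spacing = sp)  # r ~6
  lastA <- ptsA[nrow(ptsA), ]
  rel <- lastA[1:2]
  ptsA <- path_jump(ptsA, c(3 * rel / sqrt(sum(rel^2)), lastA[3] - 1), sp)
  n_left <- (1450 - 650 + 1) - nrow(ptsA)
  ptsA <- path_helix(ptsA, c(0, 0, 0), n_left, dz = -0.63, spacing = sp)

  typesA <- rep("CA", nrow(ptsA))
  residA <- seq.int(650, length.out = nrow(ptsA))
  typesA[residA %in% c(1008, 1010, 1012, 1014, 1016)] <- "POS"
  typesA[residA == 1013] <- "NEG"
  aA <- beads_to_atoms(ptsA, "A", residue_start = 650, types = typesA)
  aB <- beads_to_atoms(ptsB, "B")
  a <- rbind(aA, aB)
  a$serial <- seq_len(nrow(a))
  chains <- list(
    A = list(role = paste0(kind, "_alpha"),
             domains = list(thioester_domain = c(990, 1290),
                            thioester = c(1010, 1013),
                            substrate_interface = c(1291, 1320))),
    B = list(role = paste0(kind, "_beta"), domains = list())
  )
  molecular_model(kind, a, chains,
                  metadata = list(kind = kind,
                                  interface_dir = c(0, 1, 0),
                                  reactive_dir = c(0, 0, -1)))
}

#' @rdname make_c3b
#' @export
make_c4b <- function(spec = fixture_spec()) make_c3b(spec, kind = "c4b")

# --------------------------------------------------------------------- fx ----

#' Generate coagulation factor X
#'
#' Two chains: the compact GLA domain (fits the hexon central depression;
#' local origin at its centre) and the bulky serine-protease domain rising
#' along +z so that the docked FX protrudes well above the hexon top. The
#' canonical docking frame (GLA centred in the depression) is stored in the
#' metadata; `fx_jitter()` supplies the seeded orientation jitter used for
#' the fifteen non-central hexons.
#'
#' @param spec a `FixtureSpec`.
#' @return `MolecularModel` with chains `G` (fx_gla) and `S` (fx_protease).
#' @export
make_fx <- function(spec = fixture_spec()) {
  sp <- spec$bead_spacing
  ptsG <- path_start(c(2.8, 0, -4))
  ptsG <- path_helix(ptsG, c(0, 0, 0), 24, dz = 0.33, spacing = sp)
  ptsS <- path_start(c(0, 0, 14))
  ptsS <- path_shell(ptsS, c(0, 0, 30), 3.5, 13, 69, z_from = -0.95,
                     z_to = 0.95, n_levels = 10, spacing = sp)
  aG <- beads_to_atoms(ptsG, "G")
  aS <- beads_to_atoms(ptsS, "S")
  a <- rbind(aG, aS)
  a$serial <- seq_len(nrow(a))
  hx <- spec$calib$hexon
  molecular_model("fx", a,
                  list(G = list(role = "fx_gla", domains = list()),
                       S = list(role = "fx_protease", domains = list())),
                  metadata = list(kind = "fx",
                                  dock_z = hx$floor_z + 7,
                                  tilt_max = spec$calib$fx$tilt_max))
}

#' Seeded FX orientation jitter
#'
#' Deterministic per-slot jitter (uniform spin about the hexon axis plus a
#' tilt of at most `tilt_max` degrees) emulating the diffuse FX density over
#' non-central hexons.
#'
#' @param spec a `FixtureSpec` (uses `rng_seed` and the tilt bound).
#' @param slot_index hexon slot index (1-18).
#' @return list with `spin_deg`, `tilt_deg`, `tilt_az_deg`.
#' @export
fx_jitter <- function(spec, slot_index) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(spec$rng_seed * 1009L + as.integer(slot_index))
  list(spin_deg = stats::runif(1, 0, 360),
       tilt_deg = stats::runif(1, 0, spec$calib$fx$tilt_max),
       tilt_az_deg = stats::runif(1, 0, 360))
}

# ---------------------------------------------------------------- templates ----

#' Stored complex-template transforms
#'
#' Relative rigid transforms standing in for the experimentally derived
#' arrangements: IgM-to-C1 (identity: the C1 fixture is built in the bent-IgM
#' frame), the two IgM-to-C4b sites flanking the Fc gap adjacent to the c1s
#' chains, and the convertase-to-substrate offset (side-by-side along the
#' bound molecule's substrate-interface direction, thioester face kept
#' surface-ready).
#'
#' @param spec a `FixtureSpec`.
#' @return object of class `ComplexTemplateSet`.
#' @export
make_template_set <- function(spec = fixture_spec()) {
  cs <- spec$calib$c4b_site
  ig <- spec$calib$igm
  site_tf <- function(az_deg) {
    az <- az_deg * pi / 180
    pos <- c(cs$radius * cos(az), cs$radius * sin(az), cs$z)
    # rotate local +y (substrate interface) to point radially outward
    rot <- rt_axis_angle(c(0, 0, 1), az_deg - 90 + cs$interface_gamma)
    rigid_transform(rot$R, pos)
  }
  structure(list(
    igm_to_c1 = rt_identity(),
    igm_to_c4b_site1 = site_tf(ig$gap_az - cs$half_sep_deg),
    igm_to_c4b_site2 = site_tf(ig$gap_az + cs$half_sep_deg),
    convertase_to_substrate = rt_translation(c(0, spec$calib$conv_offset, 0))
  ), class = "ComplexTemplateSet")
}

#' Generate the complete fixture kit
#'
#' @param spec a `FixtureSpec`.
#' @return named list with every molecule model plus the template set.
#' @export
make_fixture_kit <- function(spec = fixture_spec()) {
  list(spec = spec,
       hexon = make_hexon_trimer(spec),
       penton = make_penton_base(spec),
       fiber_template = make_fiber_template(spec),
       igm_bent = make_igm(spec, "bent"),
       igm_planar = make_igm(spec, "planar"),
       c1 = make_c1(spec),
       c3b = make_c3b(spec, "c3b"),
       c4b = make_c4b(spec),
       fx = make_fx(spec),
       templates = make_template_set(spec))
}

#' Write the fixture kit to a directory
#'
#' Writes one PDB + sidecar per molecule plus a manifest JSON recording the
#' spec and template transforms.
#'
#' @param dir output directory (created if absent).
#' @param spec a `FixtureSpec`.
#' @return the directory path, invisibly.
#' @export
write_fixture_kit <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kit <- make_fixture_kit(spec)
  for (nm in setdiff(names(kit), c("spec", "templates"))) {
    write_structure(kit[[nm]], file.path(dir, paste0(nm, ".pdb")))
  }
  tpl <- lapply(kit$templates, function(tf) {
    list(rotation = as.vector(tf$R), translation = tf$t)
  })
  jsonlite::write_json(
    list(spec = spec[setdiff(names(spec), "calib")], templates = tpl),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
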