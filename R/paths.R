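# Bead-path builders. Every fixture chain is one connected path of
# pseudo-C-alpha beads with *exact* consecutive spacing (default 3.8 A):
# each primitive appends beads whose chord to the previous bead equals the
# spacing by construction (arcs pick the angular step from the chord formula,
# helices solve the chord equation for the azimuthal step, jumps move exactly
# one spacing toward a target). Shapes are therefore approximate; spacing and
# symmetry are exact, which is what the geometric pipeline relies on.

.unit <- function(v) v / sqrt(sum(v^2))

path_start <- function(p) matrix(p, 1, 3)

# n beads along a straight direction
path_line <- function(pts, dir, n, spacing = 3.8) {
  if (n <= 0) return(pts)
  d <- .unit(dir)
  last <- pts[nrow(pts), ]
  new <- t(vapply(seq_len(n), function(k) last + k * spacing * d, numeric(3)))
  rbind(pts, new)
}

# one bead exactly `spacing` from the current end, toward `target`
path_jump <- function(pts, target, spacing = 3.8) {
  last <- pts[nrow(pts), ]
  rbind(pts, last + spacing * .unit(target - last))
}

# n beads marching straight toward (and possibly through) a distant target;
# never oscillates because the count is fixed
path_toward <- function(pts, target, n, spacing = 3.8) {
  for (k in seq_len(n)) {
    last <- pts[nrow(pts), ]
    d <- target - last
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) d <- c(0, 0, 1) else d <- d / nd
    pts <- rbind(pts, last + spacing * d)
  }
  pts
}

# n beads on a helix about a vertical axis through `axis_pt` (z direction):
# each bead rises dz and advances the azimuth so the chord equals `spacing`.
# dz = 0 gives a circular arc. sign = +1 CCW, -1 CW.
path_helix <- function(pts, axis_pt, n, dz = 0, sign = 1, spacing = 3.8) {
  if (n <= 0) return(pts)
  last <- pts[nrow(pts), ]
  rel <- last[1:2] - axis_pt[1:2]
  rho <- sqrt(sum(rel^2))
  lat2 <- spacing^2 - dz^2
  if (lat2 < 0) stop("helix rise exceeds bead spacing")
  arg <- sqrt(lat2) / (2 * rho)
  if (arg > 1) stop("bead spacing exceeds helix diameter (radius ", rho, ")")
  dth <- sign * 2 * asin(arg)
  phi0 <- atan2(rel[2], rel[1])
  k <- seq_len(n)
  new <- cbind(axis_pt[1] + rho * cos(phi0 + k * dth),
               axis_pt[2] + rho * sin(phi0 + k * dth),
               last[3] + k * dz)
  rbind(pts, new)
}

# n beads spiralling in the z = const plane about axis_pt, radius changing by
# dr per bead; chord stays `spacing` (lateral step split between tangential
# and radial motion).
path_flat_spiral <- function(pts, axis_pt, n, dr, spacing = 3.8) {
  out <- pts
  for (k in seq_len(n)) {
    last <- out[nrow(out), ]
    rel <- last[1:2] - axis_pt[1:2]
    rho <- sqrt(sum(rel^2))
    rho2 <- rho + dr
    # chord^2 = rho^2 + rho2^2 - 2 rho rho2 cos(dth)
    ca <- (rho^2 + rho2^2 - spacing^2) / (2 * rho * rho2)
    if (ca > 1 || ca < -1) stop("spiral step infeasible at radius ", rho)
    dth <- acos(ca)
    phi <- atan2(rel[2], rel[1]) + dth
    out <- rbind(out, c(axis_pt[1] + rho2 * cos(phi),
                        axis_pt[2] + rho2 * sin(phi), last[3]))
  }
  out
}

# n beads walking an ellipsoidal shell (semi-axes a_xy, c_z, centred at
# `center`): latitude rings traversed bottom-up, hopping one exact chord to
# the next ring when the current ring closes. phi_span < 2*pi restricts the
# shell to an azimuthal sector (boustrophedon within the sector).
path_shell <- function(pts, center, a_xy, c_z, n, z_from = -1, z_to = 1,
                       n_levels = 8, phi0 = 0, phi_span = 2 * pi,
                       spacing = 3.8) {
  us <- seq(z_from, z_to, length.out = n_levels)  # normalized latitude
  out <- pts
  added <- 0
  dirn <- 1
  for (li in seq_along(us)) {
    z <- center[3] + c_z * us[li]
    rho <- a_xy * sqrt(max(1 - us[li]^2, 0.02))
    # hop to this ring with one exact-spacing bead
    last <- out[nrow(out), ]
    target <- c(center[1] + rho * cos(phi0), center[2] + rho * sin(phi0), z)
    dprev <- Inf
    repeat {
      out <- path_jump(out, target, spacing)
      added <- added + 1
      if (added >= n) return(out)
      dcur <- sqrt(sum((out[nrow(out), ] - target)^2))
      if (dcur < spacing || dcur >= dprev - 1e-9) break
      dprev <- dcur
    }
    # walk the ring (or sector) at this level; the angular step is computed
    # from the *actual* bead radius so every chord equals `spacing`
    steps_budget <- phi_span
    repeat {
      last <- out[nrow(out), ]
      rel <- last[1:2] - center[1:2]
      r2 <- sqrt(sum(rel^2))
      if (r2 < spacing / 2 + 0.1) break
      dth <- 2 * asin(min(1, spacing / (2 * r2)))
      if (steps_budget - dth < dth / 2) break
      phi <- atan2(rel[2], rel[1]) + dirn * dth
      out <- rbind(out, c(center[1] + r2 * cos(phi),
                          center[2] + r2 * sin(phi), last[3]))
      added <- added + 1
      steps_budget <- steps_budget - dth
      if (added >= n) return(out)
    }
    if (phi_span < 2 * pi) dirn <- -dirn
  }
  # shell exhausted before n beads: spiral gently above the top ring
  while (added < n) {
    last <- out[nrow(out), ]
    rel <- last[1:2] - center[1:2]
    r2 <- sqrt(sum(rel^2))
    if (r2 < spacing / 2 + 0.2) {
      out <- path_jump(out, last + c(2 * spacing, 0, 0.5), spacing)
    } else {
      dth <- 2 * asin(min(1, sqrt(spacing^2 - 0.25) / (2 * r2)))
      phi <- atan2(rel[2], rel[1]) + dth
      out <- rbind(out, c(center[1] + r2 * cos(phi),
                          center[2] + r2 * sin(phi), last[3] + 0.5))
    }
    added <- added + 1
  }
  out
}

# check helper used by fixture unit tests
consecutive_spacings <- function(pts) {
  if (nrow(pts) < 2) return(numeric())
  sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
}

# assemble an atoms data frame from a bead matrix
beads_to_atoms <- function(pts, chain_id, residue_start = 1,
                           types = NULL, bead_params = NULL) {
  n <- nrow(pts)
  if (is.null(types)) types <- rep("CA", n)
  if (is.null(bead_params)) bead_params <- .default_bead_table()
  p <- bead_params[types, , drop = FALSE]
  data.frame(
    serial = seq_len(n), name = types, element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    vdw_radius = p$vdw_radius, charge = p$charge,
    lj_epsilon = p$lj_epsilon, lj_rmin = p$lj_rmin,
    residue_index = seq.int(residue_start, length.out = n),
    chain_id = chain_id, stringsAsFactors = FALSE
  )
}

# bead parameter table indexed by bead type; NEG/POS are unit charges used
# for the electrostatic markers (Asp-like RGD apex, thioester face pattern)
.default_bead_table <- function() {
  tb <- data.frame(
    charge = c(0, -1, 1),
    vdw_radius = c(1.7, 1.7, 1.7),
    lj_epsilon = c(0.1, 0.1, 0.1),
    lj_rmin = c(3.4, 3.4, 3.4),
    row.names = c("CA", "NEG", "POS")
  )
  tb
}
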