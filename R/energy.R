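# Nonbonded interaction energies (Coulomb + Lennard-Jones, CHARMM-style C1
# switching) with chain/domain/residue-pair decomposition, and a fixed-base
# steepest-descent relaxation of vertex models. Units: kcal/mol, Angstrom,
# elementary charges.

#' Nonbonded energy parameters
#'
#' @param coulomb_constant Coulomb constant, kcal*A/(mol*e^2).
#' @param dielectric relative dielectric (1 = vacuum).
#' @param cutoff interaction cutoff, Angstrom.
#' @param switch_start start of the C1 switching region, Angstrom.
#' @param exclusion bonded neighbours within this many bonds (same chain)
#'   are excluded from the nonbonded sum.
#' @return object of class `NonbondedParams`.
#' @export
nonbonded_params <- function(coulomb_constant = 332.0636, dielectric = 1.0,
                             cutoff = 12, switch_start = 10, exclusion = 2) {
  stopifnot(switch_start > 0, switch_start < cutoff)
  structure(list(coulomb_constant = coulomb_constant,
                 dielectric = dielectric, cutoff = cutoff,
                 switch_start = switch_start, exclusion = exclusion),
            class = "NonbondedParams")
}

.group_cols <- function(model, idx) {
  a <- model$atoms[idx, , drop = FALSE]
  list(x = cbind(a$x, a$y, a$z), q = a$charge, e = a$lj_epsilon,
       rm = a$lj_rmin,
       ch = as.integer(factor(a$chain_id,
                              levels = unique(model$atoms$chain_id))),
       res = a$residue_index)
}

#' Nonbonded interaction energy between two atom groups
#'
#' Electrostatic term: k q_i q_j / (eps r) * S(r); van der Waals term:
#' eps_ij[(Rmin_ij/r)^12 - 2(Rmin_ij/r)^6] * S(r), with geometric-mean
#' epsilon, arithmetic-mean Rmin, and S a C1 switching function from
#' `switch_start` to `cutoff`. Pairs beyond the cutoff contribute exactly 0.
#'
#' @param model a `MolecularModel` carrying both groups.
#' @param idx_a,idx_b disjoint atom index vectors.
#' @param params a `NonbondedParams`.
#' @return named numeric: `elec`, `vdw` (kcal/mol).
#' @export
group_energy <- function(model, idx_a, idx_b, params = nonbonded_params()) {
  if (length(intersect(idx_a, idx_b)) > 0) {
    stop("groups must be disjoint")
  }
  A <- .group_cols(model, idx_a)
  B <- .group_cols(model, idx_b)
  v <- .cpp_group_energy(A$x, A$q, A$e, A$rm, A$ch, A$res,
                         B$x, B$q, B$e, B$rm, B$ch, B$res,
                         params$coulomb_constant, params$dielectric,
                         params$switch_start, params$cutoff,
                         params$exclusion)
  c(elec = v[1], vdw = v[2])
}

#' Chain- and domain-level energy decomposition
#'
#' Computes per-pair energies for named atom selections and verifies the
#' additivity identities of a pairwise sum (sub-selections of one side must
#' partition it). The percent split is 100*|elec| / (|elec| + |vdw|).
#'
#' @param model a `MolecularModel`.
#' @param groups named list of atom index vectors (e.g. C3b vs each penton
#'   chain, alpha/beta sub-chains, thioester domain, RGD loops).
#' @param pairs two-column character matrix (or list of length-2 vectors)
#'   naming which group pairs to evaluate.
#' @param params a `NonbondedParams`.
#' @return `EnergyReport`: data frame with group_a, group_b, elec, vdw,
#'   total, elec_pct, vdw_pct; metadata records the percent convention.
#' @export
decompose <- function(model, groups, pairs, params = nonbonded_params()) {
  if (is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  }
  rows <- lapply(pairs, function(p) {
    e <- group_energy(model, groups[[p[1]]], groups[[p[2]]], params)
    tot <- sum(e)
    den <- abs(e["elec"]) + abs(e["vdw"])
    data.frame(group_a = p[1], group_b = p[2],
               elec = unname(e["elec"]), vdw = unname(e["vdw"]),
               total = unname(tot),
               elec_pct = if (den > 0) unname(100 * abs(e["elec"]) / den) else NA,
               vdw_pct = if (den > 0) unname(100 * abs(e["vdw"]) / den) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percent_convention") <- "100*|elec|/(|elec|+|vdw|)"
  class(out) <- c("EnergyReport", class(out))
  out
}

#' Residue-pair interaction energy matrix
#'
#' Entry (i, j) is the nonbonded energy between residue i of group A and
#' residue j of group B; row/column sums identify residues in favorable
#' contact. A residue is favorable when its summed interaction with the
#' whole other group is at or below `favorable_threshold`.
#'
#' @param model a `MolecularModel`.
#' @param idx_a,idx_b atom index vectors (residue ranges on each side).
#' @param params a `NonbondedParams`.
#' @param favorable_threshold kcal/mol (default -1).
#' @return list: `matrix` (total energies, dimnames = residue indices),
#'   `elec`, `vdw`, `favorable_a`, `favorable_b` (residue indices), and
#'   `favorable_pairs` (data frame).
#' @export
residue_pair_matrix <- function(model, idx_a, idx_b,
                                params = nonbonded_params(),
                                favorable_threshold = -1) {
  if (length(idx_a) == 0 || length(idx_b) == 0) stop("empty residue range")
  A <- .group_cols(model, idx_a)
  B <- .group_cols(model, idx_b)
  ra <- sort(unique(A$res)); rb <- sort(unique(B$res))
  res <- .cpp_residue_matrix(A$x, A$q, A$e, A$rm, match(A$res, ra),
                             B$x, B$q, B$e, B$rm, match(B$res, rb),
                             length(ra), length(rb),
                             params$coulomb_constant, params$dielectric,
                             params$switch_start, params$cutoff)
  tot <- res$elec + res$vdw
  dimnames(tot) <- dimnames(res$elec) <- dimnames(res$vdw) <-
    list(ra, rb)
  fav_a <- ra[rowSums(tot) <= favorable_threshold]
  fav_b <- rb[colSums(tot) <= favorable_threshold]
  pr <- which(tot <= favorable_threshold, arr.ind = TRUE)
  favorable_pairs <- data.frame(res_a = ra[pr[, 1]], res_b = rb[pr[, 2]],
                                energy = tot[pr])
  list(matrix = tot, elec = res$elec, vdw = res$vdw,
       favorable_a = fav_a, favorable_b = fav_b,
       favorable_pairs = favorable_pairs)
}

#' Relaxation parameters
#'
#' @param max_steps maximum steepest-descent steps.
#' @param step_size initial displacement scale, Angstrom.
#' @param bond_k harmonic bond constant, kcal/(mol*A^2), rest length = bead
#'   spacing.
#' @param bond_r0 bond rest length, Angstrom.
#' @param tol convergence threshold on |delta E|, kcal/mol.
#' @return object of class `RelaxParams`.
#' @export
relax_params <- function(max_steps = 2000, step_size = 0.05, bond_k = 10,
                         bond_r0 = 3.8, tol = 1e-4) {
  stopifnot(step_size > 0)
  structure(list(max_steps = max_steps, step_size = step_size,
                 bond_k = bond_k, bond_r0 = bond_r0, tol = tol),
            class = "RelaxParams")
}

# default fixed set: penton base portions (residues 38-296, 377-571) and all
# hexon atoms; everything else (RGD loops, fiber, C3b) moves
.default_fixed <- function(model) {
  fixed <- rep(FALSE, nrow(model$atoms))
  for (cid in names(model$chains)) {
    role <- model$chains[[cid]]$role
    idx <- which(model$atoms$chain_id == cid)
    if (role == "hexon") fixed[idx] <- TRUE
    if (role == "penton_base") {
      res <- model$atoms$residue_index[idx]
      fixed[idx] <- (res >= 38 & res <= 296) | (res >= 377 & res <= 571)
    }
  }
  fixed
}

#' Steepest-descent relaxation with fixed base atoms
#'
#' Minimizes total nonbonded energy plus harmonic bonds between consecutive
#' residues by steepest descent with a halving line search. Fixed atoms
#' (default: the penton-base body; RGD loops, fiber and C3b move) are
#' displaced exactly zero; the energy trajectory is non-increasing.
#'
#' @param model combined vertex model.
#' @param params a `RelaxParams`.
#' @param nb a `NonbondedParams`.
#' @param fixed logical vector per atom (default from chain roles).
#' @return list: `model` (relaxed), `trajectory` (energies per accepted
#'   step), `steps`, `converged`.
#' @export
relax <- function(model, params = relax_params(), nb = nonbonded_params(),
                  fixed = NULL) {
  if (is.null(fixed)) fixed <- .default_fixed(model)
  a <- model$atoms
  x <- cbind(a$x, a$y, a$z)
  ch <- as.integer(factor(a$chain_id, levels = unique(a$chain_id)))
  # harmonic bonds between consecutive residues of the same chain
  ord <- order(ch, a$residue_index)
  bi <- ord[-length(ord)]; bj <- ord[-1]
  keep <- ch[bi] == ch[bj] & abs(a$residue_index[bj] - a$residue_index[bi]) == 1
  bonds <- cbind(bi[keep], bj[keep])
  mobile <- !fixed
  if (!any(mobile)) stop("mobile set is empty")

  eg <- function(xx, want_grad = TRUE) {
    .cpp_system_energy_gradient(xx, a$charge, a$lj_epsilon, a$lj_rmin,
                                ch, a$residue_index, fixed, bonds,
                                params$bond_k, params$bond_r0,
                                nb$coulomb_constant, nb$dielectric,
                                nb$switch_start, nb$cutoff, nb$exclusion,
                                want_grad)
  }
  cur <- eg(x)
  traj <- cur$energy
  step <- params$step_size
  converged <- FALSE
  nstep <- 0
  while (nstep < params$max_steps) {
    g <- cur$gradient
    g[fixed, ] <- 0
    gmax <- max(abs(g))
    if (gmax < 1e-12) { converged <- TRUE; break }
    moved <- FALSE
    while (step >= 1e-6) {
      xn <- x - g * (step / gmax)
      nxt <- eg(xn)
      if (is.finite(nxt$energy) && nxt$energy <= cur$energy) {
        de <- cur$energy - nxt$energy
        x <- xn; cur <- nxt
        traj <- c(traj, cur$energy)
        nstep <- nstep + 1
        moved <- TRUE
        step <- min(step * 1.5, 1.0)
        if (de < params$tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!moved) {
      if (step < 1e-6) stop("line search underflow below 1e-6 A")
      break
    }
    if (converged) break
  }
  list(model = set_coords(model, x), trajectory = traj, steps = nstep,
       converged = converged)
}

#' Generate starting vertex models with a single C3b
#'
#' Builds `n` vertex models (penton base pentamer + trimeric fiber) with one
#' C3b positioned nearby in a different orientation per pose: the C3b is
#' placed around the vertex at deterministic azimuths with its thioester
#' face toward the vertex proteins.
#'
#' @param spec a `FixtureSpec`.
#' @param n number of starting poses (default 11).
#' @return list of `MolecularModel`s, chains P1-P5, F1-F3, C3b A/B.
#' @export
make_vertex_models <- function(spec = fixture_spec(), n = 11) {
  penton <- make_penton_base(spec)
  fiber <- build_fiber(make_fiber_template(spec),
                       fiber_build_params(rise = spec$shaft_rise_per_repeat,
                                          twist = spec$shaft_twist_per_repeat,
                                          n_total_repeats = spec$n_shaft_repeats))
  fiber <- transform_model(fiber,
                           rt_translation(c(0, 0, spec$calib$penton$height + 1)))
  c3b <- make_c3b(spec)
  # reactive-foot position in the C3b local frame (the lowest face of the
  # thioester domain)
  foot_idx <- select_atoms(c3b, chain = "A", residues = c(1008, 1016),
                           range = TRUE)
  foot_local <- colMeans(coords(c3b, foot_idx))
  out <- list()
  for (k in seq_len(n)) {
    az <- 2 * pi * (k - 1) / n
    # aim the thioester foot just outside an RGD-loop apex, foot pointing
    # inward toward the vertex axis; vary standoff, height and roll per pose
    standoff <- 14 + 8 * ((k - 1) %% 3)
    foot_target <- c(standoff * cos(az), standoff * sin(az),
                     52 + 6 * ((k - 1) %% 4))
    rot <- rt_compose(rt_axis_angle(c(0, 0, 1), az * 180 / pi + 180),
                      rt_axis_angle(c(0, 0, 1), 0))
    tilt <- rt_axis_angle(c(-sin(az), cos(az), 0), 15 * ((k - 1) %% 3 - 1))
    R <- rt_compose(tilt, rot)
    tf <- rigid_transform(R$R, foot_target - as.numeric(R$R %*% foot_local))
    m3 <- transform_model(c3b, tf)
    m3$name <- sprintf("c3b_pose%02d", k)
    mm <- merge_models(list(penton, fiber, m3),
                       name = sprintf("vertex%02d", k), prefix = FALSE)
    out[[k]] <- mm
  }
  out
}

#' Vertex interaction-energy survey
#'
#' Relaxes each vertex model (fixed penton body, mobile RGD loops, fiber
#' and C3b) and reports the total nonbonded interaction energy between C3b
#' and each of the eight vertex chains (P1-P5, F1-F3). Chains out of
#' interaction range report exactly zero. Poses with at least
#' `extensive_chains` chains at or below `extensive_threshold` are flagged
#' as showing extensive interactions.
#'
#' @param vertex_models list from [make_vertex_models()].
#' @param nb a `NonbondedParams`.
#' @param relax_p a `RelaxParams`; `NULL` skips relaxation.
#' @param extensive_threshold kcal/mol (default -40).
#' @param extensive_chains chains required (default 2).
#' @return list: `table` (pose x chain energies), `extensive` (logical),
#'   `relaxed` models.
#' @export
vertex_interaction_survey <- function(vertex_models,
                                      nb = nonbonded_params(),
                                      relax_p = relax_params(max_steps = 300),
                                      extensive_threshold = -40,
                                      extensive_chains = 2) {
  chain_cols <- c(paste0("P", 1:5), paste0("F", 1:3))
  tab <- matrix(0, length(vertex_models), length(chain_cols),
                dimnames = list(vapply(vertex_models, function(m) m$name,
                                       character(1)), chain_cols))
  relaxed <- list()
  for (i in seq_along(vertex_models)) {
    m <- vertex_models[[i]]
    if (!all(c(chain_cols, "A", "B") %in% names(m$chains))) {
      stop("malformed vertex model at row ", i,
           ": need chains P1-P5, F1-F3 and C3b A/B")
    }
    if (!is.null(relax_p)) {
      m <- relax(m, relax_p, nb)$model
    }
    relaxed[[i]] <- m
    c3b_idx <- which(m$atoms$chain_id %in% c("A", "B"))
    for (cc in chain_cols) {
      idx <- which(m$atoms$chain_id == cc)
      e <- group_energy(m, c3b_idx, idx, nb)
      tab[i, cc] <- sum(e)
    }
  }
  extensive <- apply(tab, 1, function(r)
    sum(r <= extensive_threshold) >= extensive_chains)
  list(table = tab, extensive = extensive, relaxed = relaxed)
}
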