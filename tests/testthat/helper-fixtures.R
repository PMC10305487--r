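# Shared fixtures, generated once per test run. Generation is deterministic
# (pure functions of the fixture spec), so caching is purely a speed matter.

.tcache <- new.env(parent = emptyenv())

tspec <- function() fixture_spec()

tkit <- function() {
  if (is.null(.tcache$kit)) .tcache$kit <- make_fixture_kit(tspec())
  .tcache$kit
}

tfacet <- function() {
  if (is.null(.tcache$facet)) {
    k <- tkit()
    .tcache$facet <- assemble_facet(k$hexon, k$penton, k$fiber_template,
                                    tspec())
  }
  .tcache$facet
}

# brute-force all-pairs clash oracle
brute_clashes <- function(ma, mb, params = clash_params()) {
  xa <- coords(ma); xb <- coords(mb)
  ra <- ma$atoms$vdw_radius; rb <- mb$atoms$vdw_radius
  out <- NULL
  for (i in seq_len(nrow(xa))) {
    d <- sqrt(rowSums(sweep(xb, 2, xa[i, ])^2))
    thr <- if (params$use_vdw_radii) ra[i] + rb - params$overlap_tolerance
           else params$hard_cutoff
    hit <- which(d < thr)
    if (length(hit)) out <- rbind(out, cbind(i = i, j = hit, dist = d[hit]))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), dist = numeric())
  else as.data.frame(out)
}

# brute-force nonbonded energy oracle (pairwise sum with the switch)
brute_energy <- function(m, ia, ib, p = nonbonded_params()) {
  a <- m$atoms
  S <- function(r) {
    c2 <- p$cutoff^2; s2 <- p$switch_start^2; r2 <- r^2
    ifelse(r <= p$switch_start, 1, ifelse(r >= p$cutoff, 0,
      (c2 - r2)^2 * (c2 + 2 * r2 - 3 * s2) / (c2 - s2)^3))
  }
  el <- 0; vd <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    if (r >= p$cutoff) next
    if (a$chain_id[i] == a$chain_id[j] &&
        abs(a$residue_index[i] - a$residue_index[j]) <= p$exclusion) next
    el <- el + p$coulomb_constant * a$charge[i] * a$charge[j] /
      (p$dielectric * r) * S(r)
    rmin <- (a$lj_rmin[i] + a$lj_rmin[j]) / 2
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    rr6 <- (rmin / r)^6
    vd <- vd + eps * (rr6^2 - 2 * rr6) * S(r)
  }
  c(elec = el, vdw = vd)
}

# random bead model helper
random_model <- function(n, seed, box = 40, name = "rand") {
  set.seed(seed)
  molecular_model(name, data.frame(
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    charge = sample(c(-1, 0, 1), n, TRUE),
    vdw_radius = 1.7, lj_epsilon = runif(n, 0.05, 0.3),
    lj_rmin = runif(n, 3, 4),
    residue_index = seq_len(n), chain_id = "A"))
}

max_spacing_error <- function(m, spacing = 3.8) {
  errs <- unlist(lapply(names(m$chains), function(cid) {
    idx <- which(m$atoms$chain_id == cid)
    adcomplement:::consecutive_spacings(coords(m, idx)) - spacing
  }))
  max(abs(errs))
}
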