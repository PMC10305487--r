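# Nonbonded energy calculator: closed forms, oracle equivalence, additivity,
# symmetry, invariance; relaxation contract; vertex survey shape.

test_that("Coulomb, LJ minimum and cutoff follow the closed forms", {
  m <- molecular_model("t", data.frame(
    x = c(0, 3.320636), y = 0, z = 0, charge = c(1, -1), vdw_radius = 1.7,
    lj_epsilon = 0, lj_rmin = 3.4, residue_index = 1, chain_id = c("A", "B")))
  e <- group_energy(m, 1, 2)
  expect_equal(unname(e["elec"]), -100, tolerance = 1e-3)
  m2 <- molecular_model("t2", data.frame(
    x = c(0, 3.4), y = 0, z = 0, charge = 0, vdw_radius = 1.7,
    lj_epsilon = c(0.2, 0.05), lj_rmin = 3.4, residue_index = 1,
    chain_id = c("A", "B")))
  expect_equal(unname(group_energy(m2, 1, 2)["vdw"]), -sqrt(0.2 * 0.05),
               tolerance = 1e-10)
  m3 <- molecular_model("t3", data.frame(
    x = c(0, 12.5), y = 0, z = 0, charge = c(1, -1), vdw_radius = 1.7,
    lj_epsilon = 0.1, lj_rmin = 3.4, residue_index = 1,
    chain_id = c("A", "B")))
  expect_identical(sum(abs(group_energy(m3, 1, 2))), 0)
  expect_error(group_energy(m, 1, 1), "disjoint")
})

test_that("grid energy equals the brute-force oracle and is symmetric", {
  m <- random_model(600, seed = 5, box = 45)
  m$atoms$chain_id <- rep(c("A", "B"), each = 300)
  m$chains <- list(A = list(role = "hexon", domains = list()),
                   B = list(role = "hexon", domains = list()))
  ia <- which(m$atoms$chain_id == "A"); ib <- which(m$atoms$chain_id == "B")
  e <- group_energy(m, ia, ib)
  bf <- brute_energy(m, ia, ib)
  expect_equal(unname(e), unname(bf), tolerance = 1e-8)
  e_ba <- group_energy(m, ib, ia)
  expect_equal(unname(e), unname(e_ba), tolerance = 1e-10)
})

test_that("energy is invariant under a global rigid transform", {
  m <- random_model(200, seed = 6, box = 30)
  m$atoms$chain_id <- rep(c("A", "B"), each = 100)
  m$chains <- list(A = list(role = "hexon", domains = list()),
                   B = list(role = "hexon", domains = list()))
  ia <- 1:100; ib <- 101:200
  e0 <- group_energy(m, ia, ib)
  tf <- rt_compose(rt_translation(c(13, -4, 99)),
                   rt_axis_angle(c(1, 1, 2), 77))
  e1 <- group_energy(transform_model(m, tf), ia, ib)
  expect_equal(unname(e0), unname(e1), tolerance = 1e-6)
})

test_that("electrostatics scale linearly with one side's charges", {
  m <- random_model(100, seed = 8, box = 25)
  m$atoms$chain_id <- rep(c("A", "B"), each = 50)
  m$chains <- list(A = list(role = "hexon", domains = list()),
                   B = list(role = "hexon", domains = list()))
  e1 <- group_energy(m, 1:50, 51:100)
  m$atoms$charge[1:50] <- 3 * m$atoms$charge[1:50]
  e3 <- group_energy(m, 1:50, 51:100)
  expect_equal(unname(e3["elec"]), unname(3 * e1["elec"]), tolerance = 1e-8)
  expect_equal(unname(e3["vdw"]), unname(e1["vdw"]), tolerance = 1e-10)
})

test_that("decomposition satisfies the partition identities", {
  kit <- tkit()
  vm <- make_vertex_models(tspec(), 1)[[1]]
  c3b_idx <- which(vm$atoms$chain_id %in% c("A", "B"))
  alpha <- which(vm$atoms$chain_id == "A")
  beta <- which(vm$atoms$chain_id == "B")
  p2 <- which(vm$atoms$chain_id == "P2")
  groups <- list(c3b = c3b_idx, alpha = alpha, beta = beta, P2 = p2)
  rep <- decompose(vm, groups,
                   list(c("c3b", "P2"), c("alpha", "P2"), c("beta", "P2")))
  # alpha + beta additivity
  expect_equal(rep$total[1], rep$total[2] + rep$total[3], tolerance = 1e-6)
  # percent split convention
  nz <- which(rep$total != 0)
  expect_equal(rep$elec_pct[nz] + rep$vdw_pct[nz], rep(100, length(nz)),
               tolerance = 0.1)
})

test_that("base-region energy is exactly zero when only loops are in range", {
  # constructed configuration: a charged probe near a penton RGD apex,
  # beyond cutoff from every base bead
  pn <- make_penton_base(tspec())
  loop <- select_atoms(pn, chain = "P1", domain = "rgd_loop")
  apex <- loop[which.max(pn$atoms$z[loop])]
  probe_pos <- coords(pn)[apex, ] + c(0, 0, 6)
  probe <- data.frame(x = probe_pos[1], y = probe_pos[2], z = probe_pos[3],
                      charge = 1, vdw_radius = 1.7, lj_epsilon = 0.1,
                      lj_rmin = 3.4, residue_index = 1, chain_id = "Q")
  a <- rbind(pn$atoms[, names(probe)], probe)
  a$serial <- seq_len(nrow(a))
  m <- molecular_model("probe_test", a,
                       c(pn$chains, list(Q = list(role = "hexon",
                                                  domains = list()))))
  qi <- which(m$atoms$chain_id == "Q")
  base_idx <- c(select_atoms(m, chain = "P1", domain = "base_n"),
                select_atoms(m, chain = "P1", domain = "base_c"))
  loop_idx <- select_atoms(m, chain = "P1", domain = "rgd_loop")
  e_base <- group_energy(m, qi, base_idx)
  e_loop <- group_energy(m, qi, loop_idx)
  expect_identical(unname(e_base), c(0, 0))   # exact zero by cutoff
  expect_lt(e_loop["elec"], 0)                # attracted to the acidic apex
})

test_that("residue-pair matrix sums to the group energy, flags salt bridges", {
  # engineered salt bridge: one +1/-1 pair at 3 A, everything else neutral
  n <- 12
  a <- data.frame(
    x = c(seq(0, by = 3.8, length.out = n), seq(0, by = 3.8, length.out = n)),
    y = rep(c(0, 30), each = n), z = 0, charge = 0, vdw_radius = 1.7,
    lj_epsilon = 0.1, lj_rmin = 3.4,
    residue_index = rep(1:n, 2), chain_id = rep(c("A", "B"), each = n))
  a$y[n + 5] <- 3          # residue 5 of B moved next to residue 5 of A
  a$charge[5] <- 1; a$charge[n + 5] <- -1
  m <- molecular_model("sb", a,
    list(A = list(role = "hexon", domains = list()),
         B = list(role = "hexon", domains = list())))
  ia <- 1:n; ib <- (n + 1):(2 * n)
  rp <- residue_pair_matrix(m, ia, ib)
  eg <- group_energy(m, ia, ib)
  expect_equal(sum(rp$matrix), unname(sum(eg)), tolerance = 1e-4)
  expect_equal(rp$favorable_pairs$res_a, 5)
  expect_equal(rp$favorable_pairs$res_b, 5)
  expect_equal(rp$favorable_a, 5)
  expect_error(residue_pair_matrix(m, integer(), ib), "empty")
  # all-neutral groups: no favorable sets
  m0 <- m; m0$atoms$charge[] <- 0
  rp0 <- residue_pair_matrix(m0, ia, ib)
  expect_length(rp0$favorable_a, 0)
})

test_that("relaxation is monotone, keeps fixed atoms immobile, converges", {
  vm <- make_vertex_models(tspec(), 1)[[1]]
  rx <- relax(vm, relax_params(max_steps = 40))
  expect_true(all(diff(rx$trajectory) <= 1e-9))
  fixed <- adcomplement:::.default_fixed(vm)
  expect_identical(coords(rx$model)[fixed, ], coords(vm)[fixed, ])
  # an isolated pair at its LJ minimum converges immediately
  m <- molecular_model("min", data.frame(
    x = c(0, 3.4), y = 0, z = 0, charge = 0, vdw_radius = 1.7,
    lj_epsilon = 0.1, lj_rmin = 3.4, residue_index = c(1, 5),
    chain_id = c("A", "B")))
  rx2 <- relax(m, relax_params(max_steps = 50, bond_k = 0), fixed = c(TRUE, FALSE))
  expect_lt(max(abs(coords(rx2$model) - coords(m))), 0.02)
})

test_that("relaxation draws a charged RGD loop toward the thioester face", {
  # charged fixture: C3b positioned so its cationic thioester foot sits
  # within interaction range of P1's acidic RGD apex
  pn <- make_penton_base(tspec())
  c3b <- make_c3b(tspec())
  loop1 <- select_atoms(pn, chain = "P1", domain = "rgd_loop")
  apex <- coords(pn)[loop1[which.max(pn$atoms$z[loop1])], ]
  foot <- select_atoms(c3b, chain = "A", residues = c(1008, 1016),
                       range = TRUE)
  foot_cen <- colMeans(coords(c3b, foot))
  # foot pointing down onto the apex, 9 A above it
  tf <- rt_translation(apex + c(0, 0, 9) - foot_cen)
  vm <- merge_models(list(pn, transform_model(c3b, tf)), name = "charged",
                     prefix = FALSE)
  loop_idx <- select_atoms(vm, chain = "P1", domain = "rgd_loop")
  foot_idx <- select_atoms(vm, chain = "A", residues = c(1008, 1016),
                           range = TRUE)
  d0 <- min(nearest_dist(coords(vm, foot_idx), coords(vm, loop_idx), 200))
  rx <- relax(vm, relax_params(max_steps = 150))
  d1 <- min(nearest_dist(coords(rx$model, foot_idx),
                         coords(rx$model, loop_idx), 200))
  expect_lt(d1, d0)
})

test_that("vertex survey emits the 11 x 8 table with exact zeros", {
  vms <- make_vertex_models(tspec(), 11)
  sv <- vertex_interaction_survey(vms, relax_p = relax_params(max_steps = 25))
  expect_equal(dim(sv$table), c(11, 8))
  expect_equal(colnames(sv$table), c(paste0("P", 1:5), paste0("F", 1:3)))
  # a pose whose C3b is beyond the cutoff from everything: all-zero row,
  # exactly (cutoff zeros are exact, not rounded small values)
  far <- vms[[1]]
  c3b_idx <- which(far$atoms$chain_id %in% c("A", "B"))
  xyz <- coords(far)
  xyz[c3b_idx, 1] <- xyz[c3b_idx, 1] + 800
  far <- set_coords(far, xyz)
  sv_far <- vertex_interaction_survey(list(far), relax_p = NULL)
  expect_identical(unname(sv_far$table[1, ]), rep(0, 8))
  expect_false(sv_far$extensive[1])
  # malformed model -> contract error naming the row
  bad <- vms[[1]]
  bad$chains$P5 <- NULL
  bad$atoms <- bad$atoms[bad$atoms$chain_id != "P5", ]
  expect_error(vertex_interaction_survey(list(bad), relax_p = NULL),
               "malformed")
})
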