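# Structure container, PDB round trip, rigid transforms, superposition,
# clash detection.

test_that("read/write round trip preserves the model exactly", {
  kit <- tkit()
  f <- tempfile(fileext = ".pdb")
  write_structure(kit$penton, f)
  m2 <- read_structure(f)
  expect_equal(n_atoms(m2), n_atoms(kit$penton))
  expect_equal(m2$atoms$chain_id, kit$penton$atoms$chain_id)
  expect_equal(m2$atoms$residue_index, kit$penton$atoms$residue_index)
  expect_lt(max(abs(coords(m2) - coords(kit$penton))), 1e-3)
  # roles and domain annotations travel through the sidecar
  expect_equal(m2$chains$P1$role, "penton_base")
  expect_equal(as.numeric(m2$chains$P1$domains$rgd_loop), c(297, 376))
  # bead parameters restored by bead type
  neg <- m2$atoms$charge[m2$atoms$name == "NEG"]
  expect_true(all(neg == -1))
})

test_that("empty and single-atom files are handled", {
  f <- tempfile(fileext = ".pdb")
  write_structure(molecular_model("empty"), f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 0)
  m1 <- molecular_model("one", data.frame(
    x = 0, y = 0, z = 0, residue_index = 1, chain_id = "A"))
  write_structure(m1, f)
  line <- readLines(f)[1]
  expect_equal(substr(line, 31, 54), "   0.000   0.000   0.000")
})

test_that("malformed ATOM records raise errors naming the line", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A bad12.0      xx   0.000"), f)
  expect_error(read_structure(f), "line 2")
})

test_that("sidecar referencing an absent chain is a reference error", {
  m <- molecular_model("t", data.frame(
    x = 0, y = 0, z = 0, residue_index = 1, chain_id = "A"),
    chains = list(A = list(role = "hexon", domains = list())))
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  side <- jsonlite::read_json(sub("\\.pdb$", ".json", f))
  side$chains$ZZ <- side$chains$A
  jsonlite::write_json(side, sub("\\.pdb$", ".json", f), auto_unbox = TRUE)
  expect_error(read_structure(f), "ZZ")
})

test_that("serial overflow round-trips through hybrid-36 widening", {
  n <- 120000
  m <- molecular_model("big", data.frame(
    x = rep(seq_len(1000) * 4, length.out = n), y = rep(1:120, each = 1000),
    z = 0, residue_index = rep(seq_len(n %/% 48), each = 48, length.out = n),
    chain_id = "A"))
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(n_atoms(m2), n)
  serials <- adcomplement:::hy36_encode(c(99999, 100000, 120000))
  expect_equal(adcomplement:::hy36_decode(serials), c(99999, 100000, 120000))
})

test_that("rigid transforms compose, invert and preserve distances", {
  set.seed(42)
  tfa <- rt_compose(rt_translation(c(3, -2, 7)), rt_axis_angle(c(1, 2, 3), 71))
  tfb <- rt_axis_angle(c(0, 1, 0), -33, center = c(5, 0, 0))
  X <- matrix(rnorm(60), 20, 3)
  # composition associativity on coordinates
  y1 <- rt_apply(rt_compose(tfa, tfb), X)
  y2 <- rt_apply(tfa, rt_apply(tfb, X))
  expect_lt(max(abs(y1 - y2)), 1e-8)
  # inverse(T) o T = identity
  z <- rt_apply(rt_inverse(tfa), rt_apply(tfa, X))
  expect_lt(max(abs(z - X)), 1e-8)
  # distances preserved
  d0 <- as.matrix(dist(X)); d1 <- as.matrix(dist(rt_apply(tfa, X)))
  expect_lt(max(abs(d0 - d1)), 1e-8)
  # rotations orthonormal, det +1
  expect_lt(max(abs(crossprod(tfa$R) - diag(3))), 1e-8)
  expect_equal(det(tfa$R), 1, tolerance = 1e-8)
})

test_that("superposition recovers applied transforms and handles edge cases", {
  set.seed(7)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(P, P)$rmsd, 0, tolerance = 1e-8)
  tf <- rt_compose(rt_translation(c(10, 0, 0)), rt_axis_angle(c(0, 0, 1), 90))
  s <- superpose(P, rt_apply(tf, P))
  expect_lt(s$rmsd, 1e-6)
  expect_lt(max(abs(s$transform$R - tf$R)), 1e-6)
  expect_lt(max(abs(s$transform$t - tf$t)), 1e-6)
  expect_error(superpose(P[1:2, ], P[1:2, ]), "3 points")
  expect_error(superpose(P, P[1:9, ]), "equal length")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition agrees with an independent least-squares oracle", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(30), 10, 3)
  s <- superpose(A, B)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  r_oracle <- sqrt(mean(rowSums((matrix(fitted, 10, 3, byrow = TRUE) - B)^2)))
  expect_equal(s$rmsd, r_oracle, tolerance = 1e-6)
})

test_that("superposition rmsd is invariant to a common rigid motion", {
  set.seed(13)
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  r0 <- superpose(A, B)$rmsd
  g <- rt_compose(rt_translation(c(-4, 9, 2)), rt_axis_angle(c(2, -1, 1), 124))
  r1 <- superpose(rt_apply(g, A), rt_apply(g, B))$rmsd
  expect_equal(r0, r1, tolerance = 1e-6)
})

test_that("clash threshold arithmetic is exact", {
  mk <- function(x) molecular_model("m", data.frame(
    x = x, y = 0, z = 0, residue_index = 1, chain_id = "A"))
  # radii 1.7 + 1.7 - 0.6 = 2.8: no clash at 3.0, clash at 2.7
  expect_equal(nrow(detect_clashes(mk(0), mk(3.0))), 0)
  expect_equal(nrow(detect_clashes(mk(0), mk(2.7))), 1)
  # identical copies: every atom clashes with its twin
  m <- random_model(50, seed = 1)
  cl <- detect_clashes(m, m)
  expect_true(all(seq_len(50) %in% cl$i[cl$dist == 0]))
})

test_that("grid clash detection equals brute force and is symmetric", {
  a <- random_model(500, seed = 2, box = 35)
  b <- random_model(500, seed = 3, box = 35)
  g <- detect_clashes(a, b)
  bf <- brute_clashes(a, b)
  key <- function(d) paste(d$i, d$j)
  expect_setequal(key(g), key(bf))
  g2 <- detect_clashes(b, a)
  expect_setequal(paste(g$i, g$j), paste(g2$j, g2$i))
})

test_that("atom selection by role, domain and residue range works", {
  kit <- tkit()
  hx <- kit$hexon
  expect_length(select_atoms(hx, role = "hexon"),
                n_atoms(hx))
  fx_site <- select_atoms(hx, domain = "fx_site")
  expect_equal(unique(hx$atoms$residue_index[fx_site]), 425)
  rng <- select_atoms(kit$penton, chain = "P1", residues = c(297, 376),
                      range = TRUE)
  expect_equal(length(rng), 80)
})

test_that("model validation rejects broken invariants", {
  expect_error(molecular_model("bad", data.frame(
    serial = c(1, 1), x = 0, y = 0, z = 0,
    residue_index = 1:2, chain_id = "A")), "serial")
  expect_error(molecular_model("bad2", data.frame(
    x = 0, y = 0, z = 0, residue_index = 1, chain_id = "A",
    vdw_radius = -1)), "vdw_radius")
  expect_error(molecular_model("bad3", data.frame(
    x = c(0, 1), y = 0, z = 0, residue_index = c(2, 1), chain_id = "A")),
    "increasing")
  expect_error(molecular_model("bad4", data.frame(
    x = 0, y = 0, z = 0, residue_index = 5, chain_id = "A"),
    chains = list(A = list(role = "hexon", domains = list(d = c(1, 10))))),
    "domain")
})
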