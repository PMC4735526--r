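test_that("PDB parsing: fixed columns, altloc policy, model 1, waters", {
  f <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 1.5, -2.25, 3.125, "C"),
    pdb_line(2, "N", "GLY", "A", 2, 4.0, 0, 0, "N")))
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(1.5, 4.0))
  expect_equal(m$atoms$y, c(-2.25, 0))
  expect_equal(m$atoms$z, c(3.125, 0))
  expect_equal(m$atoms$element, c("C", "N"))

  # altloc: keep blank or 'A', drop 'B'; waters dropped by default
  f2 <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0, "C", alt = "A"),
    pdb_line(3, "CA", "GLY", "A", 2, 9, 0, 0, "C", alt = "B"),
    pdb_line(4, "O", "HOH", "W", 1, 5, 5, 5, "O", type = "HETATM")))
  m2 <- read_pdb(f2)
  expect_equal(nrow(m2$atoms), 2L)
  expect_equal(m2$atoms$x, c(0, 1))

  # multi-model file: model 1 only
  f3 <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
               pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0, "C"),
               "ENDMDL", "MODEL     2",
               pdb_line(1, "CA", "GLY", "A", 1, 7, 7, 7, "C"),
               pdb_line(2, "CA", "GLY", "A", 2, 8, 7, 7, "C"),
               "ENDMDL", "END"), f3)
  m3 <- read_pdb(f3)
  expect_equal(nrow(m3$atoms), 2L)
  expect_equal(m3$atoms$x, c(0, 1))

  f4 <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f4)
  expect_error(read_pdb(f4))
})

test_that("Kabsch superposition is exact under rigid motion", {
  sel <- atom_selection()
  X <- random_blob(10, seed = 1)
  expect_equal(superpose_kabsch(mk_model(X), mk_model(X), sel, sel)$rmsd, 0)

  Y <- X %*% t(rotate_z(37))
  Y <- sweep(Y, 2, c(5, -3, 2), "+")
  fit <- superpose_kabsch(mk_model(X), mk_model(Y), sel, sel)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # the returned transform maps mobile onto target
  moved <- X %*% t(fit$rotation) +
    matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_equal(moved, Y, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion oracle on random pairs", {
  sel <- atom_selection()
  for (i in 1:25) {
    A <- random_blob(10, seed = 100 + i)
    B <- random_blob(10, seed = 200 + i)
    mine <- superpose_kabsch(mk_model(A), mk_model(B), sel, sel)$rmsd
    expect_equal(mine, horn_rmsd(A, B), tolerance = 1e-9)
    # symmetric in its arguments
    expect_equal(superpose_kabsch(mk_model(B), mk_model(A),
                                  sel, sel)$rmsd, mine, tolerance = 1e-9)
    # invariant to a rigid pre-transformation of either structure
    A2 <- sweep(A %*% t(rotate_z(61)), 2, c(-2, 9, 4), "+")
    expect_equal(superpose_kabsch(mk_model(A2), mk_model(B),
                                  sel, sel)$rmsd, mine, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with the bio3d reference implementation", {
  A <- random_blob(20, seed = 51)
  B <- random_blob(20, seed = 52)
  sel <- atom_selection()
  mine <- superpose_kabsch(mk_model(A), mk_model(B), sel, sel)$rmsd
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-4)  # bio3d prints rounded values
})

test_that("atom matching drops unshared residues and errors below 3 atoms", {
  A <- mk_model(random_blob(6, seed = 61), resno = 1:6)
  B <- mk_model(random_blob(6, seed = 62), resno = 4:9)  # 3 shared
  sel <- atom_selection()
  expect_message(fit <- superpose_kabsch(A, B, sel, sel), "dropped")
  expect_equal(fit$n_atoms, 3L)
  C <- mk_model(random_blob(6, seed = 63), resno = 11:16)  # none shared
  expect_error(superpose_kabsch(A, C, sel, sel), "fewer than 3")
})

test_that("dimer RMSD tries both chain pairings and keeps the smaller", {
  a1 <- random_blob(8, seed = 71)
  a2 <- random_blob(8, seed = 72)
  dim1 <- bind_models(mk_model(a1, chain = "A", elety = "CA"),
                      mk_model(a2, chain = "B", elety = "CA"))
  # second structure has the chains relabelled the other way round
  dim2 <- bind_models(mk_model(a1, chain = "B", elety = "CA"),
                      mk_model(a2, chain = "A", elety = "CA"))
  res <- backbone_rmsd(dim1, dim2)
  expect_lt(res$rmsd, 1e-9)
  expect_equal(unname(res$mapping), c("B", "A"))
})

test_that("SASA: analytic sphere, additivity, burial and convergence", {
  one <- mk_model(c(0, 0, 0))
  a <- sum(sasa(one))
  expect_equal(a, 4 * pi * (1.70 + 1.40)^2, tolerance = 0.01)

  two <- mk_model(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sum(sasa(two)), 2 * a, tolerance = 1e-9)

  # atom enclosed by a dense cage is fully buried
  cage <- rbind(c(0, 0, 0), 2.5 * .sphere_points_test(80))
  expect_lt(sasa(mk_model(cage))[1], 1)

  blob <- mk_model(random_blob(20, seed = 81))
  a1 <- sum(sasa(blob, sphere_points = 960))
  a2 <- sum(sasa(blob, sphere_points = 1920))
  expect_lt(abs(a2 - a1) / a1, 0.005)

  strange <- mk_model(c(0, 0, 0), element = "ZN")
  expect_error(sasa(strange), "ZN")
})

test_that("interface area is zero at distance, symmetric, non-negative", {
  ga <- atom_selection(chains = "A")
  gb <- atom_selection(chains = "B")
  far <- bind_models(mk_model(random_blob(10, seed = 91), chain = "A"),
                     mk_model(random_blob(10, seed = 92) + 100,
                              chain = "B"))
  expect_equal(as.numeric(interface_area(far, ga, gb)), 0)

  # symmetric synthetic dimer: two copies of one blob 6 A apart
  blob <- random_blob(15, seed = 93, sd = 2)
  dimer <- bind_models(mk_model(blob, chain = "A"),
                       mk_model(sweep(blob, 2, c(6, 0, 0), "+"),
                                chain = "B"))
  ab <- as.numeric(interface_area(dimer, ga, gb))
  ba <- as.numeric(interface_area(dimer, gb, ga))
  expect_gt(ab, 0)
  expect_equal(ab, ba, tolerance = 1e-9)
  expect_error(interface_area(dimer, ga, ga), "disjoint")
})

test_that("RNA end-to-end distance picks terminal atoms per chain", {
  # two single-nucleotide chains, each with a 5' phosphate and a 3' O3'
  r1 <- bind_models(
    mk_model(c(0, 0, 0), chain = "R", elety = "O3'", element = "O",
             resid = "U", resno = 1),
    mk_model(c(0, 1, 0), chain = "R", elety = "P", element = "P",
             resid = "U", resno = 1))
  r2 <- bind_models(
    mk_model(c(10, 0, 0), chain = "S", elety = "P", element = "P",
             resid = "A", resno = 1),
    mk_model(c(10, 2, 0), chain = "S", elety = "O3'", element = "O",
             resid = "A", resno = 1))
  m <- bind_models(r1, r2)
  d <- rna_end_distance(m, "R", "S")
  expect_equal(unname(d["R_3p_to_S_5p"]), 10)  # O3' (0,0,0) -> P (10,0,0)
  expect_error(rna_end_distance(m, "R", "R"), "distinct")

  # a chain lacking its 3' O3' is reported with the residue
  broken <- bind_models(
    r1, mk_model(c(10, 0, 0), chain = "S", elety = "P", element = "P",
                 resid = "A", resno = 1))
  expect_error(rna_end_distance(broken, "R", "S"), "lacks")
})

test_that("5' terminal atom falls back from P to O5' to C5'", {
  r1 <- bind_models(
    mk_model(c(0, 0, 0), chain = "R", elety = "O3'", element = "O",
             resid = "U", resno = 2),
    mk_model(c(0, 5, 0), chain = "R", elety = "O5'", element = "O",
             resid = "U", resno = 1))
  r2 <- bind_models(
    mk_model(c(8, 0, 0), chain = "S", elety = "O5'", element = "O",
             resid = "A", resno = 1),
    mk_model(c(9, 0, 0), chain = "S", elety = "O3'", element = "O",
             resid = "A", resno = 3))
  m <- bind_models(r1, r2)
  d <- rna_end_distance(m, "R", "S")
  expect_equal(unname(d["R_3p_to_S_5p"]), 8)   # falls back to O5'
  expect_equal(unname(d["S_3p_to_R_5p"]),
               sqrt(9^2 + 5^2))
})
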