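test_that("ideal CG helix has the closed-form chord and extent geometry", {
  # degenerate helix: radius 0 -> straight line along z
  line <- build_ideal_cg_helix(2, radius = 0)
  expect_equal(diff(line$z), 0.15, tolerance = 1e-12)
  expect_true(all(line$x == 0) && all(line$y == 0))

  # 13-mer end-to-end distance: sqrt(rise^2 + chord^2) with the
  # 1200-degree turn folding to a 120-degree chord
  h13 <- build_ideal_cg_helix(13)
  bb <- as.matrix(h13[, c("x", "y", "z")])
  expected <- sqrt((12 * 0.15)^2 + (2 * 0.23 * sin(pi / 3))^2)
  expect_equal(sqrt(sum((bb[13, ] - bb[1, ])^2)), expected, tolerance = 1e-9)

  h25 <- build_ideal_cg_helix(25)
  expect_equal(nrow(h25), 25)
  expect_equal(diff(range(h25$z)), 24 * 0.15, tolerance = 1e-12)

  expect_error(build_ideal_cg_helix(1), "at least 2")
  expect_error(build_ideal_cg_helix(10, rise = -0.1), "positive")
})

test_that("bead structures are validated and canonically ordered", {
  h <- build_ideal_cg_helix(5)
  expect_error(bead_structure(h[, c("chain", "residue", "bead", "x", "y")]),
               "missing columns")
  dup <- rbind(h, h[1, ])
  expect_error(bead_structure(dup), "duplicate")
  bad <- h
  bad$x[1] <- NaN
  expect_error(bead_structure(bad), "finite")
  sc_only <- h
  sc_only$bead[2] <- "SC1"   # residue 2 loses its BB bead
  expect_error(bead_structure(sc_only), "BB bead")
})

test_that("coarse graining places BB beads at COM or exactly at CA", {
  pdb <- synthetic_gpa_dimer()
  atoms <- pdb[pdb$model == 1, names(pdb) != "model"]

  cg_ca <- coarse_grain(atoms, mapping = "CA")
  ca <- atoms[atoms$atom == "CA", ]
  ca <- ca[order(ca$chain, ca$residue), ]
  bb <- cg_ca[cg_ca$bead == "BB", ]
  expect_identical(bb$x, ca$x)   # bit-exact CA trace
  expect_identical(bb$y, ca$y)
  expect_identical(bb$z, ca$z)

  cg_com <- coarse_grain(atoms, mapping = "COM")
  expect_equal(sum(cg_com$bead == "BB"), 50)  # 25 residues x 2 chains
  # COM of backbone heavy atoms, hand-computed for one residue
  r1 <- atoms[atoms$chain == "A" & atoms$residue == 72 &
                atoms$atom %in% c("N", "CA", "C", "O"), ]
  w <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999)[r1$atom]
  bb1 <- cg_com[cg_com$chain == "A" & cg_com$residue == 72 &
                  cg_com$bead == "BB", ]
  expect_equal(bb1$x, sum(w * r1$x) / sum(w), tolerance = 1e-12)
  expect_equal(bb1$z, sum(w * r1$z) / sum(w), tolerance = 1e-12)

  # glycine gets no side-chain bead
  gly <- cg_com[cg_com$resname == "GLY", ]
  expect_true(all(gly$bead == "BB"))

  expect_error(coarse_grain(atoms[atoms$atom != "CA", ], mapping = "CA"),
               "CA atom")
})

test_that("segment truncation keeps exactly the requested residues and is idempotent", {
  pdb <- synthetic_gpa_dimer()
  atoms <- pdb[pdb$model == 1, names(pdb) != "model"]
  cg <- coarse_grain(atoms, "COM")

  tm <- truncate_to_segment(cg, 75, 90)
  expect_equal(sort(unique(tm$residue)), 75:90)
  expect_identical(truncate_to_segment(tm, 75, 90), tm)
  expect_error(truncate_to_segment(cg, 60, 96), "outside")
  expect_error(truncate_to_segment(cg, 80, 120), "outside")
})

test_that("multi-model PDB files round-trip through write and read", {
  pdb <- synthetic_gpa_dimer(n_models = 3, noise_sigma = 0.02, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(pdb, path)

  m1 <- read_pdb_models(path, model = 1)
  expect_equal(attr(m1, "n_models"), 3)
  ref <- pdb[pdb$model == 1, ]
  expect_equal(sort(unique(m1$chain)), c("A", "B"))
  expect_equal(m1$residue, ref$residue)
  # PDB format stores 3 decimals in Angstrom -> 1e-4 nm resolution
  expect_equal(m1$x, ref$x, tolerance = 1e-4)

  m3 <- read_pdb_models(path, model = 3)
  ref3 <- pdb[pdb$model == 3, ]
  expect_equal(m3$z, ref3$z, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(m3$x, ref$x, tolerance = 1e-6)))

  expect_error(read_pdb_models(path, model = 99), "99")
  expect_error(read_pdb_models("no/such/file.pdb"), "no such")
})

test_that("GRO frames round-trip and trajectories validate spacing", {
  h <- build_ideal_cg_helix(10)
  st <- interface_state("s", 10, 20, -30, 1.0)
  fr <- place_dimer(h, h, st)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, path, box = c(8, 8, 8))
  back <- read_gro(path)
  expect_equal(back$beads$x, fr$x, tolerance = 1e-3)  # %8.3f resolution
  expect_equal(back$beads$chain, fr$chain)
  expect_equal(back$box, c(8, 8, 8))

  traj <- data.frame(frame = rep(1:3, each = 2), time = rep(c(0, 1, 2.5), each = 2))
  expect_error(as_trajectory(traj), "uniformly spaced")
  traj$time <- rep(c(0, 1, 2), each = 2)
  expect_equal(trajectory_dt(as_trajectory(traj)), 1)
})

test_that("ideal helix geometry is preserved under rigid-body transforms", {
  h <- build_ideal_cg_helix(25)
  R <- tmdimer:::rot_z(47) %*% tmdimer:::rot_x(-31)
  moved <- tmdimer:::transform_coords(h, R, c(0.3, -1.2, 2.0))
  fit <- tmdimer:::kabsch(as.matrix(moved[, c("x", "y", "z")]),
                          as.matrix(h[, c("x", "y", "z")]))
  back <- tmdimer:::apply_kabsch(as.matrix(moved[, c("x", "y", "z")]), fit)
  rmsd <- sqrt(mean(rowSums((back - as.matrix(h[, c("x", "y", "z")]))^2)))
  expect_lt(rmsd, 1e-9)
})
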