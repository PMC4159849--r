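test_that("helix-axis fitting is exact on ideal helices and equivariant", {
  # collinear beads -> line direction
  line <- build_ideal_cg_helix(10, radius = 0)
  f <- fit_helix_axis(line)
  expect_equal(f$axis, c(0, 0, 1), tolerance = 1e-12)

  # ideal helix -> construction axis, despite non-integer turns
  h <- build_ideal_cg_helix(25)
  expect_equal(fit_helix_axis(h)$axis, c(0, 0, 1), tolerance = 1e-9)

  # equivariance under a known rotation
  R <- tmdimer:::rot_x(25) %*% tmdimer:::rot_z(110)
  moved <- tmdimer:::transform_coords(h, R)
  expect_equal(fit_helix_axis(moved)$axis, as.numeric(R %*% c(0, 0, 1)),
               tolerance = 1e-6)
  expect_error(fit_helix_axis(h[1:2, ]), "at least 3")
})

test_that("crossing angle: sign convention, chirality and rigid invariance", {
  h <- build_ideal_cg_helix(25)
  fr <- place_dimer(h, h, interface_state("s", 10, 40, -40, 1.0))
  expect_equal(as.numeric(crossing_angle(fr)), -40, tolerance = 1e-6)

  # parallel axes -> 0 with the parallel flag
  par <- place_dimer(h, h, interface_state("p", 0, 0, 0, 1.5))
  expect_true(attr(crossing_angle(par), "parallel"))

  # mirror reflection flips the sign (chirality)
  mir <- fr
  mir$y <- -mir$y
  expect_equal(as.numeric(crossing_angle(mir)), 40, tolerance = 1e-6)

  # invariance under rigid-body transforms of the whole frame
  R <- tmdimer:::rot_z(77) %*% tmdimer:::rot_x(-13)
  moved <- tmdimer:::transform_coords(fr, R, c(2, -1, 0.5))
  expect_equal(as.numeric(crossing_angle(moved)), -40, tolerance = 1e-6)
})

test_that("tilt angle folds into [0, 90] and matches constructed tilts", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_equal(tilt_angle(c(0, 0, -1)), 0)   # folded

  h <- build_ideal_cg_helix(25)
  tilted <- tmdimer:::transform_coords(h, tmdimer:::rot_x(25))
  expect_equal(tilt_angle(tilted), 25, tolerance = 1e-6)
  # signed variant carries the tilt-direction sign
  tx <- tmdimer:::transform_coords(h, tmdimer:::rot_x(90 - 65))  # tilt toward -y
  expect_equal(abs(tilt_angle(fit_helix_axis(tx)$axis, signed = TRUE)), 25,
               tolerance = 1e-6)
  expect_error(tilt_angle(c(0, 0, 0)), "zero vector")
})

test_that("helix length series matches closed-form helix geometry", {
  # straight line, rise 0.15 -> i,i+12 distance exactly 1.80 nm
  line <- build_ideal_cg_helix(25, radius = 0)
  line$frame <- 1L; line$time <- 0
  hl <- helix_length_series(line)
  expect_equal(unique(round(hl$lengths$length, 12)), 1.8)

  # ideal helix: chord + rise closed form
  h <- build_ideal_cg_helix(25)
  h$frame <- 1L; h$time <- 0
  hl2 <- helix_length_series(h)
  expected <- sqrt((12 * 0.15)^2 + (2 * 0.23 * sin(pi / 3))^2)
  expect_equal(unique(round(hl2$lengths$length, 9)),
               round(expected, 9))
  expect_equal(nrow(hl2$lengths), 25 - 12)

  # noiseless trajectory -> zero-variance distribution
  expect_equal(sd(hl2$lengths$length), 0)
  expect_equal(sum(hl2$distribution$prob), 1, tolerance = 1e-12)

  short <- build_ideal_cg_helix(10)
  short$frame <- 1L; short$time <- 0
  expect_error(helix_length_series(short), "shorter")
})

test_that("CA and COM mappings give different helix-length distributions", {
  pdb <- synthetic_gpa_dimer()
  atoms <- pdb[pdb$model == 1 & pdb$chain == "A", names(pdb) != "model"]
  br <- seq(1.2, 2.6, 0.01)
  len_of <- function(mapping) {
    cg <- coarse_grain(atoms, mapping)
    cg$chain <- "A"
    cg$frame <- 1L; cg$time <- 0
    helix_length_series(cg, breaks = br)
  }
  ca <- len_of("CA")
  com <- len_of("COM")
  expect_gt(distribution_difference(ca$distribution, com$distribution), 0)
  expect_false(isTRUE(all.equal(mean(ca$lengths$length),
                                mean(com$lengths$length), tolerance = 1e-6)))
})

test_that("distribution difference is the hand-summed L1 on shared bins", {
  br <- seq(0, 1, 0.25)
  p <- structure(list(breaks = br, prob = c(0.5, 0.5, 0, 0),
                      mapping_mode = NA), class = "length_distribution")
  q <- structure(list(breaks = br, prob = c(0.25, 0.25, 0.5, 0),
                      mapping_mode = NA), class = "length_distribution")
  expect_equal(distribution_difference(p, p), 0)
  expect_equal(distribution_difference(p, q), 0.25 + 0.25 + 0.5)
  disjoint <- structure(list(breaks = br, prob = c(0, 0, 0.5, 0.5),
                             mapping_mode = NA), class = "length_distribution")
  expect_equal(distribution_difference(p, disjoint), 2)  # L1 maximum
  expect_equal(distribution_difference(p, q, metric = "l2"),
               sqrt(0.25^2 + 0.25^2 + 0.5^2))
  expect_equal(distribution_difference(p, q, scale = 100), 100)
  bad <- structure(list(breaks = br + 1, prob = q$prob, mapping_mode = NA),
                   class = "length_distribution")
  expect_error(distribution_difference(p, bad), "binning")
})

test_that("density projection is invariant under per-frame rigid motions", {
  model <- planted_model(noise_sigma = 0, seed = 29)
  sim <- simulate_interface_markov(model, duration = 500, dt = 50)
  traj <- sim$trajectory

  dp <- density_projection(traj, bins = 30)
  # rigidly move every frame after the first (the first frame fixes the
  # reference orientation of the projection)
  moved <- dplyr::bind_rows(lapply(sort(unique(traj$frame)), function(f) {
    fr <- trajectory_frame(traj, f)
    if (f == min(traj$frame)) return(fr)
    R <- tmdimer:::rot_z(f * 31) %*% tmdimer:::rot_x(f * 7)
    tmdimer:::transform_coords(fr, R, c(f, -f, 0.1 * f))
  }))
  dp2 <- density_projection(moved, bins = 30)
  expect_equal(dp$counts, dp2$counts)

  # planted two-state data produce occupancy away from a single blob:
  # mass at the two planted interface azimuths
  expect_gt(sum(dp$counts), 0)
})
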