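test_that("place_dimer is the construction oracle for the crossing angle", {
  h <- build_ideal_cg_helix(25)
  for (ang in c(-40, -32.05, 0, 25, 170)) {
    st <- interface_state("s", phiA = 30, phiB = -60,
                          crossing_angle = ang, separation = 1.2)
    fr <- place_dimer(h, h, st)
    expect_equal(as.numeric(crossing_angle(fr)), ang, tolerance = 1e-6)
  }
  # parallel placement -> zero angle, flagged
  fr0 <- place_dimer(h, h, interface_state("p", 0, 0, 0, 1.2))
  a0 <- crossing_angle(fr0)
  expect_equal(as.numeric(a0), 0, tolerance = 1e-9)

  # helices 5 nm apart cannot touch at a 0.6 nm cutoff
  far <- place_dimer(h, h, interface_state("far", 0, 0, -40, 5))
  expect_equal(count_contacts(compute_contact_map(far)), 0)

  # overlapping placement warns rather than errors
  expect_warning(place_dimer(h, h, interface_state("ov", 0, 0, 0, 0.05)),
                 "overlap")
  expect_error(interface_state("bad", separation = -1), "positive")
  expect_error(interface_state("bad", phiA = 181), "-180")
})

test_that("markov model invariants are enforced", {
  sts <- planted_states()
  P_ok <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_s3_class(markov_interface_model(sts[1:2], P_ok, c(10, 20)),
                  "markov_interface_model")
  expect_error(markov_interface_model(sts[1:2], matrix(0.5, 2, 2), c(10, 20)),
               "zero diagonal")
  expect_error(markov_interface_model(sts[1:2], P_ok * 0.9, c(10, 20)),
               "sum to 1")
  expect_error(markov_interface_model(sts[1:2], P_ok, c(10, -1)), "positive")
  expect_error(condition_spec("x", c(0.5, 0.4)), "probability")
})

test_that("markov switching reproduces planted dwell times and is seed-reproducible", {
  sts <- planted_states()[1:2]
  P <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  model <- markov_interface_model(sts, P, mean_dwell = c(100, 50), seed = 11)

  sim <- simulate_interface_markov(model, duration = 1e5, dt = 1,
                                   coordinates = FALSE)
  ret <- retention_times(sim$labels$state, dt = 1)
  s <- ret$summary
  for (k in 1:2) {
    mu <- c(nmrlike = 100, parallel = 50)[s$cluster[k]]
    se <- mu / sqrt(s$n_dwells[k])
    expect_lt(abs(s$mean_dwell[k] - mu), 3 * se)
  }

  # single state: retention is the whole duration
  m1 <- markov_interface_model(sts[1], matrix(0, 1, 1), 100, seed = 2)
  sim1 <- simulate_interface_markov(m1, duration = 500, dt = 10,
                                    coordinates = FALSE)
  expect_true(all(sim1$labels$state == "nmrlike"))
  r1 <- retention_times(sim1$labels$state, dt = 10)
  expect_equal(nrow(r1$dwells), 1)
  expect_equal(r1$dwells$duration, 510)  # 51 stored frames x 10 ns

  # determinism
  a <- simulate_interface_markov(model, 1000, 10, seed = 99)
  b <- simulate_interface_markov(model, 1000, 10, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("condition assemblies draw from the planted state frequencies", {
  cond <- condition_spec("DUPC-like", c(0.5, 0.3, 0.2))
  draws <- sample_condition_assemblies(cond, 1e5, seed = 3)
  freq <- frequency_vector(draws, c("1", "2", "3"))
  expect_equal(unname(freq), c(0.5, 0.3, 0.2), tolerance = 0.01)

  degenerate <- condition_spec("pure", c(1, 0, 0))
  expect_true(all(sample_condition_assemblies(degenerate, 300, seed = 1) == "1"))

  expect_identical(sample_condition_assemblies(cond, 50, seed = 8),
                   sample_condition_assemblies(cond, 50, seed = 8))
})

test_that("re-analysis closure: clustering recovers the planted states exactly", {
  model <- planted_model(seed = 13)
  sim <- simulate_interface_markov(model, duration = 4000, dt = 50)
  maps <- lapply(sort(unique(sim$trajectory$frame)), function(f) {
    compute_contact_map(trajectory_frame(sim$trajectory, f))
  })
  # precondition of the property: states pairwise-separated under dice
  refs <- lapply(planted_states(), state_map)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(dice_dissimilarity(as.logical(refs[[i]]), as.logical(refs[[j]])),
              0.5)
  }
  cl <- cluster_interfaces(maps, filter_min_contacts = FALSE)
  expect_equal(length(cl$cluster_sizes), 3)
  expect_true(same_partition(cl$labels, sim$labels$state))

  # planted transition counts match the number of label changes exactly
  lab <- sim$labels$state
  net <- build_transition_net(list(lab), node_set = unique(lab),
                              min_count = 1)
  expect_equal(sum(net$edges$count), sum(lab[-1] != lab[-length(lab)]))
})

test_that("markov model round-trips through YAML configuration", {
  cfg <- list(
    states = list(
      list(id = "a", phiA = 0, phiB = 180, crossing_angle = -40, separation = 0.56),
      list(id = "b", phiA = 120, phiB = -60, crossing_angle = 0, separation = 0.56)
    ),
    transition_matrix = list(c(0, 1), c(1, 0)),
    mean_dwell = c(100, 50), noise_sigma = 0.03, seed = 4
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  model <- markov_model_from_yaml(path)
  expect_equal(length(model$states), 2)
  expect_equal(model$states[[1]]$crossing_angle, -40)
  expect_equal(model$mean_dwell, c(100, 50))
  expect_equal(model$noise_sigma, 0.03)
})
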