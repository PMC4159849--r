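test_that("dice dissimilarity matches its formula, hand cases and vegan", {
  expect_equal(dice_dissimilarity(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               0.5)   # (1+1) / (2*1 + 1 + 1)
  expect_equal(dice_dissimilarity(c(TRUE, TRUE), c(TRUE, TRUE)), 0)
  expect_equal(dice_dissimilarity(c(TRUE, FALSE), c(FALSE, TRUE)), 1)
  expect_error(dice_dissimilarity(c(FALSE, FALSE), c(FALSE, FALSE)),
               "undefined")
  expect_error(dice_dissimilarity(c(TRUE), c(TRUE, FALSE)), "equal length")

  # symmetry + bounds on random vectors, and agreement with an independent
  # implementation (vegan's binary Bray-Curtis is Dice)
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:20) {
    u <- runif(40) < 0.3
    v <- runif(40) < 0.3
    if (!any(u) || !any(v)) next
    d1 <- dice_dissimilarity(u, v)
    d2 <- dice_dissimilarity(v, u)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    dv <- as.numeric(vegan::vegdist(rbind(u, v), method = "bray",
                                    binary = TRUE))
    expect_equal(d1, dv, tolerance = 1e-12)
  }
})

test_that("UPGMA interface clustering matches a brute-force oracle", {
  # prototype-derived maps: merges on both sides of the 0.5 cutoff
  for (seed in c(1, 2, 5)) {
    maps <- proto_maps(seed = seed)
    cl <- cluster_interfaces(maps, filter_min_contacts = FALSE)
    flat <- t(sapply(maps, as.logical))
    D <- as.matrix(tmdimer:::dice_distance_matrix(flat))
    oracle <- brute_force_upgma(D, cutoff = 0.5)
    expect_true(same_partition(cl$labels, oracle))
    expect_equal(length(cl$cluster_sizes), length(unique(oracle)))
  }
  # fully separated random maps stay singletons (all dice > 0.5)
  sing <- random_maps(12, seed = 42)
  cls <- cluster_interfaces(sing, filter_min_contacts = FALSE)
  D2 <- as.matrix(tmdimer:::dice_distance_matrix(t(sapply(sing, as.logical))))
  expect_true(same_partition(cls$labels, brute_force_upgma(D2, 0.5)))

  # a tree with floating-point height jitter still cuts cleanly
  maps7 <- proto_maps(seed = 7)
  expect_silent(cl7 <- cluster_interfaces(maps7, filter_min_contacts = FALSE))
  D7 <- as.matrix(tmdimer:::dice_distance_matrix(t(sapply(maps7, as.logical))))
  expect_true(same_partition(cl7$labels, brute_force_upgma(D7, 0.5)))
})

test_that("degenerate clustering cases behave as forced", {
  m <- state_map(planted_states()[[1]])
  same <- replicate(6, m, simplify = FALSE)
  cl1 <- cluster_interfaces(same)
  expect_equal(length(cl1$cluster_sizes), 1)
  expect_true(all(cl1$labels == 1))

  m2 <- state_map(planted_states()[[2]])
  two <- c(replicate(4, m, simplify = FALSE), replicate(3, m2, simplify = FALSE))
  # groups are not fully disjoint in contacts, but well past the cutoff
  cl2 <- cluster_interfaces(two)
  expect_equal(length(cl2$cluster_sizes), 2)
  # ids ordered by decreasing size: the 4-member group is cluster 1
  expect_true(all(cl2$labels[1:4] == 1) && all(cl2$labels[5:7] == 2))

  # maps below the 19-contact threshold are excluded with NA labels
  sparse <- matrix(FALSE, 25, 25)
  sparse[cbind(1:5, 1:5)] <- TRUE
  cl3 <- cluster_interfaces(c(two, list(sparse)))
  expect_true(is.na(cl3$labels[8]))
  expect_equal(sum(cl3$kept), 7)
  expect_error(cluster_interfaces(list(sparse)), "survive")
})

test_that("cluster labels are invariant under input permutation", {
  maps <- random_maps(10, p = 0.15, seed = 31)
  cl <- cluster_interfaces(maps, filter_min_contacts = FALSE)
  set.seed(1)
  perm <- sample(10)
  cl_p <- cluster_interfaces(maps[perm], filter_min_contacts = FALSE)
  expect_true(same_partition(cl$labels[perm], cl_p$labels))
})

test_that("frequency tables conserve counts, recover planted proportions and lump small clusters", {
  # one condition, one cluster
  f1 <- cluster_frequencies(c(1L, 1L, 1L), rep("x", 3))
  expect_equal(f1$prop, 1)

  # planted condition distributions recovered within sampling error
  cond <- condition_spec("dupc", c(0.6, 0.3, 0.1))
  draws <- sample_condition_assemblies(cond, 1e5, seed = 17)
  tab <- cluster_frequencies(draws, rep("dupc", length(draws)))
  expect_equal(sort(tab$prop, decreasing = TRUE), c(0.6, 0.3, 0.1),
               tolerance = 0.01)
  expect_equal(sum(tab$n), 1e5)   # conservation

  # min-count rule: a 2-member cluster lands in "others"
  labels <- c(rep(1L, 5), rep(2L, 2))
  t2 <- cluster_frequencies(labels, rep("x", 7), min_count = 3)
  expect_true("others" %in% t2$cluster)
  expect_equal(t2$n[t2$cluster == "others"], 2)
  expect_equal(sum(t2$n), 7)

  expect_error(cluster_frequencies(labels, rep("x", 3)), "one entry per")
})

test_that("contact frequency maps are entrywise member means", {
  m <- state_map(planted_states()[[1]])
  m2 <- m
  flip <- which(as.logical(m))[1]
  m2[flip] <- FALSE

  labels_obj <- cluster_interfaces(list(m, m2), filter_min_contacts = FALSE)
  cf <- contact_frequency_map(labels_obj, 1L, list(m, m2))
  expect_equal(attr(cf, "n_members"), 2)
  expect_equal(cf[flip], 0.5)
  expect_true(all(cf >= 0 & cf <= 1))

  single <- cluster_interfaces(list(m), filter_min_contacts = FALSE)
  cf1 <- contact_frequency_map(single, 1L, list(m))
  expect_equal(unname(cf1[, ]), unname(unclass(m)[, ] * 1))
  expect_error(contact_frequency_map(single, 7L, list(m)), "no cluster")

  # planted-state cluster frequency map approaches the noiseless map
  model <- planted_model(seed = 23)
  sim <- simulate_interface_markov(model, duration = 3000, dt = 50)
  maps <- lapply(sort(unique(sim$trajectory$frame)), function(f) {
    compute_contact_map(trajectory_frame(sim$trajectory, f))
  })
  cl <- cluster_interfaces(maps, filter_min_contacts = FALSE)
  big <- as.integer(names(which.max(cl$cluster_sizes)))
  cfm <- contact_frequency_map(cl, big, maps)
  # the dominant cluster matches one planted state map closely
  agreement <- sapply(planted_states(), function(s) {
    ref <- state_map(s)
    mean((cfm > 0.5) == unclass(ref)[, ])
  })
  expect_gt(max(agreement), 0.98)
})
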