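# shared fixtures: planted interface states, random contact maps, and
# brute-force oracles used by several test files

# three well-separated planted interface states (pairwise dice of their
# noiseless maps > 0.5, within-state dice under sigma = 0.05 well below 0.5,
# each map carrying >= 19 contacts)
planted_states <- function() {
  list(
    interface_state("nmrlike", phiA = 0, phiB = 180,
                    crossing_angle = -40, separation = 0.56),
    interface_state("parallel", phiA = 120, phiB = -60,
                    crossing_angle = 0, separation = 0.56),
    interface_state("lefty", phiA = -120, phiB = 60,
                    crossing_angle = 30, separation = 0.56)
  )
}

planted_model <- function(mean_dwell = c(300, 200, 250), noise_sigma = 0.05,
                          seed = 7L) {
  P <- matrix(c(0, .5, .5,
                .5, 0, .5,
                .5, .5, 0), 3, 3, byrow = TRUE)
  markov_interface_model(planted_states(), P, mean_dwell,
                         noise_sigma = noise_sigma, seed = seed)
}

# noiseless contact map of a planted state
state_map <- function(state, helix = build_ideal_cg_helix(25)) {
  suppressWarnings(compute_contact_map(place_dimer(helix, helix, state)))
}

# random boolean contact maps with enough density that dice is defined
random_maps <- function(n, dim = 25, p = 0.08, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    matrix(runif(dim * dim) < p, dim, dim)
  })
}

# 12 maps derived from 3 random prototypes (4 noisy copies each), so that
# the UPGMA tree has merges on both sides of the 0.5 cutoff
proto_maps <- function(seed = 1, n_protos = 3, copies = 4, flips = 18) {
  set.seed(seed)
  protos <- lapply(seq_len(n_protos), function(i) {
    matrix(runif(625) < 0.12, 25, 25)
  })
  maps <- list()
  for (p in protos) {
    for (r in seq_len(copies)) {
      m <- p
      fl <- sample(625, flips)
      m[fl] <- !m[fl]
      maps[[length(maps) + 1]] <- m
    }
  }
  maps
}

# brute-force UPGMA: repeatedly merge the two clusters with the smallest
# average pairwise (original-space) distance; flat clusters = state of the
# partition once the smallest inter-cluster average exceeds the cutoff
brute_force_upgma <- function(D, cutoff) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  avg_dist <- function(a, b) mean(D[a, b])
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        d <- avg_dist(clusters[[i]], clusters[[j]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# minimal MARTINI-like ITP for a 25-residue helix (BB beads + a few SC)
toy_itp_lines <- function(n_res = 25) {
  atoms <- character(0)
  nr <- 0
  for (i in seq_len(n_res)) {
    nr <- nr + 1
    atoms <- c(atoms, sprintf("%5d %5s %5d %5s %5s %5d %8.4f",
                              nr, "P5", i, "ALA", "BB", nr, 0))
    if (i %% 3 == 0) {
      nr <- nr + 1
      atoms <- c(atoms, sprintf("%5d %5s %5d %5s %5s %5d %8.4f",
                                nr, "C1", i, "ALA", "SC1", nr, 0))
    }
  }
  bb_nr <- which(grepl(" BB ", atoms))
  bonds <- sprintf("%6d %6d %6d %8.3f %10.1f", bb_nr[-length(bb_nr)],
                   bb_nr[-1], 1L, 0.31, 1250)
  c("; toy coarse-grained helix topology",
    "[ moleculetype ]", "; name nrexcl", "HELIX 1", "",
    "[ atoms ]", atoms, "",
    "[ bonds ]", bonds)
}
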