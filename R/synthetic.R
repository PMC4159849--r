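#' Planted interface states
#'
#' An interface state is a discrete dimer architecture, parameterized by the
#' azimuthal rotation of each helix about its own axis (`phiA`, `phiB`,
#' degrees), the signed crossing angle between the helix axes (degrees,
#' negative = right-handed) and the inter-axis separation at closest
#' approach (nm).  The synthetic generator switches a two-helix system among
#' a small set of such states to emulate the discrete interface clusters
#' seen in self-assembly simulations.
#'
#' @param state_id label of the state.
#' @param phiA,phiB azimuthal rotations, degrees in (-180, 180].
#' @param crossing_angle signed crossing angle, degrees in (-180, 180].
#' @param separation inter-axis distance, nm (> 0).
#' @return An object of class `interface_state`.
#' @export
interface_state <- function(state_id, phiA = 0, phiB = 0,
                            crossing_angle = 0, separation = 0.7) {
  for (a in c(phiA, phiB, crossing_angle)) {
    if (a <= -180 || a > 180) abort("angles must lie in (-180, 180]")
  }
  if (separation <= 0) abort("separation must be positive")
  structure(list(state_id = state_id, phiA = phiA, phiB = phiB,
                 crossing_angle = crossing_angle, separation = separation),
            class = "interface_state")
}

#' Markov model over interface states
#'
#' Continuous-time Markov switching: the dimer dwells in each state for an
#' exponential time with the state's `mean_dwell` (ns), then jumps to
#' another state according to the row-stochastic embedded `transition_matrix`
#' (zero diagonal).  Frames are rendered from the current state by
#' [place_dimer()] plus isotropic Gaussian bead noise.
#'
#' @param states list of [interface_state()] objects.
#' @param transition_matrix k x k row-stochastic matrix, zero diagonal.
#' @param mean_dwell per-state mean dwell times, ns.
#' @param noise_sigma isotropic per-bead coordinate noise sd, nm.
#' @param seed default RNG seed used by [simulate_interface_markov()].
#' @return An object of class `markov_interface_model`.
#' @export
markov_interface_model <- function(states, transition_matrix, mean_dwell,
                                   noise_sigma = 0.05, seed = 1L) {
  k <- length(states)
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(k, k))) {
    abort("transition matrix dimensions must match the number of states")
  }
  if (k > 1) {
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
      abort("transition matrix rows must sum to 1")
    }
    if (any(abs(diag(transition_matrix)) > 0)) {
      abort("transition matrix must have a zero diagonal")
    }
  }
  if (length(mean_dwell) != k || any(mean_dwell <= 0)) {
    abort("mean_dwell must be positive, one value per state")
  }
  structure(list(states = states, transition_matrix = transition_matrix,
                 mean_dwell = mean_dwell, noise_sigma = noise_sigma,
                 seed = seed),
            class = "markov_interface_model")
}

#' Condition-specific interface-state frequencies
#'
#' A condition emulates a membrane environment (for example one lipid
#' species) through its stationary distribution over interface states.
#'
#' @param condition_id label (e.g. a lipid name).
#' @param state_frequencies probability vector over the model's states.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(condition_id, state_frequencies) {
  if (any(state_frequencies < 0) ||
      abs(sum(state_frequencies) - 1) > 1e-12) {
    abort("state frequencies must be a probability vector")
  }
  structure(list(condition_id = condition_id,
                 state_frequencies = state_frequencies),
            class = "condition_spec")
}

#' Place two helices into a dimer frame
#'
#' Helix A is placed with its axis along z through the origin, rotated by
#' `phiA` about its own axis.  Helix B is rotated by `phiB` about its own
#' axis, rotated by the signed crossing angle about the x axis, and shifted
#' by `separation` along x.  The construction is the oracle for the signed
#' crossing angle: [crossing_angle()] measured on the returned frame equals
#' `state$crossing_angle`.
#'
#' @param helixA,helixB bead (or atom) tibbles built along z, e.g. from
#'   [build_ideal_cg_helix()]; chain labels are forced to `"A"` / `"B"`.
#' @param state an [interface_state()].
#' @return A single-frame bead tibble of both chains.
#' @export
place_dimer <- function(helixA, helixB, state) {
  if (length(unique(helixA$residue)) != length(unique(helixB$residue))) {
    abort("helices must have equal residue counts")
  }
  a <- transform_coords(helixA, rot_z(state$phiA))
  a$chain <- "A"
  b <- transform_coords(helixB, rot_x(state$crossing_angle) %*% rot_z(state$phiB),
                        shift = c(state$separation, 0, 0))
  b$chain <- "B"
  out <- bind_rows(a, b)
  da <- as.matrix(a[, c("x", "y", "z")])
  db <- as.matrix(b[, c("x", "y", "z")])
  dmin <- sqrt(min(outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * da %*% t(db)))
  if (is.finite(dmin) && dmin < 0.1) {
    warn(sprintf("placed helices overlap (min bead distance %.3f nm)", dmin))
  }
  out
}

# internal: piecewise-constant state path of the continuous-time chain
simulate_markov_path <- function(model, duration) {
  k <- length(model$states)
  s <- sample.int(k, 1)
  t0 <- 0
  starts <- numeric(0)
  states <- integer(0)
  while (t0 < duration) {
    starts <- c(starts, t0)
    states <- c(states, s)
    t0 <- t0 + rexp(1, rate = 1 / model$mean_dwell[s])
    if (k > 1) s <- sample.int(k, 1, prob = model$transition_matrix[s, ])
  }
  list(starts = starts, states = states)
}

#' Simulate a two-helix trajectory with Markov interface switching
#'
#' Draws a continuous-time Markov state path (exponential dwell times,
#' embedded-chain jumps), stores frames every `dt` ns, renders each stored
#' frame with [place_dimer()] for the state active at the frame time and
#' adds isotropic Gaussian bead noise.  Jumps are resolved at frame
#' resolution: excursions shorter than `dt` that fall between stored frames
#' are not represented.
#'
#' @param model a [markov_interface_model()].
#' @param duration total time, ns.
#' @param dt frame spacing, ns.
#' @param helixA,helixB template helices (defaults: ideal 25-residue CG
#'   helices).
#' @param seed RNG seed (default: the model's seed).  Identical seeds give
#'   bit-identical trajectories.
#' @param coordinates if `FALSE`, only the state labels are generated
#'   (fast path for kinetic statistics).
#' @return List with `trajectory` (bead tibble with frame/time columns; or
#'   `NULL`) and `labels`, a tibble (frame, time, state) of ground-truth
#'   state ids per stored frame.
#' @export
simulate_interface_markov <- function(model, duration, dt,
                                      helixA = NULL, helixB = NULL,
                                      seed = NULL, coordinates = TRUE) {
  if (duration < dt) abort("duration must be at least dt")
  set.seed(seed %||% model$seed)
  path <- simulate_markov_path(model, duration)
  times <- seq(0, duration, by = dt)
  idx <- findInterval(times, path$starts)
  state_ids <- vapply(model$states, function(s) as.character(s$state_id), "")
  labels <- tibble(frame = seq_along(times), time = times,
                   state = state_ids[path$states[idx]])
  traj <- NULL
  if (coordinates) {
    helixA <- helixA %||% build_ideal_cg_helix(25)
    helixB <- helixB %||% build_ideal_cg_helix(25)
    placed <- map(model$states, function(s) place_dimer(helixA, helixB, s))
    frames <- map(seq_along(times), function(f) {
      fr <- placed[[path$states[idx[f]]]]
      n <- nrow(fr)
      fr$x <- fr$x + rnorm(n, sd = model$noise_sigma)
      fr$y <- fr$y + rnorm(n, sd = model$noise_sigma)
      fr$z <- fr$z + rnorm(n, sd = model$noise_sigma)
      fr$frame <- f
      fr$time <- times[f]
      fr
    })
    traj <- as_trajectory(bind_rows(frames))
  }
  list(trajectory = traj, labels = labels)
}

#' Draw final-state labels for repeated self-assembly runs of one condition
#'
#' Emulates a batch of short self-assembly simulations in one membrane:
#' each run ends in one interface state, drawn i.i.d. from the condition's
#' state-frequency distribution.
#'
#' @param condition a [condition_spec()].
#' @param n_simulations number of runs.
#' @param seed RNG seed.
#' @param state_ids labels to draw from (default `1..k` as characters).
#' @return Character vector of `n_simulations` state labels.
#' @export
sample_condition_assemblies <- function(condition, n_simulations, seed = 1L,
                                        state_ids = NULL) {
  if (n_simulations < 1) abort("need at least one simulation")
  k <- length(condition$state_frequencies)
  state_ids <- state_ids %||% as.character(seq_len(k))
  set.seed(seed)
  sample(state_ids, n_simulations, replace = TRUE,
         prob = condition$state_frequencies)
}

#' Load a Markov interface model from a YAML config
#'
#' Expected keys: `states` (list with `id`, `phiA`, `phiB`,
#' `crossing_angle`, `separation`), `transition_matrix` (list of rows),
#' `mean_dwell`, `noise_sigma`, `seed`.
#'
#' @param path YAML file path.
#' @return A [markov_interface_model()].
#' @export
markov_model_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  states <- map(cfg$states, function(s) {
    interface_state(s$id, phiA = s$phiA %||% 0, phiB = s$phiB %||% 0,
                    crossing_angle = s$crossing_angle %||% 0,
                    separation = s$separation %||% 0.7)
  })
  markov_interface_model(
    states,
    do.call(rbind, cfg$transition_matrix),
    unlist(cfg$mean_dwell),
    noise_sigma = cfg$noise_sigma %||% 0.05,
    seed = cfg$seed %||% 1L
  )
}

# --- synthetic atomistic structures -----------------------------------------

# cylindrical backbone-atom offsets of an ideal alpha helix relative to the
# CA trace (radius A, phase deg, rise A); chosen once to reproduce standard
# backbone bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A)
.helix_atom_params <- list(
  N  = c(r = 1.6076, dphi = -27.9693, dz = -0.9135),
  CA = c(r = 2.2700, dphi = 0.0000,  dz = 0.0000),
  C  = c(r = 1.5698, dphi = 25.9788, dz = 1.0560),
  O  = c(r = 2.7112, dphi = 22.9948, dz = 1.5042)
)

# GpA transmembrane 25-mer, residues 72-96 (Glu72..Arg96)
.gpa_tm_sequence <- c(
  "GLU", "ILE", "THR", "LEU", "ILE", "ILE", "PHE", "GLY", "VAL", "MET",
  "ALA", "GLY", "VAL", "ILE", "GLY", "THR", "ILE", "LEU", "LEU", "ILE",
  "SER", "TYR", "GLY", "ILE", "ARG"
)

#' Build an ideal atomistic alpha helix
#'
#' Backbone atoms N, CA, C, O (plus a CB pseudo-side-chain for non-glycine
#' residues) on an ideal alpha helix around the z axis: 100 degrees twist
#' and 0.15 nm rise per residue, with atom offsets that reproduce standard
#' backbone bond lengths.  Used to construct synthetic test structures; not
#' a substitute for experimental coordinates.
#'
#' @param sequence character vector of three-letter residue names.
#' @param chain chain label.
#' @param first_residue residue number of the first residue.
#' @return Atom tibble (chain, residue, resname, atom, x, y, z in nm),
#'   z-centred on the origin.
#' @export
build_ideal_atomistic_helix <- function(sequence, chain = "A",
                                        first_residue = 1L) {
  n <- length(sequence)
  rows <- list()
  for (i in seq_len(n)) {
    base_ang <- 100 * (i - 1)
    base_z <- 1.5 * (i - 1)
    atoms <- names(.helix_atom_params)
    for (a in atoms) {
      p <- .helix_atom_params[[a]]
      ang <- deg2rad(base_ang + p[["dphi"]])
      rows[[length(rows) + 1]] <- tibble(
        chain = chain, residue = as.integer(first_residue + i - 1),
        resname = sequence[i], atom = a,
        x = p[["r"]] * cos(ang) / 10, y = p[["r"]] * sin(ang) / 10,
        z = (base_z + p[["dz"]]) / 10
      )
    }
    if (sequence[i] != "GLY") {
      # CB radially outward from CA, 1.55 A bond
      ang <- deg2rad(base_ang)
      rows[[length(rows) + 1]] <- tibble(
        chain = chain, residue = as.integer(first_residue + i - 1),
        resname = sequence[i], atom = "CB",
        x = (2.27 + 1.5) * cos(ang) / 10, y = (2.27 + 1.5) * sin(ang) / 10,
        z = (base_z - 0.4) / 10
      )
    }
  }
  out <- bind_rows(rows)
  out$z <- out$z - mean(range(out$z))
  out
}

#' Synthetic GpA-like transmembrane dimer (atomistic)
#'
#' A code-generated stand-in for an experimentally determined dimer
#' structure: two ideal atomistic helices carrying the GpA transmembrane
#' sequence (residues 72-96), packed right-handed at a -40 degree crossing
#' angle with the GxxxG faces turned toward the interface.  It is synthetic
#' by construction and is used to exercise the atomistic-to-CG mapping,
#' contact-map and geometry code paths; it does not reproduce experimental
#' contact counts.
#'
#' @param crossing_angle signed crossing angle, degrees.
#' @param separation inter-axis separation, nm.
#' @param phiA,phiB azimuthal helix rotations, degrees (defaults face the
#'   G79/G83 side of each helix toward the partner).
#' @param n_models number of models; models beyond the first get Gaussian
#'   coordinate noise `noise_sigma` to emulate an ensemble.
#' @param noise_sigma per-atom noise sd (nm) for models > 1.
#' @param seed RNG seed for the ensemble noise.
#' @return Atom tibble with a `model` column, chains A and B.
#' @export
synthetic_gpa_dimer <- function(crossing_angle = -40, separation = 0.65,
                                phiA = 20, phiB = -160, n_models = 1L,
                                noise_sigma = 0.02, seed = 1L) {
  hA <- build_ideal_atomistic_helix(.gpa_tm_sequence, chain = "A",
                                    first_residue = 72L)
  hB <- build_ideal_atomistic_helix(.gpa_tm_sequence, chain = "B",
                                    first_residue = 72L)
  st <- interface_state("nmr_like", phiA = phiA, phiB = phiB,
                        crossing_angle = crossing_angle,
                        separation = separation)
  a <- transform_coords(hA, rot_z(st$phiA))
  b <- transform_coords(hB, rot_x(st$crossing_angle) %*% rot_z(st$phiB),
                        shift = c(st$separation, 0, 0))
  base <- bind_rows(a, b)
  set.seed(seed)
  models <- map(seq_len(n_models), function(m) {
    out <- base
    if (m > 1) {
      n <- nrow(out)
      out$x <- out$x + rnorm(n, sd = noise_sigma)
      out$y <- out$y + rnorm(n, sd = noise_sigma)
      out$z <- out$z + rnorm(n, sd = noise_sigma)
    }
    out$model <- m
    out
  })
  bind_rows(models)
}

#' GpA transmembrane sequence (residues 72-96)
#'
#' Three-letter residue names of the 25-residue GpA transmembrane helix
#' (Glu72..Arg96), carrying the G79xxxG83 packing motif and interface
#' threonine T87.
#'
#' @return Character vector of length 25.
#' @export
gpa_tm_sequence <- function() .gpa_tm_sequence
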