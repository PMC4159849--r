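#' Coarse-grained bead structures
#'
#' A bead structure is a tibble with one row per coarse-grained bead and
#' columns `chain` (character), `residue` (integer, author numbering,
#' 1-based), `resname` (three-letter residue name, may be `NA`), `bead`
#' (`"BB"` for the backbone bead, `"SC1"`.. for side-chain beads) and
#' `x`, `y`, `z` coordinates in nanometres.  `bead_structure()` validates
#' and canonically orders such a tibble.
#'
#' @param beads data frame with the columns described above.
#' @return A tibble sorted by (chain, residue, bead).
#' @export
bead_structure <- function(beads) {
  req <- c("chain", "residue", "bead", "x", "y", "z")
  missing_cols <- setdiff(req, names(beads))
  if (length(missing_cols) > 0) {
    abort(paste0("bead structure is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  beads <- as_tibble(beads)
  if (!"resname" %in% names(beads)) beads$resname <- NA_character_
  beads$residue <- as.integer(beads$residue)
  if (any(!is.finite(beads$x) | !is.finite(beads$y) | !is.finite(beads$z))) {
    abort("bead coordinates must be finite")
  }
  if (any(beads$residue < 1L)) abort("residue indices must be >= 1")
  key <- paste(beads$chain, beads$residue, beads$bead)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, residue, bead) entries in bead structure")
  }
  bb <- beads[beads$bead == "BB", ]
  all_res <- unique(paste(beads$chain, beads$residue))
  if (!all(all_res %in% paste(bb$chain, bb$residue))) {
    abort("every residue must carry a BB bead")
  }
  arrange(beads, .data$chain, .data$residue, .data$bead)
}

#' Read models from a multi-model PDB file
#'
#' Reads an atomistic structure (for example an NMR ensemble) and returns
#' the requested model as a tidy per-atom tibble with coordinates converted
#' from Angstrom to nanometres.  Residue numbering of the file is preserved.
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param model 1-based model index (default 1).
#' @return Tibble with columns `chain`, `residue`, `resname`, `atom`,
#'   `x`, `y`, `z` (nm) and attribute `n_models`.
#' @export
read_pdb_models <- function(path, model = 1L) {
  if (!file.exists(path)) abort(paste0("no such PDB file: ", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    abort(sprintf("model %d requested but file has %d model(s)", model, n_models))
  }
  sel <- pdb$atom$type == "ATOM"
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
  out <- tibble(
    chain = pdb$atom$chain[sel],
    residue = as.integer(pdb$atom$resno[sel]),
    resname = pdb$atom$resid[sel],
    atom = pdb$atom$elety[sel],
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10
  )
  attr(out, "n_models") <- n_models
  out
}

#' Write an atomistic structure (or ensemble) to a PDB file
#'
#' The inverse of [read_pdb_models()]: coordinates in nm are written in
#' Angstrom.  If the tibble has a `model` column with more than one value, a
#' multi-model file is written.
#'
#' @param structure atom tibble as returned by [read_pdb_models()],
#'   optionally with a `model` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(structure, path) {
  if (!"model" %in% names(structure)) structure$model <- 1L
  models <- sort(unique(structure$model))
  first <- structure[structure$model == models[1], ]
  xyz <- t(vapply(models, function(m) {
    sub <- structure[structure$model == m, ]
    as.numeric(t(as.matrix(sub[, c("x", "y", "z")]) * 10))
  }, numeric(nrow(first) * 3)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = first$residue, resid = first$resname,
    elety = first$atom, chain = first$chain
  )
  invisible(path)
}

# standard atomic masses of the backbone heavy atoms used for COM mapping
.backbone_masses <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999)

#' Map an atomistic structure onto coarse-grained beads
#'
#' Places one backbone (`BB`) bead per residue, either at the centre of mass
#' of the backbone heavy atoms N, CA, C, O (`mapping = "COM"`, the Martini
#' 2.x convention) or exactly at the C-alpha position (`mapping = "CA"`, the
#' convention of CA-based helix parameterizations).  Optionally one `SC1`
#' bead per residue at the centre of mass of the side-chain heavy atoms
#' (glycine gets none).
#'
#' @param structure atom tibble as returned by [read_pdb_models()].
#' @param mapping `"COM"` or `"CA"`.
#' @param side_chains logical; add `SC1` beads (default `TRUE`).
#' @return A [bead_structure()] tibble.
#' @export
coarse_grain <- function(structure, mapping = c("COM", "CA"), side_chains = TRUE) {
  mapping <- match.arg(mapping)
  backbone_names <- names(.backbone_masses)
  split_res <- split(structure,
                     list(structure$chain, structure$residue), drop = TRUE)
  beads <- map(split_res, function(res) {
    bb_atoms <- res[res$atom %in% backbone_names, ]
    if (mapping == "CA") {
      ca <- res[res$atom == "CA", ]
      if (nrow(ca) != 1) {
        abort(sprintf("residue %s:%d lacks a CA atom", res$chain[1], res$residue[1]))
      }
      bb <- c(ca$x, ca$y, ca$z)
    } else {
      if (!all(backbone_names %in% bb_atoms$atom)) {
        abort(sprintf("residue %s:%d lacks backbone atoms (need N, CA, C, O)",
                      res$chain[1], res$residue[1]))
      }
      w <- .backbone_masses[bb_atoms$atom]
      bb <- c(
        sum(w * bb_atoms$x), sum(w * bb_atoms$y), sum(w * bb_atoms$z)
      ) / sum(w)
    }
    out <- tibble(chain = res$chain[1], residue = res$residue[1],
                  resname = res$resname[1], bead = "BB",
                  x = bb[1], y = bb[2], z = bb[3])
    if (side_chains) {
      sc <- res[!res$atom %in% c(backbone_names, "OXT") &
                  !grepl("^H", res$atom), ]
      if (nrow(sc) > 0) {
        out <- bind_rows(out, tibble(
          chain = res$chain[1], residue = res$residue[1],
          resname = res$resname[1], bead = "SC1",
          x = mean(sc$x), y = mean(sc$y), z = mean(sc$z)
        ))
      }
    }
    out
  })
  out <- bead_structure(bind_rows(beads))
  attr(out, "mapping") <- mapping
  out
}

#' Truncate a structure to a residue segment
#'
#' Keeps residues `first:last` (author numbering, inclusive) of every chain.
#' Used, for example, to cut a 40-residue NMR construct down to the
#' 25-residue transmembrane helix.
#'
#' @param structure bead or atom tibble with `residue` column.
#' @param first,last first and last residue to keep (inclusive).
#' @return The truncated tibble.
#' @export
truncate_to_segment <- function(structure, first, last) {
  if (first > last) abort("first must be <= last")
  rng <- range(structure$residue)
  if (first < rng[1] || last > rng[2]) {
    abort(sprintf("segment %d..%d outside structure range %d..%d",
                  first, last, rng[1], rng[2]))
  }
  structure[structure$residue >= first & structure$residue <= last, ]
}

#' Build an ideal coarse-grained helix
#'
#' Backbone beads on a regular helix around the z axis, one bead per
#' residue.  Defaults follow alpha-helical CG geometry: 0.15 nm rise per
#' residue, 100 degrees twist, 0.23 nm helix radius.
#'
#' @param n_residues number of residues (>= 2).
#' @param rise rise per residue, nm.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, nm (0 gives a straight line).
#' @param chain chain label.
#' @param first_residue residue number of the first bead.
#' @return A [bead_structure()] tibble of BB beads, centred so the helix
#'   axis is the z axis through the origin (z spans `[-L/2, L/2]`).
#' @export
build_ideal_cg_helix <- function(n_residues, rise = 0.15, twist = 100,
                                 radius = 0.23, chain = "A",
                                 first_residue = 1L) {
  if (n_residues < 2) abort("need at least 2 residues")
  if (rise <= 0 || radius < 0) abort("rise must be positive and radius non-negative")
  i <- seq_len(n_residues) - 1
  ang <- deg2rad(twist * i)
  z <- rise * i
  bead_structure(tibble(
    chain = chain,
    residue = as.integer(first_residue + i),
    resname = NA_character_,
    bead = "BB",
    x = radius * cos(ang),
    y = radius * sin(ang),
    z = z - mean(range(z))
  ))
}

#' Read / write GRO coordinate files
#'
#' Minimal reader and writer for the fixed-width GRO format (nm units)
#' covering protein beads of a two-helix system; velocities are ignored.
#' Chain identity is recovered from the residue-number sequence restarting
#' or from a two-chain split given by `chains`.
#'
#' @param path file path.
#' @param chains character vector of chain labels to assign to contiguous
#'   blocks of residues (default `c("A","B")`, split where residue
#'   numbering restarts or decreases).
#' @return `read_gro()`: a list with `beads` (bead tibble), `title`, `box`
#'   (length-3 numeric, nm).
#' @export
read_gro <- function(path, chains = c("A", "B")) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  resno <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  atom <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  # chain breaks where residue numbering decreases
  brk <- cumsum(c(1L, diff(resno) < 0))
  if (max(brk) > length(chains)) {
    abort("more chain blocks in GRO file than chain labels supplied")
  }
  beads <- bead_structure(tibble(
    chain = chains[brk], residue = resno, resname = resname,
    bead = atom, x = x, y = y, z = z
  ))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(beads = beads, title = lines[1], box = box)
}

#' @rdname read_gro
#' @param beads bead tibble.
#' @param title title line.
#' @param box box vector (nm), written on the final line.
#' @export
write_gro <- function(beads, path, title = "tmdimer frame",
                      box = c(10, 10, 10)) {
  beads <- bead_structure(beads)
  n <- nrow(beads)
  lines <- c(
    title, sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            beads$residue,
            ifelse(is.na(beads$resname), "UNK", beads$resname),
            beads$bead, seq_len(n) %% 100000L,
            beads$x, beads$y, beads$z),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Trajectories
#'
#' A trajectory is a tibble of bead rows with additional `frame` (integer)
#' and `time` (ns) columns; frame times must be strictly increasing and
#' uniformly spaced.  `as_trajectory()` validates and returns the tibble,
#' `trajectory_dt()` returns the frame spacing in ns, `trajectory_frame()`
#' extracts one frame as a bead tibble.
#'
#' @param traj trajectory tibble.
#' @param tol relative tolerance on uniform spacing.
#' @return `as_trajectory()`: the validated tibble.
#' @export
as_trajectory <- function(traj, tol = 1e-6) {
  if (!all(c("frame", "time") %in% names(traj))) {
    abort("a trajectory needs frame and time columns")
  }
  times <- sort(unique(traj$time))
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) abort("frame times must be strictly increasing")
    if (diff(range(dts)) > tol * mean(dts)) {
      abort("frame times must be uniformly spaced")
    }
  }
  as_tibble(traj)
}

#' @rdname as_trajectory
#' @export
trajectory_dt <- function(traj) {
  times <- sort(unique(traj$time))
  if (length(times) < 2) return(NA_real_)
  mean(diff(times))
}

#' @rdname as_trajectory
#' @param which frame index to extract.
#' @export
trajectory_frame <- function(traj, which) {
  out <- traj[traj$frame == which, ]
  if (nrow(out) == 0) abort(sprintf("no frame %s in trajectory", which))
  out
}

#' Write a trajectory as a series of GRO frames plus a label sidecar
#'
#' One GRO file per stored frame (`frame_000001.gro`, ...) in `dir`, plus
#' `labels.csv` with columns frame, time and (if supplied) the true
#' interface-state label of each frame.
#'
#' @param traj trajectory tibble.
#' @param dir output directory, created if needed.
#' @param labels optional per-frame label vector (generator ground truth).
#' @param box box vector for the GRO files.
#' @return `dir`, invisibly.
#' @export
write_trajectory_gro <- function(traj, dir, labels = NULL, box = c(10, 10, 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- sort(unique(traj$frame))
  for (f in frames) {
    fr <- trajectory_frame(traj, f)
    write_gro(fr[, c("chain", "residue", "resname", "bead", "x", "y", "z")],
              file.path(dir, sprintf("frame_%06d.gro", f)),
              title = sprintf("t = %.3f ns", fr$time[1]), box = box)
  }
  sidecar <- tibble(frame = frames,
                    time = map_dbl(frames, function(f) traj$time[traj$frame == f][1]))
  if (!is.null(labels)) sidecar$label <- labels
  readr::write_csv(sidecar, file.path(dir, "labels.csv"))
  invisible(dir)
}
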