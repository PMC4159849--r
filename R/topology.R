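#' Elastic bond specification
#'
#' One class of helix-restraining harmonic bonds between backbone beads
#' `i` and `i + offset`.  Default equilibrium lengths follow the average
#' backbone i/i+3, i/i+4, i/i+5 distances of experimentally determined
#' transmembrane helices: 0.49, 0.61 and 0.82 nm.  A `force_constant` of
#' `NA`/`NULL` means the bond class is omitted.
#'
#' @param offset residue offset, one of 3, 4, 5.
#' @param force_constant kJ mol^-1 nm^-2, or `NA` to omit.
#' @param equilibrium_length nm (default by offset: 0.49 / 0.61 / 0.82).
#' @return Object of class `elastic_bond_spec`.
#' @export
elastic_bond_spec <- function(offset, force_constant = NA_real_,
                              equilibrium_length = NULL) {
  if (!offset %in% 3:5) abort("offset must be 3, 4 or 5")
  equilibrium_length <- equilibrium_length %||%
    c(`3` = 0.49, `4` = 0.61, `5` = 0.82)[[as.character(offset)]]
  force_constant <- force_constant %||% NA_real_
  if (!is.na(force_constant) && equilibrium_length <= 0) {
    abort("equilibrium length must be positive")
  }
  structure(list(offset = as.integer(offset),
                 equilibrium_length = equilibrium_length,
                 force_constant = force_constant),
            class = "elastic_bond_spec")
}

#' Read / write GROMACS ITP topology files
#'
#' A minimal line-preserving representation: the object keeps the raw
#' lines so that augmentation is strictly append-only, plus a parsed view
#' of the `[ atoms ]` section for locating backbone beads.
#'
#' @param path file path.
#' @return `read_itp()`: object of class `itp_topology` with fields
#'   `lines` and `atoms` (tibble: nr, type, resnr, residue, atom, cgnr).
#' @export
read_itp <- function(path) {
  lines <- readLines(path)
  itp_topology(lines)
}

#' @rdname read_itp
#' @param lines character vector of ITP lines.
#' @export
itp_topology <- function(lines) {
  structure(list(lines = lines, atoms = parse_itp_atoms(lines)),
            class = "itp_topology")
}

# internal: locate section bodies; returns integer line indices
itp_section_lines <- function(lines, section) {
  headers <- grep("^\\s*\\[", lines)
  names_ <- tolower(gsub("[\\[\\]\\s]", "", lines[headers], perl = TRUE))
  hit <- headers[names_ == tolower(section)]
  if (length(hit) == 0) return(integer(0))
  start <- hit[1] + 1
  nxt <- headers[headers > hit[1]]
  end <- if (length(nxt) > 0) nxt[1] - 1 else length(lines)
  idx <- start:end
  body <- lines[idx]
  idx[!grepl("^\\s*(;|#|$)", body)]
}

parse_itp_atoms <- function(lines) {
  idx <- itp_section_lines(lines, "atoms")
  if (length(idx) == 0) {
    return(tibble(nr = integer(0), type = character(0), resnr = integer(0),
                  residue = character(0), atom = character(0),
                  cgnr = integer(0)))
  }
  fields <- strsplit(trimws(sub(";.*$", "", lines[idx])), "\\s+")
  ok <- lengths(fields) >= 6
  fields <- fields[ok]
  tibble(
    nr = map_int(fields, ~ as.integer(.x[1])),
    type = map_chr(fields, 2),
    resnr = map_int(fields, ~ as.integer(.x[3])),
    residue = map_chr(fields, 4),
    atom = map_chr(fields, 5),
    cgnr = map_int(fields, ~ as.integer(.x[6]))
  )
}

#' @rdname read_itp
#' @param topology an `itp_topology`.
#' @export
write_itp <- function(topology, path) {
  writeLines(topology$lines, path)
  invisible(path)
}

#' Augment a CG topology with helix-restraining elastic bonds
#'
#' Appends one harmonic bond (function type 1) per valid backbone pair
#' `(i, i + offset)` for every [elastic_bond_spec()] whose force constant
#' is set; specs with `NA` force constants contribute nothing.  Existing
#' file content is untouched (append-only); added lines carry an
#' `; elastic i+k` comment so the augmentation is reversible by
#' inspection.  Chains are treated independently: bead pairs are formed
#' within runs of consecutive residue numbers only.
#'
#' @param topology an `itp_topology`.
#' @param specs list of [elastic_bond_spec()] objects.
#' @param bead_name name of the backbone bead (default `"BB"`).
#' @return A new `itp_topology` with the bonds appended.
#' @export
augment_topology <- function(topology, specs, bead_name = "BB") {
  active <- keep(specs, ~ !is.na(.x$force_constant))
  if (length(active) == 0) return(topology)
  bb <- topology$atoms[topology$atoms$atom == bead_name, ]
  if (nrow(bb) == 0) abort("topology has no backbone beads")
  bb <- bb[order(bb$nr), ]
  # split into chains where residue numbering restarts/jumps backwards
  chain_id <- cumsum(c(1L, diff(bb$resnr) < 0))
  existing <- itp_bond_pairs(topology)
  new_lines <- character(0)
  duplicates <- character(0)
  for (spec in active) {
    for (ch in unique(chain_id)) {
      sub <- bb[chain_id == ch, ]
      n <- nrow(sub)
      if (n <= spec$offset) next
      for (i in seq_len(n - spec$offset)) {
        ai <- sub$nr[i]
        aj <- sub$nr[i + spec$offset]
        if (paste(ai, aj) %in% existing) {
          duplicates <- c(duplicates, sprintf("%d-%d", ai, aj))
          next
        }
        new_lines <- c(new_lines, sprintf(
          "%6d %6d %6d %8.3f %10.1f ; elastic i+%d",
          ai, aj, 1L, spec$equilibrium_length, spec$force_constant,
          spec$offset))
      }
    }
  }
  if (length(duplicates) > 0) {
    warn(sprintf("%d bond(s) already present; duplicates skipped (%s%s)",
                 length(duplicates),
                 paste(utils::head(duplicates, 5), collapse = ", "),
                 if (length(duplicates) > 5) ", ..." else ""))
  }
  lines <- topology$lines
  if (length(itp_section_lines(lines, "bonds")) == 0 &&
      !any(grepl("^\\s*\\[\\s*bonds\\s*\\]", lines))) {
    lines <- c(lines, "", "[ bonds ]")
  }
  itp_topology(c(lines, new_lines))
}

# internal: "ai aj" keys of all bonds currently in the topology
itp_bond_pairs <- function(topology) {
  idx <- itp_section_lines(topology$lines, "bonds")
  if (length(idx) == 0) return(character(0))
  fields <- strsplit(trimws(sub(";.*$", "", topology$lines[idx])), "\\s+")
  fields <- fields[lengths(fields) >= 2]
  vapply(fields, function(f) paste(f[1], f[2]), "")
}

#' Parsed bond table of a topology
#'
#' @param topology an `itp_topology`.
#' @return Tibble (ai, aj, funct, length, force_constant, comment).
#' @export
itp_bonds <- function(topology) {
  idx <- itp_section_lines(topology$lines, "bonds")
  if (length(idx) == 0) {
    return(tibble(ai = integer(0), aj = integer(0), funct = integer(0),
                  length = numeric(0), force_constant = numeric(0),
                  comment = character(0)))
  }
  raw <- topology$lines[idx]
  comment <- ifelse(grepl(";", raw), sub("^[^;]*;\\s*", "", raw), "")
  fields <- strsplit(trimws(sub(";.*$", "", raw)), "\\s+")
  ok <- lengths(fields) >= 5
  tibble(
    ai = map_int(fields[ok], ~ as.integer(.x[1])),
    aj = map_int(fields[ok], ~ as.integer(.x[2])),
    funct = map_int(fields[ok], ~ as.integer(.x[3])),
    length = map_dbl(fields[ok], ~ as.numeric(.x[4])),
    force_constant = map_dbl(fields[ok], ~ as.numeric(.x[5])),
    comment = comment[ok]
  )
}

#' Screen elastic-bond force constants against a reference distribution
#'
#' For every grid point (a combination of i+3 / i+4 / i+5 force
#' constants), asks `distribution_provider` for the helix-length
#' distribution that the so-augmented topology produces, scores it against
#' the reference with [distribution_difference()], and reports the argmin.
#' The provider abstracts over the origin of the distributions (external
#' MD output files, or the package's synthetic surrogate); the screen
#' itself never runs dynamics.  Provider failures are recorded and the
#' screen continues.
#'
#' @param distribution_provider function taking (k3, k4, k5) and returning
#'   a `length_distribution` on the reference's bins.
#' @param grid data frame with columns `k3`, `k4`, `k5` (`NA` = bond
#'   omitted); default: the full `{None, 500, 1000, 5000, 10000}^3` grid.
#' @param reference reference `length_distribution`.
#' @param metric,scale passed to [distribution_difference()].
#' @return Object of class `screen_result`: tibble (k3, k4, k5, score,
#'   error) with attribute `best` (the argmin row).
#' @export
screen_bond_parameters <- function(distribution_provider, grid = NULL,
                                   reference, metric = "l1", scale = 1) {
  ks <- c(NA, 500, 1000, 5000, 10000)
  grid <- as_tibble(grid %||% expand.grid(k3 = ks, k4 = ks, k5 = ks))
  rows <- map(seq_len(nrow(grid)), function(i) {
    res <- tryCatch({
      d <- distribution_provider(grid$k3[i], grid$k4[i], grid$k5[i])
      list(score = distribution_difference(reference, d, metric = metric,
                                           scale = scale), error = NA_character_)
    }, error = function(e) list(score = NA_real_, error = conditionMessage(e)))
    tibble(k3 = grid$k3[i], k4 = grid$k4[i], k5 = grid$k5[i],
           score = res$score, error = res$error)
  })
  out <- bind_rows(rows)
  class(out) <- c("screen_result", class(out))
  if (any(is.finite(out$score))) {
    attr(out, "best") <- out[which.min(out$score), ]
  }
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("force-constant screen: %d grid points, %d failed\n",
              nrow(x), sum(!is.na(x$error))))
  best <- attr(x, "best")
  if (!is.null(best)) {
    cat(sprintf("best: k3 = %s, k4 = %s, k5 = %s (score %.4f)\n",
                format(best$k3), format(best$k4), format(best$k5),
                best$score))
  }
  invisible(x)
}
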