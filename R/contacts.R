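#' Analysis configuration
#'
#' Bundle of the interface-analysis thresholds: the residue-residue contact
#' cutoff (0.6 nm), the stable-dimer criterion (at least 19 inter-helix
#' contacts sustained for 100 ns), the frame interval used when pooling
#' structures for clustering (50 ns) and the flat-cluster cutoff on the
#' Dice dissimilarity tree (0.5).
#'
#' @param contact_cutoff contact distance cutoff, nm.
#' @param stable_contact_min minimum number of inter-helix contacts.
#' @param stable_span time span over which the contact minimum must hold, ns.
#' @param cluster_frame_interval frame sampling interval for clustering, ns.
#' @param cluster_cutoff flat-cut height on the UPGMA tree.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(contact_cutoff = 0.6, stable_contact_min = 19L,
                            stable_span = 100, cluster_frame_interval = 50,
                            cluster_cutoff = 0.5) {
  vals <- c(contact_cutoff, stable_contact_min, stable_span,
            cluster_frame_interval, cluster_cutoff)
  if (any(vals <= 0)) abort("all analysis-config values must be positive")
  structure(list(contact_cutoff = contact_cutoff,
                 stable_contact_min = as.integer(stable_contact_min),
                 stable_span = stable_span,
                 cluster_frame_interval = cluster_frame_interval,
                 cluster_cutoff = cluster_cutoff),
            class = "analysis_config")
}

# internal: minimum-image displacement-aware squared distance matrix between
# two coordinate matrices (rows = points); box = NULL for no imaging
cross_dist <- function(A, B, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    return(sqrt(pmax(d2, 0)))
  }
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], `-`)
    dk <- dk - box[k] * round(dk / box[k])
    out <- out + dk^2
  }
  sqrt(out)
}

#' Residue-residue contact map of a dimer frame
#'
#' Boolean matrix with rows = residues of chain A, columns = residues of
#' chain B; entry (i, j) is `TRUE` when the inter-residue distance is
#' strictly below the cutoff (default 0.6 nm).  The inter-residue distance
#' is the minimum over all bead pairs of the two residues
#' (`distance_mode = "min_bead"`) or the backbone-bead distance
#' (`"bb_only"`).
#'
#' @param frame single-frame bead tibble with two chains.
#' @param segment optional `c(first, last)` residue range to analyse.
#' @param cutoff contact cutoff, nm.
#' @param distance_mode `"min_bead"` or `"bb_only"`.
#' @param box optional length-3 box (nm) for minimum-image distances.
#' @return An object of class `contact_map`: the logical matrix with
#'   residue-number dimnames, plus `cutoff` and `distance_mode` attributes.
#' @export
compute_contact_map <- function(frame, segment = NULL, cutoff = 0.6,
                                distance_mode = c("min_bead", "bb_only"),
                                box = NULL) {
  distance_mode <- match.arg(distance_mode)
  chains <- sort(unique(frame$chain))
  if (length(chains) != 2) abort("frame must contain exactly two chains")
  if (!is.null(segment)) {
    frame <- truncate_to_segment(frame, segment[1], segment[2])
  }
  if (distance_mode == "bb_only") frame <- frame[frame$bead == "BB", ]
  a <- frame[frame$chain == chains[1], ]
  b <- frame[frame$chain == chains[2], ]
  res_a <- sort(unique(a$residue))
  res_b <- sort(unique(b$residue))
  if (!identical(res_a, res_b)) {
    abort("the two chains must cover the same residue segment")
  }
  D <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]), box = box)
  # reduce bead-bead distances to residue-residue minima
  ia <- match(a$residue, res_a)
  ib <- match(b$residue, res_b)
  R <- length(res_a)
  dres <- matrix(Inf, R, R)
  for (p in seq_len(nrow(D))) {
    row <- D[p, ]
    agg <- tapply(row, ib, min)
    dres[ia[p], as.integer(names(agg))] <-
      pmin(dres[ia[p], as.integer(names(agg))], agg)
  }
  m <- dres < cutoff
  dimnames(m) <- list(res_a, res_b)
  structure(m, class = c("contact_map", "matrix"),
            cutoff = cutoff, distance_mode = distance_mode)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: %d x %d residues, %d contacts (cutoff %.2f nm, %s)\n",
              nrow(x), ncol(x), sum(x), attr(x, "cutoff"),
              attr(x, "distance_mode")))
  invisible(x)
}

#' Count contacts in a contact map
#' @param map a [compute_contact_map()] result (or logical matrix).
#' @return Integer number of `TRUE` entries.
#' @export
count_contacts <- function(map) sum(map)

#' Count contacts coinciding between a map and a reference
#' @param map,reference logical contact matrices of identical shape.
#' @return Integer count of positions that are contacts in both.
#' @export
coinciding_contacts <- function(map, reference) {
  if (!all(dim(map) == dim(reference))) abort("contact-map shapes differ")
  sum(map & reference)
}

#' Interface similarity to a reference contact map
#'
#' The NMR-similarity score: the number of contacts coinciding with the
#' reference divided by the total number of reference contacts.  Extra
#' contacts absent from the reference do not lower the score; the score is
#' 1 exactly when every reference contact is present.
#'
#' @inheritParams coinciding_contacts
#' @return Numeric in `[0, 1]`.
#' @export
similarity_to_reference <- function(map, reference) {
  cref <- count_contacts(reference)
  if (cref == 0) abort("reference map has no contacts")
  coinciding_contacts(map, reference) / cref
}

#' Per-frame inter-helix contact counts of a trajectory
#'
#' @param traj trajectory tibble.
#' @param config an [analysis_config()].
#' @param segment,distance_mode passed to [compute_contact_map()].
#' @return Tibble (frame, time, n_contacts).
#' @export
contact_count_series <- function(traj, config = analysis_config(),
                                 segment = NULL,
                                 distance_mode = "min_bead") {
  frames <- sort(unique(traj$frame))
  tibble(
    frame = frames,
    time = map_dbl(frames, function(f) traj$time[traj$frame == f][1]),
    n_contacts = map_int(frames, function(f) {
      count_contacts(compute_contact_map(
        trajectory_frame(traj, f), segment = segment,
        cutoff = config$contact_cutoff, distance_mode = distance_mode))
    })
  )
}

#' Detect a stable dimer in a trajectory
#'
#' A dimer counts as stable when at least `stable_contact_min` inter-helix
#' contacts are present in every stored frame of a contiguous window
#' spanning at least `stable_span` ns (strictest reading of the sustained-
#' contact rule: each frame, not the window average, must satisfy the
#' minimum).  The window span is the time between its first and last frame.
#'
#' @param traj trajectory tibble (or a precomputed tibble from
#'   [contact_count_series()] passed as `counts`).
#' @param config an [analysis_config()].
#' @param counts optional precomputed (frame, time, n_contacts) tibble.
#' @param ... passed to [contact_count_series()].
#' @return List `(stable = logical, first_stable_time = ns or NA)`.
#' @export
detect_stable_dimer <- function(traj, config = analysis_config(),
                                counts = NULL, ...) {
  counts <- counts %||% contact_count_series(traj, config, ...)
  dt <- if (nrow(counts) > 1) mean(diff(counts$time)) else NA_real_
  if (is.na(dt) || dt > config$stable_span) {
    abort("frame spacing must not exceed the stable-dimer time span")
  }
  ok <- counts$n_contacts >= config$stable_contact_min
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    span <- counts$time[ends[i]] - counts$time[starts[i]]
    if (span >= config$stable_span) {
      return(list(stable = TRUE, first_stable_time = counts$time[starts[i]]))
    }
  }
  list(stable = FALSE, first_stable_time = NA_real_)
}

#' Serialize a contact map (or frequency map) to CSV
#'
#' Writes the matrix with residue-number headers; `read_contact_map_csv()`
#' reads it back.
#'
#' @param map contact map or contact-frequency matrix.
#' @param path file path.
#' @export
write_contact_map_csv <- function(map, path) {
  df <- as.data.frame(unclass(map))
  df <- cbind(residue_a = rownames(map), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_contact_map_csv
#' @export
read_contact_map_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
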