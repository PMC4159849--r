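#' Fit a helix axis to backbone beads
#'
#' Local-helix-axis estimate: for an ideal helix the second differences of
#' consecutive backbone positions point radially toward the axis, so cross
#' products of successive second differences lie exactly along the axis.
#' These per-window axis estimates are sign-aligned and averaged, which is
#' exact for regular helices regardless of how many turns they span (a
#' principal-component axis is biased on helices covering a non-integer
#' number of turns).  Degenerate inputs (near-collinear beads, fewer than
#' 5 points) fall back to the principal axis of the point cloud.  The
#' axis is oriented from the N terminus toward the C terminus.
#'
#' @param beads bead tibble of one helix (only `BB` beads are used), or a
#'   plain n x 3 coordinate matrix ordered N to C.
#' @return List with `axis` (unit 3-vector) and `centroid`.
#' @export
fit_helix_axis <- function(beads) {
  if (is.data.frame(beads)) {
    bb <- beads[beads$bead == "BB", ]
    bb <- bb[order(bb$residue), ]
    P <- as.matrix(bb[, c("x", "y", "z")])
  } else {
    P <- as.matrix(beads)
  }
  if (nrow(P) < 3) abort("need at least 3 backbone beads to fit an axis")
  ctr <- colMeans(P)
  nc <- P[nrow(P), ] - P[1, ]
  v <- NULL
  n <- nrow(P)
  if (n >= 5) {
    d2 <- P[-c(1, n), , drop = FALSE] * (-2) +
      P[-(1:2), , drop = FALSE] + P[1:(n - 2), , drop = FALSE]
    m <- nrow(d2)
    cr <- cbind(
      d2[-m, 2] * d2[-1, 3] - d2[-m, 3] * d2[-1, 2],
      d2[-m, 3] * d2[-1, 1] - d2[-m, 1] * d2[-1, 3],
      d2[-m, 1] * d2[-1, 2] - d2[-m, 2] * d2[-1, 1]
    )
    nrm <- sqrt(rowSums(cr^2))
    ok <- nrm > 1e-12
    if (sum(ok) >= 1) {
      u <- cr[ok, , drop = FALSE] / nrm[ok]
      sgn <- sign(u %*% nc)
      sgn[sgn == 0] <- 1
      v <- colSums(u * as.numeric(sgn))
      if (sqrt(sum(v^2)) < 1e-9) v <- NULL
    }
  }
  if (is.null(v)) {
    C <- sweep(P, 2, ctr)
    v <- svd(C, nu = 0, nv = 1)$v[, 1]
  }
  if (sum(v * nc) < 0) v <- -v
  list(axis = v / sqrt(sum(v^2)), centroid = ctr)
}

#' Signed crossing angle of a two-helix dimer
#'
#' The angle between the two fitted helix axes, signed about the line of
#' closest approach: with unit axes `a` (helix A, N-to-C) and `b` (helix
#' B) and `w` the inter-axis direction from A to B, the angle is
#' `atan2((a x b) . w_hat, a . b)` where `w_hat` is the unit common
#' perpendicular oriented from A to B.  Right-handed packings (such as
#' GxxxG dimers) come out negative.  Near-parallel axes return 0 with
#' attribute `parallel = TRUE`.
#'
#' @param frame single-frame bead tibble with two chains, or a list of two
#'   bead tibbles.
#' @param tol parallelism tolerance on `|a x b|`.
#' @return Signed angle in degrees, in `(-180, 180]`.
#' @export
crossing_angle <- function(frame, tol = 1e-9) {
  if (is.data.frame(frame)) {
    chains <- sort(unique(frame$chain))
    if (length(chains) != 2) abort("frame must contain exactly two chains")
    hA <- frame[frame$chain == chains[1], ]
    hB <- frame[frame$chain == chains[2], ]
  } else {
    hA <- frame[[1]]; hB <- frame[[2]]
  }
  fA <- fit_helix_axis(hA)
  fB <- fit_helix_axis(hB)
  a <- fA$axis; b <- fB$axis
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  nn <- sqrt(sum(n^2))
  if (nn < tol) {
    return(structure(0, parallel = TRUE))
  }
  w <- fB$centroid - fA$centroid
  s <- sign(sum(n * w))
  if (s == 0) s <- 1
  ang <- rad2deg(atan2(s * nn, sum(a * b)))
  structure(ang, parallel = FALSE)
}

#' Tilt angle of a helix axis against the membrane normal
#'
#' Unsigned mode (default) folds the angle between the axis and the normal
#' into `[0, 90]` degrees.  Signed mode reports the tilt of the
#' z-aligned-or-flipped axis with the sign of its projection on the x axis
#' (a fixed reference azimuth in the membrane plane), giving values in
#' `(-90, 90]`.
#'
#' @param axis unit 3-vector (or a bead tibble, in which case the axis is
#'   fitted first).
#' @param membrane_normal membrane normal (default z).
#' @param signed report the signed projection variant.
#' @return Angle in degrees.
#' @export
tilt_angle <- function(axis, membrane_normal = c(0, 0, 1), signed = FALSE) {
  if (is.data.frame(axis)) axis <- fit_helix_axis(axis)$axis
  na <- sqrt(sum(axis^2))
  nn <- sqrt(sum(membrane_normal^2))
  if (na == 0 || nn == 0) abort("zero vector supplied")
  ct <- sum(axis * membrane_normal) / (na * nn)
  theta <- rad2deg(acos(pmin(pmax(ct, -1), 1)))
  folded <- pmin(theta, 180 - theta)
  if (!signed) return(folded)
  ax <- if (ct < 0) -axis else axis       # orient along the normal
  s <- sign(ax[1])
  if (s == 0) s <- 1
  s * folded
}

#' Per-frame dimer geometry of a trajectory
#'
#' @param traj trajectory tibble.
#' @return Tibble (frame, time, crossing_angle, tiltA, tiltB).
#' @export
dimer_geometry_series <- function(traj) {
  frames <- sort(unique(traj$frame))
  rows <- map(frames, function(f) {
    fr <- trajectory_frame(traj, f)
    chains <- sort(unique(fr$chain))
    tibble(
      frame = f, time = fr$time[1],
      crossing_angle = as.numeric(crossing_angle(fr)),
      tiltA = tilt_angle(fr[fr$chain == chains[1], ]),
      tiltB = tilt_angle(fr[fr$chain == chains[2], ])
    )
  })
  bind_rows(rows)
}

#' Helix length series and distribution
#'
#' The local helix length is the distance between backbone beads `i` and
#' `i + i_offset` (default 12, about three helical turns); it discriminates
#' over- from under-wound helix parameterizations.  All valid `i` of every
#' chain and frame contribute.
#'
#' @param traj trajectory tibble (or a single-frame bead tibble).
#' @param i_offset residue offset (default 12).
#' @param breaks histogram bin edges in nm for the returned distribution
#'   (default `seq(1.4, 2.4, 0.01)`, widened as needed).
#' @return List with `lengths` (tibble: frame, time, chain, i, length) and
#'   `distribution` (a `length_distribution`: bin edges + probabilities).
#' @export
helix_length_series <- function(traj, i_offset = 12L,
                                breaks = seq(1.4, 2.4, by = 0.01)) {
  if (!"frame" %in% names(traj)) {
    traj$frame <- 1L
    traj$time <- 0
  }
  bb <- traj[traj$bead == "BB", ]
  nres <- count(bb, .data$frame, .data$chain)
  if (any(nres$n <= i_offset)) abort("helix shorter than the i offset")
  rows <- bb |>
    group_by(.data$frame, .data$chain) |>
    arrange(.data$residue, .by_group = TRUE) |>
    group_by(.data$frame, .data$time, .data$chain) |>
    summarise(lens = list({
      P <- cbind(.data$x, .data$y, .data$z)
      n <- nrow(P)
      if (n <= i_offset) abort("helix shorter than the i offset")
      i <- seq_len(n - i_offset)
      tibble(i = i, length = sqrt(rowSums((P[i + i_offset, , drop = FALSE] -
                                             P[i, , drop = FALSE])^2)))
    }), .groups = "drop") |>
    tidyr::unnest("lens")
  list(lengths = rows,
       distribution = length_distribution(rows$length, breaks = breaks))
}

#' Build a helix-length probability distribution
#'
#' @param lengths numeric vector of lengths, nm.
#' @param breaks bin edges, nm; extended automatically if data fall
#'   outside.
#' @param mapping_mode optional label (`"COM"` or `"CA"`) recording the
#'   bead-mapping convention of the input.
#' @return Object of class `length_distribution`: list with `breaks`,
#'   `prob` (sums to 1) and `mapping_mode`.
#' @export
length_distribution <- function(lengths, breaks = seq(1.4, 2.4, by = 0.01),
                                mapping_mode = NA_character_) {
  w <- mean(diff(breaks))
  while (min(lengths) < breaks[1]) breaks <- c(breaks[1] - w, breaks)
  while (max(lengths) >= breaks[length(breaks)]) {
    breaks <- c(breaks, breaks[length(breaks)] + w)
  }
  h <- hist(lengths, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, prob = h$counts / sum(h$counts),
                 mapping_mode = mapping_mode),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  cat(sprintf("length distribution: %d bins over [%.2f, %.2f] nm, mean %.3f nm\n",
              length(x$prob), min(x$breaks), max(x$breaks),
              sum(mids * x$prob)))
  invisible(x)
}

#' @export
autoplot.length_distribution <- function(object, ...) {
  mids <- (object$breaks[-1] + object$breaks[-length(object$breaks)]) / 2
  ggplot2::ggplot(tibble(length = mids, prob = object$prob),
                  ggplot2::aes(.data$length, .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "helix length i, i+12 (nm)", y = "probability")
}

#' Difference between two helix-length distributions
#'
#' Default metric is the L1 distance `sum |p - q|` over shared bins
#' (maximum 2 for disjoint supports), optionally multiplied by `scale`.
#' Distributions must share their binning.
#'
#' @param p,q `length_distribution` objects on identical bins.
#' @param metric `"l1"` or `"l2"`.
#' @param scale multiplicative reporting scale (default 1).
#' @return Non-negative score.
#' @export
distribution_difference <- function(p, q, metric = c("l1", "l2"), scale = 1) {
  metric <- match.arg(metric)
  if (length(p$prob) != length(q$prob) ||
      max(abs(p$breaks - q$breaks)) > 1e-9) {
    abort("distributions must share identical binning")
  }
  d <- switch(metric,
              l1 = sum(abs(p$prob - q$prob)),
              l2 = sqrt(sum((p$prob - q$prob)^2)))
  d * scale
}

#' Top-view density projection of helix B around helix A
#'
#' Superposes every frame onto the backbone beads of helix A of the first
#' frame (Kabsch least-squares fit), then bins the x/y (membrane-plane)
#' positions of helix B beads into a 2D histogram — the classic top-view
#' occupancy map of interface positions around a reference helix.
#'
#' @param traj trajectory tibble.
#' @param bins number of bins per axis.
#' @param range half-width of the square histogram window, nm.
#' @return Object of class `density_projection`: list with `counts`
#'   (bins x bins matrix), `xmids`, `ymids`.
#' @export
density_projection <- function(traj, bins = 60, range = 2.5) {
  chains <- sort(unique(traj$chain))
  if (length(chains) != 2) abort("trajectory must contain exactly two chains")
  frames <- sort(unique(traj$frame))
  ref <- trajectory_frame(traj, frames[1])
  refA <- ref[ref$chain == chains[1] & ref$bead == "BB", ]
  refA <- as.matrix(refA[order(refA$residue), c("x", "y", "z")])
  edges <- seq(-range, range, length.out = bins + 1)
  counts <- matrix(0, bins, bins)
  for (f in frames) {
    fr <- trajectory_frame(traj, f)
    A <- fr[fr$chain == chains[1] & fr$bead == "BB", ]
    A <- as.matrix(A[order(A$residue), c("x", "y", "z")])
    if (nrow(A) != nrow(refA)) abort("frames must share the helix-A segment")
    fit <- kabsch(A, refA)
    B <- apply_kabsch(as.matrix(fr[fr$chain == chains[2], c("x", "y", "z")]), fit)
    ix <- findInterval(B[, 1], edges, all.inside = FALSE)
    iy <- findInterval(B[, 2], edges, all.inside = FALSE)
    ok <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
    for (p in which(ok)) counts[ix[p], iy[p]] <- counts[ix[p], iy[p]] + 1
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(counts = counts, xmids = mids, ymids = mids),
            class = "density_projection")
}

#' @export
autoplot.density_projection <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("ix", "iy", "count")
  df$x <- object$xmids[as.integer(df$ix)]
  df$y <- object$ymids[as.integer(df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "occupancy")
}

#' Box-plot of crossing angles per interface cluster
#'
#' @param geometry tibble with columns `cluster` and `crossing_angle`
#'   (e.g. a join of [dimer_geometry_series()] with cluster labels).
#' @return A ggplot.
#' @export
plot_crossing_angles <- function(geometry) {
  ggplot2::ggplot(geometry, ggplot2::aes(factor(.data$cluster),
                                         .data$crossing_angle)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "interface cluster", y = "crossing angle (deg)")
}
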