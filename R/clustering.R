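#' Dice dissimilarity between boolean contact vectors
#'
#' `(c_TF + c_FT) / (2 c_TT + c_TF + c_FT)`: 0 for identical non-empty
#' vectors, 1 for disjoint supports.  Undefined (error) when both vectors
#' are all-`FALSE`.
#'
#' @param u,v logical vectors of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
dice_dissimilarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  u <- as.logical(u); v <- as.logical(v)
  ctt <- sum(u & v)
  ctf <- sum(u & !v)
  cft <- sum(!u & v)
  denom <- 2 * ctt + ctf + cft
  if (denom == 0) abort("dice dissimilarity undefined for two empty vectors")
  (ctf + cft) / denom
}

# internal: pairwise dice distance matrix over rows of a logical matrix
dice_distance_matrix <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  tt <- M %*% t(M)
  n_true <- rowSums(M)
  denom <- outer(n_true, n_true, `+`)       # 2 ctt + ctf + cft
  if (any(denom == 0)) abort("dice dissimilarity undefined for empty maps")
  d <- (denom - 2 * tt) / denom
  as.dist(d)
}

#' Cluster interface contact maps (Dice / UPGMA)
#'
#' Flattens each boolean contact map to a vector, builds the pairwise Dice
#' dissimilarity matrix, runs average-linkage (UPGMA) hierarchical
#' clustering, and cuts the tree at cophenetic height `cluster_cutoff`
#' (inclusive).  Maps with fewer than `stable_contact_min` contacts are
#' excluded before clustering (label `NA`).  Cluster ids are integers
#' assigned by decreasing cluster size, ties broken by first occurrence.
#'
#' @param maps list of contact maps (logical matrices of identical shape).
#' @param config an [analysis_config()]; uses `cluster_cutoff` and
#'   `stable_contact_min`.
#' @param filter_min_contacts apply the minimum-contact filter
#'   (default `TRUE`).
#' @return Object of class `interface_clustering`: list with `labels`
#'   (integer per input map, `NA` for filtered maps), `hclust` (the merge
#'   tree), `kept` (logical), `cluster_sizes`, `cutoff`.
#' @export
cluster_interfaces <- function(maps, config = analysis_config(),
                               filter_min_contacts = TRUE) {
  n <- length(maps)
  if (n == 0) abort("no contact maps supplied")
  shape <- dim(maps[[1]])
  flat <- t(vapply(maps, function(m) {
    if (!all(dim(m) == shape)) abort("contact maps must share one shape")
    as.logical(m)
  }, logical(prod(shape))))
  kept <- rep(TRUE, n)
  if (filter_min_contacts) kept <- rowSums(flat) >= config$stable_contact_min
  if (!any(kept)) abort("no contact maps survive the minimum-contact filter")
  labels <- rep(NA_integer_, n)
  if (sum(kept) == 1) {
    labels[kept] <- 1L
    hc <- NULL
    raw <- 1L
  } else {
    d <- dice_distance_matrix(flat[kept, , drop = FALSE])
    hc <- hclust(d, method = "average")
    # UPGMA merge heights are monotone in exact arithmetic; clamp the
    # floating-point jitter that would otherwise make cutree() refuse
    jitter_down <- diff(hc$height) < 0 & diff(hc$height) > -1e-8
    if (any(jitter_down)) hc$height <- cummax(hc$height)
    raw <- cutree(hc, h = config$cluster_cutoff)
    labels[kept] <- relabel_by_size(raw)
  }
  sizes <- table(labels[kept])
  structure(list(labels = labels, hclust = hc, kept = kept,
                 cluster_sizes = sizes, cutoff = config$cluster_cutoff),
            class = "interface_clustering")
}

# internal: rename cluster labels 1..K by decreasing size, ties by first
# occurrence in the input order
relabel_by_size <- function(raw) {
  first_seen <- vapply(unique(raw), function(u) which(raw == u)[1], 1L)
  sizes <- vapply(unique(raw), function(u) sum(raw == u), 1L)
  ord <- unique(raw)[order(-sizes, first_seen)]
  match(raw, ord)
}

#' @export
print.interface_clustering <- function(x, ...) {
  cat(sprintf("interface clustering: %d maps (%d kept), %d clusters, cutoff %.2f\n",
              length(x$labels), sum(x$kept), length(x$cluster_sizes), x$cutoff))
  invisible(x)
}

#' Per-condition cluster frequency table
#'
#' Counts and proportions of each interface cluster within each condition.
#' Clusters whose total count falls below `min_count` are lumped into an
#' `"others"` bucket (mirroring frequency plots that only display clusters
#' with at least a few members).
#'
#' @param clustering an [cluster_interfaces()] result, or an integer/
#'   character label vector.
#' @param conditions condition label per input map (same length as the
#'   labels; `NA`-labelled maps are dropped).
#' @param min_count minimum total cluster size displayed on its own
#'   (default 0 = no lumping).
#' @return Tibble (condition, cluster, n, prop); `prop` sums to 1 within
#'   each condition.
#' @export
cluster_frequencies <- function(clustering, conditions, min_count = 0L) {
  labels <- if (inherits(clustering, "interface_clustering")) {
    clustering$labels
  } else {
    clustering
  }
  if (length(conditions) != length(labels)) {
    abort("conditions must have one entry per clustered map")
  }
  keep <- !is.na(labels)
  df <- tibble(condition = conditions[keep], cluster = as.character(labels[keep]))
  if (min_count > 0) {
    tot <- table(df$cluster)
    small <- names(tot)[tot < min_count]
    df$cluster[df$cluster %in% small] <- "others"
  }
  df |>
    count(.data$condition, .data$cluster, name = "n") |>
    group_by(.data$condition) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Per-cluster contact frequency map
#'
#' Entrywise mean of the boolean contact maps belonging to one cluster:
#' entry (i, j) is the fraction of member structures in which residues i
#' and j are in contact (the grey-scale matrices of cluster figures).
#'
#' @param clustering an [cluster_interfaces()] result.
#' @param cluster_id integer cluster id.
#' @param maps the list of contact maps that was clustered.
#' @return Object of class `contact_frequency_map`: numeric matrix in
#'   `[0, 1]` with attributes `cluster_id` and `n_members`.
#' @export
contact_frequency_map <- function(clustering, cluster_id, maps) {
  members <- which(!is.na(clustering$labels) &
                     clustering$labels == cluster_id)
  if (length(members) == 0) abort(sprintf("no cluster %s", cluster_id))
  acc <- Reduce(`+`, map(maps[members], function(m) {
    matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }))
  structure(acc / length(members),
            class = c("contact_frequency_map", "matrix"),
            cluster_id = cluster_id, n_members = length(members))
}

#' Grey-scale rendering of a contact (frequency) map
#'
#' @param object a `contact_map` or `contact_frequency_map`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.contact_frequency_map <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object) * 1))
  names(df) <- c("residue_a", "residue_b", "frequency")
  df$residue_a <- as.integer(as.character(df$residue_a))
  df$residue_b <- as.integer(as.character(df$residue_b))
  ggplot2::ggplot(df, ggplot2::aes(.data$residue_a, .data$residue_b,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue (helix A)", y = "residue (helix B)",
                  fill = "contact\nfrequency")
}

#' @rdname autoplot.contact_frequency_map
#' @export
autoplot.contact_map <- function(object, ...) {
  m <- structure(matrix(as.numeric(object), nrow(object), ncol(object),
                        dimnames = dimnames(object)),
                 class = c("contact_frequency_map", "matrix"))
  autoplot(m, ...)
}
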