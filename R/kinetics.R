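#' Retention (dwell) times per interface cluster
#'
#' A dwell is a contiguous run of frames sharing one cluster label; its
#' duration is `run length x dt` ns.  Frames whose label is `NA`
#' ("unassigned", e.g. fewer than 19 contacts) break runs by default;
#' with `bridge_unassigned = TRUE` an unassigned stretch flanked by the
#' same cluster is absorbed into one dwell.
#'
#' @param labels cluster label per frame (vector; `NA` = unassigned).
#' @param dt frame spacing, ns.
#' @param bridge_unassigned bridge `NA` gaps between identical labels.
#' @return List with `dwells` (tibble: cluster, start_time, duration) and
#'   `summary` (tibble: cluster, n_dwells, mean_dwell, total_time).
#' @export
retention_times <- function(labels, dt, bridge_unassigned = FALSE) {
  labels <- as.character(labels)
  if (bridge_unassigned && length(labels) > 1) {
    filled <- labels
    last <- NA_character_
    na_run <- integer(0)
    for (i in seq_along(labels)) {
      if (is.na(labels[i])) {
        na_run <- c(na_run, i)
      } else {
        if (length(na_run) > 0 && !is.na(last) && labels[i] == last) {
          filled[na_run] <- last
        }
        na_run <- integer(0)
        last <- labels[i]
      }
    }
    labels <- filled
  }
  r <- rle(ifelse(is.na(labels), "\r.unassigned", labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "\r.unassigned"
  dwells <- tibble(
    cluster = r$values[keep],
    start_time = (starts[keep] - 1) * dt,
    duration = r$lengths[keep] * dt
  )
  summary <- dwells |>
    group_by(.data$cluster) |>
    summarise(n_dwells = n(), mean_dwell = mean(.data$duration),
              total_time = sum(.data$duration), .groups = "drop")
  list(dwells = dwells, summary = summary)
}

# internal: collapse a label sequence to its node-set visit subsequence
# (labels outside the node set removed, consecutive duplicates merged)
collapse_to_node_set <- function(labels, node_set) {
  v <- as.character(labels)
  v <- v[!is.na(v) & v %in% as.character(node_set)]
  if (length(v) == 0) return(character(0))
  v[c(TRUE, v[-1] != v[-length(v)])]
}

#' Build the interface transition network
#'
#' Nodes are the chosen interface clusters (typically those at least as
#' frequent as the reference cluster).  Each trajectory's label sequence is
#' collapsed to its subsequence of node-set visits, so a transition between
#' two nodes that passes through clusters outside the set counts as one
#' (indirect) transition.  Ordered visit pairs are counted pooled across
#' trajectories; self-pairs (round trips through excluded clusters) are
#' discarded.  An edge is `kept` when its count is at least `min_count`
#' and it ranks among the `top_k` outgoing edges of its source (ties
#' broken toward the smaller target id).
#'
#' @param label_seqs list of per-trajectory label vectors (`NA` allowed).
#' @param node_set cluster ids forming the nodes.
#' @param min_count minimum transition count (default 2: transitions seen
#'   only once are not reproducible).
#' @param top_k number of outgoing transitions kept per node (default 3).
#' @return Object of class `transition_net`: list with `nodes` (tibble:
#'   id, n_visits) and `edges` (tibble: from, to, count, kept).
#' @export
build_transition_net <- function(label_seqs, node_set, min_count = 2L,
                                 top_k = 3L) {
  if (length(node_set) == 0) abort("node set is empty")
  if (!is.list(label_seqs)) label_seqs <- list(label_seqs)
  node_set <- as.character(node_set)
  visits <- map(label_seqs, collapse_to_node_set, node_set = node_set)
  pairs <- bind_rows(map(visits, function(v) {
    if (length(v) < 2) return(NULL)
    tibble(from = v[-length(v)], to = v[-1])
  }))
  nodes <- tibble(id = node_set,
                  n_visits = map_int(node_set, function(s) {
                    sum(unlist(visits) == s)
                  }))
  if (nrow(pairs) == 0) {
    edges <- tibble(from = character(0), to = character(0),
                    count = integer(0), kept = logical(0))
  } else {
    edges <- pairs |>
      filter(.data$from != .data$to) |>
      count(.data$from, .data$to, name = "count") |>
      group_by(.data$from) |>
      arrange(dplyr::desc(.data$count), .data$to, .by_group = TRUE) |>
      mutate(rank = dplyr::row_number(),
             kept = .data$count >= min_count & .data$rank <= top_k) |>
      ungroup() |>
      select("from", "to", "count", "kept")
  }
  structure(list(nodes = nodes, edges = edges,
                 min_count = min_count, top_k = top_k),
            class = "transition_net")
}

#' @export
print.transition_net <- function(x, ...) {
  cat(sprintf("transition net: %d nodes, %d edges (%d kept)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$kept)))
  invisible(x)
}

# internal: igraph view of a transition net
as_igraph_net <- function(net, kept_only = TRUE) {
  e <- net$edges
  if (kept_only) e <- e[e$kept, ]
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                vertices = net$nodes$id)
}

#' Is the transition network strongly connected?
#'
#' Every node reachable from every other along directed (kept) edges —
#' the signature of interfaces that all interconvert.
#'
#' @param net a [build_transition_net()] result.
#' @param kept_only use only edges that survived pruning (default `TRUE`).
#' @return Logical.
#' @export
is_strongly_connected <- function(net, kept_only = TRUE) {
  g <- as_igraph_net(net, kept_only = kept_only)
  igraph::is_connected(g, mode = "strong")
}

#' Export a transition net as GraphML / edge-list CSV
#'
#' @param net a [build_transition_net()] result.
#' @param path output path.
#' @param kept_only export only kept edges.
#' @export
write_transition_net_graphml <- function(net, path, kept_only = TRUE) {
  g <- as_igraph_net(net, kept_only = kept_only)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_transition_net_graphml
#' @export
write_transition_net_csv <- function(net, path) {
  readr::write_csv(net$edges, path)
  invisible(path)
}

#' @export
autoplot.transition_net <- function(object, ...) {
  ids <- object$nodes$id
  k <- length(ids)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  pos <- tibble(id = ids, x = cos(ang), y = sin(ang))
  e <- object$edges[object$edges$kept, ]
  e <- left_join(e, rename(pos, xf = "x", yf = "y"), by = c(from = "id"))
  e <- left_join(e, rename(pos, xt = "x", yt = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$xf, y = .data$yf, xend = .data$xt,
                   yend = .data$yt, linewidth = .data$count),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      alpha = 0.6) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(.data$x, .data$y, label = .data$id)) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_fixed(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}
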