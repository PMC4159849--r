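#' NOE-style distance constraints
#'
#' A constraint names one atom (or atom pattern) on each helix and a
#' maximum allowed distance: a structure fulfills the constraint when the
#' corresponding inter-atomic distance does not exceed the bound.
#' Ambiguous selectors (wildcards such as `HB*` or `*`) expand to the
#' minimum distance over all matching atom pairs, the usual treatment of
#' degenerate NOE assignments.
#'
#' Constraint tables are CSVs with columns `resA`, `atomA`, `resB`,
#' `atomB`, `dmax_nm`, `source`.
#'
#' @param path CSV file path.
#' @return Tibble of constraints with a `constraint_id` column.
#' @export
read_noe_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("resA", "atomA", "resB", "atomB", "dmax_nm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("constraint table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$dmax_nm <= 0)) abort("dmax_nm must be positive")
  if (!"source" %in% names(df)) df$source <- "unknown"
  df$constraint_id <- sprintf("%s:%d%s-%d%s", df$source, df$resA, df$atomA,
                              df$resB, df$atomB)
  df
}

# internal: matching atom rows for a selector on one chain
match_atoms <- function(structure, chain, residue, atom_pattern) {
  sub <- structure[structure$chain == chain & structure$residue == residue, ]
  if (atom_pattern %in% c("*", "")) return(sub)
  sub[grepl(utils::glob2rx(atom_pattern), sub$atom), ]
}

#' Is a distance constraint fulfilled by a structure?
#'
#' @param structure atom tibble of one dimer (chains A and B; a `model`
#'   column, if present, must contain a single model).
#' @param constraint one row of a [read_noe_table()] tibble (or a list
#'   with the same fields).
#' @return `TRUE` when the (minimum, over ambiguous matches) distance is
#'   at most `dmax_nm`.
#' @export
constraint_fulfilled <- function(structure, constraint) {
  chains <- sort(unique(structure$chain))
  if (length(chains) != 2) abort("structure must contain exactly two chains")
  a <- match_atoms(structure, chains[1], constraint$resA, constraint$atomA)
  b <- match_atoms(structure, chains[2], constraint$resB, constraint$atomB)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort(sprintf("unresolvable constraint selector %d%s / %d%s",
                  constraint$resA, constraint$atomA,
                  constraint$resB, constraint$atomB))
  }
  D <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  min(D) <= constraint$dmax_nm
}

#' Constraint-fulfillment profile of structure ensembles by cluster
#'
#' For every (cluster, constraint) pair: the fraction of member structures
#' fulfilling the constraint.  Additionally, per cluster, the mean number
#' of constraints fulfilled per structure.
#'
#' @param structures list of atom tibbles (one dimer each).
#' @param clusters cluster label per structure.
#' @param constraints a [read_noe_table()] tibble.
#' @return List with `profile` (tibble: cluster, constraint_id, source,
#'   fraction) and `summary` (tibble: cluster, n_structures,
#'   mean_fulfilled).
#' @export
fulfillment_profile <- function(structures, clusters, constraints) {
  if (length(structures) != length(clusters)) {
    abort("need one cluster label per structure")
  }
  if (length(structures) == 0) abort("no structures supplied")
  ful <- vapply(structures, function(s) {
    vapply(seq_len(nrow(constraints)), function(j) {
      constraint_fulfilled(s, constraints[j, ])
    }, logical(1))
  }, logical(nrow(constraints)))
  ful <- matrix(ful, nrow = nrow(constraints))   # constraints x structures
  cl <- as.character(clusters)
  profile <- bind_rows(map(unique(cl), function(g) {
    cols <- which(cl == g)
    tibble(cluster = g,
           constraint_id = constraints$constraint_id,
           source = constraints$source,
           fraction = rowMeans(ful[, cols, drop = FALSE]))
  }))
  summary <- bind_rows(map(unique(cl), function(g) {
    cols <- which(cl == g)
    tibble(cluster = g, n_structures = length(cols),
           mean_fulfilled = mean(colSums(ful[, cols, drop = FALSE])))
  }))
  list(profile = profile, summary = summary)
}

#' Heat-map of a constraint-fulfillment profile
#'
#' @param profile the `profile` tibble from [fulfillment_profile()].
#' @return A ggplot.
#' @export
plot_fulfillment_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$constraint_id, factor(.data$cluster),
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "NOE constraint", y = "interface cluster",
                  fill = "fraction\nfulfilled") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
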