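#' Pipeline configuration
#'
#' Validates a pipeline configuration supplied as a YAML file or a list.
#' Recognised keys: `seed`, `duration` (ns), `dt` (ns), `noise_sigma`
#' (nm), `states` (list of interface-state specs: `id`, `phiA`, `phiB`,
#' `crossing_angle`, `separation`), `transition_matrix`, `mean_dwell`,
#' `conditions` (named list: condition id -> state-frequency vector),
#' `n_simulations` (assemblies per condition), `n_values` (subsample
#' sizes), `n_permutations`, and `analysis` (overrides for
#' [analysis_config()]).  Unknown keys are rejected.
#'
#' @param x path to a YAML file, or a list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  allowed <- c("seed", "duration", "dt", "noise_sigma", "states",
               "transition_matrix", "mean_dwell", "conditions",
               "n_simulations", "n_values", "n_permutations", "analysis")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(seed = 1L, duration = 5000, dt = 50, noise_sigma = 0.05,
                   n_simulations = 300L, n_permutations = 200L)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (is.null(cfg$states) || length(cfg$states) < 1) {
    abort("config needs at least one interface state")
  }
  ana <- do.call(analysis_config, cfg$analysis %||% list())
  cfg$analysis <- ana
  cfg$n_values <- cfg$n_values %||%
    unique(round(seq(5, cfg$n_simulations / 2, length.out = 10)))
  structure(cfg, class = "pipeline_config")
}

# internal: build the markov model from a pipeline config
model_from_config <- function(cfg) {
  states <- map(cfg$states, function(s) {
    interface_state(s$id, phiA = s$phiA %||% 0, phiB = s$phiB %||% 0,
                    crossing_angle = s$crossing_angle %||% 0,
                    separation = s$separation %||% 0.7)
  })
  k <- length(states)
  P <- if (!is.null(cfg$transition_matrix)) {
    do.call(rbind, cfg$transition_matrix)
  } else if (k == 1) {
    matrix(0, 1, 1)
  } else {
    (matrix(1, k, k) - diag(k)) / (k - 1)
  }
  markov_interface_model(states, P,
                         unlist(cfg$mean_dwell %||% rep(200, k)),
                         noise_sigma = cfg$noise_sigma, seed = cfg$seed)
}

#' Run the full interface-analysis pipeline
#'
#' Simulates a synthetic two-helix trajectory and per-condition assembly
#' batches, then runs every analysis stage: contact maps, Dice/UPGMA
#' clustering, per-condition cluster frequencies, per-cluster contact
#' frequency maps, dimer geometry, retention times, the pruned transition
#' network, and subsampled correlation curves with double-exponential
#' fits.  All outputs are written as CSV (plus GraphML for the net) under
#' `out_dir`, with a `manifest.json` recording package version, seed and
#' config hash.  Given one seed the outputs are byte-identical across
#' runs.
#'
#' @param config a [pipeline_config()] (or something coercible).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  ana <- cfg$analysis
  model <- stage("config", model_from_config(cfg))
  state_ids <- vapply(model$states, function(s) as.character(s$state_id), "")

  sim <- stage("simulate", simulate_interface_markov(
    model, duration = cfg$duration, dt = cfg$dt, seed = cfg$seed))
  traj <- sim$trajectory

  maps <- stage("contacts", {
    frames <- sort(unique(traj$frame))
    map(frames, function(f) compute_contact_map(
      trajectory_frame(traj, f), cutoff = ana$contact_cutoff))
  })
  clustering <- stage("cluster", cluster_interfaces(maps, ana))
  readr::write_csv(
    tibble(frame = seq_along(clustering$labels),
           time = sim$labels$time,
           true_state = sim$labels$state,
           cluster = clustering$labels),
    file.path(out_dir, "cluster_assignments.csv"))

  freq <- cluster_frequencies(clustering, rep("trajectory",
                                              length(clustering$labels)))
  readr::write_csv(freq, file.path(out_dir, "trajectory_cluster_frequencies.csv"))

  cfm <- stage("contact_frequency", contact_frequency_map(clustering, 1L, maps))
  write_contact_map_csv(cfm, file.path(out_dir, "cluster1_contact_frequency.csv"))

  geom <- stage("geometry", dimer_geometry_series(traj))
  geom$cluster <- clustering$labels
  readr::write_csv(geom, file.path(out_dir, "dimer_geometry.csv"))
  angle_summary <- geom |>
    filter(!is.na(.data$cluster)) |>
    group_by(.data$cluster) |>
    summarise(n = n(), mean_angle = mean(.data$crossing_angle),
              sd_angle = sd(.data$crossing_angle), .groups = "drop")
  readr::write_csv(angle_summary, file.path(out_dir, "crossing_angle_summary.csv"))

  kin <- stage("kinetics", {
    ret <- retention_times(clustering$labels, dt = cfg$dt)
    net <- build_transition_net(list(as.character(clustering$labels)),
                                node_set = as.character(
                                  sort(unique(stats::na.omit(clustering$labels)))))
    list(retention = ret, net = net)
  })
  readr::write_csv(kin$retention$summary, file.path(out_dir, "retention_times.csv"))
  write_transition_net_csv(kin$net, file.path(out_dir, "transition_net_edges.csv"))
  write_transition_net_graphml(kin$net, file.path(out_dir, "transition_net.graphml"))

  corr <- NULL
  if (!is.null(cfg$conditions)) {
    corr <- stage("correlate", {
      pools <- imap(cfg$conditions, function(fr, id) {
        sample_condition_assemblies(
          condition_spec(id, unlist(fr)), cfg$n_simulations,
          seed = cfg$seed + match(id, names(cfg$conditions)),
          state_ids = state_ids)
      })
      freq_table <- bind_rows(imap(pools, function(p, id) {
        tibble(condition = id, state = p)
      })) |> count(.data$condition, .data$state, name = "n")
      readr::write_csv(freq_table, file.path(out_dir, "condition_frequencies.csv"))
      ids <- names(pools)
      fits <- list()
      curves <- list()
      for (i in seq_along(ids)) {
        for (j in i:length(ids)) {
          nm <- paste0(ids[i], "-", ids[j])
          curve <- if (i == j) {
            subsampled_correlation(
              pools[[i]], n_values = cfg$n_values[2 * cfg$n_values <= cfg$n_simulations],
              n_permutations = cfg$n_permutations,
              seed = cfg$seed + 100 + i * length(ids) + j, mode = "auto",
              cluster_space = state_ids)
          } else {
            subsampled_correlation(
              pools[[i]], pools[[j]], n_values = cfg$n_values,
              n_permutations = cfg$n_permutations,
              seed = cfg$seed + 100 + i * length(ids) + j, mode = "cross",
              cluster_space = state_ids)
          }
          curves[[nm]] <- curve
          fits[[nm]] <- tryCatch(fit_double_exponential(curve),
                                 error = function(e) NULL)
        }
      }
      curve_df <- bind_rows(imap(curves, function(c, nm) {
        mutate(as_tibble(c), pair = nm)
      }))
      readr::write_csv(curve_df, file.path(out_dir, "correlation_curves.csv"))
      fit_df <- bind_rows(imap(fits, function(f, nm) {
        if (is.null(f)) return(NULL)
        tibble(pair = nm, a = f$a, b = f$b, c = f$c, d = f$d,
               limit = f$limit)
      }))
      readr::write_csv(fit_df, file.path(out_dir, "correlation_fits.csv"))
      list(pools = pools, curves = curves, fits = fits)
    })
  }

  manifest <- list(
    package = "tmdimer",
    version = as.character(utils::packageVersion("tmdimer")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    n_frames = length(unique(traj$frame)),
    n_clusters = length(clustering$cluster_sizes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = cfg, trajectory = traj, true_labels = sim$labels,
                 maps = maps, clustering = clustering, frequencies = freq,
                 geometry = geom, kinetics = kin, correlation = corr,
                 manifest = manifest))
}
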