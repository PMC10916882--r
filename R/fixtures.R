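#' Generate the deterministic fixture bundle
#'
#' Writes a micro-dataset (32 simulated samples), one default-parameter
#' trajectory CSV, the default correlation matrix and the marginal table into
#' `dir`. Everything is generated in code from `seed`, so the test suite
#' never needs a download; regeneration with the same seed is bit-identical.
#'
#' @param dir output directory (created if missing)
#' @param seed integer seed
#' @param n_samples number of requested dataset samples
#' @return invisibly, a named list of the written paths
#' @export
make_fixtures <- function(dir = tempfile("sixmass_fixtures"), seed = 1L,
                          n_samples = 32L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- phys_config()
  paths <- list(
    dataset = file.path(dir, "micro_dataset.rds"),
    labels = file.path(dir, "micro_dataset_labels.csv"),
    trajectory = file.path(dir, "default_trajectory.csv"),
    rho = file.path(dir, "rho.csv"),
    marginals = file.path(dir, "marginals.csv")
  )
  ds <- build_dataset(n_samples, seed = seed, cfg = cfg)
  save_dataset(ds, paths$dataset, labels_csv = paths$labels)

  set.seed(seed)
  rest <- rest_positions(sample_rest_positions(n = 1L)[1L, ])
  sim <- simulate_sixmass(scaling_vector(), rest, cfg)
  write_trajectories(sim$traj, paths$trajectory)

  rho <- default_rest_correlation()
  utils::write.csv(cbind(data.frame(row = rownames(rho)), as.data.frame(rho)),
                   paths$rho, row.names = FALSE)
  write_marginals(default_marginals(), paths$marginals)
  invisible(paths)
}

#' Write a run manifest
#'
#' Records command, configuration snapshot, seeds, input/output paths,
#' package versions and a timestamp as JSON next to a command-line run, so a
#' run can be reproduced bit-compatibly.
#'
#' @param path manifest path (JSON)
#' @param command command name
#' @param config named list snapshot
#' @param seed integer seed
#' @param inputs,outputs character vectors of paths
#' @return invisibly, `path`
#' @export
write_manifest <- function(path, command, config = list(), seed = NA_integer_,
                           inputs = character(), outputs = character()) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("sixmass")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
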