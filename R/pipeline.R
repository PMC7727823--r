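#' Run configuration for the pipeline entry points
#'
#' A validated named list controlling [run_simulate()] and [run_analyze()].
#' Unknown keys are rejected so typos fail before any stage runs.
#'
#' @param path YAML or JSON configuration file.
#' @return A named list (class `geosens_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

config_keys <- c(
  "out_dir", "seed", "n_frames",
  "trajectory_xyz", "shifts_csv", "bonds_csv", "topology_json",
  "delta_files", "atoms", "bonds",
  "alpha", "correction", "block_size", "tol_fs",
  "t_double_A", "t_single_A", "n_boot",
  "sigma_d_A", "ou_tau_fs", "dt_fs", "sigma_shift_ppm",
  "slope_scale", "asymmetry", "decay", "coupling",
  "delta_d_true_pm", "transition", "noise_ppm")

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  if (!is.null(cfg[["n_frames"]]) && cfg[["n_frames"]] < 1)
    abort("n_frames must be >= 1")
  if (!is.null(cfg[["alpha"]]) && (cfg[["alpha"]] < 0 || cfg[["alpha"]] > 1))
    abort("alpha must be in [0, 1]")
  structure(cfg, class = c("geosens_config", "list"))
}

cfg_get <- function(cfg, key, default) cfg[[key]] %||% default

write_provenance <- function(cfg, out_dir, stage) {
  jsonlite::write_json(
    list(stage = stage,
         package = "geosens",
         version = as.character(utils::packageVersion("geosens")),
         seed = cfg_get(cfg, "seed", 1L),
         config = unclass(cfg),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Generate a synthetic dataset bundle on disk
#'
#' Simulates a surrogate trajectory from the configuration's generator
#' settings and writes the multi-frame XYZ, the shift and bond-length CSV
#' tables, the topology JSON, the ground-truth JSON (slope map, equilibrium
#' lengths and, when a transition is configured, the true bond changes and
#' observed shift-change CSV), and a provenance record.
#'
#' @param cfg A config list (see [read_run_config()]); recognised keys
#'   include `out_dir`, `seed`, `n_frames`, the generator parameters
#'   (`sigma_d_A`, `ou_tau_fs`, `dt_fs`, `sigma_shift_ppm`, `slope_scale`,
#'   `asymmetry`, `decay`, `coupling`) and optionally `delta_d_true_pm`
#'   (named list, pm) with `transition` and `noise_ppm`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_simulate <- function(cfg) {
  cfg <- validate_config(cfg)
  out_dir <- cfg_get(cfg, "out_dir", ".")
  n_frames <- cfg_get(cfg, "n_frames", 1000L)
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort(paste0("cannot create output directory: ", out_dir))

  topo <- if (!is.null(cfg[["topology_json"]])) read_topology(cfg[["topology_json"]])
          else pcb_topology()
  map_args <- list(topo = topo)
  for (k in c("slope_scale", "asymmetry", "decay"))
    if (!is.null(cfg[[k]])) map_args[[k]] <- cfg[[k]]
  spec_args <- list(topo = topo, seed = cfg_get(cfg, "seed", 1L))
  spec_args$atoms <- cfg_get(cfg, "atoms", paste0("C", 13:18))
  spec_args$bonds <- cfg_get(cfg, "bonds",
                             bond_label(paste0("C", 13:18), paste0("C", 14:19)))
  map_args$atoms <- spec_args$atoms
  map_args$bonds <- spec_args$bonds
  spec_args$M_true <- do.call(banded_sensitivity_map, map_args)
  for (k in c("sigma_d_A", "ou_tau_fs", "dt_fs", "sigma_shift_ppm", "coupling"))
    if (!is.null(cfg[[k]])) spec_args[[k]] <- cfg[[k]]
  spec <- do.call(synthetic_spec, spec_args)

  message("simulate: ", n_frames, " frames, seed ", spec$seed)
  truth <- list(M_true = spec$M_true, d0_A = as.list(spec$d0_A),
                delta0_ppm = as.list(spec$delta0_ppm),
                sigma_d_A = spec$sigma_d_A,
                sigma_shift_ppm = spec$sigma_shift_ppm, seed = spec$seed)
  paths <- list(
    trajectory_xyz = file.path(out_dir, "trajectory.xyz"),
    shifts_csv = file.path(out_dir, "shifts.csv"),
    bonds_csv = file.path(out_dir, "bonds.csv"),
    topology_json = file.path(out_dir, "topology.json"),
    truth_json = file.path(out_dir, "truth.json"))

  if (!is.null(cfg[["delta_d_true_pm"]])) {
    dd <- unlist(cfg[["delta_d_true_pm"]])
    pair <- simulate_state_pair(spec, dd, n_frames,
                                noise_ppm = cfg_get(cfg, "noise_ppm", 0),
                                transition = cfg_get(cfg, "transition", "Pr->Pg"))
    traj <- pair$trajectory
    truth$delta_d_true_pm <- as.list(pair$delta_d_true_pm)
    paths$delta_csv <- file.path(out_dir, "observed_delta.csv")
    readr::write_csv(pair$observed_delta, paths$delta_csv)
  } else {
    traj <- simulate_trajectory(spec, n_frames)
  }

  write_xyz_trajectory(traj$frames, paths$trajectory_xyz)
  write_series_table(traj$shifts, paths$shifts_csv)
  write_series_table(traj$bonds, paths$bonds_csv)
  write_topology(topo, paths$topology_json)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  write_provenance(cfg, out_dir, "simulate")
  invisible(paths)
}

#' Run the full analysis workflow on disk inputs
#'
#' Reads bond-length and shift series (bond CSV directly, or derived from an
#' XYZ trajectory plus topology), aligns them, and writes: per-label
#' summary statistics, the significance-filtered sensitivity matrix with
#' its sign grid, and — when experimental shift-change files are supplied —
#' bond-change predictions from both inversion routes plus the bond-order /
#' conjugation / antagonism report.
#'
#' @param cfg A config list; recognised keys include the input paths
#'   (`bonds_csv` or `trajectory_xyz` + `topology_json`, `shifts_csv`,
#'   `delta_files`), subsets (`atoms`, `bonds`), filter settings (`alpha`,
#'   `correction`, `block_size`, `tol_fs`), thresholds (`t_double_A`,
#'   `t_single_A`), `n_boot`, `seed` and `out_dir`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_analyze <- function(cfg) {
  cfg <- validate_config(cfg)
  out_dir <- cfg_get(cfg, "out_dir", ".")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort(paste0("cannot create output directory: ", out_dir))
  seed <- cfg_get(cfg, "seed", 1L)
  block <- cfg_get(cfg, "block_size", 10L)

  topo <- if (!is.null(cfg[["topology_json"]]))
    read_topology(cfg[["topology_json"]]) else pcb_topology()
  bond_subset <- cfg[["bonds"]]
  topo_use <- if (!is.null(bond_subset)) subset_topology(topo, bond_subset)
              else topo
  message("analyze: reading series")
  bonds <- if (!is.null(cfg[["bonds_csv"]]))
    read_series_table(cfg[["bonds_csv"]])
  else if (!is.null(cfg[["trajectory_xyz"]]))
    compute_bond_series(read_xyz_trajectory(cfg[["trajectory_xyz"]]), topo_use)
  else abort("stage input: need bonds_csv or trajectory_xyz")
  if (is.null(cfg[["shifts_csv"]])) abort("stage input: need shifts_csv")
  shifts <- read_series_table(cfg[["shifts_csv"]])

  if (!is.null(bond_subset)) bonds <- bonds[c("time_fs", bond_subset)]
  if (!is.null(cfg[["atoms"]])) shifts <- shifts[c("time_fs", cfg[["atoms"]])]
  al <- align_series(bonds, shifts, tol_fs = cfg_get(cfg, "tol_fs", 1))

  paths <- list(summary_csv = file.path(out_dir, "series_summary.csv"),
                sensitivity_csv = file.path(out_dir, "sensitivity_matrix.csv"),
                pairs_csv = file.path(out_dir, "pair_regressions.csv"),
                signs_csv = file.path(out_dir, "sign_pattern.csv"))

  message("analyze: series summaries")
  readr::write_csv(dplyr::bind_rows(
    mutate(summarize_series_table(al$bonds, block), kind = "bond_A"),
    mutate(summarize_series_table(al$shifts, block), kind = "shift_ppm")),
    paths$summary_csv)

  message("analyze: sensitivity matrix")
  sm <- build_sensitivity_matrix(al$shifts, al$bonds,
                                 alpha = cfg_get(cfg, "alpha", 0.05),
                                 correction = cfg_get(cfg, "correction", "bh"),
                                 block_size = block)
  write_sensitivity_matrix(sm, paths$sensitivity_csv)
  readr::write_csv(tidy(sm), paths$pairs_csv)
  readr::write_csv(sign_pattern(sm), paths$signs_csv)

  delta_files <- cfg[["delta_files"]]
  if (is.null(delta_files)) {
    message("analyze: no shift-change files supplied; prediction stage skipped")
  } else {
    message("analyze: inversion and prediction")
    pca <- fit_shift_pca(al$shifts)
    model <- fit_inverse_model(pca, al$shifts, al$bonds)
    ref <- setNames(colMeans(series_matrix(al$bonds)), series_labels(al$bonds))
    patterns <- list()
    preds <- list()
    for (f in delta_files) {
      dl <- read_shift_delta(f)
      p1 <- predict_bond_deltas(model, dl, n_boot = cfg_get(cfg, "n_boot", 200L),
                                seed = seed, block_size = block)
      p2 <- pseudoinverse_predict(sm, dl, seed = seed)
      preds[[dl$transition[1]]] <- dplyr::bind_rows(p1, p2)
      patterns[[dl$transition[1]]] <-
        classify_bond_orders(ref, p1,
                             t_double_A = cfg_get(cfg, "t_double_A", 1.40),
                             t_single_A = cfg_get(cfg, "t_single_A", 1.44))
    }
    paths$predictions_csv <- file.path(out_dir, "predictions.csv")
    readr::write_csv(dplyr::bind_rows(preds), paths$predictions_csv)
    paths$conjugation_json <- file.path(out_dir, "conjugation_report.json")
    comparison <- if (length(patterns) >= 2)
      compare_states(patterns[[1]], patterns[[2]])
    write_conjugation_report(patterns, comparison, topo,
                             paths$conjugation_json)
  }
  write_provenance(cfg, out_dir, "analyze")
  invisible(paths)
}
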