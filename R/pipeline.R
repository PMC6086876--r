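# End-to-end pipeline: simulate -> extract -> arrivals -> filter -> cluster
# -> score -> render. Every stage output is a plain-text file (PDB / CSV /
# JSON) under the run directory; all randomness flows from the config seed,
# so a rerun with the same config reproduces every stage output byte for
# byte. log.txt carries wall-clock timings and is the one file excluded from
# that determinism contract.

default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = "surfchannel_run",
    system = list(n_protein_residues = 200, protein_radius = 30,
                  n_aha_like = 20, n_hmd_like = 20, n_frames = 2000,
                  step_sigma = 1.0, box_half_width = 60,
                  n_channel_walkers = 3),
    cluster = list(cutoff = 10, max_iterations = 64),
    score = list(contact_cutoff = 5),
    sites = list(list(site_id = "empty", anchor_sel = "resname PLP"),
                 list(site_id = "occupied", anchor_sel = "resname PLM")),
    arrival_cutoff = 3.5,
    site_region_cutoff = 6,
    write_trajectory = FALSE
  )
}

validate_config <- function(config) {
  base <- default_pipeline_config()
  for (key in c("seed", "outdir")) {
    if (is.null(config[[key]]))
      stop("pipeline config is missing required key: '", key, "'")
  }
  merged <- utils::modifyList(base, config)
  merged
}

log_line <- function(con, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  writeLines(msg, con, sep = "\n")
  message(msg)
}

#' Run the full analysis pipeline on a synthetic decoy system
#'
#' Stages: simulate the decoy trajectory; extract the substrate centroid
#' series; detect site arrivals; filter to arriving molecules; cluster the
#' arriving A-type centroids to convergence (per-iteration PDB snapshots);
#' score per-residue substrate population for both types and render the
#' A-type map as a B-factor-coloured PDB; write the manifest. Stage outputs,
#' a config echo and a structured log land in `config$outdir`.
#'
#' @param config named list (or path to a YAML file) with at least `seed` and
#'   `outdir`; see the vignette for the full schema. Unspecified keys take
#'   package defaults.
#' @return the run directory path, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "clusters"), showWarnings = FALSE)
  logcon <- file(file.path(outdir, "log.txt"), "wb")
  on.exit(close(logcon))
  t0 <- proc.time()[3]
  stamp <- function(stage, ...) {
    log_line(logcon, stage, sprintf("t=%.1fs ", proc.time()[3] - t0), ...)
  }

  yaml::write_yaml(config[setdiff(names(config), "outdir")],
                   file.path(outdir, "config.yaml"))

  sysc <- config$system
  spec <- decoy_spec(
    n_protein_residues = sysc$n_protein_residues,
    protein_radius = sysc$protein_radius,
    n_aha_like = sysc$n_aha_like, n_hmd_like = sysc$n_hmd_like,
    n_frames = sysc$n_frames, step_sigma = sysc$step_sigma,
    box_half_width = sysc$box_half_width,
    n_channel_walkers = sysc$n_channel_walkers,
    seed = config$seed)

  stamp("simulate", "building decoy system and walkers, seed=", config$seed)
  system <- make_decoy_system(spec)
  traj <- simulate_walkers(spec, system)
  write_structure_pdb(system$structure, file.path(outdir, "reference.pdb"))
  if (isTRUE(config$write_trajectory))
    write_trajectory(traj, file.path(outdir, "trajectory.pdb"))
  truth_out <- list(channel = system$truth$channel,
                    roles = as.list(system$truth$roles),
                    arrival_frames = as.list(system$truth$arrival_frames),
                    channel_residues = system$truth$channel_residues)
  jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  stamp("extract", "reducing substrates to centroids")
  series <- extract_centroid_series(traj)
  write_centroid_table(series, file.path(outdir, "centroids.csv"))

  stamp("arrivals", "detecting site arrivals, cutoff=", config$arrival_cutoff)
  sites <- lapply(config$sites, function(s)
    site_definition(s$site_id, s$anchor_sel,
                    arrival_cutoff = config$arrival_cutoff,
                    site_region_cutoff = config$site_region_cutoff))
  records <- detect_arrivals(series, system$structure, sites, replicate = 1)
  write_arrivals(records, file.path(outdir, "arrivals.csv"))

  stamp("filter", "restricting to arriving molecules")
  arriving <- filter_arriving(series, records)
  write_centroid_table(arriving, file.path(outdir, "arriving_centroids.csv"))

  stamp("cluster", "iterative merge clustering, cutoff=", config$cluster$cutoff)
  params <- cluster_params(cutoff = config$cluster$cutoff,
                           max_iterations = config$cluster$max_iterations)
  if (nrow(arriving) && any(arriving$substrate_type == "AHA-like")) {
    aha <- filter_type(arriving, "AHA-like")
    run <- cluster_to_convergence(aha, params,
                                  write_dir = file.path(outdir, "clusters"),
                                  run_name = "aha_arriving")
    write_merge_history(run$history, file.path(outdir, "clusters", "aha_arriving_history.jsonl"))
    stamp("cluster", "converged after ", length(run$history), " iterations, ",
          nrow(run$clouds[[length(run$clouds)]]$points), " points remain")
  } else {
    stamp("cluster", "no arriving A-type molecules; clustering skipped")
  }

  stamp("score", "per-residue contact population, cutoff=", config$score$contact_cutoff)
  for (st in c("AHA-like", "HMD-like")) {
    map <- contact_population_score(series, system$structure,
                                    contact_cutoff = config$score$contact_cutoff,
                                    substrate_type = st)
    tagname <- if (st == "AHA-like") "aha" else "hmd"
    write_score_map(map, file.path(outdir, sprintf("scores_%s.csv", tagname)))
    if (st == "AHA-like")
      write_bfactor_pdb(system$structure, map,
                        file.path(outdir, "scores_aha_bfactor.pdb"))
  }

  man <- compute_manifest(1, 1, sysc$n_aha_like + sysc$n_hmd_like, sysc$n_frames)
  jsonlite::write_json(unclass(man), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stamp("done", "outputs in ", outdir)
  invisible(outdir)
}
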