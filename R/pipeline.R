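#' Configuration for an end-to-end analysis run
#'
#' Collects everything one pass of the workbench needs: the synthetic
#' ensemble conditions (or input file paths), encodermap hyperparameters,
#' binning, seeding, EMD and clustering parameters, plus a global RNG seed
#' from which per-stage seeds are derived. Every default is either the
#' canonical tri-ubiquitin analysis value (encodermap defaults, 50 seeds,
#' min_cluster_size/min_samples 80, 0.3 nm RMSD gate, 250 ps EMD interval)
#' or a package choice documented on the argument.
#'
#' @param synthetic A [synthetic_spec()] describing the input ensemble, or
#'   `NULL` when `topology_path` is given.
#' @param topology_path,trajectory_path,partition Input files for
#'   [load_ensemble()] (used when `synthetic` is `NULL`).
#' @param hp [encodermap_hyperparams()] for the 2D map.
#' @param n_bins_x,n_bins_y Map binning (default 50 x 50).
#' @param seed_strategies Subset of `c("minima_focused", "boltzmann",
#'   "uniform")`.
#' @param n_seeds Seeds per strategy (default 50).
#' @param emd_interval_ps Time-resolved EMD interval (default 250).
#' @param cluster_k,min_cluster_size,min_samples,rmsd_cutoff,max_iter,stop_fraction
#'   Clustering workflow parameters.
#' @param rng_seed Global seed.
#' @return Object of class `bmbs_run_config`.
#' @export
run_config <- function(synthetic = NULL, topology_path = NULL,
                       trajectory_path = NULL, partition = NULL,
                       hp = encodermap_hyperparams(),
                       n_bins_x = 50L, n_bins_y = 50L,
                       seed_strategies = c("minima_focused", "boltzmann",
                                           "uniform"),
                       n_seeds = 50L, emd_interval_ps = 250,
                       cluster_k = 10L, min_cluster_size = 80L,
                       min_samples = min_cluster_size, rmsd_cutoff = 0.3,
                       max_iter = 3L, stop_fraction = 0.9, rng_seed = 1L) {
  if (is.null(synthetic)) {
    if (is.null(topology_path) || is.null(partition))
      stop_config("need either a synthetic spec or topology_path + partition")
    if (!file.exists(topology_path))
      stop_config(paste("no such file:", topology_path))
    if (is.character(partition) && !file.exists(partition))
      stop_config(paste("no such partition config:", partition))
  } else {
    stopifnot(inherits(synthetic, "bmbs_synth_spec"))
  }
  seed_strategies <- match.arg(seed_strategies,
                               c("minima_focused", "boltzmann", "uniform"),
                               several.ok = TRUE)
  structure(
    list(synthetic = synthetic, topology_path = topology_path,
         trajectory_path = trajectory_path, partition = partition,
         hp = hp, n_bins_x = as.integer(n_bins_x),
         n_bins_y = as.integer(n_bins_y), seed_strategies = seed_strategies,
         n_seeds = as.integer(n_seeds), emd_interval_ps = emd_interval_ps,
         cluster_k = as.integer(cluster_k),
         min_cluster_size = as.integer(min_cluster_size),
         min_samples = as.integer(min_samples), rmsd_cutoff = rmsd_cutoff,
         max_iter = as.integer(max_iter), stop_fraction = stop_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "bmbs_run_config"
  )
}

#' Small demonstration configuration
#'
#' A synthetic three-domain run scaled so the whole pipeline completes in a
#' few minutes on one CPU: 1,200 frames with 12-residue domains, a reduced
#' network (64 neurons, 600 steps, batch 128) and clustering with
#' min_cluster_size 40.
#'
#' @param rng_seed Global seed.
#' @return A `bmbs_run_config`.
#' @export
demo_run_config <- function(rng_seed = 1L) {
  run_config(
    synthetic = synthetic_spec(n_frames = 1200L,
                               domain_sizes = c(12L, 12L, 12L),
                               tail_mask = 0L, rng_seed = rng_seed + 100L),
    hp = encodermap_hyperparams(n_steps = 600L, n_neurons = 64L,
                                batch_size = 128L, sig_high = sigmoid_params(6, 12, 10),
                                rng_seed = rng_seed + 200L),
    n_bins_x = 30L, n_bins_y = 30L, n_seeds = 50L,
    min_cluster_size = 40L, rng_seed = rng_seed
  )
}

append_manifest <- function(manifest_path, stage, info) {
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             info)
  manifest[[length(manifest) + 1L]] <- entry
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(entry)
}

checksum <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Orchestrates ensemble input -> RMD featurisation -> map training ->
#' projection -> binning -> seeding -> EMD normalisation and seed-set EMDs
#' -> iterative clustering, writing every artifact plus an append-only JSON
#' manifest (stage, seeds, parameters, file checksums) into `out_dir`.
#' Stages run in order; a failure aborts with the stage name while earlier
#' artifacts remain on disk.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of artifact paths, invisibly; the manifest is
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "bmbs_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "manifest.json")
  paths <- list(manifest = manifest)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bmbs_stop(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)), "bmbs_stage_error")
    })
  }

  ens <- stage("ensemble", {
    if (!is.null(config$synthetic)) {
      generate_synthetic_ensemble(config$synthetic)
    } else {
      load_ensemble(config$topology_path, config$trajectory_path,
                    config$partition)
    }
  })
  paths$ensemble <- file.path(out_dir, "ensemble.pdb")
  write_ensemble_pdb(ens, paths$ensemble)
  append_manifest(manifest, "ensemble",
                  list(n_frames = n_frames(ens), source = ens$source_tag,
                       md5 = checksum(paths$ensemble)))

  feats <- stage("featurize", featurize_ensemble(ens))
  paths$features <- file.path(out_dir, "features.tsv")
  write_features(feats, paths$features)
  append_manifest(manifest, "featurize",
                  list(n_features = ncol(feats), md5 = checksum(paths$features)))

  map <- stage("train_map", train_map(feats, config$hp))
  paths$map <- file.path(out_dir, "map.rds")
  write_map(map, paths$map)
  append_manifest(manifest, "train_map",
                  list(rng_seed = config$hp$rng_seed,
                       n_steps = config$hp$n_steps,
                       final_loss = unname(map$history[nrow(map$history), "total"])))

  proj <- stage("project", project_map(map, feats))
  paths$projection <- file.path(out_dir, "projection.tsv")
  write.table(data.frame(x = proj[, 1L], y = proj[, 2L]),
              paths$projection, sep = "\t", row.names = FALSE, quote = FALSE)
  append_manifest(manifest, "project", list(md5 = checksum(paths$projection)))

  hist <- stage("bin", bin_projection(proj, config$n_bins_x, config$n_bins_y))
  norm <- stage("normalization",
                make_normalization(proj, config$n_bins_x, config$n_bins_y,
                                   rng_seed = config$rng_seed + 7L,
                                   reference_tag = ens$source_tag))
  append_manifest(manifest, "normalization",
                  list(max_emd = norm$max_emd, rng_seed = norm$rng_seed))

  seed_emds <- list()
  for (strat in config$seed_strategies) {
    fn <- switch(strat, minima_focused = seed_minima_focused,
                 boltzmann = seed_boltzmann, uniform = seed_uniform)
    ss <- stage(paste0("seed_", strat),
                fn(hist, config$n_seeds, rng_seed = config$rng_seed + 11L))
    p <- file.path(out_dir, paste0("seeds_", strat, ".tsv"))
    write_seed_set(ss, p)
    paths[[paste0("seeds_", strat)]] <- p
    sp <- file.path(out_dir, paste0("seeds_", strat, ".pdb"))
    export_seed_structures(ens, ss, sp)
    seed_hist <- bin_projection(proj[ss$frames, , drop = FALSE],
                                config$n_bins_x, config$n_bins_y,
                                extent = c(hist$xedges[1L], tail(hist$xedges, 1L),
                                           hist$yedges[1L], tail(hist$yedges, 1L)),
                                clip = TRUE)
    seed_emds[[strat]] <- normalized_emd(seed_hist, hist, norm)
    append_manifest(manifest, paste0("seed_", strat),
                    list(n = ss$n, rng_seed = ss$rng_seed,
                         emd_to_reference = seed_emds[[strat]],
                         md5 = checksum(p)))
  }

  cl <- stage("cluster",
              iterative_workflow(feats, ens, proj, k = config$cluster_k,
                                 min_cluster_size = config$min_cluster_size,
                                 min_samples = config$min_samples,
                                 rmsd_cutoff = config$rmsd_cutoff,
                                 max_iter = config$max_iter,
                                 stop_fraction = config$stop_fraction,
                                 rng_seed = config$rng_seed + 23L))
  paths$clusters <- file.path(out_dir, "clusters.tsv")
  write_cluster_assignment(cl, paths$clusters)
  append_manifest(manifest, "cluster",
                  list(n_clusters = length(cl$representatives),
                       assigned_fraction = mean(cl$labels >= 0L),
                       md5 = checksum(paths$clusters)))

  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(n_frames = n_frames(ens), n_features = ncol(feats),
         max_emd = norm$max_emd, seed_emds = seed_emds,
         n_clusters = length(cl$representatives),
         assigned_fraction = mean(cl$labels >= 0L)),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
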