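## Configuration handling and the pipeline driver binding the stages into
## reproducible runs: every output directory receives the tables the
## requested stages produce plus a provenance record (parameters, seed,
## config hash, package version).

pipeline_config_keys <- c("seed", "out_dir", "pixel_size_nm",
                          "frame_interval_s", "stages", "scene", "beads",
                          "motion", "segmentation", "puncta", "tracking",
                          "coloc_live", "runs", "proteomics", "enrichment",
                          "input")

known_stages <- c("simulate_scene", "segment", "puncta", "spread",
                  "coloc_fixed", "simulate_beads", "track", "msd",
                  "coloc_live", "simulate_runs", "runs",
                  "simulate_proteomics", "enrich")

#' Build and validate a pipeline configuration
#'
#' Configurations are plain lists (typically read from YAML with
#' [read_pipeline_config]); unknown keys are rejected so typos cannot
#' silently fall back to defaults. Every parameter is echoed into the
#' provenance record written by [run_pipeline].
#'
#' @param ... configuration entries; see `punctatrack:::pipeline_config_keys`
#'   for the accepted top-level keys and [run_pipeline] for stage names.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$pixel_size_nm <- cfg$pixel_size_nm %||% 110
  cfg$frame_interval_s <- cfg$frame_interval_s %||% 0.057
  cfg$stages <- cfg$stages %||% character(0)
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  pipeline_config(yaml::read_yaml(path))
}

## 32-bit FNV-1a hash of the YAML serialization, as a hex string; gives
## every output a config fingerprint without external digest dependencies.
config_hash <- function(cfg) {
  s <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 2166136261
  p <- 16777619
  for (b in s) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h <- ((h %/% 65536 * p) %% 65536 * 65536 + (h %% 65536) * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order, passing intermediate results
#' forward, and writes stage outputs as CSV/TSV/TIFF under
#' `config$out_dir` together with `provenance.json` (full configuration,
#' config hash, seed, package version). Stages:
#' \describe{
#'   \item{simulate_scene}{render a fixed-cell scene ([scene_spec] options
#'     under `scene`).}
#'   \item{segment}{nucleus segmentation, border-region removal, foreground
#'     mask, EDT cell assignment (`segmentation` options).}
#'   \item{puncta}{LoG puncta in channel 2 (`puncta` options), written as
#'     CSV.}
#'   \item{spread}{per-cell spread of channel 2.}
#'   \item{coloc_fixed}{object-overlap colocalization channel 2 vs 1.}
#'   \item{simulate_beads}{two-channel immobile bead movie (`beads`
#'     options).}
#'   \item{track}{spot detection + linking + length filtering on each
#'     channel (`tracking` options).}
#'   \item{msd}{per-track and weighted-mean MSD of channel 1 tracks.}
#'   \item{coloc_live}{live colocalization of channel 1 vs 2 tracks
#'     (`coloc_live` options).}
#'   \item{simulate_runs}{ground-truth run-and-pause trajectories
#'     (`motion` options).}
#'   \item{runs}{apical/basal run classification (`runs` options).}
#'   \item{simulate_proteomics}{synthetic intensity matrix (`proteomics`
#'     options).}
#'   \item{enrich}{full enrichment screen (`enrichment` options), written
#'     as TSV.}
#' }
#' A stage failure aborts the run with the stage name and cause.
#'
#' @param config a `pipeline_config` (or list coercible to one).
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  results <- list()
  for (stage in config$stages) {
    results[[stage]] <- tryCatch(
      run_stage(stage, config, env, out_dir),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
  }
  prov <- list(package = "punctatrack",
               version = as.character(utils::packageVersion("punctatrack")),
               config = unclass(config), config_hash = config_hash(config),
               seed = config$seed)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}

run_stage <- function(stage, config, env, out_dir) {
  seed <- config$seed
  px <- config$pixel_size_nm; dt <- config$frame_interval_s
  switch(stage,
    simulate_scene = {
      spec <- do.call(scene_spec, c(config$scene %||% list(),
                                    list(pixel_size_nm = px, seed = seed)))
      out <- render_fixed_cell_scene(spec)
      env$scene <- out$scene; env$truth <- out$truth
      write_image_stack(out$scene, file.path(out_dir, "scene.tif"))
      utils::write.csv(out$truth$puncta,
                       file.path(out_dir, "scene_truth_puncta.csv"),
                       row.names = FALSE)
      out
    },
    segment = {
      p <- config$segmentation %||% list()
      img <- scene_frame(env$scene, 1L, 1L)
      nuclei <- do.call(segment_nuclei, c(list(image = img), p))
      nuclei <- discard_border_regions(nuclei)
      fg <- foreground_mask(env$scene)
      part <- assign_cells_by_edt(nuclei, fg)
      env$partition <- part
      write_label_mask(nuclei, file.path(out_dir, "nuclei.tif"))
      part
    },
    puncta = {
      p <- config$puncta %||% list()
      pun <- do.call(detect_puncta_log,
                     c(list(image = scene_frame(env$scene, 1L, 2L),
                            partition = env$partition, channel = 2L), p))
      env$puncta <- pun
      write_puncta_csv(pun, file.path(out_dir, "puncta.csv"))
      utils::write.csv(puncta_summary(pun, "cell"),
                       file.path(out_dir, "puncta_summary.csv"),
                       row.names = FALSE)
      pun
    },
    spread = {
      sp <- spread_by_cell(scene_frame(env$scene, 1L, 2L), env$partition)
      utils::write.csv(sp, file.path(out_dir, "spread.csv"),
                       row.names = FALSE)
      sp
    },
    coloc_fixed = {
      p <- config$puncta %||% list()
      pun1 <- do.call(detect_puncta_log,
                      c(list(image = scene_frame(env$scene, 1L, 2L),
                             partition = env$partition, channel = 2L), p))
      pun2 <- do.call(detect_puncta_log,
                      c(list(image = scene_frame(env$scene, 1L, 1L),
                             partition = env$partition, channel = 1L), p))
      cf <- colocalize_fixed(pun1, pun2)
      utils::write.csv(cf, file.path(out_dir, "coloc_fixed.csv"),
                       row.names = FALSE)
      cf
    },
    simulate_beads = {
      b <- config$beads %||% list()
      spec <- do.call(scene_spec, c(config$scene %||% list(),
                                    list(pixel_size_nm = px, seed = seed)))
      out <- render_bead_movie(b$n_beads %||% 10L, b$n_frames %||% 60L, spec)
      env$movie <- out$scene
      write_image_stack(out$scene, file.path(out_dir, "beads.tif"))
      out
    },
    track = {
      p <- config$tracking %||% list()
      det_args <- p[intersect(names(p), c("pfa", "fit_window", "psf_sigma"))]
      tracks <- lapply(seq_len(n_channels(env$movie)), function(ch) {
        sp <- do.call(detect_spots_movie,
                      c(list(scene = env$movie, channel = ch), det_args))
        tr <- link_tracks(sp, max_disp = p$max_disp %||% 5,
                          memory = p$memory %||% 0L)
        filter_tracks(tr, min_points = p$min_points %||% 10L)
      })
      env$tracks <- tracks
      for (ch in seq_along(tracks))
        write_tracks_csv(tracks[[ch]],
                         file.path(out_dir, sprintf("tracks_ch%d.csv", ch)))
      tracks
    },
    msd = {
      m <- msd_analysis(env$tracks[[1]], pixel_size_nm = px,
                        frame_interval_s = dt)
      write_tracks_csv(m$mean, file.path(out_dir, "msd_mean.csv"))
      m
    },
    coloc_live = {
      p <- config$coloc_live %||% list()
      cl <- colocalize_live(env$tracks[[1]], env$tracks[[2]],
                            dist_nm = p$dist_nm %||% 300,
                            n_frames = p$n_frames %||% 50L,
                            pixel_size_nm = px)
      utils::write.csv(cl$per_timepoint,
                       file.path(out_dir, "coloc_live.csv"),
                       row.names = FALSE)
      cl
    },
    simulate_runs = {
      spec <- do.call(motion_spec,
                      c(list(regime = "run_and_pause"),
                        config$motion %||% list(),
                        list(frame_interval_s = dt, seed = seed)))
      env$gt_tracks <- simulate_trajectories(spec)
      write_tracks_csv(env$gt_tracks, file.path(out_dir, "trajectories.csv"))
      env$gt_tracks
    },
    runs = {
      p <- config$runs %||% list()
      rs <- do.call(classify_runs,
                    c(list(tracks = env$gt_tracks, pixel_size_nm = px,
                           frame_interval_s = dt), p))
      utils::write.csv(rs$aggregates, file.path(out_dir, "run_aggregates.csv"),
                       row.names = FALSE)
      rs
    },
    simulate_proteomics = {
      spec <- do.call(proteomics_sim_spec,
                      c(config$proteomics %||% list(), list(seed = seed)))
      sim <- simulate_proteomics_matrix(spec)
      env$proteomics <- sim$matrix
      write_proteomics_tsv(sim$matrix,
                           file.path(out_dir, "proteomics.tsv"))
      sim
    },
    enrich = {
      p <- config$enrichment %||% list()
      m <- env$proteomics %||% {
        inp <- config$input %||% list()
        read_proteomics_tsv(inp$proteomics_tsv, inp$groups)
      }
      tab <- do.call(enrichment_screen,
                     c(list(m = m, seed = seed), p))
      utils::write.table(tab, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(volcano_table(tab),
                         file.path(out_dir, "volcano.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      tab
    },
    stop("unknown stage: ", stage))
}
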