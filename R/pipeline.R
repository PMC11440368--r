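# Pipeline orchestration: reproducible end-to-end runs from synthetic
# scenarios (or pre-gridded transects) to habitat maps, importance,
# sensitivity rankings and plankton-habitat associations, with per-stage
# seeds derived from one global seed and a JSON run manifest.

#' Derive a stage-specific seed from the global seed
#'
#' Deterministic rule: the stage name is hashed (31-adic over its UTF-8
#' bytes, modulo 1e6) and added to 1000 times the global seed, modulo
#' 2^31 - 1, giving independent reproducible streams per stage.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 1e6
  as.integer((abs(global_seed) * 1000 + h) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' @param scenarios List of [front_scenario()] / [dipole_scenario()]
#'   objects (synthetic input), or `NULL` when `grid_paths` is given.
#' @param grid_paths Character vector of transect grid files to read
#'   instead of synthesizing.
#' @param patches List of [patch_spec()] objects for synthetic grids.
#' @param training A [training_config()].
#' @param clustering A [clustering_config()].
#' @param sensitivity_n Base Saltelli sample size per transect.
#' @param association An [association_config()].
#' @param association_groups Plankton groups to test (default: all).
#' @param downsample_factor Column-merge factor before the association
#'   test (default 4: 25 m cells to 100 m cells).
#' @param seed Global seed; every stochastic stage consumes a seed
#'   derived from it via [stage_seed()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenarios = NULL, grid_paths = NULL,
                            patches = list(),
                            training = training_config(),
                            clustering = clustering_config(),
                            sensitivity_n = 1024L,
                            association = association_config(),
                            association_groups = NULL,
                            downsample_factor = 4L, seed = 1L) {
  if (is.null(scenarios) && is.null(grid_paths))
    stop("provide scenarios or grid_paths")
  structure(list(scenarios = scenarios, grid_paths = grid_paths,
                 patches = patches, training = training,
                 clustering = clustering,
                 sensitivity_n = as.integer(sensitivity_n),
                 association = association,
                 association_groups = association_groups,
                 downsample_factor = as.integer(downsample_factor),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default plankton patch set for synthetic scenarios
#'
#' A pluteus patch exceeding 6 ind per microhabitat in the mixed coastal
#' column, copepods concentrated in the stratified surface layer, and
#' appendicularia along the front.
#'
#' @return List of [patch_spec()] objects.
#' @export
default_patches <- function() {
  list(patch_spec("pluteus", GT_MIXED, mean_density = 12,
                  zero_inflation = 0.3, lognormal_sigma = 0.8),
       patch_spec("copepoda", GT_SURFACE, mean_density = 8,
                  zero_inflation = 0.4, lognormal_sigma = 1),
       patch_spec("appendicularia", GT_FRONT, mean_density = 5,
                  zero_inflation = 0.5, lognormal_sigma = 1))
}

#' Synthesize the configured transects
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; grids and ground-truth maps are
#'   written there via the grid I/O dialect.
#' @return List with `grids` and `ground_truth` lists.
#' @export
pipeline_synth <- function(config, out_dir = NULL) {
  grids <- list(); gts <- list()
  for (k in seq_along(config$scenarios)) {
    sc <- config$scenarios[[k]]
    sc$seed <- stage_seed(config$seed, paste0("synth", k))
    made <- if (inherits(sc, "dipole_scenario")) make_dipole_transect(sc)
            else make_front_transect(sc)
    g <- made$grid
    if (length(config$patches))
      g <- add_plankton_patches(g, made$ground_truth, config$patches,
                                seed = stage_seed(config$seed,
                                                  paste0("patch", k)))
    grids[[g$transect_id]] <- g
    gts[[g$transect_id]] <- made$ground_truth
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(grids)) {
      write_transect_grid(grids[[id]],
                          file.path(out_dir, paste0(id, "_grid.tsv")))
      write_habitat_map(gts[[id]],
                        file.path(out_dir, paste0(id, "_truth.tsv")))
    }
  }
  list(grids = grids, ground_truth = gts)
}

#' Fit pooled scaling and build feature vectors for every transect
#'
#' @param grids Named list of [transect_grid()] objects.
#' @param out_dir Optional output directory (writes the scaling file).
#' @return List with `scaling` and `features` (named list of
#'   `mh_features`).
#' @export
pipeline_preprocess <- function(grids, out_dir = NULL) {
  scaling <- fit_scaling(grids)
  features <- lapply(grids, apply_scaling, params = scaling)
  if (!is.null(out_dir))
    write_scaling_params(scaling, file.path(out_dir, "scaling_params.tsv"))
  list(scaling = scaling, features = features)
}

.pool_features <- function(features) {
  do.call(rbind, lapply(features, function(f) f$features))
}

#' Run the full habitat-mapping pipeline
#'
#' Stages: synthesize (or read) transect grids, fit pooled scaling and
#' build microhabitat features, train the tied-weight autoencoder,
#' project all cells, cluster the pooled latents into macro-habitats,
#' compute weight-chain input importance, rank latent dimensions by
#' Sobol sensitivity per transect, downsample and run the
#' plankton-habitat association test, and (optionally) write all
#' artifacts plus a JSON manifest recording the derived stage seeds and
#' output checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list with every stage's products: `grids`, `ground_truth`,
#'   `scaling`, `features`, `model`, `history`, `latents`, `labels`
#'   (per-transect), `maps`, `surrogate`, `importance`, `rankings`,
#'   `rank_counts`, `associations`, `association_summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, t_start)
    message(sprintf("[pipeline] %-12s %6.1f s", stage,
                    as.numeric(difftime(Sys.time(), t_start,
                                        units = "secs"))))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- input grids
  ts <- Sys.time()
  if (!is.null(config$scenarios)) {
    synth <- pipeline_synth(config, out_dir)
    grids <- synth$grids; gts <- synth$ground_truth
  } else {
    grids <- lapply(config$grid_paths, read_transect_grid)
    names(grids) <- vapply(grids, `[[`, "", "transect_id")
    gts <- NULL
  }
  log_stage("input", ts)

  # --- features
  ts <- Sys.time()
  prep <- pipeline_preprocess(grids, out_dir)
  features <- prep$features
  pooled <- .pool_features(features)
  log_stage("preprocess", ts)

  # --- autoencoder
  ts <- Sys.time()
  tc <- config$training
  tc$seed <- stage_seed(config$seed, "train")
  if (tc$n_train > nrow(pooled))
    tc$n_train <- as.integer(floor(0.8 * nrow(pooled)))
  trained <- train_autoencoder(pooled, tc)
  model <- trained$model
  log_stage("train", ts)

  # --- projection
  ts <- Sys.time()
  latents <- lapply(features, function(f) project(model, f))
  pooled_latents <- do.call(rbind, latents)
  log_stage("project", ts)

  # --- clustering
  ts <- Sys.time()
  cc <- config$clustering
  cc$seed <- stage_seed(config$seed, "cluster")
  labels_pooled <- cluster_latent(pooled_latents, cc)
  sizes <- vapply(features, function(f) nrow(f$features), 0L)
  labels <- split(labels_pooled, rep(seq_along(sizes), sizes))
  names(labels) <- names(features)
  maps <- lapply(names(grids), function(id)
    build_habitat_map(grids[[id]], features[[id]], labels[[id]]))
  names(maps) <- names(grids)
  surrogate <- if (length(unique(labels_pooled[labels_pooled >= 0L])) >= 2L)
    fit_surrogate(pooled_latents, labels_pooled, cc) else NULL
  log_stage("cluster", ts)

  # --- importance
  imp <- weight_chain_importance(model)

  # --- sensitivity
  ts <- Sys.time()
  rankings <- NULL; rank_counts <- NULL
  if (!is.null(surrogate)) {
    rankings <- lapply(seq_along(latents), function(k)
      rank_dimensions(surrogate, latents[[k]], n = config$sensitivity_n,
                      seed = stage_seed(config$seed,
                                        paste0("sobol", k))))
    names(rankings) <- names(latents)
    ok <- Filter(function(e) !e$degenerate, rankings)
    if (length(ok)) rank_counts <- aggregate_rankings(rankings)
  }
  log_stage("sensitivity", ts)

  # --- association on downsampled rasters
  ts <- Sys.time()
  assoc <- list(); assoc_summary <- NULL
  test_groups <- config$association_groups
  for (id in names(grids)) {
    g4 <- downsample_grid(grids[[id]], config$downsample_factor)
    m4 <- downsample_map(maps[[id]], config$downsample_factor)
    sp <- g4$plankton
    if (!is.null(test_groups)) sp <- sp[intersect(test_groups, names(sp))]
    if (!length(sp) || !any(m4$labels >= 0L, na.rm = TRUE)) next
    ac <- config$association
    ac$seed <- stage_seed(config$seed, paste0("assoc_", id))
    assoc[[id]] <- associate(sp, m4, ac)
  }
  if (length(assoc)) assoc_summary <- summarize_associations(assoc)
  log_stage("associate", ts)

  result <- list(grids = grids, ground_truth = gts,
                 scaling = prep$scaling, features = features,
                 model = model, history = trained$history,
                 latents = latents, labels = labels, maps = maps,
                 surrogate = surrogate, importance = imp,
                 rankings = rankings, rank_counts = rank_counts,
                 associations = assoc,
                 association_summary = assoc_summary)

  if (!is.null(out_dir)) {
    write_encoder(model, file.path(out_dir, "encoder.txt"))
    utils::write.csv(trained$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    for (id in names(latents)) {
      utils::write.csv(data.frame(latents[[id]]),
                       file.path(out_dir, paste0(id, "_latent.csv")),
                       row.names = FALSE)
      write_habitat_map(maps[[id]],
                        file.path(out_dir, paste0(id, "_habitats.tsv")))
    }
    writeLines(format_importance(imp),
               file.path(out_dir, "importance.tsv"))
    if (!is.null(rank_counts))
      utils::write.csv(as.data.frame(rank_counts),
                       file.path(out_dir, "rank_counts.csv"))
    if (length(assoc))
      utils::write.csv(do.call(rbind, assoc),
                       file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
      package_version = as.character(utils::packageVersion("pelagimap")),
      global_seed = config$seed,
      stage_seeds = list(train = stage_seed(config$seed, "train"),
                         cluster = stage_seed(config$seed, "cluster")),
      epochs = tc$epochs, n_train = tc$n_train,
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipeline_config()]: `seed`, `sensitivity_n`,
#' `downsample_factor`, nested `training` / `clustering` / `association`
#' argument lists, a `scenarios` list (each with a `type` of `front` or
#' `dipole` plus scenario arguments), and a `patches` list of
#' [patch_spec()] argument sets.  Flags not present keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenarios <- NULL
  if (!is.null(y$scenarios)) {
    scenarios <- lapply(y$scenarios, function(s) {
      type <- s$type %||% "front"
      s$type <- NULL
      if (type == "dipole") do.call(dipole_scenario, s)
      else do.call(front_scenario, s)
    })
  }
  patches <- list()
  if (!is.null(y$patches))
    patches <- lapply(y$patches, function(p) do.call(patch_spec, p))
  pipeline_config(
    scenarios = scenarios, grid_paths = y$grid_paths, patches = patches,
    training = do.call(training_config, y$training %||% list()),
    clustering = do.call(clustering_config, y$clustering %||% list()),
    sensitivity_n = y$sensitivity_n %||% 1024L,
    association = do.call(association_config, y$association %||% list()),
    association_groups = y$association_groups,
    downsample_factor = y$downsample_factor %||% 4L,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
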