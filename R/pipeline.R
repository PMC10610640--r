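#' Pipeline configuration
#'
#' Collects the input paths and stage parameters used by [run_stage()].
#' Values resolve with precedence command-line flag > config file > default.
#' Input paths default to the artifacts a `simulate` stage writes under
#' `<outdir>/scene`, so `simulate` followed by `all` is self-contained.
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Integer seed forwarded to the scene generator.
#' @param dsm,dtm,thermal,cloud,roi Input paths (GeoTIFF / text cloud /
#'   WKT); `NULL` means "use the simulated scene's file".
#' @param reference_cloud Optional denser reference (LiDAR-like) cloud for
#'   volume validation.
#' @param threshold_m Canopy height threshold (2D mask and understory rule).
#' @param tail_fraction Histogram tail used for the wet/dry references.
#' @param grid_along,grid_across Plant-grid dimensions; `NULL` defaults to
#'   the simulated layout.
#' @param row_azimuth Row direction in degrees from north.
#' @param trim_m Bottom trim applied to the reference cloud.
#' @param top_cell_size,top_depth_m Top-segmentation parameters.
#' @param ground,noise [ground_params()] / [noise_params()].
#' @param scene [scene_config()] used by the `simulate` stage (its seed is
#'   overridden by `seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, dsm = NULL, dtm = NULL,
                            thermal = NULL, cloud = NULL, roi = NULL,
                            reference_cloud = NULL, threshold_m = 0.5,
                            tail_fraction = 0.005, grid_along = NULL,
                            grid_across = NULL, row_azimuth = 45,
                            trim_m = 0.20, top_cell_size = 0.25,
                            top_depth_m = 0.20, ground = ground_params(),
                            noise = noise_params(),
                            scene = scene_config(seed = seed)) {
  scene$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), dsm = dsm,
                 dtm = dtm, thermal = thermal, cloud = cloud, roi = roi,
                 reference_cloud = reference_cloud,
                 threshold_m = threshold_m, tail_fraction = tail_fraction,
                 grid_along = grid_along, grid_across = grid_across,
                 row_azimuth = row_azimuth, trim_m = trim_m,
                 top_cell_size = top_cell_size, top_depth_m = top_depth_m,
                 ground = ground, noise = noise, scene = scene),
            class = "pipeline_config")
}

pipeline_path <- function(config, name) file.path(config$outdir, name)

resolve_input <- function(config, field, scene_file) {
  p <- config[[field]]
  if (is.null(p)) p <- pipeline_path(config, file.path("scene", scene_file))
  p
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", path, "': run the '", producer,
         "' stage first", call. = FALSE)
  path
}

stage_manifest <- function(config, stage, inputs, outputs, params = list()) {
  manifest <- list(
    stage = stage, seed = config$seed,
    params = params,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest,
                       pipeline_path(config, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

write_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) sprintf("%.10g", v))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

as_canopy_mask <- function(grid, threshold_m) {
  grid$values[is.na(grid$values)] <- 0
  grid$values <- ifelse(grid$values != 0, 1, 0)
  grid$threshold_m <- threshold_m
  class(grid) <- c("canopy_mask", class(grid))
  grid
}

#' Run one pipeline stage
#'
#' Stages mirror the workflow: `simulate` writes a synthetic scene;
#' `mask2d` builds the CHM and binary canopy mask; `cwsi2d` masks the
#' thermal layer and computes the CWSI orthomosaic; `classify3d` classifies
#' ground, filters noise and removes understory from the cloud; `cwsi3d`
#' computes the CWSI point cloud; `plants` extracts per-plant mean CWSI on
#' the shared grid; `volumes` computes per-plant hull volumes; `evaluate`
#' runs the cross-model regressions; `all` chains everything. Each stage
#' writes its artifacts plus a JSON manifest (inputs with checksums,
#' parameters, seed); no stage mutates its inputs, and identical configs
#' reproduce identical text outputs.
#'
#' @param name One of `simulate`, `mask2d`, `classify3d`, `cwsi2d`,
#'   `cwsi3d`, `plants`, `volumes`, `evaluate`, `all`.
#' @param config A [pipeline_config()].
#' @return The stage manifest (for `all`, the list of manifests), invisibly.
#' @export
run_stage <- function(name = c("simulate", "mask2d", "classify3d", "cwsi2d",
                               "cwsi3d", "plants", "volumes", "evaluate",
                               "all"),
                      config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  on.exit(message(sprintf("[%s] finished in %.2fs", name,
                          as.numeric(Sys.time() - t0, units = "secs"))))
  manifest <- switch(name,
    simulate = stage_simulate(config),
    mask2d = stage_mask2d(config),
    cwsi2d = stage_cwsi2d(config),
    classify3d = stage_classify3d(config),
    cwsi3d = stage_cwsi3d(config),
    plants = stage_plants(config),
    volumes = stage_volumes(config),
    evaluate = stage_evaluate(config),
    all = lapply(c("simulate", "mask2d", "cwsi2d", "classify3d", "cwsi3d",
                   "plants", "volumes", "evaluate"),
                 run_stage, config = config))
  invisible(manifest)
}

stage_simulate <- function(config) {
  scene <- generate_scene(config$scene)
  scene_dir <- pipeline_path(config, "scene")
  scene_to_disk(scene, scene_dir)
  outs <- file.path(scene_dir, c("dsm.tif", "dtm.tif", "thermal.tif",
                                 "cloud.xyz", "plant_truth.csv"))
  stage_manifest(config, "simulate", inputs = list(), outputs = as.list(outs),
                 params = list(scene_seed = config$scene$seed))
}

stage_mask2d <- function(config) {
  dsm_p <- require_artifact(resolve_input(config, "dsm", "dsm.tif"), "simulate")
  dtm_p <- require_artifact(resolve_input(config, "dtm", "dtm.tif"), "simulate")
  chm <- compute_chm(read_raster(dsm_p), read_raster(dtm_p))
  mask <- threshold_mask(chm, config$threshold_m)
  chm_p <- pipeline_path(config, "chm.tif")
  mask_p <- pipeline_path(config, "mask.tif")
  write_raster(chm, chm_p, dtype = "float64")
  write_raster(mask, mask_p, dtype = "uint8")
  stage_manifest(config, "mask2d", list(dsm_p, dtm_p), list(chm_p, mask_p),
                 params = list(threshold_m = config$threshold_m))
}

stage_cwsi2d <- function(config) {
  thermal_p <- require_artifact(resolve_input(config, "thermal", "thermal.tif"),
                                "simulate")
  mask_p <- require_artifact(pipeline_path(config, "mask.tif"), "mask2d")
  thermal <- read_raster(thermal_p)
  mask <- as_canopy_mask(read_raster(mask_p), config$threshold_m)
  masked <- apply_mask(thermal, mask)
  vals <- masked$values[is.finite(masked$values)]
  refs <- reference_temps(vals, config$tail_fraction)
  cw <- cwsi(masked, refs)
  cw_vals <- cw$values[is.finite(cw$values)]
  summ <- summarize_thermal(vals, cw_vals, refs, spacing = thermal$dx * 100)
  cwsi_p <- pipeline_path(config, "cwsi2d.tif")
  summ_p <- pipeline_path(config, "summary_ortho.tsv")
  write_raster(cw, cwsi_p, dtype = "float64")
  write_tsv(as.data.frame(summ), summ_p)
  stage_manifest(config, "cwsi2d", list(thermal_p, mask_p),
                 list(cwsi_p, summ_p),
                 params = list(tail_fraction = config$tail_fraction))
}

stage_classify3d <- function(config) {
  cloud_p <- require_artifact(resolve_input(config, "cloud", "cloud.xyz"),
                              "simulate")
  cloud <- read_cloud(cloud_p)
  classified <- classify_ground(cloud, config$ground)
  terrain <- attr(classified, "terrain")
  canopy <- subset_cloud(classified, classified$class_label == "canopy")
  canopy <- filter_noise(canopy, config$noise)
  clean <- remove_understory(canopy, terrain, config$threshold_m)
  class_p <- pipeline_path(config, "classified.xyz")
  clean_p <- pipeline_path(config, "canopy_clean.xyz")
  terrain_p <- pipeline_path(config, "terrain.xyz")
  write_cloud(classified, class_p)
  write_cloud(clean, clean_p)
  writeLines(c("# columns: x y z",
               sprintf("%.17g %.17g %.17g", terrain$x, terrain$y, terrain$z)),
             terrain_p)
  stage_manifest(config, "classify3d", list(cloud_p),
                 list(class_p, clean_p, terrain_p),
                 params = c(unclass(config$ground), unclass(config$noise),
                            list(min_height = config$threshold_m)))
}

terrain_from_file <- function(path) {
  pts <- read_cloud(path)
  keep <- dedupe_xy(pts$coords[, 1], pts$coords[, 2])
  x <- pts$coords[keep, 1]; y <- pts$coords[keep, 2]; z <- pts$coords[keep, 3]
  structure(list(x = x, y = y, z = z, tri = cpp_delaunay(x, y)),
            class = "terrain_tin")
}

stage_cwsi3d <- function(config) {
  clean_p <- require_artifact(pipeline_path(config, "canopy_clean.xyz"),
                              "classify3d")
  clean <- read_cloud(clean_p)
  refs <- reference_temps(clean$temperature, config$tail_fraction)
  cw <- cwsi(clean, refs)
  spacing_cm <- if (n_points(cw) > 1)
    mean(cpp_knn_meandist(cw$coords, 1L)) * 100 else NA_real_
  summ <- summarize_thermal(cw$temperature, cw$scalars$cwsi, refs,
                            spacing = spacing_cm)
  cloud_p <- pipeline_path(config, "cwsi_cloud.xyz")
  summ_p <- pipeline_path(config, "summary_cloud.tsv")
  write_cloud(cw, cloud_p)
  write_tsv(as.data.frame(summ), summ_p)
  stage_manifest(config, "cwsi3d", list(clean_p), list(cloud_p, summ_p),
                 params = list(tail_fraction = config$tail_fraction))
}

pipeline_grid <- function(config) {
  roi_p <- require_artifact(resolve_input(config, "roi", "roi.wkt"), "simulate")
  txt <- paste(readLines(roi_p), collapse = " ")
  nums <- as.numeric(strsplit(gsub("[^0-9eE+.,[:space:]-]", " ", txt),
                              "[,[:space:]]+")[[1]])
  nums <- nums[!is.na(nums)]
  roi <- roi_polygon(matrix(nums, ncol = 2, byrow = TRUE))
  n_along <- if (is.null(config$grid_along)) config$scene$plants_per_row
             else config$grid_along
  n_across <- if (is.null(config$grid_across)) config$scene$n_rows
              else config$grid_across
  build_plant_grid(roi, n_along, n_across, config$row_azimuth)
}

stage_plants <- function(config) {
  cwsi2d_p <- require_artifact(pipeline_path(config, "cwsi2d.tif"), "cwsi2d")
  cloud_p <- require_artifact(pipeline_path(config, "cwsi_cloud.xyz"), "cwsi3d")
  grid <- pipeline_grid(config)
  ortho <- per_plant_cwsi(grid, read_raster(cwsi2d_p), source = "ortho")
  cloud <- per_plant_cwsi(grid, read_cloud(cloud_p), source = "cloud")
  grid_p <- pipeline_path(config, "plant_grid.wkt")
  ortho_p <- pipeline_path(config, "plants_ortho.tsv")
  cloud_tab_p <- pipeline_path(config, "plants_cloud.tsv")
  write_plant_grid(grid, grid_p)
  write_tsv(ortho, ortho_p)
  write_tsv(cloud, cloud_tab_p)
  stage_manifest(config, "plants", list(cwsi2d_p, cloud_p),
                 list(grid_p, ortho_p, cloud_tab_p),
                 params = list(n_along = grid$n_along,
                               n_across = grid$n_across,
                               row_azimuth = config$row_azimuth))
}

stage_volumes <- function(config) {
  clean_p <- require_artifact(pipeline_path(config, "canopy_clean.xyz"),
                              "classify3d")
  grid <- pipeline_grid(config)
  vols <- plant_volumes(grid, read_cloud(clean_p), source = "cloud")
  vols_p <- pipeline_path(config, "volumes.tsv")
  write_tsv(vols, vols_p)
  outs <- list(vols_p)
  ins <- list(clean_p)
  if (!is.null(config$reference_cloud)) {
    ref_p <- require_artifact(config$reference_cloud, "reference acquisition")
    ref <- read_cloud(ref_p)
    classified <- classify_ground(ref, config$ground)
    terrain <- attr(classified, "terrain")
    canopy <- subset_cloud(classified, classified$class_label == "canopy")
    canopy <- remove_understory(canopy, terrain, config$threshold_m)
    canopy <- trim_bottom(canopy, terrain, config$trim_m)
    ref_vols <- plant_volumes(grid, canopy, source = "reference")
    ref_vols_p <- pipeline_path(config, "volumes_reference.tsv")
    write_tsv(ref_vols, ref_vols_p)
    outs <- c(outs, list(ref_vols_p)); ins <- c(ins, list(ref_p))
  }
  stage_manifest(config, "volumes", ins, outs,
                 params = list(trim_m = config$trim_m))
}

stage_evaluate <- function(config) {
  ortho_p <- require_artifact(pipeline_path(config, "plants_ortho.tsv"),
                              "plants")
  cloud_p <- require_artifact(pipeline_path(config, "plants_cloud.tsv"),
                              "plants")
  records <- list(ortho = utils::read.delim(ortho_p),
                  cloud = utils::read.delim(cloud_p))
  for (nm in names(records))
    records[[nm]]$mean_cwsi[records[[nm]]$n_samples == 0] <- NA
  report <- compare_datasets(records, metric = "mean_cwsi")
  cwsi_rep_p <- pipeline_path(config, "regressions_cwsi.tsv")
  write_report(report, cwsi_rep_p)
  ins <- list(ortho_p, cloud_p)
  outs <- list(cwsi_rep_p)

  vols_p <- pipeline_path(config, "volumes.tsv")
  truth_p <- pipeline_path(config, file.path("scene", "plant_truth.csv"))
  if (file.exists(vols_p) && file.exists(truth_p)) {
    vols <- utils::read.delim(vols_p)
    truth <- utils::read.csv(truth_p)
    truth_rec <- data.frame(plant_id = truth$plant_id,
                            hull_volume = ifelse(truth$true_volume > 0,
                                                 truth$true_volume, NA))
    vrep <- compare_datasets(list(truth = truth_rec, cloud = vols),
                             metric = "hull_volume")
    vol_rep_p <- pipeline_path(config, "regressions_volume.tsv")
    write_report(vrep, vol_rep_p)
    ins <- c(ins, list(vols_p, truth_p))
    outs <- c(outs, list(vol_rep_p))
  }
  stage_manifest(config, "evaluate", ins, outs)
}
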