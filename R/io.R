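#' Write a numeric volume as multi-page 32-bit float TIFF with JSON sidecar
#'
#' Pages are the slow-axis (y) planes of a \code{[z, x, y]} array, or the
#' repeated frames of a \code{[z, x, frame]} sequence. Values are scaled
#' into [0, 1] by the recorded \code{scale} factor (the volume maximum), so
#' the round trip is lossless up to 32-bit float resolution (~1e-7
#' relative). The sidecar \code{<path>.json} records the dimensions, scale,
#' page order and any extra metadata.
#'
#' @param vol numeric 3-D array (or 2-D matrix, written as one page).
#' @param path output TIFF path.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_volume_tiff <- function(vol, path, meta = list()) {
  a <- unclass(vol)
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  stopifnot(length(dim(a)) == 3L)
  sc <- max(a, 0)
  pages <- lapply(seq_len(dim(a)[3]),
                  function(k) if (sc > 0) a[, , k] / sc else a[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- c(list(dim = dim(a), scale = sc,
                    page_order = "third_index_major",
                    format = "float32"), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by \code{\link{write_volume_tiff}}
#'
#' @param path TIFF path (sidecar \code{<path>.json} must exist).
#' @return numeric array with the sidecar attached as attribute
#'   \code{meta}.
#' @export
read_volume_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(unlist(lapply(pages, as.numeric)), dim = unlist(sidecar$dim))
  a <- a * sidecar$scale
  attr(a, "meta") <- sidecar
  a
}

#' Write repeated-frame sequences of a whole acquisition
#'
#' Stores every slow-axis position's frame sequence in one multi-page TIFF,
#' pages ordered position-major then frame (position 1 frames 1..J+1, then
#' position 2, ...), with the scan geometry in the sidecar.
#'
#' @param volume a \code{phantom_volume} or list of \code{frame_sequence}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_frame_volume <- function(volume, path) {
  frames <- if (inherits(volume, "phantom_volume")) volume$frames else volume
  g <- attr(frames[[1]], "geometry")
  nf <- dim(frames[[1]])[3]
  stacked <- array(0, c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                        nf * length(frames)))
  for (y in seq_along(frames))
    stacked[, , (y - 1L) * nf + seq_len(nf)] <- frames[[y]]
  write_volume_tiff(stacked, path,
                    meta = list(kind = "frame_volume",
                                n_positions = length(frames),
                                n_repeats = nf,
                                page_order_detail = "position_major_frame_minor",
                                geometry = unclass(g)))
}

#' Read a frame volume written by \code{\link{write_frame_volume}}
#'
#' @param path TIFF path.
#' @return list of \code{frame_sequence} arrays.
#' @export
read_frame_volume <- function(path) {
  a <- read_volume_tiff(path)
  meta <- attr(a, "meta")
  nf <- meta$n_repeats; np <- meta$n_positions
  g <- do.call(phantom_geometry, meta$geometry[c("n_depth", "n_fast",
                                                 "n_slow", "axial_pixel_um",
                                                 "lateral_pixel_um",
                                                 "n_repeats")])
  lapply(seq_len(np), function(y)
    structure(a[, , (y - 1L) * nf + seq_len(nf), drop = FALSE],
              geometry = g, position = y,
              class = c("frame_sequence", "array")))
}

#' Write / read a study cohort table as CSV
#'
#' Fixed column schema: patient_id, visit, location, bvd, vet_um, vhi, vsq.
#'
#' @param table a \code{study_table} data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the validated data.frame (read).
#' @export
write_cohort_csv <- function(table, path) {
  cols <- c("patient_id", "visit", "location", "bvd", "vet_um", "vhi", "vsq")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("patient_id", "visit", "location", "bvd", "vet_um", "vhi", "vsq")
  missing <- setdiff(cols, names(t))
  if (length(missing))
    stop("cohort CSV missing columns: ", paste(missing, collapse = ", "))
  bad_loc <- setdiff(unique(t$location), c("da", "dp", "pa", "pp"))
  if (length(bad_loc))
    stop("unknown locations in cohort CSV: ", paste(bad_loc, collapse = ", "))
  class(t) <- c("study_table", "data.frame")
  t
}

#' Default pipeline configuration
#'
#' A nested list describing one full simulated-study run: phantom geometry
#' and scene, acquisition, IBDV settings, Frangi/binarization parameters,
#' segmentation, cohort model size and statistics options. Every field can
#' be overridden before passing the list to \code{\link{run_simulate}} /
#' \code{\link{run_full}}; the resolved configuration is written next to
#' the outputs of every run.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    geometry = list(n_depth = 96L, n_fast = 96L, n_slow = 16L,
                    axial_pixel_um = 14, lateral_pixel_um = 35,
                    n_repeats = 4L),
    scene = list(thickness_um = 150, vessel_fraction = 0.2,
                 ablation_grid = FALSE),
    acquisition = list(decorrelation = 1, noise_floor = 0.05),
    ibdv = list(pairing = "interframe", lateral_window = 3L,
                depth_slab = NULL),
    frangi = list(scales = c(1, 2, 3, 4), beta = 0.5),
    binarization = list(method = "otsu", threshold = NULL,
                        hysteresis = 0.5, closing = 5L),
    segmentation = list(method = "classical", probability_threshold = 0.6,
                        min_thickness_px = 3L, max_thickness_px = 60L),
    cohort = list(n_patients = 25L),
    stats = list(test = "paired-t", comparison = "baseline"),
    seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Checks presence and basic types of every required key; the error message
#' lists all offending keys at once.
#'
#' @param config a configuration list (see \code{\link{default_config}}).
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  schema <- list(
    "geometry.n_depth" = is.numeric, "geometry.n_fast" = is.numeric,
    "geometry.n_slow" = is.numeric, "geometry.axial_pixel_um" = is.numeric,
    "geometry.n_repeats" = is.numeric,
    "scene.thickness_um" = is.numeric, "scene.vessel_fraction" = is.numeric,
    "acquisition.decorrelation" = is.numeric,
    "acquisition.noise_floor" = is.numeric,
    "ibdv.pairing" = is.character, "ibdv.lateral_window" = is.numeric,
    "frangi.scales" = is.numeric, "frangi.beta" = is.numeric,
    "binarization.method" = is.character,
    "segmentation.method" = is.character,
    "cohort.n_patients" = is.numeric,
    "stats.test" = is.character,
    "seed" = is.numeric)
  bad <- character()
  for (key in names(schema)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- config
    for (p in parts) val <- if (is.list(val)) val[[p]] else NULL
    if (is.null(val) || !schema[[key]](val)) bad <- c(bad, key)
  }
  if (length(bad))
    stop("invalid configuration; offending keys: ",
         paste(bad, collapse = ", "))
  invisible(config)
}

#' Simulate a phantom acquisition and cohort to disk
#'
#' Builds the tissue scene, renders the repeated-frame volume, generates the
#' study cohort, and writes everything (frame TIFF + sidecar, ground-truth
#' en-face vessel mask, cohort CSV, resolved config, manifest with MD5
#' checksums) into \code{out_dir}. Deterministic under the config seed.
#'
#' @param config configuration list (validated first).
#' @param out_dir output directory (created if needed).
#' @return list with the scene, volume, cohort and manifest, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  validate_config(config)
  if (missing(out_dir) || is.null(out_dir)) stop("missing output path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- do.call(phantom_geometry, config$geometry)
  scene <- make_tissue_scene(g, thickness_um = config$scene$thickness_um,
                             vessel_fraction = config$scene$vessel_fraction,
                             ablation_grid = isTRUE(config$scene$ablation_grid),
                             seed = config$seed)
  vol <- render_phantom_volume(scene,
                               decorrelation = config$acquisition$decorrelation,
                               noise_floor = config$acquisition$noise_floor,
                               seed = config$seed + 1L)
  cohort <- generate_cohort(cohort_effect_model(
    n_patients = config$cohort$n_patients, seed = config$seed + 2L))

  write_frame_volume(vol, file.path(out_dir, "frames.tif"))
  enface_truth <- apply(scene$vessel_mask, c(2, 3), any) * 1
  write_volume_tiff(enface_truth, file.path(out_dir, "vessel_truth.tif"),
                    meta = list(kind = "enface_vessel_truth",
                                vessel_fraction_true =
                                  scene$vessel_fraction_true,
                                vessel_depth_band = scene$vessel_depth_band))
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("frames.tif", "frames.tif.json", "vessel_truth.tif",
             "vessel_truth.tif.json", "cohort.csv", "config.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  message(sprintf("simulated %d-position volume and %d-patient cohort -> %s",
                  g$n_slow, config$cohort$n_patients, out_dir))
  invisible(list(scene = scene, volume = vol, cohort = cohort,
                 manifest = manifest))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes every stage in order: simulate (scene, frames, cohort), IBDV
#' variance volume, en-face projection over the vessel depth slab, Frangi
#' enhancement, binarization and BVD; classical epithelium segmentation and
#' VET on the central B-scan; cohort aggregation, baseline comparisons with
#' stars, and metric/score correlations. Stage outputs and tidy CSVs are
#' persisted under \code{out_dir}; progress and timings go to the message
#' stream. Deterministic (classical path) under the config seed.
#'
#' @param config configuration list.
#' @param out_dir output directory.
#' @return list with scan metrics, aggregates, comparisons and
#'   correlations, invisibly.
#' @export
run_full <- function(config = default_config(), out_dir) {
  t0 <- Sys.time()
  sim <- run_simulate(config, out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  vv <- stage("ibdv", compute_ibdv_volume(sim$volume,
                                          lateral_window =
                                            config$ibdv$lateral_window,
                                          pairing = config$ibdv$pairing))
  slab <- config$ibdv$depth_slab
  if (is.null(slab)) slab <- sim$scene$vessel_depth_band
  ef <- stage("enface", enface_project(vv, slab))
  write_volume_tiff(unclass(ef), file.path(out_dir, "enface.tif"),
                    meta = list(kind = "enface_sigma2", depth_slab = slab))
  vness <- stage("frangi", frangi_vesselness(ef,
                                             scales = config$frangi$scales,
                                             beta = config$frangi$beta))
  mask <- stage("binarize",
                binarize_vessels(vness, method = config$binarization$method,
                                 threshold = config$binarization$threshold,
                                 hysteresis = config$binarization$hysteresis,
                                 closing = config$binarization$closing))
  write_volume_tiff(mask * 1, file.path(out_dir, "vessel_mask.tif"),
                    meta = list(kind = "vessel_mask",
                                threshold = attr(mask, "threshold")))
  bvd <- stage("bvd", compute_bvd(mask))

  mid <- ceiling(dim(sim$volume$structural)[3] / 2)
  seg <- stage("segment", segment_epithelium_classical(
    sim$volume$structural[, , mid],
    min_thickness_px = config$segmentation$min_thickness_px,
    max_thickness_px = config$segmentation$max_thickness_px))
  vet <- stage("vet", compute_vet(seg, config$geometry$axial_pixel_um))

  metrics <- data.frame(scan = "phantom", bvd = bvd$bvd,
                        bvd_truth = sim$scene$vessel_fraction_true,
                        vet_um = vet$mean_vet_um,
                        vet_truth_um = mean(sim$scene$epi_thickness_um),
                        vet_validity = vet$validity)
  utils::write.csv(metrics, file.path(out_dir, "scan_metrics.csv"),
                   row.names = FALSE)

  cohort <- sim$cohort
  agg_bvd <- stage("aggregate", aggregate_study(cohort, "bvd"))
  agg_vet <- aggregate_study(cohort, "vet_um")
  cmp_bvd <- stage("compare", compare_to_baseline(cohort, "bvd",
                                                  test = config$stats$test,
                                                  comparison =
                                                    config$stats$comparison))
  cmp_vet <- compare_to_baseline(cohort, "vet_um", test = config$stats$test,
                                 comparison = config$stats$comparison)
  pairs <- list(c("vhi", "vsq"), c("vsq", "bvd"), c("vhi", "bvd"),
                c("vhi", "vet_um"), c("vsq", "vet_um"))
  cors <- do.call(rbind, lapply(pairs, function(p) {
    cr <- correlate_metrics(cohort, p[1], p[2])
    data.frame(metric_a = p[1], metric_b = p[2], r = cr$r, abs_r = cr$abs_r,
               strength = cr$strength, n = cr$n)
  }))
  utils::write.csv(rbind(cbind(metric = "bvd", agg_bvd),
                         cbind(metric = "vet_um", agg_vet)),
                   file.path(out_dir, "aggregates.csv"), row.names = FALSE)
  utils::write.csv(rbind(cbind(metric = "bvd", cmp_bvd),
                         cbind(metric = "vet_um", cmp_vet)),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  message(sprintf("pipeline complete in %.1f s: BVD %.1f%% (truth %.1f%%), VET %.0f um (truth %.0f um)",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  100 * bvd$bvd, 100 * sim$scene$vessel_fraction_true,
                  vet$mean_vet_um, mean(sim$scene$epi_thickness_um)))
  invisible(list(metrics = metrics, aggregates = list(bvd = agg_bvd,
                                                      vet = agg_vet),
                 comparisons = list(bvd = cmp_bvd, vet = cmp_vet),
                 correlations = cors, bvd = bvd, vet = vet, mask = mask,
                 enface = ef))
}
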