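RUN_CONFIG_KEYS <- c(
  "version", "log_level", "seed", "stages", "input_dir", "output_dir",
  "phantom",
  "plane", "n_slices", "slice_gap_mm", "v_threshold_ms", "blend_mode",
  "background_mode", "stretch_saturation",
  "intensity_threshold",
  "resample_interval_mm", "smooth_factor", "smooth_iterations",
  "n_hd_planes", "voxelize_resolution_mm",
  "extreme_fraction", "bland_altman_k")

#' Pipeline run configuration
#'
#' A declarative configuration mirroring every CLI flag.  Defaults are the
#' protocol parameters: 0.35 mm slice gap, 0.25 m/s velocity threshold,
#' 3 mm centerline resampling with factor 0.5 x 100 smoothing iterations,
#' 1000 comparison planes, 5% extremes, 1.45 x IQR agreement limits.
#' Unknown keys are rejected; the object round-trips losslessly through
#' JSON.
#'
#' @param ... configuration fields overriding the defaults
#' @return an object of class `RunConfig`
#' @export
run_config <- function(...) {
  cfg <- list(version = as.character(utils::packageVersion("cpcmra")),
              log_level = "info", seed = 1L,
              stages = c("phantom", "build", "segment", "compare",
                         "centerline", "hemo", "stats"),
              input_dir = NULL, output_dir = NULL,
              phantom = list(shape = "straight-tube"),
              plane = "transverse", n_slices = NULL, slice_gap_mm = 0.35,
              v_threshold_ms = 0.25, blend_mode = "alpha-mean",
              background_mode = "retain-magnitude",
              stretch_saturation = 0.01,
              intensity_threshold = 0.1,
              resample_interval_mm = 3.0, smooth_factor = 0.5,
              smooth_iterations = 100L,
              n_hd_planes = 1000L, voxelize_resolution_mm = 0.5,
              extreme_fraction = 0.05, bland_altman_k = 1.45)
  ov <- list(...)
  bad <- setdiff(names(ov), RUN_CONFIG_KEYS)
  if (length(bad))
    stop(sprintf("RunConfig: unknown key(s): %s", paste(bad, collapse = ", ")))
  cfg[names(ov)] <- ov
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration (JSON)
#' @param path JSON file
#' @return a `RunConfig` / `path` invisibly
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(bad))
    stop(sprintf("RunConfig: unknown key(s) in '%s': %s", path,
                 paste(bad, collapse = ", ")))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `RunConfig`
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

pipeline_log <- function(config, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CPC-MRA pipeline
#'
#' Executes the requested stages in dependency order — phantom generation
#' (or reading an existing 4D flow directory), CPC-MRA synthesis, threshold
#' segmentation and surfacing, geometric comparison against the truth
#' surface, centerline metrics, wall-shear post-processing and agreement
#' statistics — writing every artifact once under the run directory, plus
#' a manifest with the configuration hash and input hashes.  Reruns with
#' the same configuration reproduce the numeric report.
#'
#' @param config a [run_config()] (`output_dir` required)
#' @return the run directory, invisibly; reports land in
#'   `<output_dir>/reports`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$output_dir))
    stop("run_pipeline: config$output_dir is required")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop(sprintf("run_pipeline: input_dir '%s' does not exist",
                 config$input_dir))
  out <- config$output_dir
  dir.create(file.path(out, "reports"), showWarnings = FALSE,
             recursive = TRUE)
  cfg_path <- file.path(out, "config.json")
  write_run_config(config, cfg_path)
  stages <- config$stages
  truth <- NULL

  ok <- TRUE
  fail_stage <- NULL
  result <- tryCatch({
    if ("phantom" %in% stages) {
      pipeline_log(config, "info", "generating %s phantom",
                   config$phantom$shape %||% "straight-tube")
      spec <- do.call(phantom_spec, c(config$phantom,
                                      list(seed = config$seed)))
      ph <- make_phantom(spec)
      write_phantom(ph, file.path(out, "phantom"))
      dataset <- ph$dataset
      truth <- ph$truth
      spec_used <- spec
    } else {
      if (is.null(config$input_dir))
        stop("run_pipeline: need input_dir when the phantom stage is off")
      dataset <- read_flow4d(config$input_dir)
      spec_used <- NULL
    }

    cpc <- NULL
    mask <- NULL
    surf <- NULL
    if ("build" %in% stages) {
      pipeline_log(config, "info", "building CPC-MRA composite")
      cc <- cpc_config(v_threshold = config$v_threshold_ms,
                       blend_mode = config$blend_mode,
                       background_mode = config$background_mode,
                       stretch_saturation = config$stretch_saturation)
      cpc <- build_cpc(dataset, cc, plane = config$plane,
                       n_slices = config$n_slices,
                       slice_gap = config$slice_gap_mm)
      write_stack(cpc, file.path(out, "cpcmra.nii"))
    }
    if ("segment" %in% stages && !is.null(cpc)) {
      pipeline_log(config, "info", "threshold segmentation")
      mask <- largest_component(
        threshold_segment(cpc, config$intensity_threshold))
      write_mask(mask, file.path(out, "lumen_mask.nii"))
      surf <- mask_to_surface(mask)
      write_stl(surf, file.path(out, "lumen_surface.stl"))
    }
    reports <- list()
    if ("compare" %in% stages && !is.null(surf) && !is.null(truth)) {
      pipeline_log(config, "info", "surface comparison")
      dsc <- dice(surf, truth$surface,
                  resolution = config$voxelize_resolution_mm)
      hd <- slicewise_hd(surf, truth$surface,
                         n_planes = config$n_hd_planes)
      write_similarity_report(dsc, hd,
                              path = file.path(out, "reports",
                                               "similarity.json"))
      reports$similarity <- list(dice = dsc, hd_p95 = hd$hd_p95)
    }
    line <- NULL
    if ("centerline" %in% stages && !is.null(mask) && !is.null(truth)) {
      pipeline_log(config, "info", "centerline metrics")
      ends <- truth$centerline$points[c(1, nrow(truth$centerline$points)), ]
      line <- extract_centerline(mask, ends)
      line <- resample_smooth(line, config$resample_interval_mm,
                              config$smooth_factor,
                              config$smooth_iterations)
      write_centerline_csv(line, file.path(out, "centerline.csv"))
      kap <- curvature(line)
      geo <- list(length_mm = centerline_length(line),
                  tortuosity = tortuosity(line),
                  curvature_median_m1 = stats::median(kap),
                  radius_mean_mm = mean(line$radius))
      jsonlite::write_json(geo, file.path(out, "reports", "centerline.json"),
                           auto_unbox = TRUE, digits = NA)
      reports$centerline <- geo
    }
    if ("hemo" %in% stages && !is.null(spec_used) &&
        spec_used$shape == "straight-tube") {
      pipeline_log(config, "info", "wall-shear post-processing")
      fld <- phantom_wss(spec_used)
      ta <- tawss(fld)
      os <- osi(fld)
      ext <- extreme_regions(ta, config$extreme_fraction)
      hemo <- list(tawss_mean_Pa = mean(ta), tawss_max_Pa = max(ta),
                   osi_max = max(os),
                   n_upper = length(ext$upper), n_lower = length(ext$lower))
      jsonlite::write_json(hemo, file.path(out, "reports", "hemo.json"),
                           auto_unbox = TRUE, digits = NA)
      reports$hemo <- hemo
    }
    if ("stats" %in% stages && !is.null(line) && !is.null(truth)) {
      rad_truth <- rep(truth$radius, length(line$radius))
      ps <- paired_series(line$radius, rad_truth)
      ba <- bland_altman(ps, k = config$bland_altman_k)
      st <- list(
        wilcoxon_p = tryCatch(wilcoxon_signed_rank(ps)$p_value,
                              error = function(e) NA),
        ba_center = ba$center, ba_low = ba$limit_low, ba_high = ba$limit_high)
      jsonlite::write_json(st, file.path(out, "reports", "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      reports$stats <- st
    }
    reports
  }, error = function(e) {
    ok <<- FALSE
    fail_stage <<- conditionMessage(e)
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    e
  })

  manifest <- list(
    tool = "cpcmra", version = as.character(utils::packageVersion("cpcmra")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    input_md5 = if (!is.null(config$input_dir)) {
      fls <- list.files(config$input_dir, full.names = TRUE)
      as.list(tools::md5sum(fls))
    } else NULL,
    seed = config$seed,
    status = if (ok) "ok" else "failed",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!ok) stop(result)
  invisible(out)
}
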