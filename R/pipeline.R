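#' Run the full rice-identification pipeline
#'
#' Executes composite -> features -> standard curves -> SSV -> thresholds ->
#' classification -> evaluation. Deterministic given fixed inputs: two runs on
#' the same config produce identical rasters. Any stage failure aborts with
#' the stage name and cause.
#'
#' Inputs may be in-memory objects or file paths:
#' * `optical` / `sar`: a [temporal_stack()], a `<prefix>_stack.json` manifest
#'   path, or `NULL` (per `mode`);
#' * `dem`: a matrix (with the pipeline grid) or a raster path;
#' * `calendar`: a [crop_calendar()] or a data frame / list of stage windows —
#'   required;
#' * `training` / `validation`: [sample_point_set()]s or CSV/GeoJSON paths;
#' * `mode`: `"combined"` (default), `"optical-only"`, `"sar-only"`;
#' * `scaling`: `"minmax"` (default) or `"none"`;
#' * `thresholds`: `"calibrate"` (default), `"paper"` (the published rule
#'   values 0.98/0.985/0.99/0.985) or a numeric vector of four;
#' * `cloud_threshold`: cloud-score mask cut-off (default 0.3);
#' * `truth`: optional 0/1 matrix of true rice enabling the patch-size and
#'   slope analyses; `size_bins` (m2) and `slope_bins` (degrees) set the bins;
#' * `out_dir`: if given, the rice map, per-stage SSV images, curves,
#'   thresholds and the report are written there.
#'
#' @param config named list (or path to a YAML file) with the fields above.
#' @return A `pipeline_result`: list with `map` ([classify()] output), `ssv`,
#'   `curves`, `thresholds`, `composites` and `report` (metrics, confusion
#'   matrix, mode, skipped sensors, optional patch/slope tables).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$calendar)) {
    stop("config error: calendar missing", call. = FALSE)
  }
  mode <- match.arg(config$mode %||% "combined",
                    c("combined", "optical-only", "sar-only"))
  scaling <- match.arg(config$scaling %||% "minmax", c("minmax", "none"))
  calendar <- if (inherits(config$calendar, "crop_calendar")) config$calendar
              else crop_calendar(as.data.frame(config$calendar))

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs ---------------------------------------------------------------
  inputs <- step("inputs", {
    optical <- load_stack(config$optical, "optical-reflectance")
    sar <- load_stack(config$sar, "sar-db")
    if (mode != "sar-only" && is.null(optical)) {
      stop("config error: mode '", mode, "' needs an optical stack")
    }
    if (mode != "optical-only" && is.null(sar)) {
      stop("config error: mode '", mode, "' needs a SAR stack")
    }
    grid <- if (!is.null(optical)) optical$grid else sar$grid
    if (!is.null(optical) && !is.null(sar)) check_grid(sar$grid, grid, "sar stack")
    dem <- load_dem(config$dem, grid)
    training <- load_samples(config$training, grid, "training")
    validation <- load_samples(config$validation, grid, "validation")
    if (is.null(training)) stop("config error: training samples missing")
    list(optical = optical, sar = sar, grid = grid, dem = dem,
         training = training, validation = validation)
  })
  grid <- inputs$grid

  # ---- terrain features -----------------------------------------------------
  terrain <- step("features", {
    list(elevation = inputs$dem,
         slope = compute_slope(inputs$dem, grid$px))
  })

  # ---- cloud masks (optical only) -------------------------------------------
  use_optical <- mode != "sar-only"
  use_sar <- mode != "optical-only"
  cloud_masks <- NULL
  if (use_optical) {
    cloud_masks <- step("cloud-mask", {
      lapply(inputs$optical$values, function(v)
        cloud_score(v, threshold = config$cloud_threshold %||% 0.3)$mask)
    })
  }

  # ---- per-stage composites and feature images ------------------------------
  images <- step("composite", {
    out <- list()
    for (st in rice_stages()) {
      opt_c <- if (use_optical) mean_composite(inputs$optical, st, calendar,
                                               cloud_masks) else NULL
      sar_c <- if (use_sar) mean_composite(inputs$sar, st, calendar) else NULL
      out[[st]] <- build_stage_feature_image(st, optical = opt_c, sar = sar_c,
                                             terrain = terrain, grid = grid,
                                             mode = mode)
    }
    out
  })

  # ---- standard curves and SSV ----------------------------------------------
  curves <- step("curves", lapply(images, build_standard_curve, points = inputs$training))
  ssv <- step("ssv", {
    stats::setNames(lapply(rice_stages(), function(st)
      ssv_image(images[[st]], curves[[st]], scaling = scaling)), rice_stages())
  })

  # ---- thresholds and classification ----------------------------------------
  thresholds <- step("thresholds", {
    spec <- config$thresholds %||% "calibrate"
    if (is.numeric(spec)) threshold_set(spec, provenance = "user")
    else if (identical(spec, "paper")) default_thresholds()
    else if (identical(spec, "calibrate")) calibrate_thresholds(ssv, inputs$training)
    else stop("config error: thresholds must be 'calibrate', 'paper' or 4 numbers")
  })
  map <- step("classify", classify(ssv, thresholds))

  # ---- evaluation -----------------------------------------------------------
  report <- list(mode = mode, scaling = scaling,
                 features = feature_names(mode),
                 skipped_optical = !use_optical, skipped_sar = !use_sar,
                 thresholds = thresholds)
  if (!is.null(inputs$validation)) {
    report <- c(report, step("evaluate", {
      cm <- confusion(map, inputs$validation)
      list(confusion = cm, metrics = metrics(cm))
    }))
  }
  if (!is.null(config$truth)) {
    report$patch_by_size <- step("evaluate", patch_recognition_by_size(
      config$truth, map, bin_edges = config$size_bins %||% c(0, 400, 800),
      pixel_area = grid$px^2))
    report$by_slope <- step("evaluate", recognition_by_slope(
      config$truth, map, terrain$slope,
      bin_edges = config$slope_bins %||% c(0, 2, 6, 10)))
  }

  result <- structure(list(map = map, ssv = ssv, curves = curves,
                           thresholds = thresholds, composites = images,
                           report = report, grid = grid),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) step("write", write_result(result, config$out_dir))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== rice identification pipeline (", x$report$mode, " mode) ==\n", sep = "")
  print(x$thresholds)
  print(x$map)
  if (!is.null(x$report$metrics)) print(x$report$metrics)
  if (!is.null(x$report$patch_by_size)) {
    cat("recognition by patch size:\n"); print(x$report$patch_by_size)
  }
  if (!is.null(x$report$by_slope)) {
    cat("recognition by slope:\n"); print(x$report$by_slope)
  }
  invisible(x)
}

write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(result$map$values, result$grid, file.path(dir, "rice_map.asc"))
  for (st in rice_stages()) {
    write_ssv(result$ssv[[st]], file.path(dir, paste0("ssv_", st, ".json")))
    write_curve(result$curves[[st]], file.path(dir, paste0("curve_", st, ".csv")))
  }
  th <- result$thresholds
  utils::write.csv(data.frame(stage = rice_stages(), threshold = as.numeric(th),
                              provenance = attr(th, "provenance")),
                   file.path(dir, "thresholds.csv"), row.names = FALSE)
  rep <- result$report
  json_rep <- list(mode = rep$mode, scaling = rep$scaling,
                   thresholds = as.list(stats::setNames(as.numeric(th), names(th))),
                   skipped_optical = rep$skipped_optical,
                   skipped_sar = rep$skipped_sar)
  if (!is.null(rep$metrics)) {
    m <- rep$metrics
    json_rep$metrics <- list(ua_rice = m$ua_rice, pa_rice = m$pa_rice,
                             ua_nonrice = m$ua_nonrice, pa_nonrice = m$pa_nonrice,
                             oa = m$oa, kappa = m$kappa, n = m$n)
    json_rep$confusion = as.list(as.data.frame(unclass(rep$confusion)))
  }
  if (!is.null(rep$patch_by_size)) json_rep$patch_by_size <- rep$patch_by_size
  if (!is.null(rep$by_slope)) json_rep$by_slope <- rep$by_slope
  jsonlite::write_json(json_rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' Read a pipeline config file (YAML)
#'
#' Paths in the file are resolved relative to the file's directory. The
#' `calendar` section may be `default: true` or a list of stage windows.
#'
#' @param path YAML config file.
#' @return Named list ready for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  fix <- function(p) if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  for (key in c("optical", "sar", "dem", "training", "validation", "truth")) {
    cfg[[key]] <- fix(cfg[[key]])
  }
  if (isTRUE(cfg$calendar$default)) cfg$calendar <- crop_calendar()
  else if (!is.null(cfg$calendar)) {
    cfg$calendar <- crop_calendar(data.frame(
      stage = vapply(cfg$calendar, `[[`, "", "stage"),
      start = vapply(cfg$calendar, function(s) as.numeric(s$start), 0),
      end = vapply(cfg$calendar, function(s) as.numeric(s$end), 0)))
  }
  if (is.character(cfg$truth)) cfg$truth <- read_raster(cfg$truth)$values
  cfg
}

load_stack <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "temporal_stack")) return(x)
  if (is.character(x)) return(read_stack_manifest(x))
  stop("config error: stack input must be a temporal_stack or a manifest path")
}

load_dem <- function(x, grid) {
  if (is.null(x)) stop("config error: dem missing", call. = FALSE)
  if (is.matrix(x)) {
    check_layer(x, grid, "dem")
    return(x)
  }
  r <- read_raster(x)
  check_grid(r$grid, grid, "dem")
  r$values
}

load_samples <- function(x, grid, role) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "sample_point_set")) return(x)
  read_samples(x, grid, role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
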