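#' Per-stage mean composite of a temporal stack
#'
#' Per pixel and band, the arithmetic mean over all acquisitions assigned to
#' the stage that are neither nodata nor cloud-masked. SAR dB values are
#' averaged in dB space (stage-mean trajectories are reported in dB), and the
#' mean over ascending/descending acquisitions suppresses terrain-induced
#' backscatter anomalies. A pixel with zero valid dates is nodata.
#'
#' @param stack a [temporal_stack()].
#' @param stage stage name, see [rice_stages()].
#' @param calendar a [crop_calendar()].
#' @param cloud_masks optional list of logical matrices parallel to
#'   `stack$dates` (`TRUE` = drop that date at that pixel); usually from
#'   [cloud_score()] for optical stacks.
#' @return Named list of mean matrices (one per band), with attribute
#'   `n_dates` = number of acquisitions composited.
#' @export
mean_composite <- function(stack, stage, calendar, cloud_masks = NULL) {
  stage <- match.arg(stage, rice_stages())
  sel <- which(assign_stage(stack$dates, calendar) == stage)
  if (length(sel) == 0) {
    stop("stage-coverage error: no ", stack$kind, " acquisitions in stage '",
         stage, "'", call. = FALSE)
  }
  out <- stats::setNames(vector("list", length(stack$bands)), stack$bands)
  for (bn in stack$bands) {
    sum_ <- matrix(0, stack$grid$nrow, stack$grid$ncol)
    n_ <- matrix(0L, stack$grid$nrow, stack$grid$ncol)
    for (i in sel) {
      v <- stack$values[[i]][[bn]]
      bad <- is.na(v)
      if (!is.null(cloud_masks)) bad <- bad | isTRUE_mat(cloud_masks[[i]])
      v[bad] <- 0
      sum_ <- sum_ + v
      n_ <- n_ + !bad
    }
    m <- sum_ / n_
    m[n_ == 0L] <- NA_real_
    out[[bn]] <- m
  }
  attr(out, "n_dates") <- length(sel)
  out
}

# treat NULL mask as all-clear; NA in a mask counts as contaminated
isTRUE_mat <- function(m) {
  if (is.null(m)) return(FALSE)
  m | is.na(m)
}

#' Per-stage multi-band feature image
#'
#' Assembles the stage's feature vector layers in the fixed order of
#' [feature_names()]: composited reflectance bands, indices computed on the
#' composited reflectance (not per-date indices), stage-mean SAR backscatter,
#' and the stage-invariant terrain layers. The valid mask is the conjunction
#' of per-feature validity.
#'
#' @param stage stage name.
#' @param optical composited reflectance (named list of matrices) or `NULL`
#'   in sar-only mode.
#' @param sar composited VH/VV (named list) or `NULL` in optical-only mode.
#' @param terrain named list with `elevation` and `slope` matrices.
#' @param grid the pipeline [raster_grid()].
#' @param mode sensor mode, see [feature_names()].
#' @param registry index formula table, see [compute_index()].
#' @return A `stage_feature_image`: list with `stage`, `features`, `values`
#'   (named list of matrices), `grid`.
#' @export
build_stage_feature_image <- function(stage, optical = NULL, sar = NULL,
                                      terrain, grid,
                                      mode = c("combined", "optical-only", "sar-only"),
                                      registry = index_registry()) {
  mode <- match.arg(mode)
  feats <- feature_names(mode)
  values <- list()
  if (mode != "sar-only") {
    missing <- setdiff(optical_bands(), names(optical))
    if (length(missing)) {
      stop("schema error: optical composite missing band(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (bn in optical_bands()) values[[bn]] <- optical[[bn]]
    for (ix in spectral_indices()) values[[ix]] <- compute_index(optical, ix, registry)
  }
  if (mode != "optical-only") {
    missing <- setdiff(c("vh", "vv"), names(sar))
    if (length(missing)) {
      stop("schema error: SAR composite missing band(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    values$vh <- sar$vh
    values$vv <- sar$vv
  }
  missing <- setdiff(c("elevation", "slope"), names(terrain))
  if (length(missing)) {
    stop("schema error: terrain missing layer(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values$elevation <- terrain$elevation
  values$slope <- terrain$slope
  for (fn in feats) check_layer(values[[fn]], grid, fn)
  structure(list(stage = stage, features = feats, values = values[feats],
                 grid = grid),
            class = "stage_feature_image")
}

#' @export
print.stage_feature_image <- function(x, ...) {
  cat(sprintf("<stage_feature_image> stage '%s', %d features: %s\n",
              x$stage, length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' @rdname build_stage_feature_image
#' @param image a `stage_feature_image`.
#' @return For `valid_mask`: logical matrix, `TRUE` where every feature is
#'   defined.
#' @export
valid_mask <- function(image) {
  ok <- !is.na(image$values[[1]])
  for (v in image$values[-1]) ok <- ok & !is.na(v)
  ok
}

# flatten a stage_feature_image to an n_pixels x n_features matrix
# (column-major pixel order, i.e. index = (col-1)*nrow + row)
image_matrix <- function(image) {
  do.call(cbind, lapply(image$values, as.vector))
}
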