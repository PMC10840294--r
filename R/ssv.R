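#' Rice standard feature curve
#'
#' The reference vector y: the per-feature arithmetic mean over the rice
#' training pixels of one stage's feature image. Points falling on invalid
#' pixels (any feature nodata) are dropped with a message.
#'
#' @param image a stage feature image, see [build_stage_feature_image()].
#' @param points a [sample_point_set()]; only its `label == "rice"` points are
#'   used.
#' @return A `standard_curve`: list with `stage`, `features`, `values`
#'   (numeric vector y), `n` (feature count) and `sample_count`.
#' @export
build_standard_curve <- function(image, points) {
  rice <- points[points$label == "rice", , drop = FALSE]
  if (nrow(rice) == 0) {
    stop("calibration error: no rice training points supplied", call. = FALSE)
  }
  cells <- sample_cells(rice, image$grid)
  X <- image_matrix(image)[cells[, "idx"], , drop = FALSE]
  ok <- stats::complete.cases(X)
  if (any(!ok)) {
    message(sum(!ok), " rice point(s) on invalid pixels dropped from curve for stage '",
            image$stage, "'")
  }
  if (!any(ok)) {
    stop("calibration error: no rice training point falls on a valid pixel in stage '",
         image$stage, "'", call. = FALSE)
  }
  structure(list(stage = image$stage, features = image$features,
                 values = colMeans(X[ok, , drop = FALSE]),
                 n = length(image$features), sample_count = sum(ok)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> stage '%s', %d features, %d rice pixels\n",
              x$stage, x$n, x$sample_count))
  print(round(x$values, 4))
  invisible(x)
}

#' @rdname build_standard_curve
#' @param curve a `standard_curve`.
#' @param path output path for a tabular (CSV) curve file.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(feature = curve$features, value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Per-feature min-max scaling
#'
#' The feature vector mixes reflectance (0-1), indices (-1 to 1 and nm), dB
#' and degrees; without rescaling, the large-magnitude features dominate both
#' the cosine and the distance. `minmax` maps each feature band to \[0, 1\]
#' over its valid pixels (a constant band maps to 0 and is flagged
#' degenerate); the identical record must be applied to the standard curve
#' before any similarity is computed. `none` is the identity, kept for
#' sensitivity analysis.
#'
#' @param image a stage feature image.
#' @param mode `"minmax"` or `"none"`.
#' @return List with `image` (scaled copy) and `record` (data frame
#'   `feature`, `min`, `max`, `degenerate`).
#' @export
scale_features <- function(image, mode = c("minmax", "none")) {
  mode <- match.arg(mode)
  rec <- data.frame(feature = image$features, min = NA_real_, max = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  if (mode == "none") {
    rec$min <- 0; rec$max <- 1
    return(list(image = image, record = rec, mode = mode))
  }
  out <- image
  for (k in seq_along(image$features)) {
    v <- image$values[[k]]
    if (all(is.na(v))) {
      stop("empty-image error: feature '", image$features[k],
           "' has no valid pixels", call. = FALSE)
    }
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    rec$min[k] <- lo; rec$max[k] <- hi
    if (hi == lo) {
      rec$degenerate[k] <- TRUE
      w <- v; w[!is.na(w)] <- 0
      out$values[[k]] <- w
    } else {
      out$values[[k]] <- (v - lo) / (hi - lo)
    }
  }
  list(image = out, record = rec, mode = mode)
}

#' @rdname scale_features
#' @param curve a `standard_curve` to transform with an existing `record`.
#' @param record scaling record returned by `scale_features`.
#' @export
apply_scaling <- function(curve, record) {
  stopifnot(identical(curve$features, record$feature))
  span <- record$max - record$min
  v <- ifelse(record$degenerate, 0, (curve$values - record$min) / span)
  curve$values <- stats::setNames(as.numeric(v), curve$features)
  curve
}

#' Euclidean distance between feature vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dimension error: vectors of length ", length(x), " and ", length(y),
         call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Cosine similarity between feature vectors
#'
#' Clipped to \[-1, 1\] against floating-point overshoot. A zero-norm vector
#' has no direction; callers map it to nodata.
#'
#' @param x,y numeric vectors of equal length.
#' @return `sum(x*y) / (||x|| ||y||)`, or `NA` if either norm is zero.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dimension error: vectors of length ", length(x), " and ", length(y),
         call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  min(max(sum(x * y) / (nx * ny), -1), 1)
}

#' Min-max normalization of a distance image
#'
#' `(d - d_min) / (d_max - d_min)` with the extremes taken over the valid
#' pixels of the whole distance image — the normalization is scene-dependent
#' by construction. A constant-distance image maps to 0 everywhere.
#'
#' @param d distance matrix (nodata = `NA`).
#' @return List with `d_norm`, `d_min`, `d_max`.
#' @export
normalize_distance <- function(d) {
  if (all(is.na(d))) stop("empty-image error: distance image has no valid pixels",
                          call. = FALSE)
  d_min <- min(d, na.rm = TRUE); d_max <- max(d, na.rm = TRUE)
  if (d_max == d_min) {
    dn <- d
    dn[!is.na(dn)] <- 0
  } else {
    dn <- (d - d_min) / (d_max - d_min)
  }
  list(d_norm = dn, d_min = d_min, d_max = d_max)
}

#' Spectral similarity vector image for one stage
#'
#' Scales the feature image (and the curve, with the same record), then per
#' valid pixel computes the cosine similarity CS to the curve and the
#' Euclidean distance d; d is min-max normalized over the scene and
#' `ssv = cs - d_norm`. Pixels with any nodata feature, or with a zero-norm
#' scaled vector, are nodata.
#'
#' @param image a stage feature image.
#' @param curve the matching [build_standard_curve()] output (unscaled).
#' @param scaling `"minmax"` (default) or `"none"`, see [scale_features()].
#' @return An `ssv_image`: list with `stage`, matrices `ssv`, `cs`, `d`,
#'   `d_norm`, scalars `d_min`, `d_max`, and `grid`.
#' @export
ssv_image <- function(image, curve, scaling = c("minmax", "none")) {
  scaling <- match.arg(scaling)
  if (!identical(image$features, curve$features)) {
    stop("dimension error: curve features do not match image features",
         call. = FALSE)
  }
  sc <- scale_features(image, scaling)
  y <- apply_scaling(curve, sc$record)$values
  ny <- sqrt(sum(y^2))
  if (!is.finite(ny) || ny == 0) {
    stop("calibration error: scaled standard curve has zero norm", call. = FALSE)
  }
  X <- image_matrix(sc$image)
  ok <- stats::complete.cases(X)
  nr <- image$grid$nrow; nc <- image$grid$ncol
  cs <- d <- rep(NA_real_, nr * nc)
  Xv <- X[ok, , drop = FALSE]
  nx <- sqrt(rowSums(Xv^2))
  csv <- as.vector(Xv %*% y) / (nx * ny)
  csv[nx == 0] <- NA_real_
  n_zero <- sum(nx == 0)
  if (n_zero > 0) message(n_zero, " zero-norm pixel(s) set to nodata in stage '",
                          image$stage, "'")
  cs[ok] <- pmin(pmax(csv, -1), 1)
  d[ok] <- sqrt(rowSums(sweep(Xv, 2, y)^2))
  d[ok][nx == 0] <- NA_real_
  cs_m <- matrix(cs, nr, nc); d_m <- matrix(d, nr, nc)
  nd <- normalize_distance(d_m)
  structure(list(stage = image$stage, ssv = cs_m - nd$d_norm, cs = cs_m,
                 d = d_m, d_norm = nd$d_norm, d_min = nd$d_min,
                 d_max = nd$d_max, grid = image$grid),
            class = "ssv_image")
}

#' @export
print.ssv_image <- function(x, ...) {
  v <- x$ssv[!is.na(x$ssv)]
  cat(sprintf("<ssv_image> stage '%s', %d valid px, ssv range [%.4f, %.4f], d in [%.4g, %.4g]\n",
              x$stage, length(v), min(v), max(v), x$d_min, x$d_max))
  invisible(x)
}

#' @rdname ssv_image
#' @param x an `ssv_image`.
#' @param path output `.json` manifest path (4 bands: ssv, cs, d, d_norm;
#'   d_min/d_max in metadata).
#' @export
write_ssv <- function(x, path) {
  write_raster(list(ssv = x$ssv, cs = x$cs, d = x$d, d_norm = x$d_norm),
               x$grid, path,
               metadata = list(stage = x$stage, d_min = x$d_min, d_max = x$d_max))
}
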