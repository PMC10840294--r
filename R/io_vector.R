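#' Labeled sample points
#'
#' @param x,y point coordinates (grid CRS).
#' @param label class label per point, drawn from [sample_labels()].
#' @param role `"training"` or `"validation"`.
#' @return A `sample_point_set`: data frame with columns `x`, `y`, `label` and
#'   a `role` attribute. `binary_labels()` maps every non-rice label to
#'   `"non-rice"`.
#' @export
sample_point_set <- function(x, y, label, role = c("training", "validation")) {
  role <- match.arg(role)
  label <- as.character(label)
  bad <- setdiff(unique(label), sample_labels())
  if (length(bad)) {
    stop("vocabulary error: unknown label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(sample_labels(), collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y), label = label,
                       stringsAsFactors = FALSE),
            role = role, class = c("sample_point_set", "data.frame"))
}

#' @rdname sample_point_set
#' @export
sample_labels <- function() {
  c("rice", "water", "built-up", "natural-vegetation", "dry-land",
    "non-rice-other")
}

#' @rdname sample_point_set
#' @param points a `sample_point_set`.
#' @export
binary_labels <- function(points) {
  ifelse(points$label == "rice", "rice", "non-rice")
}

#' Read sample points from CSV or GeoJSON
#'
#' CSV needs columns `x`, `y`, `label`; GeoJSON must be a FeatureCollection of
#' Points with a `label` property. Points outside the grid extent are dropped
#' with a warning giving the count; unknown labels are an error.
#'
#' @param path input file (`.csv` or `.geojson`/`.json`).
#' @param grid the pipeline [raster_grid()] used for the extent check.
#' @param role `"training"` or `"validation"`.
#' @return A [sample_point_set()].
#' @export
read_samples <- function(path, grid, role = c("training", "validation")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) {
      warning("empty sample file: ", path)
      return(sample_point_set(numeric(0), numeric(0), character(0), role))
    }
    need <- c("x", "y", "label")
    if (!all(need %in% names(df))) {
      stop("schema error: ", path, " must have columns x, y, label", call. = FALSE)
    }
  } else {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats) || length(feats) == 0) {
      warning("empty sample file: ", path)
      return(sample_point_set(numeric(0), numeric(0), character(0), role))
    }
    df <- do.call(rbind, lapply(feats, function(f) {
      data.frame(x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 label = f$properties$label, stringsAsFactors = FALSE)
    }))
  }
  pts <- sample_point_set(df$x, df$y, df$label, role)
  rc <- xy_to_rowcol(grid, pts$x, pts$y)
  out <- is.na(rc[, "row"])
  if (any(out)) {
    warning(sum(out), " sample point(s) outside the grid extent dropped")
    pts <- pts[!out, , drop = FALSE]
    attr(pts, "role") <- role
    class(pts) <- c("sample_point_set", "data.frame")
  }
  pts
}

#' @rdname read_samples
#' @param points a [sample_point_set()] to write.
#' @export
write_samples <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("x", "y", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

# rows/cols of sample points on a grid, with validity filter against a mask
sample_cells <- function(points, grid) {
  rc <- xy_to_rowcol(grid, points$x, points$y)
  cbind(rc, idx = (rc[, "col"] - 1L) * grid$nrow + rc[, "row"])
}
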