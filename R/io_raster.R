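#' Raster input/output (ESRI ASCII Grid + JSON manifest)
#'
#' Rasters are stored in the plain-text ESRI ASCII Grid format (`.asc`), one
#' file per band, with full `%.17g` precision so write-then-read round-trips
#' are bit-exact. A multi-band product is a small JSON manifest (`.json`)
#' naming its band files; a temporal stack manifest additionally lists dates
#' and the stack kind. The CRS label is stored in the manifest (or a `.prj`
#' sidecar for bare single-band files).
#'
#' @name raster_io
NULL

ASC_NODATA <- -9999

#' Write a raster layer or multi-band image
#'
#' @param values a matrix (single band) or named list of matrices (multi-band).
#' @param grid the [raster_grid()] the values live on.
#' @param path output path: `.asc` for a single band, `.json` manifest for a
#'   multi-band image (band files are written next to it).
#' @param metadata optional named list stored verbatim in the manifest.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, grid, path, metadata = NULL) {
  if (is.matrix(values)) {
    if (grepl("\\.json$", path)) {
      return(write_raster(list(band1 = values), grid, path, metadata))
    }
    check_layer(values, grid)
    write_asc(values, grid, path)
    writeLines(grid$crs, paste0(path, ".prj"))
    return(invisible(path))
  }
  stopifnot(is.list(values), !is.null(names(values)), grepl("\\.json$", path))
  for (v in values) check_layer(v, grid)
  base <- sub("\\.json$", "", path)
  files <- character(0)
  for (bn in names(values)) {
    f <- paste0(base, "_", gsub("[^A-Za-z0-9_.-]", "_", bn), ".asc")
    write_asc(values[[bn]], grid, f)
    files[bn] <- basename(f)
  }
  manifest <- c(list(format = "ricessv-raster", bands = as.list(files),
                     crs = grid$crs), metadata)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a raster layer or multi-band image
#'
#' @param path an `.asc` file or a `.json` manifest written by [write_raster()].
#' @return A list with elements `values` (matrix for `.asc`, named list of
#'   matrices for a manifest), `grid`, and `metadata` (manifest extras).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.asc$", path)) {
    r <- read_asc(path)
    prj <- paste0(path, ".prj")
    if (file.exists(prj)) r$grid$crs <- readLines(prj, n = 1L)
    return(list(values = r$values, grid = r$grid, metadata = NULL))
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$bands)) stop("schema error: ", path, " is not a raster manifest",
                             call. = FALSE)
  dir <- dirname(path)
  vals <- list()
  grid <- NULL
  for (bn in names(m$bands)) {
    r <- read_asc(file.path(dir, m$bands[[bn]]))
    if (is.null(grid)) {
      grid <- r$grid
    } else {
      check_grid(r$grid, grid, what = m$bands[[bn]])
    }
    vals[[bn]] <- r$values
  }
  if (!is.null(m$crs)) grid$crs <- m$crs
  extras <- m[setdiff(names(m), c("format", "bands", "crs"))]
  list(values = vals, grid = grid, metadata = if (length(extras)) extras)
}

write_asc <- function(values, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", sprintf("%.17g", grid$xmin)),
    paste("yllcorner", sprintf("%.17g", grid$ymax - grid$nrow * grid$px)),
    paste("cellsize", sprintf("%.17g", grid$px)),
    paste("NODATA_value", ASC_NODATA)
  ), con)
  v <- values
  v[is.na(v)] <- ASC_NODATA
  txt <- apply(matrix(sprintf("%.17g", t(v)), nrow = grid$ncol), 2, paste,
               collapse = " ")
  writeLines(txt, con)
  invisible(path)
}

read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("schema error: malformed ASCII grid header in ",
                                 path, call. = FALSE)
  ncol <- as.integer(vals["ncols"]); nrow <- as.integer(vals["nrows"])
  px <- vals["cellsize"]
  grid <- raster_grid(nrow, ncol, xmin = vals[["xllcorner"]],
                      ymax = vals[["yllcorner"]] + nrow * px, px = px)
  x <- scan(path, skip = 6L, quiet = TRUE)
  if (length(x) != nrow * ncol) stop("schema error: ", path, " has ",
                                     length(x), " values, expected ",
                                     nrow * ncol, call. = FALSE)
  m <- matrix(x, nrow = nrow, ncol = ncol, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(values = m, grid = grid)
}

#' Temporal stack of co-registered rasters
#'
#' @param dates acquisition dates (`Date` or coercible); must be strictly
#'   increasing.
#' @param bands band names every date must provide.
#' @param values list (one element per date) of named lists of matrices.
#' @param kind one of `"optical-reflectance"`, `"sar-db"`, `"dem"`.
#' @param grid shared [raster_grid()].
#' @return A `temporal_stack`.
#' @export
temporal_stack <- function(dates, bands, values, kind, grid) {
  kind <- match.arg(kind, c("optical-reflectance", "sar-db", "dem"))
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("schema error: ", length(dates), " dates but ", length(values),
         " value sets", call. = FALSE)
  }
  if (length(dates) > 1 && any(diff(dates) <= 0)) {
    stop("schema error: dates must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(values)) {
    missing <- setdiff(bands, names(values[[i]]))
    if (length(missing)) {
      stop("schema error: date ", format(dates[i]), " is missing band(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (bn in bands) check_layer(values[[i]][[bn]], grid,
                                  paste0(format(dates[i]), "/", bn))
  }
  if (kind == "optical-reflectance") {
    rng <- suppressWarnings(
      range(unlist(lapply(values, function(v) lapply(v[bands], range, na.rm = TRUE))),
            na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
      stop("schema error: optical reflectance outside [0, 1]", call. = FALSE)
    }
  }
  structure(list(dates = dates, bands = bands,
                 values = lapply(values, function(v) v[bands]),
                 kind = kind, grid = grid),
            class = "temporal_stack")
}

#' @export
print.temporal_stack <- function(x, ...) {
  cat(sprintf("<temporal_stack> %s: %d dates (%s .. %s), bands: %s\n",
              x$kind, length(x$dates), format(min(x$dates)), format(max(x$dates)),
              paste(x$bands, collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Read a temporal stack from per-date raster manifests
#'
#' All files must share one grid; a mismatch is an error (never resampled).
#'
#' @param paths per-date raster files (`.json` manifests or single-band `.asc`).
#' @param dates acquisition date per file.
#' @param kind stack kind, see [temporal_stack()].
#' @param bands optional band subset/ordering; defaults to the first file's bands.
#' @return A [temporal_stack()].
#' @export
read_stack <- function(paths, dates, kind, bands = NULL) {
  stopifnot(length(paths) == length(dates))
  ord <- order(as.Date(dates))
  paths <- paths[ord]; dates <- as.Date(dates)[ord]
  grid <- NULL
  values <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    r <- read_raster(paths[i])
    v <- if (is.matrix(r$values)) list(band1 = r$values) else r$values
    if (is.null(grid)) grid <- r$grid else check_grid(r$grid, grid, paths[i])
    values[[i]] <- v
  }
  if (is.null(bands)) bands <- names(values[[1]])
  temporal_stack(dates, bands, values, kind, grid)
}

#' Write a temporal stack
#'
#' Writes one manifest + band files per date and a stack-level manifest
#' (`<prefix>_stack.json`) recording dates and kind.
#'
#' @param stack a [temporal_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Path of the stack manifest, invisibly.
#' @export
write_stack <- function(stack, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(stack$dates))
  for (i in seq_along(stack$dates)) {
    f <- file.path(dir, sprintf("%s_%s.json", prefix, format(stack$dates[i])))
    write_raster(stack$values[[i]], stack$grid, f,
                 metadata = list(date = format(stack$dates[i]), kind = stack$kind))
    files[i] <- basename(f)
  }
  sp <- file.path(dir, paste0(prefix, "_stack.json"))
  jsonlite::write_json(list(format = "ricessv-stack", kind = stack$kind,
                            dates = format(stack$dates), files = files),
                       sp, auto_unbox = TRUE, pretty = TRUE)
  invisible(sp)
}

#' @rdname write_stack
#' @param path a `<prefix>_stack.json` manifest written by [write_stack()].
#' @export
read_stack_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "ricessv-stack")) {
    stop("schema error: ", path, " is not a stack manifest", call. = FALSE)
  }
  read_stack(file.path(dirname(path), m$files), as.Date(m$dates), m$kind)
}
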