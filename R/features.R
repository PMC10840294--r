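#' Optical bands and the default feature set
#'
#' The feature dataset has three categories: the ten surface-reflectance bands,
#' six spectral indices computed from them, two SAR backscatter features
#' (VH, VV, in dB) and two terrain features (elevation in m, slope in degrees).
#' Feature order is fixed so pixel vectors and standard curves align
#' index-by-index across stages.
#'
#' @return Character vectors of names.
#' @export
optical_bands <- function() {
  c("blue", "green", "red", "rededge1", "rededge2", "rededge3",
    "nir", "narrownir", "swir1", "swir2")
}

#' @rdname optical_bands
#' @export
spectral_indices <- function() c("ndvi", "ndwi", "ndrei", "rep", "mtci", "ndsi")

#' @rdname optical_bands
#' @param mode sensor mode: `"combined"`, `"optical-only"` or `"sar-only"`.
#' @export
feature_names <- function(mode = c("combined", "optical-only", "sar-only")) {
  mode <- match.arg(mode)
  opt <- c(optical_bands(), spectral_indices())
  sar <- c("vh", "vv")
  ter <- c("elevation", "slope")
  switch(mode,
         "combined"     = c(opt, sar, ter),
         "optical-only" = c(opt, ter),
         "sar-only"     = c(sar, ter))
}

# index formulas as functions of a named list of band matrices; the literature
# names these indices but band assignments vary, so the table is overridable.
index_registry <- function() {
  list(
    ndvi = function(b) norm_diff(b$nir, b$red),
    ndwi = function(b) norm_diff(b$green, b$nir),
    ndrei = function(b) norm_diff(b$nir, b$rededge1),
    # red-edge position in nm by linear interpolation between 705 and 740 nm
    rep = function(b) {
      den <- b$rededge2 - b$rededge1
      den[!is.na(den) & den == 0] <- NA_real_
      705 + 35 * ((0.5 * (b$rededge3 + b$red) - b$rededge1) / den)
    },
    mtci = function(b) {
      den <- b$rededge1 - b$red
      den[!is.na(den) & den == 0] <- NA_real_
      (b$rededge2 - b$rededge1) / den
    },
    # soil/moisture-sensitive normalized difference (SWIR1 vs NIR)
    ndsi = function(b) norm_diff(b$swir1, b$nir)
  )
}

norm_diff <- function(a, b) {
  den <- a + b
  den[!is.na(den) & den == 0] <- NA_real_
  (a - b) / den
}

#' Compute a spectral index from reflectance bands
#'
#' Pixel-wise; nodata in any required band propagates. Zero denominators give
#' nodata at the affected pixel. Normalized-difference indices are bounded in
#' \[-1, 1\]; `rep` is a wavelength in nm; `mtci` is an unbounded ratio.
#'
#' @param bands named list of reflectance matrices (see [optical_bands()]).
#' @param name index identifier, one of [spectral_indices()].
#' @param registry formula table, overridable to register further indices.
#' @return A matrix of index values.
#' @export
compute_index <- function(bands, name, registry = index_registry()) {
  if (!name %in% names(registry)) {
    stop("unknown index '", name, "'; supported: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  registry[[name]](bands)
}

#' Cloud score and mask
#'
#' A brightness/snow-index heuristic: clouds are bright in the visible bands
#' and the infrared, and not snow. The score is the minimum of rescaled
#' brightness terms (blue; blue+green+red; NIR+SWIR1+SWIR2) and an inverted
#' snow-index term, clamped to \[0, 1\]; pixels scoring strictly above the
#' threshold are masked. The rescaling constants are conventional, not
#' physical, and can be overridden.
#'
#' @param bands named list of reflectance matrices; needs blue, green, red,
#'   nir, swir1, swir2.
#' @param threshold mask cut-off; pixels with `score > threshold` are cloud.
#' @param params rescale ranges per term.
#' @return List with `score` (matrix in \[0, 1\]) and `mask` (logical matrix,
#'   `TRUE` = cloud-contaminated; `NA` where the score is nodata).
#' @export
cloud_score <- function(bands, threshold = 0.3,
                        params = list(blue = c(0.1, 0.3),
                                      visible = c(0.2, 0.8),
                                      infrared = c(0.3, 0.8),
                                      snow = c(0.8, 0.6))) {
  need <- c("blue", "green", "red", "nir", "swir1", "swir2")
  missing <- setdiff(need, names(bands))
  if (length(missing)) {
    stop("schema error: cloud score needs band(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rescale <- function(v, r) pmin(pmax((v - r[1]) / (r[2] - r[1]), 0), 1)
  snow_index <- norm_diff(bands$green, bands$swir1)
  score <- pmin(
    rescale(bands$blue, params$blue),
    rescale(bands$blue + bands$green + bands$red, params$visible),
    rescale(bands$nir + bands$swir1 + bands$swir2, params$infrared),
    rescale(snow_index, params$snow)
  )
  list(score = score, mask = score > threshold)
}

#' Slope from a DEM by Horn's 3x3 method
#'
#' Finite differences over the 3x3 neighbourhood with border rows/columns
#' replicated; any nodata cell in the window makes the output nodata.
#'
#' @param dem elevation matrix (m).
#' @param px pixel size (m).
#' @return Slope in degrees (>= 0).
#' @export
compute_slope <- function(dem, px) {
  stopifnot(is.matrix(dem), px > 0)
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
  a <- sh(-1, -1); b <- sh(-1, 0); c_ <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((c_ + 2 * f + i) - (a + 2 * d + g)) / (8 * px)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + c_)) / (8 * px)
  s <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  s[is.na(dem)] <- NA_real_  # centre cell is part of the window too
  s
}
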