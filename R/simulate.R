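#' Default class trajectories for the scene simulator
#'
#' Per class, stage and feature (10 reflectance bands + VH/VV in dB) mean
#' values, shipped as an editable CSV asset. The rice trajectory follows the
#' qualitative dynamics the method relies on: fields flooded during sowing and
#' transplanting (low reflectance and NDVI, high NDWI, VH below -20 dB), a
#' vegetation peak in the growing stage (NDVI maximum, VH rising to about
#' -15 dB), then senescence at maturity (both declining). Values are
#' plausibility-anchored, not measurements.
#'
#' @param path optional alternative CSV (columns class, stage, feature, value).
#' @return Data frame with columns `class`, `stage`, `feature`, `value`.
#' @export
default_trajectories <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_trajectories.csv", package = "ricessv")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "stage", "feature", "value") %in% names(d)))
  d
}

#' Scene simulator configuration
#'
#' The defaults define the package's reference study conditions: a 256 x 256
#' 10 m grid (one pixel = 100 m2) over hilly terrain, about 30 rice paddies
#' with areas spanning 200-3000 m2 (so sub-400 m2 fragments are present),
#' three optical and three SAR acquisitions per phenological stage, Gaussian
#' pixel noise (SAR noisier than optical, mimicking speckle), rectangular
#' cloud blobs on optical dates, and mixed-pixel blending at paddy edges.
#'
#' @param nrow,ncol grid shape in pixels.
#' @param px pixel size in m.
#' @param n_rice_patches number of rice paddies to place.
#' @param patch_area_range paddy area range in m2.
#' @param flat_frac fraction of paddies restricted to gentle slopes (< 4 deg);
#'   the rest may land on hillsides.
#' @param noise_optical,noise_sar Gaussian noise standard deviations
#'   (reflectance units / dB).
#' @param cloud_fraction per-optical-date cloud cover fraction.
#' @param dem_base,dem_relief base elevation and relief amplitude (m).
#' @param optical_doys,sar_doys named lists (stage -> DOY vector) of
#'   acquisition days in the scene year.
#' @param mixing blend edge rice pixels with their neighbourhood class
#'   (the mixed-pixel effect that limits small-patch recognition).
#' @param sar_slope_bias extra backscatter (dB per degree of slope above
#'   6 deg) emulating terrain-induced anomalies.
#' @param trajectories class trajectory table, see [default_trajectories()].
#' @param background_weights sampling weights of the non-rice background
#'   classes.
#' @param seed integer random seed; the scene is a pure function of the
#'   config including the seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(nrow = 256, ncol = 256, px = 10,
                         n_rice_patches = 30, patch_area_range = c(200, 3000),
                         flat_frac = 0.8,
                         noise_optical = 0.012, noise_sar = 1.0,
                         cloud_fraction = 0.08,
                         dem_base = 300, dem_relief = 80,
                         optical_doys = list(sowing = c(70, 85, 100),
                                             transplanting = c(112, 120, 128),
                                             growing = c(150, 180, 210),
                                             maturity = c(235, 250, 265)),
                         sar_doys = list(sowing = c(72, 87, 102),
                                         transplanting = c(113, 121, 129),
                                         growing = c(152, 182, 212),
                                         maturity = c(237, 252, 267)),
                         mixing = TRUE, sar_slope_bias = 0.2,
                         trajectories = default_trajectories(),
                         background_weights = c("natural-vegetation" = 0.5,
                                                "dry-land" = 0.3,
                                                "built-up" = 0.1,
                                                "water" = 0.1),
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nrow >= 16, ncol >= 16, px > 0, n_rice_patches >= 0,
            length(patch_area_range) == 2, patch_area_range[1] > 0)
  class(cfg) <- "scene_config"
  cfg
}

# lookup table: list[[class]][[stage]] -> named feature vector
trajectory_lookup <- function(trajectories) {
  out <- list()
  for (cl in unique(trajectories$class)) {
    sub <- trajectories[trajectories$class == cl, ]
    out[[cl]] <- lapply(split(sub, sub$stage), function(s)
      stats::setNames(s$value, s$feature))
  }
  out
}

#' Generate a synthetic multi-temporal scene
#'
#' Builds terrain (smooth hills on a regional ramp), a non-rice background
#' (nearest-seed regions of the background classes), rice paddies grown as
#' connected blobs of the configured areas, and per-date optical and SAR
#' stacks sampled as class-stage trajectory mean + Gaussian noise. Cloud blobs
#' overwrite optical reflectance with bright values (so the cloud-score mask
#' can find them); the true masks are also returned. Fully reproducible from
#' the config seed.
#'
#' @param config a [scene_config()].
#' @return A `truth_scene`: list with `classes` (character matrix), `truth`
#'   (0/1 rice matrix), `dem`, `slope`, `optical` and `sar`
#'   [temporal_stack()]s, `cloud_masks` (list parallel to optical dates),
#'   `grid`, `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  grid <- raster_grid(nr, nc, xmin = 0, ymax = nr * config$px, px = config$px,
                      crs = "synthetic-local")
  rowm <- matrix(rep(seq_len(nr), nc), nr, nc)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)

  # --- terrain: eastward ramp + gaussian hills -------------------------------
  dem <- config$dem_base + 0.15 * config$dem_relief * colm / nc * config$px / 10
  n_hills <- max(3L, round(nr * nc / 12000))
  for (i in seq_len(n_hills)) {
    cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
    amp <- stats::runif(1, 0.4, 1) * config$dem_relief
    sig <- stats::runif(1, 0.05, 0.15) * min(nr, nc)
    dem <- dem + amp * exp(-((rowm - cy)^2 + (colm - cx)^2) / (2 * sig^2))
  }
  slope <- compute_slope(dem, config$px)

  # --- background classes: nearest-seed regions ------------------------------
  k <- max(8L, round(nr * nc / 1600))
  seeds_r <- stats::runif(k, 1, nr); seeds_c <- stats::runif(k, 1, nc)
  bg <- names(config$background_weights)
  # every background class gets at least one region so sampling never starves
  seed_cls <- c(bg, sample(bg, k - length(bg), replace = TRUE,
                           prob = config$background_weights))
  best_d <- matrix(Inf, nr, nc)
  cls_idx <- matrix(1L, nr, nc)
  for (i in seq_len(k)) {
    di <- (rowm - seeds_r[i])^2 + (colm - seeds_c[i])^2
    upd <- di < best_d
    best_d[upd] <- di[upd]
    cls_idx[upd] <- i
  }
  classes <- matrix(seed_cls[cls_idx], nr, nc)

  # --- rice paddies: connected random blobs ----------------------------------
  truth <- matrix(0L, nr, nc)
  if (config$n_rice_patches > 0) {
    # log-uniform: paddy-size distributions are right-skewed, and the hilly
    # setting is dominated by small fragmented fields
    areas <- exp(stats::runif(config$n_rice_patches,
                              log(config$patch_area_range[1]),
                              log(config$patch_area_range[2])))
    npix <- pmax(1L, as.integer(round(areas / (config$px^2))))
    on_flat <- stats::runif(config$n_rice_patches) < config$flat_frac
    for (p in seq_along(npix)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- sample.int(nr * nc, 1)
        if (truth[cand] == 1L) next
        if (on_flat[p] && slope[cand] >= 4) next
        blob <- grow_blob(cand, npix[p], truth, nr, nc)
        if (length(blob) == npix[p]) {
          truth[blob] <- 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("generation error: could not place a rice patch of ", npix[p],
             " pixels on the grid", call. = FALSE)
      }
    }
  }

  # --- mixed-pixel weights at paddy edges ------------------------------------
  look <- trajectory_lookup(config$trajectories)
  rice_frac <- box3_mean(truth)
  # dominant non-rice neighbour class per pixel (used for edge blending)
  nbcl <- neighbour_class(classes, truth)

  calendar <- crop_calendar()
  mk_dates <- function(doys) as.Date(doys - 1, origin = "2020-01-01")

  # --- optical stack ---------------------------------------------------------
  o_doys <- sort(unlist(config$optical_doys, use.names = FALSE))
  o_dates <- mk_dates(o_doys)
  cloud_masks <- vector("list", length(o_doys))
  o_vals <- vector("list", length(o_doys))
  for (t in seq_along(o_doys)) {
    st <- assign_stage(o_doys[t], calendar)
    cm <- cloud_blobs(nr, nc, config$cloud_fraction)
    cloud_masks[[t]] <- cm
    bands <- stats::setNames(vector("list", 10), optical_bands())
    for (bn in optical_bands()) {
      base <- class_mean_layer(classes, truth, bn, st, look, rice_frac, nbcl,
                               config$mixing)
      v <- base + stats::rnorm(nr * nc, 0, config$noise_optical)
      v[cm] <- 0.88 + stats::rnorm(sum(cm), 0, 0.02)
      bands[[bn]] <- matrix(pmin(pmax(v, 0), 1), nr, nc)
    }
    o_vals[[t]] <- bands
  }
  optical <- temporal_stack(o_dates, optical_bands(), o_vals,
                            "optical-reflectance", grid)

  # --- SAR stack -------------------------------------------------------------
  s_doys <- sort(unlist(config$sar_doys, use.names = FALSE))
  s_dates <- mk_dates(s_doys)
  sar_bias <- config$sar_slope_bias * pmax(slope - 6, 0)
  s_vals <- vector("list", length(s_doys))
  for (t in seq_along(s_doys)) {
    st <- assign_stage(s_doys[t], calendar)
    pol <- stats::setNames(vector("list", 2), c("vh", "vv"))
    for (bn in c("vh", "vv")) {
      base <- class_mean_layer(classes, truth, bn, st, look, rice_frac, nbcl,
                               config$mixing)
      pol[[bn]] <- matrix(base + sar_bias + stats::rnorm(nr * nc, 0, config$noise_sar),
                          nr, nc)
    }
    s_vals[[t]] <- pol
  }
  sar <- temporal_stack(s_dates, c("vh", "vv"), s_vals, "sar-db", grid)

  structure(list(classes = classes, truth = truth, dem = dem, slope = slope,
                 optical = optical, sar = sar, cloud_masks = cloud_masks,
                 grid = grid, config = config),
            class = "truth_scene")
}

#' @export
print.truth_scene <- function(x, ...) {
  cat(sprintf("<truth_scene> %d x %d px, %d rice px in %d patches, %d optical + %d SAR dates\n",
              x$grid$nrow, x$grid$ncol, sum(x$truth),
              max(label_patches(x$truth == 1)), length(x$optical$dates),
              length(x$sar$dates)))
  invisible(x)
}

# mean class value layer with mixed-pixel blending at rice edges
class_mean_layer <- function(classes, truth, feature, stage, look, rice_frac,
                             nbcl, mixing) {
  nr <- nrow(classes); nc <- ncol(classes)
  v <- matrix(NA_real_, nr, nc)
  for (cl in unique(as.vector(classes))) {
    v[classes == cl] <- look[[cl]][[stage]][[feature]]
  }
  rice_mu <- look[["rice"]][[stage]][[feature]]
  ricepx <- truth == 1L
  if (!mixing) {
    v[ricepx] <- rice_mu
    return(v)
  }
  w <- rice_frac[ricepx]
  nb <- nbcl[ricepx]
  other <- vapply(nb, function(cl)
    if (is.na(cl)) rice_mu else look[[cl]][[stage]][[feature]], numeric(1))
  v[ricepx] <- w * rice_mu + (1 - w) * other
  v
}

# 3x3 box mean of a 0/1 matrix (replicated borders)
box3_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc / 9
}

# most frequent non-rice class in each pixel's 3x3 neighbourhood (NA if none)
neighbour_class <- function(classes, truth) {
  nr <- nrow(classes); nc <- ncol(classes)
  out <- matrix(NA_character_, nr, nc)
  ricepx <- which(truth == 1L)
  for (p in ricepx) {
    r0 <- ((p - 1L) %% nr) + 1L
    c0 <- ((p - 1L) %/% nr) + 1L
    rr <- max(1, r0 - 1):min(nr, r0 + 1)
    cc <- max(1, c0 - 1):min(nc, c0 + 1)
    sub_t <- truth[rr, cc]
    sub_c <- classes[rr, cc]
    nonrice <- sub_c[sub_t == 0L]
    if (length(nonrice)) {
      tb <- table(nonrice)
      out[p] <- names(tb)[which.max(tb)]
    }
  }
  out
}

# grow a connected 4-neighbour blob of `size` pixels from `start`,
# avoiding pixels already marked in `occupied`
grow_blob <- function(start, size, occupied, nr, nc) {
  blob <- start
  frontier <- start
  taken <- c(blob)
  while (length(blob) < size) {
    cand <- integer(0)
    for (p in frontier) {
      r0 <- ((p - 1L) %% nr) + 1L
      c0 <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r0 + d[1]; cc <- c0 + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (!(q %in% taken) && occupied[q] == 0L) cand <- c(cand, q)
        }
      }
    }
    cand <- unique(cand)
    if (!length(cand)) return(blob)  # stuck; caller retries elsewhere
    add <- sample(cand, min(length(cand), size - length(blob)))
    blob <- c(blob, add)
    taken <- c(taken, add)
    frontier <- add
  }
  blob
}

# random rectangular cloud blobs covering ~fraction of the grid
cloud_blobs <- function(nr, nc, fraction) {
  cm <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(cm)
  target <- fraction * nr * nc
  guard <- 0
  while (sum(cm) < target && guard < 100) {
    h <- sample(5:max(6, nr %/% 6), 1)
    w <- sample(5:max(6, nc %/% 6), 1)
    r0 <- sample.int(nr - h + 1, 1)
    c0 <- sample.int(nc - w + 1, 1)
    cm[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
    guard <- guard + 1
  }
  cm
}

#' Draw labeled sample points from a synthetic scene
#'
#' Uniform sampling without replacement within each class. For a fixed seed
#' the per-class ordering is a single permutation: training points are taken
#' from its head and validation points from its tail, so the two roles are
#' disjoint whenever their counts sum to at most the class pixel count.
#'
#' @param scene a `truth_scene`.
#' @param n_per_class named integer vector (names from [sample_labels()]).
#' @param role `"training"` or `"validation"`.
#' @param seed seed for the per-class permutations (use the same seed for both
#'   roles to get disjoint sets).
#' @param rice_interior if `TRUE` (default), rice points are drawn from
#'   patch-interior pixels (3x3 neighbourhood at least two-thirds rice),
#'   emulating ground survey points placed inside paddies rather than on
#'   boundary mixed pixels. The patch-size and slope analyses still see every
#'   rice pixel via the truth raster.
#' @return A [sample_point_set()] of pixel-centre points.
#' @export
sample_points <- function(scene, n_per_class, role = c("training", "validation"),
                          seed = 1L, rice_interior = TRUE) {
  role <- match.arg(role)
  cls <- scene$classes
  cls[scene$truth == 1L] <- "rice"
  interior <- box3_mean(scene$truth) >= 2 / 3
  xs <- ys <- numeric(0); labs <- character(0)
  for (cl in names(n_per_class)) {
    n <- n_per_class[[cl]]
    if (n <= 0) next
    avail <- if (cl == "rice" && rice_interior) {
      which(cls == cl & interior)
    } else {
      which(cls == cl)
    }
    if (length(avail) == 0) {
      stop("sampling error: class '", cl, "' not present in the scene",
           call. = FALSE)
    }
    if (n > length(avail)) {
      stop("sampling error: requested ", n, " '", cl, "' points but only ",
           length(avail), " pixels available", call. = FALSE)
    }
    set.seed(seed + utils::head(utf8ToInt(cl), 1) * 131L)
    perm <- sample(avail)
    idx <- if (role == "training") utils::head(perm, n) else utils::tail(perm, n)
    rc <- cbind(((idx - 1L) %% scene$grid$nrow) + 1L,
                ((idx - 1L) %/% scene$grid$nrow) + 1L)
    xy <- rowcol_to_xy(scene$grid, rc[, 1], rc[, 2])
    xs <- c(xs, xy[, "x"]); ys <- c(ys, xy[, "y"]); labs <- c(labs, rep(cl, n))
  }
  sample_point_set(xs, ys, labs, role)
}

#' Write a synthetic scene to disk
#'
#' Writes the optical and SAR stacks, DEM, truth map and class raster in the
#' package's raster formats, consumable by every CLI subcommand.
#'
#' @param scene a `truth_scene`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$optical, dir, "optical")
  write_stack(scene$sar, dir, "sar")
  write_raster(scene$dem, scene$grid, file.path(dir, "dem.asc"))
  write_raster(scene$truth + 0, scene$grid, file.path(dir, "truth.asc"))
  invisible(dir)
}
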