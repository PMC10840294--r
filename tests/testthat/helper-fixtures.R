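# small in-code fixtures shared across test files

tiny_grid <- function(nr = 4, nc = 5, px = 10) raster_grid(nr, nc, px = px)

# a stage feature image straight from matrices
make_image <- function(values, grid, stage = "sowing") {
  structure(list(stage = stage, features = names(values), values = values,
                 grid = grid),
            class = "stage_feature_image")
}

# minimal ssv_image with given ssv matrix (for classify/threshold tests)
make_ssv <- function(ssv, grid, stage) {
  structure(list(stage = stage, ssv = ssv, cs = ssv * 0, d = ssv * 0,
                 d_norm = ssv * 0, d_min = 0, d_max = 1, grid = grid),
            class = "ssv_image")
}

# four aligned ssv images from a named list of matrices
make_ssv_set <- function(mats, grid) {
  stats::setNames(lapply(rice_stages(), function(st)
    make_ssv(mats[[st]], grid, st)), rice_stages())
}

# constant-band optical list over a grid
const_bands <- function(vals, nr = 4, nc = 5) {
  stats::setNames(lapply(vals, function(v) matrix(v, nr, nc)), names(vals))
}

# brute-force SSV oracle: per-pixel double loop over the scaled image
ssv_oracle <- function(image, curve, scaling = "minmax") {
  sc <- scale_features(image, scaling)
  y <- apply_scaling(curve, sc$record)$values
  nr <- image$grid$nrow; nc <- image$grid$ncol
  cs <- d <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    x <- vapply(sc$image$values, function(m) m[r, c], numeric(1))
    if (any(is.na(x))) next
    if (sum(x^2) == 0) next
    d[r, c] <- euclidean_distance(x, y)
    cs[r, c] <- cosine_similarity(x, y)
  }
  d_min <- min(d, na.rm = TRUE); d_max <- max(d, na.rm = TRUE)
  dn <- if (d_max > d_min) (d - d_min) / (d_max - d_min) else d * 0
  list(ssv = cs - dn, cs = cs, d = d, d_norm = dn)
}

# random feature image for property tests
random_image <- function(nr, nc, n_features, seed, stage = "growing") {
  set.seed(seed)
  vals <- stats::setNames(
    lapply(seq_len(n_features), function(i) matrix(stats::rnorm(nr * nc), nr, nc)),
    paste0("f", seq_len(n_features)))
  make_image(vals, raster_grid(nr, nc), stage)
}

random_curve <- function(image, seed) {
  set.seed(seed + 1)
  structure(list(stage = image$stage, features = image$features,
                 values = stats::setNames(stats::rnorm(length(image$features)),
                                          image$features),
                 n = length(image$features), sample_count = 1L),
            class = "standard_curve")
}

# small default scene reused by several files (cached per session)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene(scene_config(nrow = 96, ncol = 96,
                                            n_rice_patches = 12, seed = 42))
    }
    cache
  }
})
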