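#' Per-stage SSV thresholds
#'
#' @param values numeric vector of four thresholds, in stage order
#'   (sowing, transplanting, growing, maturity).
#' @param provenance `"calibrated"`, `"paper-default"` or `"user"`.
#' @return A `threshold_set` (named numeric vector with a provenance
#'   attribute).
#' @export
threshold_set <- function(values, provenance = "user") {
  stopifnot(length(values) == 4, all(is.finite(values)))
  structure(stats::setNames(as.numeric(values), rice_stages()),
            provenance = provenance, class = "threshold_set")
}

#' @rdname threshold_set
#' @details `default_thresholds()` returns the published decision-rule values
#'   (0.98, 0.985, 0.99, 0.985). Note the source's prose discusses 0.99 at the
#'   maturity stage while its printed rule uses 0.985; the printed rule wins.
#' @export
default_thresholds <- function() {
  threshold_set(c(0.98, 0.985, 0.99, 0.985), provenance = "paper-default")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> (", attr(x, "provenance"), ")\n", sep = "")
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Quartile-rule threshold from labeled SSV samples
#'
#' The optimal cut between rice and non-rice is the mean of the 25% quartile
#' of the rice-sample SSVs and the 75% quartile of the non-rice-sample SSVs.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), the convention under which Q25 of
#' {0.97, 0.98, 0.99, 1.00} is 0.9775.
#'
#' @param rice_ssv,nonrice_ssv numeric vectors of SSV values at rice and
#'   non-rice sample pixels.
#' @param type quantile type passed to [stats::quantile()].
#' @return Scalar threshold.
#' @export
select_threshold <- function(rice_ssv, nonrice_ssv, type = 7) {
  rice_ssv <- rice_ssv[!is.na(rice_ssv)]
  nonrice_ssv <- nonrice_ssv[!is.na(nonrice_ssv)]
  if (length(rice_ssv) == 0 || length(nonrice_ssv) == 0) {
    stop("calibration error: empty rice or non-rice SSV sample", call. = FALSE)
  }
  q_rice <- unname(stats::quantile(rice_ssv, 0.25, type = type))
  q_non <- unname(stats::quantile(nonrice_ssv, 0.75, type = type))
  if (q_rice <= q_non) {
    warning("degenerate class overlap: Q25(rice) = ", signif(q_rice, 6),
            " <= Q75(non-rice) = ", signif(q_non, 6))
  }
  (q_rice + q_non) / 2
}

#' Calibrate all four stage thresholds from training samples
#'
#' Extracts each stage's SSV at the training sample pixels (points on nodata
#' SSV are dropped) and applies [select_threshold()] per stage. The per-stage
#' per-class SSV values are attached as the `histograms` attribute so a
#' rice-vs-non-rice histogram figure can be drawn.
#'
#' @param ssv_images named list of four [ssv_image()]s (names = stages).
#' @param samples training [sample_point_set()] containing rice and non-rice
#'   points.
#' @param type quantile type, see [select_threshold()].
#' @return A [threshold_set()] with provenance `"calibrated"`.
#' @export
calibrate_thresholds <- function(ssv_images, samples, type = 7) {
  check_stage_set(ssv_images)
  lab <- binary_labels(samples)
  th <- numeric(4)
  hists <- list()
  for (k in seq_along(rice_stages())) {
    st <- rice_stages()[k]
    img <- ssv_images[[st]]
    cells <- sample_cells(samples, img$grid)
    v <- img$ssv[cells[, "idx"]]
    rice_v <- v[lab == "rice" & !is.na(v)]
    non_v <- v[lab == "non-rice" & !is.na(v)]
    if (length(rice_v) == 0 || length(non_v) == 0) {
      stop("calibration error: stage '", st,
           "' has no valid rice or non-rice samples", call. = FALSE)
    }
    th[k] <- select_threshold(rice_v, non_v, type = type)
    hists[[st]] <- list(rice = rice_v, nonrice = non_v,
                        by_class = split(v, samples$label))
  }
  out <- threshold_set(th, provenance = "calibrated")
  attr(out, "histograms") <- hists
  out
}

#' Four-stage decision rule
#'
#' A pixel is rice (1) iff its SSV meets or exceeds the stage threshold at
#' every one of the four stages (inclusive `>=`); otherwise 0. Any stage with
#' nodata SSV makes the pixel nodata.
#'
#' @param ssv_images named list of four [ssv_image()]s.
#' @param thresholds a [threshold_set()].
#' @return A `rice_map`: list with `values` (0/1/`NA` matrix), `grid`,
#'   `thresholds`.
#' @export
classify <- function(ssv_images, thresholds) {
  check_stage_set(ssv_images)
  stopifnot(inherits(thresholds, "threshold_set"))
  grid <- ssv_images[[1]]$grid
  out <- matrix(1, grid$nrow, grid$ncol)
  for (st in rice_stages()) {
    s <- ssv_images[[st]]$ssv
    out <- out * (s >= thresholds[[st]])  # NA propagates
  }
  structure(list(values = out, grid = grid, thresholds = thresholds),
            class = "rice_map")
}

#' @export
print.rice_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rice_map> %d rice px, %d non-rice px, %d nodata px\n",
              sum(v == 1, na.rm = TRUE), sum(v == 0, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

check_stage_set <- function(ssv_images) {
  missing <- setdiff(rice_stages(), names(ssv_images))
  if (length(missing)) {
    stop("schema error: missing SSV image(s) for stage(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grid <- ssv_images[[rice_stages()[1]]]$grid
  for (st in rice_stages()[-1]) check_grid(ssv_images[[st]]$grid, grid, st)
  invisible(TRUE)
}
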