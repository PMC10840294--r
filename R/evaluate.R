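#' Confusion matrix against validation points
#'
#' Rows are predicted {rice, non-rice}, columns are reference {rice, non-rice}
#' (every non-rice sub-class collapses to "non-rice"). Points on nodata
#' prediction pixels are dropped with a message.
#'
#' @param pred a `rice_map` from [classify()].
#' @param samples validation [sample_point_set()].
#' @return A `confusion_matrix` (2x2 integer matrix with dimnames).
#' @export
confusion <- function(pred, samples) {
  cells <- sample_cells(samples, pred$grid)
  v <- pred$values[cells[, "idx"]]
  keep <- !is.na(v)
  if (any(!keep)) message(sum(!keep), " validation point(s) on nodata pixels dropped")
  if (!any(keep)) stop("evaluation error: no usable validation points", call. = FALSE)
  predicted <- factor(ifelse(v[keep] == 1, "rice", "non-rice"),
                      levels = c("rice", "non-rice"))
  reference <- factor(binary_labels(samples)[keep], levels = c("rice", "non-rice"))
  cm <- table(predicted = predicted, reference = reference)
  structure(unclass(cm), class = "confusion_matrix")
}

#' @rdname confusion
#' @param counts 2x2 numeric matrix (rows = predicted, cols = reference),
#'   e.g. counts printed in a report.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0), all(counts == round(counts)))
  dimnames(counts) <- list(predicted = c("rice", "non-rice"),
                           reference = c("rice", "non-rice"))
  structure(counts, class = "confusion_matrix")
}

#' Accuracy metrics from a 2x2 confusion matrix
#'
#' User accuracy (per-predicted-class precision), producer accuracy
#' (per-reference-class recall), overall accuracy and Cohen's kappa from the
#' marginals. Ratios with a zero marginal are reported as `NA`
#' (not applicable). `rounded` carries 2-decimal half-up display values
#' computed exactly from the integer counts.
#'
#' @param cm a `confusion_matrix`.
#' @return An `accuracy_report` list: `ua_rice`, `pa_rice`, `ua_nonrice`,
#'   `pa_nonrice`, `oa`, `kappa`, `n`, `cm`, `rounded`.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  if (n <= 0) stop("evaluation error: empty confusion matrix", call. = FALSE)
  rs <- rowSums(cm); cs <- colSums(cm)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tr <- cm[1, 1] + cm[2, 2]
  s <- sum(rs * cs)
  kap <- if (n * n - s > 0) (n * tr - s) / (n * n - s) else NA_real_
  out <- list(
    ua_rice = ratio(cm[1, 1], rs[[1]]),
    pa_rice = ratio(cm[1, 1], cs[[1]]),
    ua_nonrice = ratio(cm[2, 2], rs[[2]]),
    pa_nonrice = ratio(cm[2, 2], cs[[2]]),
    oa = tr / n,
    kappa = kap,
    n = n, cm = cm
  )
  rr <- function(num, den) if (is.na(den) || den <= 0) NA_real_ else round_ratio(num, den)
  out$rounded <- list(
    ua_rice = rr(cm[1, 1], rs[[1]]), pa_rice = rr(cm[1, 1], cs[[1]]),
    ua_nonrice = rr(cm[2, 2], rs[[2]]), pa_nonrice = rr(cm[2, 2], cs[[2]]),
    oa = rr(tr, n),
    kappa = if (n * n - s > 0) round_ratio(n * tr - s, n * n - s) else NA_real_
  )
  structure(out, class = "accuracy_report")
}

# exact half-up rounding of the rational num/den to `digits` decimals,
# done in integer arithmetic so display values never depend on binary
# representation of the quotient
round_ratio <- function(num, den, digits = 2) {
  stopifnot(den > 0)
  sgn <- if (num < 0) -1 else 1
  num <- abs(num)
  scl <- 10^digits
  q <- (num * scl) %/% den
  r <- (num * scl) %% den
  if (2 * r >= den) q <- q + 1
  sgn * q / scl
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> n =", x$n, "\n")
  print(x$cm)
  r <- x$rounded
  cat(sprintf("UA rice %.2f | PA rice %.2f | UA non-rice %.2f | PA non-rice %.2f\n",
              r$ua_rice, r$pa_rice, r$ua_nonrice, r$pa_nonrice))
  cat(sprintf("OA %.2f | kappa %.2f   (unrounded: OA %.6f, kappa %.6f)\n",
              r$oa, r$kappa, x$oa, x$kappa))
  invisible(x)
}

#' Connected-component labelling of a binary raster
#'
#' @param mask logical matrix (`NA` treated as `FALSE`).
#' @param connectivity 8 (default; merges diagonally adjacent paddy pixels,
#'   the conservative choice for fragmented fields) or 4.
#' @return Integer matrix of patch ids (0 = background).
#' @export
label_patches <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  m <- !is.na(mask) & mask
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  todo <- which(m)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((p - 1L) %% nr) + 1L
      c0 <- ((p - 1L) %/% nr) + 1L
      rr <- r0 + offs[, 1]; cc <- c0 + offs[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Recognition rate by true patch size
#'
#' True rice patches are connected components of the truth raster; a truth
#' pixel counts as recognized when the prediction marks it rice (nodata
#' predictions count as unrecognized, i.e. omission). Per area bin the
#' proportion is recognized truth pixels / truth pixels in patches whose area
#' falls in the bin; the patch-weighted variant averages per-patch recognized
#' fractions instead.
#'
#' @param truth logical/0-1 matrix of true rice.
#' @param pred a `rice_map`.
#' @param bin_edges patch-area bin edges in m2 (right-open bins; `Inf`
#'   appended if absent).
#' @param pixel_area pixel area in m2 (100 at 10 m resolution).
#' @param connectivity patch connectivity, see [label_patches()].
#' @param weighting `"pixel"` or `"patch"`.
#' @return Data frame with `bin`, `area_min`, `area_max`, `n_patches`,
#'   `n_pixels`, `proportion`.
#' @export
patch_recognition_by_size <- function(truth, pred, bin_edges = c(0, 400, 800),
                                      pixel_area = 100, connectivity = 8,
                                      weighting = c("pixel", "patch")) {
  weighting <- match.arg(weighting)
  if (is.list(pred)) pred <- pred$values
  stopifnot(all(dim(truth) == dim(pred)))
  tm <- !is.na(truth) & truth == 1
  if (!any(tm)) stop("evaluation error: no rice in truth raster", call. = FALSE)
  edges <- sort(unique(c(bin_edges, Inf)))
  lab <- label_patches(tm, connectivity)
  ids <- seq_len(max(lab))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  rec <- !is.na(pred) & pred == 1
  hit <- vapply(ids, function(i) sum(rec[lab == i]), numeric(1))
  areas <- sizes * pixel_area
  bins <- cut(areas, edges, right = FALSE)
  prop <- vapply(levels(bins), function(b) {
    sel <- which(bins == b)
    if (!length(sel)) return(NA_real_)
    if (weighting == "pixel") sum(hit[sel]) / sum(sizes[sel])
    else mean(hit[sel] / sizes[sel])
  }, numeric(1))
  data.frame(bin = levels(bins),
             area_min = utils::head(edges, -1), area_max = utils::tail(edges, -1),
             n_patches = as.integer(table(bins)),
             n_pixels = as.integer(vapply(levels(bins), function(b)
               sum(sizes[bins == b]), numeric(1))),
             proportion = unname(prop), stringsAsFactors = FALSE)
}

#' Recognition rate by slope interval
#'
#' Per slope bin: recognized true-rice pixels / true-rice pixels in the bin.
#' Empty bins are reported as `NA` (not applicable).
#'
#' @param truth logical/0-1 matrix of true rice.
#' @param pred a `rice_map` (or its values matrix).
#' @param slope slope raster in degrees, aligned with `truth`.
#' @param bin_edges slope bin edges in degrees (right-open; `Inf` appended).
#' @return Data frame with `bin`, `slope_min`, `slope_max`, `n_pixels`,
#'   `proportion`.
#' @export
recognition_by_slope <- function(truth, pred, slope,
                                 bin_edges = c(0, 2, 6, 10)) {
  if (is.list(pred)) pred <- pred$values
  stopifnot(all(dim(truth) == dim(pred)), all(dim(truth) == dim(slope)))
  tm <- !is.na(truth) & truth == 1
  rec <- !is.na(pred) & pred == 1
  edges <- sort(unique(c(bin_edges, Inf)))
  bins <- cut(slope[tm], edges, right = FALSE)
  hit <- rec[tm]
  prop <- tapply(hit, bins, mean)
  npx <- tapply(hit, bins, length)
  data.frame(bin = levels(bins),
             slope_min = utils::head(edges, -1), slope_max = utils::tail(edges, -1),
             n_pixels = as.integer(ifelse(is.na(npx), 0L, npx)),
             proportion = as.numeric(prop), stringsAsFactors = FALSE)
}
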