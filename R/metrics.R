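#' Mean / max absolute deviation between corresponding contour points
#'
#' Distances are taken between corresponding landmarks: by default both
#' contours are resampled to a common point count and the truth contour's
#' start index is rotated to the point nearest the prediction's first
#' point (both contours are first normalized to the counter-clockwise
#' convention). With `resample = FALSE` the inputs are assumed already
#' corresponded and must have equal point counts.
#'
#' @param pred,truth contours.
#' @param n common point count after resampling; default the larger of the
#'   two inputs.
#' @param pixel_spacing physical size of a pixel; distances are multiplied
#'   by it (mm when the spacing is in mm/px, px at the default 1).
#' @param resample resample and start-align before measuring.
#' @return list with `mean`, `sd`, `max` point deviations.
#' @export
contour_mad <- function(pred, truth, n = NULL, pixel_spacing = 1,
                        resample = TRUE) {
  check_scalar(pixel_spacing, "pixel_spacing", lower = 0, strict = TRUE)
  p <- as_contour(pred)
  tr <- as_contour(truth)
  if (resample) {
    if (is.null(n)) n <- max(nrow(p), nrow(tr))
    p <- resample_contour(p, n)
    tr <- resample_contour(tr, n)
    d0 <- rowSums((unclass(tr) -
      matrix(p[1L, ], nrow(tr), 2L, byrow = TRUE))^2)
    k <- which.min(d0)
    tr <- tr[c(k:nrow(tr), seq_len(k - 1L)), , drop = FALSE]
  } else if (nrow(p) != nrow(tr)) {
    stop(sprintf(
      "point-count mismatch: %d vs %d (set resample = TRUE or equalize)",
      nrow(p), nrow(tr)
    ))
  }
  d <- sqrt(rowSums((unclass(p) - unclass(tr))^2)) * pixel_spacing
  list(mean = mean(d), sd = stats::sd(d), max = max(d))
}

#' Overlap metrics between binary masks
#'
#' Counts TP (both set), FP (prediction only), FN (truth only), TN
#' (neither) over pixels and reports Dice = 2TP / (2TP + FP + FN),
#' IoU = TP / (TP + FP + FN) and FPR = FP / (FP + TN). Degenerate
#' conventions: two empty masks give Dice = IoU = 1; FPR is 0 when
#' FP + TN = 0.
#'
#' @param pred,truth binary matrices (logical, or numeric with values 0/1)
#'   of identical dimensions.
#' @return list with `dice`, `iou`, `fpr` and the counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
overlap_metrics <- function(pred, truth) {
  as_binary <- function(m, name) {
    if (is.logical(m)) {
      return(m)
    }
    if (!is.numeric(m) || !all(m %in% c(0, 1))) {
      stop("`", name, "` must be binary (logical or 0/1)")
    }
    m == 1
  }
  p <- as_binary(pred, "pred")
  tr <- as_binary(truth, "truth")
  if (!identical(dim(p), dim(tr))) stop("mask dimensions differ")
  tp <- sum(p & tr)
  fp <- sum(p & !tr)
  fn <- sum(!p & tr)
  tn <- sum(!p & !tr)
  list(
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    fpr = if (fp + tn == 0) 0 else fp / (fp + tn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

# TRUE when any two non-adjacent edges of the closed polygon properly cross.
self_intersects <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 2]
  y <- pts[, 1]
  x2 <- x[c(2:n, 1L)]
  y2 <- y[c(2:n, 1L)]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    j <- j[!(i == 1L & j == n)] # skip edges sharing an endpoint
    if (length(j) == 0L) next
    d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
    d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a closed contour to a binary mask
#'
#' Sets the pixels whose centers (integer row, col) lie inside the closed
#' polygon, by the even-odd (crossing-number) rule.
#'
#' @param contour a closed contour.
#' @param dim target `c(rows, cols)` of the mask.
#' @param check verify the contour is simple (non-self-intersecting) and
#'   error otherwise; segmentation pipelines that tolerate near-degenerate
#'   contours can disable the check, since the even-odd rule itself is
#'   well-defined on any polygon.
#' @return integer 0/1 matrix of the requested dimensions.
#' @export
contour_to_mask <- function(contour, dim, check = TRUE) {
  pts <- as_contour(contour, ensure_ccw = FALSE)
  if (length(dim) != 2L || any(dim < 1)) {
    stop("`dim` must be c(rows, cols)")
  }
  if (check && self_intersects(unclass(pts))) {
    stop("contour is self-intersecting")
  }
  h <- as.integer(dim[1])
  w <- as.integer(dim[2])
  mask <- matrix(0L, h, w)
  y <- pts[, 1]
  x <- pts[, 2]
  n <- length(y)
  yn <- y[c(2:n, 1L)]
  xn <- x[c(2:n, 1L)]
  rlo <- max(1L, as.integer(ceiling(min(y))))
  rhi <- min(h, as.integer(floor(max(y))))
  clo <- max(1L, as.integer(ceiling(min(x))))
  chi <- min(w, as.integer(floor(max(x))))
  if (rhi < rlo || chi < clo) {
    return(mask)
  }
  rr <- rlo:rhi
  cc <- clo:chi
  parity <- matrix(0L, length(rr), length(cc))
  for (e in seq_len(n)) {
    if (y[e] == yn[e]) next
    hit <- (y[e] <= rr) != (yn[e] <= rr)
    if (!any(hit)) next
    xc <- x[e] + (rr[hit] - y[e]) * (xn[e] - x[e]) / (yn[e] - y[e])
    parity[hit, ] <- parity[hit, , drop = FALSE] + outer(xc, cc, `>`)
  }
  mask[rr, cc] <- parity %% 2L
  mask
}
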