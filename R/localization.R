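#' Affine placement of the prior shape
#'
#' The transform-localization parameters place the shape model's mean
#' contour onto a target image: a horizontal (column) translation `tx`, a
#' vertical (row) translation `ty`, a horizontal scale `t1` and a vertical
#' scale `t2`. There is no rotation parameter; residual rotation is
#' absorbed by the shape model's modes. Applied to a point (row, col):
#' `row' = t2 * row + ty`, `col' = t1 * col + tx`.
#'
#' @param tx,ty translation in pixels (column, row).
#' @param t1,t2 horizontal / vertical scale factors, > 0.
#' @return object of class `"transform_localization"`.
#' @export
transform_localization <- function(tx = 0, ty = 0, t1 = 1, t2 = 1) {
  check_scalar(tx, "tx")
  check_scalar(ty, "ty")
  check_scalar(t1, "t1", lower = 0, strict = TRUE)
  check_scalar(t2, "t2", lower = 0, strict = TRUE)
  structure(list(tx = tx, ty = ty, t1 = t1, t2 = t2),
    class = "transform_localization"
  )
}

#' Homogeneous 3x3 matrix of a transform
#' @param tl a transform_localization.
#' @return 3x3 matrix acting on column vectors (row, col, 1).
#' @export
tl_matrix <- function(tl) {
  stopifnot(inherits(tl, "transform_localization"))
  matrix(
    c(
      tl$t2, 0, tl$ty,
      0, tl$t1, tl$tx,
      0, 0, 1
    ),
    nrow = 3L, byrow = TRUE
  )
}

#' Apply an affine placement to a contour
#'
#' Each point is homogenized (appended 1), multiplied by the 3x3 transform
#' matrix, and dehomogenized. Point count is preserved.
#'
#' @param tl a transform_localization.
#' @param prior contour to place.
#' @return the transformed contour.
#' @export
apply_transform <- function(tl, prior) {
  m <- tl_matrix(tl)
  if (abs(det(m)) < 1e-12) stop("singular localization transform")
  pts <- as_contour(prior, ensure_ccw = FALSE)
  h <- cbind(unclass(pts), 1) %*% t(m)
  as_contour(h[, 1:2, drop = FALSE] / h[, 3], ensure_ccw = FALSE)
}

#' Serialize a transform to / from JSON
#' @param tl a transform_localization.
#' @param path JSON file path.
#' @return `read_transform()` returns a transform_localization.
#' @export
write_transform <- function(tl, path) {
  stopifnot(inherits(tl, "transform_localization"))
  jsonlite::write_json(unclass(tl), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  transform_localization(tx = obj$tx, ty = obj$ty, t1 = obj$t1, t2 = obj$t2)
}

#' Bilinear image sampling at fractional coordinates
#'
#' Implements the parameterized-sampling-grid kernel
#' `I'(i) = sum_n sum_m I[n, m] * max(0, 1 - |x_i - m|) * max(0, 1 - |y_i - n|)`:
#' at integer coordinates this collapses to the pixel value; at fractional
#' coordinates it interpolates the four surrounding pixels. Coordinates
#' outside the image are clamped to the nearest edge pixel before
#' interpolation (clamping, rather than the zero the kernel would yield,
#' avoids artificial dark rims in narrow bands near image borders).
#'
#' @param image numeric matrix (rows x cols).
#' @param coords n x 2 matrix of real (row, col) sampling positions.
#' @return numeric vector of n interpolated intensities.
#' @export
bilinear_sample <- function(image, coords) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    stop("`image` must be a non-empty numeric matrix")
  }
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2L)
  if (any(!is.finite(coords))) stop("non-finite sampling coordinate")
  h <- nrow(image)
  w <- ncol(image)
  r <- pmin(pmax(coords[, 1], 1), h)
  cc <- pmin(pmax(coords[, 2], 1), w)
  r0 <- pmax(pmin(floor(r), h - 1L), 1L)
  c0 <- pmax(pmin(floor(cc), w - 1L), 1L)
  fr <- r - r0
  fc <- cc - c0
  r1 <- pmin(r0 + 1L, h)
  c1 <- pmin(c0 + 1L, w)
  (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    (1 - fr) * fc * image[cbind(r0, c1)] +
    fr * (1 - fc) * image[cbind(r1, c0)] +
    fr * fc * image[cbind(r1, c1)]
}

# Area, centroid and second central moments of a simple closed polygon
# (uniform density), via the shoelace / Green's-theorem closed forms.
polygon_moments <- function(points) {
  x <- points[, 2]
  y <- points[, 1]
  n <- length(x)
  xn <- x[c(2:n, 1L)]
  yn <- y[c(2:n, 1L)]
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12 # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12 # integral of x^2 dA
  list(
    area = abs(a),
    centroid = c(row = cy, col = cx),
    sd_row = sqrt(ixx / a - cy^2),
    sd_col = sqrt(iyy / a - cx^2)
  )
}

#' Moment-based affine initializer
#'
#' Training-free stand-in for a learned localizer: the target structure is
#' hypoechoic (darker than its surround), so the image is smoothed and
#' thresholded midway between its robust intensity extremes; the dark
#' region's centroid gives the translation and the ratio of its second
#' central moments to the mean shape's analytic region moments gives the
#' axis scales. Deterministic for a fixed input. Downstream, the narrow
#' band tolerates placement errors up to its half-length, so a coarse
#' initialization suffices.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param model shape model whose mean contour will be placed.
#' @param blur_sigma Gaussian pre-smoothing in pixels.
#' @return a transform_localization.
#' @export
moment_initializer <- function(image, model, blur_sigma = 8) {
  stopifnot(inherits(model, "shape_model"))
  if (!is.matrix(image) || length(image) == 0L) {
    stop("`image` must be a non-empty numeric matrix")
  }
  if (stats::var(as.vector(image)) == 0) {
    stop("no structure to localize: image has zero variance")
  }
  sm <- gaussian_blur(image, blur_sigma)
  qs <- stats::quantile(sm, c(0.02, 0.98), names = FALSE)
  dark <- which(sm < mean(qs), arr.ind = TRUE)
  if (nrow(dark) < 2L) stop("no structure to localize: no dark region found")
  # Shadow artifacts can leave stray dark pixels far from the target;
  # iteratively keep only pixels inside an ellipse of 2.2 standard
  # deviations around the running centroid (a uniform elliptical region
  # has half-axis = 2 sd, so the gate never trims the target itself).
  for (iter in 1:4) {
    cy <- mean(dark[, 1])
    cx <- mean(dark[, 2])
    sy <- stats::sd(dark[, 1])
    sx <- stats::sd(dark[, 2])
    if (sy == 0 || sx == 0) break
    keep <- ((dark[, 1] - cy) / (2.2 * sy))^2 +
      ((dark[, 2] - cx) / (2.2 * sx))^2 <= 1
    if (all(keep)) break
    dark <- dark[keep, , drop = FALSE]
    if (nrow(dark) < 2L) stop("no structure to localize: no dark region found")
  }
  pm <- polygon_moments(mean_shape(model))
  t1 <- stats::sd(dark[, 2]) / pm$sd_col
  t2 <- stats::sd(dark[, 1]) / pm$sd_row
  # translation compensates for any offset of the mean shape's own centroid
  transform_localization(
    tx = mean(dark[, 2]) - t1 * pm$centroid[["col"]],
    ty = mean(dark[, 1]) - t2 * pm$centroid[["row"]],
    t1 = t1,
    t2 = t2
  )
}

#' @export
print.transform_localization <- function(x, ...) {
  cat(sprintf(
    "<transform: tx = %.2f, ty = %.2f, t1 = %.3f, t2 = %.3f>\n",
    x$tx, x$ty, x$t1, x$t2
  ))
  invisible(x)
}
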