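#' Construct a contour from landmark points
#'
#' A contour is an ordered, closed list of N (row, col) landmark points in
#' pixel coordinates. Contours are stored counter-clockwise by convention
#' (positive signed area with x = col, y = row), which makes the outward
#' normal direction unambiguous; clockwise inputs are reversed on load.
#'
#' @param points numeric N x 2 matrix (or data frame) of (row, col) points,
#'   N >= 3, consecutive points distinct.
#' @param ensure_ccw reverse the point order when the signed area is
#'   negative. Internal constructions that must preserve point
#'   correspondence pass `FALSE`.
#' @return an N x 2 matrix of class `"contour"` with columns `row`, `col`.
#' @export
as_contour <- function(points, ensure_ccw = TRUE) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points)) {
    stop("`points` must be a numeric matrix with two columns (row, col)")
  }
  if (nrow(points) < 3L) stop("a contour needs at least 3 points")
  if (any(!is.finite(points))) stop("contour coordinates must be finite")
  nxt <- points[c(2:nrow(points), 1L), , drop = FALSE]
  if (any(rowSums((points - nxt)^2) == 0)) {
    stop("consecutive contour points must be distinct")
  }
  if (ensure_ccw && signed_area(points) < 0) {
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  }
  dimnames(points) <- list(NULL, c("row", "col"))
  class(points) <- c("contour", class(matrix()))
  points
}

#' Signed area of a closed polygon
#'
#' Shoelace formula with x = col, y = row; positive for counter-clockwise
#' contours under the package convention.
#'
#' @param points N x 2 matrix of (row, col) points.
#' @return signed area in square pixels.
#' @export
signed_area <- function(points) {
  x <- points[, 2]
  y <- points[, 1]
  xn <- x[c(2:length(x), 1L)]
  yn <- y[c(2:length(y), 1L)]
  sum(x * yn - xn * y) / 2
}

#' Resample a closed contour to uniform arc-length spacing
#'
#' Places `n` points at equal arc-length steps along the closed polygon,
#' starting at the contour's first stored point and proceeding in the
#' stored orientation (this fixes the sequence start used by the
#' directional smoother downstream).
#'
#' @param contour a contour (or N x 2 matrix).
#' @param n number of output points, >= 3.
#' @return a contour with `n` points.
#' @export
resample_contour <- function(contour, n) {
  check_scalar(n, "n", lower = 3, integer = TRUE)
  pts <- as_contour(contour, ensure_ccw = FALSE)
  m <- nrow(pts)
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
    closed[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  perimeter <- s[m + 1L]
  target <- perimeter * (seq_len(n) - 1L) / n
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (target - s[idx]) / seg[idx]
  out <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE])
  as_contour(out, ensure_ccw = FALSE)
}

#' Read / write contours as CSV or JSON
#'
#' CSV files carry a `row,col` header; JSON files are a list of
#' `[row, col]` pairs. Clockwise inputs are reversed to the
#' counter-clockwise convention on read.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_contour()` returns a contour.
#' @export
read_contour <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pts <- jsonlite::fromJSON(path)
    if (is.list(pts)) pts <- do.call(rbind, pts)
  } else {
    pts <- as.matrix(utils::read.csv(path))
  }
  as_contour(pts)
}

#' @rdname read_contour
#' @param contour contour to write.
#' @export
write_contour <- function(contour, path) {
  pts <- as_contour(contour, ensure_ccw = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(pts), path, digits = NA, matrix = "rowmajor")
  } else {
    utils::write.csv(data.frame(row = pts[, 1], col = pts[, 2]), path,
      row.names = FALSE
    )
  }
  invisible(path)
}

# Flatten an N x 2 contour to the 2N vector (r1, c1, r2, c2, ...) and back.
flatten_contour <- function(points) as.vector(t(points))

unflatten_contour <- function(v) {
  as_contour(matrix(v, ncol = 2L, byrow = TRUE), ensure_ccw = FALSE)
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf(
    "<contour: %d points, signed area %.1f px^2>\n",
    nrow(x), signed_area(x)
  ))
  invisible(x)
}
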