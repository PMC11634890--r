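#' Outward unit normals of a closed contour
#'
#' The normal at point k is perpendicular to the central-difference tangent
#' (point k+1 minus point k-1, cyclic) and oriented outward: positive dot
#' product with the vector from the contour centroid to the point
#' (well-defined for the star-convex shapes this package targets).
#'
#' @param contour a closed contour (N >= 3).
#' @return N x 2 matrix of unit (row, col) normal vectors.
#' @export
compute_normals <- function(contour) {
  pts <- as_contour(contour, ensure_ccw = FALSE)
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1L)), , drop = FALSE]
  tang <- unclass(nxt - prv)
  len <- sqrt(rowSums(tang^2))
  if (any(len == 0)) {
    stop(sprintf(
      "coincident neighbouring points around point %d: tangent undefined",
      which(len == 0)[1L]
    ))
  }
  tang <- tang / len
  nrm <- cbind(-tang[, 2], tang[, 1])
  radial <- sweep(unclass(pts), 2L, colMeans(pts))
  flip <- rowSums(nrm * radial) < 0
  nrm[flip, ] <- -nrm[flip, ]
  colnames(nrm) <- c("row", "col")
  nrm
}

# Internal constructor; tests may build synthetic bands through it.
new_narrowband <- function(IM, GM, normals, offsets, L, contour, image_dim) {
  structure(
    list(
      IM = IM, GM = GM, normals = normals, offsets = offsets,
      L = as.integer(L), n = nrow(GM), contour = contour,
      image_dim = image_dim
    ),
    class = "narrowband"
  )
}

#' Sample the narrow band of normal profiles
#'
#' At each of the N contour points, 2L samples are taken at unit steps
#' along the outward normal at the signed offsets -L..-1, 1..L (the point
#' itself, offset 0, is excluded). Negative offsets lie inside the
#' contour, positive outside. `IM` holds the sampled (row, col)
#' coordinates (an N x 2L x 2 array) and `GM` the bilinearly interpolated
#' gray values, so that `GM` is the image of `IM` under the sampling map.
#'
#' @param image numeric matrix.
#' @param contour prior contour (N points).
#' @param L band half-length in pixels, >= 1.
#' @return object of class `"narrowband"` with fields `IM`, `GM`,
#'   `normals`, `offsets`, `L`, `n`, `contour`, `image_dim`.
#' @export
build_narrowband <- function(image, contour, L) {
  check_scalar(L, "L", lower = 1, integer = TRUE)
  L <- as.integer(L)
  pts <- as_contour(contour, ensure_ccw = FALSE)
  n <- nrow(pts)
  nrm <- compute_normals(pts)
  offs <- c(-L:-1L, 1L:L)
  im <- array(NA_real_, c(n, 2L * L, 2L))
  for (j in seq_along(offs)) {
    im[, j, ] <- unclass(pts) + offs[j] * nrm
  }
  coords <- cbind(as.vector(im[, , 1L]), as.vector(im[, , 2L]))
  gm <- matrix(bilinear_sample(image, coords), nrow = n)
  new_narrowband(im, gm, nrm, offs, L, pts, dim(image))
}

# signed band offset (-L..-1, 1..L) <-> profile position (1..2L)
offset_to_pos <- function(offset, L) {
  ifelse(offset < 0, offset + L + 1L, offset + L)
}

pos_to_offset <- function(pos, L) {
  ifelse(pos <= L, pos - L - 1L, pos - L)
}

#' Convert a boundary estimate back to a contour
#'
#' Point k is the prior contour point displaced along its outward normal
#' by the estimated offset. Integer offsets land exactly on the stored
#' band coordinates `IM`; fractional offsets (as produced by the
#' denoiser) interpolate along the same normal line.
#'
#' @param nb a narrowband.
#' @param est a boundary estimate (or a numeric vector of signed offsets,
#'   one per profile, each within `[-L, L]`).
#' @return a contour with `nb$n` points.
#' @export
band_to_contour <- function(nb, est) {
  stopifnot(inherits(nb, "narrowband"))
  d <- if (inherits(est, "boundary_estimate")) est$offsets else est
  if (length(d) != nb$n) {
    stop(sprintf("estimate has %d offsets; band has %d profiles",
      length(d), nb$n
    ))
  }
  if (any(!is.finite(d)) || any(abs(d) > nb$L)) {
    stop("offset index out of band")
  }
  as_contour(unclass(nb$contour) + d * nb$normals, ensure_ccw = FALSE)
}

#' Export the gray matrix as a PNG for inspection
#'
#' Writes the transposed gray matrix (profiles as columns, inside at the
#' top) so a well-placed band on a darker-inside target shows one
#' dark-to-bright transition per column.
#'
#' @param nb a narrowband.
#' @param path output PNG path.
#' @param magnify integer pixel replication factor.
#' @return the path, invisibly.
#' @export
export_narrowband_png <- function(nb, path, magnify = 1L) {
  stopifnot(inherits(nb, "narrowband"))
  check_scalar(magnify, "magnify", lower = 1, integer = TRUE)
  m <- t(nb$GM)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  if (magnify > 1L) {
    m <- m[rep(seq_len(nrow(m)), each = magnify),
      rep(seq_len(ncol(m)), each = magnify),
      drop = FALSE
    ]
  }
  png::writePNG(m, path)
  invisible(path)
}

#' @export
print.narrowband <- function(x, ...) {
  cat(sprintf(
    "<narrowband: %d profiles x %d samples (L = %d)>\n",
    x$n, ncol(x$GM), x$L
  ))
  invisible(x)
}
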