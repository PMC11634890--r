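#' Generalized Procrustes alignment of training contours
#'
#' Removes translation, isotropic scale and rotation differences between
#' landmark sets by iterative least-squares similarity fitting: each shape
#' is centered and scaled to unit centroid size, rotated onto the evolving
#' mean, and the mean is re-estimated (and re-normalized to zero centroid,
#' unit centroid size) until the summed squared residual stops decreasing.
#' Weights are uniform.
#'
#' @param shapes list of contours with equal point counts (N >= 3).
#' @param tol convergence tolerance on the residual decrease.
#' @param max_iter iteration cap.
#' @return a list with
#'   * `aligned`: list of aligned contours,
#'   * `mean`: the mean shape (zero centroid, unit centroid size),
#'   * `transforms`: per shape, `list(rotation, scale, translation)` such
#'     that `aligned = scale * (x %*% rotation) + translation` (row-vector
#'     convention, points as rows),
#'   * `residuals`: summed squared distance to the mean per iteration.
#' @export
procrustes_align <- function(shapes, tol = 1e-10, max_iter = 100L) {
  if (!is.list(shapes) || length(shapes) < 1L) {
    stop("`shapes` must be a non-empty list of contours")
  }
  shapes <- lapply(shapes, as_contour, ensure_ccw = FALSE)
  ns <- vapply(shapes, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    bad <- which(ns != ns[1L])[1L]
    stop(sprintf(
      "shape %d has %d points but shape 1 has %d: equal point counts required",
      bad, ns[bad], ns[1L]
    ))
  }
  centers <- lapply(shapes, colMeans)
  centered <- Map(function(s, c) sweep(unclass(s), 2L, c), shapes, centers)
  sizes <- vapply(centered, function(m) sqrt(sum(m^2)), numeric(1))
  if (any(sizes == 0)) {
    stop(sprintf(
      "shape %d is degenerate: all points coincident", which(sizes == 0)[1L]
    ))
  }
  unit <- Map(function(m, s) m / s, centered, sizes)

  optimal_rotation <- function(a, b) {
    # rotation R (no reflection) maximizing tr(R' a' b), i.e. aligning a to b
    m <- crossprod(a, b)
    sv <- svd(m)
    d <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    sv$u %*% d %*% t(sv$v)
  }

  mean_shape <- unit[[1L]]
  rotations <- rep(list(diag(2)), length(shapes))
  aligned <- unit
  residuals <- numeric(0)
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    rotations <- lapply(unit, optimal_rotation, b = mean_shape)
    aligned <- Map(function(u, r) u %*% r, unit, rotations)
    mean_new <- Reduce(`+`, aligned) / length(aligned)
    mean_new <- sweep(mean_new, 2L, colMeans(mean_new))
    mean_new <- mean_new / sqrt(sum(mean_new^2))
    resid <- sum(vapply(
      aligned, function(a) sum((a - mean_new)^2), numeric(1)
    ))
    residuals <- c(residuals, resid)
    mean_shape <- mean_new
    if (prev - resid < tol) break
    prev <- resid
  }

  transforms <- Map(function(r, s, c) {
    list(
      rotation = r, scale = 1 / s,
      translation = as.vector(-(c / s) %*% r)
    )
  }, rotations, sizes, centers)

  list(
    aligned = lapply(aligned, as_contour, ensure_ccw = FALSE),
    mean = as_contour(mean_shape, ensure_ccw = FALSE),
    transforms = transforms,
    residuals = residuals
  )
}

#' Fit a point distribution model
#'
#' Builds the statistical shape model from aligned contours: arithmetic
#' mean configuration, biased (1/n) covariance of the flattened landmark
#' vectors, and the smallest number `t` of leading eigen-modes whose
#' cumulative eigenvalue fraction strictly exceeds `mu`.
#'
#' @param aligned list of >= 2 aligned contours with equal point counts.
#' @param mu retained-variance fraction, strictly between 0 and 1
#'   (typically 0.95-0.98).
#' @return an object of class `"shape_model"`: `mean` (2N vector,
#'   interleaved row/col), `P` (2N x t orthonormal mode matrix),
#'   `eigenvalues` (t retained), `eigenvalues_all`, `mu`, `t`, `n_points`,
#'   `n_shapes`.
#' @export
fit_point_distribution_model <- function(aligned, mu = 0.95) {
  if (!is.list(aligned) || length(aligned) < 2L) {
    stop("at least 2 aligned shapes are required")
  }
  check_scalar(mu, "mu", lower = 0, upper = 1, strict = TRUE)
  aligned <- lapply(aligned, as_contour, ensure_ccw = FALSE)
  ns <- vapply(aligned, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("aligned shapes must share a point count")
  n_points <- ns[1L]
  x <- t(vapply(aligned, flatten_contour, numeric(2L * n_points)))
  xbar <- colMeans(x)
  xc <- sweep(x, 2L, xbar)
  cov <- crossprod(xc) / nrow(x) # biased 1/n scatter matrix
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  total <- sum(lam)
  if (total <= 1e-12 * max(1, sum(xbar^2))) {
    t_modes <- 0L
  } else {
    t_modes <- which(cumsum(lam) / total > mu)[1L]
  }
  structure(
    list(
      mean = xbar,
      P = e$vectors[, seq_len(t_modes), drop = FALSE],
      eigenvalues = lam[seq_len(t_modes)],
      eigenvalues_all = lam,
      mu = mu,
      t = t_modes,
      n_points = n_points,
      n_shapes = nrow(x)
    ),
    class = "shape_model"
  )
}

#' Mean shape of a model as a contour
#' @param model a shape model.
#' @return a contour with `model$n_points` points.
#' @export
mean_shape <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  unflatten_contour(model$mean)
}

#' Instantiate a shape from mode coefficients
#'
#' Reconstructs `mean + P %*% s` and reshapes it to a contour; the inverse
#' of [project_shape()] on the span of the retained modes.
#'
#' @param model a shape model.
#' @param s coefficient vector of length `model$t`.
#' @return a contour.
#' @export
reconstruct_shape <- function(model, s) {
  stopifnot(inherits(model, "shape_model"))
  if (length(s) != model$t) {
    stop(sprintf(
      "coefficient vector has length %d; model retains %d modes",
      length(s), model$t
    ))
  }
  v <- model$mean + if (model$t > 0L) drop(model$P %*% s) else 0
  unflatten_contour(v)
}

#' Project a shape onto the model's modes
#'
#' Returns `t(P) %*% (x - mean)`, the least-squares mode coefficients of a
#' shape in the model frame.
#'
#' @param model a shape model.
#' @param x a contour with `model$n_points` points.
#' @return numeric vector of length `model$t`.
#' @export
project_shape <- function(model, x) {
  stopifnot(inherits(model, "shape_model"))
  x <- as_contour(x, ensure_ccw = FALSE)
  if (nrow(x) != model$n_points) {
    stop(sprintf(
      "shape has %d points; model expects %d", nrow(x), model$n_points
    ))
  }
  drop(crossprod(model$P, flatten_contour(x) - model$mean))
}

#' Serialize a shape model to / from JSON
#' @param model a shape model.
#' @param path JSON file path.
#' @return `read_shape_model()` returns a shape model.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  jsonlite::write_json(
    list(
      mean = model$mean,
      P = as.vector(model$P), # column-major, 2*n_points x t
      eigenvalues = model$eigenvalues,
      eigenvalues_all = model$eigenvalues_all,
      mu = model$mu,
      t = model$t,
      n_points = model$n_points,
      n_shapes = model$n_shapes
    ),
    path,
    digits = NA
  )
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  t_modes <- as.integer(obj$t)
  p <- matrix(as.numeric(obj$P), nrow = 2L * obj$n_points, ncol = t_modes)
  structure(
    list(
      mean = as.numeric(obj$mean),
      P = p,
      eigenvalues = as.numeric(obj$eigenvalues),
      eigenvalues_all = as.numeric(obj$eigenvalues_all),
      mu = obj$mu,
      t = t_modes,
      n_points = as.integer(obj$n_points),
      n_shapes = as.integer(obj$n_shapes)
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "<shape_model: %d points, %d shapes, %d/%d modes (mu = %.2f)>\n",
    x$n_points, x$n_shapes, x$t, length(x$eigenvalues_all), x$mu
  ))
  invisible(x)
}
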