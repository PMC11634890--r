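#' Parameters of the bidirectional exponential denoiser
#'
#' @param lambda0 initial decay factor in (0, 1); the effective decay at
#'   step k is `min(lambda0, (1 + k) / (10 + k))`, so early steps weight
#'   the raw data more heavily.
#' @param alpha fusion weight in (0, 1): boundary points judged normal
#'   keep `alpha` of their raw offset; points flagged as curvature
#'   outliers keep only `1 - alpha` and are pulled toward the smoothed
#'   sequence.
#' @param curvature_threshold absolute turning angle (radians) above which
#'   a contour point is flagged anomalous.
#' @param k_step neighbour stride used when measuring the turning angle.
#' @return object of class `"etsd_params"`.
#' @export
etsd_params <- function(lambda0 = 0.9, alpha = 0.9,
                        curvature_threshold = pi / 4, k_step = 1L) {
  check_scalar(lambda0, "lambda0", lower = 0, upper = 1, strict = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  check_scalar(curvature_threshold, "curvature_threshold",
    lower = 0, strict = TRUE
  )
  check_scalar(k_step, "k_step", lower = 1, integer = TRUE)
  structure(
    list(
      lambda0 = lambda0, alpha = alpha,
      curvature_threshold = curvature_threshold, k_step = as.integer(k_step)
    ),
    class = "etsd_params"
  )
}

#' Dynamic decay schedule
#'
#' `min(lambda0, (1 + k) / (10 + k))` for iteration round k >= 1: small at
#' the start (little history has accumulated, so the raw sample dominates)
#' and saturating at `lambda0` as the sequence progresses.
#'
#' @param lambda0 initial decay in (0, 1).
#' @param k iteration round(s), >= 1; vectorized.
#' @return decay value(s).
#' @export
lambda_schedule <- function(lambda0, k) {
  check_scalar(lambda0, "lambda0", lower = 0, upper = 1, strict = TRUE)
  if (length(k) == 0L || any(!is.finite(k)) || any(k < 1) ||
    any(k != round(k))) {
    stop("`k` must contain whole numbers >= 1")
  }
  pmin(lambda0, (1 + k) / (10 + k))
}

#' Forward exponential time-series denoising
#'
#' Exponentially weighted moving average with bias correction: a
#' zero-initialized accumulator `m_k = lambda_k * m_{k-1} +
#' (1 - lambda_k) * x_k` is divided by `1 - prod(lambda_1..lambda_k)`, the
#' exact normalizer of its weights. The first output therefore equals the
#' first input, every output is a convex combination of the inputs seen so
#' far (hence bounded by their running min and max), and for a constant
#' decay the correction reduces to the familiar `1 - lambda^k`.
#'
#' @param x numeric sequence (the signed band offsets, in practice).
#' @param lambda0 initial decay in (0, 1).
#' @param dynamic use the [lambda_schedule()]; `FALSE` holds the decay
#'   fixed at `lambda0`.
#' @return smoothed sequence, same length as `x`.
#' @export
etsd_forward <- function(x, lambda0 = 0.9, dynamic = TRUE) {
  if (length(x) == 0L) stop("empty sequence")
  check_scalar(lambda0, "lambda0", lower = 0, upper = 1, strict = TRUE)
  out <- numeric(length(x))
  acc <- 0
  lam_prod <- 1
  for (k in seq_along(x)) {
    lam <- if (dynamic) lambda_schedule(lambda0, k) else lambda0
    acc <- lam * acc + (1 - lam) * x[k]
    lam_prod <- lam_prod * lam
    out[k] <- acc / (1 - lam_prod)
  }
  out
}

#' Backward exponential time-series denoising
#'
#' The second, reverse-direction pass: identical to [etsd_forward()] run
#' on the reversed sequence, with the result reversed back.
#'
#' @inheritParams etsd_forward
#' @return smoothed sequence, same length as `x`.
#' @export
etsd_backward <- function(x, lambda0 = 0.9, dynamic = TRUE) {
  rev(etsd_forward(rev(x), lambda0 = lambda0, dynamic = dynamic))
}

#' Turning angle at each contour point
#'
#' The angle between the segment to the point `k_step` ahead and the
#' segment from the point `k_step` behind (cyclic), wrapped to (-pi, pi].
#' Zero on a straight run; the exterior angle 2*pi/n on a regular n-gon.
#'
#' @param contour a closed contour.
#' @param k_step neighbour stride, >= 1.
#' @return numeric vector of N angles in radians.
#' @export
curvature <- function(contour, k_step = 1L) {
  check_scalar(k_step, "k_step", lower = 1, integer = TRUE)
  pts <- as_contour(contour, ensure_ccw = FALSE)
  n <- nrow(pts)
  ahead <- pts[((seq_len(n) - 1L + k_step) %% n) + 1L, , drop = FALSE]
  behind <- pts[((seq_len(n) - 1L - k_step) %% n) + 1L, , drop = FALSE]
  d1 <- unclass(ahead - pts)
  d0 <- unclass(pts - behind)
  if (any(rowSums(d1^2) == 0) || any(rowSums(d0^2) == 0)) {
    stop("coincident points in a curvature triple")
  }
  # x = col, y = row
  theta <- atan2(d1[, 1], d1[, 2]) - atan2(d0[, 1], d0[, 2])
  theta <- theta %% (2 * pi)
  theta[theta > pi] <- theta[theta > pi] - 2 * pi
  theta
}

#' Flag curvature outliers on a contour
#'
#' A point is anomalous when its absolute turning angle exceeds the
#' threshold — a displaced boundary point creates a sharp kink that the
#' smooth anatomy cannot produce.
#'
#' @param contour a closed contour.
#' @param params an [etsd_params()] object.
#' @param k_step neighbour stride; defaults to the one in `params`.
#' @return logical vector, `TRUE` at anomalous points.
#' @export
detect_outliers <- function(contour, params = etsd_params(),
                            k_step = params$k_step) {
  stopifnot(inherits(params, "etsd_params"))
  abs(curvature(contour, k_step)) > params$curvature_threshold
}

#' Fuse raw and smoothed sequences under an anomaly mask
#'
#' Normal points keep most of their raw value (`alpha * raw +
#' (1 - alpha) * smooth`); flagged points are pulled to the smoothed
#' sequence (`(1 - alpha) * raw + alpha * smooth`).
#'
#' @param raw,smooth numeric sequences of equal length.
#' @param mask logical anomaly flags, same length.
#' @param alpha fusion weight in (0, 1).
#' @return fused sequence.
#' @export
fuse <- function(raw, smooth, mask, alpha) {
  if (length(raw) != length(smooth) || length(raw) != length(mask)) {
    stop("`raw`, `smooth` and `mask` must have equal lengths")
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  ifelse(mask, (1 - alpha) * raw + alpha * smooth,
    alpha * raw + (1 - alpha) * smooth
  )
}

#' Bidirectional denoising of a boundary estimate
#'
#' Round 1: forward smoothing of the offset sequence, curvature-based
#' outlier detection on the corresponding contour, and fusion. Round 2:
#' backward smoothing of the fused sequence, detection, and fusion again.
#' The final offsets are clamped to the band. The closed contour is
#' treated as an open sequence per pass, starting at point 1 (fixed by the
#' resampling convention).
#'
#' @param est a boundary_estimate (from [base_operator()] or [nnvo()]).
#' @param nb the narrowband the estimate lives on.
#' @param params an [etsd_params()] object.
#' @return a boundary_estimate with (generally fractional) denoised
#'   offsets and a `diagnostics` field holding the per-stage sequences and
#'   anomaly masks.
#' @export
bidirectional_denoise <- function(est, nb, params = etsd_params()) {
  stopifnot(inherits(nb, "narrowband"), inherits(params, "etsd_params"))
  raw <- as.numeric(if (inherits(est, "boundary_estimate")) {
    est$offsets
  } else {
    est
  })
  if (length(raw) != nb$n) {
    stop("estimate length does not match the band")
  }

  fwd <- etsd_forward(raw, params$lambda0)
  mask1 <- detect_outliers(band_to_contour(nb, raw), params)
  fused1 <- fuse(raw, fwd, mask1, params$alpha)

  bwd <- etsd_backward(fused1, params$lambda0)
  mask2 <- detect_outliers(band_to_contour(nb, clamp_band(fused1, nb$L)),
    params
  )
  fused2 <- fuse(fused1, bwd, mask2, params$alpha)
  final <- clamp_band(fused2, nb$L)

  out <- new_boundary_estimate(final, rep(NA_real_, nb$n), nb$L)
  out$diagnostics <- list(
    raw = raw, forward = fwd, anomalies_forward = mask1, fused_forward = fused1,
    backward = bwd, anomalies_backward = mask2
  )
  out
}

clamp_band <- function(x, L) pmin(pmax(x, -L), L)
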