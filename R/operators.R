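# Boundary proposal operators on the narrow band.
#
# At a candidate position along a profile, the objective is the cumulative
# gray difference: the samples just outside the position minus the samples
# just inside. On a darker-inside target the true boundary maximizes it.
# Windows are truncated where they would leave the band, and each window
# sum is divided by its sample count: without the normalization a
# truncated window loses mass purely through its shorter length, which
# systematically drags the argmax toward the band center whenever the
# default full half-band window is in use. Where both windows are complete
# the normalized score is the plain windowed sum divided by the constant
# `half_window`, so the argmax is unchanged there.

# N x 2L matrix of count-normalized outer-minus-inner window sums;
# positions with an empty side (the first and last sample) are NA.
band_scores <- function(GM, half_window) {
  n <- nrow(GM)
  m <- ncol(GM)
  w <- half_window
  if (m < 3L) stop("band too narrow for the operator: need L >= 2")
  cs <- cbind(0, t(apply(GM, 1L, cumsum))) # cs[, p + 1] = sum of samples 1..p
  s <- matrix(NA_real_, n, m)
  for (p in 2:(m - 1L)) {
    hi <- min(m, p + w)
    lo <- max(1L, p - w)
    s[, p] <- (cs[, hi + 1L] - cs[, p + 1L]) / (hi - p) -
      (cs[, p] - cs[, lo]) / (p - lo)
  }
  s
}

# Argmax with the tie rule: highest score, then smallest |offset|, then the
# inside (negative) offset — absent evidence the prior is the best guess.
argmax_position <- function(score_row, L) {
  best <- max(score_row, na.rm = TRUE)
  cand <- which(score_row == best)
  offs <- pos_to_offset(cand, L)
  cand[order(abs(offs), offs)][1L]
}

new_boundary_estimate <- function(offsets, scores, L) {
  structure(
    list(offsets = offsets, scores = scores, L = as.integer(L)),
    class = "boundary_estimate"
  )
}

#' Cumulative gray difference at one band position
#'
#' Returns the sum of the `half_window` samples outside the position minus
#' the sum of the `half_window` samples inside it, on profile `k` of the
#' band. This strict form requires both windows to lie entirely inside the
#' band; the operators below use the same objective with windows truncated
#' at the band ends, which coincides with this wherever both are defined.
#'
#' @param nb a narrowband.
#' @param k profile index (1..N).
#' @param offset signed band offset in `-L..-1, 1..L`.
#' @param half_window window length per side, >= 1.
#' @return the objective value.
#' @export
cumulative_gray_difference <- function(nb, k, offset, half_window) {
  stopifnot(inherits(nb, "narrowband"))
  check_scalar(k, "k", lower = 1, upper = nb$n, integer = TRUE)
  check_scalar(half_window, "half_window", lower = 1, integer = TRUE)
  check_scalar(offset, "offset", integer = TRUE)
  if (offset == 0 || abs(offset) > nb$L) stop("offset index out of band")
  m <- 2L * nb$L
  p <- offset_to_pos(offset, nb$L)
  if (p + half_window > m || p - half_window < 1L) {
    stop("window exceeds the band")
  }
  sum(nb$GM[k, (p + 1L):(p + half_window)]) -
    sum(nb$GM[k, (p - half_window):(p - 1L)])
}

#' Per-profile boundary proposal by maximum cumulative gray difference
#'
#' For each profile independently, returns the band offset maximizing the
#' (truncated) cumulative gray difference. Ties break toward the offset
#' closest to zero, then toward the inside.
#'
#' @param nb a narrowband.
#' @param half_window window length per side; defaults to the full
#'   half-band `L`.
#' @return object of class `"boundary_estimate"`: signed `offsets` (one
#'   per profile), achieved `scores`, and `L`.
#' @export
base_operator <- function(nb, half_window = nb$L) {
  stopifnot(inherits(nb, "narrowband"))
  check_scalar(half_window, "half_window", lower = 1, integer = TRUE)
  s <- band_scores(nb$GM, half_window)
  pos <- vapply(seq_len(nb$n), function(k) argmax_position(s[k, ], nb$L), 1L)
  new_boundary_estimate(
    pos_to_offset(pos, nb$L), s[cbind(seq_len(nb$n), pos)], nb$L
  )
}

#' Neighbourhood normal vector operator
#'
#' Pools the cumulative gray difference over a cyclic window of
#' neighbouring profiles before taking the argmax: profile k's score at a
#' position is the sum of the per-profile scores of profiles
#' k - m_left .. k + m_right at that same position. Pooling suppresses
#' outliers caused by a single locally corrupted profile. The asymmetric
#' default window (10 before, 5 after) follows the operating point used
#' with N = 100 profiles.
#'
#' @inheritParams base_operator
#' @param m_left,m_right number of neighbouring profiles pooled before /
#'   after each profile (cyclic); `m_left + m_right` must be < N.
#' @return a boundary_estimate (scores are the pooled objective).
#' @export
nnvo <- function(nb, half_window = nb$L, m_left = 10L, m_right = 5L) {
  stopifnot(inherits(nb, "narrowband"))
  check_scalar(half_window, "half_window", lower = 1, integer = TRUE)
  check_scalar(m_left, "m_left", lower = 0, integer = TRUE)
  check_scalar(m_right, "m_right", lower = 0, integer = TRUE)
  if (m_left + m_right >= nb$n) {
    stop("m_left + m_right must be smaller than the number of profiles")
  }
  s <- band_scores(nb$GM, half_window)
  pooled <- matrix(0, nb$n, ncol(s))
  for (shift in seq.int(-m_left, m_right)) {
    idx <- ((seq_len(nb$n) - 1L + shift) %% nb$n) + 1L
    pooled <- pooled + s[idx, , drop = FALSE]
  }
  pos <- vapply(
    seq_len(nb$n), function(k) argmax_position(pooled[k, ], nb$L), 1L
  )
  new_boundary_estimate(
    pos_to_offset(pos, nb$L), pooled[cbind(seq_len(nb$n), pos)], nb$L
  )
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf(
    "<boundary_estimate: %d profiles, offsets in [%.2f, %.2f] (L = %d)>\n",
    length(x$offsets), min(x$offsets), max(x$offsets), x$L
  ))
  invisible(x)
}
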