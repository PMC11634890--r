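# Independent brute-force oracles, kept deliberately naive.

# Eq.-style bilinear kernel evaluated as a full double loop over pixels.
brute_bilinear <- function(image, coords) {
  h <- nrow(image)
  w <- ncol(image)
  apply(coords, 1, function(p) {
    acc <- 0
    for (n in seq_len(h)) {
      for (m in seq_len(w)) {
        acc <- acc + image[n, m] *
          max(0, 1 - abs(p[2] - m)) * max(0, 1 - abs(p[1] - n))
      }
    }
    acc
  })
}

# Count-normalized truncated outer-minus-inner window score at one band
# position, computed with explicit loops.
brute_band_score <- function(gm_row, p, w) {
  m <- length(gm_row)
  if (p < 2 || p > m - 1) {
    return(NA_real_)
  }
  outer_idx <- (p + 1):min(m, p + w)
  inner_idx <- max(1, p - w):(p - 1)
  mean(gm_row[outer_idx]) - mean(gm_row[inner_idx])
}

brute_pos_to_offset <- function(p, L) if (p <= L) p - L - 1 else p - L

# Argmax with the package's tie rule, re-derived independently: best score,
# then smallest absolute offset, then the negative (inside) offset.
brute_argmax <- function(scores, L) {
  best <- -Inf
  best_p <- NA_integer_
  for (p in seq_along(scores)) {
    if (is.na(scores[p])) next
    o <- brute_pos_to_offset(p, L)
    if (scores[p] > best) {
      best <- scores[p]
      best_p <- p
    } else if (scores[p] == best) {
      ob <- brute_pos_to_offset(best_p, L)
      if (abs(o) < abs(ob) || (abs(o) == abs(ob) && o < ob)) best_p <- p
    }
  }
  best_p
}

# Per-profile operator by exhaustive enumeration.
brute_base_operator <- function(GM, L, w) {
  vapply(seq_len(nrow(GM)), function(k) {
    scores <- vapply(seq_len(ncol(GM)), function(p) {
      brute_band_score(GM[k, ], p, w)
    }, numeric(1))
    brute_pos_to_offset(brute_argmax(scores, L), L)
  }, numeric(1))
}

# Neighbour-pooled operator by exhaustive enumeration (cyclic profiles).
brute_nnvo <- function(GM, L, w, m_left, m_right) {
  n <- nrow(GM)
  vapply(seq_len(n), function(k) {
    scores <- vapply(seq_len(ncol(GM)), function(p) {
      total <- 0
      for (shift in (-m_left):m_right) {
        j <- ((k - 1 + shift) %% n) + 1
        total <- total + brute_band_score(GM[j, ], p, w)
      }
      total
    }, numeric(1))
    brute_pos_to_offset(brute_argmax(scores, L), L)
  }, numeric(1))
}

# A synthetic narrowband carrying an arbitrary gray matrix (geometry on a
# circle so normals and contour stay consistent).
synthetic_band <- function(GM, L) {
  n <- nrow(GM)
  ctr <- circle_contour(n, r = max(4 * L, 50), center = c(300, 300))
  nrm <- compute_normals(ctr)
  offs <- c(-L:-1, 1:L)
  im <- array(NA_real_, c(n, 2 * L, 2))
  for (j in seq_along(offs)) im[, j, ] <- unclass(ctr) + offs[j] * nrm
  bandseg:::new_narrowband(im, GM, nrm, offs, L, ctr, c(600L, 600L))
}
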