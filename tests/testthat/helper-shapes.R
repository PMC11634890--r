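# Geometric fixtures built in code.

circle_contour <- function(n = 60, r = 50, center = c(100, 100)) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  as_contour(cbind(center[1] + r * sin(phi), center[2] + r * cos(phi)))
}

ellipse_contour <- function(n = 60, a = 50, b = 30, center = c(100, 100)) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  as_contour(cbind(center[1] + b * sin(phi), center[2] + a * cos(phi)))
}

# counter-clockwise square (row, col), corners only
square_contour <- function(side = 4, corner = c(0.5, 0.5)) {
  r0 <- corner[1]
  c0 <- corner[2]
  as_contour(rbind(
    c(r0, c0), c(r0, c0 + side),
    c(r0 + side, c0 + side), c(r0 + side, c0)
  ), ensure_ccw = FALSE)
}

regular_ngon <- function(n, r = 10, center = c(0, 0)) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  as_contour(cbind(center[1] + r * sin(phi), center[2] + r * cos(phi)))
}

# similarity transform of a point matrix: rotate by `angle`, scale, shift
apply_similarity <- function(pts, angle = 0, scale = 1, shift = c(0, 0)) {
  rot <- matrix(
    c(cos(angle), -sin(angle), sin(angle), cos(angle)),
    2, 2,
    byrow = TRUE
  )
  sweep(scale * (unclass(pts) %*% t(rot)), 2, shift, `+`)
}

# star-convex random contour: positive radial function with a few harmonics
random_star_contour <- function(n = 80, r = 60, center = c(150, 150),
                                seed = 1) {
  set.seed(seed)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  rr <- r * (1 + 0.15 * cos(2 * phi + runif(1, 0, 2 * pi)) +
    0.08 * cos(3 * phi + runif(1, 0, 2 * pi)))
  as_contour(cbind(center[1] + rr * sin(phi), center[2] + rr * cos(phi)))
}
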